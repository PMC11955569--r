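// Low-level sequence primitives: 2-bit k-mer machinery, dynamic-programming
// alignment with substitution-class counting (transitions vs transversions),
// read simulation, k-mer read clustering, minimal-period detection and
// consensus pileup. All randomness flows through R's RNG so that a single
// set.seed() upstream makes every output reproducible.
#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int b2c(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

static inline char compl_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

static std::string rc_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = compl_base(c);
  return r;
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string seq) { return rc_str(seq); }

// Rolling 2-bit k-mer codes; positions are 0-based. Non-ACGT breaks the run.
static void kmer_codes(const std::string& s, int k,
                       std::vector<uint64_t>& codes, std::vector<int>& pos) {
  codes.clear(); pos.clear();
  int n = (int)s.size();
  if (n < k) return;
  uint64_t code = 0;
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < n; i++) {
    int c = b2c(s[i]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    run++;
    if (run >= k) { codes.push_back(code); pos.push_back(i - k + 1); }
  }
}

static inline uint64_t rc_code(uint64_t code, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; i++) { r = (r << 2) | (3ULL - (code & 3ULL)); code >>= 2; }
  return r;
}

static std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; i--) { s[i] = "ACGT"[code & 3ULL]; code >>= 2; }
  return s;
}

// ---------------------------------------------------------------------------
// Alignment. Scoring +1 match, -1 mismatch, -2 per gap column (linear).
// mode: "global" (Needleman-Wunsch, end gaps penalized), "local"
// (Smith-Waterman), "overlap" (free end gaps on both sequences).
// Counts are per alignment column: matches, transitions (A<->G, C<->T),
// transversions, pattern-insertions (gap in subject), deletions (gap in
// pattern). Indel columns are excluded from P/Q by construction.
// ---------------------------------------------------------------------------

struct AlnRes {
  int score = 0;
  int matches = 0, transitions = 0, transversions = 0, ins = 0, del = 0, cols = 0;
  int pstart = 0, pend = -1, sstart = 0, send = -1;  // 0-based inclusive
  bool found = false;
};

static AlnRes dp_align(const std::string& P, const std::string& S, int mode,
                       int match, int mismatch, int gap, bool traceback) {
  const int m = (int)P.size(), n = (int)S.size();
  const int NEG = -1000000000;
  AlnRes res;
  // two score rows + optional full traceback pointer matrix
  std::vector<int> prev(n + 1), cur(n + 1);
  std::vector<uint8_t> tb;  // 0 stop, 1 diag, 2 up (gap in subject), 3 left
  if (traceback) tb.assign((size_t)(m + 1) * (n + 1), 0);
  auto TB = [&](int i, int j) -> uint8_t& { return tb[(size_t)i * (n + 1) + j]; };

  // init row 0
  for (int j = 0; j <= n; j++) {
    if (mode == 1) {  // global
      prev[j] = gap * j;
      if (traceback && j > 0) TB(0, j) = 3;
    } else {
      prev[j] = 0;
    }
  }
  int best = NEG, bi = -1, bj = -1;
  if (mode == 2) best = 0;  // local: empty alignment floor
  for (int i = 1; i <= m; i++) {
    if (mode == 1) {
      cur[0] = gap * i;
      if (traceback) TB(i, 0) = 2;
    } else if (mode == 0) {
      cur[0] = 0;  // overlap: free pattern prefix
    } else {
      cur[0] = 0;
    }
    for (int j = 1; j <= n; j++) {
      int sub = prev[j - 1] + ((P[i - 1] == S[j - 1]) ? match : mismatch);
      int up = prev[j] + gap;
      int left = cur[j - 1] + gap;
      int sc = sub; uint8_t ptr = 1;
      if (up > sc) { sc = up; ptr = 2; }
      if (left > sc) { sc = left; ptr = 3; }
      if (mode == 2 && sc <= 0) { sc = 0; ptr = 0; }
      cur[j] = sc;
      if (traceback) TB(i, j) = ptr;
      if (mode == 2 && sc > best) { best = sc; bi = i; bj = j; }
      if (mode == 0 && (i == m || j == n) && sc > best) { best = sc; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  if (mode == 1) { best = prev[n]; bi = m; bj = n; }
  if (mode == 0 && best == NEG) { best = 0; bi = 0; bj = 0; }
  res.score = best;
  if (!traceback || bi < 0) { res.found = (mode != 2) || best > 0; return res; }

  // traceback
  int i = bi, j = bj;
  res.pend = i - 1; res.send = j - 1;
  while (i > 0 || j > 0) {
    uint8_t ptr = TB(i, j);
    if (mode == 2 && ptr == 0) break;
    if (mode == 0 && (i == 0 || j == 0)) break;  // free ends
    if (ptr == 0) break;
    if (ptr == 1) {
      char a = P[i - 1], b = S[j - 1];
      if (a == b) res.matches++;
      else {
        int ca = b2c(a), cb = b2c(b);
        if (ca >= 0 && cb >= 0 && ((ca ^ cb) == 2)) res.transitions++;
        else res.transversions++;
      }
      res.cols++; i--; j--;
    } else if (ptr == 2) { res.ins++; res.cols++; i--; }
    else { res.del++; res.cols++; j--; }
  }
  res.pstart = i; res.sstart = j;
  res.found = (mode != 2) || best > 0;
  if (mode == 2 && best == 0) { res.pend = -1; res.send = -1; }
  return res;
}

static List aln_to_list(const AlnRes& r) {
  return List::create(
      _["score"] = r.score, _["matches"] = r.matches,
      _["transitions"] = r.transitions, _["transversions"] = r.transversions,
      _["insertions"] = r.ins, _["deletions"] = r.del, _["columns"] = r.cols,
      _["pattern_start"] = r.pstart + 1, _["pattern_end"] = r.pend + 1,
      _["subject_start"] = r.sstart + 1, _["subject_end"] = r.send + 1,
      _["found"] = r.found);
}

// [[Rcpp::export]]
List dp_align_cpp(std::string pattern, std::string subject, std::string mode,
                  int match = 1, int mismatch = -1, int gap = -2) {
  int m = (mode == "global") ? 1 : (mode == "local" ? 2 : 0);
  AlnRes r = dp_align(pattern, subject, m, match, mismatch, gap, true);
  return aln_to_list(r);
}

// Score-only local alignments of `a` against many subjects (shuffle nulls).
// [[Rcpp::export]]
IntegerVector local_score_batch_cpp(std::string a, CharacterVector subjects,
                                    int match = 1, int mismatch = -1, int gap = -2) {
  int n = subjects.size();
  IntegerVector out(n);
  for (int i = 0; i < n; i++) {
    std::string s = as<std::string>(subjects[i]);
    AlnRes r = dp_align(a, s, 2, match, mismatch, gap, false);
    out[i] = r.score;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Masking: k-mer prescreen + anchored local alignment of each read against a
// (dimerized/extended) consensus. Returns one row per accepted hit.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame mask_chunk_cpp(CharacterVector reads, std::string cons,
                         int k_filter = 12, int min_hits = 2,
                         double min_identity = 0.70, int min_span = 30,
                         int pad = 25, int min_score = 25) {
  // consensus k-mer position index (forward strand of cons only)
  std::unordered_map<uint64_t, std::vector<int>> idx;
  {
    std::vector<uint64_t> codes; std::vector<int> pos;
    kmer_codes(cons, k_filter, codes, pos);
    for (size_t i = 0; i < codes.size(); i++) {
      auto& v = idx[codes[i]];
      if ((int)v.size() < 8) v.push_back(pos[i]);
    }
  }
  const int n = (int)cons.size();
  std::vector<int> out_read, out_strand, out_matches, out_ts, out_tv, out_ins,
      out_del, out_cols, out_span, out_rs, out_cs, out_ce, out_score;
  std::vector<double> out_ident;

  std::unordered_map<int, int> votes_f, votes_r;
  const int k = k_filter;
  const uint64_t kmask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const int shift = 2 * (k - 1);
  for (int r = 0; r < reads.size(); r++) {
    std::string fwd = as<std::string>(reads[r]);
    const int rl = (int)fwd.size();
    // single rolling pass computes forward and reverse-complement codes
    votes_f.clear(); votes_r.clear();
    int hits_f = 0, hits_r = 0;
    uint64_t code = 0, rcode = 0;
    int run = 0;
    for (int i = 0; i < rl; i++) {
      int c = b2c(fwd[i]);
      if (c < 0) { run = 0; code = 0; rcode = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & kmask;
      rcode = (rcode >> 2) | ((uint64_t)(3 - c) << shift);
      run++;
      if (run < k) continue;
      int p0 = i - k + 1;  // kmer start on forward read
      auto it = idx.find(code);
      if (it != idx.end()) {
        hits_f++;
        for (int p : it->second) votes_f[p - p0]++;
      }
      it = idx.find(rcode);
      if (it != idx.end()) {
        hits_r++;
        int p0r = rl - k - p0;  // kmer start on the rc read
        for (int p : it->second) votes_r[p - p0r]++;
      }
    }
    int best_strand = (hits_r > hits_f) ? -1 : 1;
    int best_hits = std::max(hits_f, hits_r);
    if (best_hits < min_hits) continue;
    int best_diag = 0, bv = -1;
    for (auto& kv : (best_strand == 1 ? votes_f : votes_r))
      if (kv.second > bv) { bv = kv.second; best_diag = kv.first; }
    std::string s = (best_strand == 1) ? fwd : rc_str(fwd);
    int ws = std::max(0, best_diag - pad);
    int we = std::min(n, best_diag + rl + pad);
    if (we <= ws) continue;
    AlnRes a = dp_align(s, cons.substr(ws, we - ws), 2, 1, -1, -2, true);
    if (!a.found || a.cols == 0) continue;
    double ident = (double)a.matches / (double)a.cols;
    int span = a.pend - a.pstart + 1;
    if (ident < min_identity || span < min_span || a.score < min_score) continue;
    out_read.push_back(r + 1);
    out_strand.push_back(best_strand);
    out_matches.push_back(a.matches);
    out_ts.push_back(a.transitions);
    out_tv.push_back(a.transversions);
    out_ins.push_back(a.ins);
    out_del.push_back(a.del);
    out_cols.push_back(a.cols);
    out_span.push_back(span);
    out_rs.push_back(a.pstart + 1);
    out_cs.push_back(ws + a.sstart + 1);
    out_ce.push_back(ws + a.send + 1);
    out_score.push_back(a.score);
    out_ident.push_back(ident);
  }
  return DataFrame::create(
      _["read"] = out_read, _["strand"] = out_strand, _["matches"] = out_matches,
      _["transitions"] = out_ts, _["transversions"] = out_tv,
      _["insertions"] = out_ins, _["deletions"] = out_del,
      _["columns"] = out_cols, _["read_span"] = out_span,
      _["read_start"] = out_rs,
      _["cons_start"] = out_cs, _["cons_end"] = out_ce,
      _["score"] = out_score, _["identity"] = out_ident);
}

// ---------------------------------------------------------------------------
// Simulation
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
std::string random_dna_cpp(int n, double at = 0.5) {
  std::string s(n, 'A');
  double pa = at / 2.0, pt = at, pc = at + (1.0 - at) / 2.0;
  for (int i = 0; i < n; i++) {
    double u = R::unif_rand();
    s[i] = (u < pa) ? 'A' : (u < pt) ? 'T' : (u < pc) ? 'C' : 'G';
  }
  return s;
}

// Uniform fragment sampling; mate 2 is the reverse complement of the fragment
// end; substitution errors only.
// [[Rcpp::export]]
List simulate_reads_cpp(std::string genome, int n_pairs, int read_len,
                        double insert_mu, double insert_sd, double err) {
  int glen = (int)genome.size();
  CharacterVector r1(n_pairs), r2(n_pairs);
  IntegerVector start(n_pairs), frag(n_pairs);
  for (int i = 0; i < n_pairs; i++) {
    int f = (int)std::lround(R::rnorm(insert_mu, insert_sd));
    if (f < read_len) f = read_len;
    if (f > glen) f = glen;
    int s0 = (int)std::floor(R::unif_rand() * (double)(glen - f + 1));
    if (s0 > glen - f) s0 = glen - f;
    std::string a = genome.substr(s0, read_len);
    std::string b = rc_str(genome.substr(s0 + f - read_len, read_len));
    if (err > 0) {
      for (std::string* rd : {&a, &b}) {
        int ne = (int)R::rbinom((double)read_len, err);
        for (int e = 0; e < ne; e++) {
          int p = (int)std::floor(R::unif_rand() * read_len);
          if (p >= read_len) p = read_len - 1;
          int c = b2c((*rd)[p]);
          if (c < 0) continue;
          int nc = (c + 1 + (int)std::floor(R::unif_rand() * 3.0)) & 3;
          (*rd)[p] = "ACGT"[nc];
        }
      }
    }
    r1[i] = a; r2[i] = b;
    start[i] = s0 + 1; frag[i] = f;
  }
  return List::create(_["r1"] = r1, _["r2"] = r2, _["start"] = start,
                      _["frag_len"] = frag);
}

// Mutate a sequence under a K2P substitution process: per-site Poisson(total)
// event count, each event a transition with odds kappa:1 against the two
// transversion targets jointly.
// [[Rcpp::export]]
std::string mutate_seq_cpp(std::string seq, double total_rate, double kappa) {
  int n = (int)seq.size();
  double p_ts = kappa / (kappa + 2.0);
  for (int i = 0; i < n; i++) {
    int k = (int)R::rpois(total_rate);
    if (k == 0) continue;
    int c = b2c(seq[i]);
    if (c < 0) stop("non-ACGT character in sequence");
    for (int e = 0; e < k; e++) {
      if (R::unif_rand() < p_ts) {
        c = c ^ 2;  // transition: A<->G, C<->T
      } else {
        // transversion: the two bases of the other purine/pyrimidine class
        int t1 = c ^ 1, t2 = c ^ 3;
        c = (R::unif_rand() < 0.5) ? t1 : t2;
      }
    }
    seq[i] = "ACGT"[c];
  }
  return seq;
}

// ---------------------------------------------------------------------------
// k-mer read clustering (connected components over shared canonical k-mers)
// ---------------------------------------------------------------------------

struct UF {
  std::vector<int> p;
  UF(int n) : p(n) { for (int i = 0; i < n; i++) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void join(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
};

// Returns 1-based cluster id per read (0 = unassigned), ids ordered by
// decreasing cluster size. Adjacent reads in each k-mer posting list are
// linked; posting lists longer than heavy_cap union directly (abundant
// satellite k-mers are unambiguous evidence of co-membership).
// [[Rcpp::export]]
IntegerVector cluster_reads_cpp(CharacterVector reads, int k = 21,
                                int min_shared = 1, int min_cluster = 25,
                                int heavy_cap = 100) {
  int nr = reads.size();
  std::unordered_map<uint64_t, std::vector<int>> post;
  std::vector<uint64_t> codes; std::vector<int> pos;
  for (int r = 0; r < nr; r++) {
    std::string s = as<std::string>(reads[r]);
    kmer_codes(s, k, codes, pos);
    for (uint64_t c : codes) {
      uint64_t rcd = rc_code(c, k);
      uint64_t canon = std::min(c, rcd);
      auto& v = post[canon];
      if (v.empty() || v.back() != r) v.push_back(r);
    }
  }
  UF uf(nr);
  std::unordered_map<uint64_t, int> edge_count;
  for (auto& kv : post) {
    auto& v = kv.second;
    if ((int)v.size() < 2) continue;
    if ((int)v.size() > heavy_cap || min_shared <= 1) {
      for (size_t i = 1; i < v.size(); i++) uf.join(v[i - 1], v[i]);
    } else {
      for (size_t i = 1; i < v.size(); i++) {
        uint64_t key = ((uint64_t)v[i - 1] << 32) | (uint64_t)v[i];
        int c = ++edge_count[key];
        if (c == min_shared) uf.join(v[i - 1], v[i]);
      }
    }
  }
  // component sizes
  std::unordered_map<int, int> size;
  for (int r = 0; r < nr; r++) size[uf.find(r)]++;
  std::vector<std::pair<int, int>> comps;  // (size, root)
  for (auto& kv : size)
    if (kv.second >= min_cluster) comps.push_back({kv.second, kv.first});
  std::sort(comps.begin(), comps.end(), [](const std::pair<int, int>& a,
                                           const std::pair<int, int>& b) {
    return a.first > b.first || (a.first == b.first && a.second < b.second);
  });
  std::unordered_map<int, int> cid;
  for (size_t i = 0; i < comps.size(); i++) cid[comps[i].second] = (int)i + 1;
  IntegerVector out(nr);
  for (int r = 0; r < nr; r++) {
    auto it = cid.find(uf.find(r));
    out[r] = (it == cid.end()) ? 0 : it->second;
  }
  return out;
}

// Stranded k-mer counts over reads (optionally adding reverse complements),
// as parallel kmer-string / count vectors for de Bruijn graph construction.
// [[Rcpp::export]]
List kmer_counts_cpp(CharacterVector reads, int k = 21, bool both_strands = true) {
  std::unordered_map<uint64_t, int> cnt;
  std::vector<uint64_t> codes; std::vector<int> pos;
  for (int r = 0; r < reads.size(); r++) {
    std::string s = as<std::string>(reads[r]);
    kmer_codes(s, k, codes, pos);
    for (uint64_t c : codes) {
      cnt[c]++;
      if (both_strands) cnt[rc_code(c, k)]++;
    }
  }
  int n = (int)cnt.size();
  CharacterVector kmers(n);
  IntegerVector counts(n);
  int i = 0;
  for (auto& kv : cnt) { kmers[i] = decode_kmer(kv.first, k); counts[i] = kv.second; i++; }
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// Minimal period of each read: smallest p <= max_period such that
// mismatch fraction between s and s shifted by p is <= max_mismatch_frac.
// 0 when no such period exists.
// [[Rcpp::export]]
IntegerVector min_period_cpp(CharacterVector reads, int max_period = 22,
                             double max_mismatch_frac = 0.1) {
  int nr = reads.size();
  IntegerVector out(nr);
  for (int r = 0; r < nr; r++) {
    std::string s = as<std::string>(reads[r]);
    int n = (int)s.size();
    int found = 0;
    for (int p = 1; p <= max_period && p * 2 <= n; p++) {
      int mism = 0, tot = n - p;
      int allowed = (int)std::floor(max_mismatch_frac * tot);
      for (int i = 0; i < tot; i++) {
        if (s[i] != s[i + p]) { mism++; if (mism > allowed) break; }
      }
      if (mism <= allowed) { found = p; break; }
    }
    out[r] = found;
  }
  return out;
}

// Gapless pileup vote: reads (already oriented via strand) are stacked on a
// circular consensus of length L at the given 0-based offsets.
// Rows: A, C, G, T.
// [[Rcpp::export]]
IntegerMatrix pileup_cpp(CharacterVector reads, IntegerVector strand,
                         IntegerVector offset0, int L) {
  IntegerMatrix m(4, L);
  for (int r = 0; r < reads.size(); r++) {
    std::string s = as<std::string>(reads[r]);
    if (strand[r] < 0) s = rc_str(s);
    int off = offset0[r];
    for (int i = 0; i < (int)s.size(); i++) {
      int c = b2c(s[i]);
      if (c < 0) continue;
      int p = (off + i) % L;
      if (p < 0) p += L;
      m(c, p)++;
    }
  }
  return m;
}
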