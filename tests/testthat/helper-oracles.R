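# Independent oracles and small fixture builders shared across test files.
# Oracles deliberately avoid the package's own code paths: brute-force
# enumeration, direct substitution counting, and Biostrings alignment.

BASES <- c("A", "C", "G", "T")

# brute-force canonical rotation: explicit loop over every rotation of the
# sequence and of its Biostrings reverse complement
brute_canonical <- function(seq) {
  n <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  cands <- character(0)
  for (s in c(seq, rc)) {
    for (r in 0:(n - 1)) {
      cands <- c(cands, paste0(substr(s, r + 1, n), substr(s, 1, r)))
    }
  }
  min(cands)
}

# direct transition/transversion counts between two equal-length strings
# (valid because the mutation process is substitution-only)
count_pq <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  stopifnot(length(x) == length(y))
  cx <- match(x, BASES) - 1L
  cy <- match(y, BASES) - 1L
  diff <- x != y
  ts <- sum(diff & bitwXor(cx, cy) == 2L)
  tv <- sum(diff) - ts
  list(P = ts / length(x), Q = tv / length(x), n = length(x))
}

# Biostrings local alignment score of a read against the dimerized monomer,
# both strands, same scoring as the package aligner (+1/-1, linear gap -2)
brute_mask_score <- function(read, monomer) {
  dim_cons <- paste(rep(monomer, max(2, ceiling((nchar(read) + nchar(monomer)) /
                                                  nchar(monomer)) + 1)),
                    collapse = "")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  best <- -Inf
  for (r in c(read, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(read))))) {
    a <- Biostrings::pairwiseAlignment(r, dim_cons, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
    best <- max(best, Biostrings::score(a))
  }
  best
}

# one-family planted world: monomer tandem array in a background genome
plant_world <- function(monomer, genome_size, target_bp, coverage,
                        time_mya = 0.5, seed = 1, err = 0.002,
                        sexes = "M", fm_ratio = 1) {
  spec <- monomer_spec("fam1", monomer)
  plan <- species_plan("Tst", sexes = sexes, genome_size = genome_size)
  ev <- amplification_event("fam1", "Tst", time_mya = time_mya,
                            target_bp = target_bp, fm_ratio = fm_ratio)
  gb <- build_species_genomes(list(spec), plan, list(ev),
                              seed = derive_seed(seed, "g"))
  libs <- lapply(setNames(sexes, sexes), function(sx)
    simulate_reads(gb$genomes[[sx]], coverage = coverage, err = err,
                   seed = derive_seed(seed, "r", sx)))
  list(gb = gb, libs = libs, truth = gb$truth)
}

# indices of reads whose source fragment overlaps any truth array
truth_read_flags <- function(lib, truth_rows) {
  coords <- do.call(rbind, strsplit(sub("^frag[0-9]+:", "", lib$names), "-"))
  fs <- as.integer(coords[, 1]); fe <- as.integer(coords[, 2])
  olap <- rep(FALSE, length(fs))
  for (i in seq_len(nrow(truth_rows)))
    olap <- olap | (fs <= truth_rows$end[i] & fe >= truth_rows$start[i])
  # reads come ordered c(r1, r2) of the same fragments
  rep(olap, 2)
}

# binomial standard error (in percent) of a planted proportion estimated from
# n independent sampling units. The unit is the read PAIR (fragment): the two
# mates of a fragment are not independent draws.
binom_se_pct <- function(prop_pct, n_pairs) {
  p <- prop_pct / 100
  100 * sqrt(p * (1 - p) / n_pairs)
}
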