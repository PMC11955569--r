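# Cross-species comparative satellitomics: homologous-family detection with a
# shuffle null, consensus K2P distances with species-pair codes, consensus
# turnover rates, paired t-tests of landscape profiles, and intra-catalog
# shared-segment detection.

catalog_prefix <- function(catalog) attr(catalog, "prefix")

kmer_set <- function(seq, k = 12) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  s <- substring(seq, 1:(n - k + 1), k:n)
  r <- substring(revcomp_cpp(seq), 1:(n - k + 1), k:n)
  unique(c(s, r))
}

best_local <- function(a, b, gap = -2) {
  best <- NULL
  for (strand in c(1L, -1L)) {
    bb <- if (strand == 1L) b else revcomp_cpp(b)
    aln <- dp_align_cpp(a, bb, "local", gap = gap)
    if (is.null(best) || aln$score > best$aln$score)
      best <- list(strand = strand, aln = aln)
  }
  best
}

null_max_score <- function(a, b, null_shuffles, seed, gap = -2) {
  # shuffle the shorter sequence (composition-preserving), score-only
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  shuffles <- with_seed(seed, vapply(seq_len(null_shuffles),
                                     function(i) shuffle_seq(a), character(1)))
  max(local_score_batch_cpp(b, shuffles, gap = gap))
}

#' Detect homologous satellite families across species catalogs
#'
#' For every cross-species consensus pair sharing at least one `k_prescreen`-mer
#' (either strand), the best rotation/strand-aware local alignment is computed;
#' a homology link is called when its score exceeds the maximum score against
#' `null_shuffles` composition-preserving shuffles of the shorter sequence AND
#' the alignment spans at least `min_span_frac` of the shorter monomer.
#' Homology groups are the connected components of the link graph.
#'
#' In addition to the fractional span rule an absolute evidence floor applies:
#' the alignment must span at least `min(min_span_bp, shorter monomer)` bp,
#' so a chance micro-alignment cannot link a tiny monomer to a large one,
#' while genuine short families (e.g. ~20 bp monomers) can still link over
#' their full length.
#'
#' @param catalogs list of >= 2 `sat_catalog` objects with distinct prefixes.
#' @param null_shuffles shuffles per tested pair.
#' @param min_span_frac minimum aligned fraction of the shorter monomer.
#' @param min_span_bp absolute minimum aligned span (capped at the shorter
#'   monomer length).
#' @param k_prescreen prescreen k-mer size (pairs sharing no such k-mer are
#'   not tested and cannot link). Pairs whose shorter monomer is below
#'   `4 * k_prescreen` bp bypass the prescreen: a couple of substitutions can
#'   erase every k-mer of a very short monomer, and aligning such pairs
#'   outright is cheap.
#' @param seed seed for the shuffle null.
#' @return list with `membership` (data.frame: family_id, species, group,
#'   species_specific), `links` (pairwise link table with identity % and
#'   aligned span) and `records` (one row per multi-species group, members
#'   comma-separated per species).
#' @export
find_homologs <- function(catalogs, null_shuffles = 100, min_span_frac = 0.30,
                          min_span_bp = 25, k_prescreen = 12, seed = 1) {
  if (length(catalogs) < 2) stop("need >= 2 catalogs")
  prefixes <- vapply(catalogs, catalog_prefix, character(1))
  if (anyDuplicated(prefixes)) stop("catalog prefixes must be distinct")
  fams <- do.call(rbind, lapply(seq_along(catalogs), function(i) {
    df <- as.data.frame(catalogs[[i]])
    data.frame(family_id = df$family_id, species = prefixes[i],
               consensus = df$consensus, rul = df$rul,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  n <- nrow(fams)
  ksets <- lapply(fams$consensus, kmer_set, k = k_prescreen)
  links <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (fams$species[i] == fams$species[j]) next
    prescreen <- min(fams$rul[i], fams$rul[j]) >= 4 * k_prescreen
    if (prescreen && !length(intersect(ksets[[i]], ksets[[j]]))) next
    bl <- best_local(fams$consensus[i], fams$consensus[j])
    aln <- bl$aln
    if (aln$columns == 0) next
    shorter <- min(fams$rul[i], fams$rul[j])
    span <- min(aln$pattern_end - aln$pattern_start + 1,
                aln$subject_end - aln$subject_start + 1)
    if (span < max(min_span_frac * shorter, min(min_span_bp, shorter))) next
    nmax <- null_max_score(fams$consensus[i], fams$consensus[j], null_shuffles,
                           derive_seed(seed, "null", fams$family_id[i],
                                       fams$family_id[j]))
    if (aln$score > nmax) {
      links[[length(links) + 1]] <- data.frame(
        family_a = fams$family_id[i], family_b = fams$family_id[j],
        species_a = fams$species[i], species_b = fams$species[j],
        identity_pct = 100 * aln$matches / aln$columns,
        span_bp = span, score = aln$score, null_max = nmax,
        stringsAsFactors = FALSE)
    }
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(family_a = character(0), family_b = character(0),
               species_a = character(0), species_b = character(0),
               identity_pct = numeric(0), span_bp = integer(0),
               score = integer(0), null_max = integer(0))
  g <- igraph::graph_from_data_frame(
    links[, c("family_a", "family_b")], directed = FALSE,
    vertices = data.frame(name = fams$family_id))
  memb <- igraph::components(g)$membership
  membership <- data.frame(family_id = fams$family_id, species = fams$species,
                           group = as.integer(memb[fams$family_id]),
                           stringsAsFactors = FALSE)
  nsp <- tapply(membership$species, membership$group,
                function(x) length(unique(x)))
  membership$species_specific <-
    nsp[as.character(membership$group)] < 2
  multi <- sort(unique(membership$group[!membership$species_specific]))
  records <- do.call(rbind, lapply(multi, function(grp) {
    sub <- membership[membership$group == grp, ]
    row <- data.frame(group = grp)
    for (p in prefixes)
      row[[p]] <- paste(sub$family_id[sub$species == p], collapse = ",")
    row
  }))
  list(membership = membership, links = links, records = records)
}

#' Species-pair codes
#'
#' In the canonical 4-species setting (prefixes Hvi, Hro, Hdu, Hpu) the codes
#' follow the conventional ordering 1 Hvi-Hro, 2 Hvi-Hdu, 3 Hvi-Hpu,
#' 4 Hro-Hdu, 5 Hdu-Hpu, 6 Hro-Hpu; any other species set is coded by
#' lexicographic pair order.
#'
#' @param species character vector of all species prefixes.
#' @return data.frame (code, species_a, species_b).
#' @export
pair_codes <- function(species) {
  canon <- c("Hvi", "Hro", "Hdu", "Hpu")
  if (setequal(species, canon)) {
    return(data.frame(code = 1:6,
                      species_a = c("Hvi", "Hvi", "Hvi", "Hro", "Hdu", "Hro"),
                      species_b = c("Hro", "Hdu", "Hpu", "Hdu", "Hpu", "Hpu"),
                      stringsAsFactors = FALSE))
  }
  sp <- sort(unique(species))
  cmb <- utils::combn(sp, 2)
  data.frame(code = seq_len(ncol(cmb)), species_a = cmb[1, ],
             species_b = cmb[2, ], stringsAsFactors = FALSE)
}

phase_orient <- function(a, b) {
  # rotate/strand b so that a global alignment against a is in phase
  bl <- best_local(a, dimerize(b))
  aln <- bl$aln
  bb <- if (bl$strand == 1L) b else revcomp_cpp(b)
  if (aln$columns == 0) return(bb)
  rot <- (aln$subject_start - aln$pattern_start) %% nchar(b)
  rotate_seq(bb, rot)
}

#' K2P distance between the homologs of two species in a group
#'
#' The two species' consensuses (most abundant member when a species
#' contributes several) are phase-oriented and globally aligned; transitions
#' and transversions over match/mismatch columns give the K2P distance.
#'
#' @param catalogs named-by-prefix list of `sat_catalog` objects.
#' @param homologs result of [find_homologs()].
#' @param group group id.
#' @param pair character(2) of species prefixes.
#' @return list (group, pair, pair_code, K, P, Q, saturated, members).
#' @export
homolog_distance <- function(catalogs, homologs, group, pair) {
  prefixes <- vapply(catalogs, catalog_prefix, character(1))
  memb <- homologs$membership
  members <- lapply(pair, function(sp) {
    ids <- memb$family_id[memb$group == group & memb$species == sp]
    if (!length(ids)) stop("group ", group, " has no member in species ", sp)
    df <- as.data.frame(catalogs[[match(sp, prefixes)]])
    df <- df[df$family_id %in% ids, ]
    df[which.min(df$rank), ]
  })
  a <- members[[1]]$consensus
  b <- phase_orient(a, members[[2]]$consensus)
  aln <- dp_align_cpp(a, b, "global")
  denom <- aln$matches + aln$transitions + aln$transversions
  P <- aln$transitions / denom
  Q <- aln$transversions / denom
  K <- kimura2p(P, Q)
  codes <- pair_codes(unique(memb$species))
  hit <- which((codes$species_a == pair[1] & codes$species_b == pair[2]) |
               (codes$species_a == pair[2] & codes$species_b == pair[1]))
  list(group = group, pair = pair,
       pair_code = if (length(hit)) codes$code[hit] else NA_integer_,
       K = K, P = P, Q = Q, saturated = is.na(K),
       members = c(members[[1]]$family_id, members[[2]]$family_id))
}

#' Consensus turnover rate
#'
#' `CTR = K / (2 T)` in substitutions per site per My, for two lineages that
#' split `T` My ago whose homologous consensuses are `K` apart.
#'
#' @param K K2P distance (>= 0).
#' @param T_my divergence time in My (> 0).
#' @param group,pair optional labels carried through.
#' @return list (group, pair, K, T_my, ctr).
#' @export
ctr <- function(K, T_my, group = NA, pair = NA) {
  if (any(T_my <= 0)) stop("T_my must be > 0")
  stopifnot(all(K >= 0, na.rm = TRUE))
  list(group = group, pair = pair, K = K, T_my = T_my, ctr = K / (2 * T_my))
}

#' Rough age of a landscape divergence peak
#'
#' Reports `age = divergence / ctr` (My) for a peak at the given divergence
#' fraction under a consensus turnover rate `ctr`. Note this simple reading
#' does not reproduce every published peak-dating claim; see the methods
#' vignette.
#'
#' @param divergence peak divergence as a fraction (e.g. 0.02 for a 2% bin).
#' @param ctr_rate consensus turnover rate per site per My.
#' @return age in My.
#' @export
peak_age <- function(divergence, ctr_rate) {
  stopifnot(all(ctr_rate > 0))
  divergence / ctr_rate
}

#' Paired t-test between two repeat landscape profiles
#'
#' Normalized per-bin fractions of the two landscapes are compared by a paired
#' t-test across the (default 41) bins; `df = bins - 1 = 40` under the default
#' domain. The t statistic is `mean(b - a)` over its standard error. Identical
#' profiles (zero variance of differences) yield the "degenerate" sentinel.
#'
#' @param landscape_a,landscape_b `sat_landscape` objects (or data.frames with
#'   a `normalized` column) on the same bin domain.
#' @return list (t, df, p, degenerate).
#' @export
compare_landscapes <- function(landscape_a, landscape_b) {
  a <- landscape_a$normalized
  b <- landscape_b$normalized
  if (length(a) != length(b))
    stop("landscapes must share the same bin domain")
  d <- b - a
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0)
    return(list(t = NA_real_, df = n - 1L, p = NA_real_, degenerate = TRUE))
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, df = n - 1L, p = 2 * pt(-abs(tstat), df = n - 1L),
       degenerate = FALSE)
}

#' Detect a partial shared segment between two monomers
#'
#' Best local alignment between the dimerized consensuses; reported when it
#' beats the shuffle null (as in [find_homologs()]) while covering less than
#' `max_cover` of the shorter monomer -- the signature of two families sharing
#' a small ancestral segment rather than being homologous over their length.
#'
#' Alignment uses a stiffer gap penalty (default -4) than read masking:
#' segment identity is a substitution-level statistic, and a permissive gap
#' cost lets a local alignment chain chance flank matches through indels,
#' diluting the reported identity of short segments.
#'
#' @param fam_a,fam_b consensus sequences.
#' @param null_shuffles shuffles for the null.
#' @param max_cover maximum aligned fraction of the shorter monomer for the
#'   hit to count as "shared segment" (larger overlaps are plain homology).
#' @param gap per-column gap penalty used for both the observed alignment and
#'   the null.
#' @param seed seed for the null.
#' @return list (overlap_fraction, identity_pct, span_bp, score) or `NULL`
#'   when nothing passes the null.
#' @export
shared_segment <- function(fam_a, fam_b, null_shuffles = 100, max_cover = 0.5,
                           gap = -4, seed = 1) {
  assert_dna(fam_a, "fam_a"); assert_dna(fam_b, "fam_b")
  la <- nchar(fam_a); lb <- nchar(fam_b)
  da <- paste0(fam_a, fam_a); db <- paste0(fam_b, fam_b)
  bl <- best_local(da, db, gap = gap)
  aln <- bl$aln
  if (aln$columns == 0) return(NULL)
  span <- min(aln$pattern_end - aln$pattern_start + 1,
              aln$subject_end - aln$subject_start + 1)
  span <- min(span, la, lb)
  nmax <- null_max_score(da, db, null_shuffles, derive_seed(seed, "shared"),
                         gap = gap)
  if (aln$score <= nmax) return(NULL)
  shorter <- min(la, lb)
  frac <- span / shorter
  list(overlap_fraction = frac,
       identity_pct = 100 * aln$matches / aln$columns,
       span_bp = span, score = aln$score,
       partial = frac < max_cover)
}
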