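# Masking-based abundance and divergence estimation against a satellite
# catalog, Kimura two-parameter divergences, repeat landscapes, sex-bias
# classification, sub-region quantification and catalog summary statistics.

#' Kimura two-parameter distance
#'
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` where `P` and `Q` are the
#' observed transition and transversion proportions over aligned
#' (non-indel) columns. Saturated inputs (`1 - 2P - Q <= 0` or
#' `1 - 2Q <= 0`) return `NA_real_`, the sentinel used throughout to exclude
#' a hit from landscapes.
#'
#' @param P transition proportion(s).
#' @param Q transversion proportion(s).
#' @return numeric vector of distances (substitutions per site), `NA` where
#'   saturated.
#' @export
kimura2p <- function(P, Q) {
  stopifnot(all(P >= 0, na.rm = TRUE), all(Q >= 0, na.rm = TRUE))
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  out <- rep(NA_real_, length(a))
  ok <- !is.na(a) & !is.na(b) & a > 0 & b > 0
  out[ok] <- -0.5 * log(a[ok] * sqrt(b[ok]))
  out
}

hit_divergence <- function(hits) {
  denom <- hits$matches + hits$transitions + hits$transversions
  P <- ifelse(denom > 0, hits$transitions / denom, 0)
  Q <- ifelse(denom > 0, hits$transversions / denom, 0)
  kimura2p(P, Q)
}

#' Align one read against a consensus monomer (exact path)
#'
#' Local alignment of the read (both strands) against the dimerized consensus,
#' so monomer-junction reads and any rotation of the consensus are handled.
#' Transition/transversion counts are taken over match/mismatch columns only;
#' indel columns count against identity but not against K2P.
#'
#' @param read read sequence (>= 30 bp).
#' @param consensus canonical consensus monomer.
#' @param min_identity minimum alignment identity to report a hit.
#' @param min_span minimum aligned read bp.
#' @param min_score minimum alignment score (+1/-1/-2 scoring); the floor
#'   that keeps chance micro-alignments out of the masked set.
#' @return a `mask_hit` list (fields: strand, matches, transitions,
#'   transversions, indels, aligned_len, read_span, identity, divergence,
#'   cons_start, cons_end, score) or `NULL` when there is no qualifying hit.
#' @export
mask_read <- function(read, consensus, min_identity = 0.70, min_span = 30,
                      min_score = 25) {
  assert_dna(read, "read")
  if (nchar(read) < 30) stop("read must be >= 30 bp")
  dim_cons <- dimerize(consensus, min_len = nchar(read) + nchar(consensus))
  best <- NULL
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) read else revcomp_cpp(read)
    a <- dp_align_cpp(s, dim_cons, "local")
    if (is.null(best) || a$score > best$aln$score)
      best <- list(strand = strand, aln = a)
  }
  a <- best$aln
  if (!isTRUE(a$found) || a$columns == 0) return(NULL)
  identity <- a$matches / a$columns
  span <- a$pattern_end - a$pattern_start + 1L
  if (identity < min_identity || span < min_span || a$score < min_score)
    return(NULL)
  P <- a$transitions / max(1L, a$matches + a$transitions + a$transversions)
  Q <- a$transversions / max(1L, a$matches + a$transitions + a$transversions)
  structure(list(strand = best$strand, matches = a$matches,
                 transitions = a$transitions, transversions = a$transversions,
                 indels = a$insertions + a$deletions,
                 aligned_len = a$columns, read_span = span,
                 identity = identity, divergence = kimura2p(P, Q),
                 cons_start = a$subject_start, cons_end = a$subject_end,
                 score = a$score),
            class = "mask_hit")
}

#' Mask a set of reads against one consensus (fast path)
#'
#' k-mer prescreen (shared `k_filter`-mers with the dimerized consensus,
#' best-diagonal anchoring) followed by windowed local alignment in C. The
#' prescreen bounds sensitivity: reads beyond roughly 30% divergence from the
#' consensus may be missed (see the methods vignette).
#'
#' @param reads character vector of reads, or a `read_library`.
#' @param consensus consensus monomer string.
#' @param min_identity minimum alignment identity.
#' @param k_filter prescreen k-mer size.
#' @param min_hits minimum shared k-mers to attempt alignment.
#' @param min_span minimum aligned read bp.
#' @param min_score minimum alignment score (chance-hit floor).
#' @param chunk reads are processed in chunks of this size.
#' @return data.frame of hits (one row per read with a qualifying alignment)
#'   with a `total_bp` attribute (total read bp screened).
#' @export
mask_reads <- function(reads, consensus, min_identity = 0.70, k_filter = 12,
                       min_hits = 2, min_span = 30, min_score = 25,
                       chunk = 200000L) {
  if (inherits(reads, "read_library")) reads <- library_reads(reads)
  assert_dna(consensus, "consensus")
  dim_cons <- dimerize(consensus,
                       min_len = max(nchar(reads[1]), 0) + nchar(consensus))
  n <- length(reads)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    h <- mask_chunk_cpp(reads[i:j], dim_cons, as.integer(k_filter),
                        as.integer(min_hits), min_identity,
                        as.integer(min_span), 25L, as.integer(min_score))
    if (nrow(h)) {
      h$read <- h$read + (i - 1L)
      out[[length(out) + 1]] <- h
    }
    i <- j + 1L
  }
  res <- if (length(out)) do.call(rbind, out) else
    mask_chunk_cpp(character(0), dim_cons, as.integer(k_filter),
                   as.integer(min_hits), min_identity, as.integer(min_span),
                   25L, as.integer(min_score))
  attr(res, "total_bp") <- sum(nchar(reads))
  res
}

mask_catalog <- function(reads, catalog, min_identity = 0.70, k_filter = 12,
                         min_hits = 2, min_span = 30) {
  if (inherits(reads, "read_library")) reads <- library_reads(reads)
  cat_df <- as.data.frame(catalog)
  cat_df <- cat_df[order(cat_df$rank), , drop = FALSE]
  hits <- list()
  total_bp <- sum(nchar(reads))
  for (i in seq_len(nrow(cat_df))) {
    h <- mask_reads(reads, cat_df$consensus[i], min_identity = min_identity,
                    k_filter = k_filter, min_hits = min_hits,
                    min_span = min_span)
    if (nrow(h)) {
      h$family_id <- cat_df$family_id[i]
      h$family_rank <- cat_df$rank[i]
      hits[[length(hits) + 1]] <- h
    }
  }
  if (!length(hits)) {
    res <- data.frame(read = integer(0), strand = integer(0),
                      matches = integer(0), transitions = integer(0),
                      transversions = integer(0), insertions = integer(0),
                      deletions = integer(0), columns = integer(0),
                      read_span = integer(0), cons_start = integer(0),
                      cons_end = integer(0), score = integer(0),
                      identity = numeric(0), family_id = character(0),
                      family_rank = integer(0))
    attr(res, "total_bp") <- total_bp
    return(res)
  }
  h <- do.call(rbind, hits)
  # winner-take-all read assignment: best score, ties by family rank
  h <- h[order(h$read, -h$score, h$family_rank), , drop = FALSE]
  h <- h[!duplicated(h$read), , drop = FALSE]
  h$divergence <- hit_divergence(h)
  attr(h, "total_bp") <- total_bp
  h
}

#' Masking-based abundance of each catalog family
#'
#' Abundance is `100 * masked bp assigned to the family / total sampled bp`;
#' each read is assigned to at most one family (best alignment score, ties
#' broken by family rank).
#'
#' @param lib a `read_library` or character vector of reads.
#' @param catalog a `sat_catalog` (or data.frame with `family_id`, `rank`,
#'   `consensus`).
#' @param n_pairs optional number of pairs to sample from `lib` first.
#' @param seed seed for the sampling step.
#' @param min_identity minimum masking identity.
#' @param ... passed to the masker.
#' @return data.frame (family_id, masked_bp, abundance_pct) with the
#'   winner-take-all hit table in attribute `hits` and `total_bp`.
#' @export
abundance <- function(lib, catalog, n_pairs = NULL, seed = 1,
                      min_identity = 0.70, ...) {
  if (!is.null(n_pairs) && inherits(lib, "read_library"))
    lib <- sample_read_pairs(lib, n_pairs, seed = seed)
  hits <- mask_catalog(lib, catalog, min_identity = min_identity, ...)
  total_bp <- attr(hits, "total_bp")
  cat_df <- as.data.frame(catalog)
  masked <- vapply(cat_df$family_id, function(f)
    sum(hits$read_span[hits$family_id == f]), numeric(1))
  out <- data.frame(family_id = cat_df$family_id, masked_bp = masked,
                    abundance_pct = 100 * masked / total_bp,
                    row.names = NULL)
  attr(out, "hits") <- hits
  attr(out, "total_bp") <- total_bp
  out
}

#' Streaming abundance over freshly simulated coverage
#'
#' Composes [simulate_reads()] and the masker in fixed-size chunks (seeds
#' derived per chunk from `seed`), so genome-scale quantification (e.g. 20 Mb
#' at 30x) runs in constant memory. With `exclusive = TRUE` reads are assigned
#' winner-take-all across the catalog (as in [abundance()]); with
#' `exclusive = FALSE` every family (or annotated sub-region sequence) is
#' masked independently, the convention for sub-region quantification.
#'
#' @param genome genome string.
#' @param catalog a `sat_catalog`/data.frame, or a named character vector of
#'   sequences to mask against (e.g. sub-region sequences).
#' @param coverage target depth.
#' @param read_len,insert_mu,insert_sd,err passed to [simulate_reads()].
#' @param chunk_pairs pairs simulated and masked per chunk.
#' @param seed root seed.
#' @param min_identity masking identity threshold.
#' @param exclusive winner-take-all assignment across families?
#' @return data.frame (family_id, masked_bp, abundance_pct) with attributes
#'   `total_bp`, `n_reads` and the accumulated `hits` table.
#' @export
abundance_by_coverage <- function(genome, catalog, coverage = 30,
                                  read_len = 150, insert_mu = 350,
                                  insert_sd = 35, err = 0.002,
                                  chunk_pairs = 250000L, seed = 1,
                                  min_identity = 0.70, exclusive = TRUE) {
  if (is.character(catalog) && is.null(dim(catalog))) {
    nm <- names(catalog) %||% sprintf("seq%02d", seq_along(catalog))
    catalog <- data.frame(family_id = nm, rank = seq_along(catalog),
                          consensus = unname(catalog),
                          stringsAsFactors = FALSE)
  }
  cat_df <- as.data.frame(catalog)
  glen <- nchar(genome)
  n_pairs <- max(1L, as.integer(round(glen * coverage / (2 * read_len))))
  done <- 0L
  chunk_i <- 0L
  masked <- setNames(numeric(nrow(cat_df)), cat_df$family_id)
  total_bp <- 0
  n_reads <- 0L
  all_hits <- list()
  while (done < n_pairs) {
    chunk_i <- chunk_i + 1L
    np <- min(chunk_pairs, n_pairs - done)
    lib <- simulate_reads(genome, read_len = read_len, insert_mu = insert_mu,
                          insert_sd = insert_sd, err = err, n_pairs = np,
                          seed = derive_seed(seed, "chunk", chunk_i))
    reads <- library_reads(lib)
    if (exclusive) {
      h <- mask_catalog(reads, cat_df, min_identity = min_identity)
    } else {
      hs <- list()
      for (i in seq_len(nrow(cat_df))) {
        hi <- mask_reads(reads, cat_df$consensus[i],
                         min_identity = min_identity)
        if (nrow(hi)) {
          hi$family_id <- cat_df$family_id[i]
          hi$family_rank <- i
          hs[[length(hs) + 1]] <- hi
        }
      }
      h <- if (length(hs)) do.call(rbind, hs) else NULL
      if (!is.null(h)) h$divergence <- hit_divergence(h)
    }
    if (!is.null(h) && nrow(h)) {
      agg <- tapply(h$read_span, h$family_id, sum)
      masked[names(agg)] <- masked[names(agg)] + agg
      h$read <- h$read + n_reads
      all_hits[[length(all_hits) + 1]] <- h
    }
    total_bp <- total_bp + sum(nchar(reads))
    n_reads <- n_reads + length(reads)
    done <- done + np
  }
  out <- data.frame(family_id = cat_df$family_id, masked_bp = unname(masked),
                    abundance_pct = 100 * unname(masked) / total_bp,
                    row.names = NULL)
  attr(out, "total_bp") <- total_bp
  attr(out, "n_reads") <- n_reads
  attr(out, "hits") <- if (length(all_hits)) do.call(rbind, all_hits) else NULL
  out
}

#' Female/male abundance ratio and sex-bias call
#'
#' A family is called sex-biased when the F/M abundance quotient is strictly
#' greater than `threshold` (default 1.2). `abund_m == 0` with `abund_f > 0`
#' yields the "female_specific" sentinel status; a missing female abundance
#' (`NA`) yields "skipped" (species without a female library).
#'
#' @param abund_f,abund_m female and male abundance (same units).
#' @param threshold decision boundary on the ratio (strict).
#' @return data.frame (ratio, sex_biased, status).
#' @export
fm_ratio <- function(abund_f, abund_m, threshold = 1.2) {
  n <- max(length(abund_f), length(abund_m))
  abund_f <- rep_len(abund_f, n); abund_m <- rep_len(abund_m, n)
  ratio <- rep(NA_real_, n)
  status <- rep("ok", n)
  biased <- rep(FALSE, n)
  skip <- is.na(abund_f)
  status[skip] <- "skipped"
  fs <- !skip & abund_m == 0 & abund_f > 0
  status[fs] <- "female_specific"
  ab <- !skip & abund_m == 0 & abund_f == 0
  status[ab] <- "absent"
  ok <- !skip & abund_m > 0
  ratio[ok] <- abund_f[ok] / abund_m[ok]
  biased[ok] <- ratio[ok] > threshold
  biased[fs] <- TRUE
  data.frame(ratio = ratio, sex_biased = biased, status = status)
}

#' Repeat landscape of one family
#'
#' Histogram of masked bp over 41 one-percent K2P divergence bins
#' `[i, i+1)` for `i = 0..40`. Hits with divergence >= 41% are discarded and
#' counted; saturated hits (K2P undefined) likewise.
#'
#' @param hits hit table (rows for this family; needs the count columns and
#'   `read_span`).
#' @param family_id family label.
#' @param total_bp total sampled bp (denominator of the abundance axis).
#' @param n_bins number of bins (fixed at 41 by default).
#' @return a `sat_landscape`: data.frame (bin_lo_pct, bin_hi_pct,
#'   abundance_pct, normalized) with attributes `family_id`, `n_discarded`,
#'   `n_saturated`.
#' @export
landscape <- function(hits, family_id, total_bp, n_bins = 41) {
  if (!is.null(hits$family_id)) hits <- hits[hits$family_id == family_id, ]
  div <- if (!is.null(hits$divergence)) hits$divergence else hit_divergence(hits)
  div_pct <- 100 * div
  saturated <- is.na(div_pct)
  over <- !saturated & div_pct >= n_bins
  keep <- !saturated & !over
  bins <- floor(div_pct[keep])
  vals <- numeric(n_bins)
  if (any(keep)) {
    agg <- tapply(hits$read_span[keep], bins, sum)
    vals[as.integer(names(agg)) + 1L] <- agg
  }
  abund <- 100 * vals / total_bp
  norm <- if (sum(vals) > 0) vals / sum(vals) else rep(0, n_bins)
  structure(data.frame(bin_lo_pct = 0:(n_bins - 1), bin_hi_pct = 1:n_bins,
                       abundance_pct = abund, normalized = norm),
            class = c("sat_landscape", "data.frame"),
            family_id = family_id, total_bp = total_bp,
            n_discarded = sum(over), n_saturated = sum(saturated))
}

#' Quantify the parts of a composite satellite independently
#'
#' Reads are masked against each annotated sub-region sequence on its own
#' (extended across the junction), giving per-part abundances and landscapes.
#'
#' @param lib reads (`read_library` or character vector).
#' @param family a `monomer_spec` with >= 2 subregions.
#' @param min_identity masking identity threshold.
#' @param ... passed to [mask_reads()].
#' @return named list per sub-region label: list(abundance_pct, masked_bp,
#'   landscape).
#' @export
quantify_subregions <- function(lib, family, min_identity = 0.70, ...) {
  stopifnot(inherits(family, "monomer_spec"))
  if (is.null(family$subregions) || nrow(family$subregions) < 2)
    stop("family must have >= 2 annotated subregions")
  if (inherits(lib, "read_library")) lib <- library_reads(lib)
  total_bp <- sum(nchar(lib))
  out <- list()
  for (i in seq_len(nrow(family$subregions))) {
    lab <- family$subregions$label[i]
    seq_i <- subregion_seq(family, lab)
    h <- mask_reads(lib, seq_i, min_identity = min_identity, ...)
    h$divergence <- hit_divergence(h)
    masked <- sum(h$read_span)
    out[[lab]] <- list(abundance_pct = 100 * masked / total_bp,
                       masked_bp = masked,
                       landscape = landscape(h, paste0(family$family_id, ":", lab),
                                             total_bp))
  }
  out
}

#' Catalog summary statistics
#'
#' Order statistics of repeat unit length and A+T content across families,
#' plus long-satellite counts under the two cutoffs in circulation
#' (> 100 bp and > 144 bp).
#'
#' @param catalog a `sat_catalog` or compatible data.frame.
#' @return list (n_families, rul_max, rul_min, rul_med, at_max, at_min,
#'   at_med, n_long_gt100, n_long_gt144).
#' @export
summarize_catalog <- function(catalog) {
  df <- as.data.frame(catalog)
  stopifnot(nrow(df) > 0)
  list(n_families = nrow(df),
       rul_max = max(df$rul), rul_min = min(df$rul), rul_med = median(df$rul),
       at_max = max(df$at_content), at_min = min(df$at_content),
       at_med = median(df$at_content),
       n_long_gt100 = sum(df$rul > 100), n_long_gt144 = sum(df$rul > 144))
}

#' Scan a monomer for open reading frames
#'
#' Six-frame scan on the dimerized consensus (so ORFs crossing the array
#' junction are found, once); an ORF is ATG..stop, length including the stop
#' codon, of at least `min_len` bp. Coordinates are reported on the monomer
#' (1-based start, modulo monomer length).
#'
#' @param consensus monomer string.
#' @param min_len minimum ORF length in bp.
#' @return data.frame (strand, frame, start, length_bp) -- zero rows if none.
#' @export
find_orfs <- function(consensus, min_len = 100) {
  assert_dna(consensus, "consensus")
  L <- nchar(consensus)
  dim_cons <- paste0(consensus, consensus)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dim_cons else revcomp_cpp(dim_cons)
    for (frame in 0:2) {
      n_cod <- (nchar(s) - frame) %/% 3
      if (n_cod < 2) next
      starts0 <- frame + 3 * (seq_len(n_cod) - 1)
      codons <- substring(s, starts0 + 1, starts0 + 3)
      open_at <- NA_integer_
      for (ci in seq_along(codons)) {
        if (is.na(open_at) && codons[ci] == "ATG") open_at <- ci
        if (!is.na(open_at) && codons[ci] %in% stops) {
          len <- 3 * (ci - open_at + 1)
          pos0 <- starts0[open_at]          # 0-based on dimer, this strand
          if (len >= min_len && pos0 < L) {
            g0 <- if (strand == "+") pos0 else nchar(s) - pos0 - len
            out[[length(out) + 1]] <- data.frame(
              strand = strand, frame = frame + 1L,
              start = (g0 %% L) + 1L, length_bp = len)
          }
          open_at <- NA_integer_
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), length_bp = integer(0)))
  res <- unique(do.call(rbind, out))
  res[order(res$start, res$strand), , drop = FALSE]
}
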