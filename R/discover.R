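# Iterative satellitome characterization from reads: sample -> cluster ->
# tandemness -> consensus -> mask -> repeat, then abundance-ranked naming and
# variant/family/superfamily grouping. The discovery stage is a deliberately
# simplified, fully offline re-implementation of the cluster-and-filter
# satellite-mining approach: k-mer connected components, heaviest de Bruijn
# cycle with a pileup polish, and a read-periodicity fallback for monomers
# too short for the k-mer graph.

#' Canonical rotation of a circular monomer
#'
#' The lexicographically smallest string among all rotations of `seq` and all
#' rotations of its reverse complement. Gives every family a unique, stable
#' representative regardless of the phase/strand in which it was assembled.
#'
#' @param seq ACGT string.
#' @return the canonical rotation.
#' @export
canonical_rotation <- function(seq) {
  assert_dna(seq)
  n <- nchar(seq)
  cands <- character(0)
  for (s in c(seq, revcomp_cpp(seq))) {
    d <- paste0(s, s)
    cands <- c(cands, substring(d, 1:n, n:(2 * n - 1)))
  }
  min(cands)
}

#' Sample read pairs without replacement
#'
#' @param lib a `read_library`.
#' @param n_pairs number of pairs to draw (uniform, without replacement).
#' @param seed integer seed.
#' @return a `read_library` of the sampled pairs.
#' @export
sample_read_pairs <- function(lib, n_pairs, seed = 1) {
  stopifnot(inherits(lib, "read_library"))
  if (n_pairs <= 0) stop("n_pairs must be > 0")
  if (n_pairs > lib$n_pairs)
    stop("n_pairs (", n_pairs, ") exceeds pairs available (", lib$n_pairs, ")")
  idx <- with_seed(seed, sort(sample.int(lib$n_pairs, n_pairs)))
  read_library(lib$r1[idx], lib$r2[idx], names = lib$names[idx],
               read_len = lib$read_len)
}

fold_read <- function(read, p) {
  n <- nchar(read)
  chars <- strsplit(read, "", fixed = TRUE)[[1]]
  pos <- (seq_len(n) - 1L) %% p
  vapply(0:(p - 1), function(i) {
    tb <- table(chars[pos == i])
    names(tb)[which.max(tb)]          # ties: alphabetical (table order)
  }, character(1)) |> paste(collapse = "")
}

#' Cluster reads by shared k-mers
#'
#' Reads with a detectable short internal period (monomer length below the
#' k-mer scale) are routed to a periodicity-based fallback; remaining reads
#' form a graph with edges between reads sharing at least `min_shared_kmers`
#' canonical k-mers, and clusters are connected components with at least
#' `min_cluster_reads` members. Reads in no qualifying component stay
#' unassigned.
#'
#' @param reads character vector of reads.
#' @param k k-mer size (odd, 11..31).
#' @param min_shared_kmers minimum shared k-mers for an edge.
#' @param min_cluster_reads minimum component size.
#' @param short_period_max periods up to this value route a read to the
#'   short-monomer fallback (default `k + 1`).
#' @param short_mismatch_frac mismatch tolerance of the periodicity test.
#' @return list of clusters, each a list with `ids` (read indices), `reads`,
#'   `type` ("kmer" or "short") and `period` (short clusters only), ordered by
#'   decreasing size.
#' @export
cluster_reads <- function(reads, k = 21, min_shared_kmers = 1,
                          min_cluster_reads = 25, short_period_max = k + 1,
                          short_mismatch_frac = 0.1) {
  if (!length(reads)) return(list())
  stopifnot(k %% 2 == 1, k >= 11, k <= 31)
  periods <- min_period_cpp(reads, as.integer(short_period_max),
                            short_mismatch_frac)
  short_idx <- which(periods > 0)
  long_idx <- which(periods == 0)
  clusters <- list()
  if (length(long_idx)) {
    asg <- cluster_reads_cpp(reads[long_idx], as.integer(k),
                             as.integer(min_shared_kmers),
                             as.integer(min_cluster_reads), 100L)
    for (cid in setdiff(sort(unique(asg)), 0L)) {
      ids <- long_idx[asg == cid]
      clusters[[length(clusters) + 1]] <-
        list(ids = ids, reads = reads[ids], type = "kmer", period = NA_integer_)
    }
  }
  if (length(short_idx)) {
    for (p in sort(unique(periods[short_idx]))) {
      ids_p <- short_idx[periods[short_idx] == p]
      if (length(ids_p) < min_cluster_reads) next
      monomers <- vapply(reads[ids_p], function(r)
        canonical_rotation(fold_read(r, p)), character(1), USE.NAMES = FALSE)
      # greedy grouping of folded monomers by Hamming similarity
      tab <- sort(table(monomers), decreasing = TRUE)
      centers <- character(0)
      assign_to <- integer(length(monomers))
      for (m in names(tab)) {
        hit <- 0L
        for (ci in seq_along(centers)) {
          d <- sum(strsplit(centers[ci], "")[[1]] != strsplit(m, "")[[1]]) / p
          if (d <= 0.3) { hit <- ci; break }
        }
        if (hit == 0L) { centers <- c(centers, m); hit <- length(centers) }
        assign_to[monomers == m] <- hit
      }
      for (ci in seq_along(centers)) {
        ids <- ids_p[assign_to == ci]
        if (length(ids) < min_cluster_reads) next
        clusters[[length(clusters) + 1]] <-
          list(ids = ids, reads = reads[ids], type = "short", period = p)
      }
    }
  }
  if (length(clusters) > 1) {
    sz <- vapply(clusters, function(cl) length(cl$ids), integer(1))
    clusters <- clusters[order(-sz)]
  }
  clusters
}

debruijn_cycle <- function(reads, k) {
  kc <- kmer_counts_cpp(reads, as.integer(k), TRUE)
  if (!length(kc$kmer)) return(NULL)
  counts <- new.env(parent = emptyenv(), size = length(kc$kmer))
  for (i in seq_along(kc$kmer)) assign(kc$kmer[i], kc$count[i], envir = counts)
  cnt <- function(km) {
    v <- get0(km, envir = counts, ifnotfound = 0L)
    v
  }
  total_mass <- sum(kc$count)
  start <- kc$kmer[order(-kc$count, kc$kmer)][1]
  visited <- new.env(parent = emptyenv())
  path <- character(0)
  cur <- start
  closed <- FALSE
  repeat {
    assign(cur, TRUE, envir = visited)
    path <- c(path, cur)
    succs <- paste0(substr(cur, 2, k), c("A", "C", "G", "T"))
    sc <- vapply(succs, cnt, integer(1))
    unvis <- vapply(succs, function(s)
      is.null(get0(s, envir = visited, ifnotfound = NULL)), logical(1))
    best_unvis <- if (any(unvis & sc > 0)) max(sc[unvis]) else 0L
    if (start %in% succs && cnt(start) >= best_unvis && cnt(start) > 0) {
      closed <- TRUE
      break
    }
    if (best_unvis == 0L) break
    # heaviest unvisited successor; ties by lexicographic k-mer order
    cand <- succs[unvis & sc == best_unvis]
    cur <- sort(cand)[1]
  }
  if (!closed) return(list(closed = FALSE, mass_fraction = 0, seq = NULL))
  cyc_mass <- sum(vapply(path, cnt, integer(1))) +
    sum(vapply(path, function(km) cnt(revcomp_cpp(km)), integer(1)))
  seq <- paste(substr(path, 1, 1), collapse = "")
  list(closed = TRUE, mass_fraction = min(1, cyc_mass / total_mass), seq = seq)
}

#' Tandemness of a read cluster
#'
#' A cluster is tandem-positive when the heaviest simple cycle of its de
#' Bruijn graph carries at least `cycle_mass_min` of the total k-mer
#' multiplicity (both strands considered jointly). Short-period clusters are
#' tandem by construction (the periodicity test is the cycle).
#'
#' @param cluster a cluster from [cluster_reads()].
#' @param k k-mer size.
#' @param cycle_mass_min minimum heaviest-cycle mass fraction.
#' @return list (is_tandem, cycle_mass_fraction, cycle_seq).
#' @export
tandemness <- function(cluster, k = 21, cycle_mass_min = 0.8) {
  stopifnot(length(cluster$reads) > 0)
  if (identical(cluster$type, "short")) {
    return(list(is_tandem = TRUE, cycle_mass_fraction = 1, cycle_seq = NULL))
  }
  dc <- debruijn_cycle(cluster$reads, k)
  if (is.null(dc) || !dc$closed)
    return(list(is_tandem = FALSE, cycle_mass_fraction = 0, cycle_seq = NULL))
  list(is_tandem = dc$mass_fraction >= cycle_mass_min,
       cycle_mass_fraction = dc$mass_fraction, cycle_seq = dc$seq)
}

polish_candidate <- function(reads, candidate, min_identity = 0.6) {
  L <- nchar(candidate)
  dim_cand <- dimerize(candidate, min_len = max(nchar(reads)) + L)
  h <- mask_reads(reads, candidate, min_identity = min_identity, min_hits = 1)
  if (!nrow(h)) return(candidate)
  # gapless offset of each read's first base on the extended candidate
  # (alignment clipping accounted for; indels are absent in the stated world)
  off <- h$cons_start - h$read_start
  pm <- pileup_cpp(reads[h$read], h$strand, as.integer(off %% L), as.integer(L))
  cons <- vapply(seq_len(L), function(j) {
    if (sum(pm[, j]) == 0) substr(candidate, j, j)
    else c("A", "C", "G", "T")[which.max(pm[, j])]
  }, character(1))
  paste(cons, collapse = "")
}

#' Reconstruct the consensus monomer of a tandem cluster
#'
#' For k-mer clusters: the sequence spelled by the heaviest de Bruijn cycle,
#' polished by a gapless majority-vote pileup of the cluster reads anchored on
#' the dimerized candidate, returned as the canonical rotation. For
#' short-period clusters: per-read period folding plus the same pileup polish.
#'
#' @param cluster a cluster from [cluster_reads()].
#' @param k k-mer size used for the graph.
#' @param cycle_mass_min minimum heaviest-cycle mass fraction.
#' @return the consensus monomer (canonical rotation/strand).
#' @export
consensus_monomer <- function(cluster, k = 21, cycle_mass_min = 0.8) {
  if (identical(cluster$type, "short")) {
    p <- cluster$period
    monomers <- vapply(cluster$reads, function(r)
      canonical_rotation(fold_read(r, p)), character(1), USE.NAMES = FALSE)
    tab <- sort(table(monomers), decreasing = TRUE)
    cand <- names(tab)[1]
    return(canonical_rotation(polish_candidate(cluster$reads, cand)))
  }
  td <- tandemness(cluster, k = k, cycle_mass_min = cycle_mass_min)
  if (is.null(td$cycle_seq) || !td$is_tandem)
    stop("ambiguous monomer: no de Bruijn cycle carrying >= ", cycle_mass_min,
         " of k-mer mass in cluster of ", length(cluster$reads), " reads")
  canonical_rotation(polish_candidate(cluster$reads, td$cycle_seq))
}

#' Discovery configuration
#'
#' Defaults follow the pipeline's documented operating point: k = 21 for
#' monomers above the k-mer scale, permissive 70% masking identity between
#' iterations (variants up to ~40% divergence are still caught by the final
#' quantification), heaviest-cycle mass >= 0.8, clusters of >= 25 reads.
#' `n_pairs` is the per-round read sample; the full-scale default in the
#' field is 5,000,000 pairs, the fixture default here is 200,000.
#'
#' @param prefix species prefix used in family names.
#' @param n_pairs pairs sampled per discovery round.
#' @param k,k_filter graph and prescreen k-mer sizes.
#' @param min_cluster_reads,min_shared_kmers clustering parameters.
#' @param cycle_mass_min tandemness threshold.
#' @param mask_identity inter-round masking identity.
#' @param max_rounds iteration cap.
#' @param seed root seed.
#' @return a config list.
#' @export
satminer_config <- function(prefix = "Xsp", n_pairs = 200000, k = 21,
                            k_filter = 12, min_cluster_reads = 25,
                            min_shared_kmers = 1, cycle_mass_min = 0.8,
                            mask_identity = 0.70, max_rounds = 8, seed = 1) {
  list(prefix = prefix, n_pairs = n_pairs, k = k, k_filter = k_filter,
       min_cluster_reads = min_cluster_reads,
       min_shared_kmers = min_shared_kmers, cycle_mass_min = cycle_mass_min,
       mask_identity = mask_identity, max_rounds = max_rounds, seed = seed)
}

consensus_matches <- function(a, b, min_identity = 0.95, min_cover = 0.5) {
  la <- nchar(a); lb <- nchar(b)
  shorter <- min(la, lb)
  best <- 0
  for (bb in c(b, revcomp_cpp(b))) {
    aln <- dp_align_cpp(dimerize(a), bb, "local")
    if (aln$columns > 0) {
      span <- aln$subject_end - aln$subject_start + 1
      if (span >= min_cover * shorter)
        best <- max(best, aln$matches / aln$columns)
    }
  }
  best >= min_identity
}

#' Iterative satellite mining
#'
#' Repeats sample -> cluster -> tandemness -> consensus; after each round the
#' sampled reads matching any discovered consensus (at the discovery masking
#' identity) are filtered out and the remainder re-clustered, until a round
#' yields no new tandem-positive family or `max_rounds` is reached. Families
#' are then quantified on the male library, ranked by descending male
#' abundance, named `<Prefix>Sat<NN>-<RUL>`, and grouped into
#' variants/families/superfamilies.
#'
#' @param lib_m male `read_library` (abundance ranking uses the male library).
#' @param config a [satminer_config()].
#' @param lib_f optional female `read_library` (adds `abundance_F`).
#' @return a `sat_catalog`.
#' @export
iterate_satminer <- function(lib_m, config = satminer_config(), lib_f = NULL) {
  stopifnot(inherits(lib_m, "read_library"))
  n_pairs <- min(config$n_pairs, lib_m$n_pairs)
  pool_lib <- sample_read_pairs(lib_m, n_pairs,
                                seed = derive_seed(config$seed, "sample"))
  pool <- library_reads(pool_lib)
  consensuses <- character(0)
  round <- 0L
  while (round < config$max_rounds) {
    round <- round + 1L
    if (!length(pool)) break
    clusters <- cluster_reads(pool, k = config$k,
                              min_shared_kmers = config$min_shared_kmers,
                              min_cluster_reads = config$min_cluster_reads)
    new_found <- 0L
    for (cl in clusters) {
      td <- tandemness(cl, k = config$k, cycle_mass_min = config$cycle_mass_min)
      if (!td$is_tandem) next
      cons <- tryCatch(
        consensus_monomer(cl, k = config$k,
                          cycle_mass_min = config$cycle_mass_min),
        error = function(e) NULL)
      if (is.null(cons)) next
      dup <- any(vapply(consensuses, function(x)
        consensus_matches(cons, x, min_identity = 0.95), logical(1)))
      if (!dup) {
        consensuses <- c(consensuses, cons)
        new_found <- new_found + 1L
      }
    }
    if (new_found == 0L) break
    # filter out reads matching anything discovered so far, then iterate
    hit_reads <- integer(0)
    for (cons in consensuses) {
      h <- mask_reads(pool, cons, min_identity = config$mask_identity,
                      k_filter = config$k_filter, min_hits = 2)
      hit_reads <- c(hit_reads, h$read)
    }
    pool <- pool[-unique(hit_reads)]
  }
  if (round == config$max_rounds)
    warning("max_rounds reached; catalog may be incomplete")
  if (!length(consensuses)) {
    return(sat_catalog(data.frame(family_id = character(0), rank = integer(0),
                                  rul = integer(0), consensus = character(0),
                                  at_content = numeric(0),
                                  abundance_M = numeric(0),
                                  abundance_F = numeric(0)),
                       prefix = config$prefix))
  }
  # abundance on the male (and optionally female) library, then rank + name
  proto <- data.frame(family_id = sprintf("c%03d", seq_along(consensuses)),
                      rank = seq_along(consensuses), consensus = consensuses,
                      stringsAsFactors = FALSE)
  ab_m <- abundance(pool_lib, proto, min_identity = config$mask_identity)
  ab_f <- if (!is.null(lib_f)) {
    f_lib <- sample_read_pairs(lib_f, min(config$n_pairs, lib_f$n_pairs),
                               seed = derive_seed(config$seed, "sampleF"))
    abundance(f_lib, proto, min_identity = config$mask_identity)
  } else NULL
  ord <- order(-ab_m$abundance_pct, nchar(consensuses))
  df <- data.frame(
    family_id = NA_character_, rank = seq_along(ord),
    rul = nchar(consensuses)[ord], consensus = consensuses[ord],
    at_content = vapply(consensuses[ord], at_content, numeric(1),
                        USE.NAMES = FALSE),
    abundance_M = ab_m$abundance_pct[ord],
    abundance_F = if (is.null(ab_f)) NA_real_ else ab_f$abundance_pct[ord],
    stringsAsFactors = FALSE)
  df$family_id <- sprintf("%sSat%02d-%d", config$prefix, df$rank, df$rul)
  group_catalog(sat_catalog(df, prefix = config$prefix))
}

#' Construct a satellite catalog
#'
#' @param df data.frame with columns family_id, rank, rul, consensus,
#'   at_content and optional abundances/groupings.
#' @param prefix species prefix.
#' @return a `sat_catalog` (data.frame subclass).
#' @export
sat_catalog <- function(df, prefix) {
  needed <- c("family_id", "rank", "consensus")
  stopifnot(all(needed %in% names(df)))
  if (is.null(df$rul)) df$rul <- nchar(df$consensus)
  if (is.null(df$at_content) && nrow(df))
    df$at_content <- vapply(df$consensus, at_content, numeric(1),
                            USE.NAMES = FALSE)
  structure(df, prefix = prefix, class = c("sat_catalog", "data.frame"))
}

#' Validate catalog naming invariants
#'
#' Ranks must be 1..N without gaps in descending male-abundance order and each
#' name's numeric suffix must equal the consensus length.
#'
#' @param catalog a `sat_catalog`.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_catalog <- function(catalog) {
  df <- as.data.frame(catalog)
  if (!nrow(df)) return(invisible(TRUE))
  stopifnot(identical(sort(df$rank), seq_len(nrow(df))))
  suffix <- as.integer(sub(".*-", "", df$family_id))
  stopifnot(identical(suffix, df$rul), identical(df$rul, nchar(df$consensus)))
  if (!is.null(df$abundance_M) && !anyNA(df$abundance_M)) {
    o <- order(df$rank)
    stopifnot(!is.unsorted(-df$abundance_M[o]))
  }
  invisible(TRUE)
}

#' @export
print.sat_catalog <- function(x, ...) {
  cat("sat_catalog '", attr(x, "prefix"), "': ", nrow(x), " families\n",
      sep = "")
  print.data.frame(head(as.data.frame(x)[, setdiff(names(x), "consensus")], 25))
  invisible(x)
}

#' Group catalog consensuses into variants, families and superfamilies
#'
#' Single-linkage grouping on pairwise rotation/strand-aware local-alignment
#' identity over at least half the shorter monomer; nested thresholds default
#' to 95% (variant), 80% (family) and 50% (superfamily).
#'
#' @param catalog a `sat_catalog`.
#' @param thresholds named numeric vector of identity thresholds.
#' @param min_cover minimum aligned fraction of the shorter monomer.
#' @return the catalog with `variant_group`, `family_group`,
#'   `superfamily_group` columns added.
#' @export
group_catalog <- function(catalog,
                          thresholds = c(variant = 0.95, family = 0.80,
                                         superfamily = 0.50),
                          min_cover = 0.5) {
  df <- as.data.frame(catalog)
  n <- nrow(df)
  if (n == 0) return(catalog)
  ident <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      shorter <- min(df$rul[i], df$rul[j])
      best <- 0
      for (b in c(df$consensus[j], revcomp_cpp(df$consensus[j]))) {
        a <- dp_align_cpp(dimerize(df$consensus[i]), b, "local")
        if (a$columns > 0) {
          span <- a$subject_end - a$subject_start + 1
          if (span >= min_cover * shorter)
            best <- max(best, a$matches / a$columns)
        }
      }
      ident[i, j] <- ident[j, i] <- best
    }
  }
  grp <- function(thr) {
    g <- igraph::graph_from_adjacency_matrix(ident >= thr, mode = "undirected",
                                             diag = FALSE)
    igraph::components(g)$membership
  }
  out <- df
  out$variant_group <- grp(thresholds[["variant"]])
  out$family_group <- grp(thresholds[["family"]])
  out$superfamily_group <- grp(thresholds[["superfamily"]])
  sat_catalog(out, prefix = attr(catalog, "prefix"))
}
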