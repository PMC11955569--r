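# Synthetic multi-species satellitome generator: a known "library" of
# satellite monomers, per-species amplification events, two-sex genomes with
# planted tandem arrays, and paired-end reads -- plus machine-readable truth
# used by recovery tests.

#' Define a satellite monomer
#'
#' @param family_id label for the family.
#' @param seq monomer sequence (ACGT). Lengths outside the 19-5000 bp range
#'   observed for real satellite repeat units are rejected.
#' @param subregions optional data.frame with columns `label`, `start`, `end`
#'   (0-based half-open intervals on the monomer) annotating the differentiated
#'   parts of a composite satellite.
#' @return an object of class `monomer_spec`.
#' @export
monomer_spec <- function(family_id, seq, subregions = NULL) {
  assert_dna(seq, "monomer seq")
  len <- nchar(seq)
  if (len < 19 || len > 5000)
    stop("monomer length must be in [19, 5000] bp, got ", len)
  if (!is.null(subregions)) {
    stopifnot(is.data.frame(subregions),
              all(c("label", "start", "end") %in% names(subregions)))
    subregions <- subregions[order(subregions$start), , drop = FALSE]
    if (any(subregions$start < 0) || any(subregions$end > len) ||
        any(subregions$end <= subregions$start))
      stop("subregions must be non-empty 0-based half-open intervals within [0, ",
           len, ")")
    if (nrow(subregions) > 1 &&
        any(subregions$start[-1] < subregions$end[-nrow(subregions)]))
      stop("subregions overlap")
  }
  structure(list(family_id = family_id, seq = seq, length = len,
                 at_content = at_content(seq), subregions = subregions),
            class = "monomer_spec")
}

#' Extract an annotated sub-region sequence from a monomer
#'
#' @param spec a `monomer_spec` with subregions.
#' @param label the sub-region label.
#' @return the sub-region sequence.
#' @export
subregion_seq <- function(spec, label) {
  stopifnot(inherits(spec, "monomer_spec"), !is.null(spec$subregions))
  i <- match(label, spec$subregions$label)
  if (is.na(i)) stop("no subregion labelled '", label, "'")
  substr(spec$seq, spec$subregions$start[i] + 1L, spec$subregions$end[i])
}

#' Mutate a sequence under the Kimura two-parameter process
#'
#' Each site receives a Poisson(`rate * t_my`) number of substitution events;
#' each event is a transition with odds `kappa`:1 against the two transversion
#' targets jointly. The expected K2P distance of the output to the input is
#' `rate * t_my` (multiple hits are corrected by the K2P estimator, not
#' avoided).
#'
#' @param seq ACGT string.
#' @param t_my elapsed time in My.
#' @param rate substitution rate per site per My.
#' @param kappa transition:transversion odds (> 0).
#' @param seed optional integer seed.
#' @return the mutated sequence (same length).
#' @export
mutate_monomer <- function(seq, t_my, rate, kappa = 2, seed = NULL) {
  assert_dna(seq)
  stopifnot(t_my >= 0, rate >= 0, kappa > 0)
  total <- rate * t_my
  if (total == 0) return(seq)
  if (is.null(seed)) mutate_seq_cpp(seq, total, kappa)
  else with_seed(seed, mutate_seq_cpp(seq, total, kappa))
}

#' Define a species simulation plan
#'
#' @param species species label (e.g. a 3-letter prefix such as "Hvi").
#' @param sexes subset of c("M", "F") to emit genomes for.
#' @param genome_size haploid genome size in bp. Real genome sizes for the
#'   study group are unknown; 20 Mb is a documented fixture default.
#' @param rate substitution rate per site per My used when ageing array copies.
#' @param kappa transition:transversion odds.
#' @param divergence_times optional named numeric vector of split times (My)
#'   to other species, names "<other species>".
#' @return an object of class `species_plan`.
#' @export
species_plan <- function(species, sexes = c("M", "F"), genome_size = 2e7,
                         rate = 0.005, kappa = 2, divergence_times = NULL) {
  stopifnot(all(sexes %in% c("M", "F")), genome_size > 0, rate >= 0, kappa > 0)
  structure(list(species = species, sexes = sexes,
                 genome_size = as.integer(genome_size), rate = rate,
                 kappa = kappa, divergence_times = divergence_times),
            class = "species_plan")
}

#' Define an amplification event
#'
#' An event plants one tandem array (head-to-tail copies of the monomer, each
#' copy independently aged by `time_mya` under the plan's K2P process). The
#' array size can be given either as whole `copies` or as `target_bp`
#' (full copies plus a trailing partial monomer, the way real arrays truncate),
#' which lets a planted family hit an exact genome proportion.
#'
#' @param family_id monomer family planted.
#' @param species species receiving the array.
#' @param time_mya age of the amplification in My (governs the divergence
#'   cloud of the copies and hence the expected landscape peak at
#'   `rate * time_mya`).
#' @param copies integer number of monomer copies (>= 1); ignored when
#'   `target_bp` is given.
#' @param target_bp exact array length in bp (optional).
#' @param fm_ratio female:male copy ratio; the female genome receives
#'   `round(target_bp * fm_ratio)` bp of this array.
#' @param subregion optional sub-region label: only that part of the monomer is
#'   tandemly amplified (composite-satellite scenario).
#' @return an object of class `amplification_event`.
#' @export
amplification_event <- function(family_id, species, time_mya, copies = NULL,
                                target_bp = NULL, fm_ratio = 1,
                                subregion = NULL) {
  stopifnot(time_mya >= 0, fm_ratio >= 0)
  if (is.null(copies) && is.null(target_bp))
    stop("give either copies or target_bp")
  if (!is.null(copies)) stopifnot(copies >= 1)
  structure(list(family_id = family_id, species = species,
                 time_mya = time_mya, copies = copies, target_bp = target_bp,
                 fm_ratio = fm_ratio, subregion = subregion),
            class = "amplification_event")
}

build_array <- function(unit, target_bp, time_mya, rate, kappa) {
  ulen <- nchar(unit)
  n_full <- target_bp %/% ulen
  tail_bp <- target_bp %% ulen
  copies <- character(0)
  if (n_full > 0)
    copies <- vapply(seq_len(n_full), function(i)
      mutate_seq_cpp(unit, rate * time_mya, kappa), character(1))
  if (tail_bp > 0)
    copies <- c(copies, substr(mutate_seq_cpp(unit, rate * time_mya, kappa),
                               1, tail_bp))
  paste(copies, collapse = "")
}

#' Build per-sex synthetic genomes with planted satellite arrays
#'
#' The genome is i.i.d. uniform ACGT background with tandem arrays inserted at
#' random positions; the female genome differs from the male only in the copy
#' number of arrays whose event has `fm_ratio != 1`. Truth proportions are
#' computed exactly from the emitted sequences.
#'
#' @param library list of [monomer_spec()] objects.
#' @param plan a [species_plan()].
#' @param events list of [amplification_event()] for this species.
#' @param seed integer seed; all randomness derives from it.
#' @return a list with `genomes` (named list, one string per sex), `truth`
#'   (data.frame: species, sex, family_id, subregion, bp, prop_pct,
#'   expected_peak_pct, start, end) and `genome_size` per sex.
#' @export
build_species_genomes <- function(library, plan, events, seed = 1) {
  stopifnot(inherits(plan, "species_plan"))
  fam_ids <- vapply(library, function(m) m$family_id, character(1))
  events <- Filter(function(e) identical(e$species, plan$species), events)
  for (e in events)
    if (!e$family_id %in% fam_ids)
      stop("event family '", e$family_id, "' not in monomer library")
  with_seed(seed, {
    genomes <- list()
    truth <- list()
    for (sex in plan$sexes) {
      units <- list()
      for (e in events) {
        m <- library[[match(e$family_id, fam_ids)]]
        unit <- if (is.null(e$subregion)) m$seq else subregion_seq(m, e$subregion)
        bp <- if (!is.null(e$target_bp)) e$target_bp else e$copies * nchar(unit)
        if (sex == "F") bp <- round(bp * e$fm_ratio)
        if (bp <= 0) next
        units[[length(units) + 1]] <- list(
          family_id = e$family_id, subregion = e$subregion %||% NA_character_,
          seq = build_array(unit, bp, e$time_mya, plan$rate, plan$kappa),
          peak = 100 * plan$rate * e$time_mya)
      }
      sat_bp <- sum(vapply(units, function(u) nchar(u$seq), numeric(1)))
      if (sat_bp >= 0.5 * plan$genome_size)
        stop("requested satellite proportions reach ", round(100 * sat_bp /
             plan$genome_size, 1), "% of a ", plan$genome_size,
             " bp genome; increase genome_size or lower the targets")
      bg_len <- plan$genome_size - sat_bp
      bg <- random_dna_cpp(bg_len, 0.5)
      # insertion points in the background, left to right
      cuts <- sort(sample.int(bg_len + 1L, length(units), replace = FALSE) - 1L)
      pieces <- character(0)
      prev <- 0L
      at <- 0L
      rows <- list()
      for (i in seq_along(units)) {
        pieces <- c(pieces, substr(bg, prev + 1L, cuts[i]))
        at <- at + (cuts[i] - prev)
        arr <- units[[i]]$seq
        pieces <- c(pieces, arr)
        rows[[length(rows) + 1]] <- data.frame(
          species = plan$species, sex = sex,
          family_id = units[[i]]$family_id, subregion = units[[i]]$subregion,
          bp = nchar(arr), expected_peak_pct = units[[i]]$peak,
          start = at + 1L, end = at + nchar(arr))
        at <- at + nchar(arr)
        prev <- cuts[i]
      }
      pieces <- c(pieces, substr(bg, prev + 1L, bg_len))
      genomes[[sex]] <- paste(pieces, collapse = "")
      stopifnot(nchar(genomes[[sex]]) == plan$genome_size)
      tr <- if (length(rows)) do.call(rbind, rows) else
        data.frame(species = character(0), sex = character(0),
                   family_id = character(0), subregion = character(0),
                   bp = integer(0), expected_peak_pct = numeric(0),
                   start = integer(0), end = integer(0))
      tr$prop_pct <- 100 * tr$bp / plan$genome_size
      truth[[sex]] <- tr
    }
    truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
    list(genomes = genomes, truth = truth, genome_size = plan$genome_size,
         species = plan$species)
  })
}

#' Simulate paired-end reads from a genome
#'
#' Uniform fragment sampling with Normal insert sizes; mate 2 is the reverse
#' complement of the fragment end; substitution-only sequencing error.
#'
#' @param genome genome string.
#' @param coverage target depth; `n_pairs` overrides it when given.
#' @param read_len read length in bp.
#' @param insert_mu,insert_sd insert (fragment) size distribution in bp.
#' @param err per-base substitution error rate, in [0, 0.05).
#' @param n_pairs explicit number of pairs (optional).
#' @param seed integer seed; identical inputs and seed give byte-identical
#'   output.
#' @return an object of class `read_library`: list with `r1`, `r2` (character
#'   vectors), `names` (fragment coordinates for debugging), `read_len`.
#' @export
simulate_reads <- function(genome, coverage = 30, read_len = 150,
                           insert_mu = 350, insert_sd = 35, err = 0.002,
                           n_pairs = NULL, seed = 1) {
  assert_dna(genome, "genome")
  stopifnot(err >= 0, err < 0.05, read_len <= insert_mu)
  glen <- nchar(genome)
  if (is.null(n_pairs)) {
    if (coverage <= 0) stop("coverage must be > 0")
    n_pairs <- max(1L, as.integer(round(glen * coverage / (2 * read_len))))
  }
  sim <- with_seed(seed, simulate_reads_cpp(genome, as.integer(n_pairs),
                                            as.integer(read_len), insert_mu,
                                            insert_sd, err))
  nm <- sprintf("frag%07d:%d-%d", seq_len(n_pairs), sim$start,
                sim$start + sim$frag_len - 1L)
  read_library(sim$r1, sim$r2, names = nm, read_len = read_len)
}

#' Construct a read library
#'
#' @param r1,r2 character vectors of mate sequences (equal length).
#' @param names optional read names.
#' @param read_len nominal read length.
#' @return an object of class `read_library`.
#' @export
read_library <- function(r1, r2, names = NULL, read_len = nchar(r1[1])) {
  stopifnot(length(r1) == length(r2))
  structure(list(r1 = r1, r2 = r2,
                 names = names %||% sprintf("read%07d", seq_along(r1)),
                 read_len = read_len, n_pairs = length(r1)),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat("read_library:", x$n_pairs, "pairs of", x$read_len, "bp\n")
  invisible(x)
}

#' All reads of a library as one character vector
#'
#' @param lib a `read_library`.
#' @return character vector `c(r1, r2)`.
#' @export
library_reads <- function(lib) {
  stopifnot(inherits(lib, "read_library"))
  c(lib$r1, lib$r2)
}
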