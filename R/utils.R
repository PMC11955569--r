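`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' @param seq character vector of ACGT strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(seq, revcomp_cpp, character(1), USE.NAMES = FALSE)
}

assert_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop(what, " must be a single non-empty string", call. = FALSE)
  if (grepl("[^ACGT]", seq))
    stop(what, " contains non-ACGT characters", call. = FALSE)
  invisible(seq)
}

#' A+T content of a sequence
#'
#' @param seq a single ACGT string.
#' @return fraction of A or T bases.
#' @export
at_content <- function(seq) {
  assert_dna(seq)
  n <- nchar(seq)
  (n - nchar(gsub("[AT]", "", seq))) / n
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG to `seed`, runs `code`, and restores the caller's RNG state,
#' so library code never perturbs user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Derive a stage seed from a root seed and labels
#'
#' Deterministic polynomial hash of the root seed plus any labels, mapped into
#' \code{[1, 2^31 - 2]}. Used so that each stage/species/sex receives an
#' independent but reproducible stream.
#'
#' @param seed root integer seed.
#' @param ... labels (stage, species, sex, chunk index, ...).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  lab <- paste(c(as.character(seed), vapply(list(...), as.character, character(1))),
               collapse = "/")
  h <- 7
  for (v in utf8ToInt(lab)) h <- (h * 131 + v) %% 2147483629
  as.integer(h %% 2147483645) + 1L
}

#' Concatenate a monomer with itself to cross the array junction
#'
#' Satellite monomers are circular objects; linear alignment against a
#' concatenation of the monomer handles reads that span the junction and any
#' rotation of the consensus. For monomers shorter than the read length the
#' monomer is tiled until the result is at least `min_len` long (and always at
#' least two copies).
#'
#' @param seq monomer string.
#' @param min_len minimum length of the result.
#' @return the extended (dimerized) string.
#' @export
dimerize <- function(seq, min_len = 0) {
  assert_dna(seq)
  n <- nchar(seq)
  reps <- max(2, ceiling(min_len / n) + 1)
  paste(rep(seq, reps), collapse = "")
}

rotate_seq <- function(seq, r) {
  n <- nchar(seq)
  r <- ((r %% n) + n) %% n
  if (r == 0) return(seq)
  paste0(substr(seq, r + 1, n), substr(seq, 1, r))
}

shuffle_seq <- function(seq) {
  paste(sample(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Random DNA sequence
#'
#' @param n length in bp.
#' @param at target A+T fraction (A and T equiprobable, likewise C/G).
#' @param seed optional integer seed; when given the caller's RNG state is
#'   untouched.
#' @return a single ACGT string.
#' @export
random_dna <- function(n, at = 0.5, seed = NULL) {
  stopifnot(n >= 1, at >= 0, at <= 1)
  if (is.null(seed)) random_dna_cpp(as.integer(n), at)
  else with_seed(seed, random_dna_cpp(as.integer(n), at))
}
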