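# Orchestration: JSON run configuration and the end-to-end
# simulate -> discover -> quantify -> compare -> report runner.

#' Read and validate a run configuration (JSON)
#'
#' The configuration is plain JSON key-value (see the package README for the
#' schema): a root `seed`, global mutation/sequencing parameters, a list of
#' shared `ancestors` (the ancestral satellite library), per-`species` blocks
#' (sexes, genome size, planted families referencing ancestors with a
#' per-species divergence and target genome proportion), and pairwise
#' `divergence_times` in My keyed "A|B".
#'
#' @param path JSON file path.
#' @return the validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("config: seed is required")
  if (is.null(cfg$species) || !length(cfg$species))
    stop("config: non-empty species list is required")
  cfg$rate_per_my <- cfg$rate_per_my %||% 0.005
  cfg$kappa <- cfg$kappa %||% 2
  cfg$read_len <- cfg$read_len %||% 150
  cfg$insert_mu <- cfg$insert_mu %||% 350
  cfg$insert_sd <- cfg$insert_sd %||% 35
  cfg$err <- cfg$err %||% 0.002
  cfg$coverage <- cfg$coverage %||% 10
  cfg$n_pairs_discovery <- cfg$n_pairs_discovery %||% 200000
  for (sp in cfg$species) {
    if (is.null(sp$name) || is.null(sp$genome_size))
      stop("config: every species needs name and genome_size")
  }
  cfg
}

build_ancestor_library <- function(cfg) {
  lib <- list()
  for (a in cfg$ancestors %||% list()) {
    lib[[a$id]] <- random_dna(a$length, at = a$at %||% 0.5,
                              seed = derive_seed(cfg$seed, "anc", a$id))
  }
  lib
}

simulate_stage <- function(cfg, anc) {
  out <- list()
  for (sp in cfg$species) {
    sexes <- unlist(sp$sexes %||% list("M"))
    plan <- species_plan(sp$name, sexes = sexes,
                         genome_size = sp$genome_size,
                         rate = cfg$rate_per_my, kappa = cfg$kappa)
    monomers <- list()
    events <- list()
    for (f in sp$families %||% list()) {
      seq0 <- anc[[f$ancestor]]
      if (is.null(seq0)) stop("unknown ancestor '", f$ancestor, "'")
      seq_sp <- mutate_monomer(seq0, t_my = 1, rate = f$divergence_k %||% 0,
                               kappa = cfg$kappa,
                               seed = derive_seed(cfg$seed, "mut", sp$name,
                                                  f$family_id))
      monomers[[length(monomers) + 1]] <- monomer_spec(f$family_id, seq_sp)
      events[[length(events) + 1]] <- amplification_event(
        f$family_id, sp$name, time_mya = f$age_my %||% 1,
        target_bp = round(sp$genome_size * (f$prop_pct %||% 0.5) / 100),
        fm_ratio = f$fm_ratio %||% 1)
    }
    gb <- build_species_genomes(monomers, plan, events,
                                seed = derive_seed(cfg$seed, "genome", sp$name))
    libs <- list()
    for (sex in sexes) {
      libs[[sex]] <- simulate_reads(
        gb$genomes[[sex]], coverage = cfg$coverage, read_len = cfg$read_len,
        insert_mu = cfg$insert_mu, insert_sd = cfg$insert_sd, err = cfg$err,
        seed = derive_seed(cfg$seed, "reads", sp$name, sex))
    }
    out[[sp$name]] <- list(plan = plan, truth = gb$truth, libs = libs)
  }
  out
}

#' Run the full pipeline on a configuration
#'
#' Executes simulate -> discover -> quantify -> compare on every configured
#' species/sex, writes the standard TSV/FASTA outputs under `outdir`, and
#' returns a run report. Deterministic under a fixed config seed: every stage
#' seed is derived from the root seed plus stage/species/sex labels.
#'
#' @param config config list (see [read_run_config()]) or a JSON path.
#' @param outdir output directory (created if needed).
#' @return a `run_report`: per-stage summaries, warnings, written files and
#'   their md5 hashes, and the config echo.
#' @export
run_all <- function(config, outdir = tempfile("satcomp_run")) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))

  anc <- build_ancestor_library(cfg)
  sims <- simulate_stage(cfg, anc)

  catalogs <- list()
  quant <- list()
  files <- character(0)
  emit <- function(df, name, comment = NULL) {
    p <- file.path(outdir, name)
    write_tsv(df, p, comment = comment)
    files <<- c(files, p)
    p
  }
  for (spn in names(sims)) {
    sim <- sims[[spn]]
    dcfg <- satminer_config(
      prefix = spn,
      n_pairs = min(cfg$n_pairs_discovery, sim$libs$M$n_pairs),
      seed = derive_seed(cfg$seed, "discover", spn))
    for (nm in intersect(names(cfg$discover %||% list()), names(dcfg)))
      dcfg[[nm]] <- cfg$discover[[nm]]
    cat_sp <- iterate_satminer(sim$libs$M, dcfg, lib_f = sim$libs$F)
    catalogs[[spn]] <- cat_sp
    df <- as.data.frame(cat_sp)
    if (nrow(df)) {
      fa <- file.path(outdir, paste0("catalog_", spn, ".fasta"))
      write_fasta(setNames(df$consensus, df$family_id), fa)
      files <- c(files, fa)
      fm <- fm_ratio(df$abundance_F, df$abundance_M)
      if (all(is.na(df$abundance_F)))
        note("F/M classification skipped for ", spn, ": no female library")
      tab <- cbind(df[, setdiff(names(df), "consensus")],
                   fm_ratio = fm$ratio, sex_biased = fm$sex_biased,
                   fm_status = fm$status)
      emit(tab, paste0("catalog_", spn, ".tsv"),
           comment = c("rul: bp; at_content: fraction; abundance: % of sampled bp",
                       "fm_ratio: abundance_F / abundance_M (biased if > 1.2)"))
      # landscapes from a fresh masking pass on the male library
      ab <- abundance(sim$libs$M, cat_sp, min_identity = dcfg$mask_identity)
      hits <- attr(ab, "hits")
      total_bp <- attr(ab, "total_bp")
      lss <- list()
      for (fid in df$family_id) {
        ls <- landscape(hits, fid, total_bp)
        if (attr(ls, "n_saturated") > 0)
          note(attr(ls, "n_saturated"), " saturated hit(s) excluded for ", fid)
        if (attr(ls, "n_discarded") > 0)
          note(attr(ls, "n_discarded"), " hit(s) beyond the 41% bin for ", fid)
        lss[[fid]] <- ls
        ldf <- cbind(family_id = fid, as.data.frame(ls))
        emit(ldf, paste0("landscape_", spn, "_", fid, ".tsv"),
             comment = "bins: K2P divergence %, abundance: % of sampled bp")
      }
      sumtab <- as.data.frame(summarize_catalog(cat_sp))
      emit(sumtab, paste0("summary_", spn, ".tsv"))
      quant[[spn]] <- list(abundance = ab, landscapes = lss,
                           total_bp = total_bp)
    } else {
      note("no satellite families discovered for ", spn)
    }
  }

  comp <- NULL
  nonempty <- names(catalogs)[vapply(catalogs, nrow, integer(1)) > 0]
  if (length(nonempty) >= 2) {
    hom <- find_homologs(catalogs[nonempty],
                         null_shuffles = cfg$null_shuffles %||% 100,
                         seed = derive_seed(cfg$seed, "homology"))
    if (!is.null(hom$records) && nrow(hom$records))
      emit(hom$records, "homology_groups.tsv")
    times <- cfg$divergence_times %||% list()
    getT <- function(a, b) times[[paste(a, b, sep = "|")]] %||%
      times[[paste(b, a, sep = "|")]]
    drows <- list()
    for (grp in unique(hom$membership$group[!hom$membership$species_specific])) {
      sps <- unique(hom$membership$species[hom$membership$group == grp])
      if (length(sps) < 2) next
      prs <- utils::combn(sps, 2)
      for (ci in seq_len(ncol(prs))) {
        pr <- prs[, ci]
        d <- homolog_distance(catalogs[nonempty], hom, grp, pr)
        Tmy <- getT(pr[1], pr[2])
        rate <- if (!is.null(Tmy) && !is.na(d$K)) ctr(d$K, Tmy)$ctr else NA_real_
        drows[[length(drows) + 1]] <- data.frame(
          group = grp, pair_code = d$pair_code,
          species_a = pr[1], species_b = pr[2],
          member_a = d$members[1], member_b = d$members[2],
          K = if (d$saturated) NA_real_ else d$K,
          saturated = d$saturated,
          T_my = Tmy %||% NA_real_, ctr = rate)
      }
    }
    if (length(drows)) {
      dtab <- do.call(rbind, drows)
      emit(dtab, "distances_ctr.tsv",
           comment = "K: K2P distance; ctr: K/(2*T_my) per site per My")
      comp <- list(homologs = hom, distances = dtab)
    } else comp <- list(homologs = hom, distances = NULL)
  }

  report <- structure(list(
    config = cfg, outdir = outdir,
    species = lapply(sims, function(s) list(truth = s$truth)),
    catalogs = catalogs, quantify = quant, compare = comp,
    warnings = warnings_log,
    files = basename(files),
    hashes = setNames(unname(tools::md5sum(sort(files))),
                      basename(sort(files)))),
    class = "run_report")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("satcomp run:", length(x$catalogs), "species;",
      sum(vapply(x$catalogs, nrow, integer(1))), "families;",
      length(x$files), "output files in", x$outdir, "\n")
  if (length(x$warnings)) cat("warnings:\n", paste(" -", x$warnings,
                                                   collapse = "\n"), "\n")
  invisible(x)
}
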