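# Built-in comparative fixture: a four-species satellite "library" with the
# sharing structure and consensus divergences reported for the Harttia
# armored-catfish satellitomes (four species, prefixes Hvi, Hro, Hdu, Hpu).
# Every consensus is synthetic -- random ancestors mutated to the recorded
# pairwise K2P distances -- but the presence/absence pattern, repeat-unit
# lengths, multi-member groups and lineage-specific families mirror the real
# catalogs, which makes the fixture a demanding end-to-end test bed for
# homology detection and distance estimation.

# one row per homology group: member name per species ("" = absent) and the
# K2P distance used to derive that species' member from the Hvi-side ancestor
fourspecies_table <- function() {
  tab <- read.delim(text = "hvi\thro\thdu\thpu\tk_hro\tk_hdu\tk_hpu
HviSat01-2531\tHroSat02-1662\tHduSat03-2143\tHpuSat12-1973\t0.081\t0.023\t0.189
HviSat02-2707\t\tHduSat01-2707\tHpuSat04-2707\tNA\t0.004\t0.025
HviSat03-997\t\t\tHpuSat05-1068\tNA\tNA\t0.296
HviSat04-2959\tHroSat09-2961\tHduSat08-1754\tHpuSat07-2750\t0.018\t0.390\t0.180
HviSat05-177\tHroSat16-177\tHduSat06-177\tHpuSat02-177\t0.006\t0.006\t0.163
HviSat06-200\t\tHduSat04-31\t\tNA\t0.067\tNA
HviSat07-93\tHroSat01-93\tHduSat05-93\tHpuSat06-105\t0.044\t0.116\t0.316
HviSat08-4011\tHroSat14-4165\t\t\t0.016\tNA\tNA
HviSat09-815\tHroSat19-815\tHduSat11-815\tHpuSat10-781\t0.030\t0.030\t0.271
HviSat10-1666\tHroSat06-1634\tHduSat12-1670\tHpuSat14-503\t0.016\t0.023\t0.498
HviSat11-1338\tHroSat13-1440\tHduSat10-1449\tHpuSat08-1546\t0.070\t0.065\t0.771
HviSat12-144\t\tHduSat13-144\tHpuSat03-144\tNA\t0.007\t0.007
HviSat13-730\tHroSat04-920\tHduSat09-771\t\t0.092\t0.109\tNA
HviSat14-347\tHroSat08-347\tHduSat02-347\t\t0.012\t0.032\tNA
HviSat15-32\t\tHduSat14-32\tHpuSat11-32\tNA\t0\t0
HviSat16-2480\tHroSat17-2481\t\t\t0.015\tNA\tNA
HviSat18-1068\tHroSat11-534\tHduSat15-534\t\t0.038\t0.067\tNA
HviSat19-589\tHroSat18-1194\t\t\t0.107\tNA\tNA
HviSat21-575\tHroSat23-576\t\t\t0.007\tNA\tNA
\tHroSat12-144\tHduSat16-144\t\t0.05\t0.05\tNA
\tHroSat10-21\tHduSat07-21\tHpuSat01-21\t0.05\t0.05\t0.05
\tHroSat20-45\tHduSat18-45\t\t0.05\t0.05\tNA",
                    stringsAsFactors = FALSE)
  tab
}

# lineage-specific families (no cross-species counterpart)
fourspecies_specifics <- function() {
  list(
    Hvi = c("HviSat17-49", "HviSat20-47"),
    Hro = c("HroSat03-372", "HroSat05-515",  # extra members of the Sat01 group
            "HroSat07-130", "HroSat15-150", "HroSat21-60", "HroSat22-88",
            "HroSat24-210", "HroSat25-45"),
    Hdu = c("HduSat17-150"),
    Hpu = c("HpuSat09-240", "HpuSat13-320", "HpuSat15-58", "HpuSat16-410"))
}

name_rul <- function(nm) as.integer(sub(".*-", "", nm))
name_rank <- function(nm) as.integer(sub(".*Sat([0-9]+)-.*", "\\1", nm))

# derive a homolog of target length from an ancestor, then mutate to K
derive_homolog <- function(anc, target_len, K, kappa, seed) {
  with_seed(seed, {
    L <- nchar(anc)
    s <- anc
    if (target_len < L) {
      off <- sample.int(L - target_len + 1L, 1L)
      s <- substr(anc, off, off + target_len - 1L)
    } else if (target_len > L) {
      # tandem-duplication-style extension
      s <- substr(strrep(anc, ceiling(target_len / L) + 1L), 1, target_len)
    }
    if (K > 0) s <- mutate_seq_cpp(s, K, kappa)
    s
  })
}

#' Four-species comparative satellitome fixture
#'
#' Builds four synthetic catalogs (prefixes Hvi, Hro, Hdu, Hpu) from a shared
#' ancestral satellite library under the library hypothesis: 21 Hvi families
#' of which 19 have at least one cross-species counterpart and 2 are
#' lineage-specific; homologs are derived from the Hvi-side ancestor at the
#' recorded per-pair K2P distances (including length changes such as
#' truncation and tandem-duplication extension); plus the groups private to
#' the other three species and each species' lineage-specific families. The
#' Hvi/Hro/Hdu clade diversified 5.5 My ago and split from the Hpu lineage
#' 17.5 My ago (`divergence_times`).
#'
#' One Hvi group (HviSat01-2531) receives several Hro members, exercising the
#' most-abundant-member rule of [homolog_distance()].
#'
#' @param seed integer seed.
#' @param kappa transition:transversion odds of the mutation process.
#' @return list with `catalogs` (named list of 4 `sat_catalog`), `truth`
#'   (the group table with planted K values), `specifics` (per-species
#'   lineage-specific family names) and `divergence_times`.
#' @export
fourspecies_catalogs <- function(seed = 1, kappa = 2) {
  tab <- fourspecies_table()
  specifics <- fourspecies_specifics()
  species <- c("Hvi", "Hro", "Hdu", "Hpu")
  fams <- setNames(lapply(species, function(s) list()), species)
  add <- function(sp, nm, seq) {
    fams[[sp]][[length(fams[[sp]]) + 1]] <<-
      data.frame(family_id = nm, rank = name_rank(nm), rul = name_rul(nm),
                 consensus = seq, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    anc_len <- if (nzchar(row$hvi)) name_rul(row$hvi) else
      name_rul(c(row$hro, row$hdu, row$hpu)[nzchar(c(row$hro, row$hdu,
                                                     row$hpu))][1])
    anc <- random_dna(anc_len, seed = derive_seed(seed, "anc", i))
    if (nzchar(row$hvi)) add("Hvi", row$hvi, anc)
    for (sp in c("hro", "hdu", "hpu")) {
      nm <- row[[sp]]
      if (!nzchar(nm)) next
      K <- row[[paste0("k_", sp)]]
      pref <- c(hro = "Hro", hdu = "Hdu", hpu = "Hpu")[[sp]]
      add(pref, nm, derive_homolog(anc, name_rul(nm), K, kappa,
                                   derive_seed(seed, "hom", i, nm)))
    }
    # extra Hro members of the first group (multi-member homology)
    if (identical(row$hvi, "HviSat01-2531")) {
      for (nm in c("HroSat03-372", "HroSat05-515"))
        add("Hro", nm, derive_homolog(anc, name_rul(nm), 0.12, kappa,
                                      derive_seed(seed, "hom", i, nm)))
    }
  }
  for (sp in species) {
    extra <- setdiff(specifics[[sp]], c("HroSat03-372", "HroSat05-515"))
    for (nm in extra)
      add(sp, nm, random_dna(name_rul(nm),
                             seed = derive_seed(seed, "spec", sp, nm)))
  }
  catalogs <- lapply(species, function(sp) {
    df <- do.call(rbind, fams[[sp]])
    df <- df[order(df$rank), , drop = FALSE]
    rownames(df) <- NULL
    sat_catalog(df, prefix = sp)
  })
  names(catalogs) <- species
  list(catalogs = catalogs, truth = tab, specifics = specifics,
       divergence_times = c("Hvi|Hro" = 5.5, "Hvi|Hdu" = 5.5, "Hro|Hdu" = 5.5,
                            "Hvi|Hpu" = 17.5, "Hro|Hpu" = 17.5,
                            "Hdu|Hpu" = 17.5))
}
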