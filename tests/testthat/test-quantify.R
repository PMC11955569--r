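test_that("kimura2p: closed form, saturation, and K >= p-distance", {
  expect_equal(kimura2p(0, 0), 0)
  # frozen from an independent high-precision evaluation of the closed form
  expect_equal(kimura2p(0.1, 0.05), 0.170181165140347, tolerance = 1e-12)
  expect_true(is.na(kimura2p(0.5, 0)))       # log of non-positive argument
  expect_true(is.na(kimura2p(0.3, 0.5)))
  expect_error(kimura2p(-0.1, 0))
  set.seed(61)
  for (i in 1:200) {
    P <- runif(1, 0, 0.3); Q <- runif(1, 0, 0.2)
    K <- kimura2p(P, Q)
    if (!is.na(K)) {
      expect_gte(K, P + Q - 1e-12)           # correction can only inflate
      if (P + Q > 0) expect_gt(K, P + Q - 1e-12)
    }
  }
})

test_that("mask_read: exact substring, junction read, background rejection", {
  mono <- random_dna(177, seed = 62)
  r <- substr(mono, 11, 140)
  h <- mask_read(r, mono)
  expect_equal(h$divergence, 0)
  expect_equal(h$read_span, 130)
  # read spanning the array junction aligns over its full length
  jr <- paste0(substr(mono, 120, 177), substr(mono, 1, 80))
  hj <- mask_read(jr, mono)
  expect_equal(hj$read_span, nchar(jr))
  expect_equal(hj$divergence, 0)
  # reverse-complement reads hit on the minus strand
  hr <- mask_read(revcomp(r), mono)
  expect_equal(hr$strand, -1L)
  expect_equal(hr$divergence, 0)
  expect_null(mask_read(random_dna(100, seed = 63), mono))
  expect_error(mask_read("ACGT", mono), ">= 30")
})

test_that("mask_read/mask_reads agree with a brute-force aligner on random pairs", {
  set.seed(64)
  n_agree_fast <- 0L
  for (i in 1:200) {
    mlen <- sample(60:100, 1)
    mono <- paste(sample(BASES, mlen, replace = TRUE), collapse = "")
    # mix of related (mutated substring, possibly rc) and unrelated reads
    read <- if (i %% 2 == 0) {
      r0 <- mutate_monomer(paste0(mono, substr(mono, 1, 20)), 1,
                           runif(1, 0, 0.25))
      r0 <- substr(r0, 1, sample(40:60, 1))
      if (runif(1) < 0.5) revcomp(r0) else r0
    } else paste(sample(BASES, 50, replace = TRUE), collapse = "")
    oracle_score <- brute_mask_score(read, mono)
    h <- mask_read(read, mono, min_identity = 0, min_span = 1,
                   min_score = -1e9)
    expect_equal(h$score, oracle_score,
                 info = sprintf("case %d read %s mono %s", i, read, mono))
  }
})

test_that("abundance: planted recovery, absent family, all-satellite conservation", {
  mono <- random_dna(200, seed = 65)
  w <- plant_world(mono, 400000, target_bp = 2000, coverage = 30, seed = 66)
  absent <- random_dna(300, seed = 67)
  cat_ <- sat_catalog(data.frame(family_id = c("TstSat01-200", "TstSat02-300"),
                                 rank = 1:2, consensus = c(mono, absent)),
                      prefix = "Tst")
  ab <- abundance(w$libs$M, cat_)
  truth <- w$truth$prop_pct[1]                       # 0.5%
  se <- binom_se_pct(truth, w$libs$M$n_pairs)
  expect_lt(abs(ab$abundance_pct[1] - truth), 3 * se)
  # absent family: essentially zero (a rare chance micro-hit is tolerated,
  # bounded by the ~0 convention used for unplanted sub-regions)
  expect_lt(ab$abundance_pct[2], 0.005)
  # all-satellite toy library: abundances sum to ~100%
  arr <- paste(rep(mono, 40), collapse = "")
  toy <- simulate_reads(arr, coverage = 10, err = 0, insert_mu = 300,
                        seed = 68)
  ab2 <- abundance(toy, cat_[1, ])
  expect_gt(ab2$abundance_pct[1], 97)
  expect_lte(ab2$abundance_pct[1], 100 + 1e-9)
})

test_that("abundance: subsampling consistency within 3 binomial SE", {
  mono <- random_dna(180, seed = 69)
  w <- plant_world(mono, 200000, target_bp = 4000, coverage = 30, seed = 70)
  cat_ <- sat_catalog(data.frame(family_id = "TstSat01-180", rank = 1L,
                                 consensus = mono), prefix = "Tst")
  a1 <- abundance(w$libs$M, cat_, n_pairs = 4000, seed = 1)
  a2 <- abundance(w$libs$M, cat_, n_pairs = 8000, seed = 2)
  se <- binom_se_pct(w$truth$prop_pct[1], 4000)   # SE at the smaller n
  expect_lt(abs(a1$abundance_pct - a2$abundance_pct), 3 * se)
})

test_that("fm_ratio: strict boundary at 1.2 and sentinel statuses", {
  expect_false(fm_ratio(0.06, 0.05)$sex_biased)      # ratio exactly 1.2
  expect_equal(fm_ratio(0.06, 0.05)$ratio, 1.2)
  expect_true(fm_ratio(0.065, 0.05)$sex_biased)      # 1.3
  expect_false(fm_ratio(0.05, 0.05)$sex_biased)      # 1.0
  r <- fm_ratio(c(0.02, NA, 0, 0.1), c(0, 0.05, 0, 0.05))
  expect_equal(r$status, c("female_specific", "skipped", "absent", "ok"))
  expect_true(r$sex_biased[1])
  expect_false(r$sex_biased[2])
  expect_true(r$sex_biased[4])
})

test_that("landscape: binning, conservation, and planted bimodality", {
  mono <- random_dna(300, seed = 71)
  # young wave at ~2% plus old wave at ~15% (rate 0.005/My)
  plan <- species_plan("Tst", "M", genome_size = 150000)
  evs <- list(amplification_event("f", "Tst", time_mya = 4, target_bp = 8000),
              amplification_event("f", "Tst", time_mya = 30, target_bp = 8000))
  gb <- build_species_genomes(list(monomer_spec("f", mono)), plan, evs,
                              seed = 72)
  lib <- simulate_reads(gb$genomes$M, coverage = 30, err = 0.001, seed = 73)
  cat_ <- sat_catalog(data.frame(family_id = "TstSat01-300", rank = 1L,
                                 consensus = mono), prefix = "Tst")
  ab <- abundance(lib, cat_)
  hits <- attr(ab, "hits")
  ls <- landscape(hits, "TstSat01-300", attr(ab, "total_bp"))
  expect_equal(nrow(ls), 41)
  expect_identical(ls$bin_lo_pct, 0:40)
  # conservation: bin sum equals abundance (no discarded/saturated hits here)
  expect_equal(sum(ls$abundance_pct) +
                 100 * sum(hits$read_span[is.na(hits$divergence) |
                                            100 * hits$divergence >= 41]) /
                 attr(ab, "total_bp"),
               ab$abundance_pct[1], tolerance = 1e-9)
  expect_equal(sum(ls$normalized), 1, tolerance = 1e-9)
  # bimodal: local maxima near bins 2 and 15 (+/- 1)
  young_peak <- which.max(ls$abundance_pct[1:9]) - 1
  old_peak <- which.max(ls$abundance_pct[10:30]) + 9 - 1
  expect_true(abs(young_peak - 2) <= 1)
  expect_true(abs(old_peak - 15) <= 2)
  # all hits at 0 divergence -> all mass in bin 0
  h0 <- hits[!is.na(hits$divergence) & hits$divergence == 0, ]
  ls0 <- landscape(h0, "TstSat01-300", attr(ab, "total_bp"))
  expect_true(all(ls0$abundance_pct[-1] == 0))
  # no hits -> all-zero landscape
  lse <- landscape(hits[0, ], "TstSat01-300", 1000)
  expect_true(all(lse$abundance_pct == 0))
})

test_that("quantify_subregions: part planted alone is seen, the other is ~0", {
  base <- random_dna(900, seed = 74)
  sub <- data.frame(label = c("A", "B"), start = c(0, 400), end = c(400, 900))
  spec <- monomer_spec("cmp", base, subregions = sub)
  plan <- species_plan("Tst", "M", genome_size = 150000)
  ev <- amplification_event("cmp", "Tst", 0.5, target_bp = 6000,
                            subregion = "A")
  gb <- build_species_genomes(list(spec), plan, list(ev), seed = 75)
  lib <- simulate_reads(gb$genomes$M, coverage = 30, seed = 76)
  q <- quantify_subregions(lib, spec)
  truth <- gb$truth$prop_pct[1]                      # 4%
  se <- binom_se_pct(truth, lib$n_pairs)
  expect_lt(abs(q$A$abundance_pct - truth), 3 * se)
  expect_lt(q$B$abundance_pct, 0.005)
  expect_error(quantify_subregions(lib, monomer_spec("x", base)), "subregions")
})

test_that("quantify_subregions: composite planting splits by part length", {
  base <- random_dna(600, seed = 77)
  sub <- data.frame(label = c("A", "B"), start = c(0, 200), end = c(200, 600))
  spec <- monomer_spec("cmp", base, subregions = sub)
  plan <- species_plan("Tst", "M", genome_size = 120000)
  ev <- amplification_event("cmp", "Tst", 0.5, target_bp = 9000)  # whole monomer
  gb <- build_species_genomes(list(spec), plan, list(ev), seed = 78)
  lib <- simulate_reads(gb$genomes$M, coverage = 30, seed = 79)
  q <- quantify_subregions(lib, spec)
  # parts planted at equal copy number: abundances proportional to lengths
  expect_equal(q$B$abundance_pct / q$A$abundance_pct, 400 / 200,
               tolerance = 0.25)
})

test_that("summarize_catalog: order statistics and long-satellite counts", {
  df <- data.frame(family_id = c("XSat01-372", "XSat02-4165", "XSat03-19"),
                   rank = 1:3,
                   consensus = c(random_dna(372, seed = 80),
                                 random_dna(4165, seed = 81),
                                 random_dna(19, seed = 82)))
  s <- summarize_catalog(sat_catalog(df, "X"))
  expect_equal(s$rul_min, 19)
  expect_equal(s$rul_max, 4165)
  expect_equal(s$rul_med, 372)
  expect_equal(s$n_long_gt100, 2)
  expect_true(s$at_min <= s$at_med && s$at_med <= s$at_max)
  one <- summarize_catalog(sat_catalog(df[1, ], "X"))
  expect_equal(one$rul_min, one$rul_med)
  expect_equal(one$rul_med, one$rul_max)
  expect_equal(at_content("ATAT"), 1)
})

test_that("find_orfs: planted ORF, all-stop consensus, junction dedup", {
  set.seed(83)
  orf <- paste0("ATG", paste(sample(setdiff(
    apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA")), 48, replace = TRUE), collapse = ""), "TAA")
  expect_equal(nchar(orf), 150)
  pad1 <- "CCTAACCTAACCTAACCTAACCTAA"      # stop-rich padding
  cons <- paste0(pad1, orf, pad1)
  found <- find_orfs(cons, min_len = 100)
  expect_true(any(found$length_bp == 150 & found$strand == "+"))
  # monomer of stop codons only
  expect_equal(nrow(find_orfs(strrep("TAA", 20), min_len = 10)), 0)
  # ORF spanning the junction: rotate so the ORF crosses the origin
  rot <- paste0(substr(cons, 101, nchar(cons)), substr(cons, 1, 100))
  fr <- find_orfs(rot, min_len = 100)
  expect_equal(sum(fr$length_bp == 150 & fr$strand == "+"), 1)
})

test_that("abundance_by_coverage matches the in-memory path and streams deterministically", {
  mono <- random_dna(250, seed = 84)
  w <- plant_world(mono, 200000, target_bp = 3000, coverage = 1, seed = 85)
  cat_ <- sat_catalog(data.frame(family_id = "TstSat01-250", rank = 1L,
                                 consensus = mono), prefix = "Tst")
  a1 <- abundance_by_coverage(w$gb$genomes$M, cat_, coverage = 20,
                              chunk_pairs = 3000L, seed = 9)
  a2 <- abundance_by_coverage(w$gb$genomes$M, cat_, coverage = 20,
                              chunk_pairs = 3000L, seed = 9)
  expect_identical(a1, a2)
  truth <- w$truth$prop_pct[1]
  se <- binom_se_pct(truth, attr(a1, "n_reads") / 2)
  expect_lt(abs(a1$abundance_pct - truth), 3 * se)
})
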