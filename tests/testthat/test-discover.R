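test_that("canonical_rotation: examples and brute-force equivalence", {
  expect_identical(canonical_rotation("GCA"), "AGC")
  expect_identical(canonical_rotation("AAA"), "AAA")
  set.seed(31)
  for (i in 1:200) {
    n <- sample(2:64, 1)
    s <- paste(sample(BASES, n, replace = TRUE), collapse = "")
    expect_identical(canonical_rotation(s), brute_canonical(s))
  }
})

test_that("canonical_rotation: invariant under rotation and reverse complement", {
  set.seed(32)
  for (i in 1:50) {
    s <- paste(sample(BASES, sample(10:80, 1), replace = TRUE), collapse = "")
    r <- sample(nchar(s), 1)
    rot <- paste0(substr(s, r, nchar(s)), substr(s, 1, r - 1))
    expect_identical(canonical_rotation(rot), canonical_rotation(s))
    expect_identical(canonical_rotation(revcomp(rot)), canonical_rotation(s))
  }
  expect_error(canonical_rotation("ACGTN"), "non-ACGT")
})

test_that("sample_read_pairs: whole library, determinism, validation", {
  lib <- read_library(rep(strrep("ACGT", 20), 50), rep(strrep("TTCA", 20), 50))
  all_ <- sample_read_pairs(lib, 50, seed = 1)
  expect_identical(all_$r1, lib$r1)
  s1 <- sample_read_pairs(lib, 10, seed = 7)
  s2 <- sample_read_pairs(lib, 10, seed = 7)
  expect_identical(s1$r1, s2$r1)
  expect_error(sample_read_pairs(lib, 0), "n_pairs")
  expect_error(sample_read_pairs(lib, 51), "exceeds")
})

test_that("cluster_reads: one planted tandem array forms one cluster holding >=95% of satellite reads", {
  mono <- random_dna(177, seed = 11)
  w <- plant_world(mono, 150000, target_bp = 15000, coverage = 30, seed = 13)
  samp <- sample_read_pairs(w$libs$M, 500, seed = 14)   # ~1x genomic
  reads <- library_reads(samp)
  is_sat <- truth_read_flags(samp, w$truth)
  cls <- cluster_reads(reads)
  expect_gte(length(cls), 1)
  # fully-satellite reads (not boundary stragglers) must concentrate in cluster 1
  in_c1 <- seq_along(reads) %in% cls[[1]]$ids
  expect_gt(sum(in_c1 & is_sat) / sum(is_sat), 0.95)
  # purity is looser than recall: mates of boundary fragments can bridge a
  # small adjacent background pileup into the component
  expect_gt(sum(is_sat[cls[[1]]$ids]) / length(cls[[1]]$ids), 0.85)
})

test_that("cluster_reads: pure background at ~1x gives zero clusters", {
  g <- random_dna(120000, seed = 15)
  lib <- simulate_reads(g, coverage = 30, seed = 16)
  samp <- sample_read_pairs(lib, 400, seed = 17)
  expect_length(cluster_reads(library_reads(samp)), 0)
  expect_length(cluster_reads(character(0)), 0)
})

test_that("cluster_reads: two unrelated families give two clusters, no merging", {
  monoA <- random_dna(220, seed = 18)
  monoB <- random_dna(350, seed = 19)
  plan <- species_plan("Tst", "M", genome_size = 150000)
  evs <- list(amplification_event("fa", "Tst", 0.5, target_bp = 12000),
              amplification_event("fb", "Tst", 0.5, target_bp = 12000))
  gb <- build_species_genomes(list(monomer_spec("fa", monoA),
                                   monomer_spec("fb", monoB)), plan, evs,
                              seed = 20)
  lib <- simulate_reads(gb$genomes$M, coverage = 30, seed = 21)
  samp <- sample_read_pairs(lib, 600, seed = 22)
  cls <- cluster_reads(library_reads(samp))
  expect_gte(length(cls), 2)
  consA <- consensus_monomer(cls[[1]])
  consB <- consensus_monomer(cls[[2]])
  expect_setequal(c(nchar(consA), nchar(consB)), c(220, 350))
})

test_that("tandemness: tandem cluster closes a heavy cycle; dispersed decoy does not", {
  mono <- random_dna(200, seed = 23)
  w <- plant_world(mono, 100000, target_bp = 10000, coverage = 30, seed = 24)
  samp <- sample_read_pairs(w$libs$M, 400, seed = 25)
  cls <- cluster_reads(library_reads(samp))
  td <- tandemness(cls[[1]])
  expect_true(td$is_tandem)
  expect_gt(td$cycle_mass_fraction, 0.8)
  # reads tiling a single-copy gene fragment: a path, not a cycle
  frag <- random_dna(2000, seed = 26)
  dlib <- simulate_reads(frag, coverage = 20, insert_mu = 300, seed = 27)
  decoy <- list(ids = seq_len(2 * dlib$n_pairs), reads = library_reads(dlib),
                type = "kmer", period = NA_integer_)
  tdd <- tandemness(decoy)
  expect_false(tdd$is_tandem)
})

test_that("consensus_monomer: recovers the planted monomer exactly (canonical form)", {
  mono <- random_dna(177, seed = 11)
  w <- plant_world(mono, 150000, target_bp = 15000, coverage = 30, seed = 13)
  samp <- sample_read_pairs(w$libs$M, 500, seed = 14)
  cls <- cluster_reads(library_reads(samp))
  cons <- consensus_monomer(cls[[1]])
  expect_identical(cons, canonical_rotation(mono))
  # ambiguous-monomer error on a non-tandem cluster
  frag <- random_dna(1500, seed = 28)
  dlib <- simulate_reads(frag, coverage = 20, insert_mu = 300, seed = 29)
  decoy <- list(ids = seq_len(2 * dlib$n_pairs), reads = library_reads(dlib),
                type = "kmer", period = NA_integer_)
  expect_error(consensus_monomer(decoy), "ambiguous monomer")
})

test_that("short-period fallback: 19 bp monomer recovered via read periodicity", {
  mono19 <- random_dna(19, seed = 21)
  w <- plant_world(mono19, 100000, target_bp = 8000, coverage = 40, seed = 30)
  samp <- sample_read_pairs(w$libs$M, 400, seed = 31)
  cls <- cluster_reads(library_reads(samp))
  shorts <- Filter(function(cl) cl$type == "short", cls)
  expect_gte(length(shorts), 1)
  expect_equal(shorts[[1]]$period, 19)
  cons <- consensus_monomer(shorts[[1]])
  expect_identical(cons, canonical_rotation(mono19))
})

test_that("consensus of a 4-periodic repeat is the canonical 4-mer", {
  reads <- rep(substr(strrep("ACGT", 50), 1, 120), 30)
  cl <- list(ids = seq_along(reads), reads = reads, type = "short",
             period = 4L)
  expect_identical(consensus_monomer(cl), "ACGT")
})

test_that("phase/strand invariance: rotated or reverse-complemented monomer plants the same canonical consensus", {
  mono <- random_dna(160, seed = 33)
  variants <- c(mono,
                paste0(substr(mono, 61, 160), substr(mono, 1, 60)),
                revcomp(mono))
  cons <- vapply(variants, function(m) {
    w <- plant_world(m, 80000, target_bp = 8000, coverage = 30, seed = 34,
                     err = 0)
    samp <- sample_read_pairs(w$libs$M, 300, seed = 35)
    cls <- cluster_reads(library_reads(samp))
    consensus_monomer(cls[[1]])
  }, character(1), USE.NAMES = FALSE)
  expect_identical(cons[1], cons[2])
  expect_identical(cons[1], cons[3])
  expect_identical(cons[1], canonical_rotation(mono))
})

test_that("iterate_satminer: recovers planted families, names by abundance, masks to exhaustion", {
  monoA <- random_dna(300, seed = 41)   # most abundant
  monoB <- random_dna(180, seed = 42)
  mono19 <- random_dna(19, seed = 43)   # short-period family
  plan <- species_plan("Tst", "M", genome_size = 200000)
  evs <- list(amplification_event("fa", "Tst", 0.5, target_bp = 20000),
              amplification_event("fb", "Tst", 0.5, target_bp = 10000),
              amplification_event("fs", "Tst", 0.5, target_bp = 6000))
  gb <- build_species_genomes(list(monomer_spec("fa", monoA),
                                   monomer_spec("fb", monoB),
                                   monomer_spec("fs", mono19)), plan, evs,
                              seed = 44)
  lib <- simulate_reads(gb$genomes$M, coverage = 30, seed = 45)
  cfg <- satminer_config(prefix = "Tst", n_pairs = 800, seed = 46)
  cat_ <- iterate_satminer(lib, cfg)
  df <- as.data.frame(cat_)
  expect_equal(nrow(df), 3)
  expect_setequal(df$rul, c(300, 180, 19))
  validate_catalog(cat_)
  expect_identical(df$family_id[df$rank == 1], "TstSat01-300")
  expect_true(all(diff(df$abundance_M[order(df$rank)]) <= 0))
  # exhaustion: masking the sample against the catalog leaves <1% of
  # truth-labelled satellite reads unmasked
  samp <- sample_read_pairs(lib, cfg$n_pairs,
                            seed = derive_seed(cfg$seed, "sample"))
  # interior satellite reads: whole fragment inside an array (boundary reads
  # are legitimately part-background and not expected to mask)
  coords <- do.call(rbind, strsplit(sub("^frag[0-9]+:", "", samp$names), "-"))
  fs <- as.integer(coords[, 1]); fe <- as.integer(coords[, 2])
  interior <- rep(FALSE, length(fs))
  for (i in seq_len(nrow(gb$truth)))
    interior <- interior | (fs >= gb$truth$start[i] & fe <= gb$truth$end[i])
  interior <- rep(interior, 2)
  hit <- rep(FALSE, 2 * samp$n_pairs)
  for (cons in df$consensus) {
    h <- mask_reads(library_reads(samp), cons, min_identity = 0.7)
    hit[h$read] <- TRUE
  }
  expect_lt(sum(interior & !hit) / max(1, sum(interior)), 0.01)
})

test_that("iterate_satminer: satellite-free library yields an empty catalog; re-run is a fixed point", {
  g <- random_dna(100000, seed = 47)
  lib <- simulate_reads(g, coverage = 10, seed = 48)
  cfg <- satminer_config(prefix = "Emp", n_pairs = 350, seed = 49)
  cat_ <- iterate_satminer(lib, cfg)
  expect_equal(nrow(cat_), 0)
})

test_that("group_catalog: nested variant/family/superfamily partitions", {
  base <- random_dna(400, seed = 51)
  near <- mutate_monomer(base, 1, 0.03, seed = 52)       # ~97% identity
  mid <- mutate_monomer(base, 1, 0.18, seed = 53)        # ~84% identity
  far <- random_dna(400, seed = 54)
  df <- data.frame(family_id = sprintf("XxxSat%02d-400", 1:4), rank = 1:4,
                   consensus = c(base, near, mid, far))
  cat_ <- group_catalog(sat_catalog(df, prefix = "Xxx"))
  g <- as.data.frame(cat_)
  expect_equal(g$variant_group[1], g$variant_group[2])
  expect_false(g$variant_group[1] == g$variant_group[3])
  expect_equal(g$family_group[1], g$family_group[3])
  expect_false(g$superfamily_group[1] == g$superfamily_group[4])
  # nesting: variant partition refines family refines superfamily
  expect_true(all(tapply(g$family_group, g$variant_group,
                         function(x) length(unique(x))) == 1))
  expect_true(all(tapply(g$superfamily_group, g$family_group,
                         function(x) length(unique(x))) == 1))
})
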