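test_that("synthetic registries have the designed class-diagnostic digests", {
  reg <- make_alleles(sim_config(seed = 123))
  expect_identical(lengths(reg$class_index), c(A = 4L, B = 3L, C = 3L))
  hinfI <- enzyme_db()$HinfI
  sacI <- enzyme_db()$SacI
  # paper-flavoured fragments: 40 bp shared by all classes, 52 bp in A and B
  for (id in names(reg$alleles)) {
    frags <- digest(reg$alleles[[id]]$sequence, hinfI)$fragments
    expect_true(40L %in% frags)
    if (reg$alleles[[id]]$genome_class %in% c("A", "B")) {
      expect_true(52L %in% frags)
    }
  }
  # SacI cuts class B only
  for (id in names(reg$alleles)) {
    cut <- length(digest(reg$alleles[[id]]$sequence, sacI)$fragments) > 1L
    expect_identical(cut, reg$alleles[[id]]$genome_class == "B")
  }
  # all alleles full amplicon length
  expect_true(all(nchar(registry_sequences(reg)) == 569L))
})

test_that("registries pass panel invariants across seeds with stable band classes", {
  for (seed in c(1, 2, 99)) {
    reg <- make_alleles(sim_config(seed = seed))
    panel <- select_diagnostic_enzymes(reg, enzyme_db(c("SacI", "HinfI")))
    expect_identical(panel$reference_patterns$A$HinfI$bands, 477L)
    expect_identical(panel$reference_patterns$B$HinfI$bands, c(279L, 198L))
    expect_identical(panel$reference_patterns$C$HinfI$bands, 529L)
  }
  # different seeds give different sequences
  r1 <- make_alleles(sim_config(seed = 1))
  r2 <- make_alleles(sim_config(seed = 2))
  expect_false(identical(registry_sequences(r1), registry_sequences(r2)))
})

test_that("cohort generation is deterministic in the seed", {
  c1 <- make_cohort(sim_config(seed = 5, n_samples = 12))
  c2 <- make_cohort(sim_config(seed = 5, n_samples = 12))
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$flow, c2$flow)
  expect_identical(c1$traits, c2$traits)
  expect_identical(lapply(c1$samples, `[[`, "clones"),
                   lapply(c2$samples, `[[`, "clones"))
})

test_that("clone multisets are sub-multisets of the true allele draw", {
  coh <- make_cohort(sim_config(seed = 31, n_samples = 20, clone_dropout = 0.3))
  reg_seq <- registry_sequences(coh$registry)
  for (i in seq_len(nrow(coh$truth))) {
    id <- coh$truth$sample_id[i]
    truth_ids <- strsplit(coh$truth$alleles[i], ",")[[1]]
    clone_ids <- names(reg_seq)[match(unique(unname(coh$samples[[id]]$clones)),
                                      reg_seq)]
    expect_true(all(clone_ids %in% truth_ids))
  }
})

test_that("clone depth follows the 2.5x rule and covers all alleles at zero dropout", {
  coh <- make_cohort(sim_config(seed = 13, n_samples = 15, clone_dropout = 0))
  reg_seq <- registry_sequences(coh$registry)
  for (i in seq_len(nrow(coh$truth))) {
    id <- coh$truth$sample_id[i]
    p <- coh$truth$true_ploidy[i]
    expect_identical(length(coh$samples[[id]]$clones), required_clones(p))
    truth_ids <- sort(strsplit(coh$truth$alleles[i], ",")[[1]])
    clone_ids <- sort(names(reg_seq)[match(unique(unname(coh$samples[[id]]$clones)),
                                           reg_seq)])
    expect_identical(clone_ids, truth_ids)
  }
})

test_that("47-sample cohorts hit the study genotype-group frequencies", {
  # pooled over seeds the multinomial draw should track (9%, 21%, 62%)
  tab <- c(nonhybrid_alpha = 0, nonhybrid_beta = 0, hybrid_triploid = 0)
  n_seeds <- 10
  for (seed in seq_len(n_seeds)) {
    coh <- make_cohort(sim_config(seed = seed))
    s <- cohort_summary(data.frame(formula = coh$truth$true_compact,
                                   ploidy = coh$truth$true_ploidy))
    g <- setNames(s$groups$n, s$groups$group)
    tab <- tab + g[names(tab)]
  }
  shares <- tab / (47 * n_seeds)
  expect_lt(abs(shares[["nonhybrid_alpha"]] - 4 / 47), 0.04)
  expect_lt(abs(shares[["nonhybrid_beta"]] - 10 / 47), 0.05)
  expect_lt(abs(shares[["hybrid_triploid"]] - 29 / 47), 0.06)
})

test_that("generated flow peaks recover the true ploidy at 3% CV", {
  coh <- make_cohort(sim_config(seed = 77, n_samples = 47))
  gs <- genome_size(coh$flow$sample_peak, coh$flow$standard_peak)
  called <- vapply(gs, function(g) assign_ploidy(g)$ploidy, integer(1))
  expect_identical(called, coh$truth$true_ploidy)
})

test_that("trait tables stay positive with integer pinna counts", {
  d <- make_trait_table(n_per_group = 20, seed = 3)
  num_cols <- setdiff(names(d), c("sample_id", "group"))
  expect_true(all(d[num_cols] > 0))
  expect_true(all(d$PN == round(d$PN) & d$PN >= 3))
  expect_identical(as.integer(table(d$group)), rep(20L, 4))
})

test_that("cohort files write as plain text and read back", {
  dir <- file.path(tempdir(), "cohort_test")
  on.exit(unlink(dir, recursive = TRUE))
  coh <- make_cohort(sim_config(seed = 2, n_samples = 6))
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "alleles.fasta")))
  alleles <- read_fasta(file.path(dir, "alleles.fasta"))
  expect_identical(unname(alleles), unname(registry_sequences(coh$registry)))
  flow <- read_flow_csv(file.path(dir, "flow.csv"))
  expect_identical(nrow(flow), 6L)
  clones <- read_fasta(file.path(dir, "clones", "S001.fasta"))
  expect_identical(unname(clones), unname(coh$samples$S001$clones))
})
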