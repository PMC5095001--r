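test_that("truth generation is deterministic and honors requested sizes", {
  cfg <- sim_config(n_genes = 500, n_direct_pos = 40, n_direct_neg = 60)
  t1 <- generate_truth(cfg, seed = 1)
  t2 <- generate_truth(cfg, seed = 1)
  expect_identical(t1$direct_pos, t2$direct_pos)
  expect_identical(t1$mirnas, t2$mirnas)
  expect_equal(length(t1$direct_pos), 40)
  expect_equal(length(t1$direct_neg), 60)
  expect_equal(length(intersect(t1$direct_pos, t1$direct_neg)), 0)
  t3 <- generate_truth(cfg, seed = 2)
  expect_false(identical(t1$direct_pos, t3$direct_pos))
  expect_error(generate_truth(sim_config(n_genes = 50, n_direct_pos = 40,
                                         n_direct_neg = 60)),
               "infeasible")
})

test_that("planted FFL edges exist in the generated target graph", {
  b <- simulate_bundle(small_config(), seed = 7)
  tr <- b$truth
  scored <- score_targets(b$target_sources)
  kept <- scored$edges[scored$edges$retained, ]
  for (mid in tr$ffl4_mirnas) {
    planted <- tr$ffl4_primary[[mid]]
    got <- kept$gene_id[kept$mirna_id == mid]
    expect_true(all(planted %in% got), info = mid)
  }
  # planted primaries carry PPI links to direct targets
  direct <- c(tr$direct_pos, tr$direct_neg)
  prim <- tr$ffl4_primary[[tr$ffl4_mirnas[1]]]
  expect_gt(brute_cross_links(b$ppi, prim, direct), 0)
})

test_that("planted direct genes clear the correlation threshold, null genes do not", {
  cfg <- sim_config(n_genes = 150, n_direct_pos = 12, n_direct_neg = 12,
                    n_indirect_tfs = 1, n_indirect_per_tf = 4, n_cobound = 10)
  set.seed(89)
  rates <- replicate(25, {
    s <- sample.int(1e6, 1)
    tr <- generate_truth(cfg, seed = s)
    ex <- simulate_expression(tr, seed = s + 1)
    co <- correlate_with_master(ex$expr_a, ex$expr_b, "MASTER")
    planted <- c(tr$direct_pos, tr$direct_neg)
    want <- rep(c(1L, -1L), c(length(tr$direct_pos), length(tr$direct_neg)))
    nulls <- setdiff(tr$annotation$gene_id,
                     c(planted, "MASTER", unlist(tr$indirect_map),
                       names(tr$indirect_map)))
    c(hit = mean(co$sign[match(planted, co$gene_id)] == want),
      null_pass = mean(co$sign[match(nulls, co$gene_id)] != 0))
  })
  expect_gte(mean(rates["hit", ] == 1), 0.9)
  expect_lte(mean(rates["null_pass", ]), 0.05)
})

test_that("zero-delta regulators carry no conditional-correlation signal", {
  cfg <- sim_config(n_genes = 150, n_samples = 120, n_direct_pos = 15,
                    n_direct_neg = 15, n_indirect_tfs = 1,
                    n_indirect_per_tf = 3, n_cobound = 12,
                    n_comod_pos = 0, n_comod_neg = 0, n_comod_null = 2,
                    n_decoy_regulators = 0)
  set.seed(97)
  shifts <- replicate(30, {
    s <- sample.int(1e6, 1)
    tr <- generate_truth(cfg, seed = s)
    ex <- simulate_expression(tr, seed = s + 1)
    reg <- tr$comodulators$regulator_id[1]
    st <- stratify_samples(ex$expr_a, reg, 0.35)
    bound <- c(tr$direct_pos, tr$direct_neg)
    d <- mycnreg:::correlation_difference_set(ex$expr_a, "MASTER", bound,
                                              st$high, st$low, orient = TRUE)
    cb <- intersect(tr$cobound[[reg]], names(d))
    mean(d[cb], na.rm = TRUE) - mean(d, na.rm = TRUE)
  })
  # mean shift of a zero-effect regulator is zero within 3 standard errors
  expect_lt(abs(mean(shifts)), 3 * sd(shifts) / sqrt(length(shifts)))
})

test_that("count simulation means track the planted fold-change", {
  cfg <- sim_config(n_mirna = 20, n_mirna_up = 4, n_mirna_down = 4,
                    mirna_dispersion = 0.05, mirna_replicates = 6,
                    lib_factor_range = c(1, 1))
  tr <- generate_truth(cfg, seed = 3)
  cnt <- simulate_mirna_counts(tr, seed = 3)
  up <- tr$mirnas$mirna_id[tr$mirnas$lfc > 0]
  m_trt <- rowMeans(cnt$counts[up, cnt$condition == "treatment"])
  m_ctl <- rowMeans(cnt$counts[up, cnt$condition == "control"])
  expect_equal(log2(m_trt / m_ctl), rep(3, length(up)), tolerance = 0.35,
               ignore_attr = TRUE)
})

test_that("background-free peaks all map to planted loci", {
  cfg <- small_config()
  cfg$background_rate <- 0
  tr <- generate_truth(cfg, seed = 11)
  pk <- simulate_peaks(tr, seed = 11)
  expect_false(any(is.na(S4Vectors::mcols(pk$peaks)$planted_gene)))
  # full co-binding keeps every master peak positive
  cfg$co_bound_frac <- 1
  pk2 <- simulate_peaks(generate_truth(cfg, seed = 11), seed = 11)
  parts <- filter_positive_peaks(pk2$peaks, pk2$catalog)
  expect_equal(length(parts$negative), 0)
})

test_that("generated bundles are pure functions of (config, seed)", {
  b1 <- simulate_bundle(small_config(), seed = 13)
  b2 <- simulate_bundle(small_config(), seed = 13)
  expect_identical(b1$expr_a, b2$expr_a)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$ppi, b2$ppi)
  expect_identical(as.data.frame(b1$peaks), as.data.frame(b2$peaks))
})

test_that("full censoring leaves zero events and is rejected downstream", {
  cfg <- small_config()
  cfg$censor_range <- c(1, 2)          # censor everyone almost immediately
  cfg$baseline_hazard <- 1e-9
  tr <- generate_truth(cfg, seed = 17)
  ex <- simulate_expression(tr, seed = 17)
  sv <- simulate_survival(tr, ex$metadata, seed = 17)
  expect_equal(sum(sv$efs_event), 0)
  grp <- setNames(rep(1:2, length.out = nrow(sv)), sv$sample_id)
  sv$risk <- "low"
  expect_error(km_logrank(grp, sv), "Zero events")
})
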