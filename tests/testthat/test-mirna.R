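test_that("upper-quartile normalization equalizes quartiles and is idempotent", {
  set.seed(43)
  counts <- matrix(rpois(200, 50), nrow = 50,
                   dimnames = list(sprintf("m%02d", 1:50), sprintf("s%d", 1:4)))
  norm <- upper_quartile_normalize(counts)
  uqs <- apply(norm, 2, function(x) quantile(x[x > 0], 0.75))
  expect_lt(max(uqs) - min(uqs), 1e-9)
  expect_equal(upper_quartile_normalize(norm), norm, tolerance = 1e-12)
  # per-sample scale invariance: B = 2A normalizes to A
  two <- cbind(a = counts[, 1], b = counts[, 1] * 2)
  n2 <- upper_quartile_normalize(two)
  expect_equal(n2[, "a"], n2[, "b"], ignore_attr = TRUE)
  bad <- counts; bad[, 2] <- 0
  expect_error(upper_quartile_normalize(bad), "All-zero")
})

test_that("log2 fold-change has the printed closed forms", {
  expect_equal(round(compute_log2fc(314.8, 28.0), 2), 3.49)
  expect_equal(round(compute_log2fc(149.8, 7.9), 2), 4.25, tolerance = 0.02)
  expect_equal(compute_log2fc(50, 50), 0)
  expect_true(is.na(compute_log2fc(10, 0)))
})

test_that("differential-expression probability matches the brute-force oracle", {
  # 5-feature toy, 2 replicates per condition, enumerable noise set
  counts <- matrix(c(10, 12, 100, 90,
                     50, 55, 48, 52,
                     5,  4, 40, 45,
                     200, 210, 205, 195,
                     0, 0, 0, 0), nrow = 5, byrow = TRUE)
  rownames(counts) <- sprintf("m%d", 1:5)
  colnames(counts) <- c("treatment.1", "treatment.2", "control.1", "control.2")
  cond <- c("treatment", "treatment", "control", "control")
  out <- diffexp_probability(counts, cond)
  # explicit noise set: pairs (t1,t2) and (c1,c2) for every feature
  noise_m <- c(log2((counts[, 1] + 0.5) / (counts[, 2] + 0.5)),
               log2((counts[, 3] + 0.5) / (counts[, 4] + 0.5)))
  noise_d <- c(counts[, 1] - counts[, 2], counts[, 3] - counts[, 4])
  for (i in 1:4) {
    M <- log2((mean(counts[i, 1:2]) + 0.5) / (mean(counts[i, 3:4]) + 0.5))
    D <- mean(counts[i, 1:2]) - mean(counts[i, 3:4])
    expect_equal(out$probability[i],
                 mean(abs(noise_m) < abs(M) & abs(noise_d) < abs(D)),
                 info = paste("feature", i))
  }
  expect_equal(out$probability[5], 0)     # all-zero feature
  expect_true(is.na(out$log2fc[5]))
  # identical-in-all-samples feature has probability 0
  flat <- matrix(7, nrow = 1, ncol = 4,
                 dimnames = list("f", colnames(counts)))
  expect_equal(diffexp_probability(flat, cond)$probability, 0)
  expect_error(diffexp_probability(counts[, c(1, 3)], cond[c(1, 3)]),
               "two replicates")
})

test_that("probability is invariant to feature order", {
  set.seed(47)
  counts <- matrix(rpois(80, 60), nrow = 20,
                   dimnames = list(sprintf("m%02d", 1:20),
                                   c("treatment.1", "treatment.2",
                                     "control.1", "control.2")))
  cond <- c("treatment", "treatment", "control", "control")
  o1 <- diffexp_probability(counts, cond)
  perm <- sample(nrow(counts))
  o2 <- diffexp_probability(counts[perm, ], cond)
  expect_equal(o2$probability[match(o1$mirna_id, o2$mirna_id)],
               o1$probability)
})

test_that("planted fold-change at depth is recovered, null stays low", {
  set.seed(53)
  n_rep <- 20
  det <- replicate(n_rep, {
    cfg <- sim_config(n_mirna = 30, n_mirna_up = 3, n_mirna_down = 3)
    tr <- generate_truth(cfg, seed = sample.int(1e6, 1))
    cnt <- simulate_mirna_counts(tr, seed = sample.int(1e6, 1))
    norm <- upper_quartile_normalize(cnt$counts)
    de <- diffexp_probability(norm, cnt$condition)
    planted <- tr$mirnas$mirna_id[tr$mirnas$lfc != 0]
    nulls <- tr$mirnas$mirna_id[tr$mirnas$lfc == 0]
    c(hit = mean(de$probability[match(planted, de$mirna_id)] >= 0.6),
      null_low = mean(de$probability[match(nulls, de$mirna_id)] < 0.6))
  })
  expect_gte(mean(det["hit", ] == 1), 0.9)
  expect_gte(mean(det["null_low", ]), 0.8)
})

test_that("depth rescaling cancels out of the normalized relative structure", {
  cfg <- sim_config(n_mirna = 30)
  tr <- generate_truth(cfg, seed = 59)
  cnt <- simulate_mirna_counts(tr, seed = 59)
  n1 <- upper_quartile_normalize(cnt$counts)
  # a global depth change only moves the overall scale (the geometric-mean
  # target follows it); relative structure and M-values are unchanged
  n2 <- upper_quartile_normalize(cnt$counts * 2)
  expect_equal(n2, n1 * 2, tolerance = 1e-9)
  # per-sample (unequal) depth changes cancel up to one global constant
  fac <- c(1, 2, 0.5, 3)[seq_len(ncol(cnt$counts))]
  n3 <- upper_quartile_normalize(sweep(cnt$counts, 2, fac, "*"))
  expect_equal(unname(n3), unname(n1 * exp(mean(log(fac)))),
               tolerance = 1e-9)
})

test_that("selection filter applies both thresholds and counts signs", {
  rec <- data.frame(mirna_id = c("a", "b", "c", "d"),
                    mean_treatment = c(300, 40, 500, 120),
                    mean_control = c(30, 400, 60, 119),
                    log2fc = c(3.3, -3.3, 3.05, 0.01),
                    probability = c(0.9, 0.59, 0.7, 0.95))
  out <- select_diffexp(rec)
  expect_setequal(out$records$mirna_id, c("a", "c", "d"))  # b fails prob 0.59
  expect_equal(out$n_up, 3)
  expect_equal(out$n_down, 0)
  all_kept <- select_diffexp(rec, prob_min = 0, count_min = 0)
  expect_equal(nrow(all_kept$records), 4)
})

test_that("target scoring applies the confidence rule with the cap", {
  preds <- sprintf("pred%02d", 1:11)
  mk <- function(pairs) data.frame(mirna_id = pairs[, 1], gene_id = pairs[, 2],
                                   stringsAsFactors = FALSE)
  sources <- c(
    lapply(setNames(preds, preds), function(p) {
      rows <- rbind(c("miR-x", "g4"))                     # in all 11
      if (p %in% preds[1:4]) rows <- rbind(rows, c("miR-x", "g1"))  # 4 preds
      if (p %in% preds[1:3]) rows <- rbind(rows, c("miR-x", "g2"))  # 3 preds
      if (p %in% preds[1:2]) rows <- rbind(rows, c("miR-x", "g3"))  # validated+2
      mk(rows)
    }),
    list(validated = mk(rbind(c("miR-x", "g3")))))
  out <- score_targets(sources)
  e <- out$edges
  expect_equal(e$confidence[e$gene_id == "g1"], 0.4)
  expect_equal(e$confidence[e$gene_id == "g2"], 0.3)
  expect_equal(e$confidence[e$gene_id == "g3"], 1)   # validated wins
  expect_equal(e$confidence[e$gene_id == "g4"], 1)   # 11 sources, capped
  expect_true(e$retained[e$gene_id == "g1"])
  expect_false(e$retained[e$gene_id == "g2"])        # 0.3 not > 0.3
  # retention at > 0.3 is identical to retention at >= 0.4
  expect_equal(e$retained, e$confidence >= 0.4)
  expect_true(all(e$confidence %in% ((1:10) / 10)))
  expect_error(score_targets(list()), "No target sources")
  expect_error(score_targets(sources[1:3]), "Validated source")
})
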