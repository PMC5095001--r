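test_that("co-binding partition is exhaustive and boundary-exact", {
  pk <- peaks_gr(c(101, 301), c(200, 400))
  # catalog site [150,160) overlaps the first peak; [200,300) half-open
  # abuts the first peak (BED end 200 = last covered base 200 in 1-based)
  cat1 <- peaks_gr(151, 160, source = "OTHER")
  parts <- filter_positive_peaks(pk, cat1)
  expect_equal(length(parts$positive), 1)
  expect_equal(GenomicRanges::start(parts$positive), 101)
  expect_equal(length(parts$positive) + length(parts$negative), length(pk))

  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t200\t300\tOTHER"), f)
  both <- read_bed(f)
  parts2 <- filter_positive_peaks(both[1], both[2])
  expect_equal(length(parts2$positive), 0)  # no overlap across the boundary

  expect_warning(parts3 <- filter_positive_peaks(pk, cat1[0]), "Empty")
  expect_equal(length(parts3$negative), 2)
})

test_that("co-binding filter matches a brute-force pairwise overlap scan", {
  set.seed(11)
  n <- 100
  starts <- sample.int(5e5, n)
  pk <- peaks_gr(starts, starts + 200)
  cs <- sample.int(5e5, 60)
  catalog <- peaks_gr(cs, cs + 150, source = "OTHER")
  parts <- filter_positive_peaks(pk, catalog)
  brute <- vapply(seq_len(n), function(i) {
    any(GenomicRanges::start(pk)[i] <= GenomicRanges::end(catalog) &
          GenomicRanges::end(pk)[i] >= GenomicRanges::start(catalog))
  }, logical(1))
  expect_equal(length(parts$positive), sum(brute))
})

test_that("TSS profile respects strand and sums to one", {
  ann <- tiny_annotation()
  # peak midpoint exactly at gA TSS (+ strand): all mass in bin [0,200)
  pk <- peaks_gr(50000 - 50, 50000 + 50)
  prof <- tss_distance_profile(pk, ann)
  expect_equal(sum(prof$occurrence), 1)
  expect_equal(prof$occurrence[prof$bin_start == 0], 1)
  # midpoint 100 bp genomically left of the minus-strand gB TSS ->
  # downstream in transcription direction -> same bin [0,200)
  pk2 <- peaks_gr(150000 - 150, 150000 - 50)
  prof2 <- tss_distance_profile(pk2, ann)
  expect_equal(prof2$occurrence[prof2$bin_start == 0], 1)
  expect_error(tss_distance_profile(pk, ann, flank = 5000, bin = 313),
               "divisible")
})

test_that("simulated TSS offsets put the profile mode at the TSS", {
  set.seed(5)
  ann <- data.frame(gene_id = sprintf("g%d", 1:50), symbol = "s",
                    chrom = "chr1", tss = seq(1e5, by = 1e5, length.out = 50),
                    strand = rep(c("+", "-"), 25),
                    start = seq(1e5, by = 1e5, length.out = 50),
                    end = seq(1e5, by = 1e5, length.out = 50) + 1e4,
                    is_tf = FALSE, gene_class = "protein_coding")
  offs <- round(rnorm(500, 0, 300))
  gene <- sample(1:50, 500, replace = TRUE)
  mid <- ifelse(ann$strand[gene] == "+", ann$tss[gene] + offs,
                ann$tss[gene] - offs)
  pk <- peaks_gr(mid - 100, mid + 100)
  prof <- tss_distance_profile(pk, ann)
  mode_bin <- prof$bin_start[which.max(prof$occurrence)]
  expect_true(abs(mode_bin) <= 200)
})

test_that("promoter-window assignment matches the O(n*m) oracle", {
  ann <- tiny_annotation()
  # wholly 9,999 bp upstream of gA TSS: inside the -10 kb window
  near <- peaks_gr(50000 - 9999 - 50, 50000 - 9999)
  expect_true("gA" %in% assign_peaks_to_genes(near, ann)$bound_genes)
  # from 10,050 to 10,001 bp upstream: outside
  far <- peaks_gr(50000 - 10050, 50000 - 10001)
  expect_false("gA" %in% assign_peaks_to_genes(far, ann)$bound_genes)

  set.seed(21)
  n_genes <- 200
  ann2 <- data.frame(gene_id = sprintf("g%d", 1:n_genes), symbol = "s",
                     chrom = "chr1",
                     tss = sort(sample.int(2e7, n_genes)),
                     strand = sample(c("+", "-"), n_genes, TRUE),
                     is_tf = FALSE, gene_class = "protein_coding")
  ann2$start <- ann2$tss; ann2$end <- ann2$tss + 1000
  starts <- sample.int(2e7, 300)
  pk <- peaks_gr(starts, starts + sample(100:400, 300, TRUE))
  got <- assign_peaks_to_genes(pk, ann2)$bound_genes
  oracle <- character(0)
  for (i in seq_len(n_genes)) {
    lo <- if (ann2$strand[i] == "+") ann2$tss[i] - 10000 else ann2$tss[i] - 2000
    hi <- if (ann2$strand[i] == "+") ann2$tss[i] + 2000 else ann2$tss[i] + 10000
    for (j in seq_along(pk)) {
      if (GenomicRanges::start(pk)[j] <= hi && GenomicRanges::end(pk)[j] >= lo) {
        oracle <- c(oracle, ann2$gene_id[i]); break
      }
    }
  }
  expect_setequal(got, oracle)
})

test_that("miRNA binding fires via promoter or host-gene rule", {
  mirnas <- data.frame(
    mirna_id = c("m1", "m2", "m3", "m4"),
    stemloops = "x", chrom = "chr1",
    predicted_tss = c(100000, 200000, NA, NA),
    precursor_start = c(102000, 202000, 300000, NA),
    host_gene_id = c(NA, NA, "gHost", NA),
    strand = "+", stringsAsFactors = FALSE)
  pk <- peaks_gr(100500, 100700)  # inside m1 TSS-to-precursor span
  out <- assign_mirna_regulation(pk, mirnas, bound_genes = "gHost")
  expect_true(out$bound[out$mirna_id == "m1"])
  expect_true(out$via_promoter[out$mirna_id == "m1"])
  expect_true(out$bound[out$mirna_id == "m3"])   # host rule
  expect_true(out$via_host[out$mirna_id == "m3"])
  expect_false(out$bound[out$mirna_id == "m2"])  # neither rule
  expect_false(out$assessable[out$mirna_id == "m4"])
})

test_that("distance-distribution KS equals the max ECDF gap and detects shifts", {
  x <- c(1, 2, 3, 4, 5.5, 7, 8, 9, 10, 12)
  y <- c(2, 3.5, 4, 6, 6.5, 7.5, 9.5, 11, 13, 14)
  out <- compare_distance_distributions(x, y)
  expect_equal(out$statistic, enum_ks_statistic(abs(x), abs(y)))
  same <- compare_distance_distributions(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_distance_distributions(numeric(0), y), "class a")

  set.seed(31)
  hits <- replicate(40, {
    a <- abs(rnorm(500, 0, 200)); b <- abs(rnorm(500, 0, 2000))
    compare_distance_distributions(a, b)$p_value < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("qPCR fold enrichment follows 2^-(dCt)", {
  expect_equal(qpcr_fold_enrichment(30, 30), 1)
  expect_equal(qpcr_fold_enrichment(28, 30), 4)
  expect_equal(qpcr_fold_enrichment(32, 30), 0.25)
  expect_error(qpcr_fold_enrichment(NA, 30), "finite")
  expect_error(qpcr_fold_enrichment(Inf, 30), "finite")
})
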