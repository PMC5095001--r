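test_that("BED reading maps 0-based half-open coordinates and round-trips", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", f)
  gr <- read_bed(f)
  expect_equal(GenomicRanges::start(gr), 101)
  expect_equal(GenomicRanges::end(gr), 200)
  expect_equal(GenomicRanges::width(gr), 100)

  set.seed(42)
  n <- 50
  starts <- sort(sample.int(1e6, n))
  gr2 <- peaks_gr(starts, starts + sample(50:500, n, replace = TRUE),
                  source = sample(LETTERS[1:3], n, replace = TRUE))
  S4Vectors::mcols(gr2)$score <- round(runif(n, 0, 100), 3)
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr2, f2)
  back <- read_bed(f2)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr2))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr2))
  expect_equal(S4Vectors::mcols(back)$source, S4Vectors::mcols(gr2)$source)
  expect_equal(S4Vectors::mcols(back)$score, S4Vectors::mcols(gr2)$score)
})

test_that("malformed BED coordinates raise a parse error naming the line", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t200\t100"), f)
  expect_error(read_bed(f), "line 2")
  writeLines("chr1\t200\t100", f)
  expect_error(read_bed(f), "line 1")
  writeLines("chr1\tfoo\t100", f)
  expect_error(read_bed(f), "line 1")
})

test_that("target-edge confidence is a deterministic function of its inputs", {
  expect_equal(target_confidence(TRUE, 0), 1)
  expect_equal(target_confidence(FALSE, 4), 0.4)
  expect_equal(target_confidence(FALSE, 11), 1)
  expect_equal(target_confidence(c(TRUE, FALSE, FALSE), c(2, 7, 12)),
               c(1, 0.7, 1))
})

test_that("a written bundle reloads with aligned cross-references", {
  b <- simulate_bundle(small_config(), seed = 3)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  paths <- list(peaks = file.path(dir, "peaks.bed"),
                catalog = file.path(dir, "catalog.bed"),
                annotation = file.path(dir, "annotation.tsv"),
                expr_a = file.path(dir, "expr_a.tsv"),
                expr_b = file.path(dir, "expr_b.tsv"),
                counts = file.path(dir, "counts.tsv"),
                survival = file.path(dir, "survival.tsv"),
                mirna_annotation = file.path(dir, "mirna_annotation.tsv"),
                ppi = file.path(dir, "ppi.tsv"),
                targets = file.path(dir, "targets"),
                promoters = file.path(dir, "promoters.fa"))
  expect_no_warning(rb <- read_bundle(paths))
  expect_equal(dim(rb$expr_a), dim(b$expr_a))
  expect_equal(sort(rb$annotation$gene_id), sort(b$annotation$gene_id))
  expect_equal(length(rb$peaks), length(b$peaks))
  expect_equal(rb$n_orphan_target_edges, 0)
  expect_equal(nrow(rb$ppi), nrow(b$ppi))
  expect_setequal(names(rb$target_sources), names(b$target_sources))
})

test_that("extra expression samples are dropped with a warning", {
  b <- simulate_bundle(small_config(), seed = 3)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  ea <- b$expr_a
  ea <- cbind(ea, EXTRA = ea[, 1])
  write_expression(ea, file.path(dir, "expr_a.tsv"))
  paths <- list(peaks = file.path(dir, "peaks.bed"),
                catalog = file.path(dir, "catalog.bed"),
                annotation = file.path(dir, "annotation.tsv"),
                expr_a = file.path(dir, "expr_a.tsv"),
                expr_b = file.path(dir, "expr_b.tsv"),
                counts = file.path(dir, "counts.tsv"),
                survival = file.path(dir, "survival.tsv"),
                mirna_annotation = file.path(dir, "mirna_annotation.tsv"),
                ppi = file.path(dir, "ppi.tsv"),
                targets = file.path(dir, "targets"))
  expect_warning(rb <- read_bundle(paths), "EXTRA")
  expect_false("EXTRA" %in% colnames(rb$expr_a))
})

test_that("orphan target edges are counted and flagged", {
  b <- simulate_bundle(small_config(), seed = 3)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  # plant 3 orphan edges in one source
  src <- utils::read.delim(file.path(dir, "targets", "pred01.tsv"))
  orphans <- data.frame(mirna_id = src$mirna_id[1:3],
                        gene_id = c("NOPE1", "NOPE2", "NOPE3"))
  utils::write.table(rbind(src, orphans),
                     file.path(dir, "targets", "pred01.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- list(peaks = file.path(dir, "peaks.bed"),
                catalog = file.path(dir, "catalog.bed"),
                annotation = file.path(dir, "annotation.tsv"),
                expr_a = file.path(dir, "expr_a.tsv"),
                expr_b = file.path(dir, "expr_b.tsv"),
                counts = file.path(dir, "counts.tsv"),
                survival = file.path(dir, "survival.tsv"),
                mirna_annotation = file.path(dir, "mirna_annotation.tsv"),
                ppi = file.path(dir, "ppi.tsv"),
                targets = file.path(dir, "targets"))
  expect_warning(rb <- read_bundle(paths), "3 target edges")
  expect_equal(rb$n_orphan_target_edges, 3)
})

test_that("result writing emits headers, empty tables, and a manifest", {
  dir <- withr::local_tempdir()
  res <- list(calls = data.frame(gene_id = "g1", sign = 1),
              empty = data.frame(gene_id = character(0), sign = integer(0)))
  files <- write_results(res, dir, params = list(rho = 0.3), seed = 7)
  expect_true(file.exists(file.path(dir, "calls.tsv")))
  empty_lines <- readLines(file.path(dir, "empty.tsv"))
  expect_equal(length(empty_lines), 1)  # header-only, not absent
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mf$seed, 7)
  expect_equal(mf$params$rho, 0.3)
})
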