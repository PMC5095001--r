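# Synthetic-data generator: every pipeline input is generated with planted
# ground truth (direct targets, co-modulators, E-boxes, miRNA fold-changes,
# FFLs, survival effect) so each downstream stage has a recoverable answer.
# All generators are pure functions of (config, seed).

#' Default simulation configuration
#'
#' Defaults emulate the statistical structure of the study cohort at desk
#' scale: two expression platforms over 200 samples linked by a monotone
#' transform, direct targets whose population Spearman correlation with the
#' master clears the 0.3 calling threshold with a wide margin (~0.6),
#' co-modulators acting as a multiplicative interaction on the master-target
#' slope, negative-binomial miRNA counts with 2 replicates per condition,
#' a bimodal master-activity mixture defining two expression subtypes, and
#' exponential survival with a planted hazard ratio of e^1.5 for the
#' adverse (high-activity) subtype.
#'
#' @param ... Overrides for any default field.
#' @return Named list of configuration values.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 500, n_samples = 200,
    tf_fraction = 0.12,
    n_direct_pos = 40, n_direct_neg = 60,
    n_indirect_tfs = 4, n_indirect_per_tf = 10,
    direct_slope = 0.75, latent_sd = 0.6,
    platform_noise_a = 0.8, platform_noise_b = 0.8,
    comod_delta = 0.7, n_comod_pos = 2, n_comod_neg = 2, n_comod_null = 1,
    n_decoy_regulators = 3, n_cobound = 30, regulator_noise = 0.2,
    peaks_per_direct = 2, peak_width = 300, offset_sd = 300,
    background_rate = 0.3, co_bound_frac = 0.9,
    promoter_len = 400, p_ebox_activated = 0.8, p_ebox_other = 0.1,
    n_mirna = 40, n_mirna_up = 5, n_mirna_down = 5, mirna_lfc = 3,
    n_bound_null_mirna = 5, n_host_rule_mirna = 3,
    mirna_meanlog = 5, mirna_sdlog = 1.2, mirna_dispersion = 0.1,
    mirna_de_min_mean = 400,
    mirna_replicates = 2, lib_factor_range = c(0.7, 1.4),
    n_sources = 12, strong_targets = 20, decoy_targets = 30,
    n_ffl3 = 3, ffl3_planted = 12, n_ffl4 = 2, ffl4_planted = 10,
    ffl4_links = 3, n_convergent = 8, convergent_mirnas = 8,
    p_validated = 0.15, ppi_background = 300,
    hazard_beta = 1.5, baseline_hazard = 5e-4,
    censor_range = c(1000, 3650), amp_p_high = 0.45, amp_p_low = 0.05,
    gene_spacing = 50000, gene_length = 10000,
    mirna_region_start = 3e7, mirna_spacing = 30000
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("Unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Generate the planted truth model
#'
#' Lays out a synthetic genome (one chromosome, evenly spaced genes with
#' random strands), picks the planted activated/repressed direct-target
#' sets, the indirect TF layer, the co-modulators with their co-bound gene
#' sets, the miRNA fold-changes and binding routes, the FFL memberships and
#' the convergently targeted genes.
#'
#' @param config From [sim_config()].
#' @param seed Integer seed.
#' @return A `truth` list (class `"mycnreg_truth"`).
#' @export
generate_truth <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  n_direct <- cfg$n_direct_pos + cfg$n_direct_neg
  if (n_direct + cfg$n_indirect_tfs * cfg$n_indirect_per_tf + 1 > cfg$n_genes)
    stop("Config infeasible: more planted genes than genes")
  gene_id <- sprintf("G%04d", seq_len(cfg$n_genes))
  master_id <- "MASTER"
  gene_id[1] <- master_id
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  gstart <- 25000 + (seq_len(cfg$n_genes) - 1) * cfg$gene_spacing
  gend <- gstart + cfg$gene_length
  tss <- ifelse(strand == "+", gstart, gend)
  is_tf <- stats::runif(cfg$n_genes) < cfg$tf_fraction
  annotation <- data.frame(
    gene_id = gene_id, symbol = gene_id, chrom = "chr1", tss = tss,
    strand = strand, start = gstart, end = gend, is_tf = is_tf,
    gene_class = "protein_coding", stringsAsFactors = FALSE)

  pool <- setdiff(gene_id, master_id)
  direct <- sample(pool, n_direct)
  direct_pos <- direct[seq_len(cfg$n_direct_pos)]
  direct_neg <- setdiff(direct, direct_pos)
  # indirect layer TFs are activated direct targets flagged as TFs
  itf <- sample(direct_pos, cfg$n_indirect_tfs)
  annotation$is_tf[match(itf, annotation$gene_id)] <- TRUE
  remaining <- setdiff(pool, direct)
  indirect_map <- list()
  for (tf in itf) {
    indirect_map[[tf]] <- sample(remaining, cfg$n_indirect_per_tf)
    remaining <- setdiff(remaining, indirect_map[[tf]])
  }
  indirect_genes <- unlist(indirect_map, use.names = FALSE)
  indirect_sign <- stats::setNames(sample(c(1, -1), length(indirect_genes),
                                          replace = TRUE), indirect_genes)

  comods <- data.frame(
    regulator_id = sprintf("REG%02d",
                           seq_len(cfg$n_comod_pos + cfg$n_comod_neg +
                                     cfg$n_comod_null + cfg$n_decoy_regulators)),
    sign = c(rep(1, cfg$n_comod_pos), rep(-1, cfg$n_comod_neg),
             rep(0, cfg$n_comod_null), rep(0, cfg$n_decoy_regulators)),
    delta = c(rep(cfg$comod_delta, cfg$n_comod_pos + cfg$n_comod_neg),
              rep(0, cfg$n_comod_null + cfg$n_decoy_regulators)),
    planted = c(rep(TRUE, cfg$n_comod_pos + cfg$n_comod_neg),
                rep(FALSE, cfg$n_comod_null + cfg$n_decoy_regulators)),
    stringsAsFactors = FALSE)
  cobound <- lapply(seq_len(nrow(comods)), function(i)
    sample(direct, min(cfg$n_cobound, length(direct))))
  names(cobound) <- comods$regulator_id

  # miRNAs: planted up/down fold-changes; all DE miRNAs are master-bound
  # (promoter or host-gene route), plus some bound null miRNAs
  mirna_id <- sprintf("miR-%03d-5p", seq_len(cfg$n_mirna))
  lfc <- rep(0, cfg$n_mirna)
  de_idx <- seq_len(cfg$n_mirna_up + cfg$n_mirna_down)
  lfc[seq_len(cfg$n_mirna_up)] <- cfg$mirna_lfc
  lfc[cfg$n_mirna_up + seq_len(cfg$n_mirna_down)] <- -cfg$mirna_lfc
  bound <- rep(FALSE, cfg$n_mirna)
  bound[de_idx] <- TRUE
  bound[max(de_idx) + seq_len(cfg$n_bound_null_mirna)] <- TRUE
  host_rule <- rep(FALSE, cfg$n_mirna)
  host_rule[sample(which(bound), min(cfg$n_host_rule_mirna, sum(bound)))] <- TRUE
  mstrand <- sample(c("+", "-"), cfg$n_mirna, replace = TRUE)
  base <- cfg$mirna_region_start + (seq_len(cfg$n_mirna) - 1) * cfg$mirna_spacing
  precursor_start <- base + 12000
  predicted_tss <- ifelse(mstrand == "+", precursor_start - 2000,
                          precursor_start + 2000)
  predicted_tss[host_rule] <- NA
  host_gene <- rep(NA_character_, cfg$n_mirna)
  host_gene[host_rule] <- sample(direct, sum(host_rule))
  mirnas <- data.frame(
    mirna_id = mirna_id,
    stemloops = sub("^miR-(\\d+)-5p$", "mir-\\1", mirna_id),
    chrom = "chr1", predicted_tss = predicted_tss,
    precursor_start = precursor_start, host_gene_id = host_gene,
    strand = mstrand, lfc = lfc, bound = bound,
    stringsAsFactors = FALSE)

  regulated_mirnas <- mirna_id[bound & lfc != 0]
  ffl3 <- sample(regulated_mirnas, min(cfg$n_ffl3, length(regulated_mirnas)))
  rest <- setdiff(regulated_mirnas, ffl3)
  ffl4 <- sample(rest, min(cfg$n_ffl4, length(rest)))
  ffl4_primary <- lapply(stats::setNames(ffl4, ffl4), function(m)
    sample(indirect_genes, min(cfg$ffl4_planted, length(indirect_genes))))
  convergent <- sample(direct_neg, min(cfg$n_convergent, length(direct_neg)))

  truth <- list(
    config = cfg, seed = seed, master_id = master_id,
    annotation = annotation,
    direct_pos = direct_pos, direct_neg = direct_neg,
    indirect_map = indirect_map, indirect_sign = indirect_sign,
    comodulators = comods, cobound = cobound,
    mirnas = mirnas, regulated_mirnas = regulated_mirnas,
    ffl3_mirnas = ffl3, ffl4_mirnas = ffl4, ffl4_primary = ffl4_primary,
    convergent_genes = convergent)
  class(truth) <- "mycnreg_truth"
  truth
}

#' Simulate dual-platform expression and sample metadata
#'
#' Each gene has a shared latent value (its biological signal plus a latent
#' noise term reused by both platforms); platform A adds Gaussian
#' measurement noise, platform B applies a monotone exponential transform to
#' an independently re-noised copy, so the two platforms agree in rank but
#' not in scale. Direct targets are driven by the master with the planted
#' sign; co-bound genes get a multiplicative slope interaction active only
#' in samples where the co-modulator is high (positive sign) or low
#' (negative sign); indirect genes are driven by their TF's expression
#' (including the TF's own latent noise), not by the master directly.
#'
#' @param truth From [generate_truth()].
#' @param seed Integer seed.
#' @return List with `expr_a`, `expr_b` (genes + regulator rows x samples),
#'   `metadata` (`data.frame`) and `latent` internals (master values,
#'   regulator activations).
#' @export
simulate_expression <- function(truth, seed = 1) {
  set.seed(seed)
  cfg <- truth$config
  n <- cfg$n_samples
  if (n < 30) stop("n_samples must be >= 30")
  samples <- sprintf("S%03d", seq_len(n))
  # master activity is a two-component mixture: the cohort carries two
  # expression subtypes (high/low master-signature activity), which is what
  # a k = 2 consensus clustering of the signature presumes; the adverse
  # survival group is the high-activity component
  comp <- stats::rbinom(n, 1, 0.5) == 1
  m <- stats::rnorm(n, mean = ifelse(comp, 0.9, -0.9), sd = 0.55)
  regs <- truth$comodulators$regulator_id
  r_lat <- matrix(stats::rnorm(length(regs) * n), nrow = length(regs),
                  dimnames = list(regs, samples))
  act <- matrix(0, nrow = length(regs), ncol = n, dimnames = list(regs, samples))
  for (i in seq_along(regs)) {
    s <- truth$comodulators$sign[i]
    if (s > 0) act[i, ] <- as.numeric(r_lat[i, ] > stats::median(r_lat[i, ]))
    if (s < 0) act[i, ] <- as.numeric(r_lat[i, ] < stats::median(r_lat[i, ]))
  }
  gene_ids <- truth$annotation$gene_id
  sign_of <- stats::setNames(rep(0, length(gene_ids)), gene_ids)
  sign_of[truth$direct_pos] <- 1
  sign_of[truth$direct_neg] <- -1
  a <- cfg$direct_slope
  signal <- matrix(0, nrow = length(gene_ids), ncol = n,
                   dimnames = list(gene_ids, samples))
  for (g in c(truth$direct_pos, truth$direct_neg)) {
    mult <- rep(1, n)
    for (i in seq_along(regs)) {
      if (truth$comodulators$delta[i] > 0 && g %in% truth$cobound[[regs[i]]])
        mult <- mult * (1 + truth$comodulators$delta[i] * act[i, ])
    }
    signal[g, ] <- sign_of[g] * a * mult * m
  }
  signal[truth$master_id, ] <- m
  eta <- matrix(stats::rnorm(length(gene_ids) * n, sd = cfg$latent_sd),
                nrow = length(gene_ids))
  eta[match(truth$master_id, gene_ids), ] <- stats::rnorm(n, sd = 0.1)
  u <- signal + eta
  for (tf in names(truth$indirect_map)) {
    for (g in truth$indirect_map[[tf]]) {
      u[g, ] <- truth$indirect_sign[g] * u[tf, ] +
        stats::rnorm(n, sd = cfg$latent_sd)
    }
  }
  noise_a <- matrix(stats::rnorm(length(gene_ids) * n, sd = cfg$platform_noise_a),
                    nrow = length(gene_ids))
  noise_b <- matrix(stats::rnorm(length(gene_ids) * n, sd = cfg$platform_noise_b),
                    nrow = length(gene_ids))
  expr_a <- u + noise_a
  expr_b <- exp((u + noise_b) / 2)
  reg_a <- r_lat + matrix(stats::rnorm(length(regs) * n, sd = cfg$regulator_noise),
                          nrow = length(regs))
  reg_b <- exp((r_lat + matrix(stats::rnorm(length(regs) * n,
                                            sd = cfg$regulator_noise),
                               nrow = length(regs))) / 2)
  expr_a <- rbind(expr_a, reg_a)
  expr_b <- rbind(expr_b, reg_b)
  # amplification is a distinct genomic state enriched in (but not defined
  # by) the high-activity subtype; conditioning on non-amplification must
  # leave both subtypes represented, as in the cohort being emulated
  amplified <- stats::runif(n) < ifelse(comp, cfg$amp_p_high, cfg$amp_p_low)
  adverse <- comp
  metadata <- data.frame(
    sample_id = samples,
    mycn_amplified = amplified,
    risk = ifelse(adverse, "high", "low"),
    adverse = adverse,
    stringsAsFactors = FALSE)
  list(expr_a = expr_a, expr_b = expr_b, metadata = metadata,
       master_values = stats::setNames(m, samples), activation = act)
}

#' Simulate binding peaks, the multi-regulator catalog and promoter sequences
#'
#' Every direct target receives master peaks whose stranded TSS offsets are
#' drawn from a Gaussian centered on the TSS (truncated to the promoter
#' window); bound miRNAs get a peak inside their promoter span; background
#' peaks are scattered uniformly. The catalog co-locates generic regulator
#' sites on a configurable fraction of master peaks and plants each
#' candidate regulator's sites on the promoter peaks of its co-bound genes.
#' Promoter sequences carry a planted canonical E-box at a class-dependent
#' rate.
#'
#' @param truth From [generate_truth()].
#' @param seed Integer seed.
#' @return List with `peaks` (`GRanges`, source `"MASTER"`), `catalog`
#'   (`GRanges` with regulator `source`), `promoter_seqs` (named character).
#' @export
simulate_peaks <- function(truth, seed = 1) {
  set.seed(seed)
  cfg <- truth$config
  ann <- truth$annotation
  direct <- c(truth$direct_pos, truth$direct_neg)
  w <- cfg$peak_width
  mk_peak <- function(chrom, mid) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(pmax(mid - w %/% 2, 1),
                                                   mid + w %/% 2))
  }
  peak_list <- list(); peak_gene <- character(0)
  for (g in direct) {
    row <- ann[ann$gene_id == g, ]
    for (j in seq_len(cfg$peaks_per_direct)) {
      off <- pmin(pmax(stats::rnorm(1, 0, cfg$offset_sd), -9500), 1500)
      mid <- if (row$strand == "+") row$tss + off else row$tss - off
      peak_list[[length(peak_list) + 1]] <- mk_peak(row$chrom, round(mid))
      peak_gene <- c(peak_gene, g)
    }
  }
  mi <- truth$mirnas
  for (i in which(mi$bound & !is.na(mi$predicted_tss))) {
    mid <- if (mi$strand[i] == "+") mi$predicted_tss[i] + 800 else
      mi$predicted_tss[i] - 800
    peak_list[[length(peak_list) + 1]] <- mk_peak(mi$chrom[i], mid)
    peak_gene <- c(peak_gene, mi$mirna_id[i])
  }
  n_bg <- round(cfg$background_rate * cfg$n_genes)
  genome_len <- max(ann$end) + 1e6
  if (n_bg > 0) {
    mids <- sample.int(genome_len - w, n_bg)
    for (mid in mids) {
      peak_list[[length(peak_list) + 1]] <- mk_peak("chr1", mid)
      peak_gene <- c(peak_gene, NA_character_)
    }
  }
  peaks <- do.call(c, peak_list)
  S4Vectors::mcols(peaks)$source <- "MASTER"
  S4Vectors::mcols(peaks)$score <- round(stats::runif(length(peaks), 10, 100), 2)
  S4Vectors::mcols(peaks)$planted_gene <- peak_gene

  # generic co-binding support on a fraction of master peaks
  cat_list <- list(); cat_src <- character(0)
  generic <- sprintf("ENC%02d", 1:5)
  co <- which(stats::runif(length(peaks)) < cfg$co_bound_frac)
  for (i in co) {
    mid <- floor((GenomicRanges::start(peaks)[i] + GenomicRanges::end(peaks)[i]) / 2)
    cat_list[[length(cat_list) + 1]] <-
      GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(peaks)[i]),
                             IRanges::IRanges(pmax(mid - 75, 1), mid + 75))
    cat_src <- c(cat_src, sample(generic, 1))
  }
  # candidate-regulator sites on the first promoter peak of each co-bound gene
  first_peak <- match(direct, peak_gene)
  names(first_peak) <- direct
  for (reg in truth$comodulators$regulator_id) {
    for (g in truth$cobound[[reg]]) {
      i <- first_peak[[g]]
      mid <- floor((GenomicRanges::start(peaks)[i] + GenomicRanges::end(peaks)[i]) / 2)
      cat_list[[length(cat_list) + 1]] <-
        GenomicRanges::GRanges("chr1", IRanges::IRanges(pmax(mid - 75, 1), mid + 75))
      cat_src <- c(cat_src, reg)
    }
  }
  catalog <- do.call(c, cat_list)
  S4Vectors::mcols(catalog)$source <- cat_src
  S4Vectors::mcols(catalog)$score <- 0

  # promoter sequences with planted E-boxes
  rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")
  others <- sample(setdiff(ann$gene_id, c(direct, truth$master_id)), 60)
  seq_genes <- c(direct, others)
  promoter_seqs <- vapply(seq_genes, function(g) {
    p_motif <- if (g %in% truth$direct_pos) cfg$p_ebox_activated else cfg$p_ebox_other
    s <- rand_seq(cfg$promoter_len)
    if (stats::runif(1) < p_motif) {
      pos <- sample.int(cfg$promoter_len - 6, 1)
      substr(s, pos, pos + 5) <- "CACGTG"
    }
    s
  }, character(1))
  list(peaks = peaks, catalog = catalog, promoter_seqs = promoter_seqs)
}

#' Simulate miRNA counts for two conditions
#'
#' Counts are negative-binomial via a Poisson-gamma mixture around
#' condition-specific means (`treatment = control * 2^lfc`), scaled by
#' per-library depth factors so that normalization is exercised.
#'
#' @param truth From [generate_truth()].
#' @param seed Integer seed.
#' @return List with `counts` (matrix) and `condition` per sample
#'   (`"treatment"` first).
#' @export
simulate_mirna_counts <- function(truth, seed = 1) {
  set.seed(seed)
  cfg <- truth$config
  if (cfg$mirna_replicates < 2) stop("Need >= 2 replicates per condition")
  mu0 <- stats::rlnorm(cfg$n_mirna, cfg$mirna_meanlog, cfg$mirna_sdlog)
  # differentially expressed miRNAs are planted at adequate depth: the
  # knockdown contrast targets well-expressed species (low-count features
  # are below the detection filter by design)
  de <- truth$mirnas$lfc != 0
  mu0[de] <- pmax(mu0[de], cfg$mirna_de_min_mean)
  mu_trt <- mu0 * 2^truth$mirnas$lfc
  mu_ctl <- mu0
  n_rep <- cfg$mirna_replicates
  libf <- stats::runif(2 * n_rep, cfg$lib_factor_range[1], cfg$lib_factor_range[2])
  shape <- 1 / cfg$mirna_dispersion
  draw <- function(mu, f) {
    lambda <- stats::rgamma(length(mu), shape = shape, rate = shape / (mu * f))
    stats::rpois(length(mu), lambda)
  }
  cols <- list(); cond <- character(0)
  for (j in seq_len(n_rep)) {
    cols[[length(cols) + 1]] <- draw(mu_trt, libf[j]); cond <- c(cond, "treatment")
  }
  for (j in seq_len(n_rep)) {
    cols[[length(cols) + 1]] <- draw(mu_ctl, libf[n_rep + j]); cond <- c(cond, "control")
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- truth$mirnas$mirna_id
  colnames(counts) <- paste0(cond, ".", c(seq_len(n_rep), seq_len(n_rep)))
  list(counts = counts, condition = cond)
}

#' Simulate miRNA-target sources and the PPI network
#'
#' Planted FFL edges are supported by >= 4 prediction databases (or
#' validated) so they clear the confidence threshold; decoy edges by <= 3.
#' Convergently targeted genes receive retained edges from most regulated
#' miRNAs. The PPI holds planted primary-secondary links for the four-node
#' FFL miRNAs plus random background edges.
#'
#' @param truth From [generate_truth()].
#' @param seed Integer seed.
#' @return List with `target_sources` (named list of `data.frame`s, one
#'   flagged `validated`) and `ppi` (`data.frame`).
#' @export
simulate_targets_ppi <- function(truth, seed = 1) {
  set.seed(seed)
  cfg <- truth$config
  genes <- truth$annotation$gene_id
  direct <- c(truth$direct_pos, truth$direct_neg)
  indirect <- unlist(truth$indirect_map, use.names = FALSE)
  src_names <- c(sprintf("pred%02d", seq_len(cfg$n_sources - 1)), "validated")
  edges <- list()
  add_edge <- function(mirna, gene, strong) {
    n_sup <- if (strong) sample(4:10, 1) else sample(1:3, 1)
    validated <- strong && stats::runif(1) < cfg$p_validated
    srcs <- sample(sprintf("pred%02d", seq_len(cfg$n_sources - 1)), n_sup)
    if (validated) srcs <- c(srcs, "validated")
    list(mirna_id = mirna, gene_id = gene, sources = srcs)
  }
  for (i in seq_len(nrow(truth$mirnas))) {
    mid <- truth$mirnas$mirna_id[i]
    strong <- if (mid %in% truth$ffl3_mirnas) {
      k3 <- min(cfg$ffl3_planted, length(direct))
      c(sample(direct, k3),
        sample(setdiff(genes, direct), cfg$strong_targets - k3))
    } else if (mid %in% truth$ffl4_mirnas) {
      prim <- truth$ffl4_primary[[mid]]
      c(prim, sample(setdiff(genes, c(direct, indirect)),
                     max(cfg$strong_targets - length(prim), 0)))
    } else {
      sample(setdiff(genes, direct), cfg$strong_targets)
    }
    for (g in unique(strong)) edges[[length(edges) + 1]] <- add_edge(mid, g, TRUE)
    for (g in sample(genes, cfg$decoy_targets))
      edges[[length(edges) + 1]] <- add_edge(mid, g, FALSE)
  }
  conv_mirnas <- sample(truth$regulated_mirnas,
                        min(cfg$convergent_mirnas, length(truth$regulated_mirnas)))
  for (g in truth$convergent_genes) for (mid in conv_mirnas)
    edges[[length(edges) + 1]] <- add_edge(mid, g, TRUE)
  flat <- do.call(rbind, lapply(edges, function(e)
    data.frame(mirna_id = e$mirna_id, gene_id = e$gene_id, source = e$sources,
               stringsAsFactors = FALSE)))
  target_sources <- lapply(stats::setNames(src_names, src_names), function(s)
    unique(flat[flat$source == s, c("mirna_id", "gene_id")]))

  ppi <- list()
  for (mid in truth$ffl4_mirnas) {
    for (g in truth$ffl4_primary[[mid]]) {
      for (h in sample(direct, cfg$ffl4_links))
        ppi[[length(ppi) + 1]] <- c(g, h)
    }
  }
  for (j in seq_len(cfg$ppi_background)) {
    pair <- sample(genes, 2)
    ppi[[length(ppi) + 1]] <- pair
  }
  pdf <- do.call(rbind.data.frame, c(ppi, stringsAsFactors = FALSE))
  names(pdf) <- c("gene_id_a", "gene_id_b")
  pdf <- pdf[pdf$gene_id_a != pdf$gene_id_b, ]
  key <- ifelse(pdf$gene_id_a < pdf$gene_id_b,
                paste(pdf$gene_id_a, pdf$gene_id_b),
                paste(pdf$gene_id_b, pdf$gene_id_a))
  pdf <- pdf[!duplicated(key), ]
  rownames(pdf) <- NULL
  list(target_sources = target_sources, ppi = pdf)
}

#' Simulate event-free survival
#'
#' Exponential event times whose hazard is multiplied by
#' `exp(hazard_beta)` for samples in the adverse planted signature group,
#' with independent uniform administrative censoring.
#'
#' @param truth From [generate_truth()].
#' @param metadata Metadata `data.frame` from [simulate_expression()] (needs
#'   the `adverse` column).
#' @param seed Integer seed.
#' @return `metadata` extended with `efs_time` and `efs_event`.
#' @export
simulate_survival <- function(truth, metadata, seed = 1) {
  set.seed(seed)
  cfg <- truth$config
  rate <- cfg$baseline_hazard * exp(cfg$hazard_beta * metadata$adverse)
  t_event <- stats::rexp(nrow(metadata), rate)
  t_cens <- stats::runif(nrow(metadata), cfg$censor_range[1], cfg$censor_range[2])
  metadata$efs_time <- pmin(t_event, t_cens)
  metadata$efs_event <- t_event <= t_cens
  metadata
}

#' Generate the complete synthetic input bundle
#'
#' Runs every generator with sub-seeds derived from `seed` and returns the
#' in-memory bundle; when `out_dir` is given, also writes every input in its
#' on-disk format (BED, TSV, FASTA) plus `truth.json`.
#'
#' @param config From [sim_config()].
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @return List (class `"mycnreg_bundle"`) with all pipeline inputs and the
#'   `truth` model.
#' @export
simulate_bundle <- function(config = sim_config(), seed = 1, out_dir = NULL) {
  sub <- function(k) (seed * 13 + k * 101) %% 2147483647L
  truth <- generate_truth(config, sub(1))
  ex <- simulate_expression(truth, sub(2))
  pk <- simulate_peaks(truth, sub(3))
  cnt <- simulate_mirna_counts(truth, sub(4))
  tp <- simulate_targets_ppi(truth, sub(5))
  surv <- simulate_survival(truth, ex$metadata, sub(6))
  b <- list(truth = truth, annotation = truth$annotation,
            expr_a = ex$expr_a, expr_b = ex$expr_b,
            survival = surv[, c("sample_id", "efs_time", "efs_event",
                                "mycn_amplified", "risk")],
            peaks = pk$peaks, catalog = pk$catalog,
            promoters = pk$promoter_seqs,
            mirna_annotation = truth$mirnas[, c("mirna_id", "stemloops", "chrom",
                                                "predicted_tss", "precursor_start",
                                                "host_gene_id", "strand")],
            counts = cnt$counts, condition = cnt$condition,
            target_sources = tp$target_sources,
            validated_source = "validated", ppi = tp$ppi)
  class(b) <- "mycnreg_bundle"
  if (!is.null(out_dir)) write_bundle(b, out_dir)
  b
}

#' Write a bundle to disk in its on-disk input formats
#' @param bundle From [simulate_bundle()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible `out_dir`.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "targets"), showWarnings = FALSE)
  write_bed(bundle$peaks, file.path(out_dir, "peaks.bed"))
  write_bed(bundle$catalog, file.path(out_dir, "catalog.bed"))
  utils::write.table(bundle$annotation, file.path(out_dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression(bundle$expr_a, file.path(out_dir, "expr_a.tsv"))
  write_expression(bundle$expr_b, file.path(out_dir, "expr_b.tsv"))
  utils::write.table(bundle$survival, file.path(out_dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$mirna_annotation,
                     file.path(out_dir, "mirna_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression(bundle$counts, file.path(out_dir, "counts.tsv"),
                   id_col = "mirna_id")
  for (nm in names(bundle$target_sources))
    utils::write.table(bundle$target_sources[[nm]],
                       file.path(out_dir, "targets", paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$ppi, file.path(out_dir, "ppi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(bundle$promoters, file.path(out_dir, "promoters.fa"))
  if (!is.null(bundle$truth)) {
    tr <- bundle$truth
    jsonlite::write_json(
      list(master_id = tr$master_id, direct_pos = tr$direct_pos,
           direct_neg = tr$direct_neg, indirect_map = tr$indirect_map,
           comodulators = tr$comodulators,
           regulated_mirnas = tr$regulated_mirnas,
           ffl3_mirnas = tr$ffl3_mirnas, ffl4_mirnas = tr$ffl4_mirnas,
           convergent_genes = tr$convergent_genes, seed = tr$seed),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}
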