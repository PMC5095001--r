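# End-to-end orchestration: binding -> regulation -> motifs -> co-modulators
# -> miRNA -> FFL -> enriched targets -> survival, with per-stage outputs and
# a machine-readable manifest.

#' Default pipeline parameters
#'
#' The defaults are the study's analysis parameters: promoter window
#' -10 kb/+2 kb, dual-platform |rho| >= 0.3, stratum fraction 0.35, KS alpha
#' 0.05, differential-expression probability >= 0.6 and mean count >= 100,
#' target confidence > 0.3, 1000 permutations, k = 2 with 1000 k-means
#' restarts.
#'
#' @param ... Overrides.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(master_id = "MASTER", upstream = 10000, downstream = 2000,
            rho_threshold = 0.3, fraction = 0.35, alpha = 0.05,
            prob_min = 0.6, count_min = 100, conf_min = 0.3,
            ffl_alpha = 0.05, B = 1000, k = 2, kmeans_runs = 1000,
            flank = 5000, bin = 200, min_cobound = 5,
            nonamplified_only = TRUE, survival_platform = "a")
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0) stop("Unknown parameters: ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

#' Run the integrative regulatory-network pipeline
#'
#' Executes all stages on an input bundle (from [simulate_bundle()] or
#' [read_bundle()]): co-binding peak filtering, promoter-window assignment,
#' TSS-distance profiling, dual-platform correlation and regulated-gene
#' calling, TF over-representation and the indirect layer, E-box enrichment,
#' co-modulator inference, miRNA normalization/differential
#' expression/binding, target-graph scoring, 3-/4-node FFL tests, enriched
#' convergent targets, and consensus k-means survival stratification.
#' Stages may be restricted via `stages`.
#'
#' @param bundle Input bundle.
#' @param params From [pipeline_params()].
#' @param seed Integer seed (permutations and k-means restarts).
#' @param out_dir Optional directory for per-stage TSVs and the manifest.
#' @param stages Character vector of stages to run (default all, in order):
#'   `binding`, `regulation`, `motifs`, `comodulators`, `mirna`, `ffl`,
#'   `survival`. Later stages depending on skipped ones are skipped too.
#' @return List of per-stage results (class `"mycnreg_result"`).
#' @export
run_pipeline <- function(bundle, params = pipeline_params(), seed = 1,
                         out_dir = NULL,
                         stages = c("binding", "regulation", "motifs",
                                    "comodulators", "mirna", "ffl",
                                    "survival")) {
  set.seed(seed)
  res <- list(params = params, seed = seed)
  ann <- bundle$annotation

  if ("binding" %in% stages) {
    parts <- filter_positive_peaks(bundle$peaks, bundle$catalog,
                                   focal = params$master_id)
    asg <- assign_peaks_to_genes(parts$positive, ann,
                                 params$upstream, params$downstream)
    res$binding <- list(
      positive = parts$positive, negative = parts$negative,
      bound_genes = asg$bound_genes, assignments = asg$assignments,
      profile = tss_distance_profile(parts$positive, ann,
                                     params$flank, params$bin))
  }

  if ("regulation" %in% stages && !is.null(res$binding)) {
    correlations <- correlate_with_master(bundle$expr_a, bundle$expr_b,
                                          params$master_id,
                                          params$rho_threshold)
    calls <- call_regulated_genes(correlations, res$binding$bound_genes)
    regulated <- calls$gene_id[calls$status %in% c("activated", "repressed")]
    tf_univ <- ann$gene_id[ann$is_tf]
    reg_tfs <- intersect(regulated, tf_univ)
    res$regulation <- list(
      calls = calls, regulated = regulated,
      activated = calls$gene_id[calls$status == "activated"],
      repressed = calls$gene_id[calls$status == "repressed"],
      correlated_only = calls$gene_id[calls$status == "correlated_only"],
      tf_enrichment = tf_overrepresentation(regulated, tf_univ, ann$gene_id),
      indirect = infer_indirect_layer(calls, reg_tfs, bundle$expr_a,
                                      bundle$expr_b, params$rho_threshold))
  }

  if ("motifs" %in% stages && !is.null(res$regulation) &&
      !is.null(bundle$promoters)) {
    cls <- rep("no_effect", nrow(ann))
    names(cls) <- ann$gene_id
    cls[res$regulation$activated] <- "activated"
    cls[res$regulation$repressed] <- "repressed"
    counts <- scan_promoter_sequences(bundle$promoters, cls)
    res$motifs <- list(
      counts = counts,
      act_vs_rep = motif_enrichment_test(counts, "activated", "repressed"),
      act_vs_none = motif_enrichment_test(counts, "activated", "no_effect"))
  }

  if ("comodulators" %in% stages && !is.null(res$regulation)) {
    src <- S4Vectors::mcols(bundle$catalog)$source
    cand <- intersect(unique(src),
                      intersect(rownames(bundle$expr_a), rownames(bundle$expr_b)))
    win <- promoter_windows(ann, params$upstream, params$downstream)
    cobound_map <- lapply(stats::setNames(cand, cand), function(reg) {
      sites <- bundle$catalog[src == reg]
      hit <- GenomicRanges::countOverlaps(win, sites, ignore.strand = TRUE) > 0
      intersect(ann$gene_id[hit], res$binding$bound_genes)
    })
    res$comodulators <- infer_comodulators(
      bundle$expr_a, bundle$expr_b, params$master_id, cand,
      res$binding$bound_genes, cobound_map, params$fraction, params$alpha,
      params$min_cobound)
  }

  if ("mirna" %in% stages) {
    norm <- upper_quartile_normalize(bundle$counts)
    de <- diffexp_probability(norm, bundle$condition)
    sel <- select_diffexp(de, params$prob_min, params$count_min)
    mr <- assign_mirna_regulation(
      if (!is.null(res$binding)) res$binding$positive else bundle$peaks,
      bundle$mirna_annotation,
      if (!is.null(res$binding)) res$binding$bound_genes else character(0),
      params$upstream)
    scored <- score_targets(bundle$target_sources,
                            bundle$validated_source %||% "validated",
                            params$conf_min)
    bound_mirnas <- mr$mirna_id[mr$bound]
    res$mirna <- list(
      normalized = norm, diffexp = de, selected = sel,
      regulation = mr,
      regulated_mirnas = intersect(sel$records$mirna_id, bound_mirnas),
      targets = scored)
  }

  if ("ffl" %in% stages && !is.null(res$mirna) && !is.null(res$regulation)) {
    edges <- res$mirna$targets$edges
    kept <- edges[edges$retained, ]
    universe <- ann$gene_id
    regulated <- res$regulation$regulated
    corr_pool <- res$regulation$correlated_only
    ffl <- lapply(stats::setNames(res$mirna$regulated_mirnas,
                                  res$mirna$regulated_mirnas), function(mid) {
      tg <- kept$gene_id[kept$mirna_id == mid]
      f3 <- three_node_ffl(tg, regulated, universe)
      primary <- intersect(tg, corr_pool)
      f4 <- if (length(primary) >= 1 && length(corr_pool) >= length(primary))
        four_node_ffl(primary, regulated, bundle$ppi, corr_pool, params$B)
      else list(statistic = NA_real_, p_value = NA_real_)
      data.frame(mirna_id = mid, n_targets = length(tg),
                 three_node_overlap = f3$statistic, three_node_p = f3$p_value,
                 n_primary = length(primary),
                 four_node_links = f4$statistic, four_node_p = f4$p_value,
                 stringsAsFactors = FALSE)
    })
    ffl_tab <- do.call(rbind, ffl)
    rownames(ffl_tab) <- NULL
    ent <- enriched_target_test(
      regulated, res$mirna$regulated_mirnas, kept,
      all_mirnas = bundle$mirna_annotation$mirna_id, alpha = params$ffl_alpha,
      repressed_genes = res$regulation$repressed)
    res$ffl <- list(table = ffl_tab, enriched_targets = ent)
  }

  if ("survival" %in% stages && !is.null(res$regulation) &&
      !is.null(bundle$survival)) {
    expr <- if (params$survival_platform == "a") bundle$expr_a else bundle$expr_b
    surv <- bundle$survival
    keep_samples <- if (params$nonamplified_only)
      surv$sample_id[!surv$mycn_amplified] else surv$sample_id
    keep_samples <- intersect(keep_samples, colnames(expr))
    sig <- intersect(res$regulation$regulated, rownames(expr))
    if (length(sig) >= 2 && length(keep_samples) > params$k) {
      ck <- consensus_kmeans(expr[sig, keep_samples, drop = FALSE],
                             k = params$k, runs = params$kmeans_runs)
      lr <- km_logrank(ck$groups, surv)
      res$survival <- list(clustering = ck, logrank = lr)
    }
  }

  class(res) <- "mycnreg_result"
  if (!is.null(out_dir)) export_results(res, out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flatten a pipeline result into per-stage data.frames and write them with
# the run manifest.
export_results <- function(res, out_dir) {
  tabs <- list()
  if (!is.null(res$binding)) tabs$tss_profile <- res$binding$profile
  if (!is.null(res$regulation)) {
    calls <- res$regulation$calls
    tabs$regulated_genes <- data.frame(
      gene_id = calls$gene_id, sign = calls$sign, rho_A = calls$rho_a,
      rho_B = calls$rho_b, bound = calls$bound, status = calls$status,
      stringsAsFactors = FALSE)
    tabs$indirect_links <- res$regulation$indirect$links
  }
  if (!is.null(res$motifs)) tabs$motif_enrichment <- res$motifs$act_vs_rep
  if (!is.null(res$comodulators)) tabs$comodulators <- res$comodulators
  if (!is.null(res$mirna)) {
    tabs$mirna_diffexp <- res$mirna$diffexp
    tabs$mirna_regulation <- res$mirna$regulation
    tabs$target_edges <- res$mirna$targets$edges
  }
  if (!is.null(res$ffl)) {
    tabs$ffl <- res$ffl$table
    tabs$enriched_targets <- res$ffl$enriched_targets$table
  }
  if (!is.null(res$survival)) {
    tabs$survival_groups <- data.frame(
      sample_id = names(res$survival$clustering$groups),
      group = res$survival$clustering$groups,
      stability = res$survival$clustering$stability,
      stringsAsFactors = FALSE)
    tabs$km_curves <- res$survival$logrank$curves
  }
  write_results(tabs, out_dir, params = res$params, seed = res$seed)
}

#' Compare pipeline output against the planted truth
#'
#' @param res Result of [run_pipeline()] on a simulated bundle.
#' @param truth The bundle's `truth` component.
#' @return Named list of recovery metrics: `direct_recovery` (fraction of
#'   planted direct targets called with the correct sign), `comod_recovery`
#'   (fraction of planted co-modulators reported with the correct sign),
#'   `null_comod_reported` (any zero-effect regulator reported),
#'   `ffl3_max_p`, `ffl4_max_p` (largest p among planted FFL miRNAs),
#'   `mirna_detected` (fraction of planted DE miRNAs with probability >=
#'   0.6), `logrank_p`, `convergent_recovery`, `ebox_activated_p`.
#' @export
evaluate_recovery <- function(res, truth) {
  calls <- res$regulation$calls
  planted <- c(truth$direct_pos, truth$direct_neg)
  want <- c(rep("activated", length(truth$direct_pos)),
            rep("repressed", length(truth$direct_neg)))
  got <- calls$status[match(planted, calls$gene_id)]
  direct_recovery <- mean(got == want, na.rm = FALSE)

  cm <- res$comodulators
  planted_cm <- truth$comodulators[truth$comodulators$planted, ]
  match_sign <- vapply(seq_len(nrow(planted_cm)), function(i) {
    row <- cm[cm$regulator_id == planted_cm$regulator_id[i], ]
    nrow(row) == 1 && row$sign == ifelse(planted_cm$sign[i] > 0,
                                         "positive", "negative")
  }, logical(1))
  nulls <- truth$comodulators$regulator_id[!truth$comodulators$planted]
  null_reported <- any(cm$sign[cm$regulator_id %in% nulls] != "none")

  ffl_tab <- res$ffl$table
  ffl3_p <- ffl_tab$three_node_p[match(truth$ffl3_mirnas, ffl_tab$mirna_id)]
  ffl4_p <- ffl_tab$four_node_p[match(truth$ffl4_mirnas, ffl_tab$mirna_id)]

  de <- res$mirna$diffexp
  planted_de <- truth$mirnas$mirna_id[truth$mirnas$lfc != 0]
  det <- de$probability[match(planted_de, de$mirna_id)] >= 0.6

  conv <- truth$convergent_genes
  conv_rec <- mean(conv %in% res$ffl$enriched_targets$significant)

  ebox_p <- if (!is.null(res$motifs)) {
    tab <- res$motifs$act_vs_rep
    tab$p_value[tab$motif == "CACGTG"]
  } else NA_real_

  list(direct_recovery = direct_recovery,
       comod_recovery = mean(match_sign),
       null_comod_reported = null_reported,
       ffl3_max_p = if (all(is.na(ffl3_p))) NA_real_ else max(ffl3_p, na.rm = TRUE),
       ffl4_max_p = if (all(is.na(ffl4_p))) NA_real_ else max(ffl4_p, na.rm = TRUE),
       mirna_detected = mean(det, na.rm = TRUE),
       logrank_p = if (!is.null(res$survival)) res$survival$logrank$p_value
       else NA_real_,
       convergent_recovery = conv_rec,
       ebox_activated_p = ebox_p)
}
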