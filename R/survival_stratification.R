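# Consensus k-means over a gene-expression signature and Kaplan-Meier /
# log-rank comparison of the resulting patient groups.

#' Consensus k-means clustering of samples over a gene signature
#'
#' Runs k-means `runs` times with different random initial centers on
#' per-gene standardized expression (samples as observations), aligns each
#' run's labels to a reference run by maximum agreement, and assigns each
#' sample its majority label. Stability is the fraction of runs agreeing
#' with the consensus.
#'
#' @param expr Expression matrix restricted to the signature genes (genes x
#'   samples); genes with zero variance are dropped.
#' @param k Number of clusters (default 2).
#' @param runs Number of k-means restarts (default 1000).
#' @param seed Optional integer; when given, makes the restarts reproducible.
#' @return List with `groups` (named integer labels per sample), `stability`
#'   (named fraction per sample) and `sizes`.
#' @export
consensus_kmeans <- function(expr, k = 2, runs = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  if (ncol(expr) < k) stop("Fewer samples than clusters")
  keep <- apply(expr, 1, stats::sd) > 0
  z <- t(scale(t(expr[keep, , drop = FALSE])))  # per-gene z-score
  x <- t(z)                                      # samples x genes
  n <- nrow(x)
  labels <- matrix(NA_integer_, nrow = runs, ncol = n)
  for (r in seq_len(runs)) {
    km <- stats::kmeans(x, centers = k, nstart = 1, iter.max = 50)
    labels[r, ] <- km$cluster
  }
  ref <- labels[1, ]
  perms <- all_permutations(k)
  for (r in seq(2, length.out = runs - 1)) {
    agree <- vapply(perms, function(p) sum(p[labels[r, ]] == ref), numeric(1))
    labels[r, ] <- perms[[which.max(agree)]][labels[r, ]]
  }
  groups <- apply(labels, 2, function(v) {
    tab <- tabulate(v, nbins = k)
    which.max(tab)
  })
  stability <- vapply(seq_len(n), function(i) mean(labels[, i] == groups[i]),
                      numeric(1))
  names(groups) <- names(stability) <- colnames(expr)
  list(groups = groups, stability = stability,
       sizes = as.integer(tabulate(groups, nbins = k)))
}

# All permutations of 1..k as a list of integer vectors (k is tiny).
all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1)
  out <- list()  # insert k at every position of each (k-1)-permutation
  for (p in sub) for (pos in 0:(k - 1)) {
    out[[length(out) + 1]] <- as.integer(append(p, k, after = pos))
  }
  out
}

#' Kaplan-Meier curves and log-rank test between sample groups
#'
#' Product-limit survival estimate per group and the two-group (or k-group)
#' log-rank chi-square test.
#'
#' @param groups Named vector of group labels (names are sample ids).
#' @param survival_table `data.frame` with `sample_id`, `efs_time`,
#'   `efs_event` (see [read_survival()]).
#' @return List with `chisq`, `df`, `p_value`, `curves` (`data.frame` of
#'   step coordinates: group / time / surv / n_risk / n_event) and `fit`
#'   (the `survfit` object).
#' @export
km_logrank <- function(groups, survival_table) {
  st <- survival_table[match(names(groups), survival_table$sample_id), ]
  if (any(is.na(st$sample_id)))
    stop("Samples missing from the survival table: ",
         paste(names(groups)[is.na(st$sample_id)], collapse = ", "))
  if (sum(st$efs_event) == 0) stop("Zero events: log-rank test undefined")
  grp <- factor(groups)
  if (nlevels(grp) < 2) stop("Need at least two groups")
  surv <- survival::Surv(st$efs_time, st$efs_event)
  sd_fit <- survival::survdiff(surv ~ grp)
  df <- length(sd_fit$n) - 1
  p <- stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE)
  fit <- survival::survfit(surv ~ grp)
  strata_lab <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^grp=", "", strata_lab),
                       time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       stringsAsFactors = FALSE)
  list(chisq = unname(sd_fit$chisq), df = df, p_value = p,
       curves = curves, fit = fit)
}
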