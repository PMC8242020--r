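# Shared inferential machinery: label-shuffling permutation nulls with
# pooled-datapoint thresholds, repeated-measures ANOVA with partial eta
# squared, and the single-trial correlation / multiple-regression analyses.

#' Label-shuffling permutation contrast
#'
#' Builds the null distribution of a two-condition contrast (mean of the
#' second level minus mean of the first, per datapoint) by reshuffling the
#' per-trial condition labels. Two input forms:
#'
#' * a single unit: `values` a datapoints x trials matrix (or a vector, one
#'   datapoint) with one label vector;
#' * a list of units (pairs): labels are shuffled *within* each unit --
#'   preserving the pairing of simultaneous data -- the grand-mean contrast
#'   is recomputed across units, and the pooled null collects every
#'   datapoint of every permutation.
#'
#' `pooling = "pooled_datapoints"` thresholds each cell against the alpha/2
#' and 1 - alpha/2 quantiles of the pooled null (each datapoint contributes
#' to the null distribution); `"max_stat"` uses the stricter distribution of
#' the per-permutation maximum absolute contrast. With `n_perm =
#' "exhaustive"` (single unit, one datapoint) all label assignments are
#' enumerated and the p-value is the exact proportion of assignments at
#' least as extreme as the observed one; Monte-Carlo p-values use the
#' (1 + k) / (1 + B) convention.
#'
#' @param values matrix/vector, or list of such (one per unit).
#' @param labels label vector, or list of such; exactly two levels.
#' @param levels order of levels: contrast = mean(`levels[2]`) -
#'   mean(`levels[1]`). Defaults to the sorted unique labels.
#' @param alpha two-tailed significance level.
#' @param n_perm number of permutations, or `"exhaustive"`.
#' @param seed RNG seed.
#' @param pooling `"pooled_datapoints"` or `"max_stat"`.
#' @return A `permutation_result`: `observed` (per datapoint), `null`
#'   (pooled values or max-stats), `lo`, `hi` (thresholds), `mask`,
#'   `p` (scalar contrasts only), `alpha`, `n_perm`, `seed`.
#' @export
#' @examples
#' r <- permutation_contrast(c(1, 1, 0, 0), c("A", "A", "B", "B"),
#'                           levels = c("B", "A"), n_perm = "exhaustive")
#' r$p    # 2/6
permutation_contrast <- function(values, labels, levels = NULL,
                                 alpha = 0.05, n_perm = 1000, seed = 1,
                                 pooling = c("pooled_datapoints",
                                             "max_stat")) {
  pooling <- match.arg(pooling)
  listed <- is.list(values) && !is.data.frame(values)
  vlist <- if (listed) values else list(values)
  llist <- if (listed) labels else list(labels)
  vlist <- lapply(vlist, function(v)
    if (is.null(dim(v))) matrix(v, nrow = 1L) else as.matrix(v))
  if (is.null(levels)) levels <- sort(unique(unlist(llist)))
  if (length(levels) != 2L) stop("labels must have exactly two levels")
  for (i in seq_along(llist)) {
    tb <- table(factor(llist[[i]], levels))
    if (any(tb < 2L)) stop("need at least 2 trials per label in every unit")
  }
  exhaustive <- identical(n_perm, "exhaustive")
  if (exhaustive && (listed && length(vlist) > 1L))
    stop("exhaustive enumeration supports a single unit")
  if (!exhaustive && n_perm < 100L)
    message("permutation count below 100; thresholds will be coarse")

  na0 <- function(m) { m[is.na(m)] <- 0; m }
  wts <- lapply(vlist, function(v) (!is.na(v)) * 1)
  v0 <- lapply(vlist, na0)
  contrast_for <- function(u, lab) {
    b <- lab == levels[2]
    mb <- (v0[[u]] %*% b) / pmax(wts[[u]] %*% b, 1e-12)
    ma <- (v0[[u]] %*% !b) / pmax(wts[[u]] %*% !b, 1e-12)
    drop(mb - ma)
  }
  observed <- Reduce(`+`, lapply(seq_along(vlist), function(u)
    contrast_for(u, llist[[u]]))) / length(vlist)

  d <- length(observed)
  if (exhaustive) {
    lab <- llist[[1]]
    n <- length(lab); nb <- sum(lab == levels[2])
    combos <- utils::combn(n, nb)
    null <- apply(combos, 2L, function(ix) {
      l2 <- rep(levels[1], n); l2[ix] <- levels[2]
      contrast_for(1L, l2)
    })
    null <- matrix(null, nrow = d)
    n_used <- ncol(null)
  } else {
    set.seed(as.integer(seed))
    null <- matrix(0, d, n_perm)
    for (p in seq_len(n_perm)) {
      acc <- 0
      for (u in seq_along(vlist))
        acc <- acc + contrast_for(u, sample(llist[[u]]))
      null[, p] <- acc / length(vlist)
    }
    n_used <- n_perm
  }

  if (pooling == "pooled_datapoints") {
    pool <- as.vector(null)
    lo <- stats::quantile(pool, alpha / 2, names = FALSE)
    hi <- stats::quantile(pool, 1 - alpha / 2, names = FALSE)
    mask <- observed < lo | observed > hi
  } else {
    pool <- apply(abs(null), 2L, max)
    hi <- stats::quantile(pool, 1 - alpha, names = FALSE)
    lo <- -hi
    mask <- abs(observed) > hi
  }
  p <- if (d == 1L) {
    k <- sum(abs(null[1, ]) >= abs(observed) - 1e-12)
    if (exhaustive) k / n_used else (1 + k) / (1 + n_used)
  } else NA_real_
  structure(list(observed = observed, null = pool, lo = lo, hi = hi,
                 mask = mask, p = p, alpha = alpha, n_perm = n_used,
                 seed = if (exhaustive) NA else seed, pooling = pooling),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation contrast: %d datapoint(s), %d permutations (%s pooling)\n",
    length(x$observed), x$n_perm, x$pooling))
  cat(sprintf("  thresholds [%.4g, %.4g] at alpha = %g; %d significant cell(s)\n",
              x$lo, x$hi, x$alpha, sum(x$mask, na.rm = TRUE)))
  if (!is.na(x$p)) cat(sprintf("  two-tailed p = %.4g\n", x$p))
  invisible(x)
}

#' Repeated-measures ANOVA with partial eta squared
#'
#' One- or two-way within-subject ANOVA on cell means, delegated to
#' `stats::aov` with subject error strata. Partial eta squared is computed
#' per effect as SS_effect / (SS_effect + SS_error-of-its-stratum).
#'
#' @param data long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject/pair identifier column.
#' @param factors character vector of one or two within-subject factor
#'   columns (the design must be complete).
#' @return data.frame, one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `p`, `pes` (partial eta squared).
#' @export
rm_anova <- function(data, dv, subject, factors) {
  stopifnot(length(factors) %in% 1:2,
            all(c(dv, subject, factors) %in% names(data)))
  data[[subject]] <- factor(data[[subject]])
  for (f in factors) data[[f]] <- factor(data[[f]])
  cells <- table(data[[subject]],
                 interaction(data[factors], drop = FALSE))
  if (any(cells != 1L))
    stop("design must be complete with one cell mean per subject x cell")
  rhs <- paste(factors, collapse = " * ")
  err <- paste0("Error(", subject, "/(", rhs, "))")
  fml <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- stats::aov(fml, data = data)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    resid_row <- which(rn == "Residuals")
    if (!length(resid_row) || length(rn) < 2L) next
    ss_err <- tab[resid_row, "Sum Sq"]
    for (i in setdiff(seq_along(rn), resid_row)) {
      out[[length(out) + 1L]] <- data.frame(
        effect = rn[i], df1 = tab[i, "Df"], df2 = tab[resid_row, "Df"],
        F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
        pes = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + ss_err))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Single-trial correlations between neural coupling and behaviour
#'
#' Per pair and condition, the Pearson correlation across trials between
#' the coupling value at the peak spatiotemporal slice and a behavioural
#' metric; at the group level, a paired t-test contrasting the joint and
#' solo correlations and single-sample t-tests against zero per condition.
#' Pairs with fewer than `min_trials` complete trials in a condition are
#' excluded (logged in the output).
#'
#' @param trials data.frame with columns `pair`, `condition` (solo/joint),
#'   `coupling`, and the metric column.
#' @param metric name of the metric column.
#' @param min_trials minimum complete trials per pair x condition.
#' @return List `per_pair` (pair x condition r values), `group`
#'   (data.frame of t-tests: paired joint vs solo, and each condition vs 0),
#'   `excluded` (pairs dropped, with reason).
#' @export
single_trial_coupling_correlations <- function(trials, metric,
                                               min_trials = 10L) {
  stopifnot(all(c("pair", "condition", "coupling", metric) %in% names(trials)))
  ok <- is.finite(trials$coupling) & is.finite(trials[[metric]])
  trials <- trials[ok, ]
  res <- excluded <- list()
  for (p in unique(trials$pair)) {
    for (cond in c("solo", "joint")) {
      d <- trials[trials$pair == p & trials$condition == cond, ]
      if (nrow(d) < min_trials) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          pair = p, condition = cond, n = nrow(d),
          reason = "insufficient trials")
        next
      }
      r <- if (stats::sd(d$coupling) == 0 || stats::sd(d[[metric]]) == 0)
        NA_real_ else stats::cor(d$coupling, d[[metric]])
      res[[length(res) + 1L]] <- data.frame(pair = p, condition = cond,
                                            r = r, n = nrow(d))
    }
  }
  per_pair <- do.call(rbind, res)
  excluded <- if (length(excluded)) do.call(rbind, excluded) else NULL
  wide <- merge(per_pair[per_pair$condition == "joint", c("pair", "r")],
                per_pair[per_pair$condition == "solo", c("pair", "r")],
                by = "pair", suffixes = c("_joint", "_solo"))
  tt <- function(x, y = NULL, paired = FALSE) {
    t <- tryCatch(
      if (paired) stats::t.test(x, y, paired = TRUE) else stats::t.test(x),
      error = function(e) NULL)        # degenerate (constant / n < 2) input
    if (is.null(t))
      return(data.frame(t = NA_real_, df = NA_real_, p = NA_real_,
                        mean = mean(if (paired) x - y else x, na.rm = TRUE)))
    data.frame(t = unname(t$statistic), df = unname(t$parameter),
               p = t$p.value, mean = unname(t$estimate[1]))
  }
  group <- rbind(
    cbind(test = "joint_vs_solo", tt(wide$r_joint, wide$r_solo, paired = TRUE)),
    cbind(test = "joint_vs_zero", tt(wide$r_joint)),
    cbind(test = "solo_vs_zero", tt(wide$r_solo)))
  list(per_pair = per_pair, group = group, excluded = excluded)
}

#' Single-trial multiple regression on neural coupling
#'
#' Per pair, an ordinary-least-squares regression of the per-trial coupling
#' value on standardised behavioural predictors (all variables z-scored
#' within pair, so coefficients are standardised beta weights). Betas are
#' averaged across pairs and tested against zero with one-sample t-tests
#' under Bonferroni familywise control (alpha / number of predictors).
#' Unique variance per predictor is reported as the mean squared
#' semi-partial correlation.
#'
#' @param trials data.frame with `pair`, `coupling`, and predictor columns.
#' @param predictors character vector of predictor column names.
#' @param alpha familywise alpha (default 0.05; per-predictor threshold
#'   alpha / k, e.g. 0.0125 for four predictors).
#' @return List `per_pair` (pair x predictor beta matrix), `group`
#'   (data.frame: `predictor`, `beta_mean`, `beta_sd`, `t`, `df`, `p`,
#'   `significant` under Bonferroni, `unique_variance_pct`), `excluded`.
#' @export
single_trial_regression <- function(trials, predictors, alpha = 0.05) {
  stopifnot(all(c("pair", "coupling", predictors) %in% names(trials)))
  k <- length(predictors)
  betas <- sr2 <- excluded <- list()
  for (p in unique(trials$pair)) {
    d <- trials[trials$pair == p, c("coupling", predictors)]
    d <- d[stats::complete.cases(d), ]
    if (nrow(d) < k + 2L) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        pair = p, reason = "insufficient trials")
      next
    }
    z <- as.data.frame(lapply(d, function(v) {
      s <- stats::sd(v); if (s == 0) v * 0 else (v - mean(v)) / s
    }))
    X <- as.matrix(z[predictors])
    if (qr(cbind(1, X))$rank < k + 1L) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        pair = p, reason = "singular design")
      next
    }
    fit <- stats::lm(z$coupling ~ X)
    b <- stats::coef(fit)[-1]
    names(b) <- predictors
    # squared semi-partial correlation: t_j^2 * (1 - R^2) / df_resid
    sm <- summary(fit)
    tj <- sm$coefficients[-1, "t value"]
    s2 <- tj^2 * (1 - sm$r.squared) / fit$df.residual
    names(s2) <- predictors
    betas[[length(betas) + 1L]] <- b
    sr2[[length(sr2) + 1L]] <- s2
  }
  if (!length(betas)) stop("no pair yielded an estimable regression")
  B <- do.call(rbind, betas)
  S <- do.call(rbind, sr2)
  group <- do.call(rbind, lapply(predictors, function(pr) {
    t <- tryCatch(stats::t.test(B[, pr]), error = function(e) NULL)
    data.frame(predictor = pr, beta_mean = mean(B[, pr]),
               beta_sd = stats::sd(B[, pr]),
               t = if (is.null(t)) NA_real_ else unname(t$statistic),
               df = if (is.null(t)) NA_real_ else unname(t$parameter),
               p = if (is.null(t)) NA_real_ else t$p.value,
               significant = !is.null(t) && t$p.value <= alpha / k,
               unique_variance_pct = 100 * mean(S[, pr]))
  }))
  list(per_pair = B, group = group,
       excluded = if (length(excluded)) do.call(rbind, excluded) else NULL,
       alpha_per_test = alpha / k)
}
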