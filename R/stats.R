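#' Per-animal metric values grouped by dose, with a designated control
#'
#' @param groups Named list of numeric vectors, one per dose group; each
#'   group needs at least two animals.
#' @param metric Metric name (informational).
#' @param control Name of the control group (default `"saline"`).
#' @return A `grouped_metric`.
#' @export
grouped_metric <- function(groups, metric = "metric", control = "saline") {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (!control %in% names(groups))
    stop("control group '", control, "' not present", call. = FALSE)
  ns <- vapply(groups, length, 0L)
  if (any(ns < 2L))
    stop("every group needs n >= 2 (violated by: ",
         paste(names(groups)[ns < 2L], collapse = ", "), ")", call. = FALSE)
  structure(list(groups = lapply(groups, as.numeric), metric = metric,
                 control = control),
            class = "grouped_metric")
}

#' Fixed-effect one-way ANOVA
#'
#' Classical between/within decomposition across all dose groups (control
#' included).
#'
#' @param gm A [grouped_metric()].
#' @return An `anova_result`: list with `F`, `df_between`, `df_within`, `p`,
#'   and a `groups` data.frame of per-group n, mean and SEM.
#' @export
one_way_anova <- function(gm) {
  stopifnot(inherits(gm, "grouped_metric"))
  g <- gm$groups
  ns <- vapply(g, length, 0L)
  means <- vapply(g, mean, 0)
  grand <- sum(unlist(g)) / sum(ns)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  df_b <- length(g) - 1L
  df_w <- sum(ns) - length(g)
  if (df_w < 1L) stop("no within-group degrees of freedom", call. = FALSE)
  if (ss_within <= 0 && ss_between <= 0)
    stop("all values identical; ANOVA undefined", call. = FALSE)
  F_stat <- (ss_between / df_b) / (ss_within / df_w)
  structure(list(
    metric = gm$metric, F = F_stat, df_between = df_b, df_within = df_w,
    p = stats::pf(F_stat, df_b, df_w, lower.tail = FALSE),
    groups = data.frame(group = names(g), n = ns, mean = means,
                        sem = vapply(g, function(v) stats::sd(v) / sqrt(length(v)), 0),
                        row.names = NULL)),
    class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %s: F(%d, %d) = %.4g, p = %.4g\n",
              x$metric, x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Dunnett's multiple comparisons against the control
#'
#' Two-sided comparisons of every treatment group mean against the control,
#' adjusted over the max-|t| multivariate-t null with the correlation
#' structure implied by the group sizes.  With a single treatment group the
#' procedure reduces exactly to the two-sided pooled t-test.  For two or more
#' treatments the null distribution is evaluated by Monte Carlo with a fixed
#' internal seed (`n_draws` draws), so results are reproducible to about
#' three decimals; adjusted p-values are floored at the raw p.
#'
#' @param gm A [grouped_metric()].
#' @param n_draws Monte Carlo draws for the max-|t| null.
#' @return data.frame with one row per treatment group: `group`, `diff`
#'   (mean - control mean), `t`, `p_raw`, `p_adj`.
#' @export
dunnett_vs_control <- function(gm, n_draws = 1e6) {
  stopifnot(inherits(gm, "grouped_metric"))
  ctrl <- gm$groups[[gm$control]]
  trt <- gm$groups[names(gm$groups) != gm$control]
  k <- length(trt)
  n0 <- length(ctrl)
  ns <- vapply(trt, length, 0L)
  df <- n0 + sum(ns) - (k + 1L)
  s2 <- (sum((ctrl - mean(ctrl))^2) +
           sum(vapply(trt, function(v) sum((v - mean(v))^2), 0))) / df
  diffs <- vapply(trt, mean, 0) - mean(ctrl)
  tstat <- diffs / sqrt(s2 * (1 / ns + 1 / n0))
  p_raw <- 2 * stats::pt(-abs(tstat), df)
  if (k == 1L) {
    p_adj <- p_raw # documented limit: single treatment = two-sided t-test
  } else {
    lam <- sqrt(ns / (ns + n0))
    p_adj <- with_seed(195591L, {
      z0 <- stats::rnorm(n_draws)
      maxabs <- rep(0, n_draws)
      for (j in seq_len(k)) {
        tj <- lam[j] * z0 + sqrt(1 - lam[j]^2) * stats::rnorm(n_draws)
        maxabs <- pmax(maxabs, abs(tj))
      }
      maxabs <- maxabs / sqrt(stats::rchisq(n_draws, df) / df)
      vapply(abs(tstat), function(q) mean(maxabs >= q), 0)
    })
    p_adj <- pmin(1, pmax(p_adj, p_raw))
  }
  data.frame(group = names(trt), diff = unname(diffs), t = unname(tstat),
             p_raw = unname(p_raw), p_adj = unname(p_adj), row.names = NULL)
}

#' Sidak family-wise adjustment
#'
#' @param p Raw p-value(s) in `[0, 1]`.
#' @param m Family size, >= 1.
#' @return `1 - (1 - p)^m`, clipped to `[0, 1]`.
#' @export
sidak_adjust <- function(p, m) {
  if (any(m < 1)) stop("family size m must be >= 1", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must be in [0, 1]", call. = FALSE)
  pmin(pmax(1 - (1 - p)^m, 0), 1) # operand order preserves dims
}

#' Two-way treatment-by-time ANOVA with Sidak per-bin contrasts
#'
#' Fits an ordinary fixed-effects two-way ANOVA (treatment x time bin, with
#' interaction) to per-session binned metric values, then compares every
#' dose against the control within each bin using the pooled residual
#' variance.  The per-bin p-values are Sidak-adjusted within the chosen
#' family: across the bins of each dose row (default, matching a row-wise
#' reading of the published heatmaps), across the whole table, or across
#' doses within each bin.
#'
#' @param data Long data.frame with columns `session`, `group`, `bin_start`
#'   (seconds) and `value`, one row per session x bin.
#' @param control Control group label.
#' @param family Sidak family: `"per_row"`, `"per_table"` or `"per_column"`.
#' @return A `timecourse_fit`: list with `anova` (effect table), `p_raw` and
#'   `p_adj` (dose x bin matrices, columns labelled by bin end in minutes),
#'   `cell_means`, `mse`, `df_resid`.
#' @export
two_way_anova_timecourse <- function(data, control = "saline",
                                     family = c("per_row", "per_table",
                                                "per_column")) {
  family <- match.arg(family)
  stopifnot(all(c("session", "group", "bin_start", "value") %in% names(data)))
  if (!control %in% data$group)
    stop("control group '", control, "' not in data", call. = FALSE)
  data <- data[!is.na(data$value), ]
  data$group <- factor(data$group)
  data$bin <- factor(data$bin_start, levels = sort(unique(data$bin_start)))
  fit <- stats::lm(value ~ group * bin, data = data)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  dfr <- an["Residuals", "Df"]
  means <- tapply(data$value, list(data$group, data$bin), mean)
  counts <- tapply(data$value, list(data$group, data$bin), length)
  doses <- setdiff(rownames(means), control)
  bins <- colnames(means)
  p_raw <- matrix(NA_real_, length(doses), length(bins),
                  dimnames = list(doses, bins))
  for (d in doses) for (b in bins) {
    n1 <- counts[d, b]; n0 <- counts[control, b]
    if (is.na(n1) || is.na(n0) || n1 < 1 || n0 < 1) next # flagged, not imputed
    tt <- (means[d, b] - means[control, b]) / sqrt(mse * (1 / n1 + 1 / n0))
    p_raw[d, b] <- 2 * stats::pt(-abs(tt), dfr)
  }
  m <- switch(family,
              per_row = matrix(rowSums(!is.na(p_raw)), nrow(p_raw),
                               ncol(p_raw)),
              per_column = matrix(colSums(!is.na(p_raw)), nrow(p_raw),
                                  ncol(p_raw), byrow = TRUE),
              per_table = matrix(sum(!is.na(p_raw)), nrow(p_raw), ncol(p_raw)))
  p_adj <- sidak_adjust(p_raw, pmax(m, 1))
  lab <- as.character(round((as.numeric(bins) + 300) / 60)) # bin end, minutes
  colnames(p_raw) <- colnames(p_adj) <- lab
  structure(list(anova = an, p_raw = p_raw, p_adj = p_adj,
                 cell_means = means, mse = mse, df_resid = dfr,
                 family = family, control = control),
            class = "timecourse_fit")
}

#' Render a p-value heatmap table in the published format
#'
#' Clips adjusted p-values into `[0.0001, 0.9999]` (the printed range of the
#' published tables) and orders dose rows from high to low.  Full-precision
#' values remain available in the `timecourse_fit`.
#'
#' @param fit A `timecourse_fit`, or a numeric dose x bin matrix.
#' @return Numeric matrix of clipped adjusted p-values.
#' @export
pvalue_heatmap <- function(fit) {
  p <- if (inherits(fit, "timecourse_fit")) fit$p_adj else as.matrix(fit)
  p <- pmin(pmax(p, 1e-4), 0.9999)
  dose_num <- suppressWarnings(
    as.numeric(sub(".* ", "", rownames(p)))) # last token = dose in mg/kg
  if (!anyNA(dose_num))
    p <- p[order(dose_num, decreasing = TRUE), , drop = FALSE]
  p
}
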