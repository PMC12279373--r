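#' Label-randomization bootstrap null for unilateral activation
#'
#' Builds the null distribution of mean "ipsilateral" rotational velocity
#' expected when expression side is unrelated to steering: per replicate,
#' control flies (bilateral expression) are resampled with replacement and
#' each is randomly labeled "right expression" or "left expression" (a label
#' flip negates the fly's signed rotational velocity); the replicate statistic
#' is the mean ipsilateral velocity. The percentile interval of the replicate
#' statistics is the confidence interval of the mean under the null; an
#' observed unilateral mean outside it is significant.
#'
#' @param control_fly_means Signed per-fly mean rotational velocities of the
#'   control (bilateral) flies; length >= 2.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param observed Optional observed unilateral mean to test.
#' @param fixed_labels If `TRUE`, labels are drawn once per replicate fly set
#'   from the original flies and reused (sensitivity variant); default
#'   re-randomizes labels independently within each replicate.
#' @return A list: `interval` (length 2), `null` (replicate statistics),
#'   `level`, `degenerate` flag, and if `observed` is given, `observed` and
#'   `significant`.
#' @export
bootstrap_unilateral_null <- function(control_fly_means, n_boot = 1000,
                                      level = 0.95, observed = NULL,
                                      fixed_labels = FALSE) {
  x <- as.numeric(control_fly_means)
  n <- length(x)
  if (n < 2) stop("need at least 2 control flies")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (fixed_labels) {
    labels <- sample(c(-1, 1), n, replace = TRUE)
    stat <- replicate(n_boot, mean((labels * x)[sample.int(n, n, replace = TRUE)]))
  } else {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    signs <- matrix(sample(c(-1, 1), n * n_boot, replace = TRUE), nrow = n)
    stat <- colMeans(signs * matrix(x[idx], nrow = n))
  }
  interval <- unname(stats::quantile(stat, probs))
  degenerate <- interval[1] == interval[2]
  out <- list(interval = interval, null = stat, level = level,
              degenerate = degenerate)
  if (degenerate) warning("degenerate bootstrap interval (zero variance)")
  if (!is.null(observed)) {
    out$observed <- observed
    out$significant <- observed < interval[1] || observed > interval[2]
  }
  out
}

#' Two-factor genotype-by-light ANOVA with Holm correction and Tukey post hoc
#'
#' Per metric: flies contributing fewer than `min_windows` windows are
#' dropped, a fixed-effects two-factor ANOVA with interaction
#' (`value ~ genotype * light`) is fitted on the windows, and the
#' genotype-by-light interaction p-values are Holm-corrected across the
#' metrics (`m_tests`). Where the corrected interaction is significant, a
#' Tukey HSD post hoc compares light on/off within each genotype.
#'
#' @param windows Data.frame with columns `value`, `metric`, `genotype`,
#'   `light`, `fly_id`.
#' @param m_tests Number of tests for the Holm correction; defaults to the
#'   number of distinct metrics.
#' @param alpha Significance level for gating the post hoc (default 0.05).
#' @param min_windows Minimum windows a fly must contribute (default 5).
#' @return A list: `table` (data.frame: metric, p_interaction, p_corrected,
#'   significant, n_windows, n_flies) and `tukey` (named list of within-
#'   genotype light-on/off contrasts for significant metrics).
#' @export
anova_genotype_light <- function(windows, m_tests = NULL, alpha = 0.05,
                                 min_windows = 5) {
  need <- c("value", "metric", "genotype", "light", "fly_id")
  stopifnot(all(need %in% names(windows)))
  metrics <- unique(windows$metric)
  if (is.null(m_tests)) m_tests <- length(metrics)
  rows <- list(); fits <- list()
  for (m in metrics) {
    d <- windows[windows$metric == m & is.finite(windows$value), , drop = FALSE]
    tab <- table(d$fly_id)
    d <- d[d$fly_id %in% names(tab)[tab >= min_windows], , drop = FALSE]
    d$genotype <- factor(d$genotype)
    d$light <- factor(d$light)
    fit <- stats::aov(value ~ genotype * light, data = d)
    p <- summary(fit)[[1]][["Pr(>F)"]][3]
    rows[[m]] <- data.frame(metric = m, p_interaction = p,
                            n_windows = nrow(d),
                            n_flies = length(unique(d$fly_id)))
    fits[[m]] <- d
  }
  tabl <- do.call(rbind, rows)
  tabl$p_corrected <- stats::p.adjust(tabl$p_interaction, method = "holm",
                                      n = max(m_tests, nrow(tabl)))
  tabl$significant <- tabl$p_corrected < alpha
  tukey <- list()
  for (m in tabl$metric[tabl$significant]) {
    d <- fits[[m]]
    d$cell <- interaction(d$genotype, d$light)
    hsd <- stats::TukeyHSD(stats::aov(value ~ cell, data = d))$cell
    cn <- rownames(hsd)
    # keep only within-genotype light on/off contrasts
    within <- vapply(strsplit(cn, "-"), function(pair) {
      g <- vapply(strsplit(pair, ".", fixed = TRUE), `[`, "", 1)
      g[1] == g[2]
    }, logical(1))
    tukey[[m]] <- hsd[within, , drop = FALSE]
  }
  rownames(tabl) <- NULL
  list(table = tabl, tukey = tukey)
}

#' Variance attributable to fly identity
#'
#' Fits a two-factor ANOVA with fly ID and light as factors and reports the
#' fraction of total sum of squares attributable to fly ID; the analysis
#' framework assumes this fraction is small relative to total variance.
#'
#' @param windows Data.frame with columns `value`, `light`, `fly_id`.
#' @param max_fraction Flagging threshold (default 0.2).
#' @return A list: `fraction` (`NA` for constant data, flagged), `flag`
#'   (`TRUE` when the fraction exceeds `max_fraction` or is undefined),
#'   `anova` (the aov summary table).
#' @export
fly_id_variance_check <- function(windows, max_fraction = 0.2) {
  stopifnot(all(c("value", "light", "fly_id") %in% names(windows)))
  d <- windows[is.finite(windows$value), , drop = FALSE]
  if (stats::var(d$value) == 0) {
    return(list(fraction = NA_real_, flag = TRUE, anova = NULL))
  }
  d$fly_id <- factor(d$fly_id)
  d$light <- factor(d$light)
  fit <- stats::aov(value ~ fly_id + light, data = d)
  tab <- summary(fit)[[1]]
  ss <- tab[["Sum Sq"]]
  fraction <- ss[1] / sum(ss)
  list(fraction = fraction, flag = fraction > max_fraction, anova = tab)
}
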