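#' Normality-gated statistical battery for preference data
#'
#' Two tests, each Shapiro-Wilk gated at `alpha_normality`: a paired
#' comparison of social vs object exploration times (paired t-test, or the
#' Wilcoxon signed-rank test when the differences fail normality), and a
#' one-sample comparison of the preference index against the 0.5 chance
#' level (one-sample t-test, or Wilcoxon signed-rank against 0.5).
#' Degenerate constant inputs (all differences zero, all indices at
#' chance) are reported as statistic 0, p = 1.
#'
#' @param time_social,time_object Paired per-animal exploration times (s).
#' @param indices Optional per-animal preference indices; computed from the
#'   times when omitted.
#' @param alpha_normality Shapiro-Wilk gate level.
#' @return Data frame with one row per test: `test`, `statistic`, `df`,
#'   `p`, `n`, `normality_used`, `fallback_test`.
#' @export
preference_tests <- function(time_social, time_object, indices = NULL,
                             alpha_normality = 0.05) {
  n <- length(time_social)
  if (n < 3 || length(time_object) != n)
    stop_socphys("insufficient_n_error",
                 "need >= 3 paired observations")
  indices <- indices %||% preference_index(time_social, time_object)

  gated <- function(x, mu, test_label) {
    centered <- x - mu
    if (all(abs(centered - centered[1]) < 1e-12)) {
      # constant input: no variability to test
      stat <- 0; p <- if (abs(centered[1]) < 1e-12) 1 else 0
      return(data.frame(test = test_label, statistic = stat,
                        df = length(x) - 1, p = p, n = length(x),
                        normality_used = TRUE, fallback_test = "none"))
    }
    sw <- tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
    normal <- is.na(sw) || sw >= alpha_normality
    if (normal) {
      tt <- t.test(x, mu = mu)
      data.frame(test = test_label, statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value, n = length(x),
                 normality_used = TRUE, fallback_test = "none")
    } else {
      wt <- suppressWarnings(wilcox.test(x, mu = mu))
      data.frame(test = paste0(test_label, " (wilcoxon)"),
                 statistic = unname(wt$statistic), df = NA_real_,
                 p = wt$p.value, n = length(x),
                 normality_used = FALSE, fallback_test = "wilcoxon")
    }
  }

  rbind(
    gated(time_social - time_object, 0, "paired social vs object"),
    gated(indices, 0.5, "one-sample index vs 0.5")
  )
}

#' Repeated-measures two-way comparison of F-I curves
#'
#' Split-plot analysis of spike counts over current steps: `group`
#' (between cells) x `step` (repeated within cell). Between-subjects group
#' effect from the cell means; within-subject step effect and group x step
#' interaction from the multivariate linear model, with
#' Greenhouse-Geisser-corrected p-values reported alongside the
#' uncorrected ones. The Mauchly sphericity test gates which p-value is
#' recommended (`p_reported`); when the sphericity test cannot be computed
#' (few cells relative to steps), the uncorrected p is used and
#' `sphericity_p` is `NA`. Cells with missing steps are excluded listwise.
#'
#' @param fi_long Data frame with columns `cell`, `step_pA`, `n_ap`,
#'   `group`.
#' @return Data frame with rows `group`, `step`, `group:step`: `df1`,
#'   `df2`, `statistic` (F), `p`, `p_gg`, `sphericity_p`, `p_reported`,
#'   plus attribute `excluded_cells`.
#' @export
fi_comparison <- function(fi_long) {
  stopifnot(all(c("cell", "step_pA", "n_ap", "group") %in% names(fi_long)))
  steps <- sort(unique(fi_long$step_pA))
  wide <- reshape_fi_wide(fi_long, steps)
  complete <- complete.cases(wide$y)
  excluded <- wide$cell[!complete]
  y <- wide$y[complete, , drop = FALSE]
  grp <- factor(wide$group[complete])
  if (nlevels(grp) < 2)
    stop_socphys("parameter_error", "need >= 2 groups")

  # between-subjects: group effect on per-cell mean counts
  cm <- rowMeans(y)
  btw <- summary(aov(cm ~ grp))[[1]]
  row_group <- data.frame(
    effect = "group", df1 = btw$Df[1], df2 = btw$Df[2],
    statistic = btw$`F value`[1], p = btw$`Pr(>F)`[1],
    p_gg = NA_real_, sphericity_p = NA_real_)

  # within-subject: multivariate model over the step columns
  idata <- data.frame(step = factor(steps))
  mlm <- lm(y ~ grp)
  wtab <- tryCatch(
    anova(mlm, idata = idata, X = ~1, M = ~step, test = "Spherical"),
    error = function(e) NULL)
  sph_p <- tryCatch(
    mauchly.test(mlm, idata = idata, X = ~1, M = ~step)$p.value,
    error = function(e) NA_real_)
  if (is.null(wtab))
    stop_socphys("parameter_error",
                 "within-subject analysis failed (too few cells?)")
  wdf <- as.data.frame(wtab)
  # rows: (Intercept) = step main effect, grp = step x group interaction
  pick <- function(rn, label) {
    r <- wdf[rn, ]
    data.frame(effect = label, df1 = r$`num Df`, df2 = r$`den Df`,
               statistic = r$`F`, p = r$`Pr(>F)`,
               p_gg = r$`G-G Pr`, sphericity_p = sph_p)
  }
  res <- rbind(row_group,
               pick("(Intercept)", "step"),
               pick("grp", "group:step"))
  res$p_reported <- ifelse(
    !is.na(res$sphericity_p) & res$sphericity_p < 0.05 & !is.na(res$p_gg),
    res$p_gg, res$p)
  rownames(res) <- NULL
  attr(res, "excluded_cells") <- excluded
  res
}

reshape_fi_wide <- function(fi_long, steps) {
  cells <- as.character(unique(fi_long$cell))
  y <- matrix(NA_real_, length(cells), length(steps),
              dimnames = list(cells, paste0("pA", steps)))
  group <- character(length(cells))
  for (k in seq_along(cells)) {
    sub <- fi_long[fi_long$cell == cells[k], ]
    y[k, match(sub$step_pA, steps)] <- sub$n_ap
    group[k] <- as.character(sub$group[1])
  }
  list(y = y, group = group, cell = cells)
}

#' Median-absolute-deviation outlier screen
#'
#' Flags values farther than `cutoff` scaled MADs from the median. Flags
#' only: nothing is removed. With zero MAD (constant data) a warning is
#' issued and nothing is flagged.
#'
#' @param values Numeric vector, `n >= 4`.
#' @param method `"mad"` or `"none"` (no flags).
#' @param cutoff Multiples of the scaled MAD.
#' @return Logical vector of flags.
#' @export
outlier_screen <- function(values, method = c("mad", "none"), cutoff = 3.5) {
  method <- match.arg(method)
  if (length(values) < 4)
    stop_socphys("parameter_error", "outlier screen needs n >= 4")
  if (method == "none") return(rep(FALSE, length(values)))
  m <- mad(values)
  if (m == 0) {
    warning("zero MAD: no outliers flagged")
    return(rep(FALSE, length(values)))
  }
  abs(values - median(values)) > cutoff * m
}
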