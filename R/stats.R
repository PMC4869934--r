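# Group statistics and spectroscopy quantification: Kruskal-Wallis with
# Dunn post-hoc z tests, Levene's variance test, bootstrap cycle-effect
# summaries, Theil-Sen slope / Kd estimation, FCS molecule counting.

.check_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("every group needs n >= 2")
  groups
}

#' Kruskal-Wallis test with Dunn post-hoc pairwise comparisons
#'
#' Nonparametric one-way analysis on ranks: the Kruskal-Wallis H
#' statistic with tie correction, followed by Dunn's pairwise z tests
#' on mean ranks with a multiple-comparison adjustment over all tested
#' pairs (Bonferroni by default, i.e. the conventional "Dunn
#' correction").
#'
#' @param groups Named list of numeric vectors (each n >= 2).
#' @param alpha Significance level recorded in the result.
#' @param p_adjust_method Adjustment passed to [stats::p.adjust()].
#' @return An object of class `stat_result`: list with `test`,
#'   `statistic` (H), `df`, `p.value`, a `pairs` data frame (groups,
#'   z, raw and adjusted p, significance at `alpha`), and group `ns`.
#' @export
kruskal_dunn <- function(groups, alpha = 0.05,
                         p_adjust_method = "bonferroni") {
  groups <- .check_groups(groups)
  ns <- vapply(groups, length, integer(1))
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), ns)
  N <- length(x)
  r <- rank(x)
  rsum <- tapply(r, g, sum)[names(groups)]
  H <- 12 / (N * (N + 1)) * sum(rsum^2 / ns) - 3 * (N + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / tie_corr
  p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)

  rbar <- rsum / ns
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  pr <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
               (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  pair_df <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                        z = pr["z", ], p = pr["p", ])
  pair_df$p_adj <- pmin(1, stats::p.adjust(pair_df$p,
                                           method = p_adjust_method))
  pair_df$significant <- pair_df$p_adj < alpha
  structure(list(test = "Kruskal-Wallis with Dunn post-hoc",
                 statistic = unname(H), df = k - 1, p.value = p,
                 pairs = pair_df, ns = ns, alpha = alpha,
                 p_adjust_method = p_adjust_method),
            class = "stat_result")
}

#' Levene's test for equality of variances
#'
#' One-way ANOVA F statistic on absolute deviations from the group
#' centre (mean by default; the median option gives the
#' Brown-Forsythe variant).
#'
#' @param groups Named list of numeric vectors (each n >= 2).
#' @param center `"mean"` or `"median"`.
#' @param alpha Significance level recorded in the result.
#' @return A `stat_result` with the W statistic, degrees of freedom
#'   and p-value.
#' @export
levene_test <- function(groups, center = c("mean", "median"),
                        alpha = 0.05) {
  groups <- .check_groups(groups)
  center <- match.arg(center)
  cfun <- if (center == "mean") mean else stats::median
  z <- lapply(groups, function(g) abs(g - cfun(g)))
  ns <- vapply(z, length, integer(1))
  k <- length(z)
  N <- sum(ns)
  zbar_i <- vapply(z, mean, numeric(1))
  zbar <- sum(unlist(z)) / N
  num <- sum(ns * (zbar_i - zbar)^2) / (k - 1)
  den <- sum(vapply(z, function(zi) sum((zi - mean(zi))^2),
                    numeric(1))) / (N - k)
  W <- if (den == 0) 0 else num / den
  p <- if (den == 0) 1 else
    stats::pf(W, k - 1, N - k, lower.tail = FALSE)
  structure(list(test = paste0("Levene (center = ", center, ")"),
                 statistic = unname(W), df = c(k - 1, N - k),
                 p.value = p, ns = ns, alpha = alpha),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test, "\n")
  cat("  statistic =", signif(x$statistic, 5),
      " df =", paste(x$df, collapse = ", "),
      " p =", format.pval(x$p.value, digits = 4), "\n")
  cat("  group ns:", paste(names(x$ns), x$ns, sep = "=",
                           collapse = ", "), "\n")
  if (!is.null(x$pairs)) {
    cat("  pairwise (", x$p_adjust_method, "-adjusted):\n", sep = "")
    print(x$pairs, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Summary of TNF-alpha effects on cell-cycle duration
#'
#' Compares treated and untreated mitosis-to-mitosis durations:
#' difference of means, fractional difference, ratio of standard
#' deviations, and per-phase treated subsets against the untreated
#' population average, each with a seeded percentile bootstrap
#' confidence interval. Levene's test on the treated-vs-untreated
#' spread is included.
#'
#' @param untreated_h Numeric vector of untreated durations (h).
#' @param treated_h Numeric vector of treated durations (h).
#' @param phases Optional factor/character of phase-at-treatment
#'   labels aligned with `treated_h` (used for `G1/S` and `S`
#'   subsets).
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @return An object of class `cycle_effect_summary`: a list of effect
#'   estimates with `ci` attributes, subset tables and the Levene
#'   result. Uses the current RNG state; seed upstream for
#'   reproducibility.
#' @export
cycle_effect_summary <- function(untreated_h, treated_h, phases = NULL,
                                 n_boot = 2000, conf = 0.95) {
  stopifnot(length(untreated_h) >= 2, length(treated_h) >= 2)
  a <- (1 - conf) / 2
  boot_ci <- function(stat) {
    reps <- vapply(seq_len(n_boot), function(i) {
      stat(sample(untreated_h, replace = TRUE),
           sample(treated_h, replace = TRUE))
    }, numeric(1))
    stats::quantile(reps, c(a, 1 - a), names = FALSE, na.rm = TRUE)
  }
  mean_diff <- mean(treated_h) - mean(untreated_h)
  ci_diff <- boot_ci(function(u, t) mean(t) - mean(u))
  frac_diff <- mean_diff / mean(untreated_h)
  ci_frac <- boot_ci(function(u, t) (mean(t) - mean(u)) / mean(u))
  sd_ratio <- stats::sd(treated_h) / stats::sd(untreated_h)
  ci_sd <- boot_ci(function(u, t) stats::sd(t) / stats::sd(u))

  subsets <- NULL
  if (!is.null(phases)) {
    stopifnot(length(phases) == length(treated_h))
    subsets <- lapply(c("G1/S", "S"), function(ph) {
      sub <- treated_h[phases == ph]
      if (length(sub) < 2) {
        return(list(phase = ph, n = length(sub), mean_h = NA_real_,
                    frac_longer = NA_real_, ci = c(NA_real_, NA_real_)))
      }
      frac <- mean(sub) / mean(untreated_h) - 1
      reps <- vapply(seq_len(n_boot), function(i) {
        mean(sample(sub, replace = TRUE)) /
          mean(sample(untreated_h, replace = TRUE)) - 1
      }, numeric(1))
      list(phase = ph, n = length(sub), mean_h = mean(sub),
           frac_longer = frac,
           ci = stats::quantile(reps, c(a, 1 - a), names = FALSE))
    })
    names(subsets) <- c("G1/S", "S")
  }
  lev <- levene_test(list(untreated = untreated_h, treated = treated_h))
  structure(list(mean_diff_h = mean_diff, mean_diff_ci = ci_diff,
                 frac_diff = frac_diff, frac_diff_ci = ci_frac,
                 sd_ratio = sd_ratio, sd_ratio_ci = ci_sd,
                 subsets = subsets, levene = lev,
                 n_untreated = length(untreated_h),
                 n_treated = length(treated_h), conf = conf),
            class = "cycle_effect_summary")
}

#' @export
print.cycle_effect_summary <- function(x, ...) {
  fmt <- function(v, ci) sprintf("%.3g [%.3g, %.3g]", v, ci[1], ci[2])
  cat("cycle-duration effect summary (treated n =", x$n_treated,
      ", untreated n =", x$n_untreated, ")\n")
  cat("  mean difference (h):   ", fmt(x$mean_diff_h, x$mean_diff_ci), "\n")
  cat("  fractional difference: ", fmt(x$frac_diff, x$frac_diff_ci), "\n")
  cat("  SD ratio (trt/untrt):  ", fmt(x$sd_ratio, x$sd_ratio_ci), "\n")
  if (!is.null(x$subsets)) {
    for (s in x$subsets) {
      cat("  ", s$phase, "-treated subset (n = ", s$n,
          "): fractional lengthening ",
          if (is.na(s$frac_longer)) "NA" else fmt(s$frac_longer, s$ci),
          "\n", sep = "")
    }
  }
  cat("  Levene p (spread):     ",
      format.pval(x$levene$p.value, digits = 4), "\n")
  invisible(x)
}

#' Theil-Sen robust slope
#'
#' The median of all pairwise slopes (pairs with equal x skipped),
#' with a confidence interval from the rank order statistics of the
#' pairwise slopes (normal approximation to the Kendall score
#' variance).
#'
#' @param x,y Paired observations; at least two distinct `x`.
#' @param conf Confidence level.
#' @return List with `slope`, `ci` (length 2), `n` (points) and
#'   `n_pairs` (slopes used).
#' @export
theil_sen_slope <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2) stop("all x values are equal")
  n <- length(x)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  sl <- sort((dy / dx)[dx != 0])
  N <- length(sl)
  slope <- stats::median(sl)
  # rank-based CI on the ordered pairwise slopes (Sen 1968)
  varS <- n * (n - 1) * (2 * n + 5) / 18
  C <- stats::qnorm(1 - (1 - conf) / 2) * sqrt(varS)
  lo <- max(1L, floor((N - C) / 2))
  hi <- min(N, ceiling((N + C) / 2) + 1L)
  list(slope = slope, ci = c(sl[lo], sl[hi]), n = n, n_pairs = N)
}

#' Dissociation constant from FCCS concentration triplets
#'
#' For a bimolecular equilibrium, free-A times free-B equals Kd times
#' the complex concentration, so regressing `freeA * freeB` on the
#' complex concentration through the Theil-Sen estimator yields the Kd
#' as the slope.
#'
#' @param triplets Data frame with columns `freeA_nM`, `freeB_nM`,
#'   `complex_nM` (>= 2 rows).
#' @param conf Confidence level for the slope interval.
#' @return Object of class `kd_estimate` with `kd_nM`, `ci_nM`, `n`.
#' @export
estimate_kd <- function(triplets, conf = 0.95) {
  stopifnot(all(c("freeA_nM", "freeB_nM", "complex_nM") %in%
                names(triplets)), nrow(triplets) >= 2)
  ts <- theil_sen_slope(triplets$complex_nM,
                        triplets$freeA_nM * triplets$freeB_nM, conf)
  structure(list(kd_nM = ts$slope, ci_nM = ts$ci, n = ts$n,
                 conf = conf),
            class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf("Kd = %.3g nM  [%d%% CI %.3g, %.3g]  (n = %d)\n",
              x$kd_nM, round(100 * x$conf), x$ci_nM[1], x$ci_nM[2],
              x$n))
  invisible(x)
}

#' @export
coef.kd_estimate <- function(object, ...) c(kd_nM = object$kd_nM)

#' Whole-cell molecule count from FCS particle numbers
#'
#' Scales the mean particle numbers measured in the confocal volume to
#' the compartment volumes:
#' `count = n_nuc * V_nuc / V_conf + n_cyt * V_cyt / V_conf`.
#'
#' @param input List or `fcs_input` with `n_nuc`, `n_cyt` (mean
#'   particle numbers), `v_conf_fL`, `v_nuc_fL`, `v_cyt_fL`.
#' @return Whole-cell molecule count (numeric).
#' @export
molecules_per_cell <- function(input) {
  stopifnot(input$v_conf_fL > 0, input$v_nuc_fL > 0,
            input$v_cyt_fL > 0)
  if (input$n_nuc < 0 || input$n_cyt < 0)
    stop("particle numbers must be non-negative")
  input$n_nuc * input$v_nuc_fL / input$v_conf_fL +
    input$n_cyt * input$v_cyt_fL / input$v_conf_fL
}
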