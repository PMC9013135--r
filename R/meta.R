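## Per-country risk differences, DerSimonian-Laird random-effects
## meta-analysis, Mantel-Haenszel pooled odds ratios, and the
## burden-by-inequality country typology.

#' Poor vs non-poor risk difference for one country
#'
#' Weighted death rate among the poor minus that among the non-poor, per
#' 1000 live births, with an effective-sample-size SE and a normal CI.
#' Countries are classified pro-non-poor when the CI lies entirely above
#' 0, pro-poor when entirely below, otherwise insignificant.
#'
#' @param records child records for a single country (must contain both
#'   groups).
#' @param poor_cutoff passed to [dichotomize_wealth()].
#' @param conf_level confidence level (default 0.95).
#' @return a `country_rd` list: `country_id`, `rd`, `se`, `ci`,
#'   `rate_poor`, `rate_non_poor`, `n_poor`, `n_non_poor` (effective),
#'   `classification`.
#' @export
country_risk_difference <- function(records, poor_cutoff = 2L,
                                    conf_level = 0.95) {
  assert_records(records)
  cid <- as.character(records$country_id[1L])
  poor <- dichotomize_wealth(records$wealth_quintile, poor_cutoff)
  if (!any(poor) || !any(!poor))
    stop("country ", cid, ": one of the wealth groups is empty", call. = FALSE)
  pg <- weighted_prevalence(records$died[poor], records$weight[poor])
  ng <- weighted_prevalence(records$died[!poor], records$weight[!poor])
  rd <- pg$rate - ng$rate
  se <- sqrt(pg$se^2 + ng$se^2)
  ci <- norm_ci(rd, se, conf_level)
  cls <- if (ci[1L] > 0) "pro-non-poor" else if (ci[2L] < 0) "pro-poor"
         else "insignificant"
  structure(list(country_id = cid, rd = rd, se = se, ci = ci,
                 rate_poor = pg$rate, rate_non_poor = ng$rate,
                 n_poor = pg$n_eff, n_non_poor = ng$n_eff,
                 classification = cls),
            class = "country_rd")
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Inverse-variance fixed effect, Cochran's Q, the moment estimator
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`, random-effects
#' weights `1 / (se^2 + tau2)` and `I2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param estimates per-study effect estimates (any scale).
#' @param ses per-study standard errors (> 0).
#' @param conf_level confidence level (default 0.95).
#' @return a `meta_result` list with `fixed` and `random` (each
#'   `c(est, se, lower, upper)`), `tau2`, `Q`, `df`, `I2`,
#'   `weights_fixed`, `weights_random` (percents summing to 100), `k`.
#' @export
dl_random_effects <- function(estimates, ses, conf_level = 0.95) {
  k <- length(estimates)
  stopifnot(k >= 1L, length(ses) == k, all(ses > 0), all(is.finite(estimates)))
  w <- 1 / ses^2
  fixed <- sum(w * estimates) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  Q <- sum(w * (estimates - fixed)^2)
  df <- k - 1L
  if (k == 1L) {
    warning("single study: pooled estimate equals the study; heterogeneity undefined")
    tau2 <- 0
    I2 <- 0
  } else {
    tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
    I2 <- max(0, (Q - df) / Q) * 100
    if (!is.finite(I2)) I2 <- 0  # Q == 0
  }
  wr <- 1 / (ses^2 + tau2)
  random <- sum(wr * estimates) / sum(wr)
  se_random <- sqrt(1 / sum(wr))
  pack <- function(est, se) c(est = est, se = se, norm_ci(est, se, conf_level))
  structure(list(fixed = pack(fixed, se_fixed),
                 random = pack(random, se_random),
                 tau2 = tau2, Q = Q, df = df, I2 = I2,
                 weights_fixed = 100 * w / sum(w),
                 weights_random = 100 * wr / sum(wr), k = k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, digits = 3, ...) {
  cat("Random-effects meta-analysis (DerSimonian-Laird), k =", x$k, "\n")
  cat(sprintf("  fixed : %.*f (%.*f to %.*f)\n", digits, x$fixed[1],
              digits, x$fixed[3], digits, x$fixed[4]))
  cat(sprintf("  random: %.*f (%.*f to %.*f)\n", digits, x$random[1],
              digits, x$random[3], digits, x$random[4]))
  cat(sprintf("  Q = %.3f on %d df, tau2 = %.5f, I2 = %.1f%%\n",
              x$Q, x$df, x$tau2, x$I2))
  invisible(x)
}

#' Mantel-Haenszel pooled odds ratio across strata
#'
#' `OR_MH = sum(a d / n) / sum(b c / n)` with the
#' Robins-Breslow-Greenland variance for the CI, a z-test of OR = 1, and
#' a Woolf-type homogeneity chi-square (with its `I2`) across strata.
#' Any stratum containing a zero cell gets a 0.5 continuity correction in
#' the homogeneity computation; if a margin of the MH sums is zero the
#' correction is applied to the pooled estimate too and logged.
#'
#' @param strata list of length-4 vectors `c(a, b, c, d)` (exposed cases,
#'   exposed non-cases, unexposed cases, unexposed non-cases), or a 4-column
#'   matrix with one stratum per row.
#' @param conf_level confidence level (default 0.95).
#' @return an `mh_result` list: `pooled_or`, `ci`, `se_log`, `z`, `p`,
#'   `homogeneity_X2`, `df`, `p_homogeneity`, `I2`, `k`,
#'   `corrected` (strata that received the continuity correction).
#' @export
mh_pooled_or <- function(strata, conf_level = 0.95) {
  if (is.matrix(strata)) strata <- asplit(strata, 1L)
  tab <- t(vapply(strata, function(s) as.numeric(s[1:4]), numeric(4)))
  colnames(tab) <- c("a", "b", "c", "d")
  if (any(tab < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) <= 0)) stop("every stratum needs positive totals",
                                   call. = FALSE)
  k <- nrow(tab)

  n <- rowSums(tab)
  R <- tab[, "a"] * tab[, "d"] / n
  S <- tab[, "b"] * tab[, "c"] / n
  corrected <- integer(0)
  if (sum(R) == 0 || sum(S) == 0) {
    corrected <- seq_len(k)
    message("zero margin in Mantel-Haenszel sums: applying 0.5 continuity ",
            "correction to all strata")
    tab <- tab + 0.5
    n <- rowSums(tab)
    R <- tab[, "a"] * tab[, "d"] / n
    S <- tab[, "b"] * tab[, "c"] / n
  }
  or_mh <- sum(R) / sum(S)

  ## Robins-Breslow-Greenland variance of log OR_MH
  P <- (tab[, "a"] + tab[, "d"]) / n
  Qv <- (tab[, "b"] + tab[, "c"]) / n
  se_log <- sqrt(sum(P * R) / (2 * sum(R)^2) +
                 sum(P * S + Qv * R) / (2 * sum(R) * sum(S)) +
                 sum(Qv * S) / (2 * sum(S)^2))
  z <- log(or_mh) / se_log
  p <- 2 * pnorm(-abs(z))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(lower = or_mh * exp(-zq * se_log), upper = or_mh * exp(zq * se_log))

  ## Woolf homogeneity on per-stratum log ORs (0.5 correction for zero cells)
  tabh <- tab
  zero <- rowSums(tabh == 0) > 0
  if (any(zero)) {
    corrected <- sort(unique(c(corrected, which(zero))))
    message("zero cell(s) in ", sum(zero),
            " stratum/strata: 0.5 continuity correction in homogeneity test")
    tabh[zero, ] <- tabh[zero, ] + 0.5
  }
  lor <- log(tabh[, "a"] * tabh[, "d"] / (tabh[, "b"] * tabh[, "c"]))
  vlor <- rowSums(1 / tabh)
  wh <- 1 / vlor
  lor_bar <- sum(wh * lor) / sum(wh)
  X2 <- sum(wh * (lor - lor_bar)^2)
  dfh <- k - 1L
  I2 <- if (k > 1L && X2 > 0) max(0, (X2 - dfh) / X2) * 100 else 0
  p_hom <- if (dfh > 0) pchisq(X2, dfh, lower.tail = FALSE) else NA_real_

  structure(list(pooled_or = or_mh, ci = ci, se_log = se_log, z = z, p = p,
                 homogeneity_X2 = X2, df = dfh, p_homogeneity = p_hom,
                 I2 = I2, k = k, corrected = corrected),
            class = "mh_result")
}

#' @export
print.mh_result <- function(x, digits = 3, ...) {
  cat(sprintf("Mantel-Haenszel pooled OR = %.*f (%.*f to %.*f), z = %.2f, p = %.2g\n",
              digits, x$pooled_or, digits, x$ci[1], digits, x$ci[2], x$z, x$p))
  cat(sprintf("Homogeneity X2 = %.2f on %d df (p = %.2g), I2 = %.1f%%\n",
              x$homogeneity_X2, x$df, x$p_homogeneity, x$I2))
  invisible(x)
}

#' Country 2x2 death table by wealth group
#'
#' Unweighted counts (deaths / survivors among poor and non-poor), the
#' stratum input of [mh_pooled_or()].
#' @param records one country's child records.
#' @param poor_cutoff passed to [dichotomize_wealth()].
#' @return length-4 numeric vector `c(a, b, c, d)` = (poor deaths, poor
#'   survivors, non-poor deaths, non-poor survivors).
#' @export
wealth_death_table <- function(records, poor_cutoff = 2L) {
  assert_records(records)
  poor <- dichotomize_wealth(records$wealth_quintile, poor_cutoff)
  c(a = sum(records$died == 1 & poor), b = sum(records$died == 0 & poor),
    c = sum(records$died == 1 & !poor), d = sum(records$died == 0 & !poor))
}

#' Burden-by-inequality country typology
#'
#' Cross-classifies countries on overall prevalence (high/low against a
#' threshold, default the 25-per-1000 SDG benchmark) and the direction of
#' the poor/non-poor risk difference (pro-non-poor when above the RD
#' threshold, default 0).
#'
#' @param prevalence per-country overall rate per 1000.
#' @param rd per-country risk difference per 1000 (or a list of
#'   `country_rd` objects).
#' @param prevalence_threshold default 25 (per 1000).
#' @param rd_threshold default 0.
#' @return character vector of group labels, named by country when names
#'   are available.
#' @export
quadrant_classify <- function(prevalence, rd, prevalence_threshold = 25,
                              rd_threshold = 0) {
  if (is.list(rd) && all(vapply(rd, inherits, logical(1), "country_rd"))) {
    nms <- vapply(rd, `[[`, character(1), "country_id")
    rd <- vapply(rd, `[[`, numeric(1), "rd")
    names(rd) <- nms
  }
  stopifnot(length(prevalence) == length(rd),
            is.finite(prevalence_threshold), is.finite(rd_threshold))
  out <- paste0(ifelse(prevalence >= prevalence_threshold, "high", "low"),
                " prevalence, ",
                ifelse(rd > rd_threshold, "pro-non-poor", "pro-poor"))
  names(out) <- names(rd) %||% names(prevalence)
  out
}

#' Forest-plot-ready table from per-country RDs and a meta result
#' @param rds list of `country_rd`.
#' @param meta a `meta_result` from [dl_random_effects()] on the same
#'   studies (same order).
#' @return data.frame: study, estimate, CI bounds, fixed/random weight %.
#' @export
forest_table <- function(rds, meta) {
  stopifnot(length(rds) == meta$k)
  data.frame(
    study = vapply(rds, `[[`, character(1), "country_id"),
    estimate = vapply(rds, `[[`, numeric(1), "rd"),
    lower = vapply(rds, function(r) unname(r$ci[1]), numeric(1)),
    upper = vapply(rds, function(r) unname(r$ci[2]), numeric(1)),
    weight_fixed_pct = as.numeric(meta$weights_fixed),
    weight_random_pct = as.numeric(meta$weights_random),
    row.names = NULL)
}
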