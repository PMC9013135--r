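## WHO HEAT-style summary measures of wealth inequality: weighted
## subgroup prevalences and D, R, PAR, PAF with adverse-indicator
## truncation conventions.

#' Weighted prevalence of an outcome in a subgroup
#'
#' Rate per 1000 with a standard error based on the effective sample size
#' `n_eff = (sum w)^2 / sum(w^2)`; invariant to rescaling all weights by a
#' constant.
#'
#' @param died 0/1 (or logical) outcome vector for the subgroup.
#' @param weights positive sampling weights.
#' @return list with `rate` (per 1000), `se` (per 1000), `n_eff`.
#' @export
weighted_prevalence <- function(died, weights) {
  if (length(died) == 0L) stop("empty subgroup", call. = FALSE)
  stopifnot(length(weights) == length(died), all(weights > 0))
  est <- wprop(as.numeric(died), weights)
  list(rate = 1000 * est$p, se = 1000 * est$se, n_eff = est$n_eff)
}

#' Per-quintile prevalence estimates plus the national average
#'
#' @param records child records for one country (or any stratum).
#' @param weighted use sampling weights (default TRUE).
#' @return a `subgroup_estimates` object.
#' @export
estimate_subgroups <- function(records, weighted = TRUE) {
  assert_records(records)
  w <- if (weighted) records$weight else rep(1, nrow(records))
  per_q <- lapply(1:5, function(q) {
    sel <- records$wealth_quintile == q
    if (!any(sel)) stop("empty wealth quintile ", q, call. = FALSE)
    weighted_prevalence(records$died[sel], w[sel])
  })
  overall <- weighted_prevalence(records$died, w)
  subgroup_estimates(rates = vapply(per_q, `[[`, numeric(1), "rate"),
                     ses = vapply(per_q, `[[`, numeric(1), "se"),
                     n_eff = vapply(per_q, `[[`, numeric(1), "n_eff"),
                     mu = overall$rate, mu_se = overall$se,
                     weighted = weighted)
}

#' Construct quintile-level estimates directly
#'
#' Used both by [estimate_subgroups()] and for analytic scenarios where
#' rates are stated rather than estimated.
#'
#' @param rates numeric length-5 vector of per-1000 rates, quintile 1
#'   (poorest) to 5 (richest).
#' @param ses per-quintile standard errors (per 1000), default 0.
#' @param n_eff per-quintile effective sample sizes (optional).
#' @param mu national average rate per 1000; must lie within the range of
#'   the subgroup rates.
#' @param mu_se standard error of `mu`, default 0.
#' @param weighted whether estimates were weight-based (metadata).
#' @return a `subgroup_estimates` object.
#' @export
subgroup_estimates <- function(rates, ses = rep(0, 5), n_eff = rep(NA_real_, 5),
                               mu, mu_se = 0, weighted = TRUE) {
  stopifnot(length(rates) == 5L, length(ses) == 5L, all(rates >= 0),
            all(ses >= 0), length(mu) == 1L)
  if (mu < min(rates) - 1e-8 || mu > max(rates) + 1e-8)
    stop("national average must lie within the range of subgroup rates",
         call. = FALSE)
  structure(list(rates = as.numeric(rates), ses = as.numeric(ses),
                 n_eff = as.numeric(n_eff), mu = as.numeric(mu),
                 mu_se = as.numeric(mu_se), weighted = isTRUE(weighted)),
            class = "subgroup_estimates")
}

#' HEAT-style inequality summary measures
#'
#' For an adverse indicator (such as death), the most-advantaged reference
#' subgroup is the richest quintile (Q5):
#' \itemize{
#'   \item `D = rate(Q1) - rate(Q5)`, reported per 100 by default;
#'   \item `R = rate(Q1) / rate(Q5)` (undefined when the reference rate is
#'         0, flagged rather than printed as a number);
#'   \item `PAR = rate(Q5) - mu`, truncated to 0 when positive (an adverse
#'         indicator cannot have a beneficial attributable risk), with the
#'         `truncated` flag set;
#'   \item `PAF = PAR / mu * 100`, truncated with PAR, so `PAF = -100`
#'         exactly when the reference subgroup's rate is 0.
#' }
#' Confidence intervals: normal for D; log-scale delta method for R;
#' independent-variance delta method for PAR and PAF (conservative: the
#' positive correlation between the reference rate and the national
#' average through the shared sample is ignored).  Truncated measures
#' report the untruncated-width interval centred at 0.
#'
#' @param estimates a `subgroup_estimates` object.
#' @param indicator_type `"adverse"` (death-like, default) or
#'   `"favourable"` (coverage-like, sign conventions mirrored).
#' @param scale `"per100"` (default, matches conventional reporting of D
#'   and PAR against per-1000 rates) or `"per1000"`.
#' @param conf_level confidence level, default 0.95.
#' @return an `inequality_measures` object: components `D`, `R`, `PAR`,
#'   `PAF` (each `c(est, lower, upper)`), `truncated`, `r_undefined`,
#'   `reference_subgroup`, `scale`.
#' @export
compute_heat <- function(estimates, indicator_type = c("adverse", "favourable"),
                         scale = c("per100", "per1000"), conf_level = 0.95) {
  stopifnot(inherits(estimates, "subgroup_estimates"))
  indicator_type <- match.arg(indicator_type)
  scale <- match.arg(scale)
  z <- qnorm(1 - (1 - conf_level) / 2)
  k <- if (scale == "per100") 10 else 1  # per-1000 -> reporting scale

  r1 <- estimates$rates[1L]; r5 <- estimates$rates[5L]
  s1 <- estimates$ses[1L];   s5 <- estimates$ses[5L]
  mu <- estimates$mu;        smu <- estimates$mu_se

  ## D: extreme-quintile gap
  d <- (r1 - r5) / k
  sd_d <- sqrt(s1^2 + s5^2) / k
  D <- c(est = d, lower = d - z * sd_d, upper = d + z * sd_d)

  ## R: extreme-quintile ratio, log-delta CI
  r_undefined <- r5 <= 0
  if (r_undefined) {
    R <- c(est = NA_real_, lower = NA_real_, upper = NA_real_)
  } else if (r1 <= 0) {
    R <- c(est = 0, lower = NA_real_, upper = NA_real_)
  } else {
    rr <- r1 / r5
    slog <- sqrt((s1 / r1)^2 + (s5 / r5)^2)
    R <- c(est = rr, lower = rr * exp(-z * slog), upper = rr * exp(z * slog))
  }

  ## PAR / PAF with the adverse-indicator truncation convention
  par_raw <- (r5 - mu) / k
  se_par <- sqrt(s5^2 + smu^2) / k
  paf_raw <- if (mu > 0) (r5 - mu) / mu * 100 else NA_real_
  se_paf <- if (mu > 0)
    100 / mu * sqrt(s5^2 + (r5 / mu)^2 * smu^2) else NA_real_
  if (indicator_type == "favourable") {
    par_raw <- -par_raw
    paf_raw <- -paf_raw
  }
  truncated <- is.finite(par_raw) && par_raw > 0
  if (truncated) {
    PAR <- c(est = 0, lower = -z * se_par, upper = z * se_par)
    PAF <- c(est = 0, lower = -z * se_paf, upper = z * se_paf)
  } else {
    PAR <- c(est = par_raw, lower = par_raw - z * se_par,
             upper = par_raw + z * se_par)
    PAF <- c(est = paf_raw, lower = paf_raw - z * se_paf,
             upper = paf_raw + z * se_paf)
  }

  structure(list(D = D, R = R, PAR = PAR, PAF = PAF,
                 truncated = truncated, r_undefined = r_undefined,
                 reference_subgroup = 5L, indicator_type = indicator_type,
                 scale = scale, mu = mu / k),
            class = "inequality_measures")
}

#' @export
print.inequality_measures <- function(x, digits = 2, ...) {
  fmt <- function(v) sprintf("%.*f (%.*f to %.*f)", digits, v[1],
                             digits, v[2], digits, v[3])
  cat("Inequality measures (", x$indicator_type, ", reference Q",
      x$reference_subgroup, ", scale ", x$scale, ")\n", sep = "")
  cat("  D  :", fmt(x$D), "\n")
  cat("  R  :", if (x$r_undefined) "undefined (reference rate 0)"
      else fmt(x$R), "\n")
  cat("  PAR:", fmt(x$PAR), if (x$truncated) "[truncated]" else "", "\n")
  cat("  PAF:", fmt(x$PAF), if (x$truncated) "[truncated]" else "", "\n")
  invisible(x)
}

#' Per-country measures table
#'
#' @param estimates_by_country named list of `subgroup_estimates`.
#' @param ... passed to [compute_heat()].
#' @return data.frame with one row per country: D, R, PAR, PAF and CI
#'   bounds plus `truncated` and `r_undefined` flags.
#' @export
heat_table <- function(estimates_by_country, ...) {
  rows <- lapply(names(estimates_by_country), function(nm) {
    m <- compute_heat(estimates_by_country[[nm]], ...)
    data.frame(country_id = nm,
               D = m$D[1], D_lo = m$D[2], D_hi = m$D[3],
               R = m$R[1], R_lo = m$R[2], R_hi = m$R[3],
               PAR = m$PAR[1], PAR_lo = m$PAR[2], PAR_hi = m$PAR[3],
               PAF = m$PAF[1], PAF_lo = m$PAF[2], PAF_hi = m$PAF[3],
               truncated = m$truncated, r_undefined = m$r_undefined,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
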