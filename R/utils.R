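## Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a reproducible child seed from (master seed, stream index).
## Kept strictly below 2^31 so it is a valid R integer seed.
#' @noRd
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.double(seed)) * 48271 + as.double(index) * 99991) %%
               2147483629) + 1L
}

#' Weighted group assignment into k quantile bins
#'
#' Records are ranked by `x` (ties broken by `tiebreak`, then original
#' order) and cut at the weighted 1/k cumulative-share points.
#' @noRd
weighted_ntile <- function(x, w, k = 5L, tiebreak = NULL) {
  n <- length(x)
  stopifnot(length(w) == n, all(w > 0))
  ord <- if (is.null(tiebreak)) order(x) else order(x, tiebreak)
  cw <- cumsum(w[ord]) / sum(w)
  bin <- pmin(k, floor(cw * k - 1e-12) + 1L)
  out <- integer(n)
  out[ord] <- as.integer(bin)
  out
}

## Weighted mean of a 0/1 outcome with effective-sample-size SE.
#' @noRd
wprop <- function(y, w) {
  sw <- sum(w)
  p <- sum(w * y) / sw
  n_eff <- sw^2 / sum(w^2)
  se <- sqrt(max(p * (1 - p), 0) / n_eff)
  list(p = p, se = se, n_eff = n_eff)
}

#' @noRd
assert_records <- function(records) {
  req <- c("country_id", "cluster_id", "weight", "wealth_quintile", "died")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("records are missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(records$weight <= 0)) stop("all weights must be positive", call. = FALSE)
  if (!all(records$wealth_quintile %in% 1:5))
    stop("wealth_quintile must be in 1..5", call. = FALSE)
  invisible(records)
}

## format a two-sided normal CI
#' @noRd
norm_ci <- function(est, se, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  c(lower = est - z * se, upper = est + z * se)
}
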