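## Shared fixtures: all generated in code, nothing stored on disk.

## A configuration with every group difference and random effect switched
## off: the downstream null world.
null_config <- function(n_countries = 1L, clusters_per_country = 20L,
                        births_per_cluster = 50L, rate = 0.05,
                        weight_sigma = 0.3) {
  pop_config(n_countries = n_countries,
             clusters_per_country = clusters_per_country,
             births_per_cluster = births_per_cluster,
             covariates = list(),
             coefficients = list(intercept = qlogis(rate), poor = 0,
                                 covariates = list()),
             cluster_re_sd = 0, country_effect_sd = 0,
             weight_sigma = weight_sigma)
}

## Small desk-scale config with the package defaults.
small_config <- function(n_countries = 5L)
  pop_config(n_countries = n_countries, clusters_per_country = 15L,
             births_per_cluster = 25L)

## Build records directly from per-quintile death counts / sizes
## (weights 1, one cluster per quintile).
records_from_quintiles <- function(deaths, n, country = "C01") {
  stopifnot(length(deaths) == 5L, length(n) == 5L, all(deaths <= n))
  do.call(rbind, lapply(1:5, function(q) data.frame(
    country_id = country,
    cluster_id = paste0(country, "_K", q),
    weight = 1,
    wealth_quintile = q,
    died = rep(c(1L, 0L), c(deaths[q], n[q] - deaths[q])),
    stringsAsFactors = FALSE)))
}

## Two-covariate 4-vs-4 toy used for the exhaustive-enumeration checks.
## Chosen so the pooled logit converges without separation and predicted
## probabilities are distinct.
toy_8 <- function() {
  data.frame(
    country_id = "T",
    cluster_id = paste0("T_K", rep(1:2, each = 4)),
    weight = 1,
    wealth_quintile = rep(c(1L, 5L), each = 4),
    died = c(1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L),
    x1 = c("b", "b", "a", "a", "b", "a", "a", "a"),
    x2 = c("b", "a", "b", "a", "a", "b", "a", "a"),
    stringsAsFactors = FALSE)
}

## Independent brute-force evaluation of the sequential substitution for
## a fixed coefficient set and matched dummy matrices (the oracle used
## against sequential_contributions / fairlie_decompose).
oracle_sequential <- function(alpha, beta, A, B, ordering) {
  ## beta: named list covariate -> named coefficient vector over columns
  lp <- rep(alpha, nrow(A))
  for (nm in names(beta)) for (cn in names(beta[[nm]]))
    lp <- lp + beta[[nm]][[cn]] * A[, cn]
  res <- numeric(length(ordering)); names(res) <- ordering
  prev <- mean(1 / (1 + exp(-lp)))
  for (nm in ordering) {
    for (cn in names(beta[[nm]]))
      lp <- lp + beta[[nm]][[cn]] * (B[, cn] - A[, cn])
    cur <- mean(1 / (1 + exp(-lp)))
    res[nm] <- prev - cur
    prev <- cur
  }
  res
}
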