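## Plain-text round-trip I/O: records as CSV, configs as JSON.

#' Write child records to CSV
#'
#' One row per live birth; the header carries the declared covariate
#' names.  Round-trips losslessly through [read_records()].
#' @param records data.frame of child records.
#' @param path output file path.
#' @export
write_records <- function(records, path) {
  assert_records(records)
  out <- records
  ## full-precision text so the numeric fields round-trip bit-losslessly
  for (cn in names(out))
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read child records from CSV
#' @param path CSV written by [write_records()] or user data honouring the
#'   same header contract.
#' @return data.frame of child records.
#' @export
read_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$wealth_quintile <- as.integer(df$wealth_quintile)
  df$died <- as.integer(df$died)
  assert_records(df)
}

#' Serialize a population config to JSON
#' @param config a [pop_config()].
#' @param path output path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pop_config"))
  plain <- unclass(config)
  plain$covariates <- lapply(plain$covariates, unclass)
  ## named coefficient vectors as JSON objects so names survive the trip
  plain$coefficients$covariates <- lapply(plain$coefficients$covariates, as.list)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a population config from JSON
#' @param path JSON written by [write_config()].
#' @return a validated [pop_config()].
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  covs <- lapply(raw$covariates, function(r)
    covariate_spec(r$name, unlist(r$levels), unlist(r$probs_poor),
                   unlist(r$probs_nonpoor)))
  coef <- list(intercept = raw$coefficients$intercept,
               poor = raw$coefficients$poor,
               covariates = lapply(raw$coefficients$covariates, unlist))
  pop_config(n_countries = raw$n_countries,
             clusters_per_country = raw$clusters_per_country,
             births_per_cluster = raw$births_per_cluster,
             covariates = covs,
             coefficients = coef,
             cluster_re_sd = raw$cluster_re_sd,
             country_effect_sd = raw$country_effect_sd,
             weight_sigma = raw$weight_sigma)
}
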