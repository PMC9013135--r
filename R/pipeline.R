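## End-to-end orchestration: generate (or load) -> harmonize -> summary
## measures -> meta-analysis -> decomposition, with a run manifest and
## plain CSV/JSON stage outputs so each stage is independently
## re-runnable.

#' Configure a pipeline run
#'
#' Exactly one of `input_path` (CSV of child records) or `synthesis`
#' (a [pop_config()]) must be given; a seed is mandatory whenever data
#' are synthesized or a decomposition is run.
#'
#' @param input_path path to a records CSV, or `NULL`.
#' @param synthesis a [pop_config()], or `NULL`.
#' @param seed master integer seed.
#' @param output_dir directory for stage outputs.
#' @param poor_cutoff quintiles counted as poor (default 2).
#' @param scale measure reporting scale, `"per100"` or `"per1000"`.
#' @param prevalence_threshold,rd_threshold typology cutoffs
#'   (defaults 25 per 1000 and 0).
#' @param n_orderings,n_subsamples decomposition replication counts
#'   (pipeline defaults are desk-scale: 20 x 5).
#' @param ses_ingredients passed to [build_analysis_frame()]; `NULL`
#'   skips the neighbourhood composite.
#' @param decompose_countries country ids to decompose, `"pooled"` for
#'   one pooled decomposition (default), or `NULL` to skip.
#' @return a `run_config` list.
#' @export
run_config <- function(input_path = NULL, synthesis = NULL, seed = NULL,
                       output_dir = tempfile("wealthineq_run_"),
                       poor_cutoff = 2L, scale = "per100",
                       prevalence_threshold = 25, rd_threshold = 0,
                       n_orderings = 20L, n_subsamples = 5L,
                       ses_ingredients = NULL,
                       decompose_countries = "pooled") {
  if (is.null(input_path) == is.null(synthesis))
    stop("exactly one of input_path or synthesis must be set", call. = FALSE)
  if (!is.null(synthesis)) {
    stopifnot(inherits(synthesis, "pop_config"))
    if (is.null(seed))
      stop("a seed is mandatory when data are synthesized", call. = FALSE)
  }
  if (!is.null(decompose_countries) && is.null(seed))
    stop("a seed is mandatory for the decomposition", call. = FALSE)
  structure(list(input_path = input_path, synthesis = synthesis,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 output_dir = output_dir, poor_cutoff = as.integer(poor_cutoff),
                 scale = scale,
                 prevalence_threshold = prevalence_threshold,
                 rd_threshold = rd_threshold,
                 n_orderings = as.integer(n_orderings),
                 n_subsamples = as.integer(n_subsamples),
                 ses_ingredients = ses_ingredients,
                 decompose_countries = decompose_countries),
            class = "run_config")
}

#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Stages: simulate/load, harmonize, HEAT measures per country,
#' risk-difference meta-analysis + Mantel-Haenszel pooled OR + typology,
#' Fairlie decomposition.  All stage outputs are written as CSV/JSON
#' under `config$output_dir` together with a manifest recording seeds,
#' counts and every default applied.  Identical config + seed gives
#' byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return the manifest (invisibly also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)

  records <- stage("simulate", {
    if (!is.null(config$synthesis)) {
      surveys <- generate_multicountry(config$synthesis, config$seed)
      df <- bind_surveys(surveys)
      write_records(df, out("records.csv"))
      write_config(config$synthesis, out("synthesis_config.json"))
      df
    } else read_records(config$input_path)
  })

  frame <- stage("harmonize", {
    fr <- build_analysis_frame(records, poor_cutoff = config$poor_cutoff,
                               ses_ingredients = config$ses_ingredients)
    if (!is.null(fr$vif))
      jsonlite::write_json(
        list(vif = as.list(fr$vif$vif), threshold = fr$vif$threshold,
             eliminated = fr$vif$eliminated,
             retained_covariates = fr$retained_covariates,
             n_dropped_incomplete = fr$n_dropped_incomplete),
        out("vif_report.json"), auto_unbox = TRUE, digits = NA)
    fr
  })

  by_country <- split(frame$records, frame$records$country_id)

  measures <- stage("heat", {
    est <- lapply(by_country, estimate_subgroups)
    tab <- heat_table(est, scale = config$scale)
    write.csv(tab, out("heat_measures.csv"), row.names = FALSE)
    tab
  })

  meta <- stage("meta", {
    rds <- lapply(by_country, country_risk_difference,
                  poor_cutoff = config$poor_cutoff)
    dl <- dl_random_effects(vapply(rds, `[[`, numeric(1), "rd"),
                            vapply(rds, `[[`, numeric(1), "se"))
    strata <- lapply(by_country, wealth_death_table,
                     poor_cutoff = config$poor_cutoff)
    mh <- mh_pooled_or(strata)
    prev <- vapply(by_country, function(d)
      weighted_prevalence(d$died, d$weight)$rate, numeric(1))
    groups <- quadrant_classify(prev, rds,
                                prevalence_threshold = config$prevalence_threshold,
                                rd_threshold = config$rd_threshold)
    write.csv(forest_table(rds, dl), out("forest.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(random_effect = as.list(dl$random), fixed_effect = as.list(dl$fixed),
           tau2 = dl$tau2, Q = dl$Q, df = dl$df, I2 = dl$I2,
           mh_pooled_or = mh$pooled_or, mh_ci = as.list(mh$ci), mh_z = mh$z,
           mh_I2 = mh$I2,
           classification = lapply(rds, `[[`, "classification"),
           typology = as.list(groups)),
      out("meta_summary.json"), auto_unbox = TRUE, digits = NA)
    list(rds = rds, dl = dl, mh = mh, typology = groups, prevalence = prev)
  })

  decomposition <- NULL
  if (!is.null(config$decompose_countries)) {
    decomposition <- stage("decompose", {
      targets <- config$decompose_countries
      res <- if (identical(targets, "pooled")) {
        list(pooled = fairlie_decompose(
          frame$records, covariates = frame$retained_covariates,
          n_orderings = config$n_orderings,
          n_subsamples = config$n_subsamples,
          seed = derive_seed(config$seed, 777L),
          poor_cutoff = config$poor_cutoff))
      } else {
        res <- lapply(targets, function(cid)
          fairlie_decompose(by_country[[cid]],
                            covariates = frame$retained_covariates,
                            n_orderings = config$n_orderings,
                            n_subsamples = config$n_subsamples,
                            seed = derive_seed(config$seed, match(cid, targets)),
                            poor_cutoff = config$poor_cutoff))
        names(res) <- targets
        res
      }
      ct <- contribution_table(res)
      write.csv(ct$long, out("decomposition_long.csv"), row.names = FALSE)
      write.csv(data.frame(country_id = rownames(ct$wide), ct$wide,
                           check.names = FALSE),
                out("decomposition_pct_matrix.csv"), row.names = FALSE)
      res
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("wealthineq")),
    seed = config$seed,
    n_records = nrow(frame$records),
    n_countries = length(by_country),
    poor_cutoff = config$poor_cutoff,
    scale = config$scale,
    prevalence_threshold = config$prevalence_threshold,
    rd_threshold = config$rd_threshold,
    n_orderings = config$n_orderings,
    n_subsamples = config$n_subsamples,
    retained_covariates = frame$retained_covariates,
    dropped_covariates = frame$dropped_covariates,
    n_dropped_incomplete = frame$n_dropped_incomplete,
    random_effect_rd = unname(meta$dl$random["est"]),
    I2 = meta$dl$I2,
    mh_pooled_or = meta$mh$pooled_or,
    outputs = sort(unique(c(list.files(config$output_dir), "manifest.json"))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, frame = frame, measures = measures,
                 meta = meta, decomposition = decomposition))
}
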