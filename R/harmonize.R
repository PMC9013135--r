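## Harmonization: poor/non-poor dichotomy, neighbourhood SES composite,
## collinearity (VIF) screening, and assembly of the analysis frame.

#' Dichotomize a wealth quintile into poor / non-poor
#'
#' Quintiles 1-2 (the bottom 40%) are classed as poor; quintiles 3-5 as
#' non-poor.  Vectorized.
#'
#' @param quintile integer vector with values in 1..5.
#' @param poor_cutoff highest quintile still counted as poor (default 2).
#' @return logical vector, `TRUE` = poor.
#' @export
dichotomize_wealth <- function(quintile, poor_cutoff = 2L) {
  if (any(is.na(quintile)) || !all(quintile %in% 1:5))
    stop("wealth quintile must be in 1..5", call. = FALSE)
  quintile <= poor_cutoff
}

#' Neighbourhood socioeconomic composite
#'
#' Builds a cluster-level disadvantage score as the first principal
#' component of three standardized cluster rates — no maternal education,
#' no media access, maternal unemployment — and cuts clusters into
#' weighted quintiles of the score.  The component's sign is oriented so
#' that a higher score means more disadvantage (positive loading on the
#' first ingredient).
#'
#' @param records child records containing the ingredient columns.
#' @param ingredients named list of `c(var, level)` pairs: the rate of
#'   `level` within each cluster for column `var`.  The default matches
#'   [default_covariates()].
#' @param weighted use sampling weights for the cluster rates and for the
#'   quintile cut (default TRUE).
#' @return data.frame with `cluster_id`, `score`, `ses_quintile`.
#' @export
neighborhood_ses <- function(records,
                             ingredients = list(
                               no_education = c("maternal_education", "none"),
                               no_media = c("media_access", "no"),
                               unemployed = c("maternal_employment", "unemployed")),
                             weighted = TRUE) {
  assert_records(records)
  vars <- vapply(ingredients, `[`, character(1), 1L)
  miss <- setdiff(vars, names(records))
  if (length(miss))
    stop("SES ingredient columns missing from records: ",
         paste(miss, collapse = ", "), call. = FALSE)
  w <- if (weighted) records$weight else rep(1, nrow(records))
  cl <- as.character(records$cluster_id)
  cw <- tapply(w, cl, sum)
  rates <- vapply(ingredients, function(ing) {
    x <- records[[ing[1L]]]
    ok <- !is.na(x)   # rates computed among non-missing records
    num <- tapply((w * (x == ing[2L]))[ok], cl[ok], sum)
    den <- tapply(w[ok], cl[ok], sum)
    out <- setNames(rep(NA_real_, length(cw)), names(cw))
    out[names(num)] <- num / den
    out
  }, numeric(length(cw)))
  rates <- matrix(rates, nrow = length(cw),
                  dimnames = list(names(cw), names(ingredients)))
  if (anyNA(rates))
    stop("cluster(s) with no non-missing values for an SES ingredient",
         call. = FALSE)

  sds <- apply(rates, 2L, sd)
  if (all(sds < 1e-12))
    stop("degenerate SES composite: all ingredient rates have zero variance",
         call. = FALSE)
  if (any(sds < 1e-12)) {
    warning("dropping zero-variance SES ingredient(s): ",
            paste(colnames(rates)[sds < 1e-12], collapse = ", "))
    rates <- rates[, sds >= 1e-12, drop = FALSE]
  }
  pc <- prcomp(rates, center = TRUE, scale. = TRUE)
  score <- pc$x[, 1L]
  if (pc$rotation[1L, 1L] < 0) score <- -score
  q <- weighted_ntile(score, as.numeric(cw)[match(rownames(rates), names(cw))], 5L)
  data.frame(cluster_id = rownames(rates), score = as.numeric(score),
             ses_quintile = q, row.names = NULL, stringsAsFactors = FALSE)
}

#' Variance-inflation-factor screen
#'
#' Computes `VIF_j = 1 / (1 - R2_j)` for every column of a dummy-coded
#' covariate matrix, where `R2_j` comes from regressing column j on all
#' other columns (with intercept).  Columns above the threshold are
#' eliminated iteratively, worst offender first (ties broken
#' alphabetically by column name), recomputing VIFs after each drop until
#' all retained VIFs are at or below the threshold.  Perfectly collinear
#' columns get `VIF = Inf` and go first.
#'
#' @param X numeric matrix with named columns (>= 2 columns, more rows
#'   than columns).
#' @param threshold elimination threshold (default 2.5).
#' @return a `vif_report` list: `vif` (named, at entry), `threshold`,
#'   `eliminated` (in elimination order), `retained`, `vif_final`.
#' @export
vif_screen <- function(X, threshold = 2.5) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2L) stop("need at least 2 columns", call. = FALSE)
  if (nrow(X) < ncol(X)) stop("need at least as many rows as columns", call. = FALSE)

  vif_of <- function(M) {
    vapply(seq_len(ncol(M)), function(j) {
      yj <- M[, j]
      tss <- sum((yj - mean(yj))^2)
      if (tss < 1e-12) return(Inf)  # constant: collinear with intercept
      fit <- lm.fit(cbind(1, M[, -j, drop = FALSE]), yj)
      r2 <- 1 - sum(fit$residuals^2) / tss
      if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
    }, numeric(1), USE.NAMES = FALSE) |> setNames(colnames(M))
  }

  vif0 <- vif_of(X)
  eliminated <- character(0)
  keep <- X
  repeat {
    v <- if (ncol(keep) >= 2L) vif_of(keep) else setNames(1, colnames(keep))
    if (all(v <= threshold)) break
    worst <- names(v)[v == max(v)]
    drop <- sort(worst)[1L]
    eliminated <- c(eliminated, drop)
    keep <- keep[, setdiff(colnames(keep), drop), drop = FALSE]
    if (ncol(keep) == 0L) break
  }
  structure(list(vif = vif0, threshold = threshold, eliminated = eliminated,
                 retained = colnames(keep),
                 vif_final = if (ncol(keep) >= 2L) vif_of(keep)
                             else setNames(rep(1, ncol(keep)), colnames(keep))),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat("VIF screen (threshold", x$threshold, ")\n")
  print(round(x$vif, 3))
  cat("eliminated:", if (length(x$eliminated)) paste(x$eliminated, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

## Dummy-code the categorical covariates of a record table (first declared
## level of each factor = reference, dropped).
#' @noRd
dummy_code <- function(records, covariates) {
  cols <- list()
  layout <- list()
  for (nm in covariates) {
    x <- records[[nm]]
    if (is.null(x)) stop("covariate '", nm, "' not in records", call. = FALSE)
    lev <- if (is.factor(x)) levels(x) else sort(unique(x))
    for (l in lev[-1L]) {
      cn <- paste0(nm, ".", l)
      cols[[cn]] <- as.numeric(x == l)
      layout[[nm]] <- c(layout[[nm]], cn)
    }
    if (length(lev) < 2L) layout[[nm]] <- character(0)
  }
  list(X = do.call(cbind, cols), layout = layout)
}

#' Assemble the harmonized analysis frame
#'
#' Adds the poor indicator and the cluster SES quintile to the records,
#' performs complete-case deletion on the analysis covariates (with a
#' logged count), dummy-codes them and runs the VIF screen; covariates any
#' of whose dummy columns are eliminated are dropped from the retained
#' set.
#'
#' @param records child records (one country or several).
#' @param covariates character vector of covariate column names to carry
#'   into modelling; defaults to every column that is not a structural
#'   field.
#' @param poor_cutoff passed to [dichotomize_wealth()].
#' @param vif_threshold VIF elimination threshold (default 2.5).
#' @param ses_ingredients passed to [neighborhood_ses()]; `NULL` skips the
#'   composite.
#' @return an `analysis_frame` list: `records` (with `poor` and, when
#'   computed, `cluster_ses_quintile`), `retained_covariates`, `vif`
#'   (a [vif_screen()] report), `dropped_covariates`, `n_dropped_incomplete`.
#' @export
build_analysis_frame <- function(records, covariates = NULL,
                                 poor_cutoff = 2L, vif_threshold = 2.5,
                                 ses_ingredients = NULL) {
  assert_records(records)
  structural <- c("country_id", "cluster_id", "weight", "wealth_quintile",
                  "died", "poor", "cluster_ses_quintile")
  if (is.null(covariates))
    covariates <- setdiff(names(records), structural)
  records$poor <- dichotomize_wealth(records$wealth_quintile, poor_cutoff)

  ## complete-case deletion first, so every later stage sees clean data
  cc <- complete.cases(records[, covariates, drop = FALSE])
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    message("complete-case deletion: dropping ", n_dropped, " record(s)")
    records <- records[cc, , drop = FALSE]
  }

  if (!is.null(ses_ingredients)) {
    ses <- neighborhood_ses(records, ses_ingredients)
    records$cluster_ses_quintile <-
      ses$ses_quintile[match(records$cluster_id, ses$cluster_id)]
  }

  dc <- dummy_code(records, covariates)
  vif <- NULL
  retained <- covariates
  if (!is.null(dc$X) && ncol(dc$X) >= 2L) {
    vif <- vif_screen(dc$X, vif_threshold)
    bad <- unique(unlist(lapply(names(dc$layout), function(nm)
      if (any(dc$layout[[nm]] %in% vif$eliminated)) nm else NULL)))
    retained <- setdiff(covariates, bad)
  }
  structure(list(records = records,
                 retained_covariates = retained,
                 dropped_covariates = setdiff(covariates, retained),
                 vif = vif,
                 n_dropped_incomplete = n_dropped),
            class = "analysis_frame")
}

#' @export
print.analysis_frame <- function(x, ...) {
  cat("analysis frame:", nrow(x$records), "records,",
      sum(x$records$poor), "poor\n")
  cat("retained covariates:", paste(x$retained_covariates, collapse = ", "), "\n")
  if (length(x$dropped_covariates))
    cat("dropped by VIF screen:", paste(x$dropped_covariates, collapse = ", "), "\n")
  invisible(x)
}
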