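## Fairlie nonlinear decomposition of the poor/non-poor gap in death
## probability, built from scratch: pooled weighted logit, rank matching
## on predicted probability, sequential substitution of covariate blocks,
## and randomization over orderings and subsample draws.

#' Fit the pooled weighted logit supplying the common coefficients
#'
#' Weighted maximum-likelihood logistic regression of the outcome on the
#' dummy-coded covariates plus the poor-group indicator.  The group
#' indicator's coefficient is dropped at prediction time in the
#' decomposition, so the covariate coefficients are the common
#' "beta-star" of the sequential substitution.
#'
#' @param X dummy-coded design matrix (no intercept column) with named
#'   columns.
#' @param y 0/1 outcome.
#' @param weights positive sampling weights (frequency semantics: the
#'   coefficients equal the unweighted fit on row-expanded data for
#'   integer weights).
#' @param layout named list mapping each covariate to its dummy column
#'   names (as produced internally by the frame builder); columns not
#'   covered by the layout (e.g. the group indicator) are kept in the fit
#'   but excluded from substitution.
#' @return a `logit_model` list: `coefficients` (named, including
#'   `(Intercept)`), `layout`, `converged`.
#' @export
fit_pooled_logit <- function(X, y, weights = rep(1, length(y)),
                             layout = NULL) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  if (is.null(X)) X <- matrix(numeric(0), nrow = length(y), ncol = 0)
  X <- as.matrix(X)
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(
    glm.fit(Xd, y, weights = weights, family = quasibinomial(link = "logit")))
  beta <- fit$coefficients
  if (any(is.na(beta))) {
    bad <- names(beta)[is.na(beta)]
    stop("collinear design: coefficient not estimable for ",
         paste(bad, collapse = ", "), " (run vif_screen first)", call. = FALSE)
  }
  if (any(abs(beta[-1L]) > 15)) {
    bad <- names(beta[-1L])[which.max(abs(beta[-1L]))]
    stop("apparent separation: runaway coefficient for column '", bad, "'",
         call. = FALSE)
  }
  structure(list(coefficients = beta, layout = layout,
                 converged = isTRUE(fit$converged)),
            class = "logit_model")
}

## Predicted linear predictor from covariate columns only (no group
## indicator), for a dummy matrix sharing the model's columns.
#' @noRd
predict_lp <- function(model, X, exclude = character(0)) {
  beta <- model$coefficients
  use <- setdiff(names(beta), c("(Intercept)", exclude))
  lp <- rep(unname(beta["(Intercept)"]), nrow(X))
  for (cn in use) lp <- lp + beta[[cn]] * X[, cn]
  lp
}

#' Rank-match the two groups on predicted probability
#'
#' The larger group is subsampled without replacement to the smaller
#' group's size (draw probabilities proportional to sampling weights, so
#' the subsample represents the weighted population); both samples are
#' then sorted by predicted probability under the model (group indicator
#' excluded) and matched by rank.
#'
#' @param X_poor,X_nonpoor dummy matrices for the two groups, with the
#'   model's covariate columns.
#' @param model a `logit_model`.
#' @param seed integer seed for the subsample draw.
#' @param w_poor,w_nonpoor sampling weights (used only for the subsample
#'   draw probabilities).
#' @param group_col name of the group-indicator column to exclude from
#'   prediction, if present in the matrices.
#' @return list: `A` and `B` (matched dummy matrices, poor and non-poor,
#'   rows aligned by rank), `idx_A`, `idx_B` (row indices into the
#'   inputs).
#' @export
match_samples <- function(X_poor, X_nonpoor, model, seed,
                          w_poor = rep(1, nrow(X_poor)),
                          w_nonpoor = rep(1, nrow(X_nonpoor)),
                          group_col = "poor") {
  stopifnot(nrow(X_poor) >= 1L, nrow(X_nonpoor) >= 1L)
  set.seed(as.integer(seed))
  n <- min(nrow(X_poor), nrow(X_nonpoor))
  idx_A <- seq_len(nrow(X_poor))
  idx_B <- seq_len(nrow(X_nonpoor))
  if (nrow(X_poor) > n)
    idx_A <- sample(idx_A, n, replace = FALSE, prob = w_poor)
  if (nrow(X_nonpoor) > n)
    idx_B <- sample(idx_B, n, replace = FALSE, prob = w_nonpoor)
  pa <- predict_lp(model, X_poor[idx_A, , drop = FALSE], exclude = group_col)
  pb <- predict_lp(model, X_nonpoor[idx_B, , drop = FALSE], exclude = group_col)
  idx_A <- idx_A[order(pa)]
  idx_B <- idx_B[order(pb)]
  list(A = X_poor[idx_A, , drop = FALSE], B = X_nonpoor[idx_B, , drop = FALSE],
       idx_A = idx_A, idx_B = idx_B)
}

## Core sequential-substitution engine.  alpha: per-pair baseline linear
## predictor (scalar or vector); blocks_A/blocks_B: per-covariate vectors
## of X_k beta_k for the poor and matched non-poor records.  Starting from
## all-poor values, each covariate in `ordering` is switched to the
## non-poor values; its contribution is the drop in mean F at its step.
## The chain telescopes, so contributions sum exactly to
## mean F(start) - mean F(end) = the explained gap.
#' @noRd
sequential_core <- function(alpha, blocks_A, blocks_B, ordering) {
  lp <- alpha + Reduce(`+`, blocks_A, accumulate = FALSE)
  contributions <- setNames(numeric(length(ordering)), ordering)
  first <- mean(plogis(lp))
  prev <- first
  for (nm in ordering) {
    lp <- lp + (blocks_B[[nm]] - blocks_A[[nm]])
    cur <- mean(plogis(lp))
    contributions[[nm]] <- prev - cur
    prev <- cur
  }
  list(contributions = contributions, explained = first - prev)
}

## Build per-covariate linear-predictor blocks X_k beta_k from a matched
## dummy matrix and the model layout.
#' @noRd
lp_blocks <- function(model, X) {
  beta <- model$coefficients
  lapply(model$layout, function(cols) {
    lp <- numeric(nrow(X))
    for (cn in cols) lp <- lp + beta[[cn]] * X[, cn]
    lp
  })
}

#' Per-covariate contributions for one covariate ordering
#'
#' Empirical sequential substitution: all covariates start at the poor
#' group's matched values and are switched, one whole covariate (block of
#' dummy columns) at a time in the given ordering, to the matched
#' non-poor values.  The contribution of a covariate is the change in the
#' mean predicted probability at its switch step; contributions sum
#' exactly to the explained gap.
#'
#' @param pairs matched pair list from [match_samples()].
#' @param model a `logit_model` with a covariate `layout`.
#' @param ordering permutation of the model's covariate names.
#' @return named numeric vector of contributions with attribute
#'   `explained`.
#' @export
sequential_contributions <- function(pairs, model, ordering) {
  nms <- names(model$layout)
  if (length(ordering) != length(nms) || !setequal(ordering, nms))
    stop("ordering must be a permutation of the model's covariates",
         call. = FALSE)
  alpha <- unname(model$coefficients["(Intercept)"])
  res <- sequential_core(alpha, lp_blocks(model, pairs$A),
                         lp_blocks(model, pairs$B), ordering)
  out <- res$contributions
  attr(out, "explained") <- res$explained
  out
}

#' Fairlie nonlinear decomposition of the poor/non-poor gap
#'
#' Fits the pooled weighted logit (poor indicator included, dropped at
#' prediction), then averages [sequential_contributions()] over
#' `n_orderings` random covariate orderings crossed with `n_subsamples`
#' subsample/rank-match draws.  With equal group sizes the matching is
#' deterministic and a single subsample replication is used.
#'
#' @param records harmonized child records (or an `analysis_frame`, whose
#'   retained covariates become the default covariate set).
#' @param covariates character vector of covariate columns to decompose
#'   over.
#' @param n_orderings random orderings per subsample draw (default 100).
#' @param n_subsamples subsample/match draws (default 100; forced to 1
#'   when the groups are balanced).
#' @param seed master integer seed.
#' @param poor_cutoff passed to [dichotomize_wealth()].
#' @param weighted use sampling weights in the model fit, the group means
#'   and the subsample draw (default TRUE).
#' @param keep_replications keep the per-replication contribution matrix
#'   (for diagnostics and identity checks).
#' @return a `fairlie_result` list: `total_gap` (weighted mean outcome,
#'   poor minus non-poor, probability scale), `explained`, `unexplained`,
#'   `contributions` (data.frame: covariate, contribution, replication
#'   SD, pct_of_gap, pct_of_explained), `model`, `n_orderings`,
#'   `n_subsamples`, `seed`, and optionally `replications`.
#' @export
fairlie_decompose <- function(records, covariates = NULL,
                              n_orderings = 100L, n_subsamples = 100L,
                              seed = 1L, poor_cutoff = 2L, weighted = TRUE,
                              keep_replications = FALSE) {
  if (inherits(records, "analysis_frame")) {
    covariates <- covariates %||% records$retained_covariates
    records <- records$records
  }
  assert_records(records)
  if (is.null(covariates)) stop("covariates must be given", call. = FALSE)
  stopifnot(n_orderings >= 1L, n_subsamples >= 1L)

  poor <- dichotomize_wealth(records$wealth_quintile, poor_cutoff)
  w <- if (weighted) records$weight else rep(1, nrow(records))
  total_gap <- weighted.mean(records$died[poor], w[poor]) -
    weighted.mean(records$died[!poor], w[!poor])

  dc <- dummy_code(records, covariates)
  X <- cbind(dc$X, poor = as.numeric(poor))
  model <- fit_pooled_logit(X, records$died, w, layout = dc$layout)

  X_poor <- X[poor, , drop = FALSE]
  X_nonpoor <- X[!poor, , drop = FALSE]
  balanced <- nrow(X_poor) == nrow(X_nonpoor)
  ns <- if (balanced) 1L else as.integer(n_subsamples)

  nms <- names(model$layout)
  reps <- matrix(NA_real_, nrow = ns * n_orderings, ncol = length(nms),
                 dimnames = list(NULL, nms))
  expl <- numeric(ns * n_orderings)
  r <- 0L
  for (s in seq_len(ns)) {
    pairs <- match_samples(X_poor, X_nonpoor, model, derive_seed(seed, s),
                           w_poor = w[poor], w_nonpoor = w[!poor])
    bA <- lp_blocks(model, pairs$A)
    bB <- lp_blocks(model, pairs$B)
    alpha <- unname(model$coefficients["(Intercept)"])
    set.seed(derive_seed(seed, 100000L + s))
    for (o in seq_len(n_orderings)) {
      ord <- if (length(nms) > 1L) sample(nms) else nms
      res <- sequential_core(alpha, bA, bB, ord)
      r <- r + 1L
      reps[r, ] <- res$contributions[nms]
      expl[r] <- res$explained
    }
  }

  mean_contrib <- colMeans(reps)
  sd_contrib <- apply(reps, 2L, sd)
  explained <- mean(expl)
  contributions <- data.frame(
    covariate = nms,
    contribution = as.numeric(mean_contrib),
    replication_sd = as.numeric(sd_contrib),
    pct_of_gap = if (abs(total_gap) > 0) 100 * as.numeric(mean_contrib) / total_gap
                 else NA_real_,
    pct_of_explained = if (abs(explained) > 0)
      100 * as.numeric(mean_contrib) / explained else NA_real_,
    row.names = NULL)

  out <- list(total_gap = total_gap, explained = explained,
              unexplained = total_gap - explained,
              contributions = contributions, model = model,
              n_orderings = as.integer(n_orderings), n_subsamples = ns,
              seed = as.integer(seed), balanced = balanced)
  if (keep_replications) {
    out$replications <- reps
    out$replication_explained <- expl
  }
  structure(out, class = "fairlie_result")
}

#' @export
print.fairlie_result <- function(x, digits = 4, ...) {
  cat("Fairlie decomposition of the poor/non-poor gap\n")
  cat(sprintf("  total gap  : %.*f\n", digits, x$total_gap))
  cat(sprintf("  explained  : %.*f (%.1f%% of gap)\n", digits, x$explained,
              100 * x$explained / x$total_gap))
  cat(sprintf("  unexplained: %.*f\n", digits, x$unexplained))
  cat(sprintf("  replications: %d orderings x %d subsample draws\n",
              x$n_orderings, x$n_subsamples))
  print(transform(x$contributions,
                  contribution = round(contribution, digits),
                  replication_sd = signif(replication_sd, 3),
                  pct_of_gap = round(pct_of_gap, 1),
                  pct_of_explained = round(pct_of_explained, 1)))
  invisible(x)
}

#' Country-by-covariate contribution matrix
#'
#' Reshapes per-country decomposition results into long and wide percent
#' tables.  Percent-of-gap values may be negative or exceed 100 (a
#' covariate can widen or more than account for the raw gap); with a zero
#' total gap the percents are flagged undefined (NA) while absolute
#' contributions are still reported.
#'
#' @param results named list of `fairlie_result` objects (names =
#'   country ids).
#' @return list with `long` (country, covariate, contribution,
#'   pct_of_gap, pct_of_explained) and `wide` (country x covariate matrix
#'   of pct_of_gap).
#' @export
contribution_table <- function(results) {
  stopifnot(length(results) >= 1L)
  if (is.null(names(results)))
    names(results) <- paste0("country", seq_along(results))
  long <- do.call(rbind, lapply(names(results), function(nm) {
    ct <- results[[nm]]$contributions
    data.frame(country_id = nm, covariate = ct$covariate,
               contribution = ct$contribution,
               pct_of_gap = ct$pct_of_gap,
               pct_of_explained = ct$pct_of_explained, row.names = NULL)
  }))
  covs <- unique(long$covariate)
  wide <- matrix(NA_real_, nrow = length(results), ncol = length(covs),
                 dimnames = list(names(results), covs))
  for (i in seq_len(nrow(long)))
    wide[long$country_id[i], long$covariate[i]] <- long$pct_of_gap[i]
  list(long = long, wide = wide)
}
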