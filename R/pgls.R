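# Phylogenetic generalized least squares with profiled Pagel's lambda,
# marginal (drop-one) F-tests per predictor, and AIC model competition
# over all predictor subsets plus the vegetation x genome interaction.

#' Specify a PGLS model
#'
#' A model specification is the response name plus an ordered list of
#' predictor terms. Interaction terms are written `"a:b"` and are only
#' valid when both main effects are present.
#'
#' @param response Response column name (e.g. `"log10_guard_cell_length"`).
#' @param predictors Character vector of predictor terms (possibly empty
#'   for the intercept-only model).
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(response, predictors = character()) {
  predictors <- as.character(predictors)
  inter <- grepl(":", predictors, fixed = TRUE)
  for (tm in predictors[inter]) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% predictors))
      stop("interaction '", tm, "' requires both main effects in the model")
  }
  structure(list(response = response, predictors = predictors),
            class = "model_spec")
}

spec_label <- function(spec) {
  if (!length(spec$predictors)) return("(intercept only)")
  paste(spec$predictors, collapse = " + ")
}

#' Fit a phylogenetic generalized least squares model
#'
#' Fits `response ~ predictors` with Gaussian errors whose covariance is
#' `sigma2 * V(lambda)`, V being the Brownian matrix of the supplied tree
#' and lambda scaling its off-diagonal. With `lambda = "ML"` (the
#' default), lambda is estimated by maximizing the profile log-likelihood
#' over `[0, 1]`; a fixed numeric lambda may be supplied instead.
#' Categorical predictors are treatment-coded with the alphabetically
#' first level as reference. `sigma2` is the ML estimate `RSS_V / n`.
#'
#' The AIC counts `k = #coefficients + 2` parameters when lambda is
#' estimated (sigma2 and lambda), and `#coefficients + 1` when fixed.
#'
#' @param tree A dated `"phylo"` tree whose tips match `data` rows 1:1.
#' @param data A data frame with a `tip` column (or row order matching
#'   `tree$tip.label`) and the model columns.
#' @param spec A [model_spec()].
#' @param lambda `"ML"` or a fixed value in `[0, 1]`.
#' @return An object of class `"pgls_fit"` with elements `coefficients`,
#'   `lambda`, `lambda_mode`, `sigma2`, `logL`, `AIC`, `n`, `k`,
#'   `residuals`, `vcov`, `R` (phylogenetic correlation scale,
#'   `sign(slope) * sqrt(R2)` against the intercept-only model at the
#'   same lambda), plus internals used by [predictor_tests()].
#' @examples
#' sim <- simulate_study(study_config(seed = 1))
#' hl <- build_datasets(sim$traits_log, sim$tree, level = "high")
#' fit_pgls(hl$tree, hl$data,
#'          model_spec("log10_guard_cell_length",
#'                     c("log10_genome_size_2C", "vegetation")))
#' @export
fit_pgls <- function(tree, data, spec, lambda = "ML") {
  stopifnot(inherits(spec, "model_spec"))
  data <- align_to_tips(tree, data)
  y <- data[[spec$response]]
  if (is.null(y)) stop("response column not found: ", spec$response)
  X <- build_design(data, spec$predictors)
  n <- length(y)
  if (n <= ncol(X) + 2)
    stop("fewer rows (", n, ") than parameters; cannot fit")
  V <- vcv_matrix(tree)
  estimated <- identical(lambda, "ML")
  lam <- if (estimated) optimize_lambda(X, y, V) else {
    stopifnot(is.numeric(lambda), lambda >= 0)
    lambda
  }
  fit <- gls_profile(X, y, V, lam)
  k <- ncol(X) + 1L + as.integer(estimated)
  aic <- -2 * fit$logL + 2 * k
  # phylogenetic correlation: R2 against intercept-only at the same lambda
  X0 <- build_design(data, character())
  fit0 <- gls_profile(X0, y, V, lam)
  r2 <- 1 - fit$rss / fit0$rss
  slope_sign <- if (ncol(X) >= 2) sign(fit$beta[2]) else 1
  vcov_beta <- fit$vcov_beta
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = stats::setNames(as.numeric(fit$beta), colnames(X)),
    lambda = lam, lambda_mode = if (estimated) "ML" else "fixed",
    sigma2 = fit$sigma2, logL = fit$logL, AIC = aic, n = n, k = k,
    rss = fit$rss, residuals = fit$resid, vcov = vcov_beta,
    R2 = r2, R = slope_sign * sqrt(max(r2, 0)),
    spec = spec, data = data, tree_tips = tree$tip.label,
    V = V, X = X, y = y), class = "pgls_fit")
}

# Align data rows to tree tip order via a `tip` column, a `species`
# column matching tips, or row order.
align_to_tips <- function(tree, data) {
  tips <- tree$tip.label
  key <- if ("tip" %in% names(data)) data$tip
         else if ("species" %in% names(data) &&
                  all(tips %in% data$species)) data$species
         else NULL
  if (is.null(key)) {
    if (nrow(data) != length(tips))
      stop("data rows (", nrow(data), ") do not match tree tips (",
           length(tips), ") and no tip/species key is available")
    return(data)
  }
  if (!all(tips %in% key))
    stop("tips missing from data: ",
         paste(utils::head(setdiff(tips, key), 5), collapse = ", "))
  if (anyDuplicated(key)) stop("duplicate tip keys in data")
  data[match(tips, key), , drop = FALSE]
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit:", x$spec$response, "~", spec_label(x$spec), "\n")
  cat(sprintf("  lambda = %.4g (%s), sigma2 = %.4g, logL = %.4f, AIC = %.4f, n = %d\n",
              x$lambda, x$lambda_mode, x$sigma2, x$logL, x$AIC, x$n))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Marginal F-tests for PGLS predictors
#'
#' For each predictor term, refits the model with that term (all of its
#' design columns) dropped, the other terms retained and lambda reused
#' from the full fit, and forms
#' `F = ((RSS_reduced - RSS_full)/q) / (RSS_full/(n - p_full))`
#' with q = number of dropped columns. Tests are marginal (drop-one), so
#' they do not depend on predictor order; dropping a main effect whose
#' interaction remains is refused.
#'
#' @param fit A `"pgls_fit"`.
#' @return Data frame with one row per predictor: `term`, `df1`, `df2`,
#'   `F`, `p`.
#' @export
predictor_tests <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  terms <- fit$spec$predictors
  if (!length(terms)) stop("intercept-only model has no predictors to test")
  n <- fit$n
  p_full <- ncol(fit$X)
  out <- data.frame(term = terms, df1 = NA_integer_, df2 = n - p_full,
                    F = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(terms)) {
    tm <- terms[i]
    involved <- vapply(terms, function(other) {
      other != tm && tm %in% strsplit(other, ":", fixed = TRUE)[[1]]
    }, logical(1))
    if (any(involved))
      stop("cannot drop main effect '", tm,
           "' while its interaction remains: ",
           paste(terms[involved], collapse = ", "))
    reduced_terms <- setdiff(terms, tm)
    Xr <- build_design(fit$data, reduced_terms)
    fr <- gls_profile(Xr, fit$y, fit$V, fit$lambda)
    q <- p_full - ncol(Xr)
    Fstat <- ((fr$rss - fit$rss) / q) / (fit$rss / (n - p_full))
    out$df1[i] <- q
    out$F[i] <- Fstat
    out$p[i] <- stats::pf(Fstat, q, n - p_full, lower.tail = FALSE)
  }
  out
}

#' Default candidate model set
#'
#' All subsets of the three predictors (log genome size, vegetation type,
#' log dry-season precipitation), plus the vegetation x genome interaction
#' model.
#'
#' @param response Response column name.
#' @param genome,vegetation,precip Predictor column names.
#' @return List of [model_spec()] objects.
#' @export
default_candidate_specs <- function(response = "log10_guard_cell_length",
                                    genome = "log10_genome_size_2C",
                                    vegetation = "vegetation",
                                    precip = "log10_dry_quarter_precip") {
  preds <- c(genome, vegetation, precip)  # precip = NULL drops the term
  subsets <- unlist(lapply(0:length(preds), function(k)
    utils::combn(preds, k, simplify = FALSE)), recursive = FALSE)
  specs <- lapply(subsets, function(s) model_spec(response, s))
  c(specs, list(model_spec(response, c(genome, vegetation,
                                       paste0(genome, ":", vegetation)))))
}

#' AIC model competition over candidate PGLS specifications
#'
#' Fits every candidate with lambda re-estimated by ML per model, and
#' returns a table sorted by AIC with a delta-AIC column, a
#' `competitive` flag (delta < 2) and a `much_poorer` flag (delta >= 10).
#' Exact AIC ties are broken by parameter count (fewer first), then by
#' the spec label.
#'
#' @param tree,data As in [fit_pgls()].
#' @param specs List of [model_spec()] objects; defaults to
#'   [default_candidate_specs()] on the response of the first spec.
#' @return Data frame of ranked models; the fitted objects are attached
#'   as attribute `"fits"` in ranked order.
#' @export
model_selection <- function(tree, data, specs) {
  if (length(specs) < 2) stop("need at least 2 candidate specifications")
  fits <- lapply(specs, function(s) fit_pgls(tree, data, s, lambda = "ML"))
  tab <- data.frame(
    model = vapply(fits, function(f) spec_label(f$spec), character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    lambda = vapply(fits, function(f) f$lambda, numeric(1)),
    logL = vapply(fits, function(f) f$logL, numeric(1)),
    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(tab$AIC, tab$k, tab$model)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  tab$competitive <- tab$delta_AIC < 2
  tab$much_poorer <- tab$delta_AIC >= 10
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}
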