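# Nested variance components by maximum likelihood: genus /
# species-within-genus / replicate-within-species, with standard errors
# from the inverse observed information at the optimum.

# per-species sufficient statistics for the nested likelihood
nested_stats <- function(value, genus, species) {
  key <- paste(genus, species, sep = "\r")
  idx <- split(seq_along(value), key)
  ybar <- vapply(idx, function(i) mean(value[i]), numeric(1))
  ss <- vapply(idx, function(i) sum((value[i] - mean(value[i]))^2), numeric(1))
  nrep <- vapply(idx, length, integer(1))
  gen <- vapply(idx, function(i) as.character(genus[i][1]), character(1))
  glev <- sort(unique(gen))
  list(ybar = as.numeric(ybar), ss = as.numeric(ss), nrep = nrep,
       genus_id = match(gen, glev) - 1L, genus_levels = glev,
       n_species = length(ybar), n_obs = length(value))
}

#' Fit nested variance components by maximum likelihood
#'
#' Fits the random-effects model
#' `y_ijk = mu + g_i + s_ij + e_ijk`, with independent
#' `g ~ N(0, sigma2_genus)`, `s ~ N(0, sigma2_species)` and
#' `e ~ N(0, sigma2_resid)`, by maximizing the likelihood (mean profiled
#' out by GLS) over log-variances with a boundary projection at
#' `1e-12 x` the total variance. ML is the default, matching the
#' among-genus shrinkage of ML genus variances; `reml = TRUE` is
#' available for sensitivity analyses. Standard errors come from the
#' inverse observed information (central-difference Hessian of the
#' profile likelihood on the variance scale); components estimated at the
#' zero boundary are reported as 0 with `NA` standard errors and flagged.
#'
#' @param table Data frame of per-replicate records.
#' @param trait Name of the (log-scale) trait column.
#' @param genus,species,replicate Grouping column names (`replicate` is
#'   only used to check the table shape; rows within a species are the
#'   replicates).
#' @param reml Use REML instead of ML.
#' @return An object of class `"nested_vc"`: components, SEs, proportions
#'   (fractions summing to 1), `logL`, counts, `boundary` flags.
#' @examples
#' d <- simulate_nested_dataset(n_genera = 10, n_species = 3, n_reps = 2,
#'                              sigma2 = c(1, 0.5, 0.25), seed = 1)
#' fit_nested_vc(d, trait = "value")
#' @export
fit_nested_vc <- function(table, trait = "value", genus = "genus",
                          species = "species", replicate = "replicate",
                          reml = FALSE) {
  stopifnot(is.data.frame(table))
  for (cc in c(trait, genus, species))
    if (!cc %in% names(table)) stop("no such column: ", cc)
  y <- table[[trait]]
  if (anyNA(y)) stop("trait column contains NA")
  st <- nested_stats(y, table[[genus]], table[[species]])
  G <- length(st$genus_levels)
  if (G < 2)
    stop("need at least 2 genera; sigma2_genus is inestimable with ", G)
  if (stats::var(y) == 0)
    stop("all observations are identical; variance components are degenerate")

  fit <- nested_ml_cpp(st$ybar, st$ss, st$nrep, st$genus_id, G, reml)
  s2 <- fit$sigma2
  vtot <- fit$vtot
  boundary <- s2 <= 1e-9 * vtot
  s2[boundary] <- 0

  se <- rep(NA_real_, 3)
  if (any(!boundary)) {
    nll <- function(p) {
      full <- s2
      full[!boundary] <- p
      nested_nll_cpp(full, st$ybar, st$ss, st$nrep, st$genus_id, G, reml)
    }
    free <- s2[!boundary]
    H <- tryCatch(fd_hessian(nll, free), error = function(e) NULL)
    if (!is.null(H)) {
      Hi <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Hi)) {
        dg <- diag(Hi)
        ok <- dg > 0
        se[!boundary][ok] <- sqrt(dg[ok])
      }
    }
  }
  total <- sum(s2)
  structure(list(
    sigma2_genus = s2[1], sigma2_species = s2[2], sigma2_resid = s2[3],
    se = stats::setNames(se, c("genus", "species", "resid")),
    proportions = stats::setNames(s2 / total, c("genus", "species", "resid")),
    logL = fit$logL, method = if (reml) "REML" else "ML",
    boundary = stats::setNames(boundary, c("genus", "species", "resid")),
    n_genera = G, n_species = st$n_species, n_obs = st$n_obs),
    class = "nested_vc")
}

# central-difference Hessian with per-coordinate relative steps
fd_hessian <- function(f, x, rel = 1e-4) {
  p <- length(x)
  h <- pmax(abs(x) * rel, 1e-12)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        H[i, i] <- (f(x + h * (seq_len(p) == i)) - 2 * f(x) +
                      f(x - h * (seq_len(p) == i))) / h[i]^2
      } else {
        ei <- h * (seq_len(p) == i)
        ej <- h * (seq_len(p) == j)
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' @export
print.nested_vc <- function(x, ...) {
  cat(sprintf("Nested variance components (%s): %d genera, %d species, %d obs\n",
              x$method, x$n_genera, x$n_species, x$n_obs))
  comp <- c(x$sigma2_genus, x$sigma2_species, x$sigma2_resid)
  tab <- data.frame(component = c("genus", "species-within-genus",
                                  "replicate"),
                    sigma2 = comp, SE = x$se,
                    percent = 100 * x$proportions)
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("logL = %.4f\n", x$logL))
  invisible(x)
}

#' Variance proportions per level, in percent
#'
#' @param vc A `"nested_vc"` fit.
#' @return Named numeric vector (percent) for genus, species-within-genus
#'   and replicate levels.
#' @export
variance_proportions <- function(vc) {
  stopifnot(inherits(vc, "nested_vc"))
  comp <- c(genus = vc$sigma2_genus, species = vc$sigma2_species,
            resid = vc$sigma2_resid)
  total <- sum(comp)
  if (total <= 0) stop("total variance is zero; proportions undefined")
  100 * comp / total
}
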