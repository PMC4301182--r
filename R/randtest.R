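# Genus-bootstrap randomization test: is the within-genus share of
# variance, expressed relative to the among-genus component, larger for
# trait A (guard cell length) than for trait B (genome size)?

#' Genus-bootstrap test comparing within-genus variance ratios
#'
#' For each trait the statistic is `rho = sigma2_species / sigma2_genus`
#' from the nested ML fit ([fit_nested_vc()]); the test statistic is
#' `D = rho_A - rho_B`. Genera are resampled with replacement (the same
#' drawn genus list applied to both traits, duplicated genera relabeled
#' as distinct units, each genus keeping its species/replicate records
#' intact), and both rho are recomputed per replicate. The one-sided
#' p-value, for the directional claim that trait A carries relatively
#' more within-genus variance, is
#' `p = (1 + #replicates with D <= 0) / (n_reps + 1)`.
#'
#' A resample whose genus variance is estimated at the zero boundary gets
#' `rho = +Inf` (the within-genus share is then total relative to a nil
#' among-genus component); such replicates are counted in
#' `n_degenerate`.
#'
#' @param table_a,table_b Per-replicate record tables for the two traits,
#'   sharing the same genus set; every genus needs at least 2 species.
#'   Trait values should be on the log scale (the ratio statistic is
#'   scale-free either way).
#' @param trait_a,trait_b Trait column names.
#' @param genus,species Grouping column names (shared by both tables).
#' @param n_reps Number of bootstrap replicates (default 9999).
#' @param seed Optional integer seed.
#' @return An object of class `"genus_bootstrap"`: `observed_D`, `rho_a`,
#'   `rho_b`, `replicate_Ds`, `p_one_sided`, `n_reps`, `seed`,
#'   `n_degenerate`.
#' @examples
#' a <- simulate_nested_dataset(13, n_species = c(2, 3), n_reps = 2,
#'                              sigma2 = c(1, 2.6, 0.25), seed = 1)
#' b <- simulate_nested_dataset(13, n_species = c(2, 3), n_reps = 2,
#'                              sigma2 = c(1, 0.06, 0.25), seed = 2)
#' genus_bootstrap_test(a, b, n_reps = 199, seed = 3)
#' @export
genus_bootstrap_test <- function(table_a, table_b, trait_a = "value",
                                 trait_b = trait_a, genus = "genus",
                                 species = "species", n_reps = 9999,
                                 seed = NULL) {
  sa <- nested_stats(table_a[[trait_a]], table_a[[genus]],
                     table_a[[species]])
  sb <- nested_stats(table_b[[trait_b]], table_b[[genus]],
                     table_b[[species]])
  if (!identical(sa$genus_levels, sb$genus_levels))
    stop("the two tables must share the same genus set; differ on: ",
         paste(utils::head(c(setdiff(sa$genus_levels, sb$genus_levels),
                             setdiff(sb$genus_levels, sa$genus_levels)), 5),
               collapse = ", "))
  for (st in list(a = sa, b = sb)) {
    m <- tabulate(st$genus_id + 1L, nbins = length(st$genus_levels))
    if (any(m < 2))
      stop("every genus needs >= 2 species; offending: ",
           paste(st$genus_levels[m < 2], collapse = ", "))
  }
  G <- length(sa$genus_levels)

  rho_of <- function(tab, trait) {
    vc <- fit_nested_vc(tab, trait = trait, genus = genus,
                        species = species)
    if (vc$boundary["genus"]) Inf else vc$sigma2_species / vc$sigma2_genus
  }
  rho_a <- rho_of(table_a, trait_a)
  rho_b <- rho_of(table_b, trait_b)
  observed_D <- if (is.infinite(rho_a) && is.infinite(rho_b)) 0
                else rho_a - rho_b

  if (!is.null(seed)) set.seed(seed)
  boot <- genus_bootstrap_cpp(sa$ybar, sa$ss, sa$nrep, sa$genus_id,
                              sb$ybar, sb$ss, sb$nrep, sb$genus_id,
                              G, as.integer(n_reps))
  D <- boot$D
  p <- (1 + sum(D <= 0)) / (n_reps + 1)
  structure(list(observed_D = observed_D, rho_a = rho_a, rho_b = rho_b,
                 replicate_Ds = D, p_one_sided = p, n_reps = n_reps,
                 seed = seed, n_degenerate = boot$n_degenerate,
                 n_genera = G),
            class = "genus_bootstrap")
}

#' @export
print.genus_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Genus bootstrap test (%d genera, %d replicates%s)\n",
    x$n_genera, x$n_reps,
    if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  cat(sprintf("  rho_A = %.4g, rho_B = %.4g, observed D = %.4g\n",
              x$rho_a, x$rho_b, x$observed_D))
  cat(sprintf("  one-sided p = %.4g (%d degenerate replicates)\n",
              x$p_one_sided, x$n_degenerate))
  invisible(x)
}
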