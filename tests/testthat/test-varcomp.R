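test_that("degenerate nesting collapses species and replicate variance", {
  # every replicate equal within species, every species equal within genus
  vals <- c(1.0, 2.5, 4.0, 7.0)                 # one value per genus
  tab <- data.frame(genus = rep(sprintf("G%d", 1:4), each = 4),
                    species = rep(sprintf("G%d_s%d", rep(1:4, each = 2),
                                          rep(1:2, 4)), each = 2),
                    replicate = rep(1:2, 8),
                    value = rep(vals, each = 4))
  vc <- fit_nested_vc(tab)
  expect_equal(vc$sigma2_species, 0)
  expect_equal(vc$sigma2_resid, 0)
  expect_true(vc$boundary["species"] && vc$boundary["resid"])
  # ML genus variance carries the (G-1)/G shrinkage; the flat boundary
  # directions limit the attainable precision here
  expect_equal(vc$sigma2_genus, mean((vals - mean(vals))^2),
               tolerance = 1e-2)
})

test_that("single genus and constant data are refused", {
  one <- simulate_nested_dataset(1, 3, 2, seed = 1)
  expect_error(fit_nested_vc(one), "at least 2 genera")
  flat <- simulate_nested_dataset(4, 2, 2, sigma2 = c(0, 0, 0), mu = 3,
                                  seed = 1)
  expect_error(fit_nested_vc(flat), "identical")
})

test_that("ML estimates agree with lme4 and with the EM oracle", {
  for (s in 1:3) {
    d <- simulate_nested_dataset(12, 3, 2, sigma2 = c(1, 0.5, 0.25),
                                 seed = 60 + s)
    vc <- fit_nested_vc(d)
    est <- c(vc$sigma2_genus, vc$sigma2_species, vc$sigma2_resid)

    em <- em_nested(d)
    expect_equal(est, em$sigma2, tolerance = 1e-4)

    m <- lme4::lmer(value ~ 1 + (1 | genus) + (1 | genus:species),
                    data = d, REML = FALSE)
    v <- as.data.frame(lme4::VarCorr(m))
    ref <- c(v$vcov[v$grp == "genus"], v$vcov[v$grp == "genus:species"],
             v$vcov[v$grp == "Residual"])
    expect_equal(est, ref, tolerance = 1e-4)
    expect_equal(vc$logL, as.numeric(logLik(m)), tolerance = 1e-6)
  }
})

test_that("REML flag reproduces lme4's REML fit", {
  d <- simulate_nested_dataset(10, 3, 2, sigma2 = c(1, 0.4, 0.2),
                               seed = 71)
  vc <- fit_nested_vc(d, reml = TRUE)
  m <- lme4::lmer(value ~ 1 + (1 | genus) + (1 | genus:species),
                  data = d, REML = TRUE)
  v <- as.data.frame(lme4::VarCorr(m))
  ref <- c(v$vcov[v$grp == "genus"], v$vcov[v$grp == "genus:species"],
           v$vcov[v$grp == "Residual"])
  expect_equal(c(vc$sigma2_genus, vc$sigma2_species, vc$sigma2_resid),
               ref, tolerance = 1e-3)
})

test_that("scale and shift equivariance of the components", {
  d <- simulate_nested_dataset(15, 3, 2, sigma2 = c(1, 0.5, 0.25),
                               seed = 81)
  vc <- fit_nested_vc(d)
  d2 <- d
  d2$value <- 3 * d$value
  vc2 <- fit_nested_vc(d2)
  expect_equal(c(vc2$sigma2_genus, vc2$sigma2_species, vc2$sigma2_resid),
               9 * c(vc$sigma2_genus, vc$sigma2_species, vc$sigma2_resid),
               tolerance = 1e-4)
  expect_equal(vc2$proportions, vc$proportions, tolerance = 1e-5)
  d3 <- d
  d3$value <- d$value + 100
  vc3 <- fit_nested_vc(d3)
  expect_equal(vc3$sigma2_genus, vc$sigma2_genus, tolerance = 1e-5)
})

test_that("variance proportions are plain arithmetic", {
  vc <- list(sigma2_genus = 1, sigma2_species = 1, sigma2_resid = 2)
  class(vc) <- "nested_vc"
  expect_equal(unname(variance_proportions(vc)), c(25, 25, 50))
  vc0 <- list(sigma2_genus = 3, sigma2_species = 0, sigma2_resid = 0)
  class(vc0) <- "nested_vc"
  expect_equal(unname(variance_proportions(vc0)), c(100, 0, 0))

  d <- simulate_nested_dataset(10, 3, 2, seed = 91)
  f <- fit_nested_vc(d)
  comps <- c(f$sigma2_genus, f$sigma2_species, f$sigma2_resid)
  expect_equal(unname(variance_proportions(f)),
               100 * comps / sum(comps), tolerance = 1e-12)
  expect_equal(sum(f$proportions), 1, tolerance = 1e-9)

  bad <- list(sigma2_genus = 0, sigma2_species = 0, sigma2_resid = 0)
  class(bad) <- "nested_vc"
  expect_error(variance_proportions(bad), "zero")
})

test_that("standard errors are finite for interior optima", {
  d <- simulate_nested_dataset(40, 3, 2, sigma2 = c(1, 0.5, 0.25),
                               seed = 95)
  vc <- fit_nested_vc(d)
  expect_true(all(is.finite(vc$se)))
  expect_true(all(vc$se > 0))
})
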