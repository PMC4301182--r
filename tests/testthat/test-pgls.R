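pgls_fixture <- function(n = 12, seed = 1, lambda = 0.8) {
  tr <- simulate_tree(n, seed = seed)
  x <- simulate_bm_trait(tr, sigma2 = 0.02, seed = seed + 1)
  veg <- rep(c("open", "closed"), length.out = n)
  y <- 1 + 0.5 * x + 0.2 * (veg == "open") +
    simulate_bm_trait(tr, sigma2 = 0.01, lambda = lambda, seed = seed + 2)
  data <- data.frame(tip = tr$tip.label, y = as.numeric(y),
                     x = as.numeric(x), veg = veg,
                     stringsAsFactors = FALSE)
  list(tree = tr, data = data)
}

test_that("model_spec rejects interactions without both main effects", {
  expect_error(model_spec("y", c("x", "x:veg")), "both main effects")
  expect_silent(model_spec("y", c("x", "veg", "x:veg")))
})

test_that("PGLS at lambda = 0 equals OLS on an ultrametric tree", {
  fx <- pgls_fixture(15, seed = 3)
  fit <- fit_pgls(fx$tree, fx$data, model_spec("y", c("x", "veg")),
                  lambda = 0)
  ols <- coef(lm(y ~ x + veg, data = transform(fx$data,
                                               veg = factor(veg))))
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-8)
})

test_that("fixed-lambda PGLS equals whitened OLS on random instances", {
  for (s in 1:6) {
    n <- sample(8:15, 1)
    fx <- pgls_fixture(n, seed = 500 + s)
    lam <- c(0.2, 0.5, 0.9)[1 + s %% 3]
    fit <- fit_pgls(fx$tree, fx$data, model_spec("y", c("x", "veg")),
                    lambda = lam)
    X <- cbind(1, fx$data$x, fx$data$veg == "open")
    beta <- whitened_ols(X, fx$data$y, vcv_matrix(fx$tree), lam)
    expect_equal(unname(fit$coefficients), unname(beta),
                 tolerance = 1e-8)
  }
})

test_that("profile likelihood at lambda-hat dominates a fixed grid", {
  fx <- pgls_fixture(20, seed = 17)
  fit <- fit_pgls(fx$tree, fx$data, model_spec("y", "x"), lambda = "ML")
  for (l in c(0, 0.25, 0.5, 0.75, 1)) {
    f <- fit_pgls(fx$tree, fx$data, model_spec("y", "x"), lambda = l)
    expect_gte(fit$logL + 1e-7, f$logL)
  }
})

test_that("PGLS agrees with nlme::gls + corPagel", {
  fx <- pgls_fixture(30, seed = 23)
  fit <- fit_pgls(fx$tree, fx$data, model_spec("y", c("x", "veg")))
  dat <- transform(fx$data, veg = factor(veg))
  rownames(dat) <- dat$tip
  ref <- nlme::gls(y ~ x + veg, data = dat, method = "ML",
                   correlation = ape::corPagel(0.5, fx$tree,
                                               form = ~ tip))
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-3)
  expect_equal(fit$lambda,
               as.numeric(coef(ref$modelStruct$corStruct,
                               unconstrained = FALSE)),
               tolerance = 1e-3)
  expect_equal(fit$logL, as.numeric(logLik(ref)), tolerance = 1e-4)
})

test_that("rank deficiency and size guards raise clear errors", {
  fx <- pgls_fixture(12, seed = 29)
  fx$data$x2 <- fx$data$x
  expect_error(fit_pgls(fx$tree, fx$data, model_spec("y", c("x", "x2"))),
               "rank deficient")
  small <- pgls_fixture(5, seed = 31)
  expect_error(fit_pgls(small$tree, small$data,
                        model_spec("y", c("x", "veg"))),
               "fewer rows")
})

test_that("marginal F-tests: t^2 identity and interaction guard", {
  fx <- pgls_fixture(25, seed = 37)
  fit <- fit_pgls(fx$tree, fx$data, model_spec("y", c("x", "veg")))
  ft <- predictor_tests(fit)
  tstat <- fit$coefficients["x"] / sqrt(fit$vcov["x", "x"])
  expect_equal(unname(ft$F[ft$term == "x"]), unname(tstat^2),
               tolerance = 1e-6)

  fit_int <- fit_pgls(fx$tree, fx$data,
                      model_spec("y", c("x", "veg", "x:veg")))
  expect_error(predictor_tests(fit_int), "interaction remains")
})

test_that("fits are invariant to the categorical reference level", {
  fx <- pgls_fixture(18, seed = 41)
  fit1 <- fit_pgls(fx$tree, fx$data, model_spec("y", c("x", "veg")))
  flipped <- fx$data
  flipped$veg <- ifelse(flipped$veg == "open", "a_open", flipped$veg)
  fit2 <- fit_pgls(fx$tree, flipped, model_spec("y", c("x", "veg")))
  expect_equal(fit1$logL, fit2$logL, tolerance = 1e-8)
  expect_equal(fit1$AIC, fit2$AIC, tolerance = 1e-8)
  expect_equal(fit1$residuals, fit2$residuals, tolerance = 1e-8)
})

test_that("row permutation with matching tip keys leaves the fit unchanged", {
  fx <- pgls_fixture(16, seed = 43)
  fit1 <- fit_pgls(fx$tree, fx$data, model_spec("y", c("x", "veg")))
  perm <- fx$data[sample(nrow(fx$data)), ]
  fit2 <- fit_pgls(fx$tree, perm, model_spec("y", c("x", "veg")))
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-10)
  expect_equal(fit1$AIC, fit2$AIC, tolerance = 1e-10)
})

test_that("model selection ranks, flags and breaks ties deterministically", {
  fx <- pgls_fixture(25, seed = 47)
  specs <- list(model_spec("y", "x"),
                model_spec("y", "x"),               # duplicate
                model_spec("y", c("x", "veg")),
                model_spec("y", character()))
  tab <- model_selection(fx$tree, fx$data, specs)
  expect_equal(tab$AIC, sort(tab$AIC))
  expect_equal(tab$delta_AIC[1], 0)
  dup <- tab$AIC[tab$model == "x"]
  expect_equal(dup[1], dup[2])                      # determinism
  expect_true(all(tab$competitive == (tab$delta_AIC < 2)))
  expect_error(model_selection(fx$tree, fx$data, specs[1]), "at least 2")
})

test_that("AIC parameter count includes lambda only when estimated", {
  fx <- pgls_fixture(20, seed = 53)
  ml <- fit_pgls(fx$tree, fx$data, model_spec("y", "x"))
  fixed <- fit_pgls(fx$tree, fx$data, model_spec("y", "x"),
                    lambda = ml$lambda)
  expect_equal(ml$k, fixed$k + 1)
  expect_equal(ml$AIC, -2 * ml$logL + 2 * ml$k)
})
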