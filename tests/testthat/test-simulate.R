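test_that("simulated trees are dated, ultrametric and reproducible", {
  tiny <- simulate_tree(2, root_age = 10, seed = 1)
  expect_equal(unname(ape::node.depth.edgelength(tiny)[1:2]), c(10, 10))

  tr <- simulate_tree(50, seed = 2)
  expect_true(is_ultrametric(tr, tol = 1e-9))
  expect_equal(tr$Nnode, 49)                       # fully bifurcating
  expect_equal(root_age(tr), 95, tolerance = 1e-9)

  expect_identical(write_newick(simulate_tree(20, seed = 3)),
                   write_newick(simulate_tree(20, seed = 3)))
})

test_that("Brownian draws have the configured covariance structure", {
  tr <- simulate_tree(8, seed = 5, root_age = 10)
  V <- vcv_matrix(tr)
  lam <- 0.6
  sig2 <- 0.4
  target <- sig2 * lambda_vcv_for_test(V, lam)
  set.seed(6)
  draws <- vapply(1:2000, function(i)
    simulate_bm_trait(tr, sigma2 = sig2, lambda = lam, root = 2),
    numeric(8))
  emp <- stats::cov(t(draws))
  expect_lt(max(abs(emp - target)) / max(target), 0.10)
  expect_equal(unname(rowMeans(draws)), rep(2, 8), tolerance = 0.15)

  # lambda = 0: tips are independent
  draws0 <- vapply(1:2000, function(i)
    simulate_bm_trait(tr, sigma2 = sig2, lambda = 0), numeric(8))
  emp0 <- stats::cov(t(draws0))
  off <- emp0[upper.tri(emp0)]
  expect_lt(max(abs(off)), 0.15 * sig2 * root_age(tr))

  # vanishing rate pins every tip at the root value
  x <- simulate_bm_trait(tr, sigma2 = 1e-12, root = 7, seed = 8)
  expect_equal(unname(x), rep(7, 8), tolerance = 1e-4)
})

test_that("nested draws honour their variance components", {
  const <- simulate_nested_dataset(5, 3, 2, sigma2 = c(1, 0, 0), seed = 9)
  spread <- tapply(const$value, const$genus, function(v) diff(range(v)))
  expect_equal(as.numeric(spread), rep(0, 5), tolerance = 1e-12)

  # pure residual noise: among-genus ANOVA F has mean df2/(df2-2)
  fs <- vapply(1:300, function(i) {
    d <- simulate_nested_dataset(10, 3, 1, sigma2 = c(0, 0, 1),
                                 seed = 1000 + i)
    summary(stats::aov(value ~ genus, data = d))[[1]]$`F value`[1]
  }, numeric(1))
  expect_gt(mean(fs), 0.85)
  expect_lt(mean(fs), 1.35)

  # closing the loop with the ML fitter at large size
  big <- simulate_nested_dataset(200, 3, 2, sigma2 = c(1, 0.5, 0.25),
                                 seed = 12)
  vc <- fit_nested_vc(big)
  est <- c(vc$sigma2_genus, vc$sigma2_species, vc$sigma2_resid)
  expect_true(all(abs(est - c(1, 0.5, 0.25)) / c(1, 0.5, 0.25) < 0.15))
})

test_that("the synthetic study reproduces the sampling design", {
  sim <- simulate_study(study_config(seed = 42))
  expect_equal(nrow(sim$traits), 134)              # 67 species x 2 plants
  expect_equal(length(unique(sim$traits$species)), 67)
  expect_equal(length(unique(sim$traits$genus)), 48)
  n_sp <- tapply(sim$traits$species, sim$traits$genus,
                 function(s) length(unique(s)))
  expect_equal(sum(n_sp >= 2), 13)
  expect_equal(sort(unique(sim$traits$vegetation)), c("closed", "open"))
  expect_silent(validate_trait_table(sim$traits))
  expect_equal(length(sim$tree$tip.label), 48)
  expect_true(is_ultrametric(sim$tree, tol = 1e-9))

  # purely a function of the config
  sim2 <- simulate_study(study_config(seed = 42))
  expect_identical(sim$traits, sim2$traits)
  expect_identical(write_newick(sim$tree), write_newick(sim2$tree))

  # heavy-genome clade carries distinctly larger genomes
  g <- species_means(sim$traits_log)
  heavy <- g$genus %in% sim$heavy_clade
  expect_gt(mean(g$log10_genome_size_2C[heavy]),
            mean(g$log10_genome_size_2C[!heavy]) + 0.5)
})

test_that("zero within-genus genome spread shows up in the components", {
  sim <- simulate_study(study_config(seed = 3, genome_species_sd = 0,
                                     cyt_run_sd = 0.0194))
  tl <- sim$traits_log
  low <- suppressWarnings(build_datasets(tl, level = "low"))
  runs <- sim$cytometry[sim$cytometry$sample_id %in% low$species, ]
  est <- genome_size_from_run(runs$sample_peak, runs$ref_peak, runs$ref_2C)
  map <- unique(low[c("species", "genus")])
  tab <- data.frame(genus = map$genus[match(runs$sample_id, map$species)],
                    species = runs$sample_id, replicate = runs$run_id,
                    value = log10(est$genome_size_2C))
  vc <- fit_nested_vc(tab)
  expect_lt(vc$proportions["species"], 0.02)
})

test_that("cytometry runs reconstruct the simulated genome sizes", {
  sim <- simulate_study(study_config(seed = 21))
  est <- genome_size_from_run(sim$cytometry$sample_peak,
                              sim$cytometry$ref_peak,
                              sim$cytometry$ref_2C)$genome_size_2C
  by_sp <- tapply(log10(est), sim$cytometry$sample_id, mean)
  truth <- species_means(sim$traits_log)
  expect_equal(as.numeric(by_sp[truth$species]),
               truth$log10_genome_size_2C, tolerance = 1e-10)
})
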