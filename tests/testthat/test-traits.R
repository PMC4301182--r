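make_table <- function() {
  data.frame(species = rep(c("Ga_sp1", "Ga_sp2", "Gb_sp1"), each = 2),
             genus = rep(c("Ga", "Ga", "Gb"), each = 2),
             clade = "grevilleoid-proteoid",
             vegetation = rep(c("open", "closed", "open"), each = 2),
             replicate = rep(1:2, 3),
             guard_cell_length = c(20, 22, 30, 34, 40, 44),
             genome_size_2C = c(2, 2.1, 3, 3.1, 9, 9.2),
             stringsAsFactors = FALSE)
}

test_that("log_transform is base-10, renames, errors and inverts", {
  tab <- data.frame(species = "s", genus = "g", v = c(100, 9.49))
  out <- log_transform(tab, "v")
  expect_named(out, c("species", "genus", "log10_v"))
  expect_equal(out$log10_v[1], 2)
  expect_equal(signif(out$log10_v[2], 5), 0.97727)  # log10 of 9.49
  expect_equal(10^out$log10_v, tab$v, tolerance = 1e-12)

  bad <- data.frame(species = "s", genus = "g", v = c(1, 0))
  expect_error(log_transform(bad, "v"), "row 2")
  expect_error(log_transform(tab, "nope"), "no such column")
})

test_that("species_means averages replicates and is idempotent", {
  tab <- data.frame(species = c("a", "a", "b"), genus = c("A", "A", "B"),
                    x = c(1.2, 1.4, 5))
  m <- species_means(tab)
  expect_equal(m$x[m$species == "a"], 1.3)
  expect_equal(m$x[m$species == "b"], 5)     # single replicate unchanged
  expect_equal(m$n_replicates, c(2, 1))
  expect_equal(species_means(m)$x, m$x)      # idempotent

  # brute-force groupwise means with 3 replicates
  set.seed(3)
  tab3 <- data.frame(species = rep(letters[1:6], each = 3),
                     genus = rep(LETTERS[1:3], each = 6),
                     x = rnorm(18), y = rexp(18))
  m3 <- species_means(tab3)
  for (s in unique(tab3$species)) {
    expect_equal(m3$x[m3$species == s], mean(tab3$x[tab3$species == s]))
    expect_equal(m3$y[m3$species == s], mean(tab3$y[tab3$species == s]))
  }
})

test_that("validation enforces positivity and the vegetation factor", {
  tab <- make_table()
  expect_silent(validate_trait_table(tab))
  tab$guard_cell_length[2] <- -1
  expect_error(validate_trait_table(tab), "guard_cell_length")
  tab2 <- make_table()
  tab2$vegetation[1] <- "savanna"
  expect_error(validate_trait_table(tab2), "vegetation")
})

test_that("build_datasets shapes high-level data against the tree", {
  # species-terminal fixture: 51 species, 4 in a persoonioid-like clade
  sim <- simulate_study(study_config(seed = 8))
  traits <- sim$traits_log
  sm <- species_means(traits)
  sp51 <- sm$species[order(!sm$representative, sm$species)][1:51]
  tab51 <- traits[traits$species %in% sp51, ]
  tree51 <- simulate_tree(51, seed = 2, tip_labels = sort(sp51))

  hl <- build_datasets(tab51, tree51, scope = "whole-family", level = "high")
  expect_equal(nrow(hl$data), 51)
  expect_equal(length(hl$tree$tip.label), 51)
  expect_equal(hl$data$tip, hl$tree$tip.label)  # aligned

  n_pers <- length(unique(tab51$species[tab51$clade == "persoonioid"]))
  gp <- build_datasets(tab51, tree51, scope = "grevilleoid-proteoid",
                       level = "high")
  expect_equal(nrow(gp$data), 51 - n_pers)

  expect_error(build_datasets(tab51, tree51[c("edge", "Nnode")],
                              level = "high"))
})

test_that("genus fallback maps species to genus terminals", {
  sim <- simulate_study(study_config(seed = 9))
  hl <- suppressMessages(
    build_datasets(sim$traits_log, sim$tree, level = "high"))
  expect_equal(nrow(hl$data), length(sim$tree$tip.label))
  # the flagged representative is the one used for multi-species genera
  expect_true(all(hl$data$representative))
})

test_that("exclusions and the low-level shape are enforced", {
  sim <- simulate_study(study_config(seed = 10))
  tl <- sim$traits_log
  victim <- tl$species[1]
  low <- suppressWarnings(
    build_datasets(tl, level = "low", exclusions = victim))
  expect_false(victim %in% low$species)
  n_sp <- tapply(low$species, low$genus, function(s) length(unique(s)))
  expect_true(all(n_sp >= 2))
  expect_warning(build_datasets(tl, level = "low"), "single species")
})

test_that("scope partition is additive in row counts", {
  sim <- simulate_study(study_config(seed = 12))
  tl <- sim$traits_log
  whole <- suppressMessages(build_datasets(tl, sim$tree, "whole-family",
                                           "high"))
  gp <- suppressMessages(build_datasets(tl, sim$tree,
                                        "grevilleoid-proteoid", "high"))
  n_pers_genera <- length(sim$heavy_clade)
  expect_equal(nrow(whole$data), nrow(gp$data) + n_pers_genera)
})
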