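# Synthetic trees and trait tables with the statistical structure the
# analyses assume: pure-birth dated trees, Brownian traits with a lambda
# transform, nested genus/species/replicate tables, and a full synthetic
# study (tree + per-individual trait table + cytometry runs) emulating a
# 48-genus, 67-species sampling design with two replicate plants per
# species.

#' Simulate a pure-birth dated tree
#'
#' A Yule tree rescaled to the requested root age, hence ultrametric.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth Birth rate per lineage per Myr.
#' @param root_age Root age in Myr.
#' @param tip_labels Optional character vector of tip names.
#' @param seed Optional integer seed.
#' @return An ultrametric `"phylo"` tree.
#' @export
simulate_tree <- function(n_tips, birth = 0.06, root_age = 95,
                          tip_labels = NULL, seed = NULL) {
  stopifnot(n_tips >= 2)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (root_age / depth)
  if (!is.null(tip_labels)) {
    stopifnot(length(tip_labels) == n_tips)
    tree$tip.label <- tip_labels
  }
  tree
}

#' Simulate a Brownian trait with a lambda transform
#'
#' One draw from `N(root * 1, sigma2 * V(lambda))`, where V is the tree's
#' Brownian covariance matrix and lambda scales its off-diagonal. The
#' draw uses a matrix square-root factor of the full covariance, so
#' intermediate lambda values are exact (not approximated branch-wise).
#'
#' @param tree A `"phylo"` tree.
#' @param sigma2 Brownian rate (trait variance per Myr), > 0.
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @param root Root (ancestral) trait value.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm_trait <- function(tree, sigma2, lambda = 1, root = 0,
                              seed = NULL) {
  stopifnot(sigma2 > 0, lambda >= 0, lambda <= 1)
  if (!is.null(seed)) set.seed(seed)
  V <- lambda_vcv(vcv_matrix(tree), lambda)
  R <- chol(sigma2 * V)
  x <- root + as.numeric(t(R) %*% stats::rnorm(nrow(V)))
  names(x) <- tree$tip.label
  x
}

#' Simulate a nested genus/species/replicate dataset
#'
#' Draws `y_ijk = mu + g_i + s_ij + e_ijk` with independent normal
#' effects of variance `sigma2[1]` (genus), `sigma2[2]`
#' (species-within-genus) and `sigma2[3]` (replicate).
#'
#' @param n_genera Number of genera.
#' @param n_species Species per genus: a scalar, or a vector recycled
#'   across genera (e.g. `c(2, 3)` alternates 2 and 3 species).
#' @param n_reps Replicates per species.
#' @param sigma2 Length-3 vector of variance components (genus, species,
#'   replicate), all >= 0.
#' @param mu Grand mean.
#' @param seed Optional integer seed.
#' @return Data frame with columns `genus`, `species`, `replicate`,
#'   `value`.
#' @export
simulate_nested_dataset <- function(n_genera, n_species = 3, n_reps = 2,
                                    sigma2 = c(1, 0.5, 0.25), mu = 0,
                                    seed = NULL) {
  stopifnot(length(sigma2) == 3, all(sigma2 >= 0), n_genera >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- rep_len(n_species, n_genera)
  g_eff <- stats::rnorm(n_genera, 0, sqrt(sigma2[1]))
  rows <- vector("list", n_genera)
  for (i in seq_len(n_genera)) {
    s_eff <- stats::rnorm(m[i], 0, sqrt(sigma2[2]))
    e_eff <- stats::rnorm(m[i] * n_reps, 0, sqrt(sigma2[3]))
    rows[[i]] <- data.frame(
      genus = sprintf("Genus%02d", i),
      species = rep(sprintf("Genus%02d_sp%d", i, seq_len(m[i])),
                    each = n_reps),
      replicate = rep(seq_len(n_reps), m[i]),
      value = mu + g_eff[i] + rep(s_eff, each = n_reps) + e_eff,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration for a synthetic comparative study
#'
#' Defaults emulate the sampling design the analyses target: 48 genera
#' (one tree terminal each), 13 of them with 2-3 species for a total of
#' 67 species, two replicate plants per species for guard cells and two
#' replicate cytometry runs per species for genome size. Trait magnitudes
#' echo field-realistic ranges (guard cells roughly 19-72 um, 2C roughly
#' 1-60 pg with a heavy-genome clade), used as sanity bounds rather than
#' fitted values; the nested variance structure of guard cell length puts
#' most within-genus variation at the species level.
#'
#' @param seed Integer seed; every simulated quantity is a pure function
#'   of the configuration including this seed.
#' @param n_genera Number of genera (tree tips).
#' @param n_multi_2,n_multi_3 Number of genera carrying 2 resp. 3
#'   species; the rest have one.
#' @param root_age,birth Tree parameters (Myr, per-lineage birth rate).
#' @param gcl_reps Replicate plants per species for guard cells.
#' @param cyt_runs Replicate cytometry runs per species.
#' @param genome_mean_log10,genome_bm_sd Log10 2C mean and among-genus
#'   Brownian SD (at the root age).
#' @param heavy_clade_offset Log10 offset added to the heavy-genome
#'   (persoonioid-like) clade.
#' @param genome_species_sd Within-genus species SD of log10 2C.
#' @param cyt_run_sd Replicate-run SD of log10 2C.
#' @param gcl_intercept_log10 Log10 guard cell length at the mean genome
#'   size in closed forest.
#' @param beta_genome Slope of log10 guard cell length on log10 2C.
#' @param beta_vegetation Additive log10 effect of open vegetation.
#' @param beta_precip Slope on centered log10 dry-quarter precipitation
#'   (0 = no climate effect).
#' @param gcl_phylo_sd,gcl_lambda Phylogenetic residual SD (at root age)
#'   and its lambda.
#' @param gcl_species_sd,gcl_rep_sd Species-level and replicate-level
#'   residual SDs of log10 guard cell length.
#' @param p_open Probability a species is assigned to open vegetation.
#' @param veg_clumped If `TRUE`, vegetation is a two-state Markov switch
#'   evolved along the tree (habitat is phylogenetically clumped) instead
#'   of independent per species.
#' @param precip_mean_log10,precip_sd Log10 dry-quarter precipitation
#'   distribution (mm).
#' @param reference_2C Cytometry reference standard 2C (pg).
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(seed = 1, n_genera = 48, n_multi_2 = 7,
                         n_multi_3 = 6, root_age = 95, birth = 0.06,
                         gcl_reps = 2, cyt_runs = 2,
                         genome_mean_log10 = 0.7, genome_bm_sd = 0.35,
                         heavy_clade_offset = 1.0,
                         genome_species_sd = 0.01, cyt_run_sd = 0.0194,
                         gcl_intercept_log10 = log10(40),
                         beta_genome = 0.25, beta_vegetation = 0.16,
                         beta_precip = 0, gcl_phylo_sd = 0.04,
                         gcl_lambda = 1, gcl_species_sd = 0.14,
                         gcl_rep_sd = 0.04, p_open = 0.5,
                         veg_clumped = FALSE, precip_mean_log10 = 2,
                         precip_sd = 0.35, reference_2C = 9.49) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genera >= cfg$n_multi_2 + cfg$n_multi_3 + 1,
            cfg$p_open >= 0, cfg$p_open <= 1,
            cfg$gcl_lambda >= 0, cfg$gcl_lambda <= 1)
  structure(cfg, class = "study_config")
}

#' Simulate a full comparative study
#'
#' Generates a dated genus-level tree, assigns a heavy-genome clade (the
#' smallest clade of about four genera), evolves log genome size by
#' Brownian motion along the tree (nearly constant within genera), draws
#' vegetation per species, and builds guard cell length as
#' `log10 GCL = b0 + b1 (log10 2C - mean) + b2 [open] + b3 precip +
#' phylo noise + species noise + replicate noise`.
#' Cytometry runs are emitted with peak means consistent with the true
#' genome sizes against the reference standard.
#'
#' @param config A [study_config()].
#' @return A list with `tree` (tips = genera), `traits` (per-individual
#'   records, raw scale), `traits_log` (same with log10 trait columns),
#'   `cytometry` (per-run peak table), `heavy_clade` (genus names) and
#'   `config`.
#' @examples
#' sim <- simulate_study(study_config(seed = 42))
#' nrow(sim$traits)                 # 134 guard-cell rows
#' length(unique(sim$traits$species))
#' @export
simulate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  set.seed(cfg$seed)
  genera <- sprintf("Genus%02d", seq_len(cfg$n_genera))
  tree <- simulate_tree(cfg$n_genera, birth = cfg$birth,
                        root_age = cfg$root_age, tip_labels = genera)

  # heavy-genome clade: smallest internal clade of ~4 genera
  parts <- ape::prop.part(tree)
  sizes <- lengths(parts)
  ok <- which(sizes >= 2 & sizes <= 8)
  pick <- ok[which.min(abs(sizes[ok] - 4))]
  heavy <- tree$tip.label[parts[[pick]]]

  # species layout: deterministic given the config
  multi3 <- setdiff(genera, heavy)[seq_len(cfg$n_multi_3)]
  pool <- setdiff(genera, c(heavy, multi3))
  multi2 <- c(heavy[1], pool[seq_len(cfg$n_multi_2 - 1)])
  n_sp <- stats::setNames(rep(1L, cfg$n_genera), genera)
  n_sp[multi3] <- 3L
  n_sp[multi2] <- 2L

  # genome size: BM on the genus tree + heavy-clade offset
  g_log2c <- simulate_bm_trait(tree,
                               sigma2 = cfg$genome_bm_sd^2 / cfg$root_age,
                               lambda = 1, root = cfg$genome_mean_log10)
  g_log2c[heavy] <- g_log2c[heavy] + cfg$heavy_clade_offset

  # guard-cell phylogenetic residual at the genus level
  u_phylo <- simulate_bm_trait(tree,
                               sigma2 = cfg$gcl_phylo_sd^2 / cfg$root_age,
                               lambda = cfg$gcl_lambda, root = 0)

  # vegetation: per-species iid by default, or clumped along the tree
  veg_genus <- if (cfg$veg_clumped) {
    states <- ape::rTraitDisc(tree, model = "ER", k = 2, rate = 0.02,
                              states = VEG_LEVELS)
    as.character(states)
  } else NULL

  rows <- list()
  cyt <- list()
  for (gi in seq_along(genera)) {
    g <- genera[gi]
    for (si in seq_len(n_sp[g])) {
      sp <- sprintf("%s_sp%d", g, si)
      sp_log2c <- g_log2c[g] + stats::rnorm(1, 0, cfg$genome_species_sd)
      veg <- if (cfg$veg_clumped) veg_genus[gi]
             else sample(VEG_LEVELS, 1,
                         prob = c(1 - cfg$p_open, cfg$p_open))
      lprecip <- stats::rnorm(1, cfg$precip_mean_log10, cfg$precip_sd)
      sp_lgcl <- cfg$gcl_intercept_log10 +
        cfg$beta_genome * (sp_log2c - cfg$genome_mean_log10) +
        cfg$beta_vegetation * (veg == "open") +
        cfg$beta_precip * (lprecip - cfg$precip_mean_log10) +
        u_phylo[g] +
        stats::rnorm(1, 0, cfg$gcl_species_sd)
      # cytometry runs for this species
      run_l2c <- sp_log2c + stats::rnorm(cfg$cyt_runs, 0, cfg$cyt_run_sd)
      ref_peak <- stats::runif(cfg$cyt_runs, 180, 220)
      cyt[[sp]] <- data.frame(
        sample_id = sp, run_id = seq_len(cfg$cyt_runs),
        sample_peak = ref_peak * 10^run_l2c / cfg$reference_2C,
        ref_peak = ref_peak, ref_2C = cfg$reference_2C,
        stringsAsFactors = FALSE)
      measured_2c <- 10^mean(run_l2c)
      rep_lgcl <- sp_lgcl + stats::rnorm(cfg$gcl_reps, 0, cfg$gcl_rep_sd)
      rows[[sp]] <- data.frame(
        species = sp, genus = g,
        clade = if (g %in% heavy) "persoonioid" else "grevilleoid-proteoid",
        vegetation = veg, representative = si == 1L,
        replicate = seq_len(cfg$gcl_reps),
        guard_cell_length = 10^rep_lgcl,
        genome_size_2C = measured_2c,
        dry_quarter_precip = 10^lprecip,
        stringsAsFactors = FALSE)
    }
  }
  traits <- do.call(rbind, rows)
  rownames(traits) <- NULL
  cytometry <- do.call(rbind, cyt)
  rownames(cytometry) <- NULL
  validate_trait_table(traits)
  traits_log <- log_transform(traits, c("guard_cell_length",
                                        "genome_size_2C",
                                        "dry_quarter_precip"))
  list(tree = tree, traits = traits, traits_log = traits_log,
       cytometry = cytometry, heavy_clade = heavy, config = cfg)
}
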