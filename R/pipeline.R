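# End-to-end orchestration of the four-dataset workflow: per clade scope,
# a high-level (among-genus) signal + PGLS model-competition stage and a
# low-level (within-genus) variance-components + randomization stage.

#' Pipeline configuration
#'
#' Collects the inputs and settings of a full analysis run. Tree and
#' trait table may be given as objects or file paths (Newick / CSV);
#' files are read and validated here, before any stage runs.
#'
#' @param tree A `"phylo"` tree or Newick file path (tips = genera or
#'   species terminals).
#' @param traits A per-individual trait table (raw measurement scale) or
#'   CSV path.
#' @param cytometry Optional per-run cytometry peak table or CSV path;
#'   when present, low-level genome-size replicates are the individual
#'   runs re-estimated through [genome_size_from_run()].
#' @param scopes Clade scopes to analyse.
#' @param exclusions Species excluded before the low-level (within-genus)
#'   analyses, e.g. known neopolyploids.
#' @param candidate_specs Candidate model list for
#'   [model_selection()]; `NULL` for [default_candidate_specs()].
#' @param use_replicate_means Analyse species means of the replicates at
#'   high level (default) rather than replicate 1 only.
#' @param n_perm Permutations for Blomberg's K.
#' @param n_reps Bootstrap replicates for the randomization test.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(tree, traits, cytometry = NULL,
                            scopes = c("whole-family",
                                       "grevilleoid-proteoid"),
                            exclusions = character(),
                            candidate_specs = NULL,
                            use_replicate_means = TRUE,
                            n_perm = 999, n_reps = 9999, seed = 1) {
  if (is.character(tree)) {
    if (!file.exists(tree)) stop("tree file not found: ", tree)
    tree <- read_newick(file = tree)
  }
  validate_tree_quiet(tree)
  if (is.character(traits)) {
    if (!file.exists(traits)) stop("trait file not found: ", traits)
    traits <- read_trait_table(traits)
  }
  validate_trait_table(traits)
  if (is.character(cytometry)) {
    if (!file.exists(cytometry)) stop("cytometry file not found: ", cytometry)
    cytometry <- read_cytometry_runs(cytometry)
  }
  scopes <- match.arg(scopes, c("whole-family", "grevilleoid-proteoid"),
                      several.ok = TRUE)
  if (!is.null(candidate_specs) && length(candidate_specs) < 2)
    stop("candidate model set must contain at least 2 specifications")
  structure(list(tree = tree, traits = traits, cytometry = cytometry,
                 scopes = scopes, exclusions = exclusions,
                 candidate_specs = candidate_specs,
                 use_replicate_means = use_replicate_means,
                 n_perm = n_perm, n_reps = n_reps, seed = seed),
            class = "pipeline_config")
}

log_trait_cols <- function(traits) {
  cols <- intersect(c("guard_cell_length", "genome_size_2C",
                      "dry_quarter_precip"), names(traits))
  log_transform(traits, cols)
}

stage_seed <- function(config, scope, stage) {
  (config$seed * 7L + match(scope, c("whole-family",
                                     "grevilleoid-proteoid")) * 131L +
     stage * 17L) %% 2147483647L
}

#' Run the high-level (among-genus) analyses
#'
#' For each scope: phylogenetic signal (Blomberg's K with permutation p,
#' Pagel's lambda with LR p) of log genome size and log guard cell
#' length, and AIC competition of the PGLS candidate models for log
#' guard cell length. The trait table is log10-transformed and collapsed
#' to species means (or to replicate 1, see `use_replicate_means`)
#' before tip matching.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; per-scope `signal_*.csv` and
#'   `models_*.csv` files plus a `manifest.json` are written there.
#' @return Named list (one element per scope) of lists with `signal` and
#'   `models` data frames; invisibly writes files when `out_dir` is set.
#' @export
run_high_level <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  traits <- config$traits
  if (!config$use_replicate_means && "replicate" %in% names(traits))
    traits <- traits[traits$replicate == traits$replicate[1], , drop = FALSE]
  tl <- log_trait_cols(traits)
  out <- list()
  for (scope in config$scopes) {
    hl <- build_datasets(tl, config$tree, scope = scope, level = "high")
    message(sprintf("[high/%s] %d terminals, seed %d", scope,
                    nrow(hl$data), config$seed))
    sig <- list()
    for (trait in c("log10_genome_size_2C", "log10_guard_cell_length")) {
      x <- stats::setNames(hl$data[[trait]], hl$data$tip)
      bk <- blomberg_k(hl$tree, x, n_perm = config$n_perm,
                       seed = stage_seed(config, scope, 1L))
      pl <- pagel_lambda_ml(hl$tree, x)
      sig[[trait]] <- data.frame(scope = scope, trait = trait,
                                 K = bk$K, p_K = bk$p,
                                 lambda = pl$lambda, p_lambda = pl$p,
                                 stringsAsFactors = FALSE)
    }
    specs <- config$candidate_specs
    if (is.null(specs)) {
      specs <- default_candidate_specs()
      if (!"log10_dry_quarter_precip" %in% names(hl$data))
        specs <- default_candidate_specs(precip = NULL)
    }
    models <- model_selection(hl$tree, hl$data, specs)
    out[[scope]] <- list(signal = do.call(rbind, sig), models = models)
    rownames(out[[scope]]$signal) <- NULL
  }
  if (!is.null(out_dir)) write_high_level(out, config, out_dir)
  out
}

#' Run the low-level (within-genus) analyses
#'
#' For each scope: nested variance components (genus /
#' species-within-genus / replicate) of log guard cell length and of log
#' genome size, and the genus-bootstrap randomization test of whether
#' guard cell length carries relatively more within-genus variance than
#' genome size. Excluded species are removed first; genera left with one
#' species are dropped with a warning. Genome-size replicates are
#' cytometry runs when a run table is configured, otherwise the rows of
#' the trait table.
#'
#' @inheritParams run_high_level
#' @return Named list (per scope) with `varcomp` (data frame of
#'   components, SEs and percentages per trait), `randomization`
#'   (a `"genus_bootstrap"` object), and the low-level tables used.
#' @export
run_low_level <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  tl <- log_trait_cols(config$traits)
  out <- list()
  for (scope in config$scopes) {
    low_gcl <- build_datasets(tl, config$tree, scope = scope,
                              level = "low",
                              exclusions = config$exclusions)
    low_gen <- low_genome_table(config, low_gcl)
    # the two tables must cover the same genus set
    shared <- intersect(unique(low_gcl$genus), unique(low_gen$genus))
    low_gcl <- low_gcl[low_gcl$genus %in% shared, , drop = FALSE]
    low_gen <- low_gen[low_gen$genus %in% shared, , drop = FALSE]
    message(sprintf("[low/%s] %d genera, %d guard-cell rows, %d genome rows",
                    scope, length(shared), nrow(low_gcl), nrow(low_gen)))
    vc_gcl <- fit_nested_vc(low_gcl, trait = "log10_guard_cell_length")
    vc_gen <- fit_nested_vc(low_gen, trait = "log10_genome_size_2C")
    vc_tab <- rbind(vc_row(vc_gcl, scope, "log10_guard_cell_length"),
                    vc_row(vc_gen, scope, "log10_genome_size_2C"))
    rt <- genus_bootstrap_test(low_gcl, low_gen,
                               trait_a = "log10_guard_cell_length",
                               trait_b = "log10_genome_size_2C",
                               n_reps = config$n_reps,
                               seed = stage_seed(config, scope, 2L))
    out[[scope]] <- list(varcomp = vc_tab, randomization = rt,
                         guard_cell_table = low_gcl,
                         genome_table = low_gen)
  }
  if (!is.null(out_dir)) write_low_level(out, config, out_dir)
  out
}

# genome-size records at replicate (run) level for the low-level stage
low_genome_table <- function(config, low_gcl) {
  sp_keep <- unique(low_gcl$species)
  if (!is.null(config$cytometry)) {
    cyt <- config$cytometry
    if (!"genome_size_2C" %in% names(cyt)) {
      est <- genome_size_from_run(cyt$sample_peak, cyt$ref_peak, cyt$ref_2C)
      cyt$genome_size_2C <- est$genome_size_2C
    }
    cyt <- cyt[cyt$sample_id %in% sp_keep, , drop = FALSE]
    map <- unique(low_gcl[c("species", "genus")])
    tab <- data.frame(species = cyt$sample_id,
                      genus = map$genus[match(cyt$sample_id, map$species)],
                      replicate = cyt$run_id,
                      log10_genome_size_2C = log10(cyt$genome_size_2C),
                      stringsAsFactors = FALSE)
    return(tab)
  }
  low_gcl[c("species", "genus", "replicate", "log10_genome_size_2C")]
}

vc_row <- function(vc, scope, trait) {
  data.frame(scope = scope, trait = trait,
             sigma2_genus = vc$sigma2_genus,
             sigma2_species = vc$sigma2_species,
             sigma2_resid = vc$sigma2_resid,
             se_genus = vc$se["genus"], se_species = vc$se["species"],
             se_resid = vc$se["resid"],
             pct_genus = 100 * vc$proportions["genus"],
             pct_species = 100 * vc$proportions["species"],
             pct_resid = 100 * vc$proportions["resid"],
             logL = vc$logL, n_genera = vc$n_genera,
             n_species = vc$n_species, n_obs = vc$n_obs,
             row.names = NULL, stringsAsFactors = FALSE)
}

write_high_level <- function(out, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (scope in names(out)) {
    utils::write.csv(out[[scope]]$signal,
                     file.path(out_dir, paste0("signal_", scope, ".csv")),
                     row.names = FALSE)
    models <- out[[scope]]$models
    attr(models, "fits") <- NULL
    utils::write.csv(models,
                     file.path(out_dir, paste0("models_", scope, ".csv")),
                     row.names = FALSE)
  }
  write_manifest(config, out_dir, stage = "high")
}

write_low_level <- function(out, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (scope in names(out)) {
    utils::write.csv(out[[scope]]$varcomp,
                     file.path(out_dir, paste0("varcomp_", scope, ".csv")),
                     row.names = FALSE)
    rt <- out[[scope]]$randomization
    jsonlite::write_json(
      list(observed_D = rt$observed_D, rho_a = rt$rho_a, rho_b = rt$rho_b,
           p_one_sided = rt$p_one_sided, n_reps = rt$n_reps,
           seed = rt$seed, n_degenerate = rt$n_degenerate),
      file.path(out_dir, paste0("randtest_", scope, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  write_manifest(config, out_dir, stage = "low")
}

write_manifest <- function(config, out_dir, stage) {
  jsonlite::write_json(
    list(stage = stage, seed = config$seed, scopes = config$scopes,
         exclusions = config$exclusions,
         n_traits_rows = nrow(config$traits),
         n_tree_tips = length(config$tree$tip.label),
         n_perm = config$n_perm, n_reps = config$n_reps),
    file.path(out_dir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA)
}
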