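# Per-individual trait tables and construction of the four analysis
# datasets: {whole-family, ingroup-clade} x {high level (one terminal per
# genus), low level (replicate species within genera)}.

VEG_LEVELS <- c("closed", "open")

#' Validate a per-individual trait table
#'
#' A trait table holds one row per measured individual (or cytometry run)
#' with columns `species`, `genus`, `replicate`, optionally `clade`
#' (`"persoonioid"` / `"grevilleoid-proteoid"`), `vegetation` (`"open"` /
#' `"closed"`), and positive trait columns such as `guard_cell_length`
#' (micrometres) and `genome_size_2C` (picograms). `dry_quarter_precip`
#' (mm) may be zero.
#'
#' @param table A data frame.
#' @param trait_cols Trait columns that must be strictly positive when
#'   present.
#' @return `table`, invisibly.
#' @export
validate_trait_table <- function(table,
                                 trait_cols = c("guard_cell_length",
                                                "genome_size_2C")) {
  stopifnot(is.data.frame(table))
  needed <- c("species", "genus")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop("trait table lacks columns: ", paste(missing_cols, collapse = ", "))
  for (cc in intersect(trait_cols, names(table))) {
    v <- table[[cc]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      stop(sprintf("column '%s' must be positive; offending row(s): %s",
                   cc, paste(utils::head(bad, 5), collapse = ", ")))
  }
  if ("vegetation" %in% names(table)) {
    v <- stats::na.omit(unique(as.character(table$vegetation)))
    if (!all(v %in% VEG_LEVELS))
      stop("vegetation must be one of ", paste(VEG_LEVELS, collapse = "/"),
           "; found: ", paste(setdiff(v, VEG_LEVELS), collapse = ", "))
  }
  if ("dry_quarter_precip" %in% names(table)) {
    if (any(table$dry_quarter_precip < 0, na.rm = TRUE))
      stop("dry_quarter_precip must be >= 0")
  }
  invisible(table)
}

#' Read a trait table from CSV
#'
#' UTF-8, header row, comma separated; columns are referenced by name.
#'
#' @param file Path to a CSV file.
#' @return A validated data frame.
#' @export
read_trait_table <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_trait_table(tab)
  tab
}

#' Log10-transform trait columns
#'
#' Applies a base-10 logarithm to the named columns and renames them with a
#' `log10_` prefix. Trait distributions here (genome size, guard cell
#' length, dry-season precipitation) are right-skewed, and all models are
#' fitted on the log scale.
#'
#' @param table A data frame.
#' @param columns Character vector of column names to transform.
#' @return The transformed data frame.
#' @examples
#' log_transform(data.frame(species = "x", genus = "g",
#'                          genome_size_2C = 9.49), "genome_size_2C")
#' @export
log_transform <- function(table, columns) {
  stopifnot(is.data.frame(table))
  for (cc in columns) {
    if (!cc %in% names(table)) stop("no such column: ", cc)
    v <- table[[cc]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      stop(sprintf("cannot log-transform '%s': nonpositive value in row %d",
                   cc, bad[1]))
    table[[cc]] <- log10(v)
    names(table)[names(table) == cc] <- paste0("log10_", cc)
  }
  table
}

#' Collapse replicates to species means
#'
#' Averages every numeric trait column over replicates within species
#' (arithmetic mean on whatever scale the column is on; analyses call this
#' after [log_transform()], so means are taken on the log scale). Taxonomic
#' and habitat columns are carried through from the first replicate; a
#' `n_replicates` column records the replicate count. Idempotent.
#'
#' @param table A data frame with a `species` column.
#' @return One row per species.
#' @export
species_means <- function(table) {
  stopifnot(is.data.frame(table), "species" %in% names(table))
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("replicate", "n_replicates"))
  sp <- unique(table$species)
  idx <- split(seq_len(nrow(table)), table$species)[sp]
  first <- vapply(idx, `[`, integer(1), 1L)
  out <- table[first, setdiff(names(table), c(num_cols, "replicate",
                                              "n_replicates")), drop = FALSE]
  for (cc in num_cols)
    out[[cc]] <- vapply(idx, function(i) mean(table[[cc]][i]), numeric(1))
  out$n_replicates <- if ("n_replicates" %in% names(table))
    vapply(idx, function(i) table$n_replicates[i][1], numeric(1))
  else lengths(idx)
  rownames(out) <- NULL
  out
}

#' Build an analysis dataset
#'
#' Applies the clade scope filter, removes excluded species (known
#' neopolyploids are excluded before within-genus analyses), and shapes the
#' data for either the high-level (among-genus) or low-level (within-genus)
#' analyses.
#'
#' For `level = "high"` the table is collapsed to species means and matched
#' to tree tips: an exact species-name match is preferred, then a
#' genus-name fallback assuming genus monophyly (fallbacks are reported via
#' `message()`). If several species fall back to one genus tip, a
#' `representative` logical column selects the terminal; otherwise the
#' alphabetically first species is used, with a message. The returned tree
#' is pruned to the matched tips.
#'
#' For `level = "low"` replicate rows are kept and genera with fewer than
#' 2 species (after exclusions) are dropped with a warning.
#'
#' @param table A per-individual trait table.
#' @param tree A dated `"phylo"` tree (required for `level = "high"`).
#' @param scope `"whole-family"` or `"grevilleoid-proteoid"` (drops rows
#'   whose `clade` is `"persoonioid"`).
#' @param level `"high"` or `"low"`.
#' @param exclusions Character vector of species to drop.
#' @return For `"high"`: a list with elements `data` (one row per tip, with
#'   a `tip` column) and `tree`. For `"low"`: the filtered data frame.
#' @export
build_datasets <- function(table, tree = NULL,
                           scope = c("whole-family", "grevilleoid-proteoid"),
                           level = c("high", "low"),
                           exclusions = character()) {
  scope <- match.arg(scope)
  level <- match.arg(level)
  validate_trait_table(table, trait_cols = character())
  if (scope == "grevilleoid-proteoid") {
    if (!"clade" %in% names(table))
      stop("scope '", scope, "' requires a 'clade' column")
    table <- table[table$clade != "persoonioid", , drop = FALSE]
  }
  if (length(exclusions))
    table <- table[!table$species %in% exclusions, , drop = FALSE]
  if (!nrow(table)) stop("no rows left after scope/exclusion filtering")

  if (level == "low") {
    n_sp <- tapply(table$species, table$genus,
                   function(s) length(unique(s)))
    single <- names(n_sp)[n_sp < 2]
    if (length(single)) {
      warning("dropping genera with a single species at low level: ",
              paste(single, collapse = ", "))
      table <- table[!table$genus %in% single, , drop = FALSE]
    }
    if (!nrow(table)) stop("no multi-species genera available at low level")
    rownames(table) <- NULL
    return(table)
  }

  # high level
  if (is.null(tree)) stop("level 'high' requires a tree")
  sm <- species_means(table)
  tip <- ifelse(sm$species %in% tree$tip.label, sm$species, NA_character_)
  fallback <- is.na(tip) & sm$genus %in% tree$tip.label
  tip[fallback] <- sm$genus[fallback]
  if (any(fallback))
    message(sum(fallback), " species assigned to genus tips by monophyly: ",
            paste(utils::head(sm$species[fallback], 5), collapse = ", "),
            if (sum(fallback) > 5) ", ...")
  unmapped <- sm$species[is.na(tip)]
  if (length(unmapped))
    stop("species with no matching tip (species or genus): ",
         paste(unmapped, collapse = ", "))
  sm$tip <- tip
  if (anyDuplicated(tip)) {
    keep <- rep(TRUE, nrow(sm))
    for (tp in unique(tip[duplicated(tip)])) {
      rows <- which(tip == tp)
      if ("representative" %in% names(sm) &&
          any(sm$representative[rows], na.rm = TRUE)) {
        chosen <- rows[which(sm$representative[rows])[1]]
      } else {
        chosen <- rows[order(sm$species[rows])][1]
        message("tip '", tp, "': several species map to it; using ",
                sm$species[chosen])
      }
      keep[setdiff(rows, chosen)] <- FALSE
    }
    sm <- sm[keep, , drop = FALSE]
  }
  pruned <- prune_to_taxa(tree, sm$tip)
  sm <- sm[match(pruned$tip.label, sm$tip), , drop = FALSE]
  rownames(sm) <- NULL
  list(data = sm, tree = pruned)
}
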