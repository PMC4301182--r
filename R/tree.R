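# Dated-tree handling: reading, pruning, grafting and the Brownian
# variance-covariance matrix. Trees are ape "phylo" objects throughout;
# branch lengths are in Myr and working trees are ultrametric (dated).

#' Read a dated phylogeny from a Newick string or file
#'
#' Parses a Newick description into an [ape::read.tree()] `"phylo"` object and
#' validates the invariants the downstream analyses rely on: a single root,
#' unique tip labels, and strictly positive branch lengths. Dated trees are
#' expected to be ultrametric; trees that are not (within a relative
#' tolerance of `1e-6` on root-to-tip distances) trigger a warning rather
#' than an error, since published node dates are often rounded.
#'
#' @param text A Newick string (with branch lengths; `[]` comments are
#'   stripped). Exactly one of `text`/`file` must be given.
#' @param file Path to a Newick file.
#' @return A `"phylo"` tree.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' is_ultrametric(tr)
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- gsub("\\[[^]]*\\]", "", text) # bracket comments carry no data
  .newick_syntax_check(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick: ape could not parse the string")
  tree$tip.label <- sub("^'(.*)'$", "\\1", tree$tip.label)  # quoted labels
  validate_tree(tree)
  tree
}

# Cheap positional pre-check so malformed input fails with a character
# position, which ape's parser does not report.
.newick_syntax_check <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i))
    }
  }
  if (depth > 0L)
    stop(sprintf("malformed Newick: %d '(' left unclosed by character %d",
                 depth, length(chars)))
  if (!grepl(";\\s*$", text))
    stop(sprintf("malformed Newick: missing terminal ';' at character %d",
                 nchar(text)))
}

#' Validate tree invariants
#'
#' Checks that a `"phylo"` object has unique tip labels, branch lengths on
#' every edge, strictly positive branch lengths (tolerance `1e-12`), and a
#' single root. Non-ultrametric dated trees raise a warning.
#'
#' @param tree A `"phylo"` object.
#' @param ultrametric_tol Relative tolerance on root-to-tip distances.
#' @return `tree`, invisibly.
#' @export
validate_tree <- function(tree, ultrametric_tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; dated branch lengths are required")
  if (length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length))
    stop("every edge must carry a branch length")
  if (any(tree$edge.length <= 1e-12))
    stop("all branch lengths must be > 0")
  # structural root check (a basal polytomy is still a rooted tree here)
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(roots) != 1)
    stop("tree must have exactly one root; found ", length(roots))
  if (!is_ultrametric(tree, tol = ultrametric_tol))
    warning("tree is not ultrametric within tolerance ", ultrametric_tol,
            "; dated analyses assume equal root-to-tip distances")
  invisible(tree)
}

#' Test ultrametricity of a dated tree
#'
#' @param tree A `"phylo"` object.
#' @param tol Relative tolerance on the spread of root-to-tip distances.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  diff(range(d)) <= tol * max(d)
}

# Root-to-tip distances, named by tip label.
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

#' Root age of a dated tree
#'
#' Maximum root-to-tip distance, in the tree's time units (Myr here).
#' @param tree A `"phylo"` object.
#' @return Numeric scalar.
#' @export
root_age <- function(tree) max(tip_depths(tree))

#' Prune a tree to a set of tips
#'
#' Drops all tips not in `keep`, suppressing the resulting degree-2 nodes
#' (their branch lengths are summed), so root-to-tip distances of retained
#' tips are unchanged.
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `"phylo"` tree.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' prune_to_taxa(tr, c("A", "C"))
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- as.character(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown tip labels: ", paste(unknown, collapse = ", "))
  if (length(unique(keep)) < 2)
    stop("`keep` must contain at least 2 distinct tip labels")
  ape::keep.tip(tree, keep)
}

#' Graft a new terminal onto a dated tree
#'
#' Adds `new_label` as sister to an existing tip, diverging at
#' `attach_age` Myr before present, so the tree remains ultrametric. With
#' `attach_age = "interpolate"` the divergence age is taken as the midpoint
#' between the age of the sister's parent node and the present (the rule
#' used here for placing a terminal whose exact divergence date is known
#' only to lie below a dated node; pass an explicit age to override).
#'
#' @param tree An ultrametric `"phylo"` object.
#' @param sister Tip label the new terminal attaches next to.
#' @param new_label Name of the new tip.
#' @param attach_age Divergence age in Myr, or `"interpolate"`.
#' @return The augmented `"phylo"` tree.
#' @examples
#' tr <- read_newick("(A:4,B:4);")
#' graft_terminal(tr, "A", "C", attach_age = 2)
#' @export
graft_terminal <- function(tree, sister, new_label, attach_age = "interpolate") {
  if (!sister %in% tree$tip.label) stop("sister tip not found: ", sister)
  if (new_label %in% tree$tip.label)
    stop("tip label already present: ", new_label)
  tip_idx <- match(sister, tree$tip.label)
  parent <- tree$edge[tree$edge[, 2] == tip_idx, 1]
  depths <- ape::node.depth.edgelength(tree)
  parent_age <- max(depths[seq_along(tree$tip.label)]) - depths[parent]
  if (identical(attach_age, "interpolate")) {
    attach_age <- parent_age / 2
  } else {
    stopifnot(is.numeric(attach_age), length(attach_age) == 1L, attach_age > 0)
    if (attach_age >= parent_age)
      stop(sprintf(
        "attach_age (%.6g) must be younger than the sister's parent node (%.6g)",
        attach_age, parent_age))
  }
  out <- phytools::bind.tip(tree, new_label, edge.length = attach_age,
                            where = tip_idx, position = attach_age)
  validate_tree(out)
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j (the
#' Brownian-motion trait covariance up to a rate constant); the diagonal is
#' the root-to-tip distance. Wraps [ape::vcv.phylo()] and checks symmetry
#' and positive semi-definiteness.
#'
#' @param tree A `"phylo"` object.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @examples
#' vcv_matrix(read_newick("((A:1,B:1):1,C:2);"))
#' @export
vcv_matrix <- function(tree) {
  validate_tree_quiet(tree)
  V <- ape::vcv.phylo(tree)
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9 * max(ev))
    stop("phylogenetic covariance matrix is not positive semi-definite")
  V
}

# validate without the ultrametricity warning (used on hot paths where the
# caller has already warned once)
validate_tree_quiet <- function(tree) {
  suppressWarnings(validate_tree(tree))
}

#' Pairwise patristic distances between tips
#'
#' @param tree A `"phylo"` object.
#' @return Symmetric matrix of path lengths between tips.
#' @export
patristic_distances <- function(tree) {
  as.matrix(stats::cophenetic(tree))
}

#' Write a tree to a Newick string or file
#'
#' Branch lengths are written at full double precision.
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when `file` is given).
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 17)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
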