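#' Parse a Newick string into a validated phylogeny
#'
#' Thin, strict wrapper around [ape::read.tree()]: the returned tree is checked
#' for a single root, unique tip labels, and non-negative branch lengths on all
#' edges. Branch lengths are interpreted as time throughout the package.
#'
#' @param text A single Newick string (terminating `;` optional).
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(tr)) abort("Newick parse error: malformed tree string")
  validate_tree(tr)
}

#' @keywords internal
validate_tree <- function(tr, require_lengths = TRUE) {
  if (!inherits(tr, "phylo")) abort("not a 'phylo' object")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate tip label(s): ", paste(dup, collapse = ", ")))
  }
  if (require_lengths) {
    if (is.null(tr$edge.length)) abort("tree has no branch lengths")
    if (anyNA(tr$edge.length)) abort("missing branch length on one or more edges")
    if (any(tr$edge.length < 0)) abort("negative branch length")
  }
  tr$tip.label <- trimws(tr$tip.label)
  tr
}

#' Root-to-tip depths of a phylogeny
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Named numeric vector of root-to-tip path lengths, one per tip.
#' @export
tip_depths <- function(tree) {
  tree <- validate_tree(tree)
  nh <- ape::node.depth.edgelength(tree)
  setNames(nh[seq_len(ape::Ntip(tree))], tree$tip.label)
}

#' Tree height (maximum root-to-tip depth)
#' @param tree A `phylo` object.
#' @return Scalar height in the tree's time units.
#' @export
tree_height <- function(tree) max(tip_depths(tree))

#' Check ultrametricity at the package's tolerance
#'
#' A tree is treated as ultrametric when all root-to-tip depths agree within a
#' relative tolerance of the height.
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance (default 1e-6).
#' @keywords internal
assert_ultrametric <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  h <- max(d)
  disc <- (max(d) - min(d)) / h
  if (disc > tol) {
    abort(sprintf(
      "tree is not ultrametric: max relative depth discrepancy %.3g exceeds tolerance %.1g",
      disc, tol
    ))
  }
  invisible(tree)
}

#' Rescale an ultrametric tree to unit height
#'
#' Divides every branch length by the root-to-tip height so that all tips sit
#' at depth 1. Standardizes the time scale of the Brownian-motion correlation
#' matrix, making variance parameters in the regression portable across trees
#' dated in different units (e.g. Ma).
#'
#' @param tree An ultrametric `phylo` object.
#' @param tol Ultrametricity tolerance, relative (default 1e-6). Trees failing
#'   it are rejected, not silently normalized.
#' @return A `phylo` of height 1.
#' @examples
#' tr <- parse_newick("((A:14.51,B:14.51):14.51,C:29.02);")
#' tree_height(to_unit_height(tr))
#' @export
to_unit_height <- function(tree, tol = 1e-6) {
  tree <- validate_tree(tree)
  assert_ultrametric(tree, tol)
  h <- tree_height(tree)
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Brownian-motion phylogenetic correlation matrix
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j divided
#' by the tree height; the diagonal is 1. This is the correlation structure of
#' trait values under Brownian motion on an ultrametric tree, used as the
#' between-species correlation of the phylogenetic varying effects.
#'
#' @param tree An ultrametric `phylo` object.
#' @param taxa Ordered character vector of taxa to include (default: all tips
#'   in the tree's tip order).
#' @return A symmetric positive semi-definite matrix with unit diagonal,
#'   dimnames `taxa`.
#' @examples
#' phylo_correlation(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
phylo_correlation <- function(tree, taxa = tree$tip.label) {
  tree <- validate_tree(tree)
  assert_ultrametric(tree)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0L) {
    abort(paste0("taxa not in tree: ", paste(missing, collapse = ", ")))
  }
  V <- ape::vcv.phylo(tree)
  h <- tree_height(tree)
  R <- V[taxa, taxa, drop = FALSE] / h
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Clade keys of a phylogeny
#'
#' One key per internal node: the canonically (alphabetically) ordered set of
#' tip labels descending from it, collapsed into a single string. Keys are
#' topology-invariant under child reordering and are the handle used to match
#' internal nodes across the trees of a posterior sample, whose topologies may
#' differ.
#'
#' @param tree A `phylo` object.
#' @return Named character vector: names are internal node numbers (ape
#'   numbering), values are clade keys.
#' @export
clade_keys <- function(tree) {
  tree <- validate_tree(tree, require_lengths = FALSE)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  desc <- lapply(ape::prop.part(tree), function(idx) tree$tip.label[idx])
  # prop.part lists clades in node order root..root+Nnode-1
  keys <- vapply(desc, function(x) paste(sort(x), collapse = "|"), character(1))
  names(keys) <- as.character(ntip + seq_len(nnode))
  keys
}

#' @keywords internal
clade_key_of <- function(taxa) paste(sort(trimws(taxa)), collapse = "|")

#' Read a sample of phylogenies sharing one taxon set
#'
#' Reads a multi-tree Newick file or a Nexus trees file (format auto-detected
#' from the leading `#NEXUS` marker) and validates that every tree carries the
#' same tip-label set.
#'
#' @param path File containing one or more trees.
#' @return A `multiPhylo` object; attribute `n_trees` records the sample size.
#' @export
read_tree_sample <- function(path) {
  if (!file.exists(path)) abort(paste0("tree file not found: ", path))
  first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
  trees <- if (startsWith(first, "#NEXUS")) {
    ape::read.nexus(path)
  } else {
    ape::read.tree(path)
  }
  if (inherits(trees, "phylo")) trees <- c(structure(list(trees), class = "multiPhylo"))
  if (length(trees) == 0L) abort(paste0("no trees found in ", path))
  trees <- structure(lapply(trees, validate_tree), class = "multiPhylo")
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      abort(sprintf("tree %d has a different taxon set than tree 1", i))
    }
  }
  attr(trees, "n_trees") <- length(trees)
  trees
}

#' Write one or more trees as Newick text
#'
#' @param tree A `phylo` or `multiPhylo` object.
#' @param path Output file; when `NULL`, the Newick string(s) are returned.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) {
    return(ape::write.tree(tree))
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
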