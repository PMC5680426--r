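#' Parse a Newick string into a phylogenetic tree
#'
#' Reads a rooted Newick string into an [ape::phylo] object, the container
#' used by every comparative computation in the package.  Polytomies are
#' permitted anywhere (synthesis trees such as the Open Tree of Life contain
#' them); a tree whose outermost grouping is a polytomy is interpreted as
#' rooted at that node.  Branch lengths are captured when `:` annotations are
#' present and absent otherwise.
#'
#' @param text A Newick string terminated by `";"`.
#' @return An object of class `phylo` with at least two uniquely labelled
#'   tips.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' ape::Ntip(tr)
#' @seealso [write_newick()], [grafen_branch_lengths()]
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text) || !endsWith(text, ";")) {
    abort("Newick string must be non-empty and terminated by ';'.")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    abort(sprintf(
      "Unbalanced parentheses in Newick string: %d '(' vs %d ')'.",
      n_open, n_close
    ))
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(tree)) abort("Newick parse error: ape could not read the string.")
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("Expected an ape 'phylo' tree.")
  if (ape::Ntip(tree) < 2) abort("Tree must have at least 2 tips.")
  labs <- tree$tip.label
  if (any(!nzchar(labs)) || anyNA(labs)) {
    abort("Empty tip labels are not allowed.")
  }
  dup <- unique(labs[duplicated(labs)])
  if (length(dup)) {
    abort(sprintf("Duplicate tip labels: %s.", paste(dup, collapse = ", ")))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    abort("Negative branch lengths are not allowed.")
  }
  invisible(tree)
}

#' Serialize a tree to Newick
#'
#' Round-trips with [parse_newick()]: topology and labels exactly, branch
#' lengths to 10 significant digits.  Trees without branch lengths are written
#' without `:` annotations.
#'
#' @param tree A `phylo` tree.
#' @return A single Newick string ending in `";"`.
#' @export
write_newick <- function(tree) {
  validate_tree(tree)
  ape::write.tree(tree, digits = 10)
}

#' Assign Grafen branch lengths
#'
#' Computes ultrametric branch lengths from topology alone: each node gets
#' height \eqn{h(v) = ((t_v - 1)/(n - 1))^\rho} where \eqn{t_v} is the number
#' of tip descendants, so tips sit at height 0 and the root at height 1, and
#' each branch is the height difference between its ends.  Any existing branch
#' lengths are discarded.  This is the standard normalization used when a
#' synthesis-tree subtree supplies topology but no usable lengths.
#'
#' @param tree A `phylo` tree with at least 2 tips (polytomies allowed).
#' @param rho Positive power applied to the normalized node heights
#'   (default 1).
#' @return The tree with ultrametric branch lengths; every root-to-tip path
#'   has length 1.
#' @examples
#' tr <- grafen_branch_lengths(parse_newick("((A,B),(C,D));"))
#' tr$edge.length # 2/3 above each cherry, 1/3 above each tip
#' @export
grafen_branch_lengths <- function(tree, rho = 1) {
  validate_tree(tree)
  stopifnot(is.numeric(rho), length(rho) == 1, rho > 0)
  tree$edge.length <- NULL
  ape::compute.brlen(tree, method = "Grafen", power = rho)
}

#' Prune a tree to a set of tips
#'
#' Drops all tips not in `keep` and suppresses the resulting degree-2 nodes,
#' summing their incident branch lengths, so patristic distances among the
#' retained tips are unchanged.
#'
#' @param tree A `phylo` tree.
#' @param keep Character vector of tip labels to retain (at least 2, all
#'   present in the tree).
#' @return The pruned `phylo` tree.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    abort(sprintf("Tip labels not in tree: %s.", paste(missing, collapse = ", ")))
  }
  if (length(keep) < 2) abort("Need at least 2 tips to keep.")
  ape::keep.tip(tree, keep)
}

#' Patristic (cophenetic) distance matrix
#'
#' Sum of branch lengths along the path between each pair of tips.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = tip
#'   labels.
#' @export
patristic_distances <- function(tree) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian-motion trait evolution the covariance between two tips is
#' proportional to the root-to-MRCA shared path length; the diagonal holds
#' root-to-tip depths.  For a Grafen tree the diagonal is identically 1.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Symmetric positive-semidefinite matrix, dimnames = tip labels.
#' @export
phylo_vcv <- function(tree) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Test whether a tree is ultrametric
#'
#' True iff the spread between the largest and smallest root-to-tip depth is
#' at most `tol` (an absolute tolerance on the depth scale).
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param tol Non-negative absolute tolerance; default `1e-8`.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  (max(depths) - min(depths)) <= tol
}
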