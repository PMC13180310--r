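#' Read a rooted, time-calibrated tree from Newick text or a file
#'
#' Parses a Newick string (or a file containing one) into an [ape::read.tree()]
#' `phylo` object and validates the invariants the rest of the package relies
#' on: the tree is rooted, tip labels are unique, every non-root edge carries a
#' branch length (in million years, MY), and the height (maximum root-to-tip
#' path) is positive. Whether the tree is ultrametric is checked within a
#' relative tolerance and recorded as an attribute, not enforced: generalized
#' least squares works on near-ultrametric trees.
#'
#' @param x A Newick string, or the path of a file containing one.
#' @param ultrametric_tol Relative tolerance on tip depths used to flag the
#'   tree as ultrametric. Default `1e-6`.
#' @return A `phylo` object with attributes `is_ultrametric` (logical) and
#'   `height` (numeric, MY).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' attr(tr, "height")
#' @export
read_newick <- function(x, ultrametric_tol = 1e-6) {
  stopifnot(is.character(x), length(x) == 1L)
  text <- if (!grepl("(", x, fixed = TRUE) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    x
  }
  .check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("Newick parse failed: ", conditionMessage(e)))
  )
  if (is.null(tree)) abort("Newick parse failed: not a valid tree string")
  validate_tree(tree, ultrametric_tol = ultrametric_tol)
}

# Cheap structural scan so malformed strings fail with a character offset
# before ape's parser produces something cryptic.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("malformed Newick: unmatched ')' at character offset %d", i))
      }
    }
  }
  if (depth != 0L) {
    abort(sprintf(
      "malformed Newick: %d unclosed '(' (string ends at offset %d)",
      depth, length(chars)
    ))
  }
  if (!grepl(";\\s*$", text)) {
    abort(sprintf(
      "malformed Newick: missing terminal ';' at character offset %d",
      length(chars) + 1L
    ))
  }
  invisible(TRUE)
}

#' Validate a phylogeny for comparative analysis
#'
#' @param tree A `phylo` object.
#' @param ultrametric_tol Relative tolerance on tip depths for the
#'   ultrametricity flag.
#' @return The tree, with `is_ultrametric` and `height` attributes set.
#' @export
validate_tree <- function(tree, ultrametric_tol = 1e-6) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a 'phylo' object")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("duplicate tip labels: ", paste(dup, collapse = ", ")))
  }
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    abort(sprintf("missing branch length on %d edge(s)", sum(is.na(tree$edge.length))))
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths are not allowed")
  depths <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  h <- max(depths)
  if (h <= 0) abort("tree height must be positive")
  attr(tree, "height") <- h
  attr(tree, "is_ultrametric") <- (max(depths) - min(depths)) <= ultrametric_tol * h
  tree
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly, when written to a file).
#' @export
write_newick <- function(tree, path = NULL, digits = 12) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the shared path length (MY) from the root to the most
#' recent common ancestor of tips i and j; the diagonal holds tip depths. Under
#' Brownian motion the trait covariance among tips is proportional to this
#' matrix.
#'
#' @param tree A `phylo` object.
#' @return A symmetric matrix with tip labels as dimnames, in the tree's tip
#'   order.
#' @examples
#' phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
#' @export
phylo_vcv <- function(tree) {
  tree <- validate_tree(tree)
  V <- ape::vcv.phylo(tree)
  V[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Pagel's lambda branch-length transformation of a covariance matrix
#'
#' Multiplies the off-diagonal entries of a phylogenetic covariance matrix by
#' `lambda`, leaving the diagonal untouched. `lambda = 0` gives the diagonal
#' (star-phylogeny / OLS) weights, `lambda = 1` returns the matrix unchanged.
#'
#' @param V A phylogenetic covariance matrix (see [phylo_vcv()]).
#' @param lambda Signal multiplier in `[0, 1]`.
#' @return The transformed matrix.
#' @export
apply_lambda <- function(V, lambda) {
  stopifnot(is.matrix(V))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    abort("`lambda` must be a single value in [0, 1]")
  }
  d <- diag(V)
  Vl <- V * lambda
  diag(Vl) <- d
  Vl
}

#' Substitute tip labels (congener replacement)
#'
#' Relabels tips, as when taxa missing from a published phylogeny are
#' represented by closely related congeners. Topology and branch lengths are
#' untouched; each substitution is recorded in the returned tree's
#' `substitutions` attribute.
#'
#' @param tree A `phylo` object.
#' @param mapping Named character vector, `old_label = "new_label"`.
#' @return The relabelled tree.
#' @export
substitute_tips <- function(tree, mapping) {
  tree <- validate_tree(tree)
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  missing_old <- setdiff(names(mapping), tree$tip.label)
  if (length(missing_old)) {
    abort(paste0("tips not in tree: ", paste(missing_old, collapse = ", ")))
  }
  kept <- setdiff(tree$tip.label, names(mapping))
  collide <- intersect(unname(mapping), kept)
  if (anyDuplicated(unname(mapping))) {
    collide <- union(collide, unname(mapping)[duplicated(unname(mapping))])
  }
  if (length(collide)) {
    abort(paste0("replacement labels collide: ", paste(unique(collide), collapse = ", ")))
  }
  idx <- match(names(mapping), tree$tip.label)
  log <- tibble::tibble(old = tree$tip.label[idx], new = unname(mapping))
  tree$tip.label[idx] <- unname(mapping)
  tree <- validate_tree(tree)
  attr(tree, "substitutions") <- log
  tree
}

#' Resolve polytomies to a binary tree
#'
#' Ornstein-Uhlenbeck regime weights and the reversible-jump shift sampler
#' need a binary tree; polytomies are resolved with zero-length edges (a
#' likelihood-neutral change) with a warning.
#'
#' @param tree A `phylo` object.
#' @return A binary `phylo` object.
#' @export
resolve_binary <- function(tree) {
  tree <- validate_tree(tree)
  if (ape::is.binary(tree)) return(tree)
  warn("tree contains polytomies; resolving to binary with zero-length edges")
  validate_tree(ape::multi2di(tree, random = FALSE))
}

# ---- internal tree geometry helpers -----------------------------------------

# Depth (distance from root) of every node, tips first.
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

tree_height <- function(tree) {
  max(node_depths(tree)[seq_len(ape::Ntip(tree))])
}

# E x Ntip logical matrix: does edge e lie on the root path of tip i?
# Equivalently, is tip i a descendant of the child node of edge e.
edge_tip_matrix <- function(tree) {
  n <- ape::Ntip(tree)
  E <- nrow(tree$edge)
  out <- matrix(FALSE, E, n)
  # post-order accumulation of descendant tip sets
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  for (e in seq_len(E)) out[e, desc[[tree$edge[e, 2]]]] <- TRUE
  out
}

# For each tip, the ordered (root -> tip) vector of edge indices on its path.
lineage_edges <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  parent_edge <- integer(n + tree$Nnode)
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  lapply(seq_len(n), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      path <- c(e, path)
      node <- tree$edge[e, 1]
    }
    path
  })
}
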