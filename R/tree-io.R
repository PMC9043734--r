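# Newick tree I/O on top of ape's "phylo", with validation and a canonical
# serialization so that written trees are diff-stable.

#' Parse a Newick string into a validated rooted tree
#'
#' Wraps [ape::read.tree()] with the validation this pipeline relies on:
#' unique tip labels, non-negative branch lengths, a single root.  Internal
#' node labels, when present, are interpreted as clade labels (e.g. region
#' names such as `"Himalaya"`) and are used by [assign_origin()].
#'
#' @param text A Newick string (must end in `;`).
#' @param ultrametric If `TRUE`, additionally require all root-to-tip path
#'   lengths to be equal within `tol` (relative).
#' @param tol Relative tolerance for the ultrametricity check.
#' @return An object of class `"phylo"`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tree_height(tr)
parse_newick <- function(text, ultrametric = FALSE, tol = 1e-6) {
  stopifnot(is.character(text), length(text) == 1)
  if (!grepl(";", text)) stop("newick parse error: no terminating ';'")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop(sprintf("newick parse error: unbalanced parentheses (%d '(' vs %d ')')",
                 n_open, n_close))
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: unreadable tree string")
  validate_tree(tr, ultrametric = ultrametric, tol = tol)
  tr
}

#' Validate a phylo object against the pipeline's tree invariants
#'
#' @param tree A `"phylo"` object.
#' @inheritParams parse_newick
#' @return The tree, invisibly, if valid; otherwise an error.
#' @export
validate_tree <- function(tree, ultrametric = FALSE, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has NA branch lengths")
  if (any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1]
    stop(sprintf("negative branch length %g on edge to node %d",
                 tree$edge.length[bad], tree$edge[bad, 2]))
  }
  # exactly one root: one node that never appears as a child
  parents <- unique(tree$edge[, 1])
  roots <- setdiff(parents, tree$edge[, 2])
  if (length(roots) != 1) stop("tree must have exactly one root")
  if (ultrametric) {
    d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
    h <- max(d)
    if (h > 0 && (max(d) - min(d)) / h > tol) {
      stop("tree is not ultrametric within tolerance")
    }
  }
  invisible(tree)
}

#' Serialize a tree to canonical Newick
#'
#' Children of every internal node are ordered by their smallest descendant
#' tip label, so two topologically identical trees always serialize to the
#' same string.  Branch lengths are written with 10 significant digits;
#' internal (clade) labels are preserved.
#'
#' @param tree A `"phylo"` object.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  validate_tree(tree)
  tree <- canonical_rotate(tree)
  ape::write.tree(tree, digits = digits)
}

# Rotate children so each internal node lists children ordered by their
# minimum descendant tip label.
canonical_rotate <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  minlab <- character(ntip + nnode)
  minlab[seq_len(ntip)] <- tree$tip.label
  new_edge_order <- integer(0)
  # compute minimum descendant label bottom-up
  po <- ape::postorder(tree)
  for (ei in po) {
    child <- tree$edge[ei, 2]
    parent <- tree$edge[ei, 1]
    if (child <= ntip) minlab[child] <- tree$tip.label[child]
    if (minlab[parent] == "" || minlab[child] < minlab[parent]) {
      minlab[parent] <- minlab[child]
    }
  }
  # re-order rows of edge so children appear sorted; rebuild via pre-order
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  stack <- root
  while (length(stack) > 0) {
    nd <- stack[[1]]; stack <- stack[-1]
    rows <- kids[[as.character(nd)]]
    if (is.null(rows)) next
    rows <- rows[order(minlab[tree$edge[rows, 2]], method = "radix")]
    new_edge_order <- c(new_edge_order, rows)
    stack <- c(tree$edge[rows, 2], stack)
  }
  tree$edge <- tree$edge[new_edge_order, , drop = FALSE]
  tree$edge.length <- tree$edge.length[new_edge_order]
  attr(tree, "order") <- NULL
  tree
}

#' Root-to-node path lengths
#'
#' @param tree A `"phylo"` object.
#' @return Numeric vector of depths (distance from the root) for all nodes,
#'   tips first.
#' @export
node_depths <- function(tree) {
  ntip <- ape::Ntip(tree)
  depth <- numeric(ntip + tree$Nnode)
  root <- ntip + 1L
  # pre-order fill
  ord <- rev(ape::postorder(tree))
  for (ei in ord) {
    p <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    depth[ch] <- depth[p] + tree$edge.length[ei]
  }
  depth
}

#' Height of a rooted tree (maximum root-to-tip depth)
#' @param tree A `"phylo"` object.
#' @return A single number.
#' @export
tree_height <- function(tree) max(node_depths(tree)[seq_len(ape::Ntip(tree))])

#' Node ages of an ultrametric tree (time before present)
#' @param tree An ultrametric `"phylo"` object.
#' @return Numeric vector over all nodes (tips first); tips have age ~0.
#' @export
node_ages <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_len(ape::Ntip(tree))]) - d
}

#' Attach a clade label to the MRCA of a set of tips
#'
#' Clade labels ride on internal node labels; [assign_origin()] reads them.
#' A sidecar table (node number, label) can also be applied with this helper.
#'
#' @param tree A `"phylo"` object.
#' @param tips Character vector of tip labels (length >= 2) whose MRCA gets
#'   the label, or an integer node number.
#' @param label The clade label string.
#' @return The modified tree.
#' @export
label_clade <- function(tree, tips, label) {
  validate_tree(tree)
  ntip <- ape::Ntip(tree)
  if (is.character(tips)) {
    miss <- setdiff(tips, tree$tip.label)
    if (length(miss) > 0) stop("unknown tip(s): ", paste(miss, collapse = ", "))
    node <- ape::getMRCA(tree, tips)
  } else {
    node <- as.integer(tips)
  }
  if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
  tree$node.label[node - ntip] <- label
  tree
}

# tips descending from each node, as a list of integer vectors
descendant_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  res <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) res[[i]] <- i
  for (ei in ape::postorder(tree)) {
    p <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    res[[p]] <- c(res[[p]], res[[ch]])
  }
  res
}
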