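#' Read and validate a time-calibrated tree
#'
#' Reads a rooted, fully bifurcating, time-calibrated phylogeny from a newick
#' string or file and checks the invariants the rate machinery relies on:
#' branch lengths present and strictly positive on every edge, unique tip
#' labels, at least two tips, no polytomies. Node annotations in the newick
#' are accepted and ignored.
#'
#' Node ages are measured backwards from the present: by default the root age
#' equals the maximum root-to-tip path length, so the most distant tip sits at
#' age 0 and shallower (fossil) tips have positive ages.
#'
#' @param source A newick string (containing `;`) or a path to a newick file.
#' @param root_age Optional root age overriding the default convention.
#' @return An object of class `phylo` (see [ape::read.tree()]) that passes
#'   [pr_validate_tree()].
#' @export
#' @examples
#' tr <- pr_read_tree("((A:1,B:1):0.5,C:1.5);")
#' pr_node_ages(tr)
pr_read_tree <- function(source, root_age = NULL) {
  stopifnot(is.character(source), length(source) == 1L)
  tree <- if (grepl(";", source, fixed = TRUE)) {
    tryCatch(ape::read.tree(text = source),
             error = function(e) stop("unparseable newick: ", conditionMessage(e), call. = FALSE))
  } else {
    if (!file.exists(source)) stop("tree file not found: ", source, call. = FALSE)
    tryCatch(ape::read.tree(source),
             error = function(e) stop("unparseable newick: ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(tree) || !inherits(tree, "phylo")) stop("unparseable newick", call. = FALSE)
  pr_validate_tree(tree)
  if (!is.null(root_age)) attr(tree, "root_age") <- root_age
  tree
}

#' Check the tree invariants required by the rate machinery
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly, if valid; otherwise an error.
#' @export
pr_validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  n <- length(tree$tip.label)
  if (n < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    stop("every edge must carry a branch length", call. = FALSE)
  }
  if (any(tree$edge.length <= 0)) {
    stop("all branch lengths must be strictly positive", call. = FALSE)
  }
  # a rooted strictly bifurcating tree has exactly N - 1 internal nodes
  if (tree$Nnode != n - 1L || !ape::is.rooted(tree)) {
    stop("tree must be rooted and strictly bifurcating; polytomies are not ",
         "supported, resolve them before analysis", call. = FALSE)
  }
  invisible(tree)
}

# depth of every node (root-to-node path length); nodes indexed 1..(2N-1)
node_depths <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  depth <- numeric(n + m)
  root <- n + 1L
  # edges in preorder: reorder guarantees parents before children
  eo <- ape::reorder.phylo(tree, "postorder")
  for (i in rev(seq_len(nrow(eo$edge)))) {
    depth[eo$edge[i, 2L]] <- depth[eo$edge[i, 1L]] + eo$edge.length[i]
  }
  depth[root] <- 0
  depth
}

#' Node ages of a time tree
#'
#' Age = root age minus root-to-node path length. The default root age is the
#' maximum root-to-tip distance, so the deepest tip has age 0 and fossil tips
#' end at positive ages.
#'
#' @inheritParams pr_validate_tree
#' @param root_age Root age; defaults to `attr(tree, "root_age")` or the
#'   deepest root-to-tip distance.
#' @return Named numeric vector over all nodes (tips first, then internal
#'   nodes), names as in [pr_branch_labels()] plus the root.
#' @export
pr_node_ages <- function(tree, root_age = NULL) {
  depth <- node_depths(tree)
  n <- length(tree$tip.label)
  if (is.null(root_age)) root_age <- attr(tree, "root_age")
  if (is.null(root_age)) root_age <- max(depth[seq_len(n)])
  ages <- root_age - depth
  names(ages) <- node_names(tree)
  ages
}

# canonical node names: tip labels for tips, "N<id>" for internal nodes
node_names <- function(tree) {
  n <- length(tree$tip.label)
  c(tree$tip.label, paste0("N", n + seq_len(tree$Nnode)))
}

# resolve a node given by label, "N<id>" name, or integer id
resolve_node <- function(tree, node) {
  nm <- node_names(tree)
  if (is.character(node)) {
    idx <- match(node, nm)
    if (anyNA(idx)) stop("unknown node: ", paste(node[is.na(idx)], collapse = ", "), call. = FALSE)
    return(idx)
  }
  node <- as.integer(node)
  if (any(node < 1L | node > length(nm))) stop("node id out of range", call. = FALSE)
  node
}

#' Branch labels
#'
#' Every branch is identified by the node below it (its child): the tip label
#' for pendant branches, `"N<id>"` for internal branches. One label per edge,
#' in the tree's edge-matrix order.
#'
#' @inheritParams pr_validate_tree
#' @return Character vector of length `nrow(tree$edge)`.
#' @export
pr_branch_labels <- function(tree) {
  node_names(tree)[tree$edge[, 2L]]
}

# list of root-to-node paths as edge-row indices, for all nodes
root_paths <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  parent_edge <- integer(n + m)             # edge row whose child is this node
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  parent_node <- integer(n + m)
  parent_node[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- n + 1L
  lapply(seq_len(n + m), function(v) {
    path <- integer(0)
    while (v != root) {
      path <- c(parent_edge[v], path)
      v <- parent_node[v]
    }
    path
  })
}

path_matrix <- function(tree, rows) {
  ne <- nrow(tree$edge)
  paths <- root_paths(tree)
  L <- matrix(0, length(rows), ne,
              dimnames = list(node_names(tree)[rows], pr_branch_labels(tree)))
  for (i in seq_along(rows)) {
    p <- paths[[rows[i]]]
    L[i, p] <- tree$edge.length[p]
  }
  L
}

#' Tip-to-root path matrix
#'
#' The design matrix of the ridge rate regression: one row per tip, one column
#' per branch; the entry is the branch length when the branch lies on the
#' root-to-tip path and 0 otherwise. Row sums therefore equal root-to-tip
#' distances.
#'
#' @inheritParams pr_validate_tree
#' @return Numeric matrix, tips x branches, dimnames set to tip labels and
#'   branch labels.
#' @export
#' @examples
#' pr_tip_path_matrix(pr_read_tree("((A:1,B:1):0.5,C:1.5);"))
pr_tip_path_matrix <- function(tree) {
  pr_validate_tree(tree)
  path_matrix(tree, seq_along(tree$tip.label))
}

#' Node-to-root path matrix
#'
#' As [pr_tip_path_matrix()] but with internal nodes as rows; the root row is
#' all zeros (its path is empty). Multiplying by the branch-rate matrix yields
#' ancestral state deviations from the root.
#'
#' @inheritParams pr_validate_tree
#' @return Numeric matrix, internal nodes (root first) x branches.
#' @export
pr_node_path_matrix <- function(tree) {
  pr_validate_tree(tree)
  n <- length(tree$tip.label)
  path_matrix(tree, n + seq_len(tree$Nnode))
}

#' Patristic and edge-count distances between nodes
#'
#' `pr_patristic()` sums branch lengths along the tree path between two nodes;
#' `pr_node_distance()` counts edges along the same path. Both accept tip
#' labels, `"N<id>"` names, or integer node ids.
#'
#' @inheritParams pr_validate_tree
#' @param a,b Nodes.
#' @return A single non-negative number, zero iff `a == b`.
#' @export
#' @examples
#' tr <- pr_read_tree("((A:1,B:1):0.5,C:1.5);")
#' pr_patristic(tr, "A", "C")   # 3
#' pr_node_distance(tr, "A", "B")  # 2
pr_patristic <- function(tree, a, b) {
  path_between(tree, a, b, tree$edge.length)
}

#' @rdname pr_patristic
#' @export
pr_node_distance <- function(tree, a, b) {
  path_between(tree, a, b, rep(1, nrow(tree$edge)))
}

path_between <- function(tree, a, b, weights) {
  a <- resolve_node(tree, a)
  b <- resolve_node(tree, b)
  paths <- root_paths(tree)
  pa <- paths[[a]]
  pb <- paths[[b]]
  # symmetric difference of the two root paths
  shared <- intersect(pa, pb)
  sum(weights[setdiff(pa, shared)]) + sum(weights[setdiff(pb, shared)])
}

# pairwise patristic distance matrix among a set of nodes
patristic_matrix <- function(tree, nodes) {
  nodes <- resolve_node(tree, nodes)
  paths <- root_paths(tree)
  k <- length(nodes)
  D <- matrix(0, k, k, dimnames = list(node_names(tree)[nodes], node_names(tree)[nodes]))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      pa <- paths[[nodes[i]]]; pb <- paths[[nodes[j]]]
      shared <- intersect(pa, pb)
      d <- sum(tree$edge.length[c(setdiff(pa, shared), setdiff(pb, shared))])
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# tip ids descending from a node (the node itself if it is a tip)
clade_tips <- function(tree, node) {
  node <- resolve_node(tree, node)
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  kids <- tree$edge[, 2L][tree$edge[, 1L] == node]
  sort(unlist(lapply(kids, clade_tips, tree = tree)))
}

# internal node ids whose clade (incl self for tips? no: internal only)
internal_nodes <- function(tree) {
  n <- length(tree$tip.label)
  n + seq_len(tree$Nnode)
}

# mrca of a set of tip labels/ids
mrca_node <- function(tree, tips) {
  tips <- resolve_node(tree, tips)
  if (length(tips) == 1L) return(tips)
  ape::getMRCA(tree, tips)
}
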