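# --- internal mutable tree representation -----------------------------------
# Node ids are stable across prune/graft operations (unlike ape's renumbering),
# which keeps the swap bookkeeping honest. Ages are absolute (time before
# present); edge lengths are implied by age differences.

as_nodelist <- function(tree) {
  ages <- pr_node_ages(tree)
  n <- length(tree$tip.label)
  m <- tree$Nnode
  parent <- integer(n + m)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  children <- vector("list", n + m)
  for (i in seq_len(nrow(tree$edge)))
    children[[tree$edge[i, 1L]]] <- c(children[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  list(parent = parent, children = children, age = unname(ages),
       label = c(tree$tip.label, rep(NA_character_, m)),
       alive = rep(TRUE, n + m), root = n + 1L)
}

nl_newick <- function(nl, v) {
  kids <- nl$children[[v]]
  if (!length(kids)) return(nl$label[v])
  inner <- vapply(kids, function(k)
    paste0(nl_newick(nl, k), ":", format(nl$age[v] - nl$age[k], digits = 17)),
    character(1))
  paste0("(", paste(inner, collapse = ","), ")")
}

nl_to_phylo <- function(nl) {
  txt <- paste0(nl_newick(nl, nl$root), ";")
  out <- ape::read.tree(text = txt)
  attr(out, "root_age") <- nl$age[nl$root]
  out
}

# edge-count distance between two live nodes
nl_edge_dist <- function(nl, a, b) {
  path_up <- function(v) {
    p <- integer(0)
    while (v != nl$root) { p <- c(p, v); v <- nl$parent[v] }
    c(p, nl$root)
  }
  pa <- path_up(a); pb <- path_up(b)
  shared <- intersect(pa, pb)
  (length(pa) - length(shared)) + (length(pb) - length(shared))
}

# remove tip t; its parent collapses away; returns (nl, sibling id)
nl_prune <- function(nl, t) {
  p <- nl$parent[t]
  sib <- setdiff(nl$children[[p]], t)
  g <- nl$parent[p]
  if (g == 0L || p == nl$root) {
    nl$parent[sib] <- 0L
    nl$root <- sib
  } else {
    nl$children[[g]] <- replace(nl$children[[g]], nl$children[[g]] == p, sib)
    nl$parent[sib] <- g
  }
  nl$alive[c(t, p)] <- FALSE
  nl$children[[p]] <- integer(0)
  list(nl = nl, sibling = sib)
}

# graft tip t onto the branch above node c at absolute age a_m
nl_graft <- function(nl, t, c_node, a_m) {
  g <- nl$parent[c_node]
  stopifnot(g != 0L, a_m > nl$age[c_node], a_m < nl$age[g], a_m > nl$age[t])
  w <- length(nl$parent) + 1L
  nl$parent <- c(nl$parent, g)
  nl$children <- c(nl$children, list(c(c_node, t)))
  nl$age <- c(nl$age, a_m)
  nl$label <- c(nl$label, NA_character_)
  nl$alive <- c(nl$alive, TRUE)
  nl$children[[g]] <- replace(nl$children[[g]], nl$children[[g]] == c_node, w)
  nl$parent[c_node] <- w
  nl$parent[t] <- w
  nl$alive[t] <- TRUE
  nl
}

#' Randomize internal node ages
#'
#' Each selected internal node (a random subset holding the given fraction of
#' non-root internal nodes) gets a new age drawn uniformly between the age of
#' its oldest daughter and the age of its parent, the only interval that
#' keeps every edge positive. Nodes are processed root-down so that a
#' perturbed parent constrains its perturbed children. Branch lengths are
#' recomputed from the new ages; the root age is untouched.
#'
#' @param tree A validated `phylo` tree.
#' @param fraction Fraction of non-root internal nodes to perturb, in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @return A validated `phylo` tree with the same topology and tip ages.
#' @export
pr_randomize_ages <- function(tree, fraction, seed = NULL) {
  pr_validate_tree(tree)
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(tree)
  n <- length(tree$tip.label)
  root <- n + 1L
  inner <- setdiff(internal_nodes(tree), root)
  ages <- unname(pr_node_ages(tree))
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  with_seed(seed, {
    chosen <- sample(inner, floor(fraction * length(inner)))
    # root-down order: shallower (older) first
    for (v in chosen[order(-ages[chosen])]) {
      lo <- max(ages[kids[[as.character(v)]]])
      hi <- ages[parent[v]]
      repeat {
        a <- stats::runif(1, lo, hi)
        if (a > lo && a < hi) break
      }
      ages[v] <- a
    }
    out <- tree
    out$edge.length <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
    attr(out, "root_age") <- ages[root]
    pr_validate_tree(out)
    out
  })
}

#' Swap tip positions within a bounded topological neighbourhood
#'
#' A random subset of tips (the given fraction) is moved, one at a time: the
#' tip is pruned and reattached onto a branch whose child node lies within
#' `max_dist` edges of the tip's parent at the time of the move, at the
#' temporal midpoint of that branch; the tip keeps its own age. Targets whose
#' midpoint would give a non-positive pendant branch (or would sit above the
#' root) are redrawn; a tip with no feasible target is left in place with a
#' warning. The tip set is always conserved and the output satisfies every
#' tree invariant.
#'
#' @param tree A validated `phylo` tree.
#' @param fraction Fraction of tips to move, in \[0, 1\].
#' @param max_dist Maximum edge-count distance between the old parent and the
#'   new attachment branch's child node (>= 1); 2 by default, with 3 the
#'   other commonly used radius.
#' @param seed Integer seed.
#' @return A validated `phylo` tree; attribute `"swaps"` is a tibble logging,
#'   per selected tip, the old parent, the target, the edge distance used and
#'   whether the move was applied.
#' @export
pr_swap_tips <- function(tree, fraction, max_dist = 2, seed = NULL) {
  pr_validate_tree(tree)
  stopifnot(fraction >= 0, fraction <= 1, max_dist >= 1)
  if (fraction == 0) {
    attr(tree, "swaps") <- tibble::tibble(
      tip = character(0), old_parent = integer(0), target = integer(0),
      edge_dist = integer(0), moved = logical(0))
    return(tree)
  }
  n <- length(tree$tip.label)
  nl <- as_nodelist(tree)
  log <- list()
  with_seed(seed, {
    chosen <- sample.int(n, floor(fraction * n))
    for (t in chosen) {
      p <- nl$parent[t]
      live <- which(nl$alive)
      cand <- live[live != t & live != nl$root]
      dists <- vapply(cand, nl_edge_dist, integer(1), nl = nl, a = p)
      cand <- cand[dists >= 1 & dists <= max_dist]
      dists <- dists[dists >= 1 & dists <= max_dist]
      pruned <- nl_prune(nl, t)
      nl2 <- pruned$nl; sib <- pruned$sibling
      moved <- FALSE; pick <- NA_integer_; pick_d <- NA_integer_
      ord <- sample.int(length(cand))
      for (i in ord) {
        c_node <- cand[i]
        if (c_node == p) c_node <- sib            # old parent collapsed into sibling edge
        if (c_node == nl2$root) next              # cannot attach above the root
        a_m <- (nl2$age[nl2$parent[c_node]] + nl2$age[c_node]) / 2
        if (a_m <= nl2$age[t]) next               # pendant branch would be non-positive
        nl <- nl_graft(nl2, t, c_node, a_m)
        moved <- TRUE; pick <- cand[i]; pick_d <- dists[i]
        break
      }
      if (!moved) {
        warning("no feasible reattachment for tip '", nl$label[t],
                "'; left in place", call. = FALSE)
        # nl unchanged (prune was applied to a copy)
      }
      log[[length(log) + 1L]] <- tibble::tibble(
        tip = tree$tip.label[t], old_parent = p, target = pick,
        edge_dist = pick_d, moved = moved)
    }
  })
  out <- nl_to_phylo(nl)
  pr_validate_tree(out)
  stopifnot(setequal(out$tip.label, tree$tip.label))
  attr(out, "swaps") <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(tip = character(0), old_parent = integer(0),
                   target = integer(0), edge_dist = integer(0),
                   moved = logical(0))
  out
}

#' Randomize a tree's topology and node ages together
#'
#' Convenience wrapper applying [pr_swap_tips()] then [pr_randomize_ages()],
#' with independent child seeds derived from `seed`.
#'
#' @inheritParams pr_swap_tips
#' @param tip_fraction,age_fraction Fractions of tips to move and of internal
#'   nodes to re-age.
#' @return A validated `phylo` tree.
#' @export
pr_randomize_tree <- function(tree, tip_fraction = 0.5, age_fraction = 0.5,
                              max_dist = 2, seed = NULL) {
  seeds <- child_seeds(seed, 2)
  out <- pr_swap_tips(tree, tip_fraction, max_dist = max_dist, seed = seeds[[1]])
  pr_randomize_ages(out, age_fraction, seed = seeds[[2]])
}

#' Rate comparison between a focal clade and the rest under tree uncertainty
#'
#' Repeatedly randomizes the tree (tip swaps within `max_dist` edges plus node
#' age jitter), refits the ridge rates, and records the difference
#' \eqn{\Delta} between the mean branch-rate magnitude of the focal clade
#' (the MRCA of `focal_tips` in each randomized tree, stem branch included)
#' and the mean over all remaining branches. Reports the \eqn{\Delta}
#' distribution, the fraction of replicates with \eqn{\Delta > 0}, and a
#' one-sided sign-test p-value for a positive median.
#'
#' @param tree A validated `phylo` tree.
#' @param traits Trait table.
#' @param focal_tips Character vector (>= 2) of tip labels defining the focal
#'   clade by their MRCA.
#' @param replicates Number of randomized trees.
#' @param tip_fraction,age_fraction,max_dist Randomization intensity (see
#'   [pr_swap_tips()], [pr_randomize_ages()]).
#' @param lambda Ridge penalty passed to [pr_rates()] (`"auto"` or numeric).
#' @param seed Integer seed; the replicate stream is fully reproducible.
#' @return An object of class `pr_uncertainty`: per-replicate tibble
#'   (`replicate`, `delta`), `fraction_positive`, sign-test `p_value`, and
#'   the fixed-tree `delta_observed`.
#' @export
pr_uncertainty_rates <- function(tree, traits, focal_tips, replicates = 100,
                                 tip_fraction = 0.5, age_fraction = 0.5,
                                 max_dist = 2, lambda = "auto", seed = NULL) {
  pr_validate_tree(tree)
  Y <- pr_trait_matrix(tree, traits)
  stopifnot(length(focal_tips) >= 2, all(focal_tips %in% tree$tip.label),
            replicates >= 1)
  delta_of <- function(tr) {
    fit <- pr_rates(tr, Y[tr$tip.label, , drop = FALSE], lambda = lambda,
                    seed = 1L)
    mrca <- mrca_node(tr, focal_tips)
    members <- c(mrca, descendant_nodes(tr, mrca))
    focal <- tr$edge[, 2L] %in% members
    mean(fit$rates$rate[focal]) - mean(fit$rates$rate[!focal])
  }
  seeds <- child_seeds(seed, replicates)
  deltas <- vapply(seq_len(replicates), function(r) {
    rt <- pr_randomize_tree(tree, tip_fraction, age_fraction,
                            max_dist = max_dist, seed = seeds[[r]])
    stopifnot(setequal(rt$tip.label, tree$tip.label))  # focal tips conserved
    delta_of(rt)
  }, numeric(1))
  npos <- sum(deltas > 0)
  structure(list(
    replicates = tibble::tibble(replicate = seq_len(replicates), delta = deltas),
    fraction_positive = npos / replicates,
    p_value = stats::binom.test(npos, replicates, p = 0.5,
                                alternative = "greater")$p.value,
    delta_observed = delta_of(tree)),
    class = "pr_uncertainty")
}

#' @export
print.pr_uncertainty <- function(x, ...) {
  cat("Focal-clade rate difference under tree randomization\n")
  cat(sprintf("  fixed tree delta = %.4g; %d replicates, %.0f%% positive, sign-test p = %.3g\n",
              x$delta_observed, nrow(x$replicates), 100 * x$fraction_positive,
              x$p_value))
  invisible(x)
}

#' @method tidy pr_uncertainty
#' @export
tidy.pr_uncertainty <- function(x, ...) x$replicates

#' @method glance pr_uncertainty
#' @export
glance.pr_uncertainty <- function(x, ...) {
  tibble::tibble(n_replicates = nrow(x$replicates),
                 delta_observed = x$delta_observed,
                 delta_median = stats::median(x$replicates$delta),
                 fraction_positive = x$fraction_positive,
                 p_value = x$p_value)
}

#' @method autoplot pr_uncertainty
#' @export
autoplot.pr_uncertainty <- function(object, ...) {
  ggplot2::ggplot(object$replicates, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$delta_observed, colour = "red") +
    ggplot2::labs(x = expression(Delta ~ "(focal - background mean |rate|)"),
                  y = "replicates") +
    ggplot2::theme_minimal()
}
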