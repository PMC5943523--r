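#' Angle between two vectors, in degrees
#'
#' \eqn{\theta = \arccos(A \cdot B / (|A||B|))}, with the cosine clipped to
#' \[-1, 1\] against rounding; always in \[0, 180\].
#'
#' @param a,b Nonzero numeric vectors of equal length.
#' @return Angle in degrees.
#' @export
#' @examples
#' pr_angle(c(1, 0), c(0, 1))   # 90
pr_angle <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("angle undefined for a zero vector", call. = FALSE)
  acos(max(-1, min(1, sum(a * b) / (na * nb)))) * 180 / pi
}

#' Resultant rate vector along a node-to-tip path
#'
#' The component-wise sum of the fitted per-branch rate vectors over every
#' branch on the path from `node` down to `tip` -- the net direction of
#' phenotypic change accumulated from the ancestor to the species.
#'
#' @param fit A [pr_rates()] object.
#' @param node Ancestral (internal) node.
#' @param tip A tip descending from `node`.
#' @return Named numeric vector (one entry per trait).
#' @export
pr_resultant <- function(fit, node, tip) {
  stopifnot(inherits(fit, "pr_rates"))
  tree <- fit$tree
  node <- resolve_node(tree, node)
  tip <- resolve_node(tree, tip)
  if (!(tip %in% c(node, clade_tips(tree, node))))
    stop("tip does not descend from the reference node", call. = FALSE)
  paths <- root_paths(tree)
  edges <- setdiff(paths[[tip]], paths[[node]])
  v <- colSums(fit$beta[edges, , drop = FALSE])
  stats::setNames(v, colnames(fit$beta))
}

#' Per-species trajectory angles relative to an ancestral reference
#'
#' For every grouped species, sums the fitted branch rate vectors along the
#' path from `ref_node` to the species (the resultant vector) and measures
#' its angle to a reference direction at the ancestor. The reference is
#' either the estimated ancestral phenotype vector at `ref_node`
#' (`reference = "state"`, the default: direction relative to the ancestral
#' position in trait space) or the rate vector of the branch subtending
#' `ref_node` (`reference = "branch"`).
#'
#' @param fit A [pr_rates()] object.
#' @param ref_node The ancestral reference node (label, `"N<id>"`, id, or a
#'   character vector of >= 2 tips whose MRCA is taken).
#' @param groups Data frame with columns `species` and `group`, or a named
#'   character vector (names = species).
#' @param reference `"state"` or `"branch"` (see above).
#' @return An object of class `pr_angles`: per-species tibble (`species`,
#'   `group`, `angle` in degrees, `magnitude` of the resultant), plus the
#'   reference vector and node.
#' @export
pr_trajectory_angles <- function(fit, ref_node, groups,
                                 reference = c("state", "branch")) {
  stopifnot(inherits(fit, "pr_rates"))
  reference <- match.arg(reference)
  tree <- fit$tree
  if (is.character(ref_node) && length(ref_node) > 1)
    ref_node <- mrca_node(tree, ref_node)
  ref_node <- resolve_node(tree, ref_node)
  if (ref_node <= length(tree$tip.label))
    stop("ref_node must be an internal node", call. = FALSE)
  if (is.data.frame(groups)) {
    gmap <- stats::setNames(as.character(groups$group), as.character(groups$species))
  } else {
    gmap <- stats::setNames(as.character(groups), names(groups))
  }
  tips_in <- node_names(tree)[clade_tips(tree, ref_node)]
  outside <- setdiff(names(gmap), tips_in)
  if (length(outside))
    stop("species outside the reference clade: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  ref_vec <- if (reference == "state") {
    anc <- pr_ancestral(fit)
    unlist(anc[anc$node == node_names(tree)[ref_node], -1L])
  } else {
    e <- which(tree$edge[, 2L] == ref_node)
    if (!length(e)) stop("ref_node is the root: it has no subtending branch",
                         call. = FALSE)
    fit$beta[e, ]
  }
  if (sqrt(sum(ref_vec^2)) == 0)
    stop("reference vector is zero; angles undefined", call. = FALSE)
  species <- names(gmap)
  res <- lapply(species, function(sp) pr_resultant(fit, ref_node, sp))
  mags <- vapply(res, function(v) sqrt(sum(v^2)), numeric(1))
  if (any(mags == 0))
    stop("zero resultant vector for: ",
         paste(species[mags == 0], collapse = ", "), call. = FALSE)
  out <- tibble::tibble(
    species = species,
    group = unname(gmap),
    angle = vapply(res, pr_angle, numeric(1), b = ref_vec),
    magnitude = mags)
  structure(list(angles = out, ref_node = node_names(tree)[ref_node],
                 ref_vector = ref_vec, reference = reference),
            class = "pr_angles")
}

#' @export
print.pr_angles <- function(x, ...) {
  cat("Trajectory angles to", x$ref_node,
      sprintf("(reference = %s)\n", x$reference))
  print(dplyr::summarise(dplyr::group_by(x$angles, .data$group),
                         n = dplyr::n(), mean_angle = mean(.data$angle)))
  invisible(x)
}

#' @method tidy pr_angles
#' @export
tidy.pr_angles <- function(x, ...) x$angles

#' @method glance pr_angles
#' @export
glance.pr_angles <- function(x, ...) {
  x$angles |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean_angle = mean(.data$angle),
                     .groups = "drop")
}

#' Permutation test for between-group divergence of trajectory angles
#'
#' For each pair of groups, the observed absolute difference in mean angle is
#' compared against a null family built by shuffling the species' group
#' labels within the pair. The test is one-tailed -- a difference larger than
#' chance means divergent trajectories, otherwise parallel -- and uses the
#' add-one rule \eqn{p = (1 + \#\{null \ge obs\}) / (n_{perm} + 1)}, so p is
#' never exactly zero and is bit-reproducible from `seed`.
#'
#' @param x A [pr_trajectory_angles()] object, or a data frame with `group`
#'   and `angle` columns.
#' @param n_perm Number of label shuffles (default 10000).
#' @param seed Integer seed.
#' @return Tibble: one row per group pair with group mean angles, observed
#'   absolute difference, permutation p-value, and `n_perm`.
#' @export
pr_angle_test <- function(x, n_perm = 10000, seed = NULL) {
  d <- if (inherits(x, "pr_angles")) x$angles else tibble::as_tibble(x)
  stopifnot(all(c("group", "angle") %in% names(d)), n_perm >= 1)
  groups <- sort(unique(d$group))
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(d$group)
  if (any(sizes < 2)) stop("every group needs at least 2 members", call. = FALSE)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  with_seed(seed, {
    rows <- lapply(pairs, function(pr) {
      a1 <- d$angle[d$group == pr[1]]
      a2 <- d$angle[d$group == pr[2]]
      obs <- abs(mean(a1) - mean(a2))
      pool <- c(a1, a2)
      n1 <- length(a1)
      null <- replicate(n_perm, {
        idx <- sample.int(length(pool), n1)
        abs(mean(pool[idx]) - mean(pool[-idx]))
      })
      tibble::tibble(group1 = pr[1], group2 = pr[2],
                     mean1 = mean(a1), mean2 = mean(a2),
                     diff = obs,
                     p = (1 + sum(null >= obs)) / (n_perm + 1),
                     n_perm = n_perm)
    })
    dplyr::bind_rows(rows)
  })
}

#' Plot trajectory angles by group
#'
#' @param object A [pr_trajectory_angles()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pr_angles
#' @export
autoplot.pr_angles <- function(object, ...) {
  ggplot2::ggplot(object$angles,
                  ggplot2::aes(x = .data$group, y = .data$angle)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = sprintf("angle to %s (degrees)", object$ref_node)) +
    ggplot2::theme_minimal()
}
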