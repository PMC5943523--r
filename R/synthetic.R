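#' Simulate a random time-calibrated tree
#'
#' Draws a random binary coalescent-shaped topology, rescales it to the
#' requested depth, and optionally truncates a fraction of pendant branches so
#' that those tips end at positive ages, emulating fossil taxa. All generators
#' in the package are bit-reproducible from `seed`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param depth Root age in time units (default 50, a primate-like timescale).
#' @param fossil_fraction Fraction of tips in `[0, 1)` to truncate to positive
#'   ages; the truncation point is uniform over the middle 10--90% of the
#'   pendant branch.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A validated `phylo` tree with tip labels `t1 ... tN`.
#' @export
#' @examples
#' tr <- pr_simulate_tree(10, seed = 1)
#' range(pr_node_ages(tr))
pr_simulate_tree <- function(n_tips, depth = 50, fossil_fraction = 0, seed = NULL) {
  stopifnot(n_tips >= 2, depth > 0, fossil_fraction >= 0, fossil_fraction < 1)
  with_seed(seed, {
    tree <- ape::rcoal(n_tips)
    tree$edge.length <- tree$edge.length * depth / max(node_depths(tree)[seq_len(n_tips)])
    n_fossil <- floor(fossil_fraction * n_tips)
    if (n_fossil > 0) {
      fossil <- sample.int(n_tips, n_fossil)
      for (tip in fossil) {
        e <- which(tree$edge[, 2L] == tip)
        tree$edge.length[e] <- tree$edge.length[e] * stats::runif(1, 0.1, 0.9)
      }
    }
    pr_validate_tree(tree)
    tree
  })
}

#' Simulate multivariate Brownian traits on a tree
#'
#' Accumulates independent Gaussian increments along every branch, with
#' variance = branch length x rate. Inside the clade subtended by
#' `shift_node` (stem branch included) the rate is multiplied by
#' `shift_multiplier`, producing the clade-level rate-regime structure the
#' shift-detection machinery is designed to recover. The root phenotype is 0
#' on every trait, so root-estimate recovery has a known truth.
#'
#' @param tree A validated `phylo` tree.
#' @param n_traits Number of trait columns.
#' @param sigma2 Background Brownian rate, scalar or per-trait vector
#'   (trait-units squared per time unit).
#' @param shift_node Internal node (label, `"N<id>"`, or id) defining the
#'   elevated-rate clade; `NULL` for a uniform-rate tree.
#' @param shift_multiplier Rate multiplier inside the shift clade (> 0).
#' @param seed Integer seed.
#' @return A tibble with column `species` followed by one numeric column per
#'   trait; attribute `"node_states"` holds simulated internal-node states.
#' @export
pr_simulate_traits <- function(tree, n_traits = 4, sigma2 = 1, shift_node = NULL,
                               shift_multiplier = 1, seed = NULL) {
  pr_validate_tree(tree)
  stopifnot(all(sigma2 >= 0), shift_multiplier > 0)
  n <- length(tree$tip.label)
  sigma2 <- rep_len(sigma2, n_traits)
  mult <- rep(1, nrow(tree$edge))
  if (!is.null(shift_node)) {
    sn <- resolve_node(tree, shift_node)
    if (sn <= n) stop("shift_node must be an internal node", call. = FALSE)
    # regime membership: child is the shift node itself or any of its descendants
    desc <- c(sn, descendant_nodes(tree, sn))
    mult[tree$edge[, 2L] %in% desc] <- shift_multiplier
  }
  with_seed(seed, {
    states <- matrix(0, n + tree$Nnode, n_traits)
    eo <- ape::reorder.phylo(tree, "postorder")
    ord <- rev(seq_len(nrow(eo$edge)))    # preorder: parents before children
    midx <- match(paste(eo$edge[, 1L], eo$edge[, 2L]), paste(tree$edge[, 1L], tree$edge[, 2L]))
    for (i in ord) {
      sd_br <- sqrt(eo$edge.length[i] * sigma2 * mult[midx[i]])
      states[eo$edge[i, 2L], ] <- states[eo$edge[i, 1L], ] + stats::rnorm(n_traits) * sd_br
    }
    tips <- states[seq_len(n), , drop = FALSE]
    colnames(tips) <- paste0("trait", seq_len(n_traits))
    out <- tibble::tibble(species = tree$tip.label)
    out <- dplyr::bind_cols(out, tibble::as_tibble(tips))
    nodes <- states[n + seq_len(tree$Nnode), , drop = FALSE]
    dimnames(nodes) <- list(node_names(tree)[n + seq_len(tree$Nnode)],
                            colnames(tips))
    attr(out, "node_states") <- nodes
    out
  })
}

# all descendant node ids (tips + internal) of a node
descendant_nodes <- function(tree, node) {
  kids <- tree$edge[, 2L][tree$edge[, 1L] == node]
  if (!length(kids)) return(integer(0))
  c(kids, unlist(lapply(kids, descendant_nodes, tree = tree)))
}

#' A jaw-profile-like consensus configuration
#'
#' Nine 2-D landmarks tracing an open arc with interior points, used as the
#' default template for [pr_simulate_landmarks()].
#'
#' @return A 9 x 2 numeric matrix.
#' @export
pr_default_consensus <- function() {
  theta <- seq(-0.2 * pi, 0.9 * pi, length.out = 7)
  arc <- cbind(cos(theta), 0.6 * sin(theta))
  rbind(arc, c(0.2, 0.15), c(-0.3, 0.1))
}

#' Simulate landmark configurations
#'
#' Generates specimens per species as the consensus configuration (plus a
#' group-specific mean shape shift for species in the second group), perturbed
#' by isotropic Gaussian landmark noise, then hit with a random rotation,
#' translation and positive scaling -- i.e. exactly the nuisance variation
#' Generalized Procrustes superimposition is meant to remove.
#'
#' @param n_species Number of species.
#' @param n_specimens Specimens per species (>= 1).
#' @param consensus k x 2 landmark template (default [pr_default_consensus()]).
#' @param noise_sd Isotropic landmark noise standard deviation, in consensus
#'   coordinate units.
#' @param group_shift k x 2 displacement added to the consensus for species in
#'   group "B"; `NULL` disables grouping. The default moves two landmarks by
#'   0.15 units, a clearly detectable two-group shape difference.
#' @param seed Integer seed.
#' @return A long tibble (`specimen`, `species`, `group`, `landmark`, `x`,
#'   `y`) consumable by [pr_gpa()].
#' @export
pr_simulate_landmarks <- function(n_species = 20, n_specimens = 3,
                                  consensus = pr_default_consensus(),
                                  noise_sd = 0.05, group_shift = NULL,
                                  seed = NULL) {
  stopifnot(nrow(consensus) >= 3, ncol(consensus) == 2, n_specimens >= 1, noise_sd >= 0)
  if (max(dist(consensus)) == 0) stop("degenerate consensus configuration", call. = FALSE)
  k <- nrow(consensus)
  species <- sprintf("sp%02d", seq_len(n_species))
  group <- if (is.null(group_shift)) rep("A", n_species)
           else rep(c("A", "B"), length.out = n_species)
  shift <- group_shift
  with_seed(seed, {
    rows <- list()
    idx <- 1L
    for (s in seq_len(n_species)) {
      base <- consensus
      if (!is.null(shift) && group[s] == "B") base <- base + shift
      for (r in seq_len(n_specimens)) {
        cfg <- base + matrix(stats::rnorm(2 * k, sd = noise_sd), k, 2)
        ang <- stats::runif(1, 0, 2 * pi)
        R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
        scale <- exp(stats::runif(1, -0.5, 0.5))
        shiftxy <- stats::rnorm(2, sd = 2)
        cfg <- scale * cfg %*% R + matrix(shiftxy, k, 2, byrow = TRUE)
        rows[[idx]] <- tibble::tibble(
          specimen = sprintf("%s_%02d", species[s], r),
          species = species[s], group = group[s],
          landmark = seq_len(k), x = cfg[, 1], y = cfg[, 2])
        idx <- idx + 1L
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Default two-group shape displacement for the landmark generator
#'
#' Moves landmarks 3 and 6 by 0.15 units along y, a shape effect three times
#' the default landmark noise.
#'
#' @param k Number of landmarks.
#' @return k x 2 displacement matrix.
#' @export
pr_default_group_shift <- function(k = 9) {
  m <- matrix(0, k, 2)
  m[3, 2] <- 0.15
  m[6, 2] <- -0.15
  m
}
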