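#' Maximum-likelihood Brownian rate of a clade
#'
#' For the subtree rooted at `node`, computes the ML single-rate Brownian
#' estimate of the tip data: per trait, \eqn{\hat\sigma^2 = z^T C^{-1} z / n}
#' with `z` the tip values centered on the subtree GLS mean and `C` the
#' subtree variance-covariance (shared path lengths from the clade root). The
#' multivariate value is the mean of the per-trait estimates, a scale-balanced
#' scalar for ranking clades.
#'
#' ML (divide by n) rather than REML is used here on purpose: ranking needs a
#' consistent ordering, not an unbiased level.
#'
#' @param tree A validated `phylo` tree.
#' @param traits Trait table (see [pr_trait_matrix()]).
#' @param node Internal node defining the clade (>= 2 tips).
#' @return The scalar rate; attribute `"per_trait"` carries the per-trait
#'   estimates. An all-identical clade yields 0 with a warning (degenerate).
#' @export
pr_clade_rate <- function(tree, traits, node) {
  Y <- pr_trait_matrix(tree, traits)
  node <- resolve_node(tree, node)
  tips <- clade_tips(tree, node)
  if (length(tips) < 2) stop("clade must contain at least 2 tips", call. = FALSE)
  sub <- if (length(tips) == length(tree$tip.label)) tree else
    ape::extract.clade(tree, node)
  Ys <- Y[sub$tip.label, , drop = FALSE]
  C <- ape::vcv.phylo(sub)[sub$tip.label, sub$tip.label]
  R <- tryCatch(chol(C), error = function(e)
    stop("singular clade covariance", call. = FALSE))
  ones <- rep(1, nrow(Ys))
  Ci1 <- chol_solve(R, ones)
  mu <- drop(crossprod(Ci1, Ys)) / sum(Ci1)
  Z <- sweep(Ys, 2, mu)
  s2 <- colSums(Z * chol_solve(R, Z)) / nrow(Ys)
  if (all(s2 == 0)) warning("degenerate clade: identical tip values", call. = FALSE)
  structure(mean(s2), per_trait = s2)
}

#' Rank clades by Brownian rate
#'
#' Every internal node whose clade holds at least `min_size` tips (the root
#' excluded: a whole-tree "shift" is just a rescaled background) is scored
#' with [pr_clade_rate()] and sorted by descending rate; ties break toward the
#' larger clade, then the smaller node id.
#'
#' @inheritParams pr_clade_rate
#' @param min_size Minimum clade size in tips (>= 2), default 5.
#' @return Tibble: `node` (label), `node_id`, `n_tips`, `sigma2`, descending.
#' @export
pr_rank_clades <- function(tree, traits, min_size = 5) {
  stopifnot(min_size >= 2)
  Y <- pr_trait_matrix(tree, traits)
  n <- length(tree$tip.label)
  root <- n + 1L
  cand <- setdiff(internal_nodes(tree), root)
  sizes <- vapply(cand, function(v) length(clade_tips(tree, v)), integer(1))
  keep <- sizes >= min_size
  if (!any(keep)) stop("no clade reaches min_size = ", min_size, call. = FALSE)
  cand <- cand[keep]; sizes <- sizes[keep]
  s2 <- vapply(cand, function(v) as.numeric(pr_clade_rate(tree, Y, v)), numeric(1))
  ord <- order(-s2, -sizes, cand)
  tibble::tibble(node = node_names(tree)[cand[ord]], node_id = cand[ord],
                 n_tips = sizes[ord], sigma2 = s2[ord])
}

#' Enumerate candidate shift models
#'
#' All subsets of the candidate nodes; the empty subset is the single-rate
#' (pure Brownian motion) model, so `n` candidates yield `2^n` models. Nested
#' candidates are allowed: a branch always belongs to the regime of its
#' nearest enclosing shift node.
#'
#' @param nodes Character or integer vector of candidate shift nodes
#'   (possibly empty).
#' @return List of model skeletons; each element is the (possibly empty)
#'   vector of shift nodes.
#' @export
#' @examples
#' length(pr_shift_models(c("N11", "N15", "N20")))  # 8
pr_shift_models <- function(nodes) {
  n <- length(nodes)
  models <- list(nodes[integer(0)])
  if (n == 0) return(models)
  for (k in seq_len(n)) {
    combos <- utils::combn(n, k, simplify = FALSE)
    models <- c(models, lapply(combos, function(i) nodes[i]))
  }
  models
}

# regime label per edge: nearest enclosing shift node (stem branch included),
# else "bg"
regime_assignment <- function(tree, shift_nodes) {
  shift_nodes <- if (length(shift_nodes)) resolve_node(tree, shift_nodes) else integer(0)
  regimes <- rep("bg", nrow(tree$edge))
  if (!length(shift_nodes)) return(regimes)
  n <- length(tree$tip.label)
  if (any(shift_nodes <= n)) stop("shift nodes must be internal", call. = FALSE)
  if ((n + 1L) %in% shift_nodes)
    stop("a shift at the root leaves no background regime", call. = FALSE)
  # depth in edges from root, to find the *nearest* enclosing shift node
  depth_e <- integer(n + tree$Nnode)
  eo <- ape::reorder.phylo(tree, "postorder")
  for (i in rev(seq_len(nrow(eo$edge))))
    depth_e[eo$edge[i, 2L]] <- depth_e[eo$edge[i, 1L]] + 1L
  for (s in shift_nodes[order(depth_e[shift_nodes])]) {   # shallow first, deep overwrite
    members <- c(s, descendant_nodes(tree, s))
    regimes[tree$edge[, 2L] %in% members] <- node_names(tree)[s]
  }
  regimes
}

# per-regime shared-path covariance pieces: C = sum_r sigma2_r C_r
regime_covariances <- function(tree, regimes) {
  n <- length(tree$tip.label)
  pieces <- lapply(unique(regimes), function(r) matrix(0, n, n))
  names(pieces) <- unique(regimes)
  for (e in seq_len(nrow(tree$edge))) {
    tb <- clade_tips(tree, tree$edge[e, 2L])
    pieces[[regimes[e]]][tb, tb] <- pieces[[regimes[e]]][tb, tb] + tree$edge.length[e]
  }
  for (r in names(pieces)) dimnames(pieces[[r]]) <- list(tree$tip.label, tree$tip.label)
  pieces
}

# concentrated REML log-likelihood of Y under N(1 mu', R (x) V)
reml_loglik <- function(V, Y) {
  n <- nrow(Y); p <- ncol(Y)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(ll = -Inf))
  ones <- rep(1, n)
  Ci1 <- chol_solve(R, ones)
  s11 <- sum(Ci1)
  mu <- drop(crossprod(Ci1, Y)) / s11
  E <- sweep(Y, 2, mu)
  M <- crossprod(E, chol_solve(R, E)) / (n - 1)
  Rm <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(Rm)) return(list(ll = NA_real_, degenerate = TRUE))
  ll <- -0.5 * ((n - 1) * p * log(2 * pi) + p * chol_logdet(R) +
                  (n - 1) * chol_logdet(Rm) + p * log(s11) + (n - 1) * p)
  list(ll = ll, mu = mu, trait_cov = M)
}

#' Fit a multi-rate Brownian model by restricted maximum likelihood
#'
#' Tip data are modelled as matrix-normal with tree covariance
#' \eqn{V = \sum_r m_r C_r}, where `C_r` accumulates the shared-path
#' contributions of the branches in regime `r` (regimes: nearest enclosing
#' shift node, else background with multiplier fixed at 1), and a common
#' across-trait covariance shared by all regimes (proportional model). The
#' regime multipliers are optimized on the log scale against the REML
#' log-likelihood with the trait covariance concentrated out; per-regime
#' rates are reported as multiplier x mean trait variance.
#'
#' @inheritParams pr_clade_rate
#' @param shift_nodes Vector of internal shift nodes (possibly empty = pure
#'   Brownian motion).
#' @return An object of class `pr_bm_fit`: log-likelihood, regime table
#'   (`regime`, `n_branches`, `multiplier`, `sigma2`), regime count,
#'   convergence flag.
#' @export
pr_fit_multirate <- function(tree, traits, shift_nodes = character(0)) {
  pr_validate_tree(tree)
  Y <- pr_trait_matrix(tree, traits)
  regimes <- regime_assignment(tree, shift_nodes)
  pieces <- regime_covariances(tree, regimes)
  if (any(vapply(pieces, function(m) all(m == 0), logical(1))))
    stop("a regime contributes to no tip path; its rate is unidentifiable",
         call. = FALSE)
  shift_regimes <- setdiff(names(pieces), "bg")
  objective <- function(theta) {
    V <- pieces[["bg"]]
    for (i in seq_along(shift_regimes)) V <- V + exp(theta[i]) * pieces[[shift_regimes[i]]]
    out <- reml_loglik(V, Y)
    if (isTRUE(out$degenerate))
      stop("degenerate fit: zero residual trait variance", call. = FALSE)
    out
  }
  if (length(shift_regimes) == 0) {
    fit <- objective(numeric(0))
    mult <- numeric(0); conv <- TRUE
  } else {
    negll <- function(theta) -objective(theta)$ll
    opt <- stats::optim(rep(0, length(shift_regimes)), negll,
                        method = if (length(shift_regimes) == 1) "Brent" else "Nelder-Mead",
                        lower = if (length(shift_regimes) == 1) log(1e-6) else -Inf,
                        upper = if (length(shift_regimes) == 1) log(1e6) else Inf,
                        control = if (length(shift_regimes) == 1) list() else
                          list(maxit = 2000, reltol = 1e-12))
    conv <- opt$convergence == 0
    if (!conv) warning("multirate REML optimizer did not converge (code ",
                       opt$convergence, ")", call. = FALSE)
    mult <- exp(opt$par)
    fit <- objective(opt$par)
  }
  base <- mean(diag(fit$trait_cov))
  regime_names <- c("bg", shift_regimes)
  multipliers <- c(bg = 1, stats::setNames(mult, shift_regimes))
  structure(list(
    shift_nodes = if (length(shift_nodes)) node_names(tree)[resolve_node(tree, shift_nodes)]
                  else character(0),
    logLik = fit$ll,
    n_regimes = length(regime_names),
    regimes = tibble::tibble(
      regime = regime_names,
      n_branches = vapply(regime_names, function(r) sum(regimes == r), integer(1)),
      multiplier = unname(multipliers[regime_names]),
      sigma2 = unname(multipliers[regime_names]) * base),
    trait_cov = fit$trait_cov,
    converged = conv,
    n_tips = nrow(Y), n_traits = ncol(Y),
    data_digest = sum(Y) + nrow(Y) * 1e-9),
    class = "pr_bm_fit")
}

#' @export
print.pr_bm_fit <- function(x, ...) {
  cat(sprintf("Multi-rate Brownian REML fit: %d regime(s), logLik = %.4f\n",
              x$n_regimes, x$logLik))
  print(x$regimes)
  invisible(x)
}

#' Compare fitted multi-rate Brownian models by likelihood-ratio tests
#'
#' Nested pairs (one shift set a subset of the other) are contrasted by a
#' chi-square likelihood-ratio test with degrees of freedom equal to the
#' difference in regime count. The winner is the most complex model that
#' significantly (alpha) beats every nested simpler model, falling back to
#' the single-rate Brownian model; with identical likelihoods the simpler
#' model wins.
#'
#' @param fits List of `pr_bm_fit` objects on the same data, including the
#'   pure Brownian (no-shift) model.
#' @param alpha Significance level for each likelihood-ratio test.
#' @return List: `best` (a `pr_bm_fit`), `table` (tibble with model id,
#'   regimes, logLik, LRT against the Brownian model, and whether the model
#'   beats all nested submodels).
#' @export
pr_compare_models <- function(fits, alpha = 0.05) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, logical(1), "pr_bm_fit")))
  dg <- vapply(fits, function(f) f$data_digest, numeric(1))
  if (max(dg) - min(dg) > 1e-8 * max(1, abs(dg[1])))
    stop("models were fitted on different data", call. = FALSE)
  shift_sets <- lapply(fits, function(f) sort(f$shift_nodes))
  if (!any(lengths(shift_sets) == 0))
    stop("the pure Brownian model must be among the fits", call. = FALSE)
  ll <- vapply(fits, function(f) f$logLik, numeric(1))
  k <- vapply(fits, function(f) f$n_regimes, numeric(1))
  bm <- which(lengths(shift_sets) == 0)[1]
  lrt_p <- function(i, j) {  # i complex, j nested simpler
    stat <- max(0, 2 * (ll[i] - ll[j]))
    stats::pchisq(stat, df = k[i] - k[j], lower.tail = FALSE)
  }
  beats_all <- vapply(seq_along(fits), function(i) {
    nested <- which(vapply(seq_along(fits), function(j) {
      length(shift_sets[[j]]) < length(shift_sets[[i]]) &&
        all(shift_sets[[j]] %in% shift_sets[[i]])
    }, logical(1)))
    length(nested) > 0 && all(vapply(nested, function(j)
      ll[i] > ll[j] && lrt_p(i, j) < alpha, logical(1)))
  }, logical(1))
  candidates <- which(beats_all)
  best <- if (length(candidates)) {
    candidates[order(-k[candidates], -ll[candidates])][1]
  } else bm
  tab <- tibble::tibble(
    model = vapply(shift_sets, function(s)
      if (length(s)) paste(s, collapse = "+") else "BM", character(1)),
    n_regimes = as.integer(k),
    logLik = ll,
    aic = 2 * k - 2 * ll,          # reported for reference, not the decision rule
    lrt_vs_bm = ifelse(seq_along(fits) == bm, NA_real_,
                       pmax(0, 2 * (ll - ll[bm]))),
    p_vs_bm = ifelse(seq_along(fits) == bm, NA_real_,
                     stats::pchisq(pmax(0, 2 * (ll - ll[bm])), df = k - k[bm],
                                   lower.tail = FALSE)),
    beats_nested = beats_all,
    selected = seq_along(fits) == best)
  list(best = fits[[best]], table = tab)
}

#' Cluster candidate shift nodes by patristic distance
#'
#' Average-linkage hierarchical clustering of the candidates'
#' patristic-distance matrix. The number of groups k is chosen by maximizing
#' the mean silhouette width over k = 2 ... min(8, n-1), with a bootstrap
#' majority vote (resampling candidates with replacement) to stabilize the
#' choice; each group is represented by its highest-rate node.
#'
#' @param tree A validated `phylo` tree.
#' @param ranking A [pr_rank_clades()] tibble (or at least `node` and
#'   `sigma2` columns) with >= 2 rows.
#' @param n_boot Bootstrap resamples for the vote.
#' @param seed Integer seed.
#' @return List: `k`, `groups` (tibble `node`, `sigma2`, `group`),
#'   `representatives` (one node per group, highest rate first).
#' @export
pr_cluster_candidates <- function(tree, ranking, n_boot = 100, seed = NULL) {
  stopifnot(nrow(ranking) >= 2)
  nodes <- ranking$node
  D <- patristic_matrix(tree, nodes)
  n <- length(nodes)
  best_k <- function(Dm) {
    m <- nrow(Dm)
    ks <- 2:min(8, m - 1)
    if (!length(ks) || max(Dm) == 0) return(2L)
    hc <- stats::hclust(stats::as.dist(Dm), method = "average")
    sil <- vapply(ks, function(k) {
      cl <- stats::cutree(hc, k = k)
      if (length(unique(cl)) < 2) return(-Inf)
      mean(cluster::silhouette(cl, stats::as.dist(Dm))[, "sil_width"])
    }, numeric(1))
    ks[which.max(sil)]
  }
  votes <- with_seed(seed, {
    replicate(n_boot, {
      idx <- unique(sample.int(n, n, replace = TRUE))
      if (length(idx) < 3) return(NA_integer_)
      best_k(D[idx, idx, drop = FALSE])
    })
  })
  votes <- votes[!is.na(votes)]
  k <- if (length(votes)) as.integer(names(sort(table(votes), decreasing = TRUE))[1])
       else best_k(D)
  k <- min(k, n - 1L)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  cl <- stats::cutree(hc, k = max(2L, k))
  groups <- tibble::tibble(node = nodes, sigma2 = ranking$sigma2, group = unname(cl))
  reps <- groups |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_max(.data$sigma2, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$sigma2))
  list(k = max(2L, k), groups = groups, representatives = reps$node)
}

#' Scan a tree for clade-level rate shifts
#'
#' The full rate-by-clade pipeline: rank all clades of at least `min_size`
#' tips by Brownian rate, take the top `top_n` nodes (or, with
#' `cluster = TRUE`, let a bootstrapped cluster analysis of the candidates'
#' patristic distances set the number of nodes to carry forward), enumerate
#' all `2^n` shift combinations including the no-shift model, fit each by
#' multi-rate REML and select the winner by likelihood-ratio ladder.
#'
#' @inheritParams pr_clade_rate
#' @param min_size Minimum clade size for candidates.
#' @param top_n Number of top-rate candidate nodes to search over.
#' @param cluster If `TRUE`, the candidate count is set by
#'   [pr_cluster_candidates()] instead of `top_n`.
#' @param n_boot Bootstrap resamples for the cluster vote.
#' @param alpha Likelihood-ratio test level.
#' @param seed Integer seed (clustering only).
#' @return An object of class `pr_shift_scan`: ranking, candidate nodes,
#'   fitted models, comparison table, selected model.
#' @export
#' @examples
#' tr <- pr_simulate_tree(40, seed = 1)
#' y  <- pr_simulate_traits(tr, n_traits = 2, seed = 2)
#' scan <- pr_shift_scan(tr, y, min_size = 5, top_n = 2)
#' tidy(scan)
pr_shift_scan <- function(tree, traits, min_size = 5, top_n = 3, cluster = FALSE,
                          n_boot = 100, alpha = 0.05, seed = NULL) {
  Y <- pr_trait_matrix(tree, traits)
  ranking <- pr_rank_clades(tree, Y, min_size = min_size)
  n_cand <- if (cluster) {
    pr_cluster_candidates(tree, ranking, n_boot = n_boot, seed = seed)$k
  } else top_n
  n_cand <- min(n_cand, nrow(ranking))
  candidates <- ranking$node[seq_len(n_cand)]
  models <- pr_shift_models(candidates)
  fits <- lapply(models, function(m) pr_fit_multirate(tree, Y, m))
  cmp <- pr_compare_models(fits, alpha = alpha)
  structure(list(ranking = ranking, candidates = candidates, fits = fits,
                 table = cmp$table, best = cmp$best),
            class = "pr_shift_scan")
}

#' @export
print.pr_shift_scan <- function(x, ...) {
  cat("Rate-by-clade shift scan\n")
  cat("  candidates:", paste(x$candidates, collapse = ", "), "\n")
  sel <- x$best$shift_nodes
  cat("  selected model:",
      if (length(sel)) paste(sel, collapse = " + ") else "single-rate BM", "\n")
  invisible(x)
}

#' @method tidy pr_shift_scan
#' @export
tidy.pr_shift_scan <- function(x, ...) x$table

#' @method glance pr_shift_scan
#' @export
glance.pr_shift_scan <- function(x, ...) {
  tibble::tibble(
    n_candidates = length(x$candidates),
    n_models = length(x$fits),
    selected = if (length(x$best$shift_nodes))
      paste(x$best$shift_nodes, collapse = "+") else "BM",
    logLik = x$best$logLik,
    n_regimes = x$best$n_regimes)
}

#' Plot the clade-rate ranking of a shift scan
#'
#' @param object A [pr_shift_scan()] object.
#' @param n_top Number of top clades to display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pr_shift_scan
#' @export
autoplot.pr_shift_scan <- function(object, n_top = 20, ...) {
  d <- utils::head(object$ranking, n_top)
  d$node <- factor(d$node, levels = rev(d$node))
  d$selected <- d$node %in% object$best$shift_nodes
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sigma2, y = .data$node,
                                  fill = .data$selected)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::labs(x = expression(hat(sigma)^2), y = "clade (node below)",
                  fill = "in selected model") +
    ggplot2::theme_minimal()
}
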