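#' Brownian-motion GLS estimate of the root phenotype
#'
#' Per-trait generalized least squares mean of the tip values under Brownian
#' motion, weighting by the tree's tip variance-covariance matrix (shared
#' root-to-tip path lengths). This is the phenotype against which per-branch
#' transformations are measured: tip values are centered on it before the
#' ridge solve and it is added back to ancestral estimates.
#'
#' @param tree A validated `phylo` tree.
#' @param traits Trait table (see [pr_trait_matrix()]).
#' @return Named numeric vector, one value per trait.
#' @export
pr_root_estimate <- function(tree, traits) {
  Y <- pr_trait_matrix(tree, traits)
  C <- ape::vcv.phylo(tree)[rownames(Y), rownames(Y)]
  R <- tryCatch(chol(C), error = function(e)
    stop("singular tip covariance (duplicated zero-length tips?)", call. = FALSE))
  ones <- rep(1, nrow(Y))
  Ci1 <- chol_solve(R, ones)
  drop(crossprod(Ci1, Y)) / sum(Ci1)
}

#' Default ridge-penalty grid
#'
#' Thirty log-spaced values from 1e-6 to 1e3, the search space for
#' cross-validated penalty selection.
#'
#' @param n Number of grid points.
#' @return Numeric vector, increasing.
#' @export
pr_lambda_grid <- function(n = 30) 10^seq(-6, 3, length.out = n)

#' Fit per-branch evolutionary rates by phylogenetic ridge regression
#'
#' Solves, independently for each trait column of the root-centered tip data,
#' the penalized least-squares system
#' \deqn{\hat\beta = (L^T L + \lambda I)^{-1} L^T y}
#' where `L` is the tip-to-root path matrix ([pr_tip_path_matrix()]): each
#' branch receives one regression coefficient per trait, interpretable as the
#' rate of phenotypic change along that branch (trait units per time unit).
#' The scalar evolutionary rate of a branch is the Euclidean norm of its
#' coefficient vector across traits.
#'
#' With `lambda = "auto"` the penalty is chosen by k-fold cross-validated
#' prediction error of tip phenotypes over `grid` (one shared penalty for the
#' whole multivariate block; ties go to the larger penalty). `lambda = 0` is
#' only admissible when the system is full rank (star trees); on other trees
#' it fails with an explicit error since `t(L) %*% L` is then singular.
#'
#' @param tree A validated `phylo` tree.
#' @param traits Trait table (see [pr_trait_matrix()]).
#' @param lambda `"auto"`, or a single penalty >= 0.
#' @param grid Penalty grid used when `lambda = "auto"`.
#' @param folds Number of cross-validation folds.
#' @param seed Seed fixing the fold assignment.
#' @return An object of class `pr_rates`: a list with the per-branch
#'   coefficient matrix `beta`, the rate table (see [tidy.pr_rates()]), the
#'   root estimate, the penalty used and the cross-validation trace.
#' @seealso [pr_ancestral()], [pr_select_lambda()]
#' @export
#' @examples
#' tr <- pr_simulate_tree(20, seed = 1)
#' y  <- pr_simulate_traits(tr, n_traits = 2, seed = 2)
#' fit <- pr_rates(tr, y, lambda = 1)
#' tidy(fit)
pr_rates <- function(tree, traits, lambda = "auto", grid = pr_lambda_grid(),
                     folds = 5, seed = NULL) {
  pr_validate_tree(tree)
  Y <- pr_trait_matrix(tree, traits)
  cv <- NULL
  if (identical(lambda, "auto")) {
    sel <- pr_select_lambda(tree, Y, grid = grid, folds = folds, seed = seed)
    lambda <- sel$lambda
    cv <- sel$cv
  }
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  L <- pr_tip_path_matrix(tree)
  root <- pr_root_estimate(tree, Y)
  beta <- ridge_solve(L, sweep(Y, 2, root), lambda)
  ages <- pr_node_ages(tree)
  child <- tree$edge[, 2L]
  rates <- tibble::tibble(
    branch = pr_branch_labels(tree),
    parent = node_names(tree)[tree$edge[, 1L]],
    length = tree$edge.length,
    age = ages[child],
    is_tip = child <= length(tree$tip.label))
  betas <- tibble::as_tibble(beta, .name_repair = "minimal")
  names(betas) <- paste0("beta_", colnames(Y))
  rates <- dplyr::bind_cols(rates, betas)
  rates$rate <- sqrt(rowSums(beta^2))
  structure(list(tree = tree, traits = Y, beta = beta, rates = rates,
                 root = root, lambda = lambda, cv = cv),
            class = "pr_rates")
}

ridge_solve <- function(L, Yc, lambda) {
  A <- crossprod(L)
  diag(A) <- diag(A) + lambda
  R <- tryCatch(chol(A), error = function(e) {
    if (lambda == 0)
      stop("t(L) %*% L is singular at lambda = 0 (more branches than tips); ",
           "use lambda > 0", call. = FALSE)
    stop("ridge system not positive definite: ", conditionMessage(e), call. = FALSE)
  })
  B <- chol_solve(R, crossprod(L, Yc))
  dimnames(B) <- list(colnames(L), colnames(Yc))
  B
}

#' Cross-validated selection of the ridge penalty
#'
#' k-fold cross-validation over tips: each fold is held out, the root and the
#' branch coefficients are re-estimated from the remaining tips, and held-out
#' phenotypes are predicted as root + sum of rate x length along their
#' root-to-tip path. Returns the penalty minimizing the mean squared
#' prediction error across traits; exact ties are broken toward the larger
#' (more conservative) penalty.
#'
#' @inheritParams pr_rates
#' @return List with `lambda` (the choice) and `cv` (tibble of per-penalty
#'   mean squared errors).
#' @export
pr_select_lambda <- function(tree, traits, grid = pr_lambda_grid(), folds = 5,
                             seed = NULL) {
  Y <- pr_trait_matrix(tree, traits)
  stopifnot(length(grid) >= 1, all(is.finite(grid)))
  if (any(grid < 0)) stop("penalty grid must be non-negative", call. = FALSE)
  n <- nrow(Y)
  folds <- min(folds, n)
  L <- pr_tip_path_matrix(tree)
  C <- ape::vcv.phylo(tree)[rownames(Y), rownames(Y)]
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  mse <- vapply(grid, function(lam) {
    err <- 0
    for (f in seq_len(folds)) {
      test <- fold_id == f
      Rtr <- chol(C[!test, !test, drop = FALSE])
      ones <- rep(1, sum(!test))
      Ci1 <- chol_solve(Rtr, ones)
      root <- drop(crossprod(Ci1, Y[!test, , drop = FALSE])) / sum(Ci1)
      beta <- ridge_solve(L[!test, , drop = FALSE],
                          sweep(Y[!test, , drop = FALSE], 2, root), lam)
      pred <- sweep(L[test, , drop = FALSE] %*% beta, 2, root, "+")
      err <- err + sum((Y[test, , drop = FALSE] - pred)^2)
    }
    err / (n * ncol(Y))
  }, numeric(1))
  best <- max(grid[mse <= min(mse) + 1e-12])
  list(lambda = best,
       cv = tibble::tibble(lambda = grid, mse = mse, selected = grid == best))
}

#' Ancestral state estimates from a rate fit
#'
#' Multiplies the node-to-root path matrix by the fitted branch coefficients
#' and adds the root estimate back, yielding one phenotype estimate per
#' internal node and trait. The root row equals the root estimate exactly
#' (its path is empty).
#'
#' @param fit A [pr_rates()] object.
#' @return Tibble: `node` plus one column per trait.
#' @export
pr_ancestral <- function(fit) {
  stopifnot(inherits(fit, "pr_rates"))
  Lp <- pr_node_path_matrix(fit$tree)
  A <- sweep(Lp %*% fit$beta, 2, fit$root, "+")
  dplyr::bind_cols(tibble::tibble(node = rownames(A)),
                   tibble::as_tibble(A, .name_repair = "minimal"))
}

#' Predicted tip phenotypes under the fitted rates
#'
#' Root estimate plus the accumulated rate x length contributions along each
#' root-to-tip path; useful for reconstruction diagnostics.
#'
#' @param object A [pr_rates()] object.
#' @param ... Unused.
#' @return Tibble: `species` plus predicted trait columns.
#' @export
predict.pr_rates <- function(object, ...) {
  L <- pr_tip_path_matrix(object$tree)
  P <- sweep(L %*% object$beta, 2, object$root, "+")
  dplyr::bind_cols(tibble::tibble(species = rownames(P)),
                   tibble::as_tibble(P, .name_repair = "minimal"))
}

#' @export
print.pr_rates <- function(x, ...) {
  cat("Phylogenetic ridge regression fit\n")
  cat(sprintf("  %d tips, %d branches, %d trait(s); lambda = %g\n",
              length(x$tree$tip.label), nrow(x$beta), ncol(x$beta), x$lambda))
  cat(sprintf("  branch rate magnitudes: median %.4g, max %.4g\n",
              stats::median(x$rates$rate), max(x$rates$rate)))
  invisible(x)
}

#' Tidy a ridge rate fit
#'
#' @param x A [pr_rates()] object.
#' @param ... Unused.
#' @return The per-branch rate table: branch id (child node), parent, branch
#'   length, node age, one `beta_*` column per trait and the scalar `rate`
#'   magnitude.
#' @importFrom generics tidy
#' @method tidy pr_rates
#' @export
tidy.pr_rates <- function(x, ...) x$rates

#' @importFrom generics glance
#' @method glance pr_rates
#' @export
glance.pr_rates <- function(x, ...) {
  obs <- x$traits
  pred <- as.matrix(predict(x)[, -1L])
  tibble::tibble(
    n_tips = nrow(obs), n_traits = ncol(obs), n_branches = nrow(x$beta),
    lambda = x$lambda,
    tip_cor = stats::cor(as.vector(obs), as.vector(pred)),
    mean_rate = mean(x$rates$rate))
}

#' Plot branch rate magnitudes against node age
#'
#' @param object A [pr_rates()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @method autoplot pr_rates
#' @export
autoplot.pr_rates <- function(object, ...) {
  d <- object$rates
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$rate,
                                  shape = .data$is_tip)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "node age (time units)",
                  y = "rate magnitude |β|",
                  shape = "pendant branch") +
    ggplot2::theme_minimal()
}
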