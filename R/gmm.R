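#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances between each landmark and the
#' configuration centroid: the size variable removed by Procrustes
#' superimposition and used as the allometry proxy.
#'
#' @param config k x 2 numeric matrix (k >= 3 landmarks).
#' @return Positive scalar; an error for degenerate (all-coincident)
#'   configurations.
#' @export
#' @examples
#' pr_centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
pr_centroid_size <- function(config) {
  config <- as.matrix(config)
  stopifnot(ncol(config) == 2, nrow(config) >= 3, !anyNA(config))
  cs <- sqrt(sum(scale(config, scale = FALSE)^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincide", call. = FALSE)
  cs
}

# long tibble (specimen, landmark, x, y, [species], [group]) -> k x 2 x n array
landmarks_to_array <- function(landmarks) {
  if (is.array(landmarks) && length(dim(landmarks)) == 3) return(landmarks)
  d <- tibble::as_tibble(landmarks)
  stopifnot(all(c("specimen", "landmark", "x", "y") %in% names(d)))
  specimens <- unique(d$specimen)
  ks <- table(d$specimen)
  if (length(unique(ks)) != 1)
    stop("all specimens must have the same landmark count", call. = FALSE)
  k <- unique(as.integer(ks))
  if (k < 3) stop("need at least 3 landmarks", call. = FALSE)
  A <- array(NA_real_, c(k, 2, length(specimens)),
             dimnames = list(NULL, c("x", "y"), specimens))
  for (s in specimens) {
    ds <- d[d$specimen == s, ]
    ds <- ds[order(ds$landmark), ]
    A[, , s] <- cbind(ds$x, ds$y)
  }
  if (anyNA(A)) stop("missing landmarks", call. = FALSE)
  meta <- dplyr::distinct(d, dplyr::across(dplyr::any_of(c("specimen", "species", "group"))))
  attr(A, "meta") <- meta
  A
}

# optimal proper rotation aligning X to G (both centered): X %*% R ~ G
procrustes_rotation <- function(X, G) {
  M <- crossprod(X, G)
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {               # keep it a rotation, not a reflection
    u <- sv$u; u[, 2] <- -u[, 2]
    R <- u %*% t(sv$v)
  }
  X %*% R
}

#' Generalized Procrustes superimposition
#'
#' Centers every configuration at the origin, scales it to unit centroid
#' size, and iteratively rotates all configurations to their running
#' consensus until the consensus changes by less than `tol` (Frobenius norm;
#' at the fixed point the consensus equals the arithmetic mean of the aligned
#' set). The aligned set is finally rotated as a block so the consensus sits
#' on its principal axes with a fixed sign convention, making the output
#' deterministic and order-invariant. Original centroid sizes are retained.
#'
#' @param landmarks A long tibble (`specimen`, `landmark`, `x`, `y`, and
#'   optionally `species`/`group`) as produced by [pr_simulate_landmarks()]
#'   or [pr_read_tps()], or a k x 2 x n array.
#' @param tol Convergence tolerance on the consensus.
#' @param max_iter Iteration cap (an error past it).
#' @return An object of class `pr_gpa`: aligned k x 2 x n array, consensus,
#'   named centroid-size vector, specimen metadata, iteration count.
#' @export
pr_gpa <- function(landmarks, tol = 1e-10, max_iter = 100) {
  A <- landmarks_to_array(landmarks)
  meta <- attr(A, "meta")
  k <- dim(A)[1]; n <- dim(A)[3]
  if (n < 2) stop("need at least 2 configurations", call. = FALSE)
  csize <- numeric(n)
  for (i in seq_len(n)) {
    X <- scale(A[, , i], scale = FALSE)
    csize[i] <- pr_centroid_size(A[, , i])
    A[, , i] <- X / csize[i]
  }
  names(csize) <- dimnames(A)[[3]]
  G <- A[, , 1]
  iter <- 0
  repeat {
    iter <- iter + 1
    for (i in seq_len(n)) A[, , i] <- procrustes_rotation(A[, , i], G)
    Gnew <- apply(A, c(1, 2), mean)
    if (sqrt(sum((Gnew - G)^2)) < tol) { G <- Gnew; break }
    G <- Gnew
    if (iter >= max_iter)
      stop("Procrustes superimposition did not converge in ", max_iter,
           " iterations", call. = FALSE)
  }
  # deterministic orientation: consensus principal axes, fixed signs
  ev <- eigen(stats::cov(G), symmetric = TRUE)$vectors
  if (det(ev) < 0) ev[, 2] <- -ev[, 2]
  Gr <- G %*% ev
  for (j in 1:2) if (Gr[which.max(abs(Gr[, j])), j] < 0) {
    ev[, j] <- -ev[, j]
  }
  if (det(ev) < 0) ev[, 2] <- -ev[, 2]
  G <- G %*% ev
  for (i in seq_len(n)) A[, , i] <- A[, , i] %*% ev
  structure(list(aligned = A, consensus = G, csize = csize, meta = meta,
                 iterations = iter),
            class = "pr_gpa")
}

#' @export
print.pr_gpa <- function(x, ...) {
  d <- dim(x$aligned)
  cat(sprintf("Procrustes-aligned landmark set: %d specimens x %d landmarks (converged in %d iterations)\n",
              d[3], d[1], x$iterations))
  invisible(x)
}

# flatten aligned configs to an n x 2k matrix (x coords then y coords)
flatten_configs <- function(A) {
  n <- dim(A)[3]
  t(vapply(seq_len(n), function(i) as.vector(A[, , i]), numeric(2 * dim(A)[1])))
}

#' Relative warps (principal axes of Procrustes shape variation)
#'
#' Projects the aligned configurations onto the tangent space at the
#' consensus (removing the residual centroid-size direction) and decomposes
#' their covariance into orthogonal axes of maximal variance -- the warp
#' weight exponent is 0, i.e. uniform and non-uniform shape components are
#' pooled and the analysis coincides with a principal component analysis of
#' the aligned coordinates. For k 2-D landmarks at most 2k - 4 axes carry
#' variance (2 centering, 1 scaling, 1 rotation constraint).
#'
#' With `by_species = TRUE`, species means of the aligned coordinates (from
#' the `species` metadata column) feed the ordination, giving one score row
#' per species as the rate machinery expects.
#'
#' @param gpa A [pr_gpa()] object.
#' @param by_species Average aligned coordinates per species before the
#'   decomposition?
#' @return An object of class `pr_rwa`: `scores` tibble (id column plus
#'   `RW1`, `RW2`, ...), `variance` tibble (`axis`, `var`, `prop`,
#'   `cum_prop`), number of nonzero axes, consensus, total Procrustes
#'   variance, and the mean log centroid size bookkeeping.
#' @export
pr_relative_warps <- function(gpa, by_species = FALSE) {
  stopifnot(inherits(gpa, "pr_gpa"))
  X <- flatten_configs(gpa$aligned)
  ids <- dimnames(gpa$aligned)[[3]]
  lncs <- log(gpa$csize)
  if (by_species) {
    if (is.null(gpa$meta) || !"species" %in% names(gpa$meta))
      stop("no species metadata on the aligned set", call. = FALSE)
    sp <- gpa$meta$species[match(ids, gpa$meta$specimen)]
    X <- rowsum(X, sp)
    X <- X / as.vector(table(sp)[rownames(X)])
    lncs <- tapply(lncs, sp, mean)[rownames(X)]
    ids <- rownames(X)
  }
  g <- as.vector(gpa$consensus)
  g <- g / sqrt(sum(g^2))
  Xt <- X - (X %*% g) %*% t(g)      # tangent-space projection at the consensus
  pca <- stats::prcomp(Xt, center = TRUE)
  vars <- pca$sdev^2
  nz <- sum(vars > max(vars) * 1e-10)
  scores <- pca$x
  colnames(scores) <- paste0("RW", seq_len(ncol(scores)))
  id_col <- if (by_species) "species" else "specimen"
  sc <- dplyr::bind_cols(tibble::tibble(!!id_col := ids),
                         tibble::as_tibble(scores))
  structure(list(
    scores = sc, id = id_col,
    variance = tibble::tibble(axis = paste0("RW", seq_along(vars)),
                              var = vars, prop = vars / sum(vars),
                              cum_prop = cumsum(vars) / sum(vars)),
    n_axes = nz, consensus = gpa$consensus, total_variance = sum(vars),
    lncs = stats::setNames(as.numeric(lncs), ids)),
    class = "pr_rwa")
}

#' @export
print.pr_rwa <- function(x, ...) {
  cat(sprintf("Relative warps: %d rows, %d axes with nonzero variance\n",
              nrow(x$scores), x$n_axes))
  print(utils::head(x$variance, 4))
  invisible(x)
}

#' @method tidy pr_rwa
#' @export
tidy.pr_rwa <- function(x, ...) x$scores

#' @method glance pr_rwa
#' @export
glance.pr_rwa <- function(x, ...) {
  tibble::tibble(n_rows = nrow(x$scores), n_axes = x$n_axes,
                 total_variance = x$total_variance,
                 prop_first4 = sum(x$variance$prop[1:min(4, nrow(x$variance))]))
}

#' Leading shape axes reaching a cumulative-variance target
#'
#' The trait block the rate machinery consumes by default: the smallest set
#' of leading axes whose cumulative variance fraction reaches `target`
#' (default 90%).
#'
#' @param rwa A [pr_relative_warps()] object.
#' @param target Cumulative variance fraction in (0, 1\].
#' @return Tibble: id column plus the selected `RW*` columns.
#' @export
pr_leading_axes <- function(rwa, target = 0.9) {
  stopifnot(inherits(rwa, "pr_rwa"), target > 0, target <= 1)
  n <- which(rwa$variance$cum_prop >= target - 1e-12)[1]
  rwa$scores[, c(1L, 1L + seq_len(n)), drop = FALSE]
}

#' Remove the allometric (size) component from shape scores
#'
#' Regresses each shape axis on log centroid size by ordinary least squares
#' and returns the residual scores; the per-axis slopes and R-squared values
#' are attached so the strength of allometry is visible. An external size
#' measure (e.g. ln body mass) can be supplied instead of the stored log
#' centroid sizes.
#'
#' @param rwa A [pr_relative_warps()] object.
#' @param sizes Optional named numeric vector of sizes (log scale) matching
#'   the score rows; defaults to the log centroid sizes carried by `rwa`.
#' @return A `pr_rwa` object with residual scores; component `allometry`
#'   holds the per-axis regression table.
#' @export
pr_size_correct <- function(rwa, sizes = NULL) {
  stopifnot(inherits(rwa, "pr_rwa"))
  ids <- rwa$scores[[1L]]
  s <- if (is.null(sizes)) rwa$lncs[ids] else sizes[ids]
  if (anyNA(s)) stop("sizes missing for some rows", call. = FALSE)
  if (stats::var(s) == 0) stop("zero variance in sizes", call. = FALSE)
  S <- as.matrix(rwa$scores[, -1L, drop = FALSE])
  sc <- s - mean(s)
  slopes <- drop(crossprod(sc, scale(S, scale = FALSE))) / sum(sc^2)
  fitted <- outer(sc, slopes) + matrix(colMeans(S), nrow(S), ncol(S), byrow = TRUE)
  resid <- S - fitted
  r2 <- 1 - colSums(resid^2) / colSums(scale(S, scale = FALSE)^2)
  out <- rwa
  out$scores <- dplyr::bind_cols(rwa$scores[, 1L],
                                 tibble::as_tibble(resid))
  out$allometry <- tibble::tibble(axis = colnames(S), slope = slopes,
                                  r_squared = ifelse(is.nan(r2), 0, r2))
  out
}

#' Regression of log centroid size on an external log size measure
#'
#' The sanity check that centroid size works as a body-size proxy: ordinary
#' least squares of `lncs` on `ln_size` with slope, R-squared and p-value.
#'
#' @param lncs Named numeric vector of log centroid sizes.
#' @param ln_size Named numeric vector of the external log size (e.g. ln body
#'   mass), matched by name.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
pr_size_regression <- function(lncs, ln_size) {
  common <- intersect(names(lncs), names(ln_size))
  if (length(common) < 3) stop("need >= 3 matched names", call. = FALSE)
  fit <- stats::lm(lncs[common] ~ ln_size[common])
  sm <- summary(fit)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(common))
}

#' Average rows per species
#'
#' Arithmetic mean of numeric columns per species; single-specimen species
#' pass through unchanged. Errors if any row is unmapped.
#'
#' @param scores Tibble whose first column identifies specimens, remaining
#'   columns numeric.
#' @param species Named character vector (names = specimens) or a data frame
#'   with `specimen` and `species` columns.
#' @return Tibble: `species` plus per-species means.
#' @export
pr_species_means <- function(scores, species) {
  d <- tibble::as_tibble(scores)
  if (is.data.frame(species))
    species <- stats::setNames(as.character(species$species),
                               as.character(species$specimen))
  ids <- as.character(d[[1L]])
  sp <- species[ids]
  if (anyNA(sp))
    stop("unmapped specimens: ",
         paste(utils::head(ids[is.na(sp)], 5), collapse = ", "), call. = FALSE)
  d$..species <- unname(sp)
  d |>
    dplyr::group_by(.data$..species) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     .groups = "drop") |>
    dplyr::rename(species = "..species")
}

#' Plot the first two relative warps
#'
#' @param object A [pr_relative_warps()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pr_rwa
#' @export
autoplot.pr_rwa <- function(object, ...) {
  d <- object$scores
  v <- object$variance$prop
  ggplot2::ggplot(d, ggplot2::aes(x = .data$RW1, y = .data$RW2)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = sprintf("RW1 (%.1f%%)", 100 * v[1]),
                  y = sprintf("RW2 (%.1f%%)", 100 * v[2])) +
    ggplot2::theme_minimal()
}
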