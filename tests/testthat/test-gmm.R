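test_that("centroid size follows its definition and similarity invariances", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(pr_centroid_size(square), sqrt(2))
  expect_equal(pr_centroid_size(square * 3.5), 3.5 * sqrt(2))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- square %*% R + matrix(c(5, -2), 4, 2, byrow = TRUE)
  expect_equal(pr_centroid_size(moved), sqrt(2), tolerance = 1e-12)
  expect_error(pr_centroid_size(matrix(1, 4, 2)), "degenerate")
})

test_that("superimposition removes similarity transforms exactly", {
  lm0 <- pr_simulate_landmarks(n_species = 8, n_specimens = 1, noise_sd = 0,
                               seed = 61)
  g <- pr_gpa(lm0)
  X <- phyloridge:::flatten_configs(g$aligned)
  expect_lt(sum(scale(X, scale = FALSE)^2) / nrow(X), 1e-15)

  # consensus is the arithmetic mean of the aligned set at convergence
  lm <- pr_simulate_landmarks(n_species = 10, n_specimens = 2, seed = 62)
  g2 <- pr_gpa(lm)
  expect_equal(g2$consensus, apply(g2$aligned, c(1, 2), mean), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(abs(apply(g2$aligned, 3, function(m) sum(scale(m, scale = FALSE)^2)) - 1) < 1e-9))
})

test_that("two-configuration alignment matches the closed-form Procrustes fit", {
  withr::with_seed(63, {
    for (i in 1:5) {
      X <- matrix(stats::rnorm(12), 6, 2)
      Y <- matrix(stats::rnorm(12), 6, 2)
      A <- array(c(X, Y), c(6, 2, 2), dimnames = list(NULL, NULL, c("s1", "s2")))
      g <- pr_gpa(A)
      d_gpa <- sqrt(sum((g$aligned[, , 1] - g$aligned[, , 2])^2))
      # oracle: optimal-rotation distance between unit-size centered configs
      Xc <- scale(X, scale = FALSE); Xc <- Xc / sqrt(sum(Xc^2))
      Yc <- scale(Y, scale = FALSE); Yc <- Yc / sqrt(sum(Yc^2))
      M <- crossprod(Xc, Yc)
      sv <- svd(M)
      tr_sig <- sum(sv$d[1]) + sign(det(M)) * sv$d[2]
      d_opa <- sqrt(max(0, 2 - 2 * tr_sig))
      expect_equal(d_gpa, d_opa, tolerance = 1e-9)
    }
  })
})

test_that("alignment is invariant to specimen order", {
  lm <- pr_simulate_landmarks(n_species = 8, n_specimens = 2, seed = 64)
  g1 <- pr_gpa(lm)
  ids <- rev(unique(lm$specimen))
  lm2 <- dplyr::arrange(lm, match(specimen, ids), landmark)
  g2 <- pr_gpa(lm2)
  expect_equal(g1$consensus, g2$consensus, tolerance = 1e-9)
})

test_that("relative warps span exactly 2k - 4 axes with coherent variances", {
  lm <- pr_simulate_landmarks(n_species = 12, n_specimens = 2, seed = 65)
  rwa <- pr_relative_warps(pr_gpa(lm))
  expect_equal(rwa$n_axes, 14)           # 9 landmarks: 2 * 9 - 4
  expect_equal(sum(rwa$variance$prop), 1, tolerance = 1e-12)
  expect_true(all(diff(rwa$variance$var) <= 1e-15))
  expect_equal(sum(rwa$variance$var), rwa$total_variance, tolerance = 1e-12)

  # scores match an independent eigen-decomposition up to axis sign
  X <- phyloridge:::flatten_configs(pr_gpa(lm)$aligned)
  g <- as.vector(pr_gpa(lm)$consensus); g <- g / sqrt(sum(g^2))
  Xt <- X - (X %*% g) %*% t(g)
  Xc <- scale(Xt, scale = FALSE)
  eig <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
  sc_oracle <- Xc %*% eig$vectors
  S <- as.matrix(rwa$scores[, -1])
  for (j in 1:14) {
    expect_lt(min(max(abs(S[, j] - sc_oracle[, j])),
                  max(abs(S[, j] + sc_oracle[, j]))), 1e-8)
  }

  # score columns are mutually uncorrelated
  cv <- crossprod(scale(S[, 1:14], scale = FALSE)) / (nrow(S) - 1)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
})

test_that("size correction behaves as a per-axis regression residual", {
  lm <- pr_simulate_landmarks(n_species = 15, n_specimens = 2, seed = 66)
  rwa <- pr_relative_warps(pr_gpa(lm))
  ids <- rwa$scores[[1]]
  n <- length(ids)

  # scores exactly linear in size: residuals vanish
  rw_lin <- rwa
  s <- rwa$lncs[ids]
  lin <- outer(s - mean(s), c(2, -1, 0.5)) + matrix(1, n, 3)
  colnames(lin) <- paste0("RW", 1:3)
  rw_lin$scores <- dplyr::bind_cols(rwa$scores[, 1], tibble::as_tibble(lin))
  out <- pr_size_correct(rw_lin)
  expect_lt(max(abs(as.matrix(out$scores[, -1]))), 1e-10)
  expect_equal(unname(out$allometry$r_squared), rep(1, 3), tolerance = 1e-8)

  # scores orthogonal to size: residuals equal the centered inputs
  v <- s - mean(s)
  orth <- cbind(RW1 = withr::with_seed(5, stats::resid(stats::lm(stats::rnorm(n) ~ v))))
  rw_orth <- rwa
  rw_orth$scores <- dplyr::bind_cols(rwa$scores[, 1], tibble::as_tibble(orth))
  out2 <- pr_size_correct(rw_orth)
  expect_equal(as.matrix(out2$scores[, -1]), unname(orth - mean(orth)),
               tolerance = 1e-10, ignore_attr = TRUE)

  # random scores: two-pass least-squares oracle
  out3 <- pr_size_correct(rwa)
  S <- as.matrix(rwa$scores[, -1])
  res_oracle <- apply(S, 2, function(col) stats::resid(stats::lm(col ~ s)))
  expect_equal(unname(as.matrix(out3$scores[, -1])), unname(res_oracle),
               tolerance = 1e-10)
  bad <- rwa; bad$lncs[] <- 1
  expect_error(pr_size_correct(bad), "zero variance")
})

test_that("external size regression recovers a known allometric slope", {
  withr::with_seed(67, {
    mass <- stats::rnorm(30, 8, 2)
    lncs <- 0.3 * mass + stats::rnorm(30, 0, 0.1)
    names(mass) <- names(lncs) <- sprintf("sp%02d", 1:30)
    fit <- pr_size_regression(lncs, mass)
    expect_equal(fit$slope, 0.3, tolerance = 0.05)
    expect_gt(fit$r_squared, 0.9)
    expect_lt(fit$p_value, 0.001)
  })
})

test_that("species averaging matches a group-by oracle", {
  sc <- tibble::tibble(specimen = c("a1", "a2", "b1"),
                       RW1 = c(1, 3, 5), RW2 = c(0, 2, -2))
  map <- c(a1 = "A", a2 = "A", b1 = "B")
  out <- pr_species_means(sc, map)
  expect_equal(out$RW1[out$species == "A"], 2)
  expect_equal(out$RW1[out$species == "B"], 5)    # singletons pass through
  expect_equal(out$RW2[out$species == "A"], 1)

  sc2 <- tibble::tibble(specimen = c("x", "y"), RW1 = c(4, 4))
  expect_equal(pr_species_means(sc2, c(x = "S", y = "S"))$RW1, 4)
  expect_error(pr_species_means(sc, map[-1]), "unmapped")

  lm <- pr_simulate_landmarks(n_species = 6, n_specimens = 3, seed = 68)
  rwa <- pr_relative_warps(pr_gpa(lm))
  map2 <- stats::setNames(sub("_[0-9]+$", "", rwa$scores$specimen),
                          rwa$scores$specimen)
  out2 <- pr_species_means(rwa$scores, map2)
  oracle <- stats::aggregate(rwa$scores[, -1], by = list(unname(map2)), FUN = mean)
  expect_equal(out2$RW1, oracle$RW1[match(out2$species, oracle$Group.1)],
               tolerance = 1e-12)
})

test_that("a two-group shape difference loads on the first relative warp", {
  lm <- pr_simulate_landmarks(n_species = 20, n_specimens = 3,
                              group_shift = pr_default_group_shift(), seed = 69)
  rwa <- pr_relative_warps(pr_gpa(lm), by_species = TRUE)
  sc <- tidy(rwa)
  grp <- unique(lm[, c("species", "group")])
  m <- dplyr::inner_join(sc, grp, by = "species")
  r <- abs(stats::cor(m$RW1, as.numeric(m$group == "B")))
  expect_gt(r, 0.9)
})
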