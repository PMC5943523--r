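test_that("clade Brownian rate matches the closed-form cherry and scales with time", {
  tr <- cherry()
  y <- tibble::tibble(species = c("A", "B"), z = c(0, 2))
  # GLS mean 1, z = (-1, 1), C = diag(1, 1): sigma2 = 2 / 2 = 1
  expect_equal(as.numeric(pr_clade_rate(tr, y, "N3")), 1)

  expect_warning(
    s0 <- pr_clade_rate(tr, tibble::tibble(species = c("A", "B"), z = c(2, 2)), "N3"),
    "degenerate")
  expect_equal(as.numeric(s0), 0)

  rc <- random_case(8, n_tips = 12)
  node <- node_with_clade_size(rc$tree, 6)
  s1 <- as.numeric(pr_clade_rate(rc$tree, rc$traits, node))
  scaled <- rc$tree
  scaled$edge.length <- scaled$edge.length * 4
  expect_equal(as.numeric(pr_clade_rate(scaled, rc$traits, node)), s1 / 4,
               tolerance = 1e-10)

  expect_error(pr_clade_rate(rc$tree, rc$traits, rc$tree$tip.label[1]), "2 tips")
})

test_that("clade rate equals a generic numerical ML optimizer", {
  # independent route: optimize the dense multivariate-normal likelihood in
  # (mu, sigma2) directly
  for (seed in 1:10) {
    rc <- random_case(seed, n_tips = 10, n_traits = 1)
    node <- node_with_clade_size(rc$tree, 6)
    sub <- ape::extract.clade(rc$tree, node)
    y <- pr_trait_matrix(rc$tree, rc$traits)[sub$tip.label, 1]
    C <- ape::vcv.phylo(sub)[names(y), names(y)]
    nll <- function(par) {
      -sum(mvtnorm_log <- {
        S <- exp(par[2]) * C
        -0.5 * (length(y) * log(2 * pi) + as.numeric(determinant(S)$modulus) +
                  t(y - par[1]) %*% solve(S) %*% (y - par[1]))
      })
    }
    opt <- stats::optim(c(mean(y), 0), nll, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    expect_equal(as.numeric(pr_clade_rate(rc$tree, rc$traits[, 1:2], node)),
                 exp(opt$par[2]), tolerance = 1e-5)
  }
})

test_that("candidate ranking finds the fast-rate region and respects min size", {
  tr <- pr_simulate_tree(100, seed = 41)
  node <- node_with_clade_size(tr, 20)
  desc <- phyloridge:::descendant_nodes(tr, node)
  hits <- sum(vapply(1:10, function(r) {
    y <- pr_simulate_traits(tr, n_traits = 2, shift_node = node,
                            shift_multiplier = 10, seed = 4000 + r)
    top <- pr_rank_clades(tr, y, min_size = 5)$node_id[1]
    top %in% desc || pr_node_distance(tr, top, node) <= 1
  }, logical(1)))
  expect_gte(hits, 9)

  y <- pr_simulate_traits(tr, n_traits = 2, seed = 1)
  expect_error(pr_rank_clades(tr, y, min_size = 101), "min_size")
  rk <- pr_rank_clades(tr, y, min_size = 5)
  expect_true(all(diff(rk$sigma2) <= 0))
  expect_true(all(rk$n_tips >= 5))
  expect_false(paste0("N", 101) %in% rk$node)   # the root is not a candidate
})

test_that("under uniform Brownian motion no clade is a stable top candidate", {
  tr <- pr_simulate_tree(50, seed = 42)
  tops <- vapply(1:25, function(r) {
    y <- pr_simulate_traits(tr, n_traits = 2, seed = 7000 + r)
    pr_rank_clades(tr, y, min_size = 5)$node[1]
  }, character(1))
  expect_gt(length(unique(tops)), 3)
  expect_lt(max(table(tops)) / length(tops), 0.5)
})

test_that("model enumeration yields every subset of the candidates", {
  expect_length(pr_shift_models(c("N11", "N15", "N20")), 8)
  expect_length(pr_shift_models(character(0)), 1)
  expect_length(pr_shift_models("N11"), 2)

  # regimes partition the branches for every model, nesting included
  tr <- pr_simulate_tree(30, seed = 43)
  outer_node <- node_with_clade_size(tr, 12)
  inner <- phyloridge:::descendant_nodes(tr, outer_node)
  inner_node <- inner[inner > length(tr$tip.label)][1]
  for (m in pr_shift_models(c(outer_node, inner_node))) {
    reg <- phyloridge:::regime_assignment(tr, m)
    expect_length(reg, nrow(tr$edge))
    expect_equal(sort(unique(reg)),
                 sort(c("bg", phyloridge:::node_names(tr)[m])))
  }
  # nearest enclosing shift node wins for nested shifts
  reg <- phyloridge:::regime_assignment(tr, c(outer_node, inner_node))
  inner_edges <- tr$edge[, 2] %in% c(inner_node,
                                     phyloridge:::descendant_nodes(tr, inner_node))
  expect_true(all(reg[inner_edges] == phyloridge:::node_names(tr)[inner_node]))
})

test_that("multi-rate REML reduces to closed-form single-rate Brownian REML", {
  for (seed in 1:8) {
    rc <- random_case(seed, n_tips = 12, n_traits = 1)
    fit <- pr_fit_multirate(rc$tree, rc$traits, character(0))
    y <- stats::setNames(pr_trait_matrix(rc$tree, rc$traits)[, 1],
                         rc$tree$tip.label)
    expect_equal(fit$logLik, bm_reml_oracle(rc$tree, y), tolerance = 1e-6)
  }
})

test_that("multi-rate REML agrees with an independent comparative implementation", {
  library(phytools)
  tr <- pr_simulate_tree(30, depth = 10, seed = 2)
  node <- node_with_clade_size(tr, 10)
  y <- pr_simulate_traits(tr, n_traits = 1, shift_node = node,
                          shift_multiplier = 8, seed = 3)
  fit <- pr_fit_multirate(tr, y, node)
  yv <- stats::setNames(pr_trait_matrix(tr, y)[, 1], tr$tip.label)
  painted <- phytools::paintSubTree(tr, node = node, state = "2", stem = TRUE)
  ref <- phytools::brownieREML(painted, yv)
  expect_equal(fit$logLik, ref$logL.multiple, tolerance = 1e-5)
  expect_equal(sort(fit$regimes$sigma2), sort(unname(ref$sig2.multiple)),
               tolerance = 1e-4)
})

test_that("shift models recover a simulated rate ratio and never lose likelihood", {
  tr <- pr_simulate_tree(100, seed = 44)
  node <- node_with_clade_size(tr, 20)
  ratios <- vapply(1:10, function(r) {
    y <- pr_simulate_traits(tr, n_traits = 2, shift_node = node,
                            shift_multiplier = 10, seed = 5000 + r)
    fit <- pr_fit_multirate(tr, y, node)
    fit$regimes$multiplier[fit$regimes$regime != "bg"]
  }, numeric(1))
  expect_gte(sum(ratios >= 5 & ratios <= 20), 8)

  # likelihood monotonicity under nesting
  y <- pr_simulate_traits(tr, n_traits = 2, shift_node = node,
                          shift_multiplier = 10, seed = 5999)
  second <- node_with_clade_size(tr, 8)
  ll_bm <- pr_fit_multirate(tr, y, character(0))$logLik
  ll_1 <- pr_fit_multirate(tr, y, node)$logLik
  ll_2 <- pr_fit_multirate(tr, y, unique(c(node, second)))$logLik
  expect_gte(ll_1, ll_bm - 1e-8)
  expect_gte(ll_2, ll_1 - 1e-8)

  yc <- y; yc[, -1] <- 1
  expect_error(pr_fit_multirate(tr, yc, node), "degenerate")
})

test_that("model comparison prefers simplicity at equal fit and flags mismatched data", {
  mk_fit <- function(shifts, ll, k, digest) {
    structure(list(shift_nodes = shifts, logLik = ll, n_regimes = k,
                   regimes = tibble::tibble(), trait_cov = NULL,
                   converged = TRUE, n_tips = 10, n_traits = 1,
                   data_digest = digest), class = "pr_bm_fit")
  }
  cmp <- pr_compare_models(list(mk_fit(character(0), -50, 1, 1),
                                mk_fit("N12", -50, 2, 1)))
  expect_length(cmp$best$shift_nodes, 0)

  cmp2 <- pr_compare_models(list(mk_fit(character(0), -80, 1, 1),
                                 mk_fit("N12", -50, 2, 1)))
  expect_equal(cmp2$best$shift_nodes, "N12")

  expect_error(pr_compare_models(list(mk_fit(character(0), -50, 1, 1),
                                      mk_fit("N12", -50, 2, 99))),
               "different data")
  expect_error(pr_compare_models(list(mk_fit("N12", -50, 2, 1),
                                      mk_fit("N13", -49, 2, 1))),
               "Brownian model")
})

test_that("candidate clustering separates distant groups and is reproducible", {
  # two clades 40 time units apart; candidates split between them
  tr <- pr_read_tree(paste0(
    "(((a1:1,a2:1):1,(a3:1,a4:1):1):40,((b1:1,b2:1):1,(b3:1,b4:1):1):40);"))
  nn <- phyloridge:::node_names(tr)
  cand_ids <- (length(tr$tip.label) + 2):(length(tr$tip.label) + tr$Nnode)
  ranking <- tibble::tibble(node = nn[cand_ids], sigma2 = seq_along(cand_ids))
  cl <- pr_cluster_candidates(tr, ranking, n_boot = 50, seed = 5)
  expect_equal(cl$k, 2)
  side <- function(node) {
    tips <- tr$tip.label[phyloridge:::clade_tips(tr, node)]
    all(startsWith(tips, "a")) || all(startsWith(tips, "b"))
  }
  expect_true(all(vapply(cl$groups$node, side, logical(1))))
  grp_a <- cl$groups$group[vapply(cl$groups$node, function(nd)
    all(startsWith(tr$tip.label[phyloridge:::clade_tips(tr, nd)], "a")), logical(1))]
  expect_length(unique(grp_a), 1)

  cl2 <- pr_cluster_candidates(tr, ranking, n_boot = 50, seed = 5)
  expect_identical(cl$groups, cl2$groups)

  # near-coincident candidates collapse to the minimum group count
  tr2 <- pr_simulate_tree(20, seed = 6)
  rk2 <- pr_rank_clades(tr2, pr_simulate_traits(tr2, seed = 7), min_size = 3)
  tiny <- tr2
  cl3 <- pr_cluster_candidates(tiny, rk2[1:4, ], n_boot = 20, seed = 8)
  expect_gte(cl3$k, 2)
  expect_error(pr_cluster_candidates(tr, ranking[1, ]), "nrow")
})

test_that("the full scan selects a shift near the truth under a strong signal", {
  tr <- pr_simulate_tree(100, seed = 45)
  node <- node_with_clade_size(tr, 20)
  y <- pr_simulate_traits(tr, n_traits = 4, shift_node = node,
                          shift_multiplier = 10, seed = 46)
  scan <- pr_shift_scan(tr, y, min_size = 5, top_n = 3)
  expect_length(scan$fits, 8)
  sel <- scan$best$shift_nodes
  expect_gt(length(sel), 0)
  d <- min(vapply(sel, function(s) pr_node_distance(tr, s, node), numeric(1)))
  expect_lte(d, 1)
  expect_true(all(c("aic", "p_vs_bm") %in% names(tidy(scan))))

  # clustering mode picks the candidate count from the tree geometry
  tr2 <- pr_simulate_tree(40, seed = 47)
  node2 <- node_with_clade_size(tr2, 10)
  y2 <- pr_simulate_traits(tr2, n_traits = 2, shift_node = node2,
                           shift_multiplier = 10, seed = 48)
  scan2 <- pr_shift_scan(tr2, y2, min_size = 5, cluster = TRUE, n_boot = 20,
                         seed = 49)
  expect_equal(length(scan2$fits), 2^length(scan2$candidates))
  expect_s3_class(glance(scan2), "tbl_df")
})

test_that("result objects render as ggplots", {
  rc <- random_case(91, n_tips = 15, n_traits = 2)
  fit <- pr_rates(rc$tree, rc$traits, lambda = 1)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  scan <- pr_shift_scan(rc$tree, rc$traits, min_size = 4, top_n = 2)
  expect_s3_class(ggplot2::autoplot(scan), "ggplot")
})
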