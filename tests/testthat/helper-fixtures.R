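# Shared fixtures: everything is generated in code, nothing read from disk.

tree3 <- function() pr_read_tree("((A:1,B:1):0.5,C:1.5);")

cherry <- function(l = 1) pr_read_tree(sprintf("(A:%g,B:%g);", l, l))

# a random tree + BM traits, for parameterised oracle tests
random_case <- function(seed, n_tips = 10, n_traits = 2, depth = 10) {
  tr <- pr_simulate_tree(n_tips, depth = depth, fossil_fraction = 0.2, seed = seed)
  list(tree = tr,
       traits = pr_simulate_traits(tr, n_traits = n_traits, seed = seed + 500))
}

# pick an internal node whose clade size is closest to `target` tips
node_with_clade_size <- function(tree, target) {
  inner <- (length(tree$tip.label) + 2):(length(tree$tip.label) + tree$Nnode)
  sizes <- vapply(inner, function(v)
    length(phyloridge:::clade_tips(tree, v)), integer(1))
  inner[which.min(abs(sizes - target))]
}

# dense GLS mean, computed by plain solve() -- the independent route
gls_mean_oracle <- function(C, Y) {
  Ci <- solve(C)
  ones <- rep(1, nrow(C))
  drop(t(ones) %*% Ci %*% Y) / drop(t(ones) %*% Ci %*% ones)
}

# closed-form single-rate Brownian REML log-likelihood (dense solve route)
bm_reml_oracle <- function(tree, y) {
  C <- ape::vcv.phylo(tree)[names(y), names(y)]
  n <- length(y)
  Ci <- solve(C)
  mu <- sum(Ci %*% y) / sum(Ci)
  z <- y - mu
  s2 <- drop(t(z) %*% Ci %*% z) / (n - 1)
  -0.5 * ((n - 1) * log(2 * pi) + (n - 1) * log(s2) +
            as.numeric(determinant(C)$modulus) + log(sum(Ci)) + (n - 1))
}
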