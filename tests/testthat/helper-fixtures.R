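# Shared fixture builders for the test suite. Everything is generated in
# code from fixed seeds; no data files.

# two-species shape data with given slope vectors, sizes uniform on (0, 2)
make_two_species <- function(slope_a, slope_b, n = 30L, noise_sd = 0.1,
                             intercept_b = NULL, seed = 1L,
                             range_b = c(0, 2)) {
  set.seed(seed)
  q <- length(slope_a)
  if (is.null(intercept_b)) intercept_b <- rep(0, q)
  sa <- runif(n, 0, 2)
  sb <- runif(n, range_b[1], range_b[2])
  Ya <- sa %*% t(slope_a) + matrix(rnorm(n * q, sd = noise_sd), n, q)
  Yb <- rep(1, n) %*% t(intercept_b) + sb %*% t(slope_b) +
    matrix(rnorm(n * q, sd = noise_sd), n, q)
  shape_data(rbind(Ya, Yb), c(sa, sb), rep(c("a", "b"), each = n))
}

# Brownian tip data on a tree (optionally multivariate)
sim_bm_tips <- function(tree, q = 1L, sigma2 = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  ch <- chol(sigma2 * ape::vcv(tree))
  X <- t(ch) %*% matrix(rnorm(n * q), n, q)
  rownames(X) <- tree$tip.label
  if (q == 1L) setNames(drop(X), tree$tip.label) else X
}

# ultrametric test tree of a given size
test_tree <- function(n, seed = 1L) {
  set.seed(seed)
  ape::rphylo(n, birth = 1, death = 0)
}

# small aligned landmark block: semicircle of landmarks with noise
make_curve_block <- function(n_spec = 4L, k = 7L, noise_sd = 0.02,
                             seed = 3L, sliders = NULL) {
  set.seed(seed)
  th <- seq(0, pi, length.out = k)
  template <- cbind(cos(th), sin(th))
  A <- array(0, c(n_spec, k, 2))
  for (i in seq_len(n_spec))
    A[i, , ] <- template + matrix(rnorm(2 * k, sd = noise_sd), k, 2)
  landmark_block(A, sliders = sliders)
}
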