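# Heterochrony battery: peramorphosis test, Tfh1/Tfh2, pair classification.

test_that("peramorphosis test detects adult-shape divergence on shared lines", {
  # duplicated species under two labels: distance ~ 0, p ~ 1
  set.seed(31)
  n <- 30
  s <- runif(n, 0, 2)
  Y <- s %*% t(c(1, 0, 0)) + matrix(rnorm(3 * n, sd = 0.05), n, 3)
  d_id <- shape_data(rbind(Y, Y), c(s, s), rep(c("a", "b"), each = n))
  r_id <- peramorphosis_test(d_id, c("a", "b"), n_perm = 199, seed = 1)
  expect_lt(r_id$adult_distance, 0.1)
  expect_gt(r_id$p, 0.5)

  # truncation at 60% of the size range: significant adult difference in
  # the vast majority of replicates
  hits <- vapply(1:20, function(i) {
    d <- make_two_species(c(1, 0, 0), c(1, 0, 0), n = 30, noise_sd = 0.05,
                          range_b = c(0, 1.2), seed = 300 + i)
    peramorphosis_test(d, c("a", "b"), n_perm = 199, seed = i)$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  expect_error(peramorphosis_test(d_id, c("a", "b"),
                                  gate_p = c(slope = 0.01)), "precondition")
  # BH adjustment across tested pairs
  out <- peramorphosis_tests(d_id, list(c("a", "b")), n_perm = 99, seed = 2)
  expect_true(all(out$p_adjusted >= out$p))
})

test_that("Tfh1 pooled residual SS matches a normal-equations oracle", {
  set.seed(32)
  d <- make_two_species(c(1, 0.5), c(0.8, 0.2), n = 20, noise_sd = 0.2)
  t1 <- tfh1(d, c("a", "b"), n_perm = 49, seed = 1)
  X <- cbind(1, d$size)
  B <- solve(crossprod(X), crossprod(X, d$Y))
  ss_oracle <- sum((d$Y - X %*% B)^2)
  expect_lt(abs(t1$ss_resid - ss_oracle), 1e-9)
  expect_gte(t1$ss_excess, -1e-9)
})

test_that("Tfh1 supports scaling on shared lines and rejects offset lines", {
  # same line, different size ranges: ontogenetic scaling retained
  set.seed(33)
  p_scaling <- vapply(1:15, function(i) {
    d <- make_two_species(c(1, 0, 0), c(1, 0, 0), n = 25, noise_sd = 0.05,
                          range_b = c(0, 1), seed = 400 + i)
    tfh1(d, c("a", "b"), n_perm = 199, seed = i)$p
  }, 0)
  expect_gt(mean(p_scaling >= 0.05), 0.8)

  # parallel offset lines: rejected in nearly all replicates
  p_offset <- vapply(1:15, function(i) {
    d <- make_two_species(c(1, 0, 0), c(1, 0, 0), n = 25, noise_sd = 0.05,
                          intercept_b = c(0, 0.5, 0), seed = 500 + i)
    tfh1(d, c("a", "b"), n_perm = 199, seed = i)$p
  }, 0)
  expect_gt(mean(p_offset < 0.05), 0.95)

  expect_error(tfh1(shape_data(matrix(1:4, 2), c(1, 1), c("a", "b")),
                    c("a", "b")), "singular")
})

test_that("Tfh1 rejection rate is near alpha when one species is split", {
  set.seed(34)
  ps <- vapply(1:100, function(i) {
    n <- 30
    s <- runif(n, 0, 2)
    Y <- s %*% t(c(1, 0.3)) + matrix(rnorm(2 * n, sd = 0.1), n, 2)
    d <- shape_data(Y, s, sample(rep(c("a", "b"), n / 2)))
    tfh1(d, c("a", "b"), n_perm = 99, seed = i)$p
  }, 0)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.06)
})

test_that("Tfh2 measures perpendicular scatter about the shape-space line", {
  # specimens exactly on the line: SS_perp = 0
  s <- seq(0, 2, length.out = 20)
  Y <- s %*% t(c(1, 1, 0))
  d <- shape_data(Y[, , drop = FALSE], s, rep(c("a", "b"), each = 10))
  t2 <- tfh2(d, c("a", "b"), n_perm = 19, seed = 1)
  expect_lt(t2$ss_perp, 1e-18)

  # rigid rotation of shape space leaves the statistic unchanged
  set.seed(35)
  dd <- make_two_species(c(1, 0.5, 0), c(1, 0.5, 0), n = 20, noise_sd = 0.1)
  t_a <- tfh2(dd, c("a", "b"), n_perm = 9, seed = 1)
  th <- 0.7
  R <- diag(3)
  R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  dr <- shape_data(dd$Y %*% R, dd$size, dd$species)
  t_b <- tfh2(dr, c("a", "b"), n_perm = 9, seed = 1)
  expect_lt(abs(t_a$ss_perp - t_b$ss_perp), 1e-9)

  # zero slope: degenerate line
  d0 <- shape_data(matrix(5, 20, 2), seq(0, 2, length.out = 20),
                   rep(c("a", "b"), 10))
  expect_error(tfh2(d0, c("a", "b")), "degenerate")
})

test_that("Tfh2 supports dissociation on one shape line, rejects two lines", {
  # shape ranges overlap but sizes are shifted: dissociation retained
  set.seed(36)
  p_diss <- vapply(1:15, function(i) {
    set.seed(600 + i)
    n <- 25
    sa <- runif(n, 0, 1.5)
    sb <- runif(n, 0.8, 2.3)
    v <- c(1, 0, 0)
    Ya <- sa %*% t(v) + matrix(rnorm(3 * n, sd = 0.05), n, 3)
    Yb <- rep(1, n) %*% t(-0.8 * v) + sb %*% t(v) +
      matrix(rnorm(3 * n, sd = 0.05), n, 3)
    d <- shape_data(rbind(Ya, Yb), c(sa, sb), rep(c("a", "b"), each = n))
    tfh2(d, c("a", "b"), n_perm = 199, seed = i)$p
  }, 0)
  expect_gt(mean(p_diss >= 0.05), 0.8)

  # two parallel shape-space lines 5 SD apart: rejected
  p_two <- vapply(1:15, function(i) {
    d <- make_two_species(c(1, 0, 0), c(1, 0, 0), n = 25, noise_sd = 0.1,
                          intercept_b = c(0, 0.5, 0), seed = 700 + i)
    tfh2(d, c("a", "b"), n_perm = 199, seed = i)$p
  }, 0)
  expect_gt(mean(p_two < 0.05), 0.95)
})

test_that("pair classification walks both decision paths", {
  c1 <- classify_pair(angle_p = 0.01)
  expect_equal(c1$category, "slope_shift")
  c2 <- classify_pair(angle_p = 0.5, intercept_p = 0.01)
  expect_equal(c2$category, "parallel_intercept_shift")
  c3 <- classify_pair(angle_p = 0.5, intercept_p = 0.4, peram_p = 0.01)
  expect_equal(c3$category, "peramorphosis_paedomorphosis")
  c4 <- classify_pair(angle_p = 0.5, intercept_p = 0.4, peram_p = 0.6)
  expect_equal(c4$category, "conserved")
  c5 <- classify_pair(angle_p = 0.5, intercept_p = NA)
  expect_equal(c5$category, "not_tested")

  expect_equal(classify_pair(0.5, 0.5, 0.5, tfh1_p = 0.3)$heterochrony,
               "ontogenetic_scaling")
  expect_equal(classify_pair(0.5, 0.5, 0.5, tfh1_p = 0.01,
                             tfh2_p = 0.3)$heterochrony,
               "size_shape_dissociation")
  expect_equal(classify_pair(0.5, 0.5, 0.5, tfh1_p = 0.01,
                             tfh2_p = 0.01)$heterochrony, "none")
  expect_equal(classify_pair(0.5, 0.5, 0.5, tfh1_p = NA)$heterochrony,
               "not_tested")
})

test_that("truncation fixtures support scaling, never reach dissociation", {
  set.seed(37)
  for (i in 1:5) {
    d <- make_two_species(c(1, 0.2, 0), c(1, 0.2, 0), n = 30,
                          noise_sd = 0.03, range_b = c(0, 1),
                          seed = 800 + i)
    bt <- heterochrony_battery(d, n_perm = 199, n_perm_tfh2 = 199,
                               seed = i)
    expect_true(bt$heterochrony %in% c("ontogenetic_scaling"))
    expect_true(is.na(bt$tfh2_p))
  }
})
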