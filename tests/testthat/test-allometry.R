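# Per-species allometric fits, isometry and homogeneity-of-slopes tests,
# pairwise trajectory comparisons, hierarchical partitioning.

test_that("unique-allometry fits reproduce hand OLS and trajectory lengths", {
  # exact line: sizes (1,2,3), first shape variable (0,1,2)
  d <- shape_data(cbind(c(0, 1, 2), c(5, 5, 5)), c(1, 2, 3), rep("a", 3))
  f <- suppressWarnings(fit_unique_allometries(d, min_n = 2))
  expect_equal(unname(f$slopes["a", ]), c(1, 0))
  expect_equal(unname(f$intercepts["a", ]), c(-1, 5))
  expect_equal(unname(f$trajectories$lengths["a"]), 2) # ||yhat(3)-yhat(1)||
  expect_equal(unname(f$trajectories$pred_juvenile["a", ]), c(0, 5))
  expect_equal(unname(f$trajectories$pred_adult["a", ]), c(2, 5))

  # size-constant shape: zero slope, zero length
  d0 <- shape_data(matrix(3, 4, 2), c(1, 2, 3, 4), rep("a", 4))
  f0 <- suppressWarnings(fit_unique_allometries(d0, min_n = 2))
  expect_equal(unname(f0$slopes["a", ]), c(0, 0))
  expect_equal(unname(f0$trajectories$lengths["a"]), 0)

  # noiseless synthetic series: exact recovery
  ds <- simulate_dataset(sim_spec(n_species = 8, n_specimens = c(6, 10),
                                  q_traits = 4, noise_sd = 0, seed = 21))
  fr <- fit_unique_allometries(ds$shape, min_n = 2)
  expect_lt(max(abs(fr$slopes[rownames(ds$truth$slopes), ] -
                      ds$truth$slopes)), 1e-10)
  expect_lt(max(abs(fr$intercepts[rownames(ds$truth$intercepts), ] -
                      ds$truth$intercepts)), 1e-10)

  # predictions at observed sizes reproduce OLS fitted values exactly
  i <- ds$shape$species == "sp01"
  X <- cbind(1, ds$shape$size[i])
  fitted <- X %*% rbind(fr$intercepts["sp01", ], fr$slopes["sp01", ])
  expect_lt(max(abs(fitted - ds$shape$Y[i, ])), 1e-10)

  expect_error(fit_unique_allometries(
    shape_data(matrix(1, 2, 2), c(1, 1), c("a", "a"))), "size variance")
})

test_that("trajectory length is invariant to shifting all sizes", {
  set.seed(22)
  d <- make_two_species(c(1, 0, 0), c(0.5, 0.5, 0), n = 15)
  f1 <- fit_unique_allometries(d)
  d2 <- d
  d2$size <- d$size + 10
  f2 <- fit_unique_allometries(d2)
  expect_equal(f1$trajectories$lengths, f2$trajectories$lengths,
               tolerance = 1e-9)
  expect_equal(f1$slopes, f2$slopes, tolerance = 1e-9)
  # intercepts absorb the shift
  expect_false(isTRUE(all.equal(f1$intercepts, f2$intercepts)))
})

test_that("isometry test separates allometric from isometric growth", {
  # constant shape, zero noise: F = 0, p = 1, isometric
  d0 <- shape_data(matrix(2, 10, 3), seq(1, 2, length.out = 10),
                   rep("a", 10))
  r0 <- isometry_test(d0, n_perm = 99, seed = 1)
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  expect_true(r0$isometric)
  expect_equal(r0$R2, 0)

  # strong allometry: rejected virtually always
  set.seed(23)
  rej <- vapply(1:30, function(i) {
    s <- runif(30, 0, 2)
    Y <- s %*% t(c(1, 1, 0)) + matrix(rnorm(90, sd = 0.1), 30, 3)
    isometry_test(shape_data(Y, s, rep("a", 30)),
                  n_perm = 999, seed = i)$p
  }, 0)
  expect_true(all(rej <= 0.001))

  expect_error(isometry_test(shape_data(matrix(1, 5, 2), rep(1, 5),
                                        rep("a", 5))), "size variance")
})

test_that("HOST detects slope heterogeneity and respects its null", {
  # identical slopes, zero noise: interaction F = 0
  s <- rep(seq(0, 2, length.out = 10), 2)
  Y <- s %*% t(c(1, 0.5))
  d0 <- shape_data(Y, s, rep(c("a", "b"), each = 10))
  h0 <- host_test(d0, n_perm = 99, seed = 1)
  expect_equal(h0$F, 0)
  expect_gt(h0$p, 0.9)

  # orthogonal slopes: strongly rejected across replicates
  ps <- vapply(1:20, function(i)
    host_test(make_two_species(c(1, 0, 0, 0), c(0, 1, 0, 0), seed = i),
              n_perm = 499, seed = i)$p, 0)
  expect_gt(mean(ps < 0.01), 0.95)

  expect_error(host_test(shape_data(matrix(1:6, 3), c(1, 2, 3),
                                    c("a", "a", "b")), n_perm = 9),
               "single specimen")
  expect_error(host_test(make_two_species(c(1, 0), c(1, 0)),
                         species_subset = "a"), "2 species")
})

test_that("pairwise angles and length differences behave geometrically", {
  # analytic 45 degrees between (1,0) and (sqrt(2)/2, sqrt(2)/2)
  set.seed(24)
  d <- make_two_species(c(1, 0), sqrt(c(0.5, 0.5)), n = 40, noise_sd = 0.05)
  pw <- pairwise_trajectories(d, n_perm = 199, seed = 1)
  expect_lt(abs(pw$angles$statistic["a", "b"] - 45), 6)
  expect_equal(pw$angles$statistic["a", "b"], pw$angles$statistic["b", "a"])
  expect_equal(diag(pw$angles$statistic), c(a = 0, b = 0))
  expect_true(all(pw$angles$statistic >= 0 & pw$angles$statistic <= 180))
  expect_lt(pw$angles$p["a", "b"], 0.05)

  # same trajectory under two labels: angle ~ 0 and both tests null
  d2 <- make_two_species(c(1, 0.3), c(1, 0.3), n = 40, noise_sd = 0.05,
                         seed = 7)
  pw2 <- pairwise_trajectories(d2, n_perm = 199, seed = 2)
  expect_lt(pw2$angles$statistic["a", "b"], 15)
  expect_gt(pw2$angles$p["a", "b"], 0.05)
  expect_gt(pw2$lengths$p["a", "b"], 0.05)
})

test_that("pairwise tests are calibrated on a shared single trajectory", {
  # two species simulated from one trajectory: ~95% non-significant
  set.seed(25)
  res <- t(vapply(1:40, function(i) {
    d <- make_two_species(c(1, 0.5), c(1, 0.5), n = 25, noise_sd = 0.15,
                          seed = 100 + i)
    pw <- pairwise_trajectories(d, n_perm = 199, seed = i)
    c(pw$angles$p["a", "b"], pw$lengths$p["a", "b"])
  }, c(0, 0)))
  expect_gt(mean(res[, 1] >= 0.05), 0.8)
  expect_gt(mean(res[, 2] >= 0.05), 0.8)
})

test_that("intercept test finds offsets and refuses heterogeneous slopes", {
  # pseudo-species from one sample: distance ~ 0, p high
  set.seed(26)
  d <- make_two_species(c(1, 0), c(1, 0), n = 40, noise_sd = 0.1)
  r <- intercept_test(d, c("a", "b"), n_perm = 199, seed = 1)
  expect_lt(r$distance, 0.1)
  expect_gt(r$p, 0.05)

  # parallel offset by 5 noise SD: detected essentially always
  hits <- vapply(1:15, function(i) {
    dp <- make_two_species(c(1, 0), c(1, 0), n = 25, noise_sd = 0.1,
                           intercept_b = c(0, 0.5), seed = 200 + i)
    intercept_test(dp, c("a", "b"), n_perm = 199, seed = i)$p < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.99)

  expect_error(intercept_test(d, c("a", "b"), slope_p = 0.01),
               "heterogeneous")
  # BH adjustment across pairs
  dp <- make_two_species(c(1, 0), c(1, 0), n = 20, noise_sd = 0.1, seed = 3)
  out <- intercept_tests(dp, list(c("a", "b"), c("b", "a")), n_perm = 99,
                         seed = 2)
  expect_true(all(out$p_adjusted >= out$p))
})

test_that("hierarchical partitioning reconstructs the full-model R2", {
  set.seed(27)
  X <- matrix(rnorm(300), 100, 3,
              dimnames = list(NULL, c("angle", "length", "intercept")))
  y <- X %*% c(1, 2, 0) + rnorm(100)
  hp <- hier_part(y, X)
  expect_equal(sum(hp$independent), attr(hp, "R2_full"), tolerance = 1e-10)
  expect_equal(hp$joint + hp$independent,
               vapply(1:3, function(k)
                 summary(lm(y ~ X[, k]))$r.squared, 0),
               tolerance = 1e-10)
  expect_equal(sum(hp$pct_independent), 100)

  # response identical to one predictor, others noise: ~100% independent
  y2 <- X[, 1]
  hp2 <- hier_part(y2, X)
  expect_gt(hp2$pct_independent[1], 95)

  # constant predictor: zero independent effect with a warning
  X3 <- cbind(X[, 1:2], flat = 1)
  expect_warning(hp3 <- hier_part(y, X3), "constant")
  expect_equal(hp3$independent[3], 0)
})

test_that("trajectory attribute table aligns pairs with their contrasts", {
  set.seed(28)
  d <- make_two_species(c(1, 0), c(0, 1), n = 20, noise_sd = 0.1)
  tab <- trajectory_attribute_table(d, n_perm = 49, seed = 1)
  expect_equal(nrow(tab), 1)
  expect_true(all(c("disparity", "angle", "length_diff",
                    "intercept_dist") %in% names(tab)))
  f <- fit_unique_allometries(d)
  expect_equal(tab$disparity,
               sqrt(sum((f$trajectories$pred_adult["a", ] -
                           f$trajectories$pred_adult["b", ])^2)))
})

test_that("per-trait ontogenetic change is classified by sign and signal", {
  set.seed(29)
  n <- 25
  s <- runif(n, 0, 2)
  Y <- cbind(up = 0.8 * s, down = -0.8 * s, flat = 0) +
    matrix(rnorm(3 * n, sd = 0.1), n, 3)
  colnames(Y) <- c("up", "down", "flat")
  d <- shape_data(Y, s, rep("a", n))
  tab <- ontogenetic_shift_table(d, n_perm = 199, seed = 1)
  expect_equal(tab$change[tab$trait == "up"], "increases")
  expect_equal(tab$change[tab$trait == "down"], "decreases")
  expect_equal(tab$change[tab$trait == "flat"], "isometric")
  expect_error(ontogenetic_shift_table(d, trait_index = 9), "out of range")

  # constructed clade: 11 of 14 species with negative tail slope
  sps <- sprintf("s%02d", 1:14)
  neg <- c(rep(TRUE, 11), rep(FALSE, 3))
  parts <- lapply(1:14, function(i) {
    si <- runif(12, 0, 2)
    slope <- if (neg[i]) -0.6 else 0.6
    cbind(si * slope + rnorm(12, sd = 0.05), si)
  })
  dd <- shape_data(do.call(rbind, lapply(parts, function(p)
    cbind(tail_length = p[, 1]))),
    unlist(lapply(parts, function(p) p[, 2])),
    rep(sps, each = 12))
  tt <- ontogenetic_shift_table(dd, n_perm = 199, seed = 2)
  expect_equal(mean(tt$change == "decreases") * 100, 78.57, tolerance = 0.01)
})
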