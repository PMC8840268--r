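# Shape extraction: log-shape ratios, GPA, semilandmark sliding, object
# symmetry, and the sexual-dimorphism filter.

test_that("log-shape ratios divide by the geometric mean and log-transform", {
  body <- as_linear_table(data.frame(specimen_id = c("s1", "s2"),
                                     species = "A", sex = "M",
                                     t1 = c(2, 5), t2 = c(8, 5)))
  out <- log_shape_ratios(body)$body
  # traits (2, 8): GM 4, shape (ln .5, ln 2), size ln 4
  expect_equal(unname(out$Y[1, ]), c(log(0.5), log(2)))
  expect_equal(out$size[1], log(4))
  # all traits equal c: shape zero, size ln c
  expect_equal(unname(out$Y[2, ]), c(0, 0))
  expect_equal(out$size[2], log(5))
  expect_error(
    as_linear_table(data.frame(specimen_id = "s", species = "A", sex = "M",
                               t1 = 0, t2 = 1)), "positive")

  # row-wise geometric mean of exp(Y) is 1 when size uses the same traits
  set.seed(11)
  tab <- as_linear_table(data.frame(specimen_id = paste0("s", 1:10),
                                    species = "A", sex = "M",
                                    a = runif(10, 1, 9), b = runif(10, 1, 9),
                                    c = runif(10, 1, 9)))
  Y <- log_shape_ratios(tab)$body$Y
  expect_lt(max(abs(rowMeans(Y))), 1e-9)   # log GM of ratios = 0
})

test_that("combined size pools both tables and warns on unmatched specimens", {
  body <- as_linear_table(data.frame(specimen_id = c("s1", "s2"),
                                     species = "A", sex = "M",
                                     t1 = c(2, 2), t2 = c(2, 2)))
  limbs <- as_linear_table(data.frame(specimen_id = "s1", species = "A",
                                      sex = "M", u1 = 16, u2 = 16))
  expect_warning(out <- log_shape_ratios(body, limbs), "one table only")
  # s1: combined GM over (2,2,16,16) = exp(mean(log)) = sqrt(2*16) ... = 32^(1/2)?
  expect_equal(out$body$size[1], mean(log(c(2, 2, 16, 16))))
  expect_equal(out$body$size[2], log(2))
  expect_equal(out$limbs$size[1], out$body$size[1])
})

test_that("GPA removes location, scale, orientation and specimen order", {
  tri <- rbind(c(0, 0), c(3, 0), c(3, 4))
  rot <- function(X, th) X %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  A <- array(0, c(2, 3, 2))
  A[1, , ] <- tri
  A[2, , ] <- rot(tri, pi / 2) + 5
  g <- gpa(landmark_block(A))
  expect_lt(max(abs(g$block$coords[1, , ] - g$block$coords[2, , ])), 1e-10)
  # centroid size of the 3-4-5 triangle at (0,0),(3,0),(3,4) by the direct
  # formula: sqrt of summed squared deviations from the centroid
  expect_equal(g$centroid_sizes[1], sqrt(sum(scale(tri, scale = FALSE)^2)))

  set.seed(12)
  base <- array(rnorm(5 * 6 * 2), c(5, 6, 2))
  g1 <- gpa(landmark_block(base))
  tr <- base
  for (i in 1:5) tr[i, , ] <- rot(base[i, , ], runif(1, 0, 2 * pi)) *
    runif(1, 0.5, 2) + rnorm(1)
  g2 <- gpa(landmark_block(tr))
  m1 <- mean_shape(g1$block)
  m2 <- mean_shape(g2$block)
  # mean shapes agree up to rotation: align and compare
  R <- ontotraj:::.opt_rotation(m2, m1)
  expect_lt(max(abs(m2 %*% R - m1)), 1e-6)
  # specimen order invariance
  g3 <- gpa(landmark_block(base[5:1, , ]))
  expect_lt(max(abs(mean_shape(g3$block) %*%
                      ontotraj:::.opt_rotation(mean_shape(g3$block), m1) -
                      m1)), 1e-6)
  expect_error(gpa(landmark_block(array(1, c(2, 4, 2)))), "degenerate")
})

test_that("two-specimen GPA matches the closed-form SVD superimposition", {
  set.seed(13)
  X1 <- matrix(rnorm(12), 6, 2)
  X2 <- matrix(rnorm(12), 6, 2)
  A <- array(0, c(2, 6, 2))
  A[1, , ] <- X1
  A[2, , ] <- X2
  g <- gpa(landmark_block(A))
  # oracle: centre/scale both, rotate X2 onto X1 by SVD; the pairwise
  # Procrustes distance must match the GPA result
  cs <- function(X) {
    Xc <- scale(X, scale = FALSE)
    Xc / sqrt(sum(Xc^2))
  }
  A <- cs(X1); B <- cs(X2)
  sv <- svd(crossprod(B, A))
  R <- sv$u %*% diag(c(1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
  d_oracle <- sqrt(sum((B %*% R - A)^2))
  d_gpa <- sqrt(sum((g$block$coords[1, , ] - g$block$coords[2, , ])^2))
  expect_lt(abs(d_gpa - d_oracle), 1e-9)
})

test_that("semilandmark sliding minimizes bending energy", {
  sliders <- rbind(c(2, 3, 4), c(3, 4, 5), c(4, 5, 6))
  blk <- make_curve_block(n_spec = 4, k = 7, sliders = sliders)
  aligned <- gpa(blk)$block
  # no sliders: identity
  nos <- aligned
  nos$sliders <- NULL
  expect_identical(slide_semilandmarks(nos), nos)

  slid <- slide_semilandmarks(aligned)
  path <- attr(slid, "energy_path")
  expect_true(all(diff(path) <= 1e-12))
  expect_lt(path[length(path)], path[1])

  # one-semilandmark toy: the analytic slide position matches a dense grid
  # search over tangent displacements minimizing bending energy
  blk1 <- make_curve_block(n_spec = 3, k = 7, seed = 5,
                           sliders = rbind(c(3, 4, 5)))
  al1 <- gpa(blk1)$block
  M <- mean_shape(al1)
  Be <- ontotraj:::.bending_energy_matrix(M)
  X <- al1$coords[1, , ]
  tang <- X[5, ] - X[3, ]
  tang <- tang / sqrt(sum(tang^2))
  energy_at <- function(t_amt) {
    Xp <- X
    Xp[4, ] <- X[4, ] + t_amt * tang
    V <- Xp - M
    sum(V * (Be %*% V))
  }
  grid <- seq(-0.5, 0.5, by = 1e-5)
  t_grid <- grid[which.min(vapply(grid, energy_at, 0))]
  # a single slide pass of the package must land on the grid minimum
  one_pass <- slide_semilandmarks(al1, max_outer = 1L, re_align = FALSE)
  slid_pos <- one_pass$coords[1, 4, ]
  expect_lt(max(abs(slid_pos - (X[4, ] + t_grid * tang))), 1e-4)

  # coincident neighbours leave the tangent undefined
  bad <- al1
  bad$coords[1, 3, ] <- bad$coords[1, 5, ]
  expect_error(slide_semilandmarks(bad), "landmark 4")
})

test_that("symmetric component fixes symmetric shapes and symmetrizes others", {
  # perfectly symmetric configuration is a fixed point
  S <- rbind(c(0, 1), c(0, -1), c(1, 0.5), c(-1, 0.5))
  A <- array(0, c(2, 4, 2))
  A[1, , ] <- S
  A[2, , ] <- S * 1.1
  blk <- landmark_block(A, symmetry_pairs = rbind(c(3, 4)),
                        midline_idx = c(1, 2))
  al <- gpa(blk)$block
  sym <- symmetric_component(al)
  expect_lt(max(abs(sym$coords - al$coords)), 1e-10)

  # asymmetric pair at (1, .9) and (-1, 1.1) with a long stabilizing
  # midline: symmetric component averages the pair to equal heights
  B <- rbind(c(0, 10), c(0, -10), c(1, 0.9), c(-1, 1.1))
  A2 <- array(0, c(2, 4, 2))
  A2[1, , ] <- B
  A2[2, , ] <- B
  blk2 <- landmark_block(A2, symmetry_pairs = rbind(c(3, 4)),
                         midline_idx = c(1, 2))
  al2 <- gpa(blk2)$block
  sym2 <- symmetric_component(al2)
  X <- sym2$coords[1, , ]
  # paired landmarks now mirror each other about the midline axis
  expect_lt(abs(X[3, 2] - X[4, 2]), 1e-3)
  expect_lt(abs(X[3, 1] + X[4, 1]), 1e-3)
  # and the result matches the hand-symmetrized configuration (pair heights
  # averaged to 1.0), up to the Procrustes frame
  E <- rbind(c(0, 10), c(0, -10), c(1, 1), c(-1, 1))
  Ec <- scale(E, scale = FALSE)
  Ec <- Ec / sqrt(sum(Ec^2))
  R <- ontotraj:::.opt_rotation(X, Ec)
  expect_lt(max(abs(X %*% R - Ec)), 1e-3)

  # idempotence: symmetrizing a symmetric component changes nothing
  sym3 <- symmetric_component(sym2)
  expect_lt(max(abs(sym3$coords - sym2$coords)), 1e-9)

  bad <- landmark_block(A2, symmetry_pairs = rbind(c(3, 4)),
                        midline_idx = 1)
  expect_error(symmetric_component(gpa(bad)$block), "unpaired")
})

test_that("dimorphism filter removes females only where sex matters", {
  # males only: untested pass-through
  set.seed(14)
  d0 <- shape_data(matrix(rnorm(40), 10, 4), rnorm(10), rep("sp", 10),
                   sex = rep("M", 10))
  out0 <- dimorphism_filter(d0, n_perm = 99, seed = 1)
  expect_equal(out0$report$action, "untested")
  expect_equal(nrow(out0$data$Y), 10)

  # strongly dimorphic species (3 SD mean shift): females removed
  n <- 20
  Ym <- matrix(rnorm(n * 4), n, 4)
  Yf <- matrix(rnorm(n * 4), n, 4)
  Yf[, 1] <- Yf[, 1] + 3
  d1 <- shape_data(rbind(Ym, Yf), rnorm(2 * n), rep("sp", 2 * n),
                   sex = rep(c("M", "F"), each = n))
  out1 <- dimorphism_filter(d1, n_perm = 199, seed = 2)
  expect_equal(out1$report$action, "females_removed")
  expect_equal(nrow(out1$data$Y), n)
  expect_true(all(out1$data$sex == "M"))
})

test_that("dimorphism filter type-I removal rate is near alpha", {
  # same-distribution sexes: removal should occur at roughly the alpha rate
  set.seed(15)
  removed <- vapply(1:120, function(i) {
    Y <- matrix(rnorm(30 * 3), 30, 3)
    d <- shape_data(Y, rnorm(30), rep("sp", 30),
                    sex = rep(c("M", "F"), 15))
    out <- dimorphism_filter(d, n_perm = 99, seed = i)
    out$report$action[1] == "females_removed"
  }, TRUE)
  expect_lt(abs(mean(removed) - 0.05), 0.05)
})

test_that("TPS files are parsed into landmark blocks", {
  tmp <- tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "1 1", "ID=alpha",
               "LM=3", "0 0", "2 0", "2 2", "ID=beta"), tmp)
  blk <- read_tps(tmp)
  expect_equal(dim(blk$coords), c(2, 3, 2))
  expect_equal(blk$specimen_id, c("alpha", "beta"))
  expect_equal(blk$coords[2, 3, ], c(2, 2))
})
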