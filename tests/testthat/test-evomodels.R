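# Trait-evolution model fitting and AICc comparison.

test_that("BM likelihood matches a hand-built Gaussian density", {
  # 3-taxon tree ((A:1,B:1):1,C:2), trait (0,1,4), sigma2 = 1, root 0:
  # covariance [[2,1,0],[1,2,0],[0,0,2]]
  t3 <- read_newick("((A:1,B:1):1,C:2);")
  x3 <- c(A = 0, B = 1, C = 4)
  V <- rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2))
  ll_oracle <- -0.5 * (3 * log(2 * pi) +
                         as.numeric(determinant(V)$modulus) +
                         drop(t(x3) %*% solve(V) %*% x3))
  expect_equal(bm_loglik(t3, x3, sigma2 = 1, root_state = 0), ll_oracle,
               tolerance = 1e-9)

  # ML fit equals the analytic GLS/profile solution on a larger tree
  tr <- test_tree(20, seed = 61)
  x <- sim_bm_tips(tr, seed = 62)
  fit <- fit_gauss_model(tr, x, "BM")
  C <- ape::vcv(tr)[names(x), names(x)]
  Ci <- solve(C)
  a <- sum(Ci %*% x) / sum(Ci)
  s2 <- drop(t(x - a) %*% Ci %*% (x - a)) / 20
  expect_equal(fit$parameters$root_state, a, tolerance = 1e-8)
  expect_equal(fit$parameters$sigma2, s2, tolerance = 1e-8)
  expect_equal(fit$logLik, bm_loglik(tr, x, s2, a), tolerance = 1e-8)
})

test_that("OU and EB nest BM as limiting cases", {
  tr <- test_tree(25, seed = 63)
  x <- sim_bm_tips(tr, seed = 64)
  bm <- fit_gauss_model(tr, x, "BM")
  ou <- fit_gauss_model(tr, x, "OU")
  eb <- fit_gauss_model(tr, x, "EB")
  # nesting: the richer models can only do at least as well
  expect_gte(ou$logLik, bm$logLik - 1e-6)
  expect_gte(eb$logLik, bm$logLik - 1e-6)
  # on BM data the extra parameters sit at their BM limits
  # (alpha at its lower bound / r near 0) within optimizer tolerance
  expect_lt(abs(ou$logLik - bm$logLik), 0.5)
  expect_equal(eb$parameters$r <= 0, TRUE)

  # EB covariance at r -> 0 equals the BM covariance
  C <- ape::vcv(tr)
  r0 <- 1e-13
  expect_lt(max(abs(expm1(r0 * C) / r0 - C)), 1e-8)
})

test_that("likelihoods are invariant to tip ordering", {
  tr <- test_tree(15, seed = 65)
  x <- sim_bm_tips(tr, seed = 66)
  perm <- sample(names(x))
  f1 <- fit_gauss_model(tr, x, "BM")
  f2 <- fit_gauss_model(tr, x[perm], "BM")
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-10)
  m1 <- fit_interaction_model(tr, x, "DDl", n_starts = 2)
  m2 <- fit_interaction_model(tr, x[perm], "DDl", n_starts = 2)
  expect_equal(m1$logLik, m2$logLik, tolerance = 1e-8)
})

test_that("BMS and OUM use the regime painting", {
  set.seed(67)
  tr <- test_tree(26, seed = 67)
  ct <- ontotraj:::.clade_tips(tr)
  v <- which(lengths(ct) >= 8)[2] + 26
  inside <- tr$edge[, 2] %in% c(ct[[v - 26]],
                                ontotraj:::.clade_nodes(tr, v), v)
  segs <- data.frame(edge = seq_len(nrow(tr$edge)),
                     regime = ifelse(inside, "derived", "ancestral"),
                     duration = tr$edge.length)
  pt <- read_painted_tree(tree = tr, segments = segs)

  # rate multiplied by 9 inside the painted clade
  tr_scaled <- tr
  tr_scaled$edge.length[inside] <- tr_scaled$edge.length[inside] * 9
  x <- sim_bm_tips(tr_scaled, seed = 68)
  bms <- fit_gauss_model(tr, x, "BMS", painting = pt)
  expect_equal(bms$k, 3)
  sig <- bms$parameters$sigma2
  expect_gt(sig["derived"] / sig["ancestral"], 2)
  expect_gte(bms$logLik, fit_gauss_model(tr, x, "BM")$logLik - 1e-6)

  # optimum shifted inside the clade: OUM recovers separated optima
  x2 <- sim_bm_tips(tr, sigma2 = 0.1, seed = 69) +
    3 * (tr$tip.label %in% tr$tip.label[ct[[v - 26]]])
  oum <- fit_gauss_model(tr, x2, "OUM", painting = pt)
  expect_equal(oum$k, 4)
  th <- oum$parameters$theta
  expect_gt(th["derived"] - th["ancestral"], 1)
})

test_that("interaction models reduce to BM and respect sympatry input", {
  tr <- test_tree(18, seed = 70)
  x <- sim_bm_tips(tr, seed = 71)
  bm <- fit_gauss_model(tr, x, "BM")
  # S = 0 / b = 0 give exactly the BM covariance
  symp <- matrix(1, 18, 18, dimnames = list(tr$tip.label, tr$tip.label))
  C <- ape::vcv(tr)
  for (m in c("MC", "DDl", "DD2")) {
    V0 <- ontotraj:::.interaction_cov(tr, m, 0, symp)
    expect_lt(max(abs(V0[rownames(C), rownames(C)] - C)), 1e-6)
  }
  # fitted models therefore never fall below BM by more than tolerance
  for (m in c("MC", "DDl", "DD2")) {
    f <- fit_interaction_model(tr, x, m, n_starts = 2)
    expect_gte(f$logLik, bm$logLik - 1e-4)
    expect_equal(f$k, 3)
  }
  ntr <- tr
  ntr$edge.length[1] <- ntr$edge.length[1] * 3
  expect_error(fit_interaction_model(ntr, x, "MC"), "ultrametric")
})

test_that("matching competition pulls covariances when S < 0", {
  tr <- test_tree(12, seed = 72)
  symp <- matrix(1, 12, 12, dimnames = list(tr$tip.label, tr$tip.label))
  V_bm <- ontotraj:::.interaction_cov(tr, "MC", 0, symp)
  V_mc <- ontotraj:::.interaction_cov(tr, "MC", -2, symp)
  # matching competition shrinks the total variance relative to BM
  expect_lt(sum(diag(V_mc)), sum(diag(V_bm)))
  # diversity dependence with b < 0 slows later evolution
  V_dd <- ontotraj:::.interaction_cov(tr, "DDl", -0.05, symp)
  expect_lt(sum(diag(V_dd)), sum(diag(V_bm)))
})

test_that("AICc and Akaike weights follow their formulas", {
  # k = 2, n = 10, lnL = -5: AICc = 10 + 4 + 12/7
  expect_equal(ontotraj:::.aicc(-5, 2, 10), 10 + 4 + 12 / 7)
  expect_error(ontotraj:::.aicc(-5, 9, 10), "undefined")

  mkfit <- function(model, aicc) {
    structure(list(model = model, parameters = list(), logLik = NA_real_,
                   k = 2L, AICc = aicc, AICcw = NA_real_, n = 10L,
                   convergence = 0L, data_fingerprint = "fp"),
              class = "model_fit")
  }
  eq <- compare_models(list(mkfit("A", 10), mkfit("B", 10)))
  expect_equal(eq$AICcw, c(0.5, 0.5))
  tw <- compare_models(list(mkfit("A", 10), mkfit("B", 12)))
  expect_equal(tw$AICcw, c(exp(0) / (exp(0) + exp(-1)),
                           exp(-1) / (exp(0) + exp(-1))),
               tolerance = 1e-3)
  expect_equal(round(tw$AICcw, 3), c(0.731, 0.269))
  expect_equal(sum(tw$AICcw), 1, tolerance = 1e-9)

  bad <- mkfit("C", 11)
  bad$data_fingerprint <- "other"
  expect_error(compare_models(list(mkfit("A", 10), bad)), "identical data")
})

test_that("the eight-model wrapper returns a coherent ranking", {
  tr <- test_tree(20, seed = 73)
  segs <- data.frame(edge = seq_len(nrow(tr$edge)), regime = "all",
                     duration = tr$edge.length)
  # a painting with a single regime collapses BMS to BM, so paint a clade
  ct <- ontotraj:::.clade_tips(tr)
  v <- which(lengths(ct) >= 6)[2] + 20
  inside <- tr$edge[, 2] %in% c(ct[[v - 20]],
                                ontotraj:::.clade_nodes(tr, v), v)
  segs$regime <- ifelse(inside, "in", "out")
  pt <- read_painted_tree(tree = tr, segments = segs)
  x <- sim_bm_tips(tr, seed = 74)
  out <- fit_evolution_models(tr, x, painting = pt, n_starts = 2)
  expect_setequal(out$table$model,
                  c("BM", "OU", "EB", "BMS", "OUM", "MC", "DDl", "DD2"))
  expect_equal(sum(out$table$AICcw), 1, tolerance = 1e-9)
  expect_true(!is.unsorted(out$table$AICc))
})

test_that("slope PC1 summarizes trajectory directions", {
  ds <- simulate_dataset(sim_spec(n_species = 10, n_specimens = c(6, 8),
                                  q_traits = 4, noise_sd = 0.01, seed = 75))
  fit <- fit_unique_allometries(ds$shape, min_n = 2)
  pc1 <- slopes_pc1(fit)
  expect_equal(names(pc1), fit$species)
  expect_equal(mean(pc1), 0, tolerance = 1e-9)
})
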