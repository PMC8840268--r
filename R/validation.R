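# Simulation-based validation utilities: type-I calibration of the
# permutation tests, parameter-recovery checks, and detection power on
# constructed fixtures. These drive both the test suite and the
# reproducibility script.

#' Type-I error calibration of the permutation tests
#'
#' Simulates data under the null hypothesis of the chosen test and returns
#' the rejection rate at level `alpha`:
#' * `host` — two species sharing one allometric slope (the size-by-species
#'   interaction is null).
#' * `isometry` — one species whose shape is independent of size.
#' * `tfh1` — one species split at random into two labels (exchangeable).
#' * `manova` — a Brownian response independent of size and habitat; the
#'   rejection rate of the size term is reported.
#'
#' @param test Which test to calibrate.
#' @param n_sims Number of simulated datasets.
#' @param n_perm Permutations (or Brownian simulations) per dataset.
#' @param n Specimens per species (species per tree for `manova`).
#' @param q Shape variables.
#' @param alpha Nominal level.
#' @param seed Seed.
#' @return The empirical rejection rate.
#' @export
calibrate_type1 <- function(test = c("host", "isometry", "tfh1", "manova"),
                            n_sims = 1000L, n_perm = 999L, n = 30L, q = 6L,
                            alpha = 0.05, seed = 1L) {
  test <- match.arg(test)
  slope <- c(1, 0.5, rep(0, q - 2))
  rej <- logical(n_sims)
  if (test == "manova") {
    # marginal calibration: a fresh tree, predictors and Brownian response
    # per simulated dataset
    for (i in seq_len(n_sims)) {
      set.seed(child_seed(seed, paste0("manova.", i)))
      tr <- ape::rphylo(n, birth = 1, death = 0)
      ch <- chol(ape::vcv(tr))
      sz <- setNames(rnorm(n), tr$tip.label)
      hb <- setNames(sample(habitat_categories()[1:3], n, replace = TRUE),
                     tr$tip.label)
      Y <- t(ch) %*% matrix(rnorm(n * q), n, q)
      rownames(Y) <- tr$tip.label
      r <- phylo_manova(tr, Y, sz, hb, n_sim = n_perm,
                        seed = child_seed(seed, paste0("manova.null.", i)))
      rej[i] <- r$p[r$term == "size"] < alpha
    }
    return(mean(rej))
  }
  for (i in seq_len(n_sims)) {
    set.seed(child_seed(seed, paste0(test, ".data.", i)))
    test_seed <- child_seed(seed, paste0(test, ".perm.", i))
    if (test == "host") {
      s <- runif(2 * n, 0, 2)
      Y <- s %*% t(slope) + matrix(rnorm(2 * n * q, sd = 0.1), 2 * n, q)
      d <- shape_data(Y, s, rep(c("a", "b"), each = n))
      rej[i] <- host_test(d, n_perm = n_perm, seed = test_seed)$p < alpha
    } else if (test == "isometry") {
      s <- runif(n, 0, 2)
      Y <- matrix(rnorm(n * q, sd = 0.1), n, q)
      d <- shape_data(Y, s, rep("a", n))
      rej[i] <- isometry_test(d, n_perm = n_perm,
                              seed = test_seed)$p[1] < alpha
    } else { # tfh1
      s <- runif(n, 0, 2)
      Y <- s %*% t(slope) + matrix(rnorm(n * q, sd = 0.1), n, q)
      d <- shape_data(Y, s, sample(rep(c("a", "b"), length.out = n)))
      rej[i] <- tfh1(d, c("a", "b"), n_perm = n_perm,
                     seed = test_seed)$p < alpha
    }
  }
  mean(rej)
}

#' Brownian calibration of multivariate K
#'
#' Simulates Brownian traits on pure-birth trees and returns the mean
#' K-mult, which should sit near its Brownian expectation of 1.
#'
#' @param n_reps Number of replicates.
#' @param n_tips Tips per tree.
#' @param q Traits.
#' @param seed Seed.
#' @return Mean K across replicates.
#' @export
k_mult_calibration <- function(n_reps = 500L, n_tips = 50L, q = 2L,
                               seed = 1L) {
  ks <- vapply(seq_len(n_reps), function(i) {
    set.seed(child_seed(seed, paste0("ktree.", i)))
    tr <- ape::rphylo(n_tips, 1, 0)
    X <- t(chol(ape::vcv(tr))) %*% matrix(rnorm(n_tips * q), n_tips, q)
    rownames(X) <- tr$tip.label
    k_mult(tr, X, n_perm = 0)$K
  }, 0)
  mean(ks)
}

#' Brownian rate recovery
#'
#' Simulates Brownian traits with a known rate and refits BM by maximum
#' likelihood; returns the median relative error of the rate estimate.
#'
#' @param n_reps Number of replicates.
#' @param n_tips Tips per tree.
#' @param sigma2 Generating rate.
#' @param seed Seed.
#' @return Median of `|sigma2_hat - sigma2| / sigma2`.
#' @export
bm_sigma2_recovery <- function(n_reps = 200L, n_tips = 100L, sigma2 = 0.5,
                               seed = 1L) {
  errs <- vapply(seq_len(n_reps), function(i) {
    set.seed(child_seed(seed, paste0("bmrec.", i)))
    tr <- ape::rphylo(n_tips, 1, 0)
    x <- drop(t(chol(sigma2 * ape::vcv(tr))) %*% rnorm(n_tips))
    names(x) <- tr$tip.label
    abs(fit_gauss_model(tr, x, "BM")$parameters$sigma2 - sigma2) / sigma2
  }, 0)
  stats::median(errs)
}

#' Interaction models collapse to BM at zero interaction
#'
#' Evaluates the MC/DDl/DD2 likelihood at `S = 0` / `b = 0` on Brownian data
#' and compares it with the analytic BM maximum likelihood.
#'
#' @param n_tips Tips of the test tree.
#' @param seed Seed.
#' @return Maximum absolute log-likelihood difference across the three
#'   models.
#' @export
interaction_bm_reduction <- function(n_tips = 25L, seed = 1L) {
  set.seed(child_seed(seed, "ibr"))
  tr <- ape::rphylo(n_tips, 1, 0)
  x <- drop(t(chol(ape::vcv(tr))) %*% rnorm(n_tips))
  names(x) <- tr$tip.label
  bm <- fit_gauss_model(tr, x, "BM")
  symp <- matrix(1, n_tips, n_tips,
                 dimnames = list(tr$tip.label, tr$tip.label))
  ones <- matrix(1, n_tips, 1)
  devs <- vapply(c("MC", "DDl", "DD2"), function(m) {
    V0 <- .interaction_cov(tr, m, 0, symp)
    ll <- .profiled_mvn_ll(x[rownames(V0)], V0, ones)$ll
    abs(ll - bm$logLik)
  }, 0)
  max(devs)
}

#' Power of the D test on divergence fixtures
#'
#' @param n_reps Number of fixture replicates.
#' @param strength Divergence strength of the fixture.
#' @param n_species,n Fixture dimensions.
#' @param n_perm Permutations per test.
#' @param alpha Level.
#' @param seed Seed.
#' @return Proportion of replicates with p < alpha.
#' @export
d_test_power <- function(n_reps = 100L, strength = 5, n_species = 20L,
                         n = 10L, n_perm = 999L, alpha = 0.05, seed = 1L) {
  hits <- vapply(seq_len(n_reps), function(i) {
    fx <- make_divergence_fixture(n_species, strength, n = n,
                                  seed = child_seed(seed,
                                                    paste0("dfix.", i)))
    d_test(fx, n_perm = n_perm,
           seed = child_seed(seed, paste0("dtest.", i)))$p < alpha
  }, TRUE)
  mean(hits)
}

#' Detection rate of a ten-fold rate-shifted clade
#'
#' Simulates a trait whose Brownian rate is multiplied by `rate_factor`
#' inside one clade, runs the ridge-regression rates and the clade shift
#' search, and reports how often that clade is flagged as faster.
#'
#' @param n_reps Replicates.
#' @param n_tips Tree size.
#' @param rate_factor Rate multiplier inside the clade.
#' @param clade_range Acceptable clade sizes for the implanted shift.
#' @param n_perm Rate shuffles per shift search.
#' @param seed Seed.
#' @return Proportion of replicates in which the implanted clade (or a clade
#'   within it) is flagged `"higher"`.
#' @export
shift_detection_rate <- function(n_reps = 100L, n_tips = 40L,
                                 rate_factor = 10, clade_range = c(8L, 15L),
                                 n_perm = 1000L, seed = 1L) {
  hits <- vapply(seq_len(n_reps), function(i) {
    set.seed(child_seed(seed, paste0("shift.", i)))
    tr <- ape::rphylo(n_tips, 1, 0)
    ct <- .clade_tips(tr)
    ok <- which(lengths(ct) >= clade_range[1] & lengths(ct) <= clade_range[2])
    if (!length(ok)) return(NA)
    v <- ok[1] + n_tips
    inside <- tr$edge[, 2] %in% c(ct[[v - n_tips]], .clade_nodes(tr, v), v)
    tr_hot <- tr
    tr_hot$edge.length[inside] <- tr_hot$edge.length[inside] * rate_factor
    x <- drop(t(chol(ape::vcv(tr_hot))) %*% rnorm(n_tips))
    names(x) <- tr$tip.label
    f <- rr_rates(tr, x)
    s <- search_shift(f, min_clade_size = 6L, n_perm = n_perm,
                      seed = child_seed(seed, paste0("shiftperm.", i)))
    clade_members <- tr$tip.label[ct[[v - n_tips]]]
    flagged <- s$node[s$verdict == "higher"]
    any(vapply(flagged, function(nd) {
      tips_nd <- tr$tip.label[ct[[nd - n_tips]]]
      all(tips_nd %in% clade_members) || all(clade_members %in% tips_nd)
    }, TRUE))
  }, TRUE)
  mean(hits, na.rm = TRUE)
}

#' Classification accuracy on the constructed trajectory fixtures
#'
#' Runs the full heterochrony battery on [make_heterochrony_fixtures()] and
#' compares the resulting classifications with the constructed truth.
#'
#' @param n Specimens per fixture species.
#' @param n_perm,n_perm_tfh2 Permutation counts for the battery.
#' @param seed Seed.
#' @return List: `accuracy` (fraction of fixture pairs classified into their
#'   constructed cell on both decision paths) and `table` (the merged
#'   battery/truth table).
#' @export
fixture_classification <- function(n = 30L, n_perm = 999L,
                                   n_perm_tfh2 = 499L, seed = 1L) {
  fx <- make_heterochrony_fixtures(n = n,
                                   seed = child_seed(seed, "fixtures"))
  bt <- heterochrony_battery(fx$data, n_perm = n_perm,
                             n_perm_tfh2 = n_perm_tfh2,
                             seed = child_seed(seed, "battery"))
  key <- paste(bt$species_1, bt$species_2)
  truth_key <- paste(fx$expected$species_1, fx$expected$species_2)
  m <- merge(bt[key %in% truth_key, ], fx$expected,
             by = c("species_1", "species_2"), suffixes = c("", "_true"))
  ok <- m$category == m$category_true & m$heterochrony == m$heterochrony_true
  list(accuracy = mean(ok), table = m)
}
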