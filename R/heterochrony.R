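# Heterochrony test battery: peramorphosis test, ontogenetic scaling (Tfh1),
# size-shape dissociation (Tfh2), and the decision-path classification of
# species pairs.

# pooled and per-group residual SS of the multivariate regression of shape
# on size
.pooled_resid_ss <- function(Y, s) {
  X <- cbind(1, s)
  sum(qr.resid(qr(X), Y)^2)
}

.group_resid_ss <- function(Y, s, labels) {
  tot <- 0
  for (g in unique(labels)) {
    i <- labels == g
    if (sum(i) < 3L || var(s[i]) == 0) {
      # a pseudo-group too small to regress contributes its centred SS
      tot <- tot + sum(scale(Y[i, , drop = FALSE], scale = FALSE)^2)
    } else {
      tot <- tot + .pooled_resid_ss(Y[i, , drop = FALSE], s[i])
    }
  }
  tot
}

#' Peramorphosis/paedomorphosis test for a species pair
#'
#' For a pair sharing a common slope and intercept, tests whether the two
#' species nevertheless differ in adult morphology: the statistic is the
#' Euclidean distance between the shapes each species' own regression
#' predicts at its maximum observed size. The null permutes specimen species
#' labels (shape-size tuples intact) and refits. A significant distance with
#' conserved trajectory geometry indicates heterochrony expressed as
#' paedomorphosis or peramorphosis.
#'
#' @param data A [shape_data] object.
#' @param pair Character vector of two species.
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @param gate_p Optional named vector `c(slope = , intercept = )` of
#'   upstream p-values; the test refuses pairs whose slope or intercept
#'   already differs at `alpha`.
#' @param alpha Significance level for the refusal gate.
#' @return List: `adult_distance`, `p`, `n_permutations`.
#' @export
peramorphosis_test <- function(data, pair, n_perm = 999, seed = NULL,
                               gate_p = NULL, alpha = 0.05) {
  if (length(pair) != 2L) stop("`pair` must name two species")
  if (!is.null(gate_p) && any(gate_p < alpha, na.rm = TRUE))
    stop("pair fails the common-slope/common-intercept precondition")
  d <- filter_species(data, pair)
  s <- d$size
  stat_fun <- function(labels) {
    pred <- lapply(unique(labels), function(g) {
      i <- labels == g
      if (sum(i) < 2L || var(s[i]) == 0) return(NULL)
      cf <- qr.coef(qr(cbind(1, s[i])), d$Y[i, , drop = FALSE])
      cf[1, ] + cf[2, ] * max(s[i])
    })
    pred <- Filter(Negate(is.null), pred)
    if (length(pred) < 2L) return(NA_real_)
    sqrt(sum((pred[[1]] - pred[[2]])^2))
  }
  null <- label_perm_stats(d$species, stat_fun, n_perm = n_perm, seed = seed)
  v <- null[, 1]
  list(adult_distance = v[1],
       p = mean(v >= v[1], na.rm = TRUE),
       n_permutations = n_perm)
}

#' Peramorphosis tests over many pairs with BH adjustment
#' @param data A [shape_data] object.
#' @param pairs List of 2-element character vectors or a 2-column matrix.
#' @param n_perm,seed Passed to [peramorphosis_test()].
#' @return Data frame: species_1, species_2, adult_distance, p, p_adjusted.
#' @export
peramorphosis_tests <- function(data, pairs, n_perm = 999, seed = NULL) {
  if (is.matrix(pairs)) pairs <- asplit(pairs, 1)
  rows <- lapply(pairs, function(pr) {
    r <- peramorphosis_test(data, pr, n_perm = n_perm,
                            seed = if (is.null(seed)) NULL
                                   else child_seed(seed,
                                     paste0("peram.", paste(pr, collapse = "|"))))
    data.frame(species_1 = pr[1], species_2 = pr[2],
               adult_distance = r$adult_distance, p = r$p)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adjusted <- bh_adjust(out$p)$adjusted
  out
}

#' Tfh1: test of ontogenetic scaling
#'
#' Ontogenetic scaling — two species lying on a single shape-size trajectory
#' and differing only by extension or truncation — is the *null* hypothesis.
#' The descriptive statistic is the residual sum of squares of the pooled
#' multivariate regression of shape on size (`ss_resid`). Because that pooled
#' quantity is unchanged by relabelling, the permutation comparison uses the
#' label-dependent excess `ss_excess = ss_resid - ss_separate`, the part of
#' the pooled residual SS explained by fitting the two species separately;
#' the null permutes specimen species labels (each specimen keeps its
#' shape-size pairing). A large observed excess relative to the permuted ones
#' rejects scaling. No multiple-testing correction is applied, keeping the
#' test conservative in favour of its heterochrony null.
#'
#' @param data A [shape_data] object.
#' @param pair Character vector of two species.
#' @param n_perm Number of permutations (10000 in full-scale analyses).
#' @param seed Seed.
#' @return List: `ss_resid` (pooled residual SS), `ss_excess`, `p`
#'   (p >= alpha supports ontogenetic scaling), `n_permutations`.
#' @export
tfh1 <- function(data, pair, n_perm = 999, seed = NULL) {
  if (length(pair) != 2L) stop("`pair` must name two species")
  d <- filter_species(data, pair)
  s <- d$size
  if (var(s) == 0) stop("pooled design is singular (no size variation)")
  ss_pooled <- .pooled_resid_ss(d$Y, s)
  stat_fun <- function(labels) ss_pooled - .group_resid_ss(d$Y, s, labels)
  null <- label_perm_stats(d$species, stat_fun, n_perm = n_perm, seed = seed)
  v <- null[, 1]
  list(ss_resid = ss_pooled, ss_excess = v[1],
       p = mean(v >= v[1]), n_permutations = n_perm)
}

# perpendicular SS of shapes about the line traced in shape space by a
# shape~size regression of (Y, s); infinite line by default, optionally
# clamped to the fitted segment
.perp_ss <- function(Y, s, clamp = FALSE) {
  cf <- qr.coef(qr(cbind(1, s)), Y)
  b <- cf[2, ]
  nb <- sqrt(sum(b^2))
  if (nb < 1e-10 * (max(abs(Y)) + 1))
    stop("degenerate regression line (zero slope)")
  u <- b / nb
  ctr <- cf[1, ] + b * mean(s)
  Dev <- sweep(Y, 2, ctr)
  t_proj <- drop(Dev %*% u)
  if (clamp) {
    t_rng <- range((range(s) - mean(s)) * nb)
    t_proj <- pmin(pmax(t_proj, t_rng[1]), t_rng[2])
  }
  sum(Dev^2) - 2 * sum(t_proj * drop(Dev %*% u)) + sum(t_proj^2)
}

# a group's line in shape space: centre point and unit direction, from the
# group's own shape~size regression when possible, else its principal axis
.shape_line <- function(Y, s) {
  ok <- nrow(Y) >= 3L && var(s) > 0
  if (ok) {
    cf <- qr.coef(qr(cbind(1, s)), Y)
    b <- cf[2, ]
    nb <- sqrt(sum(b^2))
    if (nb > 1e-10 * (max(abs(Y)) + 1))
      return(list(ctr = cf[1, ] + b * mean(s), u = b / nb))
  }
  Dev <- scale(Y, scale = FALSE)
  sv <- svd(Dev, nu = 0, nv = 1)
  list(ctr = colMeans(Y), u = drop(sv$v))
}

.perp_ss_to_line <- function(Y, line) {
  Dev <- sweep(Y, 2, line$ctr)
  sum(Dev^2) - sum((Dev %*% line$u)^2)
}

# cross-projection SS: every specimen's squared distance to the OTHER
# group's shape-space line; label-dependent, exchangeable under shape-space
# overlap regardless of how sizes are distributed between the groups
.cross_perp_ss <- function(Y, s, labels) {
  gs <- unique(labels)
  if (length(gs) != 2L) return(NA_real_)
  i1 <- labels == gs[1]
  l1 <- .shape_line(Y[i1, , drop = FALSE], s[i1])
  l2 <- .shape_line(Y[!i1, , drop = FALSE], s[!i1])
  .perp_ss_to_line(Y[i1, , drop = FALSE], l2) +
    .perp_ss_to_line(Y[!i1, , drop = FALSE], l1)
}

#' Tfh2: test of size-shape dissociation
#'
#' Applied to pairs for which ontogenetic scaling (Tfh1) was rejected:
#' size-shape dissociation — the two species sharing one trajectory in shape
#' space while occupying it at different sizes — is the null hypothesis.
#' The descriptive statistic is the sum of squared distances from each
#' specimen's shape to its nearest point on the line traced in shape space by
#' the pooled shape~size regression (the size dimension is discarded; by
#' default the infinite line is used, `clamp = TRUE` restricts projections to
#' the fitted segment). Because that pooled quantity is unchanged by
#' relabelling, the permutation comparison uses the label-dependent
#' cross-projection SS (`ss_cross`): each specimen's squared shape-space
#' distance to the *other* species' line, summed over all specimens, with
#' specimen labels permuted. Species occupying one shape trajectory at
#' different sizes are thereby not penalised. No multiple-testing correction
#' is applied, keeping the test conservative in favour of its heterochrony
#' null.
#'
#' @param data A [shape_data] object.
#' @param pair Character vector of two species.
#' @param n_perm Number of permutations (500 in full-scale analyses).
#' @param seed Seed.
#' @param clamp Clamp projections to the fitted segment (default infinite
#'   line).
#' @return List: `ss_perp` (pooled perpendicular SS), `ss_cross`, `p`
#'   (p >= alpha supports size-shape dissociation), `n_permutations`.
#' @export
tfh2 <- function(data, pair, n_perm = 500, seed = NULL, clamp = FALSE) {
  if (length(pair) != 2L) stop("`pair` must name two species")
  d <- filter_species(data, pair)
  s <- d$size
  ss_pooled <- .perp_ss(d$Y, s, clamp)
  stat_fun <- function(labels) .cross_perp_ss(d$Y, s, labels)
  null <- label_perm_stats(d$species, stat_fun, n_perm = n_perm, seed = seed)
  v <- null[, 1]
  list(ss_perp = ss_pooled, ss_cross = v[1],
       p = mean(v >= v[1]), n_permutations = n_perm)
}

#' Classify a species pair along the two heterochrony decision paths
#'
#' Path A walks the trajectory-geometry decision tree: a significant angle
#' means a slope shift; otherwise a significant intercept distance means
#' parallel (offset) trajectories; otherwise a significant adult-shape
#' difference means paedomorphosis/peramorphosis; otherwise the trajectories
#' are conserved. Path B, run independently, asks whether the pair overlaps
#' in size-shape space (Tfh1 null retained: ontogenetic scaling) or, failing
#' that, overlaps in shape space only (Tfh2 null retained: size-shape
#' dissociation).
#'
#' @param angle_p Unadjusted pairwise angle p-value.
#' @param intercept_p BH-adjusted intercept-test p-value (`NA` if untested).
#' @param peram_p BH-adjusted peramorphosis-test p-value (`NA` if untested).
#' @param tfh1_p Tfh1 p-value.
#' @param tfh2_p Tfh2 p-value (`NA` if Tfh1 was not rejected).
#' @param alpha Significance level.
#' @return List of class `pair_classification`: `category` (path A),
#'   `heterochrony` (path B: `"ontogenetic_scaling"`,
#'   `"size_shape_dissociation"`, or `"none"`), and `p_values`.
#' @export
classify_pair <- function(angle_p, intercept_p = NA, peram_p = NA,
                          tfh1_p = NA, tfh2_p = NA, alpha = 0.05) {
  category <- if (is.na(angle_p)) {
    "not_tested"
  } else if (angle_p < alpha) {
    "slope_shift"
  } else if (is.na(intercept_p)) {
    "not_tested"
  } else if (intercept_p < alpha) {
    "parallel_intercept_shift"
  } else if (is.na(peram_p)) {
    "not_tested"
  } else if (peram_p < alpha) {
    "peramorphosis_paedomorphosis"
  } else {
    "conserved"
  }
  heterochrony <- if (is.na(tfh1_p)) {
    "not_tested"
  } else if (tfh1_p >= alpha) {
    "ontogenetic_scaling"
  } else if (is.na(tfh2_p)) {
    "not_tested"
  } else if (tfh2_p >= alpha) {
    "size_shape_dissociation"
  } else {
    "none"
  }
  structure(list(category = category, heterochrony = heterochrony,
                 p_values = c(angle = angle_p, intercept = intercept_p,
                              peramorphosis = peram_p, tfh1 = tfh1_p,
                              tfh2 = tfh2_p),
                 alpha = alpha),
            class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  cat(sprintf("pair_classification: %s / %s\n", x$category, x$heterochrony))
  invisible(x)
}

#' Run the full heterochrony battery over all species pairs
#'
#' Orchestrates the decision paths for every unordered species pair: pairwise
#' angle comparisons (residual randomization, unadjusted), intercept tests on
#' common-slope pairs (BH-adjusted), peramorphosis tests on common-slope-and-
#' intercept pairs (BH-adjusted), Tfh1 on all pairs, and Tfh2 where Tfh1
#' rejects, then classifies each pair with [classify_pair()].
#'
#' @param data A [shape_data] object.
#' @param n_perm Permutations for the residual-randomization and label tests.
#' @param n_perm_tfh2 Permutations for Tfh2.
#' @param alpha Significance level.
#' @param seed Seed (child streams per test).
#' @return Data frame with one row per pair: the test statistics and
#'   p-values, and the two classifications.
#' @export
heterochrony_battery <- function(data, n_perm = 999, n_perm_tfh2 = 500,
                                 alpha = 0.05, seed = NULL) {
  pw <- pairwise_trajectories(data, n_perm = n_perm,
                              seed = if (is.null(seed)) NULL
                                     else child_seed(seed, "pairwise"))
  sps <- pw$fit$species
  pairs <- t(combn(sps, 2))
  np <- nrow(pairs)
  angle_p <- vapply(seq_len(np), function(i)
    pw$angles$p[pairs[i, 1], pairs[i, 2]], 0)
  common_slope <- !is.na(angle_p) & angle_p >= alpha

  intercept_p <- rep(NA_real_, np)
  intercept_d <- rep(NA_real_, np)
  if (any(common_slope)) {
    it <- intercept_tests(data, pairs[common_slope, , drop = FALSE],
                          n_perm = n_perm,
                          seed = if (is.null(seed)) NULL
                                 else child_seed(seed, "intercept"))
    intercept_p[common_slope] <- it$p_adjusted
    intercept_d[common_slope] <- it$distance
  }
  common_both <- common_slope & !is.na(intercept_p) & intercept_p >= alpha

  peram_p <- rep(NA_real_, np)
  peram_d <- rep(NA_real_, np)
  if (any(common_both)) {
    pt <- peramorphosis_tests(data, pairs[common_both, , drop = FALSE],
                              n_perm = n_perm,
                              seed = if (is.null(seed)) NULL
                                     else child_seed(seed, "peram"))
    peram_p[common_both] <- pt$p_adjusted
    peram_d[common_both] <- pt$adult_distance
  }

  tfh1_p <- tfh2_p <- rep(NA_real_, np)
  for (i in seq_len(np)) {
    pr <- pairs[i, ]
    t1 <- tfh1(data, pr, n_perm = n_perm,
               seed = if (is.null(seed)) NULL
                      else child_seed(seed, paste0("tfh1.", paste(pr, collapse = "|"))))
    tfh1_p[i] <- t1$p
    if (t1$p < alpha) {
      t2 <- tfh2(data, pr, n_perm = n_perm_tfh2,
                 seed = if (is.null(seed)) NULL
                        else child_seed(seed, paste0("tfh2.", paste(pr, collapse = "|"))))
      tfh2_p[i] <- t2$p
    }
  }

  cls <- lapply(seq_len(np), function(i)
    classify_pair(angle_p[i], intercept_p[i], peram_p[i],
                  tfh1_p[i], tfh2_p[i], alpha))
  data.frame(species_1 = pairs[, 1], species_2 = pairs[, 2],
             angle = vapply(seq_len(np), function(i)
               pw$angles$statistic[pairs[i, 1], pairs[i, 2]], 0),
             angle_p = angle_p,
             intercept_dist = intercept_d, intercept_p = intercept_p,
             adult_distance = peram_d, peramorphosis_p = peram_p,
             tfh1_p = tfh1_p, tfh2_p = tfh2_p,
             category = vapply(cls, `[[`, "", "category"),
             heterochrony = vapply(cls, `[[`, "", "heterochrony"))
}
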