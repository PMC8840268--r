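# Per-species allometric model fitting and trajectory comparison:
# isometry test, homogeneity-of-slopes test, pairwise angle/length/intercept
# comparisons, and hierarchical partitioning of disparity drivers.

# ---------------------------------------------------------------------------
# Unique-allometry fits and trajectory attributes

#' Fit per-species allometric regressions
#'
#' Ordinary least-squares regression of shape on size performed separately
#' for each species (the unique-allometry model), returning per-species
#' intercept and slope vectors together with trajectory attributes: the
#' trajectory length is the Euclidean distance between the shapes predicted
#' at that species' own smallest and largest observed size.
#'
#' @param data A [shape_data] object.
#' @param min_n Minimum specimens per species (species below this trigger a
#'   warning; species with fewer than 2 specimens or no size variation are an
#'   error).
#' @return A list of class `allometric_fit` with elements `species`,
#'   `intercepts` (species x q), `slopes` (species x q), `resid_ss`,
#'   `size_range` (species x 2), `n`, and `trajectories`, a list of class
#'   `trajectory_set` holding `lengths`, `directions` (unit slope vectors),
#'   `pred_juvenile` and `pred_adult` predicted-shape matrices.
#' @export
fit_unique_allometries <- function(data, min_n = 5L) {
  sps <- sort(unique(data$species))
  q <- ncol(data$Y)
  S <- length(sps)
  intercepts <- slopes <- matrix(NA_real_, S, q,
                                 dimnames = list(sps, colnames(data$Y)))
  size_range <- matrix(NA_real_, S, 2, dimnames = list(sps, c("min", "max")))
  resid_ss <- setNames(numeric(S), sps)
  n <- setNames(integer(S), sps)
  for (si in seq_along(sps)) {
    i <- data$species == sps[si]
    n[si] <- sum(i)
    if (n[si] < 2L) stop("species ", sps[si], " has a single specimen")
    s <- data$size[i]
    if (var(s) == 0) stop("species ", sps[si], " has zero size variance")
    X <- cbind(1, s)
    cf <- qr.coef(qr(X), data$Y[i, , drop = FALSE])
    intercepts[si, ] <- cf[1, ]
    slopes[si, ] <- cf[2, ]
    resid_ss[si] <- sum((data$Y[i, , drop = FALSE] - X %*% cf)^2)
    size_range[si, ] <- range(s)
  }
  if (any(n < min_n))
    warning("species below the minimum sample size (", min_n, "): ",
            paste(sps[n < min_n], collapse = ", "))
  pred_juv <- intercepts + slopes * size_range[, 1]
  pred_adu <- intercepts + slopes * size_range[, 2]
  lens <- sqrt(rowSums((pred_adu - pred_juv)^2))
  snorm <- sqrt(rowSums(slopes^2))
  dirs <- slopes / ifelse(snorm > 0, snorm, 1)
  dirs[snorm == 0, ] <- NA_real_
  structure(list(species = sps, intercepts = intercepts, slopes = slopes,
                 resid_ss = resid_ss, size_range = size_range, n = n,
                 trajectories = structure(
                   list(lengths = lens, directions = dirs,
                        pred_juvenile = pred_juv, pred_adult = pred_adu),
                   class = "trajectory_set")),
            class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("allometric_fit: %d species, %d shape variables\n",
              length(x$species), ncol(x$slopes)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Isometry test

#' Test each species for isometric growth
#'
#' Fits the multivariate regression of shape on size within each species and
#' assesses the size effect with a distance-based F statistic under residual
#' randomization. A non-significant size effect (p >= alpha) labels the
#' species isometric; a significant one indicates allometric scaling.
#'
#' @param data A [shape_data] object.
#' @param species Optional subset of species to test (default all).
#' @param n_perm Number of permutations.
#' @param alpha Significance level for the isometry label.
#' @param seed Seed (a per-species child stream is derived from it).
#' @return Data frame: species, n, F, R2, p, isometric.
#' @export
isometry_test <- function(data, species = NULL, n_perm = 999, alpha = 0.05,
                          seed = NULL) {
  sps <- sort(unique(data$species))
  if (!is.null(species)) sps <- intersect(sps, species)
  rows <- lapply(sps, function(sp) {
    i <- data$species == sp
    s <- data$size[i]
    if (var(s) == 0) stop("species ", sp, " has zero size variance")
    fit <- rrpp_model_test(data$Y[i, , drop = FALSE],
                           X_full = cbind(1, s),
                           X_reduced = matrix(1, sum(i), 1),
                           n_perm = n_perm,
                           seed = if (is.null(seed)) NULL
                                  else child_seed(seed, paste0("iso.", sp)))
    data.frame(species = sp, n = sum(i), F = fit$F, R2 = fit$R2, p = fit$p,
               isometric = fit$p >= alpha)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# ---------------------------------------------------------------------------
# Homogeneity of slopes test

#' Homogeneity of slopes test (HOST)
#'
#' Nested comparison of the additive model (shape ~ size + species) against
#' the unique-allometry model (shape ~ size + species + size:species),
#' testing the size-by-species interaction with a distance-based F under
#' residual randomization of the additive model. Rejection means species
#' trajectories differ in slope.
#'
#' @param data A [shape_data] object.
#' @param species_subset Optional species subset (e.g. a clade).
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @return List of class `host_result`: `F`, `p`, `df`, `n_permutations`,
#'   `species`.
#' @export
host_test <- function(data, species_subset = NULL, n_perm = 999, seed = NULL) {
  if (!is.null(species_subset)) data <- filter_species(data, species_subset)
  sps <- unique(data$species)
  if (length(sps) < 2L) stop("HOST needs at least 2 species")
  cnt <- species_counts(data)
  if (any(cnt < 2L))
    stop("species with a single specimen: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  fit <- rrpp_model_test(
    data$Y,
    X_full = .allometry_design(data$size, data$species, "unique"),
    X_reduced = .allometry_design(data$size, data$species, "additive"),
    n_perm = n_perm, seed = seed)
  structure(list(F = fit$F, p = fit$p, df = fit$df,
                 n_permutations = n_perm, species = sort(sps)),
            class = "host_result")
}

#' @export
print.host_result <- function(x, ...) {
  cat(sprintf(
    "Homogeneity of slopes test: F = %.4g (df %d, %d), p = %.4g [%d perms]\n",
    x$F, x$df[1], x$df[2], x$p, x$n_permutations))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pairwise trajectory comparisons

.pairwise_from_vec <- function(v, sps, what) {
  S <- length(sps)
  m <- matrix(0, S, S, dimnames = list(sps, sps))
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# slope/intercept coefficient extraction for the unique design:
# rows 1..S are intercept vectors, rows S+1..2S the slope vectors
.unique_coefs <- function(qrX, Y, S) {
  cf <- qr.coef(qrX, Y)
  list(intercepts = cf[seq_len(S), , drop = FALSE],
       slopes = cf[S + seq_len(S), , drop = FALSE])
}

.angles_deg <- function(slopes) {
  nrm <- sqrt(rowSums(slopes^2))
  U <- slopes / nrm
  cosm <- tcrossprod(U)
  cosm <- pmin(pmax(cosm, -1), 1)
  ang <- acos(cosm) * 180 / pi
  ang[nrm == 0, ] <- NA_real_
  ang[, nrm == 0] <- NA_real_
  ang
}

#' Pairwise comparisons of trajectory angles and lengths
#'
#' For every species pair, computes the angle (degrees) between the
#' full-dimensional allometric slope vectors and the absolute difference in
#' trajectory lengths, and tests both against null distributions obtained by
#' residual randomization of the reduced, common-slope model
#' (shape ~ size + species). Because every pairwise statistic is computed
#' from the same randomized residuals, no multiple-testing adjustment is
#' applied to these p-values.
#'
#' Species whose estimated slope vector is exactly zero have undefined
#' angles; their comparisons are reported as `NA` (flagged not-tested).
#'
#' @param data A [shape_data] object.
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @return List of class `pairwise_trajectories` with components `angles` and
#'   `lengths`, each a list holding `statistic` and `p` square matrices
#'   (species x species, zero diagonal), plus `fit`, the observed
#'   [fit_unique_allometries()] result.
#' @export
pairwise_trajectories <- function(data, n_perm = 999, seed = NULL) {
  fit <- fit_unique_allometries(data)
  sps <- fit$species
  S <- length(sps)
  if (S < 2L) stop("need at least 2 species")
  Xu <- .allometry_design(data$size, data$species, "unique")
  qrXu <- qr(Xu)
  smin <- fit$size_range[, 1]
  smax <- fit$size_range[, 2]
  up <- upper.tri(matrix(0, S, S))
  stat_fun <- function(Yp) {
    cf <- .unique_coefs(qrXu, Yp, S)
    ang <- .angles_deg(cf$slopes)
    pj <- cf$intercepts + cf$slopes * smin
    pa <- cf$intercepts + cf$slopes * smax
    lens <- sqrt(rowSums((pa - pj)^2))
    dl <- abs(outer(lens, lens, "-"))
    c(ang[up], dl[up])
  }
  null <- rrpp_null_stats(data$Y,
                          .allometry_design(data$size, data$species,
                                            "additive"),
                          stat_fun, n_perm = n_perm, seed = seed)
  obs <- null[1, ]
  pvals <- apply(null, 2, function(col)
    if (anyNA(col)) NA_real_ else mean(col >= col[1]))
  n_pair <- S * (S - 1) / 2
  ang_idx <- seq_len(n_pair)
  res <- list(
    angles = list(statistic = .pairwise_from_vec(obs[ang_idx], sps),
                  p = .pairwise_from_vec(pvals[ang_idx], sps)),
    lengths = list(statistic = .pairwise_from_vec(obs[-ang_idx], sps),
                   p = .pairwise_from_vec(pvals[-ang_idx], sps)),
    fit = fit, n_permutations = n_perm)
  diag(res$angles$p) <- diag(res$lengths$p) <- NA_real_
  class(res) <- "pairwise_trajectories"
  res
}

#' @export
print.pairwise_trajectories <- function(x, ...) {
  cat(sprintf("pairwise_trajectories: %d species, %d permutations\n",
              nrow(x$angles$statistic), x$n_permutations))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Intercept test

#' Test for distinct intercepts under a common slope
#'
#' For a species pair whose slopes are statistically homogeneous, fits the
#' common-slope model (shape ~ size + species) and uses the Euclidean
#' distance between the two species' intercept vectors as the statistic,
#' against a null built by permuting specimen species labels. A significant
#' result indicates parallel (offset) trajectories.
#'
#' @param data A [shape_data] object.
#' @param pair Character vector of two species names.
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @param slope_p Optional unadjusted pairwise angle p-value for the pair;
#'   if supplied and below `alpha` the test refuses to run (the common-slope
#'   model is not defensible for that pair).
#' @param alpha Significance level used for the refusal gate.
#' @return List: `distance`, `p`, `n_permutations`.
#' @export
intercept_test <- function(data, pair, n_perm = 999, seed = NULL,
                           slope_p = NULL, alpha = 0.05) {
  if (length(pair) != 2L) stop("`pair` must name two species")
  if (!is.null(slope_p) && slope_p < alpha)
    stop("pair has heterogeneous slopes (angle p = ", signif(slope_p, 3),
         "); the intercept test assumes a common slope")
  d <- filter_species(data, pair)
  s <- d$size
  stat_fun <- function(labels) {
    X <- cbind(1, s, as.numeric(labels == pair[2]))
    cf <- qr.coef(qr(X), d$Y)
    sqrt(sum(cf[3, ]^2))
  }
  null <- label_perm_stats(d$species, stat_fun, n_perm = n_perm, seed = seed)
  list(distance = null[1, 1], p = mean(null[, 1] >= null[1, 1]),
       n_permutations = n_perm)
}

#' Intercept tests over many pairs with BH adjustment
#'
#' Runs [intercept_test()] for each pair and adjusts the p-values across
#' tested pairs by the Benjamini-Hochberg procedure.
#'
#' @param data A [shape_data] object.
#' @param pairs List of 2-element character vectors (or a 2-column matrix).
#' @param n_perm,seed Passed to [intercept_test()].
#' @return Data frame: species_1, species_2, distance, p, p_adjusted.
#' @export
intercept_tests <- function(data, pairs, n_perm = 999, seed = NULL) {
  if (is.matrix(pairs)) pairs <- asplit(pairs, 1)
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    r <- intercept_test(data, pr, n_perm = n_perm,
                        seed = if (is.null(seed)) NULL
                               else child_seed(seed, paste(pr, collapse = "|")))
    data.frame(species_1 = pr[1], species_2 = pr[2],
               distance = r$distance, p = r$p)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adjusted <- bh_adjust(out$p)$adjusted
  out
}

# ---------------------------------------------------------------------------
# Hierarchical partitioning

.r2_subset <- function(y, X, subset) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(0)
  if (length(subset) == 0L) return(0)
  Xs <- cbind(1, X[, subset, drop = FALSE])
  res <- qr.resid(qr(Xs), y)
  1 - sum(res^2) / ss_tot
}

#' Hierarchical partitioning of R-squared
#'
#' Exact enumeration over all predictor subsets: for each predictor, the
#' independent effect is the average improvement in R-squared from adding it,
#' weighted over hierarchy levels; the joint effect is the predictor's
#' single-variable R-squared minus its independent effect. The independent
#' effects sum exactly to the full-model R-squared.
#'
#' @param response Numeric response vector (e.g. pairwise adult disparity).
#' @param predictors Data frame or matrix of predictors (e.g. pairwise angle,
#'   absolute length difference, intercept distance).
#' @return Data frame: predictor, independent, joint, pct_independent
#'   (independent effect as a percentage of the summed independent effects),
#'   with attribute `R2_full`.
#' @export
hier_part <- function(response, predictors) {
  X <- as.matrix(as.data.frame(predictors))
  p <- ncol(X)
  if (p < 1L) stop("need at least one predictor")
  const <- apply(X, 2, function(col) var(col) == 0)
  if (any(const))
    warning("constant predictor(s): ",
            paste(colnames(X)[const], collapse = ", "),
            " (independent effect is 0)")
  y <- as.numeric(response)
  nsub <- 2^p
  r2 <- numeric(nsub)     # R2 by subset bitmask + 1
  for (mask in seq_len(nsub) - 1L) {
    subset <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0L)
    r2[mask + 1L] <- .r2_subset(y, X, subset)
  }
  indep <- numeric(p)
  for (k in seq_len(p)) {
    bit_k <- 2^(k - 1L)
    acc <- 0
    for (mask in seq_len(nsub) - 1L) {
      if (bitwAnd(mask, bit_k) > 0L) next
      s <- sum(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0L)
      w <- factorial(s) * factorial(p - s - 1L) / factorial(p)
      acc <- acc + w * (r2[mask + bit_k + 1L] - r2[mask + 1L])
    }
    indep[k] <- acc
  }
  alone <- vapply(seq_len(p), function(k) r2[2^(k - 1L) + 1L], 0)
  joint <- alone - indep
  out <- data.frame(predictor = colnames(X) %||% paste0("x", seq_len(p)),
                    independent = indep, joint = joint,
                    pct_independent = if (sum(indep) > 0)
                      indep / sum(indep) * 100 else rep(0, p))
  attr(out, "R2_full") <- r2[nsub]
  out
}

#' Pairwise trajectory-attribute table for hierarchical partitioning
#'
#' Assembles, over all species pairs, adult morphological disparity (distance
#' between predicted adult phenotypes) and the three trajectory-attribute
#' contrasts: angle (degrees), absolute length difference, and intercept
#' distance.
#'
#' @param data A [shape_data] object.
#' @param pw Result of [pairwise_trajectories()] (computed if `NULL`).
#' @param n_perm,seed Used when `pw` must be computed, and for the intercept
#'   distances.
#' @return Data frame with one row per unordered species pair.
#' @export
trajectory_attribute_table <- function(data, pw = NULL, n_perm = 999,
                                       seed = NULL) {
  if (is.null(pw)) pw <- pairwise_trajectories(data, n_perm, seed)
  fit <- pw$fit
  sps <- fit$species
  pairs <- t(combn(sps, 2))
  pa <- fit$trajectories$pred_adult
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    it <- intercept_test(data, c(a, b), n_perm = n_perm,
                         seed = if (is.null(seed)) NULL
                                else child_seed(seed, paste(a, b, sep = "|")))
    data.frame(species_1 = a, species_2 = b,
               disparity = sqrt(sum((pa[a, ] - pa[b, ])^2)),
               angle = pw$angles$statistic[a, b],
               length_diff = pw$lengths$statistic[a, b],
               intercept_dist = it$distance)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# ---------------------------------------------------------------------------
# Per-trait ontogenetic change

#' Sign and significance of per-trait ontogenetic change
#'
#' For linear datasets (log-shape-ratio slopes are interpretable trait by
#' trait), classifies each species' ontogenetic change in each trait as
#' relatively increasing, decreasing, or isometric, from the sign of the
#' univariate slope and a per-trait residual-randomization test of the size
#' effect. A negative slope for, e.g., relative tail length means the species
#' has a relatively longer tail as a juvenile.
#'
#' @param data A [shape_data] object (log-shape ratios).
#' @param trait_index Trait column indices to classify (default all).
#' @param alpha Significance level.
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @return Data frame: species, trait, slope, p, change
#'   (`"increases"`, `"decreases"`, `"isometric"`).
#' @export
ontogenetic_shift_table <- function(data, trait_index = NULL, alpha = 0.05,
                                    n_perm = 999, seed = NULL) {
  q <- ncol(data$Y)
  if (is.null(trait_index)) trait_index <- seq_len(q)
  if (any(trait_index < 1L | trait_index > q))
    stop("trait index out of range")
  sps <- sort(unique(data$species))
  traits <- colnames(data$Y) %||% paste0("trait", seq_len(q))
  rows <- list()
  for (sp in sps) {
    i <- data$species == sp
    s <- data$size[i]
    for (j in trait_index) {
      y <- data$Y[i, j, drop = FALSE]
      fit <- rrpp_model_test(y, cbind(1, s), matrix(1, sum(i), 1),
                             n_perm = n_perm,
                             seed = if (is.null(seed)) NULL
                                    else child_seed(seed,
                                      paste0("shift.", sp, ".", j)))
      beta <- qr.coef(qr(cbind(1, s)), y)[2, 1]
      change <- if (fit$p >= alpha || beta == 0) "isometric"
                else if (beta > 0) "increases" else "decreases"
      rows[[length(rows) + 1L]] <-
        data.frame(species = sp, trait = traits[j], slope = beta,
                   p = fit$p, change = change)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
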