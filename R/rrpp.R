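# Residual-randomization permutation machinery shared by all linear-model
# tests (distance-based statistics on multivariate shape data).

# Hat (projection) matrix of a design, via QR with rank detection.
.hat_matrix <- function(X) {
  qx <- qr(X)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  tcrossprod(Q)
}

.design_rank <- function(X) qr(X)$rank

# Permutation index matrix: first column is the identity (observed
# arrangement counts as one permutation: add-one rule).
.perm_indices <- function(n, n_perm, seed) {
  if (!is.null(seed)) set.seed(seed)
  cbind(seq_len(n),
        vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
}

#' Distance-based linear model test by residual randomization
#'
#' Compares a full against a nested reduced linear model for a multivariate
#' response using the distance-based (trace of cross-product) F statistic.
#' The null distribution is built by residual randomization: rows of the
#' reduced-model residuals are permuted, added back to the reduced-model
#' fitted values, and the statistic recomputed. The observed arrangement is
#' included in the null (add-one rule).
#'
#' @param Y Numeric response matrix (observations x variables).
#' @param X_full Full-model design matrix.
#' @param X_reduced Reduced-model design matrix (nested in the full model).
#' @param n_perm Number of random permutations.
#' @param seed Optional seed for the permutation stream.
#' @return List with `F` (observed statistic), `p`, `R2` (partial R-squared of
#'   the added terms relative to total SS), `df` (effect and residual df),
#'   `SS` (effect and residual sums of squares), and `n_permutations`.
#' @export
rrpp_model_test <- function(Y, X_full, X_reduced, n_perm = 999, seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Hf <- .hat_matrix(X_full)
  Hr <- .hat_matrix(X_reduced)
  rf <- .design_rank(X_full)
  rr <- .design_rank(X_reduced)
  df_eff <- rf - rr
  df_res <- n - rf
  if (df_eff < 1L) stop("full model does not add terms beyond the reduced model")
  if (df_res < 1L) stop("no residual degrees of freedom")
  A <- Hf - Hr             # effect projector
  B <- diag(n) - Hf        # full-model residual projector
  Fit_r <- Hr %*% Y
  Res_r <- Y - Fit_r
  perms <- .perm_indices(n, n_perm, seed)
  ss_tot <- sum(scale(Y, scale = FALSE)^2)
  # sums of squares at or below numerical noise are treated as exact zeros,
  # so degenerate (noise-free) responses give F = 0, not 0/0
  tol <- 1e-12 * max(sum(Y^2), .Machine$double.xmin)
  Fs <- numeric(ncol(perms))
  for (j in seq_len(ncol(perms))) {
    Yp <- Fit_r + Res_r[perms[, j], , drop = FALSE]
    ss_eff <- sum(Yp * (A %*% Yp))
    ss_res <- sum(Yp * (B %*% Yp))
    Fs[j] <- if (ss_res <= tol) {
      if (ss_eff <= tol) 0 else Inf
    } else {
      (ss_eff / df_eff) / (ss_res / df_res)
    }
  }
  ss_eff_obs <- sum(Y * (A %*% Y))
  ss_res_obs <- sum(Y * (B %*% Y))
  p <- mean(Fs >= Fs[1])
  list(F = Fs[1], p = p,
       R2 = if (ss_tot > 0) ss_eff_obs / ss_tot else 0,
       df = c(effect = df_eff, residual = df_res),
       SS = c(effect = ss_eff_obs, residual = ss_res_obs, total = ss_tot),
       n_permutations = n_perm)
}

#' Null statistics by residual randomization of a reduced model
#'
#' Generic engine for statistics that are functions of the response matrix:
#' permutes reduced-model residuals and evaluates `stat_fun` on each permuted
#' response. Row 1 of the result corresponds to the observed data.
#'
#' @param Y Response matrix.
#' @param X_reduced Reduced-model design matrix generating the null.
#' @param stat_fun Function `Y -> numeric vector` of statistics.
#' @param n_perm Number of random permutations.
#' @param seed Optional seed.
#' @return Matrix `(n_perm + 1) x n_stats`; first row observed.
#' @export
rrpp_null_stats <- function(Y, X_reduced, stat_fun, n_perm = 999, seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Hr <- .hat_matrix(X_reduced)
  Fit_r <- Hr %*% Y
  Res_r <- Y - Fit_r
  perms <- .perm_indices(n, n_perm, seed)
  s1 <- stat_fun(Y)
  out <- matrix(NA_real_, ncol(perms), length(s1))
  out[1, ] <- s1
  for (j in 2:ncol(perms)) {
    out[j, ] <- stat_fun(Fit_r + Res_r[perms[, j], , drop = FALSE])
  }
  colnames(out) <- names(s1)
  out
}

#' Null statistics by label permutation
#'
#' Permutes a grouping label vector (specimens keep their own response and
#' size values) and evaluates `stat_fun` on each permuted labelling. Row 1
#' corresponds to the observed labels.
#'
#' @param labels Grouping vector.
#' @param stat_fun Function `labels -> numeric vector`.
#' @param n_perm Number of random permutations.
#' @param seed Optional seed.
#' @return Matrix `(n_perm + 1) x n_stats`; first row observed.
#' @export
label_perm_stats <- function(labels, stat_fun, n_perm = 999, seed = NULL) {
  n <- length(labels)
  perms <- .perm_indices(n, n_perm, seed)
  s1 <- stat_fun(labels)
  out <- matrix(NA_real_, ncol(perms), length(s1))
  out[1, ] <- s1
  for (j in 2:ncol(perms)) out[j, ] <- stat_fun(labels[perms[, j]])
  colnames(out) <- names(s1)
  out
}

# Design matrices for the standard allometric models on a shape_data object.
# model: "size" (Y ~ size), "additive" (Y ~ size + species),
#        "unique" (Y ~ size * species), "null" (intercept only)
.allometry_design <- function(size, species, model) {
  n <- length(size)
  species <- factor(species)
  switch(model,
    null = matrix(1, n, 1),
    size = cbind(1, size),
    additive = {
      if (nlevels(species) < 2L) cbind(1, size)
      else cbind(1, size, stats::model.matrix(~ species)[, -1, drop = FALSE])
    },
    unique = {
      # species-wise intercept and slope columns; coefficients map directly
      # onto per-species (intercept, slope) pairs
      Xi <- stats::model.matrix(~ 0 + species)
      Xs <- Xi * size
      colnames(Xs) <- paste0(colnames(Xi), ":size")
      cbind(Xi, Xs)
    },
    stop("unknown model: ", model))
}
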