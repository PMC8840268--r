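# Juvenile-vs-adult comparative analyses: the D convergence/divergence test,
# multivariate Blomberg's K and the delta-K contrast, the simulation-based
# phylogenetic MANOVA, and phylomorphospace coordinates.

#' Per-species predicted stage shapes
#'
#' Extracts the predicted smallest-juvenile and largest-adult shapes from a
#' unique-allometry fit, as species-by-variables matrices.
#'
#' @param fit An `allometric_fit` (from [fit_unique_allometries()]).
#' @return List of class `stage_means`: `juvenile`, `adult` matrices and
#'   `species`.
#' @export
stage_means <- function(fit) {
  structure(list(juvenile = fit$trajectories$pred_juvenile,
                 adult = fit$trajectories$pred_adult,
                 species = fit$species),
            class = "stage_means")
}

.sum_pairwise_dist <- function(M) sum(dist(M))

#' Ontogenetic convergence/divergence test (D)
#'
#' Compares morphological disparity among predicted juvenile shapes (summed
#' pairwise Euclidean distances, `D_j`) with disparity among predicted adult
#' shapes (`D_a`); the statistic is `D = D_j - D_a`. Positive D means adults
#' are more similar than juveniles (ontogenetic convergence); negative D
#' means juveniles are more similar (divergence). The null randomizes
#' morphology with respect to size: each permutation draws two random
#' specimens per species as its juvenile and adult representatives. The
#' p-value is one-sided on the side of the observed sign.
#'
#' The test is designed for clades in which slope homogeneity has been
#' rejected; pass the clade's HOST p-value through `host_p` to enforce that
#' gate.
#'
#' @param data A [shape_data] object.
#' @param clade_species Optional species subset defining the clade.
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @param host_p Optional HOST p-value for the clade; if supplied and
#'   >= `alpha` the test refuses to run.
#' @param alpha Gate significance level.
#' @return List of class `d_result`: `D`, `D_j`, `D_a`, `p`,
#'   `n_permutations`.
#' @export
d_test <- function(data, clade_species = NULL, n_perm = 999, seed = NULL,
                   host_p = NULL, alpha = 0.05) {
  if (!is.null(host_p) && host_p >= alpha)
    stop("clade did not reject slope homogeneity (HOST p = ",
         signif(host_p, 3), "); D test not applicable")
  if (!is.null(clade_species)) data <- filter_species(data, clade_species)
  cnt <- species_counts(data)
  if (length(cnt) < 2L) stop("need at least 2 species")
  if (any(cnt < 2L))
    stop("species with < 2 specimens (null undrawable): ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  fit <- fit_unique_allometries(data, min_n = 2L)
  sm <- stage_means(fit)
  D_j <- .sum_pairwise_dist(sm$juvenile)
  D_a <- .sum_pairwise_dist(sm$adult)
  D <- D_j - D_a
  sp_idx <- split(seq_along(data$species), data$species)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(rep) {
    reps <- vapply(sp_idx, function(ii) sample(ii, 2L), integer(2))
    Dj <- .sum_pairwise_dist(data$Y[reps[1, ], , drop = FALSE])
    Da <- .sum_pairwise_dist(data$Y[reps[2, ], , drop = FALSE])
    Dj - Da
  }, 0)
  p <- if (D >= 0) permutation_pvalue(D, null, "greater")
       else permutation_pvalue(D, null, "less")
  structure(list(D = D, D_j = D_j, D_a = D_a, p = p,
                 n_permutations = n_perm),
            class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf("D test: D = %.4g (D_j = %.4g, D_a = %.4g), p = %.4g\n",
              x$D, x$D_j, x$D_a, x$p))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Phylogenetic signal

#' Multivariate Blomberg's K
#'
#' Ratio of the observed dispersion of tip values around the phylogenetic
#' (GLS) mean to the phylogenetically corrected dispersion, scaled by its
#' Brownian-motion expectation, generalized to multivariate data by summing
#' trait-wise cross-products. K = 1 is the Brownian expectation; K > 1 means
#' more signal than BM, K < 1 less. Significance by permuting tips.
#'
#' @param tree A `phylo` object with positive branch lengths.
#' @param X Tip data: matrix (rows named by tip) or named vector.
#' @param n_perm Number of tip permutations (0 skips the test).
#' @param seed Seed.
#' @return List: `K`, `p` (`NA` when `n_perm = 0`), `n_permutations`.
#' @export
k_mult <- function(tree, X, n_perm = 999, seed = NULL) {
  validate_phylogeny(tree)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1, dimnames = list(names(X)))
  X <- as.matrix(X)
  if (!is.null(rownames(X))) {
    if (!setequal(rownames(X), tree$tip.label))
      stop("tip data rows do not match tree tips")
    X <- X[tree$tip.label, , drop = FALSE]
  } else if (nrow(X) != length(tree$tip.label)) {
    stop("tip data rows do not match tree tips")
  }
  C <- ape::vcv(tree)
  Ci <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance matrix"))
  N <- nrow(X)
  e_bm <- (sum(diag(C)) - N / sum(Ci)) / (N - 1)
  k_stat <- function(Xp) {
    a <- colSums(Ci %*% Xp) / sum(Ci)
    Dv <- sweep(Xp, 2, a)
    num <- sum(Dv^2)
    den <- sum(Dv * (Ci %*% Dv))
    (num / den) / e_bm
  }
  K <- k_stat(X)
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i)
      k_stat(X[sample.int(N), , drop = FALSE]), 0)
    p <- permutation_pvalue(K, null, "greater")
  }
  list(K = K, p = p, n_permutations = n_perm)
}

#' Contrast of phylogenetic signal between growth stages (delta-K)
#'
#' Computes multivariate Blomberg's K for predicted adult shapes (`K_a`) and
#' predicted juvenile shapes (`K_j`) and their difference `delta_K = K_a -
#' K_j`. The null randomizes morphology with respect to size, drawing two
#' random specimens per species as stage representatives; `p` is the
#' proportion of permuted differences at least as large as the observed one.
#'
#' @param tree A `phylo` whose tips are the species in `data`.
#' @param data A [shape_data] object (>= 2 specimens per species).
#' @param fit Optional precomputed `allometric_fit`.
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @return List of class `delta_k_result`: `delta_K`, `K_a`, `K_j`, `p`,
#'   `n_permutations`.
#' @export
delta_k_test <- function(tree, data, fit = NULL, n_perm = 999, seed = NULL) {
  cnt <- species_counts(data)
  if (any(cnt < 2L))
    stop("species with < 2 specimens: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  if (is.null(fit)) fit <- fit_unique_allometries(data, min_n = 2L)
  sm <- stage_means(fit)
  K_a <- k_mult(tree, sm$adult, n_perm = 0)$K
  K_j <- k_mult(tree, sm$juvenile, n_perm = 0)$K
  dK <- K_a - K_j
  sp_idx <- split(seq_along(data$species), data$species)[fit$species]
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(rep) {
    reps <- vapply(sp_idx, function(ii) sample(ii, 2L), integer(2))
    J <- data$Y[reps[1, ], , drop = FALSE]
    A <- data$Y[reps[2, ], , drop = FALSE]
    rownames(J) <- rownames(A) <- fit$species
    k_mult(tree, A, n_perm = 0)$K - k_mult(tree, J, n_perm = 0)$K
  }, 0)
  structure(list(delta_K = dK, K_a = K_a, K_j = K_j,
                 p = permutation_pvalue(dK, null, "greater"),
                 n_permutations = n_perm),
            class = "delta_k_result")
}

#' @export
print.delta_k_result <- function(x, ...) {
  cat(sprintf("delta-K: K_a = %.3f, K_j = %.3f, dK = %.3f, p = %.4g\n",
              x$K_a, x$K_j, x$delta_K, x$p))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Simulation-based phylogenetic MANOVA

.seq_term_projectors <- function(designs) {
  # designs: list of nested design matrices X0 subset X1 subset ... Xm
  hats <- lapply(designs, .hat_matrix)
  ranks <- vapply(designs, .design_rank, 0L)
  m <- length(designs) - 1L
  lapply(seq_len(m), function(t)
    list(A = hats[[t + 1L]] - hats[[t]],
         df = ranks[t + 1L] - ranks[t]))
}

#' Phylogenetic MANOVA by Brownian simulation
#'
#' Tests the influence of size, habitat use, and their interaction on a
#' multivariate species-level response while accounting for phylogeny.
#' The response is reduced by covariance-based PCA to the smallest number of
#' components reaching the cumulative-variance threshold; sequential
#' (type I) distance-based F statistics are computed for each term; and the
#' null distribution of each F is obtained by simulating responses under a
#' multivariate Brownian-motion model whose rate matrix is estimated (ML)
#' from the retained components, keeping the predictors fixed.
#'
#' @param tree A `phylo`; tips must match the response rows.
#' @param Y Species-by-variables response matrix (rows named by species).
#' @param size Numeric per-species size covariate (e.g. log max SVL).
#' @param habitat Character/factor per-species habitat category.
#' @param n_sim Number of Brownian simulations.
#' @param retain Cumulative variance threshold for PC retention.
#' @param seed Seed.
#' @return Data frame of class `phylo_manova`: term, df, F, p, plus
#'   attributes `n_pcs` and `unstable_terms`.
#' @export
phylo_manova <- function(tree, Y, size, habitat, n_sim = 999,
                         retain = 0.95, seed = NULL) {
  validate_phylogeny(tree)
  Y <- as.matrix(Y)
  if (!is.null(rownames(Y))) {
    if (!setequal(rownames(Y), tree$tip.label))
      stop("response rows do not match tree tips")
    ord <- match(tree$tip.label, rownames(Y))
    Y <- Y[ord, , drop = FALSE]
    size <- size[ord]
    habitat <- habitat[ord]
  }
  if (all(apply(Y, 2, var) == 0))
    stop("response has zero variance across species")
  pc <- prcomp(Y, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= retain)[1]
  Z <- pc$x[, seq_len(k), drop = FALSE]
  habitat <- factor(habitat)
  unstable <- character()
  if (nlevels(habitat) > 1L) {
    tab <- table(habitat)
    if (any(tab < 2L)) unstable <- "size:habitat"
  }
  n <- nrow(Z)
  X0 <- matrix(1, n, 1)
  X1 <- cbind(X0, size)
  X2 <- if (nlevels(habitat) > 1L)
    cbind(X1, stats::model.matrix(~ habitat)[, -1, drop = FALSE]) else X1
  X3 <- if (nlevels(habitat) > 1L)
    cbind(X2, stats::model.matrix(~ size:habitat)[, -1, drop = FALSE]) else X2
  designs <- list(X0, X1, X2, X3)
  terms <- c("size", "habitat", "size:habitat")
  keep <- c(TRUE, nlevels(habitat) > 1L, nlevels(habitat) > 1L)
  projs <- .seq_term_projectors(designs)
  rk_full <- .design_rank(X3)
  df_res <- n - rk_full
  if (df_res < 1L) stop("no residual degrees of freedom")
  B <- diag(n) - .hat_matrix(X3)
  f_stats <- function(Zp) {
    tol <- 1e-12 * max(sum(Zp^2), .Machine$double.xmin)
    ss_res <- max(sum(Zp * (B %*% Zp)), 0)
    vapply(projs, function(pr) {
      if (pr$df == 0L) return(NA_real_)
      ss_eff <- sum(Zp * (pr$A %*% Zp))
      if (ss_res <= tol) {
        if (ss_eff <= tol) 0 else Inf
      } else {
        (ss_eff / pr$df) / (ss_res / df_res)
      }
    }, 0)
  }
  F_obs <- f_stats(Z)
  # ML Brownian rate matrix on the full response; each simulated dataset
  # replays the whole pipeline (PCA, retention, F), so the PC-truncation
  # step is part of the null distribution too
  q <- ncol(Y)
  C <- ape::vcv(tree)
  Ci <- solve(C)
  a <- colSums(Ci %*% Y) / sum(Ci)
  Dv <- sweep(Y, 2, a)
  R <- crossprod(Dv, Ci %*% Dv) / n
  cholC <- chol(C)
  cholR <- tryCatch(chol(R), error = function(e) {
    ev <- eigen(R, symmetric = TRUE)
    chol(ev$vectors %*% diag(pmax(ev$values, 1e-12), q) %*% t(ev$vectors))
  })
  if (!is.null(seed)) set.seed(seed)
  exceed <- rep(0, length(F_obs))
  for (s in seq_len(n_sim)) {
    G <- matrix(rnorm(n * q), n, q)
    Ys <- rep(1, n) %*% t(a) + t(cholC) %*% G %*% cholR
    pcs <- prcomp(Ys, center = TRUE, scale. = FALSE)
    ks <- which(cumsum(pcs$sdev^2) / sum(pcs$sdev^2) >= retain)[1]
    exceed <- exceed + (f_stats(pcs$x[, seq_len(ks), drop = FALSE]) >= F_obs)
  }
  p <- (exceed + 1) / (n_sim + 1)
  out <- data.frame(term = terms[keep],
                    df = vapply(projs, `[[`, 0L, "df")[keep],
                    F = F_obs[keep], p = p[keep])
  attr(out, "n_pcs") <- k
  attr(out, "unstable_terms") <- unstable
  class(out) <- c("phylo_manova", class(out))
  out
}

# ---------------------------------------------------------------------------
# Phylomorphospace

#' Phylomorphospace node coordinates
#'
#' Estimates internal-node coordinates for a 2D ordination (e.g. the first
#' two PCs of stage shapes, or of trajectory slopes for the
#' "phyloallomspace") by maximum-likelihood Brownian ancestral estimation,
#' and returns the edge list for plotting the tree in the ordination.
#'
#' @param tree A `phylo`.
#' @param tip_coords Tips-by-2 matrix, rows named by tip label.
#' @return List: `node_coords` ((n_tips + n_nodes) x 2 matrix, tips first),
#'   `edges` (the tree's edge matrix).
#' @export
phylomorphospace_coords <- function(tree, tip_coords) {
  validate_phylogeny(tree)
  tip_coords <- as.matrix(tip_coords)
  if (ncol(tip_coords) != 2L) stop("tip coordinates must be 2D")
  if (!is.null(rownames(tip_coords)))
    tip_coords <- tip_coords[tree$tip.label, , drop = FALSE]
  n <- length(tree$tip.label)
  anc <- apply(tip_coords, 2, function(v) {
    if (var(v) == 0) rep(v[1], tree$Nnode)
    else as.numeric(phytools::fastAnc(tree, setNames(v, tree$tip.label)))
  })
  coords <- rbind(tip_coords, anc)
  rownames(coords) <- c(tree$tip.label, n + seq_len(tree$Nnode))
  list(node_coords = coords, edges = tree$edge)
}

#' Composite habitat category per growth stage
#'
#' Returns the habitat label for a stage, or — for trajectory-level analyses
#' — a composite label in which species that shift habitat between stages
#' form their own category (e.g. `"trunk>terrestrial"`).
#'
#' @param habitat A `habitat_table`.
#' @param stage `"juvenile"`, `"adult"`, or `"composite"`.
#' @return Named character vector by species.
#' @export
stage_habitat <- function(habitat,
                          stage = c("juvenile", "adult", "composite")) {
  stage <- match.arg(stage)
  lab <- switch(stage,
    juvenile = habitat$juvenile_habitat,
    adult = habitat$adult_habitat,
    composite = ifelse(habitat$shift,
                       paste0(habitat$juvenile_habitat, ">",
                              habitat$adult_habitat),
                       habitat$adult_habitat))
  setNames(lab, habitat$species)
}
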