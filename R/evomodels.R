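# Trait-evolution model fitting on trajectory attributes: BM, multi-rate BM
# (non-censored), OU, multi-optimum OU, early burst, matching competition,
# and linear/exponential diversity dependence, compared by AICc weights.

# ---------------------------------------------------------------------------
# shared helpers

.align_trait <- function(tree, x) {
  x <- drop(x)
  if (!is.null(names(x))) {
    if (!setequal(names(x), tree$tip.label))
      stop("trait names do not match tree tips")
    x <- x[tree$tip.label]
  } else if (length(x) != length(tree$tip.label)) {
    stop("trait length does not match number of tips")
  }
  if (any(!is.finite(x))) stop("trait values must be finite")
  x
}

.data_fingerprint <- function(tree, x) {
  paste0(length(x), ":", signif(sum(x), 12), ":", signif(sum(x^2), 12), ":",
         signif(sum(tree$edge.length), 12))
}

# Gaussian log-likelihood with GLS-profiled mean (design W) and profiled
# overall scale: V = s * V0. Returns loglik at the ML scale plus estimates.
.profiled_mvn_ll <- function(x, V0, W) {
  n <- length(x)
  ch <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  logdet <- 2 * sum(log(diag(ch)))
  Wt <- backsolve(ch, W, transpose = TRUE)
  xt <- backsolve(ch, x, transpose = TRUE)
  beta <- tryCatch(qr.coef(qr(Wt), xt), error = function(e) NULL)
  if (is.null(beta)) return(list(ll = -Inf))
  beta[is.na(beta)] <- 0   # aliased (rank-deficient) mean columns pinned
  r <- xt - Wt %*% beta
  rss <- sum(r^2)
  s <- rss / n
  if (s <= 0) return(list(ll = -Inf))
  ll <- -0.5 * (n * log(2 * pi) + logdet + n * log(s) + n)
  list(ll = ll, scale = s, beta = drop(beta))
}

.aicc <- function(ll, k, n) {
  if (n <= k + 1) stop("AICc undefined: n <= k + 1")
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# shared-path durations per regime: for every tip pair, time spent in each
# regime on the path from the root to the pair's MRCA
.regime_shared_times <- function(tree) {
  regs <- painting_regimes(tree)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  parent <- rep(NA_integer_, nn)
  parent_edge <- rep(NA_integer_, nn)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    parent_edge[tree$edge[e, 2]] <- e
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  # per-node cumulative time in each regime from root to that node
  cum <- matrix(0, nn, length(regs), dimnames = list(NULL, regs))
  ord <- order(depth)
  for (v in ord) {
    if (v == root) next
    e <- parent_edge[v]
    cum[v, ] <- cum[parent[v], ]
    m <- tree$maps[[e]]
    for (r in names(m)) cum[v, r] <- cum[v, r] + m[r]
  }
  mrca <- ape::mrca(tree)
  out <- lapply(regs, function(r) {
    M <- matrix(cum[mrca, r], n, n,
                dimnames = list(tree$tip.label, tree$tip.label))
    diag(M) <- cum[seq_len(n), r]
    M
  })
  names(out) <- regs
  out
}

# per-tip regime weight matrix for the multi-optimum OU expectation:
# W[i, r] is the weight of optimum r in E[x_i], including the decayed root
# contribution assigned to the root regime
.oum_weights <- function(tree, alpha) {
  regs <- painting_regimes(tree)
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  parent_edge <- setNames(rep(NA_integer_, n + tree$Nnode), NULL)
  parent <- parent_edge
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    parent_edge[tree$edge[e, 2]] <- e
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  root_regime <- names(tree$maps[[which(tree$edge[, 1] == root)[1]]])[1]
  W <- matrix(0, n, length(regs), dimnames = list(tree$tip.label, regs))
  for (i in seq_len(n)) {
    Ti <- depth[i]
    # walk root -> tip collecting segment contributions
    path <- integer()
    v <- i
    while (v != root) { path <- c(parent_edge[v], path); v <- parent[v] }
    t0 <- 0
    for (e in path) {
      m <- tree$maps[[e]]
      for (sj in seq_along(m)) {
        t1 <- t0 + m[sj]
        W[i, names(m)[sj]] <- W[i, names(m)[sj]] +
          exp(-alpha * (Ti - t1)) - exp(-alpha * (Ti - t0))
        t0 <- t1
      }
    }
    W[i, root_regime] <- W[i, root_regime] + exp(-alpha * Ti)
  }
  W
}

# fixed-root OU among-tip covariance (up to sigma^2): root held at the
# optimum, so V -> BM's sigma^2 * C as alpha -> 0
.ou_cov <- function(alpha, Cshared, depth_tips) {
  Ti <- outer(depth_tips, depth_tips, "+")
  exp(-alpha * (Ti - 2 * Cshared)) * (1 - exp(-2 * alpha * Cshared)) /
    (2 * alpha)
}

# ---------------------------------------------------------------------------
# Gaussian (non-interaction) models

#' Fit a Gaussian trait-evolution model
#'
#' Maximum-likelihood fit of one of the classical Gaussian models of
#' continuous-trait evolution on a phylogeny, through the model-implied
#' among-tip covariance matrix:
#' * `BM` — Brownian motion (rate `sigma2`, root state).
#' * `BMS` — Brownian motion with one rate per regime of a branch painting
#'   (non-censored: a single root state, covariances accumulate per-regime
#'   time along shared paths).
#' * `OU` — Ornstein-Uhlenbeck with a single optimum; the root is held at
#'   the optimum (`root = "fixed"`, the default) so that the model nests BM
#'   continuously as `alpha -> 0`; `root = "stationary"` instead draws the
#'   root from the stationary distribution.
#' * `OUM` — OU with one optimum per regime of the painting (single `alpha`
#'   and `sigma2`).
#' * `EB` — early burst, rate decaying as `exp(r t)` with `r <= 0`.
#'
#' @param tree A `phylo`; `BMS`/`OUM` require a regime painting (`maps`).
#' @param x Named trait vector (tips).
#' @param model One of `"BM"`, `"BMS"`, `"OU"`, `"OUM"`, `"EB"`.
#' @param painting Optional painted tree carrying `maps` (defaults to `tree`
#'   itself when painted).
#' @param root Root treatment for OU-type models.
#' @param n_starts Number of random multi-starts for the optimizer.
#' @param seed Seed for the multi-start draws.
#' @return A `model_fit`: list with `model`, `parameters`, `logLik`, `k`,
#'   `AICc`, `n`, `convergence`.
#' @export
fit_gauss_model <- function(tree, x, model = c("BM", "BMS", "OU", "OUM", "EB"),
                            painting = NULL, root = c("fixed", "stationary"),
                            n_starts = 5L, seed = 1L) {
  model <- match.arg(model)
  root <- match.arg(root)
  validate_phylogeny(tree)
  x <- .align_trait(tree, x)
  n <- length(x)
  C <- ape::vcv(tree)
  depth_tips <- diag(C)
  ones <- matrix(1, n, 1)
  fp <- .data_fingerprint(tree, x)
  set.seed(seed)

  if (model == "BM") {
    pr <- .profiled_mvn_ll(x, C, ones)
    fit <- list(parameters = list(sigma2 = pr$scale, root_state = pr$beta),
                logLik = pr$ll, k = 2L, convergence = 0L)
  } else if (model == "EB") {
    obj <- function(r) {
      V0 <- if (abs(r) < 1e-12) C else expm1(r * C) / r
      -.profiled_mvn_ll(x, V0, ones)$ll
    }
    best <- .multistart_1d(obj, lower = -10 / max(depth_tips), upper = 0,
                           n_starts = n_starts)
    r <- best$par
    V0 <- if (abs(r) < 1e-12) C else expm1(r * C) / r
    pr <- .profiled_mvn_ll(x, V0, ones)
    fit <- list(parameters = list(sigma2 = pr$scale, r = r,
                                  root_state = pr$beta),
                logLik = pr$ll, k = 3L, convergence = best$convergence)
  } else if (model == "OU") {
    # stationary root: sigma^2/(2 alpha) exp(-alpha d_ij) with d the
    # patristic distance; fixed root: conditional OU covariance (nests BM)
    Dpat <- outer(depth_tips, depth_tips, "+") - 2 * C
    ou_v0 <- function(alpha) {
      if (root == "fixed") .ou_cov(alpha, C, depth_tips)
      else exp(-alpha * Dpat) / (2 * alpha)
    }
    obj <- function(la) .ou_neg_ll(x, ou_v0(exp(la)), ones)
    best <- .multistart_1d(obj, lower = log(1e-8), upper = log(50 / max(depth_tips)),
                           n_starts = n_starts)
    alpha <- exp(best$par)
    pr <- .profiled_mvn_ll(x, ou_v0(alpha), ones)
    fit <- list(parameters = list(sigma2 = pr$scale, alpha = alpha,
                                  theta = pr$beta),
                logLik = pr$ll, k = 3L, convergence = best$convergence)
  } else if (model == "BMS") {
    pt <- painting %||% tree
    if (is.null(pt$maps)) stop("BMS requires a regime painting")
    Sh <- .regime_shared_times(pt)
    Sh <- lapply(Sh, function(M) M[tree$tip.label, tree$tip.label])
    regs <- names(Sh)
    R <- length(regs)
    if (R == 1L) return(fit_gauss_model(tree, x, "BM", seed = seed))
    obj <- function(lr) {      # lr: log relative rates for regimes 2..R
      w <- c(1, exp(lr))
      V0 <- Reduce(`+`, Map(function(wi, Mi) wi * Mi, w, Sh))
      -.profiled_mvn_ll(x, V0, ones)$ll
    }
    best <- .multistart_nd(obj, dim = R - 1L, lower = -12, upper = 12,
                           n_starts = n_starts)
    w <- c(1, exp(best$par))
    V0 <- Reduce(`+`, Map(function(wi, Mi) wi * Mi, w, Sh))
    pr <- .profiled_mvn_ll(x, V0, ones)
    sig <- pr$scale * w
    names(sig) <- regs
    fit <- list(parameters = list(sigma2 = sig, root_state = pr$beta),
                logLik = pr$ll, k = R + 1L, convergence = best$convergence)
  } else { # OUM
    pt <- painting %||% tree
    if (is.null(pt$maps)) stop("OUM requires a regime painting")
    regs <- painting_regimes(pt)
    obj <- function(la) {
      alpha <- exp(la)
      V0 <- .ou_cov(alpha, C, depth_tips)
      W <- .oum_weights(pt, alpha)[tree$tip.label, , drop = FALSE]
      ll <- .profiled_mvn_ll(x, V0, W)$ll
      if (!is.finite(ll)) 1e10 else -ll
    }
    best <- .multistart_1d(obj, lower = log(1e-6), upper = log(50 / max(depth_tips)),
                           n_starts = n_starts)
    alpha <- exp(best$par)
    V0 <- .ou_cov(alpha, C, depth_tips)
    W <- .oum_weights(pt, alpha)[tree$tip.label, , drop = FALSE]
    pr <- .profiled_mvn_ll(x, V0, W)
    theta <- setNames(pr$beta, colnames(W))
    fit <- list(parameters = list(sigma2 = pr$scale, alpha = alpha,
                                  theta = theta),
                logLik = pr$ll, k = 2L + length(theta),
                convergence = best$convergence)
  }
  .finish_fit(fit, model, n, fp)
}

.ou_neg_ll <- function(x, V0, W) {
  ll <- .profiled_mvn_ll(x, V0, W)$ll
  if (!is.finite(ll)) 1e10 else -ll
}

.finish_fit <- function(fit, model, n, fp) {
  structure(list(model = model, parameters = fit$parameters,
                 logLik = fit$logLik, k = fit$k,
                 AICc = .aicc(fit$logLik, fit$k, n), AICcw = NA_real_,
                 n = n, convergence = fit$convergence,
                 data_fingerprint = fp),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit %s: logLik = %.4f, k = %d, AICc = %.4f%s\n",
              x$model, x$logLik, x$k, x$AICc,
              if (!is.na(x$AICcw)) sprintf(", AICcw = %.3f", x$AICcw) else ""))
  invisible(x)
}

.multistart_1d <- function(obj, lower, upper, n_starts = 5L) {
  starts <- unique(c(lower + (upper - lower) * 0.5,
                     runif(max(n_starts - 1L, 0L), lower, upper)))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(optim(s, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("optimizer failed for all starts")
  best
}

.multistart_nd <- function(obj, dim, lower, upper, n_starts = 5L) {
  starts <- c(list(rep(0, dim)),
              lapply(seq_len(max(n_starts - 1L, 0L)), function(i)
                runif(dim, lower, upper)))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(optim(s, obj, method = "L-BFGS-B",
                        lower = rep(lower, dim), upper = rep(upper, dim)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("optimizer failed for all starts")
  best
}

#' Brownian-motion log-likelihood at fixed parameters
#'
#' Evaluates the multivariate-normal log density of tip data under Brownian
#' motion with given rate and root state (no estimation), e.g. for checking
#' fitted models against directly constructed covariances.
#'
#' @param tree A `phylo`.
#' @param x Named trait vector.
#' @param sigma2 BM rate.
#' @param root_state Root state (trait units).
#' @return The log-likelihood.
#' @export
bm_loglik <- function(tree, x, sigma2, root_state) {
  x <- .align_trait(tree, x)
  V <- sigma2 * ape::vcv(tree)
  ch <- chol(V)
  r <- backsolve(ch, x - root_state, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
}

# ---------------------------------------------------------------------------
# lineage-interaction models (MC, DDl, DD2)

# Chronology of a (possibly non-binary) rooted tree: branching events in
# depth order, the set of alive edges in each inter-event epoch, and the
# descendant tip set of each edge.
.tree_chronology <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  children_edges <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  tipsets <- vector("list", nrow(tree$edge))
  # postorder accumulation of descendant tips per edge
  for (e in ape::postorder(tree)) {
    child <- tree$edge[e, 2]
    if (child <= n) tipsets[[e]] <- child
    else tipsets[[e]] <- unlist(tipsets[children_edges[[as.character(child)]]])
  }
  internal <- setdiff(unique(tree$edge[, 1]), root)
  events <- data.frame(node = internal, time = depth[internal])
  events <- events[order(events$time), , drop = FALSE]
  list(root = root, depth = depth, children_edges = children_edges,
       tipsets = tipsets, events = events, n_tips = n,
       height = max(depth[seq_len(n)]))
}

# lineage-level sympatry among alive edges: sympatric if any tip pair
# descending from the two edges co-occurs
.lineage_sympatry <- function(alive, tipsets, symp) {
  p <- length(alive)
  A <- diag(p)
  if (p > 1L) {
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      A[i, j] <- A[j, i] <-
        as.numeric(any(symp[tipsets[[alive[i]]], tipsets[[alive[j]]]] > 0))
    }
  }
  A
}

# Among-tip covariance (sigma^2 = 1) for MC / DDl / DD2; linear in the base
# rate, so the overall scale is profiled out in the likelihood.
.interaction_cov <- function(tree, model, par, symp, chron = NULL) {
  ch <- chron %||% .tree_chronology(tree)
  root <- ch$root
  alive <- ch$children_edges[[as.character(root)]]
  p <- length(alive)
  V <- matrix(0, p, p)
  t_now <- 0
  events <- rbind(ch$events, data.frame(node = NA, time = ch$height))
  for (ev in seq_len(nrow(events))) {
    dt <- events$time[ev] - t_now
    if (dt > 1e-12) {
      A <- .lineage_sympatry(alive, ch$tipsets, symp)
      if (model == "MC") {
        S <- par
        # S <= 0: deviations from the co-occurring mean are damped
        Psi <- diag(length(alive)) - sweep(A, 1, rowSums(A), "/")
        M <- S * Psi
        if (max(abs(M)) < 1e-14) {
          V <- V + dt * diag(length(alive))
        } else {
          deriv <- function(t, v, parms) {
            Vm <- matrix(v, length(alive))
            list(as.vector(M %*% Vm + Vm %*% t(M) + diag(length(alive))))
          }
          sol <- deSolve::ode(as.vector(V), c(0, dt), deriv, NULL,
                              method = "ode45")
          V <- matrix(sol[nrow(sol), -1], length(alive))
          V <- (V + t(V)) / 2
        }
      } else {
        ni <- rowSums(A)   # co-occurring lineage count, self included
        rate <- if (model == "DDl") pmax(1 + par * ni, 1e-8)
                else exp(par * ni)
        V <- V + dt * diag(rate, length(alive))
      }
    }
    t_now <- events$time[ev]
    if (!is.na(events$node[ev])) {
      # branching: replace the ending edge by the node's child edges
      node <- events$node[ev]
      end_edge <- which(tree$edge[, 2] == node)
      k <- match(end_edge, alive)
      kids <- ch$children_edges[[as.character(node)]]
      keep <- setdiff(seq_along(alive), k)
      newV <- matrix(0, length(keep) + length(kids),
                     length(keep) + length(kids))
      newV[seq_along(keep), seq_along(keep)] <- V[keep, keep, drop = FALSE]
      for (ki in seq_along(kids)) {
        r <- length(keep) + ki
        newV[r, seq_along(keep)] <- V[k, keep]
        newV[seq_along(keep), r] <- V[keep, k]
        for (kj in seq_along(kids))
          newV[r, length(keep) + kj] <- V[k, k]
      }
      alive <- c(alive[keep], kids)
      V <- newV
    }
  }
  tip_nodes <- tree$edge[alive, 2]
  ord <- order(tip_nodes)
  V <- V[ord, ord, drop = FALSE]
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  V
}

#' Fit a lineage-interaction trait-evolution model
#'
#' Maximum-likelihood fit of models in which co-occurring lineages influence
#' each other's trait evolution, with competition restricted to sympatric
#' taxa:
#' * `MC` — matching competition: each lineage's mean is attracted toward
#'   the mean trait of co-occurring lineages at rate `S <= 0`; the among-tip
#'   covariance is integrated through time (ODE) between branching events.
#' * `DDl` — diversity-dependent (linear): the BM rate varies as
#'   `sigma0^2 + b * n(t)`, with `n(t)` the lineage's co-occurring lineage
#'   count.
#' * `DD2` — diversity-dependent (exponential): rate `sigma0^2 * exp(b n(t))`.
#'
#' All three reduce to BM when `S = 0` / `b = 0`. The base rate is profiled
#' out analytically; the interaction parameter is optimized.
#'
#' @param tree Ultrametric `phylo`.
#' @param x Named trait vector.
#' @param model One of `"MC"`, `"DDl"`, `"DD2"`.
#' @param sympatry Binary species co-occurrence matrix (default: all
#'   sympatric).
#' @param n_starts Multi-start count for the 1D optimization.
#' @param seed Seed for multi-start draws.
#' @return A `model_fit` (k = 3: base rate, interaction parameter, root).
#' @export
fit_interaction_model <- function(tree, x, model = c("MC", "DDl", "DD2"),
                                  sympatry = NULL, n_starts = 5L, seed = 1L) {
  model <- match.arg(model)
  validate_phylogeny(tree, require_ultrametric = TRUE, tol = 1e-4)
  x <- .align_trait(tree, x)
  n <- length(x)
  if (is.null(sympatry)) {
    sympatry <- matrix(1, n, n, dimnames = list(tree$tip.label,
                                                tree$tip.label))
  } else {
    sympatry <- validate_sympatry(sympatry)[tree$tip.label, tree$tip.label]
  }
  chron <- .tree_chronology(tree)
  ones <- matrix(1, n, 1)
  fp <- .data_fingerprint(tree, x)
  set.seed(seed)
  obj <- function(par) {
    V0 <- tryCatch(.interaction_cov(tree, model, par, sympatry, chron),
                   error = function(e) NULL)
    if (is.null(V0)) return(1e10)
    ll <- .profiled_mvn_ll(x, V0, ones)$ll
    if (!is.finite(ll)) 1e10 else -ll
  }
  H <- chron$height
  bounds <- switch(model,
    MC = c(-20 / H, 0),
    DDl = c(-0.9 / n, 5 / n),    # keep rates positive over observed richness
    DD2 = c(-8 / n, 8 / n))
  best <- .multistart_1d(obj, lower = bounds[1], upper = bounds[2],
                         n_starts = n_starts)
  par <- best$par
  V0 <- .interaction_cov(tree, model, par, sympatry, chron)
  pr <- .profiled_mvn_ll(x, V0, ones)
  params <- switch(model,
    MC = list(sigma2 = pr$scale, S = par, root_state = pr$beta),
    DDl = list(sigma2_0 = pr$scale, b = par * pr$scale,
               root_state = pr$beta),
    DD2 = list(sigma2_0 = pr$scale, b = par, root_state = pr$beta))
  .finish_fit(list(parameters = params, logLik = pr$ll, k = 3L,
                   convergence = best$convergence),
              model, n, fp)
}

# ---------------------------------------------------------------------------
# model comparison

#' Compare fitted models by AICc weight
#'
#' Ranks a set of `model_fit`s fitted to the same data: computes AICc
#' differences to the best model and Akaike weights
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`.
#'
#' @param fits List of `model_fit` objects (same tree and trait).
#' @return Data frame sorted by AICc: model, k, logLik, AICc, delta_AICc,
#'   AICcw.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "model_fit")) fits <- list(fits)
  fps <- vapply(fits, `[[`, "", "data_fingerprint")
  if (length(unique(fps)) != 1L)
    stop("model fits were not computed on identical data")
  aicc <- vapply(fits, `[[`, 0, "AICc")
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = vapply(fits, `[[`, "", "model"),
                    k = vapply(fits, `[[`, 0L, "k"),
                    logLik = vapply(fits, `[[`, 0, "logLik"),
                    AICc = aicc, delta_AICc = delta, AICcw = w)
  out[order(out$AICc), , drop = FALSE]
}

#' Fit the full eight-model set to a trajectory attribute
#'
#' Convenience wrapper fitting BM, BMS, OU, OUM, EB, MC, DDl and DD2 to one
#' trait (trajectory lengths, or the first PC of the slopes) and comparing
#' them by AICc weight. BMS/OUM are skipped (with a message) when no painting
#' is available; MC/DDl/DD2 require an ultrametric tree.
#'
#' @param tree A `phylo` (painted for BMS/OUM).
#' @param x Named trait vector.
#' @param painting Optional painted tree.
#' @param sympatry Optional sympatry matrix.
#' @param n_starts,seed Passed to the fitters.
#' @return List: `fits` (named list of `model_fit`) and `table`
#'   (the [compare_models()] ranking).
#' @export
fit_evolution_models <- function(tree, x, painting = NULL, sympatry = NULL,
                                 n_starts = 5L, seed = 1L) {
  pt <- painting %||% (if (!is.null(tree$maps)) tree else NULL)
  fits <- list()
  for (m in c("BM", "OU", "EB"))
    fits[[m]] <- fit_gauss_model(tree, x, m, n_starts = n_starts, seed = seed)
  if (!is.null(pt)) {
    for (m in c("BMS", "OUM"))
      fits[[m]] <- fit_gauss_model(tree, x, m, painting = pt,
                                   n_starts = n_starts, seed = seed)
  } else {
    message("no regime painting supplied: skipping BMS and OUM")
  }
  for (m in c("MC", "DDl", "DD2"))
    fits[[m]] <- fit_interaction_model(tree, x, m, sympatry = sympatry,
                                       n_starts = n_starts, seed = seed)
  list(fits = fits, table = compare_models(fits))
}

#' First principal component of per-species slope vectors
#'
#' The direction of ontogenetic change summarized as the first PC
#' (covariance-based) of the species-by-variables slope matrix, for use as a
#' univariate trait in evolutionary model fitting.
#'
#' @param fit An `allometric_fit`.
#' @return Named numeric vector of PC1 scores by species.
#' @export
slopes_pc1 <- function(fit) {
  pc <- prcomp(fit$slopes, center = TRUE, scale. = FALSE)
  setNames(pc$x[, 1], fit$species)
}
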