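# Branch-specific evolutionary rates by phylogenetic ridge regression,
# clade rate-shift search, and robustness resampling under tree modification.

# branch incidence matrix: L[i, e] = length of edge e if e lies on the path
# from the root to tip/node i, else 0
.path_matrix <- function(tree, to = "tips") {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  parent <- parent_edge <- rep(NA_integer_, nn)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    parent_edge[tree$edge[e, 2]] <- e
  }
  targets <- if (to == "tips") seq_len(n) else seq_len(nn)
  L <- matrix(0, length(targets), nrow(tree$edge))
  for (ti in seq_along(targets)) {
    v <- targets[ti]
    while (!is.na(parent[v])) {
      e <- parent_edge[v]
      L[ti, e] <- tree$edge.length[e]
      v <- parent[v]
    }
  }
  rownames(L) <- if (to == "tips") tree$tip.label else NULL
  L
}

#' Branch-specific evolutionary rates by phylogenetic ridge regression
#'
#' Assigns a signed rate to every branch so that root-to-tip sums of
#' rate-times-branch-length reproduce the tip phenotypes, with an L2 penalty
#' on the rates: minimize `||y - root - L beta||^2 + lambda ||beta||^2`,
#' where `L` maps each branch on a root-to-tip path to its length. The root
#' state is the phylogenetic (GLS) mean; the penalty `lambda` is chosen by
#' leave-one-out cross-validated prediction error on the tips over a
#' log-spaced grid. Ancestral node states are partial path sums.
#'
#' When a covariate is supplied (typically the trait itself, to keep rates
#' from scaling with trait magnitude), log absolute rates are regressed on
#' the branch-wise covariate (mean of the parent and child node estimates of
#' the covariate's own ancestral reconstruction) and the residuals are
#' returned as the adjusted log rates.
#'
#' @param tree A `phylo`.
#' @param x Named trait vector over tips.
#' @param covariate Optional named vector over tips.
#' @param lambda Optional fixed penalty (skips cross-validation).
#' @param lambda_grid Log-spaced candidate penalties (relative to the mean
#'   squared singular value of `L`).
#' @return An object of class `rate_field`: `rates` (per edge, named by
#'   child node), `log_abs_rates` (covariate-adjusted when requested),
#'   `node_states` (ancestral estimates, tips included), `root`, `lambda`,
#'   `covariate_adjusted`, `cv_error`, and the `tree`.
#' @export
rr_rates <- function(tree, x, covariate = NULL, lambda = NULL,
                     lambda_grid = 10^seq(-4, 2, length.out = 25)) {
  validate_phylogeny(tree)
  x <- .align_trait(tree, x)
  n <- length(x)
  C <- ape::vcv(tree)
  Ci <- solve(C)
  root_state <- sum(Ci %*% x) / sum(Ci)
  yc <- x - root_state
  L <- .path_matrix(tree, "tips")
  sv <- svd(L)
  d2 <- sv$d^2
  uy <- crossprod(sv$u, yc)
  cv_err <- NA_real_
  if (is.null(lambda)) {
    grid <- lambda_grid * mean(d2)
    errs <- vapply(grid, function(lam) {
      shrink <- d2 / (d2 + lam)
      # leave-one-out residuals from the ridge hat matrix
      H <- sv$u %*% (shrink * t(sv$u))
      h <- diag(H)
      r <- yc - H %*% yc
      if (any(h >= 1 - 1e-10)) return(Inf)
      mean((r / (1 - h))^2)
    }, 0)
    if (all(!is.finite(errs)))
      stop("lambda search failed: no penalty gave finite leave-one-out ",
           "error (n = ", n, ", grid spans ", signif(min(grid), 3), "..",
           signif(max(grid), 3), ")")
    lambda <- grid[which.min(errs)]
    cv_err <- min(errs)
  }
  beta <- sv$v %*% (sv$d * uy / (d2 + lambda))
  beta <- drop(beta)
  Lnode <- .path_matrix(tree, "nodes")
  states <- drop(Lnode %*% beta) + root_state
  names(beta) <- tree$edge[, 2]
  log_abs <- log(pmax(abs(beta), 1e-12))
  adjusted <- FALSE
  if (!is.null(covariate)) {
    covariate <- .align_trait(tree, covariate)
    anc <- phytools::fastAnc(tree, covariate)
    cov_states <- c(covariate, as.numeric(anc))
    branch_cov <- (cov_states[tree$edge[, 1]] +
                   cov_states[tree$edge[, 2]]) / 2
    fitc <- lm.fit(cbind(1, branch_cov), log_abs)
    log_abs <- fitc$residuals
    adjusted <- TRUE
  }
  structure(list(rates = beta, log_abs_rates = setNames(log_abs,
                                                        tree$edge[, 2]),
                 node_states = states, root = root_state, lambda = lambda,
                 covariate_adjusted = adjusted, cv_error = cv_err,
                 tree = tree),
            class = "rate_field")
}

#' @export
print.rate_field <- function(x, ...) {
  cat(sprintf(
    "rate_field: %d branches, lambda = %.4g%s, root state = %.4g\n",
    length(x$rates), x$lambda,
    if (x$covariate_adjusted) " (covariate-adjusted)" else "", x$root))
  invisible(x)
}

# descendant tips of each internal node
.clade_tips <- function(tree) {
  n <- length(tree$tip.label)
  out <- vector("list", tree$Nnode)
  for (e in ape::postorder(tree)) {
    child <- tree$edge[e, 2]
    parent <- tree$edge[e, 1]
    add <- if (child <= n) child else out[[child - n]]
    out[[parent - n]] <- c(out[[parent - n]], add)
  }
  out
}

#' Search for clade-level rate shifts
#'
#' For every clade with at least `min_clade_size` species, compares the mean
#' absolute rate of the clade's branches with the mean background rate
#' (log-transforming rates is left to visualization; when a covariate was
#' regressed out in [rr_rates()], the adjusted log-rate residuals are the
#' comparable quantity and are used instead). The null distribution shuffles
#' rates across branches; `p` is the fraction of shuffled differences below
#' the observed one, so `p > 0.975` flags significantly higher clade rates
#' and `p < 0.025` significantly lower ones.
#'
#' @param field A `rate_field` from [rr_rates()].
#' @param min_clade_size Minimum species per tested clade.
#' @param n_perm Number of rate shuffles.
#' @param seed Seed.
#' @return Data frame of class `shift_report`: node, n_tips, clade_mean,
#'   background_mean, p, verdict (`"higher"`, `"lower"`, `"none"`).
#' @export
search_shift <- function(field, min_clade_size = 6L, n_perm = 1000L,
                         seed = NULL) {
  tree <- field$tree
  n <- length(tree$tip.label)
  rates <- if (field$covariate_adjusted) field$log_abs_rates
           else abs(field$rates)
  tips <- .clade_tips(tree)
  sizes <- lengths(tips)
  root_node <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  cand <- which(sizes >= min_clade_size & sizes < n) + n
  cand <- setdiff(cand, root_node)
  if (!length(cand)) {
    out <- data.frame(node = integer(), n_tips = integer(),
                      clade_mean = numeric(), background_mean = numeric(),
                      p = numeric(), verdict = character())
    class(out) <- c("shift_report", class(out))
    return(out)
  }
  # clade branch sets: all edges in the subtree plus the stem edge
  edge_in <- lapply(cand, function(v) {
    members <- c(tips[[v - n]], .clade_nodes(tree, v))
    which(tree$edge[, 2] %in% c(members, v))
  })
  if (!is.null(seed)) set.seed(seed)
  m <- length(rates)
  obs <- vapply(seq_along(cand), function(i) {
    inb <- edge_in[[i]]
    mean(rates[inb]) - mean(rates[-inb])
  }, 0)
  below <- ties <- numeric(length(cand))
  for (b in seq_len(n_perm)) {
    rp <- rates[sample.int(m)]
    for (i in seq_along(cand)) {
      inb <- edge_in[[i]]
      d <- mean(rp[inb]) - mean(rp[-inb])
      below[i] <- below[i] + (d < obs[i] - 1e-12)
      ties[i] <- ties[i] + (abs(d - obs[i]) <= 1e-12)
    }
  }
  p <- (below + 0.5 * ties) / n_perm   # mid-p rank; ties count half
  verdict <- ifelse(p > 0.975, "higher", ifelse(p < 0.025, "lower", "none"))
  out <- data.frame(node = cand, n_tips = sizes[cand - n],
                    clade_mean = vapply(seq_along(cand), function(i)
                      mean(rates[edge_in[[i]]]), 0),
                    background_mean = vapply(seq_along(cand), function(i)
                      mean(rates[-edge_in[[i]]]), 0),
                    p = p, verdict = verdict)
  class(out) <- c("shift_report", class(out))
  out
}

# internal nodes inside the clade rooted at v (excluding v)
.clade_nodes <- function(tree, v) {
  n <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == v, 2]
  out <- integer()
  while (length(kids)) {
    internal <- kids[kids > n]
    out <- c(out, internal)
    kids <- tree$edge[tree$edge[, 1] %in% internal, 2]
  }
  out
}

# jitter internal-node ages within their parent/child bracket, keeping the
# tree ultrametric-compatible; ages measured as depth from the root
.perturb_node_ages <- function(tree, frac, protected_nodes) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  internal <- setdiff(seq_len(tree$Nnode) + n,
                      setdiff(tree$edge[, 1], tree$edge[, 2])[1])
  internal <- setdiff(internal, protected_nodes)
  pick <- internal[runif(length(internal)) < frac]
  for (v in pick) {
    parent <- tree$edge[tree$edge[, 1] != 0 & tree$edge[, 2] == v, 1]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    lo <- depth[parent]
    hi <- min(depth[kids])
    if (hi - lo < 1e-9) next
    new_d <- runif(1, lo + 0.05 * (hi - lo), hi - 0.05 * (hi - lo))
    shift <- new_d - depth[v]
    ei <- which(tree$edge[, 2] == v)
    tree$edge.length[ei] <- tree$edge.length[ei] + shift
    ek <- which(tree$edge[, 1] == v)
    tree$edge.length[ek] <- tree$edge.length[ek] - shift
    depth[v] <- new_d
  }
  tree
}

#' Robustness of rate shifts to tree modification
#'
#' Re-evaluates detected rate shifts over `n_iter` modified trees: each
#' iteration removes a fraction of tips at random and jitters the ages of a
#' fraction of the remaining internal nodes within their parent/child
#' bracket; nodes whose posterior support exceeds `support_threshold` (from
#' the tree's `node_support` attribute) are protected from age perturbation.
#' Rates and shifts are re-estimated on each modified tree, and each original
#' shift counts as recovered when the MRCA of its surviving species is
#' flagged with the same verdict.
#'
#' @param tree A `phylo` (ideally with a `node_support` attribute).
#' @param x Named trait vector.
#' @param shifts A `shift_report` from [search_shift()] (rows with verdict
#'   `"none"` are ignored).
#' @param covariate Optional covariate passed to [rr_rates()].
#' @param n_iter Number of tree-modification iterations.
#' @param drop_frac Fraction of tips removed per iteration.
#' @param perturb_frac Fraction of internal nodes age-jittered per iteration.
#' @param min_clade_size,n_perm Passed to [search_shift()].
#' @param support_threshold Nodes above this support keep their age.
#' @param seed Seed.
#' @return Data frame: node, verdict, recovered, tested, proportion.
#' @export
overfit_rr <- function(tree, x, shifts, covariate = NULL, n_iter = 100L,
                       drop_frac = 0.25, perturb_frac = 0.25,
                       min_clade_size = 6L, n_perm = 1000L,
                       support_threshold = 0.95, seed = NULL) {
  sh <- shifts[shifts$verdict != "none", , drop = FALSE]
  if (n_iter == 0L || nrow(sh) == 0L) {
    return(data.frame(node = sh$node, verdict = sh$verdict,
                      recovered = integer(nrow(sh)),
                      tested = integer(nrow(sh)),
                      proportion = numeric(nrow(sh))))
  }
  x <- .align_trait(tree, x)
  n <- length(tree$tip.label)
  tips <- .clade_tips(tree)
  shift_tips <- lapply(sh$node, function(v) tree$tip.label[tips[[v - n]]])
  sup <- attr(tree, "node_support")
  protected <- if (is.null(sup)) integer()
               else which(!is.na(sup) & sup > support_threshold) + n
  if (!is.null(seed)) set.seed(seed)
  recovered <- tested <- integer(nrow(sh))
  for (it in seq_len(n_iter)) {
    drop_n <- max(1L, round(drop_frac * n))
    dropped <- sample(tree$tip.label, drop_n)
    tr2 <- ape::drop.tip(tree, dropped)
    if (is.null(tr2) || length(tr2$tip.label) < 2 * min_clade_size) next
    # map supported nodes onto the reduced tree via surviving tip sets;
    # monophyly of protected clades is preserved because modifications are
    # tip removals and bracket-respecting age jitters only
    prot2 <- integer()
    if (length(protected)) {
      prot2 <- unique(vapply(protected, function(v) {
        surv <- intersect(tree$tip.label[tips[[v - n]]], tr2$tip.label)
        if (length(surv) < 2L) NA_integer_ else ape::getMRCA(tr2, surv)
      }, integer(1)))
      prot2 <- prot2[!is.na(prot2)]
    }
    tr2 <- .perturb_node_ages(tr2, perturb_frac, prot2)
    f2 <- tryCatch(rr_rates(tr2, x[tr2$tip.label],
                            covariate = if (is.null(covariate)) NULL
                                        else covariate[tr2$tip.label]),
                   error = function(e) NULL)
    if (is.null(f2)) next
    s2 <- search_shift(f2, min_clade_size = min_clade_size, n_perm = n_perm,
                       seed = sample.int(2^30, 1))
    n2 <- length(tr2$tip.label)
    for (si in seq_len(nrow(sh))) {
      surv <- intersect(shift_tips[[si]], tr2$tip.label)
      if (length(surv) < min_clade_size) next
      tested[si] <- tested[si] + 1L
      node2 <- if (length(surv) == 1L) NA_integer_
               else ape::getMRCA(tr2, surv)
      hit <- s2$node == node2 & s2$verdict == sh$verdict[si]
      if (any(hit)) recovered[si] <- recovered[si] + 1L
    }
  }
  data.frame(node = sh$node, verdict = sh$verdict, recovered = recovered,
             tested = tested,
             proportion = ifelse(tested > 0, recovered / tested, NA_real_))
}
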