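# Synthetic-data generation: trees, habitat regimes, species-level
# trajectory parameters evolving on the tree, and individual-level
# ontogenetic series with the statistical structure the analyses assume.

#' Simulation specification
#'
#' Defines the conditions for a synthetic comparative-ontogeny dataset.
#' Defaults emulate a clade-scale museum study of lizard ontogenetic series:
#' tens of species with 5-50 specimens each spanning hatchling-to-adult size
#' ranges (about 1.8 natural-log units of growth), per-species
#' shape-on-size trajectories whose slope and intercept vectors evolve on a
#' pure-birth tree, six discrete habitat-use regimes evolving under a
#' symmetric Markov process, and isotropic Gaussian specimen noise on the
#' log-shape-ratio scale.
#'
#' @param n_species Number of species.
#' @param n_specimens Length-2 range; per-species specimen counts are drawn
#'   uniformly from it.
#' @param q_traits Number of shape variables.
#' @param tree_model Only `"pure-birth"` is implemented.
#' @param trait_model `"BM"` or `"OU"` for slope/intercept evolution.
#' @param sigma2_slope,sigma2_intercept BM rates (per unit tree height) of
#'   the slope and intercept vectors.
#' @param ou_alpha OU pull (used when `trait_model = "OU"`).
#' @param size_width Ontogenetic log-size span per species.
#' @param sigma2_size BM rate of the species' base (hatchling) log size.
#' @param noise_sd Specimen-level isotropic noise SD (log-shape units).
#' @param habitat_rate Transition rate of the habitat Markov process.
#' @param shift_fraction Fraction of species given an ontogenetic habitat
#'   shift (juvenile and adult categories differ); applied exactly.
#' @param landmarks Also emit 2D landmark configurations, produced by
#'   thin-plate-spline warping of a template curve (exercises the
#'   alignment and sliding machinery).
#' @param seed Master seed; the whole dataset is a deterministic function of
#'   the spec.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(n_species = 30L, n_specimens = c(5L, 50L), q_traits = 9L,
                     tree_model = "pure-birth", trait_model = c("BM", "OU"),
                     sigma2_slope = 0.01, sigma2_intercept = 0.01,
                     ou_alpha = 1, size_width = 1.8, sigma2_size = 0.3,
                     noise_sd = 0.05, habitat_rate = 0.5,
                     shift_fraction = 0.25, landmarks = FALSE, seed = 1L) {
  trait_model <- match.arg(trait_model)
  tree_model <- match.arg(tree_model, "pure-birth")
  if (n_species < 1L || q_traits < 1L) stop("counts must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(n_specimens) != 2L || any(n_specimens < 2L))
    stop("n_specimens must be a range with minimum >= 2")
  if (shift_fraction < 0 || shift_fraction > 1)
    stop("shift_fraction must lie in [0, 1]")
  structure(as.list(environment()), class = "sim_spec")
}

# multivariate BM / OU realization of a q-vector on a tree; returns a
# tips x q matrix. OU is simulated around the root value as optimum.
.sim_traits_on_tree <- function(tree, q, sigma2, model = "BM", alpha = 1,
                                root = rep(0, q)) {
  n <- length(tree$tip.label)
  C <- ape::vcv(tree)
  V <- if (model == "BM") {
    sigma2 * C
  } else {
    # conditional (root-anchored) OU covariance
    depth <- diag(C)
    sigma2 / (2 * alpha) *
      exp(-alpha * (outer(depth, depth, "+") - 2 * C)) *
      (1 - exp(-2 * alpha * C))
  }
  ch <- chol(V + diag(1e-12, n))
  X <- t(ch) %*% matrix(rnorm(n * q), n, q)
  sweep(X, 2, root, "+")
}

#' Simulate a full synthetic dataset
#'
#' Generates, deterministically from the spec's seed: a pure-birth tree
#' (scaled to unit height), species slope/intercept vectors evolving along
#' it, a habitat history with the requested fraction of ontogenetic habitat
#' shifts, and per-specimen ontogenetic series (size uniform over the
#' species range; shape = intercept + slope * size + isotropic noise).
#'
#' @param spec A [sim_spec()].
#' @return List of class `sim_dataset`: `shape` ([shape_data]), `tree`
#'   (`phylo`, unit height), `habitat` (`habitat_table`), and `truth`
#'   (generating tree, slope/intercept matrices, base sizes, habitat
#'   history).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  S <- spec$n_species
  q <- spec$q_traits
  tree <- ape::rphylo(S, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  tree$tip.label <- sprintf("sp%02d", seq_len(S))
  slopes <- .sim_traits_on_tree(tree, q, spec$sigma2_slope,
                                spec$trait_model, spec$ou_alpha,
                                root = rep(0.1, q))
  intercepts <- .sim_traits_on_tree(tree, q, spec$sigma2_intercept,
                                    spec$trait_model, spec$ou_alpha)
  rownames(slopes) <- rownames(intercepts) <- tree$tip.label
  base_size <- drop(.sim_traits_on_tree(tree, 1, spec$sigma2_size,
                                        "BM", root = 3))
  names(base_size) <- tree$tip.label
  # habitat: Markov juvenile state; exact shift fraction for adults
  cats <- habitat_categories()
  Q <- matrix(spec$habitat_rate / (length(cats) - 1), length(cats),
              length(cats), dimnames = list(cats, cats))
  diag(Q) <- -spec$habitat_rate
  juv <- as.character(ape::rTraitDisc(tree, model = Q,
                                      states = cats, root.value = 1))
  n_shift <- round(spec$shift_fraction * S)
  shifters <- sample(tree$tip.label, n_shift)
  adu <- setNames(juv, tree$tip.label)
  for (sp in shifters)
    adu[sp] <- sample(setdiff(cats, adu[sp]), 1)
  habitat <- as_habitat_table(data.frame(species = tree$tip.label,
                                         juvenile_habitat = juv,
                                         adult_habitat = unname(adu)))
  # specimen-level series
  counts <- sample(seq(spec$n_specimens[1], spec$n_specimens[2]), S,
                   replace = TRUE)
  rows <- sum(counts)
  Y <- matrix(NA_real_, rows, q,
              dimnames = list(NULL, paste0("trait", seq_len(q))))
  size <- numeric(rows)
  species <- character(rows)
  at <- 0L
  for (si in seq_len(S)) {
    sp <- tree$tip.label[si]
    ii <- at + seq_len(counts[si])
    s <- runif(counts[si], base_size[sp], base_size[sp] + spec$size_width)
    E <- if (spec$noise_sd > 0)
      matrix(rnorm(counts[si] * q, sd = spec$noise_sd), counts[si], q)
      else matrix(0, counts[si], q)
    Y[ii, ] <- rep(1, counts[si]) %*% t(intercepts[sp, ]) +
      s %*% t(slopes[sp, ]) + E
    size[ii] <- s
    species[ii] <- sp
    at <- at + counts[si]
  }
  lm_block <- NULL
  if (isTRUE(spec$landmarks)) {
    lm_block <- .emit_landmarks(species, size, slopes, spec$noise_sd)
  }
  structure(list(shape = shape_data(Y, size, species,
                                    dataset_tag = "synthetic"),
                 landmarks = lm_block,
                 tree = tree, habitat = habitat,
                 truth = list(tree = tree, slopes = slopes,
                              intercepts = intercepts,
                              base_size = base_size,
                              juvenile_habitat = setNames(juv,
                                                          tree$tip.label),
                              adult_habitat = adu,
                              shifters = shifters)),
            class = "sim_dataset")
}

# thin-plate-spline warp: map `points` under the deformation taking
# ctrl_src onto ctrl_dst
.tps_warp <- function(points, ctrl_src, ctrl_dst) {
  m <- nrow(ctrl_src)
  U <- function(r2) ifelse(r2 == 0, 0, r2 * log(r2)) / 2
  D2 <- as.matrix(dist(ctrl_src))^2
  K <- U(D2)
  Q <- cbind(1, ctrl_src)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  W <- solve(L, rbind(ctrl_dst - ctrl_src, matrix(0, 3, 2)))
  d2 <- outer(rowSums(points^2), rowSums(ctrl_src^2), "+") -
    2 * points %*% t(ctrl_src)
  d2[d2 < 0] <- 0
  points + U(d2) %*% W[seq_len(m), , drop = FALSE] +
    cbind(1, points) %*% W[m + 1:3, , drop = FALSE]
}

# landmark configurations per specimen: a semicircular template warped by a
# species-level TPS deformation (driven by the species slope vector, scaled
# by specimen size) plus isotropic digitising noise
.emit_landmarks <- function(species, size, slopes, noise_sd, k = 12L) {
  th <- seq(0, pi, length.out = k)
  template <- cbind(cos(th), sin(th))
  ctrl <- rbind(c(-1, 0), c(1, 0), c(0, 1), c(-0.5, 0.5), c(0.5, 0.5))
  n <- length(species)
  A <- array(0, c(n, k, 2))
  sps <- rownames(slopes)
  for (i in seq_len(n)) {
    v <- slopes[match(species[i], sps), ]
    amp <- 0.2 * tanh(v[seq_len(min(10, length(v)))])
    amp <- c(amp, rep(0, 10 - length(amp)))
    disp <- 0.3 * matrix(amp, 5, 2) * size[i] / max(abs(size) + 1e-9)
    A[i, , ] <- .tps_warp(template, ctrl, ctrl + disp) +
      matrix(rnorm(2 * k, sd = noise_sd * 0.2), k, 2)
  }
  sliders <- cbind(2:(k - 3), 3:(k - 2), 4:(k - 1))
  landmark_block(A, specimen_id = paste0("lm", seq_len(n)),
                 species = species, sliders = sliders)
}

#' Constructed species pairs realizing each trajectory-evolution scenario
#'
#' Builds one [shape_data] object containing labelled species pairs, each
#' engineered to land in a known cell of the trajectory/heterochrony
#' classification:
#' * `truncation` — same line in size-shape space, one species stopping at a
#'   fraction of the other's size range (peramorphosis by the geometric
#'   path; ontogenetic scaling by the overlap path).
#' * `dissociation` — the same shape trajectory occupied at shifted sizes
#'   (intercept offset along the shared slope; size-shape dissociation).
#' * `rotated` — slope vectors at a wide angle (slope shift).
#' * `parallel` — equal slopes, intercepts offset orthogonally to the slope
#'   (parallel trajectories; no shape-space overlap).
#' * `identical` — one distribution under two labels (conserved;
#'   ontogenetic scaling).
#'
#' @param n Specimens per species.
#' @param q Number of shape variables (>= 2).
#' @param noise_sd Specimen noise SD.
#' @param seed Seed.
#' @return List: `data` ([shape_data]) and `expected` (data frame: pair
#'   label, species names, expected classification on each decision path).
#' @export
make_heterochrony_fixtures <- function(n = 30L, q = 4L, noise_sd = 0.02,
                                       seed = 1L) {
  stopifnot(q >= 2L)
  set.seed(seed)
  v <- c(1, rep(0, q - 1))          # shared slope direction
  w <- c(0, 1, rep(0, q - 2))       # direction orthogonal to v
  gen <- function(sp, intercept, slope, smin, smax) {
    s <- runif(n, smin, smax)
    Y <- rep(1, n) %*% t(intercept) + s %*% t(slope) +
      matrix(rnorm(n * q, sd = noise_sd), n, q)
    list(Y = Y, size = s, species = rep(sp, n))
  }
  rot <- v * cos(pi / 3) + w * sin(pi / 3)
  parts <- list(
    gen("trunc_a", rep(0, q), v, 0, 2),
    gen("trunc_b", rep(0, q), v, 0, 1.2),
    gen("dissoc_a", rep(0, q), v, 0, 1.5),
    gen("dissoc_b", -0.8 * v, v, 0.8, 2.3),
    gen("rot_a", rep(0, q), v, 0, 2),
    gen("rot_b", rep(0, q), rot, 0, 2),
    gen("par_a", rep(0, q), v, 0, 2),
    gen("par_b", 0.5 * w, v, 0, 2))
  # identical pair: one sample duplicated under two labels
  ident <- gen("ident_a", rep(0, q), v, 0, 2)
  parts <- c(parts, list(ident,
                         list(Y = ident$Y, size = ident$size,
                              species = rep("ident_b", n))))
  data <- shape_data(do.call(rbind, lapply(parts, `[[`, "Y")),
                     unlist(lapply(parts, `[[`, "size")),
                     unlist(lapply(parts, `[[`, "species")),
                     dataset_tag = "fixtures")
  expected <- data.frame(
    pair = c("truncation", "dissociation", "rotated", "parallel",
             "identical"),
    species_1 = c("trunc_a", "dissoc_a", "rot_a", "par_a", "ident_a"),
    species_2 = c("trunc_b", "dissoc_b", "rot_b", "par_b", "ident_b"),
    category = c("peramorphosis_paedomorphosis", "parallel_intercept_shift",
                 "slope_shift", "parallel_intercept_shift", "conserved"),
    heterochrony = c("ontogenetic_scaling", "size_shape_dissociation",
                     "none", "none", "ontogenetic_scaling"))
  list(data = data, expected = expected)
}

#' Ontogenetic convergence/divergence fixture
#'
#' Constructs species whose predicted juvenile shapes lie within a unit
#' radius and whose predicted adult shapes lie within radius
#' `1 + divergence_strength`: positive strength makes adults more disparate
#' (ontogenetic divergence, D < 0), negative strength (> -1) makes adults
#' tighter (convergence, D > 0).
#'
#' @param n_species Number of species (>= 3).
#' @param divergence_strength Relative inflation of the adult shape cloud.
#' @param n Specimens per species.
#' @param q Shape variables.
#' @param noise_sd Specimen noise SD.
#' @param seed Seed.
#' @return A [shape_data] object; attribute `truth` stores the generating
#'   juvenile and adult shape matrices.
#' @export
make_divergence_fixture <- function(n_species = 20L, divergence_strength = 5,
                                    n = 10L, q = 4L, noise_sd = 0.05,
                                    seed = 1L) {
  if (n_species < 3L) stop("need at least 3 species")
  if (divergence_strength <= -1) stop("divergence_strength must be > -1")
  set.seed(seed)
  dirs <- matrix(rnorm(n_species * q), n_species, q)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  r_j <- runif(n_species)
  juv <- dirs * r_j
  adu <- dirs * r_j * (1 + divergence_strength)
  sps <- sprintf("sp%02d", seq_len(n_species))
  Y <- NULL; size <- NULL; species <- NULL
  for (i in seq_len(n_species)) {
    s <- runif(n, 0, 1)
    Yi <- rep(1, n) %*% t(juv[i, ]) + s %*% t(adu[i, ] - juv[i, ]) +
      matrix(rnorm(n * q, sd = noise_sd), n, q)
    Y <- rbind(Y, Yi)
    size <- c(size, s)
    species <- c(species, rep(sps[i], n))
  }
  out <- shape_data(Y, size, species, dataset_tag = "divergence_fixture")
  attr(out, "truth") <- list(juvenile = juv, adult = adu)
  out
}
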