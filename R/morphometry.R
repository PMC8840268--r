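# Conversion of raw measurements into size-corrected shape data:
# log-shape ratios for linear data; GPA + semilandmark sliding + object
# symmetry for 2D landmark data; sexual-dimorphism filtering.

# ---------------------------------------------------------------------------
# Log-shape ratios

#' Log-shape ratios from linear measurement tables
#'
#' Computes per-specimen size as the natural log of the geometric mean of all
#' measurements — pooling the two tables for specimens present in both, so
#' body and limb shape share a common size axis — then expresses shape as the
#' log of each trait divided by the specimen's geometric mean.
#' Specimens present in only one table fall back to the geometric mean of
#' their available traits (with a warning naming them).
#'
#' @param body A `linear_table` of body measurements.
#' @param limbs Optional `linear_table` of limb measurements.
#' @return A list with `body` and (if supplied) `limbs` entries, each a
#'   [shape_data] object whose `size` is the log combined geometric mean.
#' @export
log_shape_ratios <- function(body, limbs = NULL) {
  tabs <- list(body = body, limbs = limbs)
  tabs <- tabs[!vapply(tabs, is.null, TRUE)]
  logs <- lapply(tabs, function(tab) {
    tm <- as.matrix(tab[attr(tab, "traits")])
    if (any(tm <= 0)) stop("all trait values must be strictly positive")
    rownames(tm) <- tab$specimen_id
    log(tm)
  })
  ids <- unique(unlist(lapply(tabs, `[[`, "specimen_id")))
  # log GM = mean of log traits over the combined trait set
  size <- setNames(numeric(length(ids)), ids)
  for (id in ids) {
    vals <- unlist(lapply(logs, function(lt)
      if (id %in% rownames(lt)) lt[id, ] else NULL))
    size[id] <- mean(vals)
  }
  if (length(tabs) == 2L) {
    only <- ids[!(ids %in% tabs[[1]]$specimen_id &
                  ids %in% tabs[[2]]$specimen_id)]
    if (length(only))
      warning(length(only), " specimen(s) present in one table only; ",
              "size falls back to the geometric mean of available traits: ",
              paste(head(only, 5), collapse = ", "),
              if (length(only) > 5) ", ..." else "")
  }
  out <- lapply(names(tabs), function(nm) {
    tab <- tabs[[nm]]
    lt <- logs[[nm]]
    s <- size[tab$specimen_id]
    shape_data(lt - s, s, tab$species, tab$sex, dataset_tag = nm)
  })
  names(out) <- names(tabs)
  out
}

# ---------------------------------------------------------------------------
# Landmark blocks

#' Construct a landmark block
#'
#' @param coords Array `n_specimens x n_landmarks x 2` of raw 2D coordinates.
#' @param specimen_id,species,sex Per-specimen labels.
#' @param fixed_idx Indices of fixed landmarks.
#' @param sliders Matrix with columns `before, slider, after`: each
#'   semilandmark and the neighbours defining its tangent. `NULL` for none.
#' @param symmetry_pairs Matrix with two columns: left/right paired landmark
#'   indices. `NULL` if symmetry is not used.
#' @param midline_idx Indices of unpaired midline landmarks.
#' @return An object of class `landmark_block`.
#' @export
landmark_block <- function(coords, specimen_id = NULL, species = NULL,
                           sex = NULL, fixed_idx = NULL, sliders = NULL,
                           symmetry_pairs = NULL, midline_idx = integer()) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 2L)
  n <- dim(coords)[1]
  k <- dim(coords)[2]
  if (is.null(specimen_id)) specimen_id <- paste0("spec", seq_len(n))
  if (is.null(species)) species <- rep("sp", n)
  if (is.null(sex)) sex <- rep("unknown", n)
  if (!is.null(sliders)) {
    sliders <- matrix(as.integer(sliders), ncol = 3L,
                      dimnames = list(NULL, c("before", "slider", "after")))
    if (any(sliders < 1L | sliders > k))
      stop("slider neighbour triples reference invalid landmark indices")
  }
  if (!is.null(symmetry_pairs)) {
    symmetry_pairs <- matrix(as.integer(symmetry_pairs), ncol = 2L)
    if (length(intersect(as.vector(symmetry_pairs), midline_idx)))
      stop("symmetry pairs must be disjoint from midline landmarks")
    paired <- sort(c(as.vector(symmetry_pairs), midline_idx))
    if (!identical(paired, seq_len(k)[seq_along(paired)]) &&
        length(paired) == k && anyDuplicated(paired))
      stop("symmetry pairing is inconsistent")
  }
  structure(list(coords = coords, specimen_id = specimen_id,
                 species = species, sex = sex,
                 fixed_idx = fixed_idx %||% setdiff(seq_len(k),
                   if (is.null(sliders)) integer() else sliders[, "slider"]),
                 sliders = sliders, symmetry_pairs = symmetry_pairs,
                 midline_idx = midline_idx),
            class = "landmark_block")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.landmark_block <- function(x, ...) {
  cat(sprintf("landmark_block: %d specimens, %d landmarks (%d sliding)\n",
              dim(x$coords)[1], dim(x$coords)[2],
              if (is.null(x$sliders)) 0L else nrow(x$sliders)))
  invisible(x)
}

#' Read landmarks from a TPS file
#'
#' Minimal reader for the TPS layout: `LM=<k>` followed by `k` lines of
#' `x y`, with optional `ID=` / `IMAGE=` lines per specimen.
#'
#' @param path TPS file path.
#' @param ... Passed to [landmark_block()] (slider/pair definitions).
#' @return A `landmark_block`.
#' @export
read_tps <- function(path, ...) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no LM= records found in TPS file")
  configs <- list()
  ids <- character()
  for (si in seq_along(starts)) {
    i <- starts[si]
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[i], ignore.case = TRUE))
    block <- lines[(i + 1):(i + k)]
    xy <- do.call(rbind, lapply(strsplit(block, "\\s+"), as.numeric))
    if (ncol(xy) != 2L) stop("TPS record ", si, " is not 2D")
    configs[[si]] <- xy
    end <- if (si < length(starts)) starts[si + 1] - 1 else length(lines)
    idl <- grep("^ID\\s*=", lines[(i + k):end], ignore.case = TRUE, value = TRUE)
    ids[si] <- if (length(idl)) sub("^ID\\s*=\\s*", "", idl[1],
                                    ignore.case = TRUE) else paste0("spec", si)
  }
  ks <- vapply(configs, nrow, 0L)
  if (length(unique(ks)) != 1L)
    stop("TPS records have differing landmark counts")
  coords <- aperm(simplify2array(configs), c(3, 1, 2))
  landmark_block(coords, specimen_id = ids, ...)
}

.centroid_size <- function(X) {
  sqrt(sum(scale(X, scale = FALSE)^2))
}

# Optimal rotation (no reflection) aligning X onto M, both centered.
.opt_rotation <- function(X, M) {
  S <- crossprod(X, M)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

#' Generalized Procrustes analysis
#'
#' Removes location, scale and orientation from a set of 2D landmark
#' configurations: each is centred, scaled to unit centroid size, and rotated
#' (rotations only, no reflection) to minimise summed squared distances to an
#' iteratively updated mean shape. Iteration stops when the mean shape moves
#' by less than `tol` (root summed squared change).
#'
#' @param block A `landmark_block`.
#' @param tol Convergence tolerance on the mean shape (default 1e-8).
#' @param max_iter Maximum number of iterations.
#' @return List with `block` (the aligned `landmark_block`) and
#'   `centroid_sizes` (pre-scaling centroid size per specimen).
#' @export
gpa <- function(block, tol = 1e-8, max_iter = 100L) {
  A <- block$coords
  n <- dim(A)[1]; k <- dim(A)[2]
  if (n < 2L) stop("GPA needs at least 2 specimens")
  if (k < 3L) stop("GPA needs at least 3 landmarks")
  cs <- numeric(n)
  for (i in seq_len(n)) {
    X <- scale(A[i, , ], scale = FALSE)
    cs[i] <- sqrt(sum(X^2))
    if (cs[i] < .Machine$double.eps * k)
      stop("degenerate configuration (all landmarks coincident): specimen ", i)
    A[i, , ] <- X / cs[i]
  }
  M <- A[1, , ]
  M <- M / sqrt(sum(M^2))
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n)) A[i, , ] <- A[i, , ] %*% .opt_rotation(A[i, , ], M)
    Mn <- apply(A, c(2, 3), mean)
    Mn <- scale(Mn, scale = FALSE)
    Mn <- Mn / sqrt(sum(Mn^2))
    delta <- sqrt(sum((Mn - M)^2))
    M <- Mn
    if (delta < tol) break
  }
  out <- block
  out$coords <- A
  attr(out, "mean_shape") <- M
  list(block = out, centroid_sizes = cs)
}

#' Mean shape of an aligned block
#' @param block An aligned `landmark_block`.
#' @return `k x 2` matrix.
#' @export
mean_shape <- function(block) apply(block$coords, c(2, 3), mean)

# Thin-plate-spline bending energy matrix of a 2D reference configuration
# (upper-left k x k block of the inverse TPS system matrix).
.bending_energy_matrix <- function(M) {
  k <- nrow(M)
  D2 <- as.matrix(dist(M))^2
  K <- ifelse(D2 == 0, 0, D2 * log(D2)) / 2  # r^2 log r = (r^2 log r^2)/2
  Q <- cbind(1, M)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Li <- solve(L)
  Li[seq_len(k), seq_len(k), drop = FALSE]
}

#' Total bending energy of a block relative to its mean shape
#' @param block Aligned `landmark_block`.
#' @return Summed thin-plate-spline bending energy across specimens.
#' @export
total_bending_energy <- function(block) {
  M <- mean_shape(block)
  Be <- .bending_energy_matrix(M)
  tot <- 0
  for (i in seq_len(dim(block$coords)[1])) {
    V <- block$coords[i, , ] - M
    tot <- tot + sum(V * (Be %*% V))
  }
  tot
}

#' Slide semilandmarks by bending-energy minimisation
#'
#' Displaces each semilandmark along its local tangent direction (central
#' difference between its neighbour triple on the specimen's own
#' configuration) so that the thin-plate-spline bending energy relative to
#' the current mean shape is minimised, re-runs GPA, and iterates the two
#' steps to joint convergence.
#'
#' @param aligned A GPA-aligned `landmark_block` with slider triples.
#' @param max_outer Maximum outer (slide + GPA) iterations.
#' @param tol Convergence tolerance on the total bending energy.
#' @param re_align Re-run GPA after each slide pass (default). Disabling it
#'   exposes the raw slid positions of a single pass, e.g. for checking the
#'   tangent solve against direct minimisation.
#' @return The slid and re-aligned `landmark_block`, with attribute
#'   `energy_path` recording total bending energy after each outer iteration.
#' @export
slide_semilandmarks <- function(aligned, max_outer = 5L, tol = 1e-8,
                                re_align = TRUE) {
  block <- aligned
  if (is.null(block$sliders) || nrow(block$sliders) == 0L) return(block)
  energy <- total_bending_energy(block)
  path <- energy
  for (outer in seq_len(max_outer)) {
    prev <- block
    M <- mean_shape(block)
    Be <- .bending_energy_matrix(M)
    sl <- block$sliders
    m <- nrow(sl)
    n <- dim(block$coords)[1]
    for (i in seq_len(n)) {
      X <- block$coords[i, , ]
      U <- matrix(0, m, 2)
      for (s in seq_len(m)) {
        tang <- X[sl[s, "after"], ] - X[sl[s, "before"], ]
        nt <- sqrt(sum(tang^2))
        if (nt < 1e-12)
          stop("undefined tangent (coincident neighbours) at landmark ",
               sl[s, "slider"])
        U[s, ] <- tang / nt
      }
      V <- X - M
      idx <- sl[, "slider"]
      # quadratic in slide amounts t: sum_c (v_c + Ec t)' Be (v_c + Ec t)
      Bs <- Be[idx, idx, drop = FALSE]
      G <- (U %*% t(U)) * Bs                      # m x m system matrix
      rhs <- -rowSums(U * (Be[idx, , drop = FALSE] %*% V))
      t_amt <- tryCatch(solve(G, rhs), error = function(e)
        MASS_ginv_solve(G, rhs))
      Xnew <- X
      Xnew[idx, ] <- X[idx, ] + t_amt * U
      block$coords[i, , ] <- Xnew
    }
    if (re_align) block <- gpa(block)$block
    new_energy <- total_bending_energy(block)
    # converged: a pass that no longer lowers the energy is discarded
    if (re_align && new_energy > energy) { block <- prev; break }
    path <- c(path, new_energy)
    if (energy - new_energy < tol) { energy <- new_energy; break }
    energy <- new_energy
  }
  attr(block, "energy_path") <- path
  block
}

# Pseudo-inverse fallback for (near-)singular slide systems.
MASS_ginv_solve <- function(G, rhs) {
  sv <- svd(G)
  pos <- sv$d > max(sv$d) * 1e-10
  drop(sv$v[, pos, drop = FALSE] %*%
         ((t(sv$u[, pos, drop = FALSE]) %*% rhs) / sv$d[pos]))
}

#' Symmetric component of shape
#'
#' For configurations with object symmetry, averages each configuration with
#' its reflected and relabelled copy: the copy is mirrored (x negated),
#' paired landmarks are swapped, the copy is rigidly aligned back onto the
#' original (rotation + translation, no reflection), and the two are
#' averaged. The symmetrised block is then re-aligned by GPA.
#'
#' @param aligned A GPA-aligned `landmark_block` with `symmetry_pairs` (and
#'   optionally `midline_idx`) defined.
#' @return The symmetrised, re-aligned `landmark_block`.
#' @export
symmetric_component <- function(aligned) {
  block <- aligned
  if (is.null(block$symmetry_pairs))
    stop("block has no symmetry pairs defined")
  k <- dim(block$coords)[2]
  paired <- c(as.vector(block$symmetry_pairs), block$midline_idx)
  if (length(unique(paired)) != k)
    stop("unpaired non-midline landmark(s): ",
         paste(setdiff(seq_len(k), paired), collapse = ", "))
  relabel <- seq_len(k)
  relabel[block$symmetry_pairs[, 1]] <- block$symmetry_pairs[, 2]
  relabel[block$symmetry_pairs[, 2]] <- block$symmetry_pairs[, 1]
  for (i in seq_len(dim(block$coords)[1])) {
    X <- block$coords[i, , ]
    Xr <- X
    Xr[, 1] <- -Xr[, 1]
    Xr <- Xr[relabel, ]
    # rigid alignment of the mirrored copy back onto the original
    cX <- colMeans(X); cR <- colMeans(Xr)
    Xc <- sweep(X, 2, cX); Rc <- sweep(Xr, 2, cR)
    R <- .opt_rotation(Rc, Xc)
    Xr_aligned <- sweep(Rc %*% R, 2, cX, "+")
    block$coords[i, , ] <- (X + Xr_aligned) / 2
  }
  gpa(block)$block
}

#' Shape data from an aligned landmark block
#'
#' Flattens aligned coordinates into a specimens x (2k) shape matrix with
#' log centroid size as the size variable.
#'
#' @param block Aligned `landmark_block`.
#' @param centroid_sizes Pre-scaling centroid sizes (from [gpa()]).
#' @param dataset_tag Dataset label (default `"head"`).
#' @return A [shape_data] object.
#' @export
landmarks_to_shape_data <- function(block, centroid_sizes,
                                    dataset_tag = "head") {
  n <- dim(block$coords)[1]; k <- dim(block$coords)[2]
  Y <- matrix(block$coords, n, 2 * k)
  colnames(Y) <- c(paste0("x", seq_len(k)), paste0("y", seq_len(k)))
  shape_data(Y, log(centroid_sizes), block$species, block$sex, dataset_tag)
}

# ---------------------------------------------------------------------------
# Sexual dimorphism filter

#' Filter sexually dimorphic species
#'
#' For each species sampled for both sexes, runs a residual-randomization
#' ANOVA of shape on sex (distance-based F). Where sex has a significant
#' effect, female specimens are discarded (sampling in this kind of study is
#' typically male-biased). Species with a single sex pass through untested.
#'
#' @param data A [shape_data] object with sex labels.
#' @param alpha Significance level.
#' @param n_perm Permutations for the per-species ANOVA.
#' @param seed Seed for the permutation streams.
#' @param min_n Minimum retained sample size per species; a removal that
#'   would drop a species below this is still performed but flagged.
#' @return List with `data` (filtered [shape_data]) and `report` (data frame:
#'   species, n_male, n_female, p, action).
#' @export
dimorphism_filter <- function(data, alpha = 0.05, n_perm = 999, seed = NULL,
                              min_n = 5L) {
  sps <- sort(unique(data$species))
  rows <- list()
  drop <- rep(FALSE, nrow(data$Y))
  for (sp in sps) {
    i <- data$species == sp
    sexes <- data$sex[i]
    nm <- sum(sexes == "M"); nf <- sum(sexes == "F")
    if (nm == 0L || nf == 0L) {
      rows[[sp]] <- data.frame(species = sp, n_male = nm, n_female = nf,
                               p = NA_real_, action = "untested")
      next
    }
    fit <- rrpp_model_test(data$Y[i, , drop = FALSE],
                           X_full = stats::model.matrix(~ factor(sexes)),
                           X_reduced = matrix(1, sum(i), 1),
                           n_perm = n_perm,
                           seed = if (is.null(seed)) NULL
                                  else child_seed(seed, paste0("dimorph.", sp)))
    action <- "retained"
    if (fit$p < alpha) {
      drop[i & data$sex == "F"] <- TRUE
      action <- "females_removed"
      if (sum(i) - nf < min_n)
        action <- "females_removed_below_min_n"
    }
    rows[[sp]] <- data.frame(species = sp, n_male = nm, n_female = nf,
                             p = fit$p, action = action)
  }
  list(data = subset_shape_data(data, !drop),
       report = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
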