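#' @importFrom stats p.adjust lm.fit coef rnorm runif sd var quantile
#'   optim na.omit setNames prcomp cov dist
#' @importFrom utils read.csv write.csv combn head
NULL

# ---------------------------------------------------------------------------
# Run configuration

#' Analysis run configuration
#'
#' Bundles the reproducibility and inference settings shared by every
#' permutation test in the package: the master seed, the number of
#' permutations, the significance level, and the size transform used when
#' building shape data.
#'
#' All randomness in the package flows through seeds derived deterministically
#' from the master seed via [child_seed()], so individual analyses are
#' order-independent.
#'
#' @param seed Integer master seed.
#' @param n_permutations Number of permutations for permutation tests
#'   (default 10000).
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @param size_transform Label of the size transform; only `"log"` (natural
#'   logarithm) is implemented.
#' @param output_dir Optional output directory for result tables.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_permutations = 10000L, alpha = 0.05,
                       size_transform = "log", output_dir = NULL) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  if (!is.numeric(n_permutations) || n_permutations < 1)
    stop("`n_permutations` must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)")
  size_transform <- match.arg(size_transform, "log")
  structure(list(seed = as.integer(seed),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha,
                 size_transform = size_transform,
                 output_dir = output_dir),
            class = "run_config")
}

#' Derive a deterministic child seed
#'
#' Hashes a master seed together with a character label into a new seed, so
#' that each analysis owns an independent, order-invariant random stream.
#' The result is always a non-negative integer below 2^31.
#'
#' @param seed Integer master seed.
#' @param label Character label identifying the consumer.
#' @return A single integer seed.
#' @export
child_seed <- function(seed, label) {
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# ---------------------------------------------------------------------------
# Trees

#' Read a newick tree
#'
#' Parses a newick string (or file) into an `ape` phylogeny, validating tip
#' label uniqueness and branch-length positivity, and parsing numeric node
#' labels into posterior-support values.
#'
#' @param text Newick string, or the path of a file containing one.
#' @return An object of class `phylo` with an additional `node_support`
#'   attribute (numeric vector over internal nodes, `NA` where no support was
#'   annotated).
#' @export
read_newick <- function(text) {
  if (length(text) != 1L || !is.character(text))
    stop("`text` must be a single newick string or file path")
  if (file.exists(text) && !grepl(";", text, fixed = TRUE))
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  .check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("malformed newick: parser returned no tree")
  validate_phylogeny(tree)
  support <- rep(NA_real_, tree$Nnode)
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    ok <- !is.na(sup) & sup >= 0 & sup <= 1
    support[ok] <- sup[ok]
  }
  attr(tree, "node_support") <- support
  tree
}

# Cheap syntactic pre-check so parse errors can name a character offset.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed newick: unbalanced ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed newick: %d unclosed '(' at character %d",
                 depth, length(chars)))
  if (!grepl(";", text, fixed = TRUE))
    stop(sprintf("malformed newick: missing ';' terminator at character %d",
                 nchar(text)))
  invisible(TRUE)
}

#' Validate a phylogeny
#'
#' Checks tip-label uniqueness and strict branch-length positivity; optionally
#' checks ultrametricity within a relative tolerance of the tree height.
#'
#' @param tree A `phylo` object.
#' @param require_ultrametric Require the tree to be ultrametric.
#' @param tol Relative ultrametricity tolerance (fraction of tree height).
#' @return The tree, invisibly.
#' @export
validate_phylogeny <- function(tree, require_ultrametric = FALSE, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a `phylo` object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length <= 0))
    stop("all branch lengths must be strictly positive")
  if (require_ultrametric) {
    depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
    if (diff(range(depths)) > tol * max(depths))
      stop("tree is not ultrametric within tolerance")
  }
  invisible(tree)
}

#' Write a tree as newick
#'
#' @param tree A `phylo` object; a `node_support` attribute, if present, is
#'   emitted as node labels.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @return The newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, file = NULL) {
  sup <- attr(tree, "node_support")
  if (!is.null(sup) && any(!is.na(sup))) {
    tree$node.label <- ifelse(is.na(sup), "", format(sup, digits = 15))
  }
  txt <- ape::write.tree(tree, digits = 15)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a regime-painted tree
#'
#' Reads a phylogeny whose branches are painted with discrete regimes
#' (e.g. habitat-use categories), in either of two dialects:
#' a SIMMAP-style annotated newick string, or a plain `phylo` plus a
#' segment table with columns `edge` (index into `tree$edge` rows),
#' `regime`, and `duration`. Segment durations on each branch must sum to the
#' branch length within `1e-6` (stored values are validated at `1e-9` after
#' renormalisation is *not* applied; mismatches are an error).
#'
#' @param text SIMMAP-annotated newick string or file path (ignored when
#'   `tree` and `segments` are supplied).
#' @param tree Optional `phylo` when using the table dialect.
#' @param segments Optional data frame `edge, regime, duration`.
#' @return A `phylo` with a `maps` component: one named numeric vector per
#'   edge, names are regimes, values are durations in branch order from the
#'   rootward end.
#' @export
read_painted_tree <- function(text = NULL, tree = NULL, segments = NULL) {
  if (!is.null(tree) && !is.null(segments)) {
    validate_phylogeny(tree)
    if (!all(c("edge", "regime", "duration") %in% names(segments)))
      stop("segment table needs columns edge, regime, duration")
    maps <- vector("list", nrow(tree$edge))
    for (e in seq_len(nrow(tree$edge))) {
      seg <- segments[segments$edge == e, , drop = FALSE]
      if (nrow(seg) == 0L)
        stop("edge ", e, " has no regime segments")
      maps[[e]] <- setNames(seg$duration, as.character(seg$regime))
    }
    tree$maps <- maps
  } else {
    if (is.null(text)) stop("supply `text` or (`tree`, `segments`)")
    if (file.exists(text) && !grepl(";", text, fixed = TRUE))
      text <- paste(readLines(text, warn = FALSE), collapse = "\n")
    tree <- phytools::read.simmap(text = text, format = "phylip")
    validate_phylogeny(tree)
  }
  .validate_painting(tree)
  tree
}

.validate_painting <- function(tree, tol = 1e-6) {
  if (is.null(tree$maps)) stop("tree has no regime painting")
  sums <- vapply(tree$maps, sum, 0)
  bad <- which(abs(sums - tree$edge.length) > tol)
  if (length(bad))
    stop("regime segment durations do not sum to branch length on edge(s) ",
         paste(bad, collapse = ", "))
  invisible(tree)
}

#' Regimes present in a painting
#' @param tree A painted `phylo` (with `maps`).
#' @return Character vector of regime labels.
#' @export
painting_regimes <- function(tree) {
  sort(unique(unlist(lapply(tree$maps, names))))
}

# ---------------------------------------------------------------------------
# p-values

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of raw p-values.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return An object of class `p_value_vector`: list with `raw`, `adjusted`,
#'   and `method` fields. Adjusted values never fall below the raw values and
#'   are capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  structure(list(raw = p, adjusted = p.adjust(p, method = "BH"),
                 method = "benjamini-hochberg"),
            class = "p_value_vector")
}

#' Permutation p-value
#'
#' Computes the proportion of null draws at least as extreme as the observed
#' statistic, with the observed value itself included in the null (add-one
#' rule), so p is always in (0, 1\].
#'
#' @param observed Observed statistic (single number).
#' @param null_draws Numeric vector of statistics under the null.
#' @param tail One of `"greater"`, `"less"`, `"two-sided"`.
#' @return A single p-value.
#' @export
permutation_pvalue <- function(observed,
                               null_draws,
                               tail = c("greater", "less", "two-sided")) {
  tail <- match.arg(tail)
  if (length(null_draws) == 0L) stop("empty null distribution")
  n <- length(null_draws)
  switch(tail,
    greater = (sum(null_draws >= observed) + 1) / (n + 1),
    less = (sum(null_draws <= observed) + 1) / (n + 1),
    `two-sided` = {
      ctr <- abs(observed - mean(null_draws))
      (sum(abs(null_draws - mean(null_draws)) >= ctr) + 1) / (n + 1)
    })
}

# ---------------------------------------------------------------------------
# Tabular readers

#' Read a linear morphometric table
#'
#' CSV with columns `specimen_id`, `species`, `sex`, then one column per
#' linear trait (mm, strictly positive).
#'
#' @param path CSV path.
#' @return A `data.frame` of class `linear_table`.
#' @export
read_linear_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  as_linear_table(x)
}

#' Coerce a data frame to a linear morphometric table
#' @param x Data frame with `specimen_id`, `species`, `sex` and trait columns.
#' @return `x` validated, with class `linear_table` prepended.
#' @export
as_linear_table <- function(x) {
  need <- c("specimen_id", "species", "sex")
  if (!all(need %in% names(x)))
    stop("linear table needs columns: ", paste(need, collapse = ", "))
  traits <- setdiff(names(x), need)
  if (length(traits) == 0L) stop("no trait columns found")
  tm <- as.matrix(x[traits])
  if (!is.numeric(tm)) stop("trait columns must be numeric")
  if (any(is.na(tm))) stop("missing trait values are not allowed")
  if (any(tm <= 0)) stop("all trait values must be strictly positive (mm)")
  if (!all(x$sex %in% c("M", "F", "unknown")))
    stop("sex must be one of M, F, unknown")
  class(x) <- c("linear_table", class(x))
  attr(x, "traits") <- traits
  x
}

#' Read a habitat-use table
#'
#' CSV with columns `species`, `juvenile_habitat`, `adult_habitat`, each label
#' one of the six habitat-use categories (amphibious, canopy, cryptic,
#' escarpment, terrestrial, trunk). A logical `shift` column (juvenile and
#' adult habitat differ) is added if absent.
#'
#' @param path CSV path.
#' @return Data frame of class `habitat_table`.
#' @export
read_habitat_table <- function(path) {
  as_habitat_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_habitat_table
#' @param x Data frame to validate.
#' @export
as_habitat_table <- function(x) {
  need <- c("species", "juvenile_habitat", "adult_habitat")
  if (!all(need %in% names(x)))
    stop("habitat table needs columns: ", paste(need, collapse = ", "))
  cats <- habitat_categories()
  bad <- setdiff(unique(c(x$juvenile_habitat, x$adult_habitat)), cats)
  if (length(bad))
    stop("unknown habitat categories: ", paste(bad, collapse = ", "))
  if (is.null(x$shift)) x$shift <- x$juvenile_habitat != x$adult_habitat
  class(x) <- c("habitat_table", class(x))
  x
}

#' The six habitat-use categories
#' @return Character vector of category labels.
#' @export
habitat_categories <- function() {
  c("amphibious", "canopy", "cryptic", "escarpment", "terrestrial", "trunk")
}

#' Read a sympatry matrix
#'
#' Species-by-species binary co-occurrence matrix (CSV, first column = species
#' names). Must be symmetric with a unit diagonal.
#'
#' @param path CSV path.
#' @return A numeric matrix with species dimnames.
#' @export
read_sympatry <- function(path) {
  x <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(x)
  validate_sympatry(m)
}

#' @rdname read_sympatry
#' @param m Matrix to validate.
#' @export
validate_sympatry <- function(m) {
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
    stop("sympatry matrix must be symmetric")
  if (any(diag(m) != 1)) stop("sympatry matrix must have a unit diagonal")
  if (!all(m %in% c(0, 1))) stop("sympatry matrix must be binary")
  m
}
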