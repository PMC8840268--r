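# Shape data container: the common currency of all downstream tests.

#' Construct a shape-data object
#'
#' Holds a specimens-by-shape-variables matrix together with per-specimen
#' size, species and sex labels. Shape variables are log-shape ratios for
#' linear data or Procrustes-aligned coordinates for landmark data; size is
#' the natural log of the geometric-mean size or of centroid size.
#'
#' @param Y Numeric matrix, specimens x shape variables.
#' @param size Numeric vector of log sizes, one per specimen.
#' @param species Character/factor vector of species labels.
#' @param sex Optional character vector (`"M"`, `"F"`, `"unknown"`).
#' @param dataset_tag One of `"body"`, `"limbs"`, `"head"`, or any label.
#' @return An object of class `shape_data`.
#' @export
shape_data <- function(Y, size, species, sex = NULL, dataset_tag = "body") {
  Y <- as.matrix(Y)
  if (!is.numeric(Y)) stop("Y must be numeric")
  n <- nrow(Y)
  if (length(size) != n || length(species) != n)
    stop("size and species must align with the rows of Y")
  if (is.null(sex)) sex <- rep("unknown", n)
  if (length(sex) != n) stop("sex must align with the rows of Y")
  structure(list(Y = Y, size = as.numeric(size),
                 species = as.character(species), sex = as.character(sex),
                 dataset_tag = dataset_tag),
            class = "shape_data")
}

#' @export
print.shape_data <- function(x, ...) {
  cat(sprintf("shape_data [%s]: %d specimens, %d shape variables, %d species\n",
              x$dataset_tag, nrow(x$Y), ncol(x$Y),
              length(unique(x$species))))
  invisible(x)
}

#' Subset a shape-data object by specimen
#' @param data A `shape_data` object.
#' @param i Logical or integer specimen index.
#' @return The subsetted `shape_data`.
#' @export
subset_shape_data <- function(data, i) {
  shape_data(data$Y[i, , drop = FALSE], data$size[i], data$species[i],
             data$sex[i], data$dataset_tag)
}

#' Subset a shape-data object by species
#' @param data A `shape_data` object.
#' @param species Character vector of species to keep.
#' @return The subsetted `shape_data`.
#' @export
filter_species <- function(data, species) {
  subset_shape_data(data, data$species %in% species)
}

#' Per-species specimen counts
#' @param data A `shape_data` object.
#' @return Named integer vector.
#' @export
species_counts <- function(data) {
  tab <- table(data$species)
  setNames(as.integer(tab), names(tab))
}
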