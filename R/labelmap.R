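#' Instance label maps
#'
#' A per-pixel integer map in which 0 denotes background and each positive
#' value identifies one cell instance. Target cells (the class to be
#' segmented, e.g. large HL60-like nuclei) carry ids from the set `L`
#' (`target_ids`); non-target distractor objects (e.g. small granulocyte-like
#' cells) carry ids from the disjoint set `Lambda` (`distractor_ids`).
#'
#' A clean (high-quality) map stores only target footprints in `values`.
#' The footprints of the distractor objects, which the inclusion
#' perturbation may add as false foreground, are kept in the separate
#' `distractor_footprints` matrix so that a map knows about objects that are
#' present in the image but absent from its annotation.
#'
#' @param values Integer matrix (H x W); 0 background, positive = instance id.
#' @param target_ids Integer vector `L`. Defaults to all positive ids found
#'   in `values` that are not distractor ids.
#' @param distractor_ids Integer vector `Lambda`, disjoint from `target_ids`.
#' @param distractor_footprints Integer matrix of the same size as `values`
#'   holding distractor shapes by their ids (0 elsewhere), or `NULL`.
#' @return An object of class `instance_label_map`.
#' @export
instance_label_map <- function(values, target_ids = NULL,
                               distractor_ids = integer(),
                               distractor_footprints = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "integer"
  if (any(values < 0, na.rm = TRUE)) stop("instance ids must be non-negative")
  distractor_ids <- as.integer(distractor_ids)
  present <- setdiff(sort(unique(as.vector(values))), 0L)
  if (is.null(target_ids)) target_ids <- setdiff(present, distractor_ids)
  target_ids <- as.integer(target_ids)
  if (length(intersect(target_ids, distractor_ids)) > 0L)
    stop("target_ids and distractor_ids must be disjoint (L ∩ Λ = ∅)")
  if (is.null(distractor_footprints)) {
    distractor_footprints <- matrix(0L, nrow(values), ncol(values))
  } else {
    if (!is.matrix(distractor_footprints) ||
        !all(dim(distractor_footprints) == dim(values)))
      stop("`distractor_footprints` must be a matrix of the same size as `values`")
    storage.mode(distractor_footprints) <- "integer"
    fp_ids <- setdiff(unique(as.vector(distractor_footprints)), 0L)
    if (!all(fp_ids %in% distractor_ids))
      stop("distractor_footprints contains ids not listed in distractor_ids")
  }
  structure(list(values = values,
                 target_ids = target_ids,
                 distractor_ids = distractor_ids,
                 distractor_footprints = distractor_footprints),
            class = "instance_label_map")
}

#' @export
print.instance_label_map <- function(x, ...) {
  pres <- present_target_ids(x)
  cat(sprintf("instance_label_map: %d x %d, %d/%d target cells present, %d distractors known\n",
              nrow(x$values), ncol(x$values), length(pres),
              length(x$target_ids), length(x$distractor_ids)))
  invisible(x)
}

#' @export
dim.instance_label_map <- function(x) dim(x$values)

is_label_map <- function(x) inherits(x, "instance_label_map")

#' Target ids with at least one pixel in the map
#' @param label An `instance_label_map`.
#' @return Integer vector of target ids whose footprint is non-empty.
#' @export
present_target_ids <- function(label) {
  stopifnot(is_label_map(label))
  pres <- setdiff(unique(as.vector(label$values)), 0L)
  sort(intersect(label$target_ids, pres))
}

present_distractor_ids <- function(label) {
  pres <- setdiff(unique(as.vector(label$distractor_footprints)), 0L)
  sort(intersect(label$distractor_ids, pres))
}

#' Binarize a label to a foreground mask
#'
#' Bridges instance labels to the binary pixel-wise classification targets
#' used by the segmentation and upgrade networks: 1 wherever the map carries
#' a positive instance id, 0 elsewhere.
#'
#' @param label An `instance_label_map`, or a numeric/integer matrix.
#' @return Integer 0/1 matrix of the same size.
#' @export
binarize <- function(label) {
  v <- if (is_label_map(label)) label$values else label
  if (!is.matrix(v)) stop("cannot binarize: not a matrix or instance_label_map")
  m <- (v > 0) + 0L
  dim(m) <- dim(v)
  m
}

# round-half-away-from-zero; base round() is banker's rounding, which would
# break exactness at the rates the perturbations are defined with
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
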