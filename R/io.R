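#' Equidistant circular slice sampler
#'
#' Selects annotation slices spread through one or more volumes: each used
#' volume is divided into `n_slices` contiguous equal sections and the
#' middle slice of a section is taken ("middle" = section start +
#' `floor(section_length / 2)`). With a single volume all sections come
#' from it; with several, slice `i` is taken from section `i` of volume
#' `((i - 1) mod n_volumes) + 1`, round-robin, so consecutive picks come
#' from different volumes.
#'
#' @param volumes List of volumes (from [generate_volumes()]), or an
#'   integer vector of volume lengths.
#' @param n_slices Total slices to select.
#' @param n_volumes Number of volumes to draw from.
#' @return A `sampler_plan` data frame (volume, section, slice) with
#'   1-based slice indices; pairs are distinct and the selection is
#'   deterministic.
#' @export
sample_slices <- function(volumes, n_slices, n_volumes = 1L) {
  lens <- if (is.numeric(volumes)) as.integer(volumes)
  else vapply(volumes, function(v) length(v$slices), integer(1))
  n_slices <- as.integer(n_slices); n_volumes <- as.integer(n_volumes)
  stopifnot(n_slices >= 1, n_volumes >= 1)
  if (n_volumes > length(lens))
    stop("n_volumes exceeds the number of available volumes")
  used <- lens[seq_len(n_volumes)]
  if (any(used < n_slices))
    stop(sprintf("n_slices (%d) exceeds the length of a used volume (min %d)",
                 n_slices, min(used)))
  section_middle <- function(len, section, n_sections) {
    s0 <- floor((section - 1) * len / n_sections)
    s1 <- floor(section * len / n_sections)
    as.integer(s0 + floor((s1 - s0) / 2) + 1L)  # 1-based
  }
  rows <- lapply(seq_len(n_slices), function(i) {
    v <- ((i - 1L) %% n_volumes) + 1L
    data.frame(volume = v, section = i,
               slice = section_middle(lens[v], i, n_slices))
  })
  plan <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(plan[, c("volume", "slice")]))
  class(plan) <- c("sampler_plan", "data.frame")
  plan
}

#' Split images and labels into overlapping patches
#'
#' Sliding-window tiling with stride `patch - overlap`; the final row and
#' column of windows are anchored to the image edge so every pixel is
#' covered. Windows are half-open on 0-based coordinates (the returned
#' anchors are 1-based R indices). Patches whose label contains no target
#' pixels are dropped when `drop_empty`.
#'
#' @param ds An [annotated_dataset()].
#' @param patch Patch side length (pixels).
#' @param overlap Overlap between neighbouring patches (pixels).
#' @param drop_empty Drop patches without target-cell pixels.
#' @return An `annotated_dataset` of patches; ids record the source sample
#'   and anchor.
#' @export
patch_dataset <- function(ds, patch = 500L, overlap = 100L,
                          drop_empty = TRUE) {
  stopifnot(inherits(ds, "annotated_dataset"), overlap < patch)
  stride <- patch - overlap
  anchors <- function(n) {
    if (n < patch)
      stop(sprintf("image (%d px) smaller than patch (%d px)", n, patch))
    a <- seq(1L, n - patch + 1L, by = stride)
    if (a[length(a)] + patch - 1L < n) a <- c(a, n - patch + 1L)
    a
  }
  images <- list(); labels <- list(); ids <- character(); prov <- character()
  truths <- list()
  for (i in seq_len(length(ds))) {
    im <- ds$images[[i]]
    if (dim(im)[1] < patch || dim(im)[2] < patch)
      stop(sprintf("sample %s: image %d x %d smaller than patch %d",
                   ds$ids[i], dim(im)[1], dim(im)[2], patch))
    lab <- ds$labels[[i]]
    for (r in anchors(dim(im)[1])) for (cc in anchors(dim(im)[2])) {
      rw <- r:(r + patch - 1L); cw <- cc:(cc + patch - 1L)
      plab <- if (is_label_map(lab)) {
        instance_label_map(lab$values[rw, cw, drop = FALSE],
                           target_ids = lab$target_ids,
                           distractor_ids = lab$distractor_ids,
                           distractor_footprints =
                             lab$distractor_footprints[rw, cw, drop = FALSE])
      } else lab[rw, cw, drop = FALSE]
      tmask <- if (is_label_map(plab)) {
        v <- plab$values
        (matrix(v %in% plab$target_ids, nrow(v)) & v > 0)
      } else plab > 0
      if (drop_empty && !any(tmask)) next
      images[[length(images) + 1L]] <- im[rw, cw, , drop = FALSE]
      labels[[length(labels) + 1L]] <- plab
      ids <- c(ids, sprintf("%s_r%04d_c%04d", ds$ids[i], r, cc))
      prov <- c(prov, ds$provenance[i])
      if (!is.null(ds$truth))
        truths[[length(truths) + 1L]] <- ds$truth[[i]][rw, cw, drop = FALSE]
    }
  }
  if (length(images) == 0) stop("no patches retained")
  out <- annotated_dataset(images, labels, provenance = prov[1], ids = ids,
                           intensity_max = ds$intensity_max,
                           truth = if (!is.null(ds$truth)) truths)
  out$provenance <- prov
  out
}

#' Read and write images and label maps
#'
#' Images: 8/16-bit grayscale and 8-bit RGB TIFF, plus 8-bit PNG. Labels:
#' integer maps stored as 16-bit grayscale TIFF (lossless round trip for
#' ids up to 65535) or 8-bit PNG (ids up to 255). Coordinates are (row,
#' col); a label file holding an RGB image is rejected.
#'
#' @param image `H x W x C` array of integer intensities.
#' @param path File path; format chosen by extension (`.tif`/`.tiff` or
#'   `.png`).
#' @param bit_depth 8 or 16.
#' @return `read_image` returns an `H x W x C` integer array with
#'   attribute `bit_depth`; `read_label` an integer matrix.
#' @export
write_image <- function(image, path, bit_depth = 16L) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  imax <- 2^bit_depth - 1
  if (any(image < 0 | image > imax)) stop("intensities outside dtype range")
  x <- image / imax
  if (dim(x)[3] == 1L) dim(x) <- dim(x)[1:2]
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(x, path, bits.per.sample = as.integer(bit_depth))
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (bit_depth != 8L) stop("PNG images are written as 8-bit only")
    png::writePNG(x, path)
  } else stop("unsupported image format: ", path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    bits <- if (max(raw) > 255) 16L else attr(raw, "bits.per.sample") %||%
      (if (max(raw) > 255) 16L else 8L)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    raw <- round(png::readPNG(path) * 255)
    bits <- 8L
  } else stop("unsupported image format: ", path)
  if (is.matrix(raw)) dim(raw) <- c(dim(raw), 1L)
  storage.mode(raw) <- "integer"
  attr(raw, "bit_depth") <- as.integer(bits)
  raw
}

#' @rdname write_image
#' @param label Integer label matrix.
#' @export
write_label <- function(label, path) {
  if (is_label_map(label)) label <- label$values
  stopifnot(is.matrix(label))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (max(label) > 65535) stop("label ids exceed 16-bit range")
    tiff::writeTIFF(label / 65535, path, bits.per.sample = 16L)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (max(label) > 255) stop("label ids exceed the 8-bit PNG range")
    png::writePNG(label / 255, path)
  } else stop("unsupported label format: ", path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_label <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    if (!is.matrix(raw))
      stop("label file is not a single-channel integer map: ", path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    raw <- png::readPNG(path)
    if (!is.matrix(raw))
      stop("label file is not a single-channel integer map: ", path)
    raw <- round(raw * 255)
  } else stop("unsupported label format: ", path)
  storage.mode(raw) <- "integer"
  raw
}

#' Save and load dataset manifests
#'
#' A manifest records, per slice, the image path, label path, volume id,
#' slice index, split tag and provenance, plus free-form metadata (e.g. the
#' instance id ranges). Stored as JSON with a format version.
#'
#' @param manifest List with `records` (data frame) and optional `metadata`.
#' @param path JSON file path.
#' @param check_paths Verify at load that all referenced files exist.
#' @return `load_manifest` returns the manifest list.
#' @export
save_manifest <- function(manifest, path) {
  stopifnot(is.data.frame(manifest$records))
  req <- c("image", "label", "volume_id", "slice_index", "split", "provenance")
  missing_cols <- setdiff(req, names(manifest$records))
  if (length(missing_cols))
    stop("manifest records lack columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(manifest$records[, c("volume_id", "slice_index")]))
    stop("duplicate (volume_id, slice_index) pairs in manifest")
  if (!all(manifest$records$split %in% c("train", "val", "test")))
    stop("split tags must be train/val/test")
  obj <- list(format_version = "1.0",
              metadata = manifest$metadata %||% list(),
              records = manifest$records)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname save_manifest
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version)) stop("not a manifest (no format_version)")
  rec <- as.data.frame(obj$records)
  if (check_paths) {
    base <- dirname(path)
    paths <- file.path(base, c(rec$image, rec$label))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("manifest references missing files:\n  ",
           paste(missing, collapse = "\n  "))
  }
  if (anyDuplicated(rec[, c("volume_id", "slice_index")]))
    stop("duplicate (volume_id, slice_index) pairs in manifest")
  list(format_version = obj$format_version, metadata = obj$metadata,
       records = rec)
}

#' Write volumes to disk with a manifest
#'
#' Per-slice TIFF image + 16-bit TIFF label (+ distractor footprint map),
#' indexed by a JSON manifest whose metadata records the instance id
#' ranges.
#'
#' @param volumes Volumes from [generate_volumes()].
#' @param dir Output directory (created if needed).
#' @param split Split tag applied to all slices.
#' @return Path of the manifest, invisibly.
#' @export
write_volumes <- function(volumes, dir, split = "train") {
  if (inherits(volumes, "cell_volume")) volumes <- list(volumes)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (v in volumes) {
    bd <- v$bit_depth
    for (s in seq_along(v$slices)) {
      sl <- v$slices[[s]]
      stem <- sprintf("v%02d_s%03d", v$volume_id, s)
      img_f <- paste0(stem, "_img.tif")
      lab_f <- paste0(stem, "_lab.tif")
      fp_f <- paste0(stem, "_distractors.tif")
      write_image(sl$image, file.path(dir, img_f), bit_depth = bd)
      write_label(sl$label$values, file.path(dir, lab_f))
      write_label(sl$label$distractor_footprints, file.path(dir, fp_f))
      rows[[length(rows) + 1L]] <-
        data.frame(image = img_f, label = lab_f, distractors = fp_f,
                   volume_id = v$volume_id, slice_index = s,
                   split = split, provenance = "high_quality")
    }
  }
  manifest <- list(records = do.call(rbind, rows),
                   metadata = list(bit_depth = volumes[[1]]$bit_depth,
                                   target_id_start = 1L,
                                   distractor_id_start = DISTRACTOR_ID_OFFSET + 1L))
  mpath <- file.path(dir, "manifest.json")
  save_manifest(manifest, mpath)
  invisible(mpath)
}

#' Load a dataset from a manifest
#'
#' @param path Manifest JSON path.
#' @param split Optional split filter.
#' @return An [annotated_dataset()].
#' @export
load_dataset <- function(path, split = NULL) {
  man <- load_manifest(path)
  rec <- man$records
  if (!is.null(split)) rec <- rec[rec$split %in% split, , drop = FALSE]
  base <- dirname(path)
  images <- lapply(file.path(base, rec$image), read_image)
  d_start <- man$metadata$distractor_id_start %||% (DISTRACTOR_ID_OFFSET + 1L)
  labels <- lapply(seq_len(nrow(rec)), function(i) {
    v <- read_label(file.path(base, rec$label[i]))
    fp <- if (!is.null(rec$distractors) && !is.na(rec$distractors[i]))
      read_label(file.path(base, rec$distractors[i])) else NULL
    dids <- if (!is.null(fp)) sort(setdiff(unique(as.vector(fp)), 0L)) else integer()
    instance_label_map(v, distractor_ids = dids, distractor_footprints = fp)
  })
  bd <- man$metadata$bit_depth %||% 16L
  annotated_dataset(images, labels,
                    provenance = rec$provenance[1] %||% "high_quality",
                    ids = sprintf("v%02d_s%03d", rec$volume_id, rec$slice_index),
                    intensity_max = 2^bd - 1)
}

#' Load a structured configuration file
#'
#' YAML or JSON by extension.
#'
#' @param path Config path.
#' @return Named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: ", path)
}
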