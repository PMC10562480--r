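#' Write one subject's slices and masks to disk
#'
#' NIfTI output stores intensities as-is with the pixel spacing in the
#' header; PNG output rescales intensities to the file's unit range and
#' records the original range in a JSON sidecar (the habitat pipeline is
#' invariant to that affine rescaling).
#'
#' @param slices A [slice_pair()].
#' @param dir Output directory (created if needed).
#' @param format `"nifti"` or `"png"`.
#' @return Named character vector of the four file paths written.
#' @export
write_subject <- function(slices, dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  hg_assert(inherits(slices, "slice_pair"), "slices must be a slice_pair")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- slices$subject_id
  parts <- list(t1c = slices$t1c, flair = slices$flair,
                roi_t1 = slices$roi_t1 * 1, roi_flair = slices$roi_flair * 1)
  ext <- if (format == "nifti") ".nii.gz" else ".png"
  paths <- file.path(dir, paste0(id, "_", names(parts), ext))
  names(paths) <- names(parts)
  if (format == "nifti") {
    for (k in names(parts)) {
      img <- RNifti::asNifti(parts[[k]],
                             pixdim = c(slices$spacing_mm, 1))
      RNifti::writeNifti(img, paths[[k]])
    }
  } else {
    ranges <- list()
    for (k in names(parts)) {
      m <- parts[[k]]
      rng <- range(m)
      scaled <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
      png::writePNG(scaled, paths[[k]])
      ranges[[k]] <- rng
    }
    jsonlite::write_json(list(spacing_mm = slices$spacing_mm,
                              intensity_range = ranges),
                         file.path(dir, paste0(id, "_meta.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  paths
}

read_image_2d <- function(path, slice_selection = "max-area", mask = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)[1:2]
    arr <- as.array(img)
    list(data = arr, spacing = spacing)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3) arr <- arr[, , 1]
    list(data = arr, spacing = NULL)
  } else {
    hg_error(sprintf("unsupported image format: %s", path),
             "habitatgraph_io_error")
  }
}

select_slice <- function(arr, mask_arr, slice_selection) {
  if (length(dim(arr)) == 2) return(list(img = arr, mask = mask_arr, index = 1L))
  hg_assert(length(dim(arr)) == 3, "images must be 2D or 3D")
  idx <- if (identical(slice_selection, "max-area")) {
    areas <- apply(mask_arr > 0, 3, sum)
    which.max(areas)  # ties: lowest index
  } else {
    as.integer(slice_selection)
  }
  list(img = arr[, , idx], mask = mask_arr[, , idx], index = as.integer(idx))
}

#' Read one subject's paired slices from image files
#'
#' Accepts NIfTI (2D, or 3D with a slice chosen by maximum in-mask area on
#' the T1 ROI — ties resolved to the lowest index — or an explicit index)
#' or 2D grayscale PNG. For 3D input the same slice index is used for both
#' sequences. Pixel spacing is taken from the NIfTI header, or from
#' `spacing_mm` for PNG.
#'
#' @param paths Named list/vector with `t1c`, `flair`, `roi_t1`,
#'   `roi_flair` file paths.
#' @param slice_selection `"max-area"` or an integer slice index.
#' @param spacing_mm Fallback (row, col) spacing in mm for formats without
#'   a header (default 1 mm isotropic).
#' @param subject_id Identifier for the returned object.
#' @return A [slice_pair()].
#' @export
read_subject <- function(paths, slice_selection = "max-area",
                         spacing_mm = c(1, 1), subject_id = "subject") {
  for (k in c("t1c", "flair", "roi_t1", "roi_flair")) {
    hg_assert(!is.null(paths[[k]]) && file.exists(paths[[k]]),
              sprintf("missing input file for '%s'", k),
              "habitatgraph_io_error")
  }
  t1 <- read_image_2d(paths[["t1c"]])
  fl <- read_image_2d(paths[["flair"]])
  m1 <- read_image_2d(paths[["roi_t1"]])
  m2 <- read_image_2d(paths[["roi_flair"]])
  hg_assert(identical(dim(t1$data), dim(m1$data)),
            "T1 image and ROI shapes differ", "habitatgraph_io_error")
  hg_assert(identical(dim(fl$data), dim(m2$data)),
            "FLAIR image and ROI shapes differ", "habitatgraph_io_error")
  s1 <- select_slice(t1$data, m1$data, slice_selection)
  idx <- if (length(dim(fl$data)) == 3) s1$index else slice_selection
  s2 <- select_slice(fl$data, m2$data,
                     if (length(dim(fl$data)) == 3) s1$index else idx)
  spacing <- if (!is.null(t1$spacing)) t1$spacing else as.numeric(spacing_mm)
  slice_pair(s1$img, s2$img, s1$mask > 0, s2$mask > 0,
             spacing_mm = spacing, subject_id = subject_id)
}

#' Write a synthetic cohort and its manifest to disk
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory.
#' @param format `"nifti"` or `"png"`.
#' @return Path of the manifest CSV (columns: subject_id, the four file
#'   paths, label).
#' @export
write_cohort <- function(cohort, dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(subj) {
    paths <- write_subject(subj$slices, dir, format)
    data.frame(subject_id = subj$slices$subject_id,
               t1c = paths[["t1c"]], flair = paths[["flair"]],
               roi_t1 = paths[["roi_t1"]], roi_flair = paths[["roi_flair"]],
               label = subj$label, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  path
}
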