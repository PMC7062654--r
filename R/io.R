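#' Read a 2-D image from NIfTI, 16-bit PNG or CSV grid
#'
#' NIfTI volumes with a single non-singleton slice dimension are squeezed to
#' 2-D; multi-slice volumes require an explicit `slice` index. Pixel spacing
#' is taken from the NIfTI header when present, otherwise `default_spacing`
#' is used (1.4 mm isotropic, a typical reconstructed breast-DWI
#' resolution).
#'
#' @param path file path (`.nii`, `.nii.gz`, `.png`, `.csv`).
#' @param modality modality tag, see [annotated_image()].
#' @param slice optional slice index for multi-slice NIfTI volumes.
#' @param default_spacing spacing used when the format carries none.
#' @param id identifier; defaults to the file base name.
#' @return An [annotated_image()].
#' @export
read_image <- function(path, modality = c("ADC", "DWI_HIGH_B", "B0"),
                       slice = NULL, default_spacing = c(1.4, 1.4),
                       id = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(id)) id <- sub("\\.(nii(\\.gz)?|png|csv)$", "", basename(path))
  fmt <- file_format(path)
  spacing <- default_spacing
  if (fmt == "nifti") {
    vol <- RNifti::readNifti(path)
    pd <- attr(vol, "pixdim")
    arr <- as.array(vol)
    arr <- squeeze_volume(arr, slice)
    if (!is.null(pd) && length(pd) >= 2 && all(pd[1:2] > 0))
      spacing <- as.numeric(pd[1:2])
    pixels <- arr
  } else if (fmt == "png") {
    raw <- png::readPNG(path)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1L]  # grayscale channel
    pixels <- round(raw * 65535)
  } else if (fmt == "csv") {
    pixels <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    dimnames(pixels) <- NULL
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  annotated_image(pixels, spacing = spacing, modality = modality, id = id)
}

file_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.png$", path, ignore.case = TRUE)) return("png")
  if (grepl("\\.(csv|txt)$", path, ignore.case = TRUE)) return("csv")
  "unknown"
}

squeeze_volume <- function(arr, slice = NULL) {
  d <- dim(arr)
  if (length(d) == 2L) return(arr)
  d <- d[d > 0]
  extra <- d[-(1:2)]
  if (all(extra == 1L)) {
    dim(arr) <- d[1:2]
    return(arr)
  }
  if (length(d) == 3L) {
    if (is.null(slice))
      stop("multi-slice volume: supply a slice index", call. = FALSE)
    if (slice < 1 || slice > d[3]) stop("slice index out of range", call. = FALSE)
    return(arr[, , slice])
  }
  stop("volumes with more than 3 dimensions are not supported", call. = FALSE)
}

#' Write a 2-D image as NIfTI or CSV grid
#'
#' @param image an [annotated_image()] or a bare numeric matrix.
#' @param path destination (`.nii`, `.nii.gz` or `.csv`).
#' @export
write_image <- function(image, path) {
  pixels <- if (inherits(image, "annotated_image")) image$pixels else as.matrix(image)
  spacing <- if (inherits(image, "annotated_image")) image$spacing else c(1, 1)
  fmt <- file_format(path)
  if (fmt == "nifti") {
    arr <- array(pixels, dim = c(dim(pixels), 1L))
    attr(arr, "pixdim") <- c(spacing, 1)
    RNifti::writeNifti(arr, path, datatype = "double")
  } else if (fmt == "csv") {
    utils::write.table(format_real(pixels), path, sep = ",",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    stop("unsupported output format: ", path, call. = FALSE)
  }
  invisible(path)
}

format_real <- function(x) {
  out <- sprintf("%.15g", x)
  dim(out) <- dim(x)
  out
}

#' Read a binary ROI mask paired with an image
#'
#' Nonzero pixels become true. The mask must be congruent with the image and
#' satisfy the ROI invariants (at least 16 pixels, single 8-connected
#' component).
#'
#' @param path mask file (NIfTI/PNG/CSV).
#' @param image the [annotated_image()] the mask belongs to.
#' @param id lesion identifier; defaults to the file base name.
#' @return A [roi_mask()].
#' @export
read_mask <- function(path, image, id = NULL) {
  img <- read_image(path, modality = "ADC", id = "mask",
                    default_spacing = image$spacing)
  if (is.null(id)) id <- sub("\\.(nii(\\.gz)?|png|csv)$", "", basename(path))
  m <- roi_mask(img$pixels != 0, id = id)
  check_congruent(image, m)
  m
}

#' Write a mask as NIfTI or CSV (0/1)
#' @param mask a [roi_mask()].
#' @param path destination path.
#' @export
write_mask <- function(mask, path) {
  m <- mask$mask * 1
  fmt <- file_format(path)
  if (fmt == "nifti") {
    arr <- array(m, dim = c(dim(m), 1L))
    RNifti::writeNifti(arr, path, datatype = "uint8")
  } else if (fmt == "csv") {
    utils::write.table(m, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else stop("unsupported output format: ", path, call. = FALSE)
  invisible(path)
}

#' Assemble a feature table
#'
#' A feature table is a data frame with columns `lesion_id`, `label`, then
#' one numeric column per feature in canonical catalogue order. Missing
#' (incomputable) features are `NA`.
#'
#' @param values numeric matrix or data frame, lesions x features.
#' @param labels class label per lesion.
#' @param ids lesion identifiers (unique).
#' @return A `data.frame` of class `feature_table`.
#' @export
feature_table <- function(values, labels, ids = NULL) {
  values <- as.data.frame(values, check.names = FALSE)
  if (anyDuplicated(names(values)))
    stop("duplicate feature names in table", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("lesion_%03d", seq_len(nrow(values)))
  if (anyDuplicated(ids)) stop("lesion ids must be unique", call. = FALSE)
  stopifnot(length(labels) == nrow(values), length(ids) == nrow(values))
  out <- cbind(data.frame(lesion_id = as.character(ids),
                          label = as.character(labels),
                          stringsAsFactors = FALSE),
               values)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @rdname feature_table
#' @param table a `feature_table`.
#' @return `feature_names()`: the feature column names in canonical order.
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("lesion_id", "label"))
}

#' Write / read a feature table as CSV
#'
#' One row per lesion; columns are `lesion_id`, `label`, then features in
#' canonical order. Reals are written with 15 significant digits so a
#' write/read round trip preserves at least 12; missing features are written
#' as empty cells.
#'
#' @param table a [feature_table()].
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  if (nrow(table) == 0L) stop("empty feature table", call. = FALSE)
  if (anyDuplicated(names(table)))
    stop("duplicate feature names", call. = FALSE)
  out <- table
  for (nm in feature_names(table)) {
    v <- out[[nm]]
    out[[nm]] <- ifelse(is.na(v), "", sprintf("%.15g", v))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("lesion_id", "label") %in% names(raw)))
    stop("not a feature table CSV (missing lesion_id/label)", call. = FALSE)
  feats <- setdiff(names(raw), c("lesion_id", "label"))
  vals <- lapply(raw[feats], function(v) {
    v[v == ""] <- NA_character_
    as.numeric(v)
  })
  feature_table(as.data.frame(vals, check.names = FALSE, optional = TRUE),
                labels = raw$label, ids = raw$lesion_id)
}

#' Read / write a cohort manifest (JSON)
#'
#' A manifest maps lesion ids to image and mask files and a class label.
#' Relative paths are resolved against the manifest's directory. Each entry
#' has fields `id`, `image`, `mask`, optionally `mask_dwi` (the dilated
#' variant), and `label`.
#'
#' @param path manifest JSON path.
#' @return A list with `entries` (data frame) and `classes` (ordered label
#'   set).
#' @export
read_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- as.data.frame(man$entries, stringsAsFactors = FALSE)
  req <- c("id", "image", "mask", "label")
  if (!all(req %in% names(entries)))
    stop("manifest entries need fields id, image, mask, label", call. = FALSE)
  if (anyDuplicated(entries$id))
    stop("duplicate lesion ids in manifest", call. = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  entries$image <- resolve(entries$image)
  entries$mask <- resolve(entries$mask)
  if ("mask_dwi" %in% names(entries))
    entries$mask_dwi <- resolve(entries$mask_dwi)
  for (f in c(entries$image, entries$mask))
    if (!file.exists(f)) stop("manifest references missing file: ", f,
                              call. = FALSE)
  classes <- if (!is.null(man$classes)) as.character(man$classes)
             else unique(entries$label)
  entries <- entries[order(match(entries$label, classes), entries$id), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  list(entries = entries, classes = classes)
}

#' @rdname read_manifest
#' @param manifest a list with `entries` and `classes`.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(list(classes = manifest$classes,
                            entries = manifest$entries),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
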