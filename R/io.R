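#' Write an RGB tile to PNG or TIFF
#'
#' Format follows the file extension (`.png`, `.tif`/`.tiff`).
#'
#' @param tile an [rgb_tile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tile <- function(tile, path) {
  stopifnot(inherits(tile, "rgb_tile"))
  img <- tile$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else {
    fq_stop(sprintf("unsupported tile format '%s' (use png or tiff)", ext),
            "fq_parameter_error")
  }
  invisible(path)
}

#' Read an RGB tile from PNG or TIFF
#'
#' @param path input path (`.png`, `.tif`, `.tiff`).
#' @return An [rgb_tile()] with 0-255 channel values.
#' @export
read_tile <- function(path) {
  if (!file.exists(path)) {
    fq_stop(sprintf("tile file not found: %s", path), "fq_validation_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    fq_stop(sprintf("unsupported tile format '%s'", ext), "fq_parameter_error")
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  rgb_tile(round(img * 255), provenance = path)
}

#' Write a phantom as a label PNG plus JSON sidecar
#'
#' The label map is stored as a single-channel PNG (class code / 255) and
#' the sidecar (`<path>.json`) records the class fractions, pixel size and
#' generator seed.
#'
#' @param phantom a [generate_phantom()] result.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  png::writePNG(phantom$label_map / 255, path)
  meta <- list(classes = TISSUE_CLASSES,
               true_fractions = as.list(phantom$true_fractions),
               true_fibrosis_pct = phantom$true_fibrosis_pct,
               pixel_size_um = phantom$pixel_size_um,
               seed = phantom$seed)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom written by [write_phantom()]
#'
#' @param path the label PNG path.
#' @return A `tissue_phantom`.
#' @export
read_phantom <- function(path) {
  if (!file.exists(path)) {
    fq_stop(sprintf("phantom file not found: %s", path), "fq_validation_error")
  }
  lab <- round(png::readPNG(path) * 255)
  if (length(dim(lab)) == 3L) lab <- lab[, , 1L]
  if (!all(lab %in% 1:4)) {
    fq_stop("label PNG contains codes outside 1..4", "fq_validation_error")
  }
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  new_tissue_phantom(matrix(as.integer(lab), nrow(lab), ncol(lab)),
                     pixel_size_um = meta$pixel_size_um %||% 0.5,
                     seed = meta$seed %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to disk with a manifest
#'
#' Writes every tile (PNG), every phantom (label PNG + JSON sidecar) and a
#' manifest CSV with columns `slide_id`, `true_fibrosis_pct`, `tile_path`,
#' `label_path`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return Manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fq_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(sl) {
    tile_path <- file.path(dir, paste0(sl$slide_id, "_tile.png"))
    label_path <- file.path(dir, paste0(sl$slide_id, "_labels.png"))
    write_tile(sl$tile, tile_path)
    write_phantom(sl$phantom, label_path)
    data.frame(slide_id = sl$slide_id,
               true_fibrosis_pct = sl$true_fibrosis_pct,
               tile_path = basename(tile_path),
               label_path = basename(label_path))
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
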