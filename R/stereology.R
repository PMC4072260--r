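#' Build a systematic point grid over a region of interest
#'
#' Places a regular lattice with the given sampling interval inside a
#' half-open rectangular ROI `(row0, col0, row1, col1)` (0-based pixel
#' coordinates, exclusive upper edge), anchored at the ROI origin plus an
#' offset. A uniformly random offset (seeded) makes the point-count
#' estimator unbiased. `pattern_size` is the rendered marker extent only;
#' counting always uses the single pixel at each lattice node.
#'
#' @param roi numeric length 4: `c(row0, col0, row1, col1)`, half-open.
#' @param sampling_interval lattice spacing in pixels (default 200, the
#'   whole-slide setting at 0.5 um/pixel).
#' @param pattern_size marker glyph extent in pixels (default 20); affects
#'   only [render_grid_overlay()].
#' @param offset length-2 `(dr, dc)` in `[0, interval)`, or `"random"`.
#' @param seed integer seed used when `offset = "random"`.
#' @return Object of class `point_grid`: `points` (n x 2 matrix of 0-based
#'   row/col), `roi`, `sampling_interval`, `pattern_size`, `offset`.
#' @examples
#' g <- build_grid(c(0, 0, 1000, 1000), 200)
#' nrow(g$points)  # 25
#' @export
build_grid <- function(roi, sampling_interval = 200L, pattern_size = 20L,
                       offset = c(0L, 0L), seed = 1L) {
  if (length(roi) != 4L || roi[3] <= roi[1] || roi[4] <= roi[2]) {
    fq_stop("`roi` must be c(row0, col0, row1, col1) with row1 > row0, col1 > col0",
            "fq_parameter_error")
  }
  if (sampling_interval < 1) {
    fq_stop("`sampling_interval` must be >= 1", "fq_parameter_error")
  }
  if (identical(offset, "random")) {
    seed <- check_seed(seed)
    offset <- withr::with_seed(seed, stats::runif(2L, 0, sampling_interval))
  }
  if (length(offset) != 2L || any(offset < 0) || any(offset >= sampling_interval)) {
    fq_stop("`offset` must be two values in [0, sampling_interval)",
            "fq_parameter_error")
  }
  n_r <- ceiling((roi[3] - roi[1] - offset[1]) / sampling_interval)
  n_c <- ceiling((roi[4] - roi[2] - offset[2]) / sampling_interval)
  rows <- roi[1] + offset[1] + sampling_interval * seq_len(max(n_r, 0L)) - sampling_interval
  cols <- roi[2] + offset[2] + sampling_interval * seq_len(max(n_c, 0L)) - sampling_interval
  if (length(rows) == 0L || length(cols) == 0L) {
    fq_stop("ROI too small for a single grid point at this offset",
            "fq_empty_grid_error")
  }
  pts <- cbind(row = rep(rows, times = length(cols)),
               col = rep(cols, each = length(rows)))
  structure(list(points = pts, roi = roi,
                 sampling_interval = sampling_interval,
                 pattern_size = pattern_size, offset = offset),
            class = "point_grid")
}

#' Label grid points from a ground-truth phantom
#'
#' Automated stand-in for an observer marking every grid point: each point
#' takes the phantom class at its pixel. Point coordinates are truncated to
#' the containing pixel.
#'
#' @param grid a [build_grid()] result.
#' @param phantom a [generate_phantom()] result (or an integer label matrix
#'   with codes indexing [TISSUE_CLASSES]).
#' @return Object of class `point_labels`: data frame with `point_id`,
#'   `row`, `col`, `label`.
#' @export
auto_label_points <- function(grid, phantom) {
  stopifnot(inherits(grid, "point_grid"))
  lab_map <- if (inherits(phantom, "tissue_phantom")) phantom$label_map else phantom
  stopifnot(is.matrix(lab_map))
  r <- floor(grid$points[, 1]); c <- floor(grid$points[, 2])
  if (any(r < 0) || any(c < 0) || any(r >= nrow(lab_map)) || any(c >= ncol(lab_map))) {
    fq_stop("grid points fall outside the label map", "fq_indexing_error")
  }
  codes <- lab_map[cbind(r + 1L, c + 1L)]
  new_point_labels(data.frame(
    point_id = seq_along(codes),
    row = r, col = c,
    label = TISSUE_CLASSES[codes],
    stringsAsFactors = FALSE
  ))
}

new_point_labels <- function(df) {
  structure(list(points = df), class = "point_labels")
}

#' Read stereology point labels from CSV
#'
#' Expects columns `point_id`, `row`, `col`, `label` with labels drawn from
#' [TISSUE_CLASSES]. Rows are returned ordered by `point_id`.
#'
#' @param path CSV file path.
#' @return A `point_labels` object.
#' @export
load_point_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("point_id", "row", "col", "label")
  if (!all(need %in% names(df))) {
    fq_stop(sprintf("point-label CSV must have columns %s",
                    paste(need, collapse = ", ")), "fq_validation_error")
  }
  if (anyDuplicated(df$point_id)) {
    dup <- df$point_id[duplicated(df$point_id)][1L]
    fq_stop(sprintf("duplicated point_id %s in %s", dup, path),
            "fq_validation_error")
  }
  bad <- which(!df$label %in% TISSUE_CLASSES)
  if (length(bad)) {
    fq_stop(sprintf("unknown class '%s' at row %d of %s",
                    df$label[bad[1L]], bad[1L], path), "fq_validation_error")
  }
  if (anyNA(df[need])) {
    fq_stop(sprintf("missing values in point-label CSV %s", path),
            "fq_validation_error")
  }
  new_point_labels(df[order(df$point_id), need])
}

#' Write stereology point labels to CSV
#'
#' @param labels a `point_labels` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_point_labels <- function(labels, path) {
  stopifnot(inherits(labels, "point_labels"))
  utils::write.csv(labels$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Point-count area fraction with Weibel uncertainty
#'
#' The fibrosis area fraction is the ratio of points marked fibrosis to the
#' points counted after ignoring the glass and other categories. The
#' uncertainty is the Weibel point-counting relative standard error,
#' `RSE = sqrt((1 - p) / (p * n))`, undefined (NA) at p = 0.
#'
#' @param labels a `point_labels` object.
#' @return Object of class `point_count_result`: `counts` (per class),
#'   `n_effective`, `fraction`, `pct`, `uncertainty_rse`.
#' @examples
#' df <- data.frame(point_id = 1:5, row = 0:4, col = 0,
#'                  label = c("FIBROSIS", "MYOCARDIUM", "MYOCARDIUM",
#'                            "GLASS", "OTHER"))
#' estimate_area_fraction(structure(list(points = df), class = "point_labels"))
#' @export
estimate_area_fraction <- function(labels) {
  stopifnot(inherits(labels, "point_labels"))
  lab <- labels$points$label
  counts <- vapply(TISSUE_CLASSES, function(cl) sum(lab == cl), integer(1))
  n_eff <- counts[["MYOCARDIUM"]] + counts[["FIBROSIS"]]
  if (n_eff == 0L) {
    fq_stop("no tissue points: all grid points are glass or other",
            "fq_no_tissue_error")
  }
  p <- counts[["FIBROSIS"]] / n_eff
  rse <- if (p > 0) sqrt((1 - p) / (p * n_eff)) else NA_real_
  structure(list(counts = counts, n_effective = n_eff,
                 fraction = p, pct = 100 * p, uncertainty_rse = rse),
            class = "point_count_result")
}

#' @export
print.point_count_result <- function(x, ...) {
  cat(sprintf("Point count: %d effective points, fibrosis %.2f%% (RSE %s)\n",
              x$n_effective, x$pct,
              if (is.na(x$uncertainty_rse)) "undefined"
              else sprintf("%.3f", x$uncertainty_rse)))
  print(x$counts)
  invisible(x)
}

#' Sampling interval that guarantees a minimum point count
#'
#' Largest integer lattice spacing whose systematic grid places at least
#' `min_points` points on `area_px` pixels of tissue:
#' `floor(sqrt(area_px / min_points))`. Used to plan grids on small tiles
#' so the point-count floor for the smallest biopsies (500 points) or the
#' general 150-200-point precision recommendation is met.
#'
#' @param area_px tissue area in pixels.
#' @param min_points required number of test points (default 500).
#' @return Integer sampling interval (>= 1).
#' @export
recommended_sampling_interval <- function(area_px, min_points = 500L) {
  if (area_px <= 0 || min_points < 1) {
    fq_stop("`area_px` and `min_points` must be positive", "fq_parameter_error")
  }
  max(1L, as.integer(floor(sqrt(area_px / min_points))))
}

#' Render a grid overlay on a tile
#'
#' Draws cross markers of extent `pattern_size` at every grid point, for
#' visual inspection of grid placement.
#'
#' @param tile an [rgb_tile()].
#' @param grid a [build_grid()] result.
#' @param colour marker RGB triple, default bright green.
#' @return An [rgb_tile()] with the overlay burned in.
#' @export
render_grid_overlay <- function(tile, grid, colour = c(0, 200, 0)) {
  stopifnot(inherits(tile, "rgb_tile"), inherits(grid, "point_grid"))
  px <- tile$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  half <- max(1L, grid$pattern_size %/% 2L)
  for (i in seq_len(nrow(grid$points))) {
    r <- floor(grid$points[i, 1]) + 1L
    c <- floor(grid$points[i, 2]) + 1L
    if (r < 1 || r > h || c < 1 || c > w) next
    rr <- max(1L, r - half):min(h, r + half)
    cc <- max(1L, c - half):min(w, c + half)
    for (ch in 1:3) {
      px[rr, c, ch] <- colour[ch]
      px[r, cc, ch] <- colour[ch]
    }
  }
  rgb_tile(px, provenance = "grid overlay")
}
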