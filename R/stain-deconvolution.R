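#' Convert an RGB tile to optical density
#'
#' Per channel, `OD = -log10((pixel + 1) / I0)` with a one-count guard
#' against zero intensities; pixels brighter than the background clamp to
#' OD 0. Stains add linearly in OD space (Beer-Lambert), which is what
#' makes linear unmixing valid.
#'
#' @param tile an [rgb_tile()] or an h x w x 3 array in 0-255.
#' @param background_intensity per-channel white level I0, each > 0.
#' @return h x w x 3 numeric array of optical densities (>= 0).
#' @export
rgb_to_od <- function(tile, background_intensity = c(255, 255, 255)) {
  px <- if (inherits(tile, "rgb_tile")) tile$pixels else tile
  if (length(dim(px)) != 3L || dim(px)[3] != 3L) {
    fq_stop("`tile` must be an h x w x 3 array", "fq_parameter_error")
  }
  if (any(background_intensity <= 0)) {
    fq_stop("`background_intensity` channels must be > 0", "fq_parameter_error")
  }
  n <- prod(dim(px)[1:2])
  i0 <- rep(background_intensity, each = n)
  od <- -log10((px + 1) / i0)
  od[od < 0] <- 0
  od
}

#' Unmix optical densities into per-stain amounts
#'
#' Solves the linear Beer-Lambert mixture per pixel:
#' `amounts = OD %*% inverse(stain matrix)`. Exact (to numerical precision)
#' on noiseless composed input; amounts may come out slightly negative in
#' the presence of noise and are deliberately not clamped.
#'
#' @param od h x w x 3 OD array from [rgb_to_od()] (or an n x 3 matrix).
#' @param matrix a [stain_matrix()].
#' @return Object of class `concentration_maps`: `amounts` (n x 3 matrix,
#'   columns = stains) plus the source dimensions.
#' @export
deconvolve <- function(od, matrix = stain_matrix()) {
  stopifnot(inherits(matrix, "stain_matrix"))
  dm <- dim(od)
  if (length(dm) == 3L && dm[3] == 3L) {
    odm <- base::matrix(od, nrow = dm[1] * dm[2], ncol = 3L)
    shape <- dm[1:2]
  } else if (length(dm) == 2L && dm[2] == 3L) {
    odm <- od
    shape <- c(dm[1], 1L)
  } else {
    fq_stop("`od` must be h x w x 3 or n x 3", "fq_parameter_error")
  }
  amounts <- odm %*% matrix$inverse
  colnames(amounts) <- c("stain1", "stain2", "stain3")
  structure(list(amounts = amounts, shape = shape),
            class = "concentration_maps")
}

#' Classify pixels by stain presence
#'
#' A stain is present where its deconvolved amount strictly exceeds its
#' threshold; the per-pixel presence pattern maps to one of the eight
#' categories in [STAIN_CATEGORIES] (all-absent pixels are NONE).
#'
#' @param conc a [deconvolve()] result.
#' @param thresholds length-3 nonnegative OD amounts, default 0.15 each.
#' @return Object of class `stain_combination_map`: integer matrix
#'   `category` (codes index [STAIN_CATEGORIES]).
#' @export
classify_stains <- function(conc, thresholds = c(0.15, 0.15, 0.15)) {
  stopifnot(inherits(conc, "concentration_maps"))
  if (length(thresholds) != 3L || any(thresholds < 0)) {
    fq_stop("`thresholds` must be three values >= 0", "fq_parameter_error")
  }
  a <- conc$amounts
  pat <- (a[, 1] > thresholds[1]) +
    2L * (a[, 2] > thresholds[2]) +
    4L * (a[, 3] > thresholds[3])
  # presence bit pattern (s1 + 2 s2 + 4 s3) -> category code
  code_of_pattern <- c(1L, 2L, 3L, 5L, 4L, 6L, 7L, 8L)  # NONE,S1,S2,S12,S3,S13,S23,S123
  category <- matrix(code_of_pattern[pat + 1L], conc$shape[1], conc$shape[2])
  structure(list(category = category), class = "stain_combination_map")
}

#' Colocalization fractions and fibrosis percentage
#'
#' Tissue is the set of non-NONE pixels; the percentage of each of the
#' seven stained categories is reported over tissue, and the fibrosis
#' percentage is the sum of the collagen-bearing combinations
#' S3 + S23 + S13.
#'
#' @param map a [classify_stains()] result.
#' @return Object of class `colocalization_result`: `pct_per_category`
#'   (named, all 8 categories; NONE as % of all pixels for reference is not
#'   included — stained categories sum to 100 over tissue), `fibrosis_pct`,
#'   `tissue_pixel_count` and `markup` (an [rgb_tile()] false-colour image).
#' @export
colocalization_fractions <- function(map) {
  stopifnot(inherits(map, "stain_combination_map"))
  cat_int <- map$category
  counts <- tabulate(cat_int, nbins = 8L)
  names(counts) <- STAIN_CATEGORIES
  tissue <- sum(counts[-1L])
  if (tissue == 0L) {
    fq_stop("no tissue pixels: every pixel classified as NONE", "fq_no_tissue_error")
  }
  pct <- 100 * counts[-1L] / tissue
  fibrosis_pct <- unname(pct["S3"] + pct["S23"] + pct["S13"])
  structure(list(
    pct_per_category = pct,
    fibrosis_pct = fibrosis_pct,
    tissue_pixel_count = tissue,
    counts = counts,
    markup = markup_stain_combinations(cat_int)
  ), class = "colocalization_result")
}

#' Eight-colour markup palette for stain combinations
#'
#' Fixed documented palette, one colour per [STAIN_CATEGORIES] entry;
#' NONE renders white.
#'
#' @return 8x3 numeric matrix of 0-255 RGB rows named by category.
#' @export
stain_markup_palette <- function() {
  p <- rbind(
    NONE = c(255, 255, 255),
    S1   = c( 64,  64,  64),   # nuclear stain only: dark grey
    S2   = c(220,  60,  60),   # red stain only
    S3   = c( 60,  60, 220),   # collagen blue only
    S12  = c(230, 140,  40),   # nuclei + red: orange
    S13  = c(140,  60, 200),   # nuclei + blue: violet
    S23  = c( 60, 180, 180),   # red + blue: teal
    S123 = c( 20,  20,  20)    # all three: near-black
  )
  colnames(p) <- c("R", "G", "B")
  p
}

markup_stain_combinations <- function(cat_int) {
  pal <- stain_markup_palette()
  px <- pal[as.vector(cat_int), , drop = FALSE]
  rgb_tile(array(px, dim = c(nrow(cat_int), ncol(cat_int), 3L)),
           provenance = "stain-combination markup")
}

#' Run the full colocalization route on a tile
#'
#' Convenience wrapper: OD conversion, deconvolution, per-pixel stain
#' classification and fraction computation.
#'
#' @inheritParams rgb_to_od
#' @inheritParams classify_stains
#' @param matrix a [stain_matrix()].
#' @return A `colocalization_result` (see [colocalization_fractions()]).
#' @export
quantify_colocalization <- function(tile, matrix = stain_matrix(),
                                    background_intensity = c(255, 255, 255),
                                    thresholds = c(0.15, 0.15, 0.15)) {
  od <- rgb_to_od(tile, background_intensity)
  conc <- deconvolve(od, matrix)
  colocalization_fractions(classify_stains(conc, thresholds))
}

#' @export
print.colocalization_result <- function(x, ...) {
  cat(sprintf("Colocalization result: %d tissue px, fibrosis %.2f%%\n",
              x$tissue_pixel_count, x$fibrosis_pct))
  print(round(x$pct_per_category, 2))
  invisible(x)
}
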