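#' Generate a ground-truth tissue phantom
#'
#' Builds a per-pixel class map (GLASS / MYOCARDIUM / FIBROSIS / OTHER)
#' emulating an endomyocardial biopsy tile: a tissue blob on glass, small
#' "other" inclusions, and collagen laid down as strands/patches obtained by
#' quantile-thresholding an anisotropically smoothed Gaussian random field.
#' The number of fibrosis pixels is fixed by counting, so the achieved
#' fibrosis fraction of tissue (denominator = myocardium + fibrosis pixels)
#' matches `target_fibrosis_fraction` up to a single-pixel rounding.
#'
#' @param height,width tile dimensions in pixels (>= 32).
#' @param target_fibrosis_fraction fibrosis fraction of tissue pixels, 0-1.
#' @param morphology list of morphology settings; recognised entries
#'   `tissue_fraction` (fraction of the tile covered by tissue, default 0.7),
#'   `tissue_sigma` (edge smoothness of the tissue blob, default
#'   `min(height, width)/16`), `fibrosis_sigma` (length-2 Gaussian smoothing
#'   of the collagen field in the row/col directions; unequal values give
#'   strand-like anisotropy, default `c(2, 8)`), `other_fraction` (fraction
#'   of tissue assigned to the OTHER class, default 0.02) and `other_sigma`
#'   (blob scale of OTHER inclusions, default 3).
#' @param seed integer seed; the phantom is deterministic given it.
#' @param pixel_size_um physical pixel pitch, default 0.5 um/pixel.
#' @return Object of class `tissue_phantom`: `label_map` (integer matrix,
#'   codes index [TISSUE_CLASSES]), `pixel_size_um`, `true_fractions`
#'   (per-class pixel fractions) and `true_fibrosis_pct` (fibrosis % of
#'   tissue, glass and other excluded).
#' @examples
#' ph <- generate_phantom(64, 64, 0.2, seed = 1)
#' ph$true_fibrosis_pct
#' @export
generate_phantom <- function(height, width, target_fibrosis_fraction,
                             morphology = list(), seed,
                             pixel_size_um = 0.5) {
  if (!is.numeric(height) || !is.numeric(width) || height < 32 || width < 32) {
    fq_stop("`height` and `width` must be >= 32 pixels", "fq_parameter_error")
  }
  if (!is.numeric(target_fibrosis_fraction) ||
      target_fibrosis_fraction < 0 || target_fibrosis_fraction > 1) {
    fq_stop("`target_fibrosis_fraction` must be in [0, 1]", "fq_parameter_error")
  }
  seed <- check_seed(seed)
  height <- as.integer(height); width <- as.integer(width)

  mp <- utils::modifyList(list(
    tissue_fraction = 0.7,
    tissue_sigma    = min(height, width) / 16,
    fibrosis_sigma  = c(2, 8),
    other_fraction  = 0.02,
    other_sigma     = 3
  ), morphology)
  if (mp$tissue_fraction <= 0 || mp$tissue_fraction > 1) {
    fq_stop("`tissue_fraction` must be in (0, 1]", "fq_parameter_error")
  }
  if (mp$other_fraction < 0 || mp$other_fraction >= 1) {
    fq_stop("`other_fraction` must be in [0, 1)", "fq_parameter_error")
  }

  lab <- withr::with_seed(seed, {
    n <- height * width
    # tissue blob: smooth noise plus a radial bias keeps tissue contiguous
    ft <- gaussian_blur(matrix(stats::rnorm(n), height, width), mp$tissue_sigma)
    ft <- (ft - mean(ft)) / max(stats::sd(ft), 1e-12)
    rr <- (row(ft) - (height + 1) / 2) / (height / 2)
    cc <- (col(ft) - (width + 1) / 2) / (width / 2)
    score_t <- ft - 1.5 * (rr^2 + cc^2)
    n_tissue <- max(1L, round(mp$tissue_fraction * n))
    tissue <- rank(-score_t, ties.method = "first") <= n_tissue

    lab <- matrix(1L, height, width)          # GLASS

    # OTHER inclusions: small smooth blobs inside the tissue
    n_other <- round(mp$other_fraction * n_tissue)
    if (n_other > 0L) {
      fo <- gaussian_blur(matrix(stats::rnorm(n), height, width), mp$other_sigma)
      so <- fo
      so[!tissue] <- -Inf
      other <- rank(-so, ties.method = "first") <= n_other
      lab[other] <- 4L
    } else other <- matrix(FALSE, height, width)

    # fibrosis strands among the remaining tissue pixels, exact count
    rem <- tissue & !other
    n_rem <- sum(rem)
    ff <- gaussian_blur(matrix(stats::rnorm(n), height, width), mp$fibrosis_sigma)
    sf <- ff
    sf[!rem] <- -Inf
    k <- round(target_fibrosis_fraction * n_rem)
    if (k > 0L) {
      fib <- rank(-sf, ties.method = "first") <= k
      lab[fib] <- 3L
      lab[rem & !fib] <- 2L
    } else {
      lab[rem] <- 2L
    }
    lab
  })

  new_tissue_phantom(lab, pixel_size_um, seed)
}

new_tissue_phantom <- function(label_map, pixel_size_um, seed = NA_integer_) {
  stopifnot(is.matrix(label_map), all(label_map %in% 1:4))
  counts <- tabulate(label_map, nbins = 4L)
  fr <- counts / length(label_map)
  names(fr) <- TISSUE_CLASSES
  structure(list(
    label_map = label_map,
    pixel_size_um = pixel_size_um,
    true_fractions = fr,
    true_fibrosis_pct = fibrosis_pct_of_tissue(counts),
    seed = seed
  ), class = "tissue_phantom")
}

# fibrosis % of tissue pixels; denominator excludes GLASS and OTHER
fibrosis_pct_of_tissue <- function(counts) {
  denom <- counts[2L] + counts[3L]
  if (denom == 0L) return(NA_real_)
  100 * counts[3L] / denom
}

#' @export
print.tissue_phantom <- function(x, ...) {
  d <- dim(x$label_map)
  cat(sprintf("Tissue phantom %d x %d px (%.2f um/px)\n", d[1], d[2], x$pixel_size_um))
  print(round(100 * x$true_fractions, 2))
  cat(sprintf("fibrosis %% of tissue: %.2f\n", x$true_fibrosis_pct))
  invisible(x)
}

#' Construct an RGB tile
#'
#' Thin wrapper validating a height x width x 3 array of 8-bit channel
#' values and attaching a provenance tag.
#'
#' @param pixels numeric array `c(h, w, 3)` with values in 0-255.
#' @param provenance free-text origin tag (synthetic seed or file path).
#' @return Object of class `rgb_tile`.
#' @export
rgb_tile <- function(pixels, provenance = "unknown") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    fq_stop("`pixels` must be an h x w x 3 array", "fq_parameter_error")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    fq_stop("channel values must lie in [0, 255]", "fq_parameter_error")
  }
  structure(list(pixels = pixels, provenance = provenance), class = "rgb_tile")
}

#' @export
print.rgb_tile <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("RGB tile %d x %d px (%s)\n", d[1], d[2], x$provenance))
  invisible(x)
}

#' Render a phantom as a trichrome-stained RGB tile
#'
#' Composes per-pixel stain OD amounts (class means plus Gaussian camera
#' noise in OD units, clamped at zero) through the Beer-Lambert law:
#' `intensity = I0 * 10^(-amounts %*% od_vectors)`, then rounds to 8-bit.
#' Glass pixels carry zero mean OD and render at the background intensity.
#'
#' @param phantom a [generate_phantom()] result.
#' @param model a [stain_model()].
#' @param noise_sd SD of the per-pixel, per-stain OD noise (default 0.02).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return An [rgb_tile()].
#' @export
render_trichrome <- function(phantom, model = stain_model(), noise_sd = 0.02,
                             seed = 1L) {
  stopifnot(inherits(phantom, "tissue_phantom"), inherits(model, "stain_model"))
  if (noise_sd < 0) fq_stop("`noise_sd` must be >= 0", "fq_parameter_error")
  seed <- check_seed(seed)
  lab <- phantom$label_map
  n <- length(lab)
  amounts <- model$mean_od_per_class[as.vector(lab), , drop = FALSE]
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, matrix(stats::rnorm(3L * n, 0, noise_sd), n, 3L))
    amounts <- pmax(amounts + noise, 0)
  }
  od <- amounts %*% model$od_vectors
  px <- round(rep(model$background_intensity, each = n) * 10^(-od))
  px <- pmin(pmax(px, 0), 255)
  rgb_tile(array(px, dim = c(nrow(lab), ncol(lab), 3L)),
           provenance = sprintf("synthetic seed=%d noise_sd=%g", seed, noise_sd))
}

#' Generate a synthetic study cohort with known truth
#'
#' Draws per-slide true fibrosis percentages stratified-uniformly across
#' `fibrosis_range`, builds one phantom and one rendered tile per slide, and
#' applies a mild per-slide log-normal jitter to the staining amounts
#' (slide-to-slide staining variability).
#'
#' @param n_slides number of slides (>= 1).
#' @param fibrosis_range length-2 numeric, percent range `(lo, hi)` with
#'   `0 <= lo <= hi <= 100`; default `c(0, 90)`.
#' @param model a [stain_model()] shared by the cohort.
#' @param noise_sd per-pixel OD noise SD passed to [render_trichrome()].
#' @param tile_size length-2 integer tile dimensions, default `c(256, 256)`.
#' @param amount_jitter_sd SD of the per-slide log-normal multiplier applied
#'   stain-wise to the class OD amounts (default 0.05).
#' @param morphology passed to [generate_phantom()].
#' @param seed integer master seed; everything is reproducible from it.
#' @return Object of class `fq_cohort`: list of slides, each with
#'   `slide_id`, `true_fibrosis_pct`, `phantom` and `tile`.
#' @export
generate_cohort <- function(n_slides, fibrosis_range = c(0, 90),
                            model = stain_model(), noise_sd = 0.02,
                            tile_size = c(256L, 256L),
                            amount_jitter_sd = 0.05,
                            morphology = list(), seed) {
  if (!is.numeric(n_slides) || n_slides < 1) {
    fq_stop("`n_slides` must be >= 1", "fq_parameter_error")
  }
  lo <- fibrosis_range[1L]; hi <- fibrosis_range[2L]
  if (!is.numeric(fibrosis_range) || length(fibrosis_range) != 2L ||
      lo < 0 || hi > 100 || lo > hi) {
    fq_stop("`fibrosis_range` must satisfy 0 <= lo <= hi <= 100", "fq_parameter_error")
  }
  seed <- check_seed(seed)
  n_slides <- as.integer(n_slides)

  plan <- withr::with_seed(seed, {
    u <- stats::runif(n_slides)
    truth_pct <- lo + (hi - lo) * (seq_len(n_slides) - 1 + u) / n_slides
    list(truth_pct = truth_pct,
         sub_seeds = sample.int(2147483646L, 2L * n_slides),
         jitter = matrix(stats::rnorm(3L * n_slides, 0, amount_jitter_sd),
                         n_slides, 3L))
  })

  slides <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    amounts_i <- sweep(model$mean_od_per_class, 2L, exp(plan$jitter[i, ]), `*`)
    model_i <- stain_model(model$od_vectors, model$background_intensity, amounts_i)
    ph <- generate_phantom(tile_size[1L], tile_size[2L],
                           plan$truth_pct[i] / 100,
                           morphology = morphology,
                           seed = plan$sub_seeds[2L * i - 1L])
    tile <- render_trichrome(ph, model_i, noise_sd = noise_sd,
                             seed = plan$sub_seeds[2L * i])
    slides[[i]] <- list(slide_id = sprintf("S%03d", i),
                        true_fibrosis_pct = ph$true_fibrosis_pct,
                        phantom = ph, tile = tile)
  }
  structure(slides, class = "fq_cohort", seed = seed)
}

#' @export
print.fq_cohort <- function(x, ...) {
  tr <- vapply(x, `[[`, numeric(1), "true_fibrosis_pct")
  cat(sprintf("Synthetic cohort: %d slides, true fibrosis %.1f-%.1f%%\n",
              length(x), min(tr), max(tr)))
  invisible(x)
}

#' Simulate a pathologist's visual fibrosis score
#'
#' Adds Gaussian reading noise to the true percentages, rounds to the
#' pathologist's reporting step, and clips to \[0, 100\]:
#' `clip(step * round((truth + noise)/step), 0, 100)`.
#'
#' @param truths numeric vector of true fibrosis percentages.
#' @param noise_sd SD of the reading noise in percentage points (default 4).
#' @param rounding_step reporting granularity in percentage points
#'   (default 5, the typical visual-scoring step).
#' @param seed integer seed.
#' @return Numeric vector of scores, same length as `truths`.
#' @examples
#' simulate_pathologist(c(13.2, 40), noise_sd = 0, seed = 1)
#' @export
simulate_pathologist <- function(truths, noise_sd = 4, rounding_step = 5, seed = 1L) {
  if (rounding_step <= 0) fq_stop("`rounding_step` must be > 0", "fq_parameter_error")
  if (noise_sd < 0) fq_stop("`noise_sd` must be >= 0", "fq_parameter_error")
  seed <- check_seed(seed)
  noisy <- if (noise_sd > 0) {
    truths + withr::with_seed(seed, stats::rnorm(length(truths), 0, noise_sd))
  } else truths
  pmin(pmax(rounding_step * round(noisy / rounding_step), 0), 100)
}
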