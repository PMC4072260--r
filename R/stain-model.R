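#' Stain matrix for colour deconvolution
#'
#' Builds the 3x3 matrix of unit optical-density (OD) direction vectors used
#' for linear stain unmixing (Ruifrok-Johnston colour deconvolution). Rows
#' are stains, columns the R, G, B channels. Rows are normalised to unit
#' Euclidean length; the unmixing inverse is precomputed and stored.
#'
#' @param vectors 3x3 numeric matrix, one OD direction per row
#'   (stain 1 = nuclear counterstain, stain 2 = cytoplasm red,
#'   stain 3 = collagen blue). Defaults to [trichrome_od_vectors()].
#' @return An object of class `stain_matrix` with elements `vectors`
#'   (unit rows) and `inverse` (the 3x3 unmixing matrix).
#' @examples
#' sm <- stain_matrix()
#' rowSums(sm$vectors^2)  # all 1
#' @export
stain_matrix <- function(vectors = trichrome_od_vectors()) {
  vectors <- as.matrix(vectors)
  if (!all(dim(vectors) == c(3L, 3L)) || !is.numeric(vectors)) {
    fq_stop("`vectors` must be a numeric 3x3 matrix (rows = stains)",
            "fq_parameter_error")
  }
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) fq_stop("stain vectors must be nonzero", "fq_parameter_error")
  vectors <- vectors / nrm
  rc <- rcond(vectors)
  if (!is.finite(rc) || rc < 1e-8) {
    fq_stop("stain matrix is singular or near-singular; stains are not separable",
            "fq_configuration_error")
  }
  rownames(vectors) <- c("stain1", "stain2", "stain3")
  colnames(vectors) <- c("R", "G", "B")
  structure(list(vectors = vectors, inverse = solve(vectors)),
            class = "stain_matrix")
}

#' Default Masson-trichrome OD direction vectors
#'
#' Documented default stain directions for a Masson trichrome:
#' stain 1 Weigert's iron hematoxylin (brown-black nuclei, broad absorption
#' strongest in blue), stain 2 Biebrich scarlet / acid fuchsin (red
#' cytoplasm and muscle, absorbing green and blue), stain 3 aniline blue
#' (collagen, absorbing red and green). The triple is chosen to be
#' physically plausible and well conditioned for unmixing; every entry can
#' be overridden through [stain_matrix()].
#'
#' @return 3x3 numeric matrix of unit rows.
#' @export
trichrome_od_vectors <- function() {
  v <- rbind(
    stain1 = c(0.52, 0.46, 0.72),
    stain2 = c(0.10, 0.74, 0.67),
    stain3 = c(0.80, 0.59, 0.11)
  )
  colnames(v) <- c("R", "G", "B")
  v / sqrt(rowSums(v^2))
}

#' Rendering model for synthetic trichrome tiles
#'
#' Couples the stain OD directions with the per-channel background (glass)
#' white level and the mean OD amount each tissue class deposits on each
#' stain. Used by [render_trichrome()]; the same OD directions feed the
#' colocalization route so that synthetic tiles are exactly unmixable.
#'
#' The default class amounts put myocardium mostly on the red stain with a
#' nuclear component, fibrosis mostly on the collagen blue, and leave the
#' OTHER class nearly unstained (glass-like areas inside the myocardium).
#'
#' @param od_vectors 3x3 matrix of stain OD directions (rows normalised).
#' @param background_intensity numeric length 3, per-channel white level in
#'   (0, 255].
#' @param mean_od_per_class named list or 4x3 matrix: mean OD amount per
#'   stain for GLASS, MYOCARDIUM, FIBROSIS, OTHER.
#' @return Object of class `stain_model`.
#' @export
stain_model <- function(od_vectors = trichrome_od_vectors(),
                        background_intensity = c(255, 255, 255),
                        mean_od_per_class = default_class_amounts()) {
  sm <- stain_matrix(od_vectors)
  background_intensity <- as.numeric(background_intensity)
  if (length(background_intensity) != 3L ||
      any(background_intensity <= 0) || any(background_intensity > 255)) {
    fq_stop("`background_intensity` must be three values in (0, 255]",
            "fq_parameter_error")
  }
  amounts <- mean_od_per_class
  if (is.list(amounts)) amounts <- do.call(rbind, amounts[TISSUE_CLASSES])
  amounts <- as.matrix(amounts)
  if (!all(rownames(amounts) == TISSUE_CLASSES) || ncol(amounts) != 3L) {
    fq_stop("`mean_od_per_class` must give 3 stain amounts for each of GLASS, MYOCARDIUM, FIBROSIS, OTHER",
            "fq_parameter_error")
  }
  if (any(amounts < 0)) fq_stop("OD amounts must be >= 0", "fq_parameter_error")
  structure(list(od_vectors = sm$vectors,
                 stain_matrix = sm,
                 background_intensity = background_intensity,
                 mean_od_per_class = amounts),
            class = "stain_model")
}

#' Default per-class stain OD amounts
#'
#' Mean OD deposited by each tissue class on (stain1, stain2, stain3).
#' Values sit in the light-to-moderate staining regime where an 8-bit
#' render-unmix round trip stays quantization-limited (about 0.01 OD).
#'
#' @return 4x3 numeric matrix, rows named by [TISSUE_CLASSES].
#' @export
default_class_amounts <- function() {
  m <- rbind(
    GLASS      = c(0.00, 0.00, 0.00),
    MYOCARDIUM = c(0.20, 0.55, 0.02),
    FIBROSIS   = c(0.15, 0.04, 0.60),
    OTHER      = c(0.08, 0.03, 0.03)
  )
  colnames(m) <- c("stain1", "stain2", "stain3")
  m
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat("Stain matrix (rows = unit OD vectors)\n")
  print(round(x$vectors, 4))
  invisible(x)
}

#' @export
print.stain_model <- function(x, ...) {
  cat("Trichrome stain model\n")
  cat("  background intensity:", paste(x$background_intensity, collapse = ", "), "\n")
  cat("  OD vectors:\n")
  print(round(x$od_vectors, 4))
  cat("  mean OD per class:\n")
  print(x$mean_od_per_class)
  invisible(x)
}
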