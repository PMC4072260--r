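#' Per-pixel colour + texture features
#'
#' Computes the 9 features the trainable classifier uses: the 3 optical
#' densities plus the local mean and local (population) standard deviation
#' of each OD channel over a square window. This realises
#' "spatial recognition without morphological features": only pointwise
#' colour and local-neighbourhood statistics, no object-level shape.
#' Edges are handled by symmetric reflection; `window = 1` degenerates to
#' mean = OD and SD = 0.
#'
#' @param tile an [rgb_tile()] or h x w x 3 array.
#' @param window odd window size in pixels (default 7, i.e. about 3.5 um of
#'   context at 0.5 um/pixel).
#' @param background_intensity per-channel white level for the OD transform.
#' @return Object of class `feature_stack`: `features` (n x 9 matrix,
#'   pixels in column-major order), `shape`, `window`.
#' @export
extract_features <- function(tile, window = 7L,
                             background_intensity = c(255, 255, 255)) {
  if (window < 1 || window %% 2 == 0) {
    fq_stop("`window` must be an odd positive integer", "fq_parameter_error")
  }
  od <- rgb_to_od(tile, background_intensity)
  h <- dim(od)[1]; w <- dim(od)[2]
  feats <- matrix(0, h * w, 9L)
  for (ch in 1:3) {
    plane <- od[, , ch]
    bs <- box_stats(plane, as.integer(window))
    feats[, ch] <- as.vector(plane)
    feats[, 3L + ch] <- as.vector(bs$mean)
    feats[, 6L + ch] <- as.vector(bs$sd)
  }
  colnames(feats) <- c(paste0("od", 1:3), paste0("lmean", 1:3), paste0("lsd", 1:3))
  structure(list(features = feats, shape = c(h, w), window = as.integer(window)),
            class = "feature_stack")
}

#' Assemble a training set of marked regions
#'
#' Each example is a tile, a logical mask selecting the marked region, and
#' the class of that region. Classes come from `class_vocabulary`
#' (default glass / myocardium / fibrosis, the three classes the trainable
#' route distinguishes).
#'
#' @param examples list of `list(tile =, mask =, class =)` entries.
#' @param class_vocabulary ordered character vector of allowed classes.
#' @return Object of class `training_set`.
#' @export
training_set <- function(examples,
                         class_vocabulary = c("GLASS", "MYOCARDIUM", "FIBROSIS")) {
  if (!length(examples)) fq_stop("empty training set", "fq_validation_error")
  for (ex in examples) {
    if (!all(c("tile", "mask", "class") %in% names(ex))) {
      fq_stop("each example needs tile, mask and class", "fq_validation_error")
    }
    px <- if (inherits(ex$tile, "rgb_tile")) ex$tile$pixels else ex$tile
    if (!identical(dim(ex$mask), dim(px)[1:2])) {
      fq_stop("mask dimensions must match the tile", "fq_validation_error")
    }
    if (!ex$class %in% class_vocabulary) {
      fq_stop(sprintf("class '%s' not in vocabulary", ex$class),
              "fq_validation_error")
    }
  }
  structure(list(examples = examples, class_vocabulary = class_vocabulary),
            class = "training_set")
}

#' Build a synthetic three-class training montage
#'
#' Renders one tile of vertical class bands (glass, myocardium, fibrosis)
#' with the given stain model and returns it as a marked training set —
#' the synthetic analogue of an observer outlining example regions of each
#' class on a slide.
#'
#' @param model a [stain_model()].
#' @param band_width width of each class band in pixels (default 48).
#' @param height montage height in pixels (default 96).
#' @param noise_sd OD noise passed to [render_trichrome()].
#' @param seed integer seed.
#' @return A [training_set()] with one region per class.
#' @export
build_training_montage <- function(model = stain_model(), band_width = 48L,
                                   height = 96L, noise_sd = 0.02, seed = 1L) {
  classes <- c("GLASS", "MYOCARDIUM", "FIBROSIS")
  lab <- matrix(rep(1:3, each = band_width), nrow = height,
                ncol = 3L * band_width, byrow = TRUE)
  ph <- new_tissue_phantom(lab, pixel_size_um = 0.5)
  tile <- render_trichrome(ph, model, noise_sd = noise_sd, seed = seed)
  examples <- lapply(1:3, function(k) {
    list(tile = tile, mask = lab == k, class = classes[k])
  })
  training_set(examples, classes)
}

#' Train the per-pixel tissue classifier
#'
#' Fits a multinomial logistic model on the 9 colour + texture features of
#' the marked pixels. The iteration budget caps the optimiser's iterations;
#' inverse-frequency class weights (switchable) balance unequal region
#' sizes. Training accuracy is estimated by reclassifying the training
#' pixels with the fitted model.
#'
#' @param training a [training_set()].
#' @param iteration_budget maximum training iterations (default 1000).
#' @param window feature window passed to [extract_features()].
#' @param background_intensity per-channel white level.
#' @param class_weights use inverse-frequency class weights (default TRUE).
#' @param seed integer seed (initial weights are randomised).
#' @return List with `model` (class `genie_model`) and `report` (class
#'   `training_report`: `training_accuracy`, `n_iterations`, `confusion`).
#' @export
train_classifier <- function(training, iteration_budget = 1000L, window = 7L,
                             background_intensity = c(255, 255, 255),
                             class_weights = TRUE, seed = 1L) {
  stopifnot(inherits(training, "training_set"))
  seed <- check_seed(seed)
  feats <- list(); labs <- character(0)
  for (ex in training$examples) {
    fs <- extract_features(ex$tile, window, background_intensity)
    sel <- as.vector(ex$mask)
    feats[[length(feats) + 1L]] <- fs$features[sel, , drop = FALSE]
    labs <- c(labs, rep(ex$class, sum(sel)))
  }
  x <- do.call(rbind, feats)
  present <- intersect(training$class_vocabulary, unique(labs))
  if (length(present) < 2L) {
    fq_stop("training set must contain at least two classes",
            "fq_validation_error")
  }
  n_per <- table(factor(labs, levels = present))
  if (any(n_per < 50L)) {
    fq_stop("each class needs at least 50 labelled pixels",
            "fq_validation_error")
  }
  y <- factor(labs, levels = present)
  w <- if (class_weights) {
    as.numeric((length(y) / (length(present) * n_per))[y])
  } else rep(1, length(y))
  df <- data.frame(.class = y, x)
  fit <- withr::with_seed(seed, nnet::multinom(
    .class ~ ., data = df, weights = w,
    maxit = as.integer(iteration_budget), decay = 1e-4,
    trace = FALSE, MaxNWts = 5000L
  ))
  pred <- predict(fit, newdata = df, type = "class")
  confusion <- table(truth = y, predicted = pred)
  model <- structure(list(
    fit = fit,
    vocabulary = present,
    window = as.integer(window),
    background_intensity = background_intensity,
    feature_names = colnames(x),
    format_version = 1L
  ), class = "genie_model")
  report <- structure(list(
    training_accuracy = mean(pred == y),
    n_iterations = as.integer(iteration_budget),
    confusion = confusion
  ), class = "training_report")
  list(model = model, report = report)
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf("Training report: accuracy %.4f (%d iteration budget)\n",
              x$training_accuracy, x$n_iterations))
  print(x$confusion)
  invisible(x)
}

#' Classify every pixel of a tile
#'
#' Applies a trained [train_classifier()] model to a tile and computes the
#' fibrosis percentage of tissue (glass ignored):
#' `100 * fibrosis / (fibrosis + myocardium)`.
#'
#' @param tile an [rgb_tile()] or h x w x 3 array.
#' @param model a `genie_model`.
#' @return Object of class `class_map`: `class` (integer matrix indexing
#'   `vocabulary`), `vocabulary`, `fibrosis_pct_of_tissue` (NA when the
#'   tile contains no tissue — use [genie_fibrosis_fraction()] for the
#'   checked accessor).
#' @export
classify_tile <- function(tile, model) {
  stopifnot(inherits(model, "genie_model"))
  fs <- extract_features(tile, model$window, model$background_intensity)
  if (!identical(colnames(fs$features), model$feature_names)) {
    fq_stop("feature definition does not match the trained model",
            "fq_configuration_error")
  }
  pred <- predict(model$fit, newdata = as.data.frame(fs$features), type = "class")
  codes <- match(as.character(pred), model$vocabulary)
  cls <- matrix(codes, fs$shape[1], fs$shape[2])
  counts <- tabulate(codes, nbins = length(model$vocabulary))
  names(counts) <- model$vocabulary
  nf <- if ("FIBROSIS" %in% model$vocabulary) counts[["FIBROSIS"]] else 0L
  nm <- if ("MYOCARDIUM" %in% model$vocabulary) counts[["MYOCARDIUM"]] else 0L
  pct <- if (nf + nm > 0L) 100 * nf / (nf + nm) else NA_real_
  structure(list(class = cls, vocabulary = model$vocabulary,
                 counts = counts, fibrosis_pct_of_tissue = pct),
            class = "class_map")
}

#' Fibrosis percentage of tissue from a class map
#'
#' `100 * n_FIBROSIS / (n_FIBROSIS + n_MYOCARDIUM)`; glass is ignored.
#' Raises a no-tissue error when the map contains neither fibrosis nor
#' myocardium pixels.
#'
#' @param class_map a [classify_tile()] result.
#' @return Percentage in \[0, 100\].
#' @export
genie_fibrosis_fraction <- function(class_map) {
  stopifnot(inherits(class_map, "class_map"))
  if (is.na(class_map$fibrosis_pct_of_tissue)) {
    fq_stop("no tissue pixels: tile classified entirely as glass",
            "fq_no_tissue_error")
  }
  class_map$fibrosis_pct_of_tissue
}

#' Class-map markup image
#'
#' False-colour rendering of a [classify_tile()] result: glass white,
#' myocardium red, fibrosis blue.
#'
#' @param class_map a `class_map`.
#' @return An [rgb_tile()].
#' @export
render_class_markup <- function(class_map) {
  stopifnot(inherits(class_map, "class_map"))
  pal <- rbind(GLASS = c(255, 255, 255),
               MYOCARDIUM = c(220, 60, 60),
               FIBROSIS = c(60, 60, 220))
  px <- pal[class_map$vocabulary[as.vector(class_map$class)], , drop = FALSE]
  rgb_tile(array(px, dim = c(dim(class_map$class), 3L)),
           provenance = "class markup")
}

#' Save / load a trained classifier
#'
#' The model is written as a single portable RDS file carrying a
#' format-version header.
#'
#' @param model a `genie_model`.
#' @param path file path.
#' @return `path` (save) or the restored `genie_model` (load).
#' @export
save_genie_model <- function(model, path) {
  stopifnot(inherits(model, "genie_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_genie_model
#' @export
load_genie_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "genie_model") || is.null(model$format_version)) {
    fq_stop("not a fibroquant classifier file", "fq_validation_error")
  }
  model
}
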