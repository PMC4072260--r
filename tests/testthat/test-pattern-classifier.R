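test_that("feature extraction computes local statistics with the right degeneracies", {
  # constant tile: all local SDs are exactly zero
  flat <- array(120, c(16, 16, 3))
  fs <- extract_features(flat, window = 5)
  expect_true(all(fs$features[, 7:9] == 0))
  expect_equal(fs$features[, 4:6], fs$features[, 1:3], ignore_attr = TRUE)

  # window = 1 degenerates to raw OD and zero SD
  set.seed(1)
  noisy <- array(sample(0:255, 16 * 16 * 3, TRUE), c(16, 16, 3))
  f1 <- extract_features(noisy, window = 1)
  expect_equal(f1$features[, 4:6], f1$features[, 1:3], ignore_attr = TRUE)
  expect_true(all(f1$features[, 7:9] == 0))

  expect_error(extract_features(flat, window = 4), class = "fq_parameter_error")
})

test_that("local SD on a checkerboard matches the closed-form population SD", {
  px <- array(0, c(8, 8, 3))
  for (ch in 1:3) px[, , ch] <- ifelse((row(matrix(0, 8, 8)) + col(matrix(0, 8, 8))) %% 2 == 0, 200, 50)
  fs <- extract_features(px, window = 3)
  od <- rgb_to_od(px)
  a <- od[4, 4, 1]; b <- od[4, 5, 1]   # the two alternating OD values, channel 1
  m <- (5 * a + 4 * b) / 9             # (4,4) has 5 cells of its own colour in the 3x3
  idx <- (4 - 1) * 8 + 4               # column-major index of pixel (4,4)
  expect_equal(unname(fs$features[idx, 7]),
               sqrt((5 * (a - m)^2 + 4 * (b - m)^2) / 9), tolerance = 1e-9)
})

test_that("training on separable synthetic classes reaches near-perfect accuracy, deterministically", {
  mont <- build_training_montage(noise_sd = 0.02, seed = 2)
  tr1 <- train_classifier(mont, iteration_budget = 1000, seed = 4)
  expect_gte(tr1$report$training_accuracy, 0.99)
  expect_equal(sum(tr1$report$confusion), 96L * 144L)
  expect_true(all(rowSums(tr1$report$confusion) ==
                    table(factor(rep(c("GLASS", "MYOCARDIUM", "FIBROSIS"),
                                     each = 96 * 48),
                                 levels = tr1$model$vocabulary))))

  tr2 <- train_classifier(mont, iteration_budget = 1000, seed = 4)
  expect_identical(coef(tr1$model$fit), coef(tr2$model$fit))
  expect_identical(tr1$report$training_accuracy, tr2$report$training_accuracy)

  single <- training_set(mont$examples[2], mont$class_vocabulary)
  expect_error(train_classifier(single, seed = 1), class = "fq_validation_error")
})

test_that("duplicating every training region leaves the fitted model unchanged", {
  mont <- build_training_montage(noise_sd = 0.02, seed = 5)
  doubled <- training_set(c(mont$examples, mont$examples), mont$class_vocabulary)
  tr <- train_classifier(mont, iteration_budget = 300, seed = 7)
  trd <- train_classifier(doubled, iteration_budget = 300, seed = 7)
  # class proportions are unchanged, so inverse-frequency weighting keeps the
  # decision rule the same; coefficients may shift slightly through the
  # ridge penalty, so compare decisions, not parameters
  expect_equal(tr$report$training_accuracy, trd$report$training_accuracy)
  probe <- render_trichrome(generate_phantom(64, 64, 0.35, seed = 9),
                            noise_sd = 0.02, seed = 11)
  expect_identical(classify_tile(probe, tr$model)$class,
                   classify_tile(probe, trd$model)$class)
})

test_that("classification recovers clean synthetic tiles and the tissue rule", {
  mont <- build_training_montage(noise_sd = 0.02, seed = 2)
  model <- train_classifier(mont, seed = 4)$model

  glass_tile <- render_trichrome(uniform_phantom("GLASS", 64, 64), noise_sd = 0.02, seed = 3)
  cm <- classify_tile(glass_tile, model)
  expect_gte(mean(model$vocabulary[cm$class] == "GLASS"), 0.99)
  expect_error(genie_fibrosis_fraction(cm), class = "fq_no_tissue_error")

  ph <- generate_phantom(128, 128, 0.30, seed = 10)
  tile <- render_trichrome(ph, noise_sd = 0, seed = 1)
  est <- genie_fibrosis_fraction(classify_tile(tile, model))
  expect_lt(abs(est - ph$true_fibrosis_pct), 2)
})

test_that("the fibrosis fraction arithmetic ignores glass", {
  cm <- structure(list(class = matrix(0L, 1, 1),
                       vocabulary = c("GLASS", "MYOCARDIUM", "FIBROSIS"),
                       counts = c(GLASS = 5000L, MYOCARDIUM = 800L, FIBROSIS = 200L),
                       fibrosis_pct_of_tissue = 100 * 200 / 1000),
                  class = "class_map")
  expect_equal(genie_fibrosis_fraction(cm), 20)
})

test_that("permuting the class vocabulary permutes outputs consistently", {
  mont <- build_training_montage(noise_sd = 0.02, seed = 2)
  perm_examples <- rev(mont$examples)
  mont_perm <- training_set(perm_examples, rev(mont$class_vocabulary))
  m1 <- train_classifier(mont, seed = 4)$model
  m2 <- train_classifier(mont_perm, seed = 4)$model
  tile <- render_trichrome(generate_phantom(64, 64, 0.4, seed = 3),
                           noise_sd = 0.02, seed = 6)
  c1 <- classify_tile(tile, m1)
  c2 <- classify_tile(tile, m2)
  expect_equal(m1$vocabulary[c1$class], m2$vocabulary[c2$class])
})

test_that("models survive a save/load round trip", {
  mont <- build_training_montage(noise_sd = 0.02, seed = 2)
  model <- train_classifier(mont, iteration_budget = 200, seed = 4)$model
  path <- withr::local_tempfile(fileext = ".rds")
  save_genie_model(model, path)
  back <- load_genie_model(path)
  expect_identical(coef(back$fit), coef(model$fit))
  expect_identical(back$vocabulary, model$vocabulary)
})
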