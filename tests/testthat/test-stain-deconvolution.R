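test_that("OD conversion matches the guarded closed form", {
  px <- array(0, dim = c(1, 3, 3))
  px[1, 1, ] <- c(255, 255, 255)   # white background
  px[1, 2, ] <- c(25.5, 25.5, 25.5) # one decade of attenuation
  px[1, 3, ] <- c(0, 0, 0)          # fully dark, guard kicks in
  od <- rgb_to_od(px, c(255, 255, 255))
  expect_equal(od[1, 1, ], c(0, 0, 0))                      # clamped at 0
  expect_equal(od[1, 2, ], rep(-log10(26.5 / 255), 3))      # ~0.983, epsilon effect
  expect_equal(od[1, 3, ], rep(log10(255), 3))              # ~2.407
  expect_true(all(od >= 0))
})

test_that("deconvolution is linear and inverts composition to numerical precision", {
  sm <- stain_matrix()
  # zero OD -> zero amounts
  expect_true(all(deconvolve(array(0, c(4, 4, 3)), sm)$amounts == 0))

  # basis case: OD equal to one stain vector
  od3 <- array(rep(sm$vectors[3, ], each = 1), c(1, 1, 3))
  expect_equal(as.vector(deconvolve(od3, sm)$amounts), c(0, 0, 1),
               tolerance = 1e-9)

  # round trip on random nonnegative amounts
  set.seed(123)
  a <- matrix(runif(300, 0, 1.5), ncol = 3)
  od <- a %*% sm$vectors
  rec <- deconvolve(array(od, c(100, 1, 3)), sm)$amounts
  expect_lt(max(abs(rec - a)), 1e-9)

  expect_error(stain_matrix(matrix(1, 3, 3)), class = "fq_configuration_error")
})

test_that("stain presence follows the strict-threshold truth table for all 8 patterns", {
  thr <- c(0.15, 0.15, 0.15)
  hi <- 0.5
  pats <- expand.grid(s1 = c(FALSE, TRUE), s2 = c(FALSE, TRUE), s3 = c(FALSE, TRUE))
  amounts <- as.matrix(pats) * hi
  map <- classify_stains(conc_from_amounts(amounts), thr)
  expected <- c("NONE", "S1", "S2", "S12", "S3", "S13", "S23", "S123")
  expect_equal(STAIN_CATEGORIES[as.vector(map$category)], expected)

  # amounts exactly at the threshold count as absent (strict >)
  at <- classify_stains(conc_from_amounts(rbind(c(0.15, 0.15, 0.15))), thr)
  expect_equal(STAIN_CATEGORIES[at$category[1, 1]], "NONE")

  # negative amounts simply fail the threshold
  neg <- classify_stains(conc_from_amounts(rbind(c(-0.4, 0.2, -0.1))), thr)
  expect_equal(STAIN_CATEGORIES[neg$category[1, 1]], "S2")
})

test_that("colocalization fractions follow the tissue-denominator rule", {
  codes <- c(rep(4L, 30), rep(6L, 10), rep(3L, 60), rep(1L, 900))  # S3, S13, S2, NONE
  map <- structure(list(category = matrix(codes, 100, 10)),
                   class = "stain_combination_map")
  res <- colocalization_fractions(map)
  expect_equal(res$tissue_pixel_count, 100L)
  expect_equal(res$fibrosis_pct, 40)
  expect_equal(sum(res$pct_per_category), 100, tolerance = 1e-9)

  all_s3 <- structure(list(category = matrix(4L, 5, 5)),
                      class = "stain_combination_map")
  expect_equal(colocalization_fractions(all_s3)$fibrosis_pct, 100)

  all_none <- structure(list(category = matrix(1L, 5, 5)),
                        class = "stain_combination_map")
  expect_error(colocalization_fractions(all_none), class = "fq_no_tissue_error")
})

test_that("raising the collagen threshold never increases the fibrosis estimate", {
  ph <- generate_phantom(96, 96, 0.35, seed = 3)
  tile <- render_trichrome(ph, noise_sd = 0.05, seed = 8)
  od <- rgb_to_od(tile)
  conc <- deconvolve(od)
  prev <- Inf
  for (t3 in c(0.05, 0.15, 0.3, 0.5, 0.7)) {
    res <- colocalization_fractions(
      classify_stains(conc, c(0.15, 0.15, t3)))
    expect_lte(res$fibrosis_pct, prev + 1e-12)
    prev <- res$fibrosis_pct
  }
})

test_that("consistently permuting stains permutes the category percentages", {
  ph <- generate_phantom(96, 96, 0.3, seed = 6)
  tile <- render_trichrome(ph, noise_sd = 0.03, seed = 2)
  v <- trichrome_od_vectors()
  thr <- c(0.1, 0.15, 0.2)
  base <- colocalization_fractions(classify_stains(
    deconvolve(rgb_to_od(tile), stain_matrix(v)), thr))
  # swap stains 2 and 3 in the matrix and the thresholds
  swapped <- colocalization_fractions(classify_stains(
    deconvolve(rgb_to_od(tile), stain_matrix(v[c(1, 3, 2), ])),
    thr[c(1, 3, 2)]))
  perm <- c(S1 = "S1", S2 = "S3", S3 = "S2", S12 = "S13",
            S13 = "S12", S23 = "S23", S123 = "S123")
  expect_equal(unname(swapped$pct_per_category[perm]),
               unname(base$pct_per_category[names(perm)]))
})

test_that("noiseless synthetic tiles are recovered within one percentage point", {
  for (target in c(0.1, 0.5, 0.85)) {
    ph <- generate_phantom(128, 128, target, seed = round(100 * target))
    tile <- render_trichrome(ph, noise_sd = 0, seed = 1)
    res <- quantify_colocalization(tile)
    expect_lt(abs(res$fibrosis_pct - ph$true_fibrosis_pct), 1)
  }
})

test_that("the markup uses the documented eight-colour palette with NONE white", {
  pal <- stain_markup_palette()
  expect_identical(rownames(pal), STAIN_CATEGORIES)
  expect_equal(unname(pal["NONE", ]), c(255, 255, 255))
  codes <- matrix(c(1L, 4L), 1, 2)
  mk <- fibroquant:::markup_stain_combinations(codes)
  expect_equal(mk$pixels[1, 1, ], unname(pal["NONE", ]))
  expect_equal(mk$pixels[1, 2, ], unname(pal["S3", ]))
})
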