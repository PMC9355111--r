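test_that("image fraction is fat over tissue on the percent scale", {
  expect_equal(image_steatosis_fraction(
    list(fat_pixels = 0, tissue_pixels = 10000))$steatosis_percent, 0)
  expect_equal(image_steatosis_fraction(
    list(fat_pixels = 10000, tissue_pixels = 10000))$steatosis_percent, 100)
  expect_equal(image_steatosis_fraction(
    list(fat_pixels = 580, tissue_pixels = 10000))$steatosis_percent, 5.8)
  expect_error(image_steatosis_fraction(
    list(fat_pixels = 0, tissue_pixels = 0)), "no-tissue")
})

test_that("phantom image fraction lands near the rendered ground truth", {
  ph <- generate_he_phantom(phantom_spec(target_fat_fraction = 0.12, seed = 31))
  seg <- segment_image(ph$image)
  sc <- image_steatosis_fraction(seg)
  expect_lt(abs(sc$steatosis_percent - ph$truth$fat_fraction_percent), 1.5)
})

test_that("liver score applies the one-pass +/- 1 SD omission rule", {
  # zero variance: nothing omitted
  expect_equal(liver_steatosis_score(c(10, 10, 10))$final_percent, 10)

  # hand-computed: m = 21.5, s = sd = 19.1; 50 falls outside [2.4, 40.6]
  ls <- liver_steatosis_score(c(10, 12, 14, 50))
  expect_equal(ls$mean, 21.5)
  expect_equal(ls$sd, sd(c(10, 12, 14, 50)))
  expect_equal(ls$retained, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(ls$final_percent, 12)

  # singleton passes through
  expect_equal(liver_steatosis_score(7.3)$final_percent, 7.3)
  expect_error(liver_steatosis_score(numeric(0)), "at least one")

  # scores exactly at m +/- s are retained (closed interval)
  x <- c(0, 10, 20)  # m = 10, s = 10; all endpoints inclusive
  expect_true(all(liver_steatosis_score(x)$retained))
})

test_that("outlier omission never empties the retained set and is permutation-invariant", {
  set.seed(77)
  for (i in 1:1000) {
    x <- runif(sample(1:8, 1), 0, 100)
    ls <- liver_steatosis_score(x)
    expect_gt(sum(ls$retained), 0)
    expect_gte(ls$final_percent, min(x[ls$retained]))
    expect_lte(ls$final_percent, max(x[ls$retained]))
  }
  x <- runif(7, 0, 60)
  p <- sample(7)
  expect_equal(liver_steatosis_score(x)$final_percent,
               liver_steatosis_score(x[p])$final_percent)
})

test_that("strict control estimate counts green over green plus black", {
  # constructed counts: 580 green / 9420 black -> 5.8%
  img <- array(0L, dim = c(100, 100, 3))
  img[, , 1:3] <- 0L                        # all black
  sel <- seq_len(580)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[sel] <- c(0L, 200L, 0L)[ch]
    img[, , ch] <- plane
  }
  expect_equal(strict_estimate_from_control(img), 5.8)

  # all black: 0%
  expect_equal(strict_estimate_from_control(array(0L, dim = c(20, 20, 3))), 0)

  # half green / half gray: gray excluded, so 100%
  img2 <- array(128L, dim = c(20, 20, 3))
  for (ch in 1:3) {
    plane <- img2[, , ch]
    plane[1:200] <- c(0L, 200L, 0L)[ch]
    img2[, , ch] <- plane
  }
  expect_equal(strict_estimate_from_control(img2), 100)

  # no green or black at all: error
  expect_error(strict_estimate_from_control(array(128L, dim = c(10, 10, 3))),
               "no green or black")
})

test_that("strict estimate is noise-tolerant via nearest-colour classification", {
  ctrl <- generate_control_phantom(phantom_spec(target_fat_fraction = 0.08,
                                                seed = 19))
  noisy <- ctrl$image + array(sample(-20:20, length(ctrl$image), TRUE),
                              dim = dim(ctrl$image))
  noisy[noisy < 0] <- 0L; noisy[noisy > 255] <- 255L
  expect_equal(strict_estimate_from_control(noisy),
               ctrl$truth$fat_fraction_percent, tolerance = 1e-6)
})

test_that("strict estimate agrees with the pipeline fraction convention", {
  # mapping green -> fat and green + black -> tissue must give the same
  # number as the strict estimate on the identical control image
  ctrl <- generate_control_phantom(phantom_spec(target_fat_fraction = 0.15,
                                                seed = 8))
  img <- ctrl$image
  green_n <- sum(img[, , 1] == 0 & img[, , 2] == 200 & img[, , 3] == 0)
  black_n <- sum(img[, , 1] == 0 & img[, , 2] == 0 & img[, , 3] == 0)
  sc <- image_steatosis_fraction(list(fat_pixels = green_n,
                                      tissue_pixels = green_n + black_n))
  expect_equal(sc$steatosis_percent, strict_estimate_from_control(img))
  expect_equal(sc$steatosis_percent, ctrl$truth$fat_fraction_percent)
})
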