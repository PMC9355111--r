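cfg <- seg_config()

test_that("all-tissue phantoms score zero steatosis", {
  for (s in 1:3) {
    ph <- generate_he_phantom(phantom_spec(droplet_count = 0, border = FALSE,
                                           seed = s))
    seg <- segment_image(ph$image, cfg)
    expect_equal(seg$fat_pixels, 0)
    expect_equal(seg$steatosis_percent, 0)
    expect_equal(nrow(seg$regions), 0L)
  }
})

test_that("non-overlapping droplets are each recovered as one region", {
  set.seed(3)
  m <- matrix(FALSE, 640, 480)
  placed <- 0
  centers <- list()
  while (placed < 30) {
    cx <- runif(1, 20, 620); cy <- runif(1, 20, 460)
    if (length(centers) &&
        any(vapply(centers, function(p) sum((p - c(cx, cy))^2), 1) < 30^2)) next
    m <- disk_mask(8, base = m, nx = 640, ny = 480, cx = cx, cy = cy)
    centers[[placed + 1]] <- c(cx, cy); placed <- placed + 1
  }
  seg <- segment_image(he_image(m), cfg)
  expect_equal(nrow(seg$regions), 30L)
  expect_lt(abs(seg$fat_pixels - sum(m)) / sum(m), 0.02)
})

test_that("tears and lumina are excluded while droplets are kept", {
  m <- matrix(FALSE, 640, 480)
  for (cx in seq(60, 600, by = 60)) m <- disk_mask(8, base = m, nx = 640,
                                                   ny = 480, cx = cx, cy = 100)
  truth_fat <- sum(m)
  # a ~3000 px tear and an elongated ~1000 px lumen
  tear <- disk_mask(31, nx = 640, ny = 480, cx = 320, cy = 300)
  expect_gt(sum(tear), 2000)
  lumen <- matrix(FALSE, 640, 480)
  lumen[101:180, 401:413] <- TRUE  # 80 x 13 = 1040 px, C1 well below 0.3
  seg <- segment_image(he_image(m | tear | lumen), cfg)
  expect_equal(nrow(seg$regions), 10L)
  expect_lt(abs(seg$fat_pixels - truth_fat) / truth_fat, 0.05)
  # excluded artifact pixels belong to neither fat nor tissue
  expect_equal(seg$tissue_pixels,
               sum(!(m | tear | lumen)) + seg$fat_pixels)
})

test_that("every stage's white set stays within the binarized white set", {
  ph <- generate_he_phantom(phantom_spec(droplet_count = 25, clustering = 0.4,
                                         tears = 1, lumina = 1, seed = 9))
  seg <- segment_image(ph$image, cfg, keep_stages = TRUE)
  st <- seg$stages
  expect_true(all(st$eroded <= st$binarized))
  expect_true(all(st$background_filtered <= st$eroded))
  expect_true(all(st$first_pass <= st$background_filtered))
  expect_true(all(st$dilated <= st$binarized))
  expect_true(all(seg$final_mask <= st$dilated))
})

test_that("adding one disjoint droplet adds exactly one region and never lowers fat", {
  set.seed(5)
  base <- matrix(FALSE, 640, 480)
  for (cx in seq(80, 560, by = 80)) base <- disk_mask(9, base = base, nx = 640,
                                                      ny = 480, cx = cx, cy = 240)
  seg0 <- segment_image(he_image(base), cfg)
  for (r in c(4, 7, 11)) {
    extra <- disk_mask(r, base = base, nx = 640, ny = 480, cx = 320, cy = 100)
    seg1 <- segment_image(he_image(extra), cfg)
    expect_equal(nrow(seg1$regions), nrow(seg0$regions) + 1L)
    expect_gte(seg1$fat_pixels, seg0$fat_pixels)
  }
})

test_that("segmentation is deterministic", {
  ph <- generate_he_phantom(phantom_spec(droplet_count = 15, tears = 1,
                                         seed = 13))
  s1 <- segment_image(ph$image, cfg)
  s2 <- segment_image(ph$image, cfg)
  expect_identical(s1$final_mask, s2$final_mask)
  expect_identical(s1$steatosis_percent, s2$steatosis_percent)
})

test_that("non-reference frame sizes warn and rescale area thresholds", {
  m <- disk_mask(5, nx = 320, ny = 240, cx = 160, cy = 120)
  expect_warning(seg <- segment_image(he_image(m), cfg), "rescaled")
  expect_equal(seg$area_scale, 0.25)
  expect_equal(nrow(seg$regions), 1L)
  # rescaling off: same image, no warning
  cfg2 <- seg_config(rescale = FALSE)
  expect_silent(seg2 <- segment_image(he_image(m), cfg2))
  expect_equal(seg2$area_scale, 1)
})

test_that("degenerate inputs raise the no-tissue error", {
  dark <- array(5L, dim = c(64, 64, 3))
  expect_error(suppressWarnings(segment_image(dark, cfg)), "no-tissue")
})

test_that("unknown configuration keys are rejected", {
  expect_error(read_seg_config(NULL, not_a_key = 1), "unknown configuration")
  f <- tempfile(fileext = ".yaml")
  writeLines(c("lower_bound: 90", "c2_min_second: 0.8"), f)
  expect_error(read_seg_config(f), "unknown configuration")
  writeLines(c("lower_bound: 90", "second_c2_min: 0.8"), f)
  cfg3 <- read_seg_config(f)
  expect_equal(cfg3$lower_bound, 90)
  expect_equal(cfg3$second_c2_min, 0.8)
})
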