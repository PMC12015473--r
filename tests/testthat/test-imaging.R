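# Imaging: reading, segmentation, and calibrated morphometrics.

test_that("read_scan attaches the stated dpi and promotes grayscale", {
  tmp <- withr::local_tempfile(fileext = ".png")
  px <- array(runif(30 * 20 * 3), c(30, 20, 3))
  png::writePNG(px, tmp)
  img <- read_scan(tmp, dpi = 600, accession_id = "A1")
  expect_s3_class(img, "scan_image")
  expect_equal(dim(img$pixels), c(30, 20, 3))
  expect_equal(px_scale(img), 2.54 / 600)

  # grayscale promotion: R = G = B
  png::writePNG(matrix(runif(25), 5, 5), tmp)
  g <- read_scan(tmp, dpi = 600)
  expect_equal(g$pixels[, , 1], g$pixels[, , 2])
  expect_equal(g$pixels[, , 1], g$pixels[, , 3])

  # degenerate 1x1 black scan is valid; segmentation yields no buds
  png::writePNG(array(0, c(1, 1, 3)), tmp)
  tiny <- read_scan(tmp, dpi = 600)
  expect_warning(masks <- segment_buds(tiny), "degenerate|background")
  expect_length(masks, 0)

  expect_error(read_scan(tmp, dpi = -1), "positive")
  expect_error(read_scan(file.path(tempdir(), "nope.png")), "not found")
})

test_that("segmentation finds exactly the placed shapes, none border-touching", {
  sc <- three_bud_scene()
  masks <- segment_buds(sc$image)
  expect_length(masks, nrow(sc$truth))
  expect_false(any(vapply(masks, `[[`, TRUE, "touches_border")))
  # reading order: row-major by bbox top-left
  tops <- vapply(masks, function(m) m$bbox[1], 1)
  lefts <- vapply(masks, function(m) m$bbox[2], 1)
  expect_equal(order(tops, lefts), seq_along(masks))
  # masks are single 8-connected components with tight bboxes
  for (m in masks) {
    expect_gt(sum(m$mask), 0)
    expect_true(any(m$mask[1, ]) && any(m$mask[nrow(m$mask), ]) &&
                any(m$mask[, 1]) && any(m$mask[, ncol(m$mask)]))
  }
})

test_that("uniform black image segments to an empty list", {
  img <- scan_image(array(0L, c(64, 64, 3)), dpi = 600)
  expect_warning(masks <- segment_buds(img), "degenerate|background")
  expect_length(masks, 0)
})

test_that("border-touching components are excluded by default, kept on request", {
  # bright block overlapping the top border
  px <- array(10L, c(120, 120, 3))
  px[1:40, 40:80, ] <- 200L
  img <- scan_image(px, dpi = 600)
  cfg <- segmentation_config(min_area_cm2 = 0.001)
  expect_length(segment_buds(img, cfg), 0)
  cfg2 <- segmentation_config(min_area_cm2 = 0.001, exclude_border = FALSE)
  kept <- segment_buds(img, cfg2)
  expect_length(kept, 1)
  expect_true(kept[[1]]$touches_border)
})

test_that("label8 merges diagonally-touching pixels into one component", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- m[3, 3] <- m[4, 4] <- TRUE   # diagonal chain
  m[6, 6] <- TRUE                          # separate
  lab <- budmetrics:::label8(m)
  expect_equal(max(lab), 2L)
  expect_equal(length(unique(lab[cbind(2:4, 2:4)])), 1L)
})

test_that("measured features match closed forms within 2% at 600 dpi", {
  cases <- list(
    list(kind = "stadium", L = 2.65, W = 0.35, ang = 23),
    list(kind = "stadium", L = 1.60, W = 0.45, ang = 77),
    list(kind = "ellipse", L = 2.65, W = 0.35, ang = 33),
    list(kind = "circle",  L = 1.00, W = 1.00, ang = 0))
  for (cs in cases) {
    rm_ <- render_and_measure(cs$kind, cs$L, cs$W, cs$ang)
    f <- rm_$features; sp <- rm_$shape
    expect_lt(abs(f$length_cm / cs$L - 1), 0.02, label =
      sprintf("%s length", cs$kind))
    expect_lt(abs(f$width_cm / cs$W - 1), 0.02)
    expect_lt(abs(f$perimeter_cm / sp$perimeter_cm - 1), 0.02)
    expect_lt(abs(f$area_cm2 / sp$area_cm2 - 1), 0.02)
    # all invariants of a feature row
    expect_gte(f$length_cm, f$width_cm)
    expect_gte(f$perimeter_cm, 2 * sqrt(pi * f$area_cm2))
    expect_lte(f$area_cm2, f$length_cm * f$width_cm * 1.001)
  }
})

test_that("circle forces L = W and stadium area matches aW + pi(W/2)^2", {
  rm_ <- render_and_measure("circle", 1, 1)
  expect_lt(abs(rm_$features$length_cm - rm_$features$width_cm), 0.02)
  expect_lt(abs(rm_$features$area_cm2 - pi / 4), 0.02 * pi / 4)

  a <- 2.65 - 0.35
  expect_equal(shape_spec("stadium", 2.65, 0.35, c(1, 1))$area_cm2,
               a * 0.35 + pi * (0.35 / 2)^2)
  expect_equal(shape_spec("stadium", 2.65, 0.35, c(1, 1))$perimeter_cm,
               2 * a + pi * 0.35)
})

test_that("single-pixel mask gets the degenerate convention", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  s <- 2.54 / 600
  expect_message(f <- measure_bud(m, s), "degenerate")
  expect_equal(unlist(f),
               c(length_cm = s, width_cm = s, perimeter_cm = 4 * s,
                 area_cm2 = s^2))
})

test_that("features are stable under rescaling and rotation of the scene", {
  # scale equivariance: same shape at 300 and 600 dpi
  f1 <- render_and_measure("stadium", 2.0, 0.4, 30, dpi = 300)$features
  f2 <- render_and_measure("stadium", 2.0, 0.4, 30, dpi = 600)$features
  s300 <- 2.54 / 300
  expect_lt(abs(f1$length_cm - f2$length_cm), 2 * s300)
  expect_lt(abs(f1$width_cm - f2$width_cm), 2 * s300)
  expect_lt(abs(f1$perimeter_cm - f2$perimeter_cm), 4 * s300)

  # rotation invariance at 600 dpi: <= 2% feature change
  fa <- render_and_measure("stadium", 2.0, 0.4, 0)$features
  fb <- render_and_measure("stadium", 2.0, 0.4, 52.3)$features
  for (col in names(fa))
    expect_lt(abs(fb[[col]] / fa[[col]] - 1), 0.02, label = col)
})

test_that("extract_features composes per-mask measurements and survives failures", {
  sc <- three_bud_scene()
  tab <- extract_features(list(sc$image))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$bud_index, 1:3)
  # composition: rows equal direct measure_bud calls
  masks <- segment_buds(sc$image)
  direct <- do.call(rbind, lapply(masks, measure_bud,
                                  s = px_scale(sc$image)))
  expect_equal(tab$length_cm, direct$length_cm)
  expect_equal(tab$area_cm2, direct$area_cm2)

  expect_equal(nrow(extract_features(list())), 0)

  # two images -> 6 rows
  tab2 <- extract_features(list(sc$image, sc$image))
  expect_equal(nrow(tab2), 6)
})

test_that("validation regression behaves on identity, bias and noise", {
  truth <- c(1.5, 2.0, 2.5, 3.0, 3.5)
  v <- validate_against_reference(truth, truth)
  expect_equal(v$r_squared, 1)
  expect_equal(v$rmse, 0)
  v2 <- validate_against_reference(truth + 0.05, truth)
  expect_equal(v2$r_squared, 1)
  expect_equal(v2$rmse, 0.05)
  expect_error(validate_against_reference(truth, rep(2, 5)), "variance")
})
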