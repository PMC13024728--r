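test_that("alignment puts the top-to-low axis vertical at length Lref", {
  img <- matrix(128, 150, 160)
  vert <- neck_boxes(pixel_box(40, 10, 60, 30), pixel_box(40, 110, 60, 130))
  al <- align_neck(img, vert, nset_config(Lref = 200))
  expect_equal(al$phi, pi / 2)
  expect_equal(al$angle, 0)
  expect_equal(al$s, 2)

  horiz <- neck_boxes(pixel_box(10, 40, 30, 60), pixel_box(110, 40, 130, 60))
  al2 <- align_neck(img, horiz, nset_config(Lref = 200))
  expect_equal(al2$phi, 0)
  expect_equal(al2$angle, pi / 2)
  ct <- c((al2$boxes$top$xmin + al2$boxes$top$xmax) / 2,
          (al2$boxes$top$ymin + al2$boxes$top$ymax) / 2)
  cl <- c((al2$boxes$low$xmin + al2$boxes$low$xmax) / 2,
          (al2$boxes$low$ymin + al2$boxes$low$ymax) / 2)
  expect_equal(cl[1] - ct[1], 0, tolerance = 1e-8)
  expect_equal(cl[2] - ct[2], 200, tolerance = 1e-8)

  expect_error(neck_boxes(pixel_box(10, 10, 30, 30), pixel_box(10, 10, 30, 30)),
               class = "tfm_degenerate_axis")
})

test_that("the ROI is the margin-expanded union of the two boxes", {
  b <- neck_boxes(pixel_box(10, 10, 30, 30), pixel_box(10, 70, 30, 90))
  r0 <- neck_roi(b, 200, 200, margin_frac = 0)
  expect_equal(unlist(r0[c("xmin", "ymin", "xmax", "ymax")], use.names = FALSE),
               c(10, 10, 30, 90))
  r1 <- neck_roi(b, 200, 200, margin_frac = 0.10)
  expect_equal(unlist(r1[c("xmin", "ymin", "xmax", "ymax")], use.names = FALSE),
               c(8, 2, 32, 98))
  same <- neck_boxes(pixel_box(10, 10, 30, 30), pixel_box(10, 25, 30, 45))
  ru <- neck_roi(same, 200, 200, margin_frac = 0)
  expect_equal(unlist(ru[c("xmin", "ymin", "xmax", "ymax")], use.names = FALSE),
               c(10, 10, 30, 45))
})

skin_block <- function(h, w, rgb = c(200, 140, 110)) {
  img <- array(0, c(h, w, 3))
  for (k in 1:3) img[, , k] <- rgb[k]
  img
}

test_that("skin masking keeps skin, rejects non-skin, and opening removes salt noise", {
  full <- enhance_and_mask(skin_block(60, 40))
  expect_true(all(full$mask == 1L))

  blue <- skin_block(60, 40, rgb = c(0, 0, 255))
  expect_error(enhance_and_mask(blue), class = "tfm_no_skin_detected")

  # white background, centered skin rectangle, isolated skin salt outside
  img <- skin_block(80, 60, rgb = c(255, 255, 255))
  for (k in 1:3) img[20:60, 20:40, k] <- c(200, 140, 110)[k]
  for (k in 1:3) img[5, 5, k] <- c(200, 140, 110)[k]
  for (k in 1:3) img[70, 55, k] <- c(200, 140, 110)[k]
  m <- enhance_and_mask(img)$mask
  expect_equal(m[5, 5], 0L)
  expect_equal(m[70, 55], 0L)
  inner <- m[22:58, 22:38]
  expect_true(all(inner == 1L))
  expect_true(all(m[1:17, ] == 0L) && all(m[63:80, ] == 0L))
})

test_that("width profile measures per-row extents with the documented band arithmetic", {
  mask <- matrix(0L, 120, 100)
  mask[, 31:70] <- 1L
  p <- width_profile(mask, S = 60)
  expect_true(all(p$rows$valid))
  expect_true(all(p$rows$W == 40))
  expect_equal(p$Wtop, 40); expect_equal(p$Wbot, 40)
  expect_true(all(p$dev == 0))

  # a gap row is flagged invalid and skipped
  mask2 <- mask
  mask2[62, ] <- 0L  # sampled row i=30 maps to 0-based y=61
  p2 <- width_profile(mask2, S = 60)
  expect_false(p2$rows$valid[31])
  expect_equal(p2$Wtop, 40)

  # exact linear-taper arithmetic on the discrete grid
  W <- 40 + 40 * (0:59) / 59
  pl <- width_profile_from_widths(W)
  expect_equal(pl$Wtop, mean(W[7:13]))
  expect_equal(pl$Wtop, 46.10169, tolerance = 1e-6)
  expect_equal(pl$Wbot, 73.89831, tolerance = 1e-6)
  expect_true(all(pl$dev[pl$rows$valid] < 1e-9))

  # an entirely empty band aborts
  mask3 <- mask
  mask3[95:110, ] <- 0L  # covers the 80-90% band rows
  expect_error(width_profile(mask3, S = 60), class = "tfm_insufficient_profile")
})

test_that("morphology indices hit their closed-form fixed points", {
  mask <- matrix(0L, 120, 100)
  mask[, 31:70] <- 1L  # centered: midline 49.5, xL 30, xR 69
  m <- neck_metrics(width_profile(mask, S = 60))
  expect_equal(m$TLR, 1)
  expect_equal(m$BPI, 0)
  expect_equal(m$BAR, 0)
  expect_equal(m$ASR, 0)

  W <- 40 + 40 * (0:59) / 59
  mt <- neck_metrics(width_profile_from_widths(W))
  expect_equal(mt$TLR, 0.6238, tolerance = 1e-3)
  expect_equal(mt$BPI, 0)

  masym <- neck_metrics(width_profile_from_widths(rep(40, 60),
                                                  WL = rep(30, 60),
                                                  WR = rep(10, 60)))
  expect_equal(masym$ASR, 0.5)
})

test_that("threshold calibration uses the sample standard deviation", {
  one <- function(v) list(TLR = v, BPI = v, BAR = v, ASR = v)
  thr <- nset_calibrate(lapply(1:3, one), k = 2)
  expect_equal(thr$metrics$mu, rep(2, 4))
  expect_equal(thr$metrics$sigma, rep(1, 4))
  expect_equal(thr$metrics$theta, rep(4, 4))
  expect_equal(thr$n, 3L)

  same <- nset_calibrate(lapply(c(0.7, 0.7, 0.7), one), k = 5)
  expect_equal(same$metrics$theta, rep(0.7, 4))

  expect_error(nset_calibrate(list(one(1))), class = "tfm_insufficient_cohort")
})

test_that("the vote rule is strict, pure and bounded", {
  thr <- nset_calibrate(lapply(c(1, 2, 3), function(v)
    list(TLR = v, BPI = v, BAR = v, ASR = v)), k = 2)  # theta = 4 each
  two <- structure(list(TLR = 5, BPI = 5, BAR = 1, ASR = 1),
                   class = "neck_metrics")
  d2 <- nset_decide(two, thr, q = 2)
  expect_equal(d2$score, 2L)
  expect_equal(d2$result, "Swollen")

  one_above <- structure(list(TLR = 5, BPI = 1, BAR = 1, ASR = 1),
                         class = "neck_metrics")
  expect_equal(nset_decide(one_above, thr, q = 2)$result, "Normal")

  # exact equality does not vote
  at <- structure(list(TLR = 4, BPI = 4, BAR = 4, ASR = 4),
                  class = "neck_metrics")
  d0 <- nset_decide(at, thr, q = 2)
  expect_equal(d0$score, 0L)

  expect_identical(nset_decide(two, thr, 2)[c("votes", "score", "result")],
                   nset_decide(two, thr, 2)[c("votes", "score", "result")])
  set.seed(8)
  for (rep in 1:20) {
    m <- structure(as.list(setNames(runif(4, 0, 8),
                                    c("TLR", "BPI", "BAR", "ASR"))),
                   class = "neck_metrics")
    sc <- nset_decide(m, thr)$score
    expect_true(sc %in% 0:4)
  }
})

test_that("the pipeline separates zero-bulge from large-bulge phantoms", {
  cohort <- make_reference_cohort(8, seed = 31)
  met <- lapply(cohort, function(ph) run_nset(ph$image, ph$boxes)$metrics)
  thr <- nset_calibrate(met, k = 2)

  normal <- make_neck_phantom(top_width = 95, bottom_width = 150,
                              noise_sd = 2, seed = 77)
  rn <- run_nset(normal$image, normal$boxes, thr)
  expect_equal(rn$decision$result, "Normal")

  big <- make_neck_phantom(width = 340, top_width = 95, bottom_width = 150,
                           bulge_amplitude = 0.6, noise_sd = 2, seed = 78)
  rb <- run_nset(big$image, big$boxes, thr)
  expect_equal(rb$decision$result, "Swollen")
  expect_gte(rb$decision$score, 2L)
})

test_that("bulge indices grow with amplitude and asymmetry with shift", {
  amp <- c(0, 0.2, 0.4, 0.6)
  bpi <- bar <- numeric(length(amp))
  for (k in seq_along(amp)) {
    ph <- make_neck_phantom(width = 340, bulge_amplitude = amp[k])
    m <- run_nset(ph$image, ph$boxes)$metrics
    bpi[k] <- m$BPI; bar[k] <- m$BAR
  }
  expect_true(all(diff(bpi) > -0.005))
  expect_true(all(diff(bar) > -0.005))

  shifts <- c(0, 6, 12, 18)
  asr <- vapply(shifts, function(d) {
    ph <- make_neck_phantom(shift = d)
    run_nset(ph$image, ph$boxes)$metrics$ASR
  }, numeric(1))
  expect_true(all(diff(asr) > -0.005))
})
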