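test_that("estimate_baseline reports far-window statistics", {
  z <- seq(0, 100, length.out = 200)
  fc <- force_curve(z, rep(5, 200))
  bl <- estimate_baseline(fc)
  expect_equal(bl$mean, 5)
  expect_equal(bl$sd, 0)
  expect_equal(bl$window[2], 100)

  # sampled statistics on pure noise stay within sampling bounds
  set.seed(101)
  fc2 <- force_curve(seq(0, 100, length.out = 500), rnorm(500, 0, 2))
  bl2 <- estimate_baseline(fc2)
  expect_lt(abs(bl2$mean), 3 * 2 / sqrt(125))
  expect_lt(abs(bl2$sd - 2) / 2, 0.15)

  # an adhesion well near z = 0 does not leak into the far window
  z3 <- seq(0, 100, length.out = 400)
  well <- ifelse(z3 < 10, -200, 0)
  set.seed(7)
  noise <- rnorm(400, 0, 2)
  bl_well <- estimate_baseline(force_curve(z3, noise + well))
  bl_flat <- estimate_baseline(force_curve(z3, noise))
  expect_equal(bl_well$mean, bl_flat$mean)
  expect_equal(bl_well$sd, bl_flat$sd)

  expect_error(estimate_baseline(fc, window_fraction = 0.6), "0, 0.5")
  expect_error(estimate_baseline(force_curve(seq(0, 1, length.out = 16),
                                             rep(0, 16))),
               "at least 8")
})

test_that("align_curve recovers vertical and horizontal offsets exactly", {
  base <- make_contact_curve()
  shifted <- force_curve(base$z + 12, base$force + 7, segment = "retract")
  al <- align_curve(shifted)
  expect_true(al$contact)
  expect_equal(al$z, base$z, tolerance = 1e-9)
  expect_equal(al$force, base$force, tolerance = 1e-9)

  # idempotence on an already-aligned curve
  al2 <- align_curve(al)
  expect_equal(al2$z, al$z, tolerance = 1e-9)
  expect_equal(al2$force, al$force, tolerance = 1e-9)
})

test_that("align_curve flags non-contacting curves", {
  set.seed(5)
  fc <- force_curve(seq(0, 100, length.out = 128), rnorm(128, 20, 2))
  al <- align_curve(fc)
  expect_false(al$contact)
  expect_equal(mean(al$force[97:128]), 0, tolerance = 1)  # vertical applied
  expect_equal(al$z, fc$z)                                # z untouched
})

test_that("detect_onset applies the k-consecutive, m-sd rule", {
  z <- seq(0, 100, length.out = 501)  # grid step 0.2 contains z = 20
  bl <- fixed_baseline(mean = 0, sd = 2, window = c(75, 100))
  step <- force_curve(z, ifelse(z <= 20, -20, 0))
  step$aligned <- TRUE
  expect_equal(detect_onset(step, bl), 20)

  # a run of exactly k - 1 outliers does not trigger
  f3 <- rep(0, 501)
  f3[200:202] <- -20
  run3 <- force_curve(z, f3)
  run3$aligned <- TRUE
  expect_true(is.na(detect_onset(run3, bl, k = 4)))
  expect_false(is.na(detect_onset(run3, bl, k = 3)))

  expect_error(detect_onset(step, fixed_baseline(sd = 0)), "sd must be")
})

test_that("onset false-positive rate on noise is under 1%", {
  set.seed(202)
  hits <- 0L
  for (i in 1:500) {
    fc <- force_curve(seq(0, 250, length.out = 500), rnorm(500, 0, 5))
    if (!is.na(detect_onset(fc))) hits <- hits + 1L
  }
  expect_lt(hits / 500, 0.01)
})

test_that("adhesion_force is the clamped global minimum magnitude", {
  z <- seq(0, 50, length.out = 64)
  f <- rep(1, 64)
  f[10] <- -500
  expect_equal(adhesion_force(force_curve(z, f)), 500)
  expect_equal(adhesion_force(force_curve(z, rep(2, 64))), 0)
  f2 <- rep(0, 64)
  f2[10] <- -120
  f2[40] <- -80
  expect_equal(adhesion_force(force_curve(z, f2)), 120)
})

test_that("work_of_adhesion integrates sub-zero area in aJ", {
  # rectangle: -100 pN over 10 nm = 1000 pN nm = 1 aJ, exactly
  rect <- make_polyline_curve(c(0, 10, 10, 50), c(-100, -100, 0, 0),
                              points_per_seg = 21L)  # grid contains z = 5
  expect_equal(work_of_adhesion(rect), 1)
  # triangle: -200 pN apex over a 20 nm base = 2 aJ, exactly
  tri <- make_polyline_curve(c(0, 10, 20, 50), c(0, -200, 0, 0))
  expect_equal(work_of_adhesion(tri), 2)
  # positive regions contribute nothing
  mixed <- make_polyline_curve(c(0, 10, 10, 50), c(-100, -100, 300, 300))
  expect_equal(work_of_adhesion(mixed), 1)
  # z_max truncates the integration domain
  expect_equal(work_of_adhesion(rect, z_max = 5), 0.5)
})

test_that("work scales bilinearly and vanishes with adhesion force", {
  set.seed(31)
  for (i in 1:5) {
    z <- seq(0, 80, length.out = 300)
    f <- rnorm(300, -20, 30)
    fc <- force_curve(z, f)
    fc2 <- force_curve(2 * z, 2 * f)
    expect_equal(work_of_adhesion(fc2), 4 * work_of_adhesion(fc),
                 tolerance = 1e-12)
    expect_equal(work_of_adhesion(fc) == 0, adhesion_force(fc) == 0)
  }
  expect_equal(work_of_adhesion(force_curve(seq(0, 9, length.out = 20),
                                            rep(3, 20))), 0)
})

test_that("count_events separates ruptures and ignores noise", {
  bl <- fixed_baseline(sd = 5)
  # three well-separated triangular ruptures
  three <- make_polyline_curve(
    c(0, 10, 10.01, 14, 24, 24.01, 28, 43, 43.01, 60),
    c(0, -60, 0, 0, -80, 0, 0, -70, 0, 0), points_per_seg = 24L)
  expect_equal(count_events(three, bl), 3L)
  # one deep pull-off
  one <- make_polyline_curve(c(0, 170, 170.01, 500), c(0, -400, 0, 0),
                             points_per_seg = 64L)
  expect_equal(count_events(one, bl), 1L)
  # flat noise
  set.seed(9)
  noise <- force_curve(seq(0, 100, length.out = 512), rnorm(512, 0, 5))
  expect_equal(count_events(noise, bl), 0L)
  # minima closer than min_separation merge into one event
  close_pair <- make_polyline_curve(
    c(0, 5, 5.5, 6, 6.01, 30), c(0, -60, -25, -80, 0, 0),
    points_per_seg = 32L)
  expect_equal(count_events(close_pair, bl, min_separation = 2), 1L)
})

test_that("jump_to_contact finds scripted snap-ins only", {
  z <- seq(-2, 60, length.out = 512)
  bl <- fixed_baseline(sd = 5)
  f <- ifelse(z >= 0 & z <= 8, -150, 0) + ifelse(z < 0, -100 * z, 0)
  app <- force_curve(z, f, segment = "approach")
  jtc <- jump_to_contact(app, bl)
  expect_lt(abs(jtc - 8), 2 * diff(z)[1])
  # monotone repulsive approach: no snap
  rep_app <- force_curve(z, ifelse(z >= 0, 60 * exp(-z / 5), 60),
                         segment = "approach")
  expect_true(is.na(jump_to_contact(rep_app, bl)))
})

test_that("summarize_curves computes closed-form statistics", {
  m <- data.frame(id = c("a", "b", "c"), segment = "retract",
                  contact = TRUE, F_adh_pN = c(10, 10, 10),
                  W_adh_aJ = c(1, 2, 3), n_events = c(1L, 1L, 1L),
                  onset_z_nm = c(5, 5, 5), jump_to_contact_z_nm = NA_real_,
                  interaction_range_nm = 5)
  sm <- summarize_curves(m)
  w <- sm[sm$metric == "W_adh_aJ", ]
  expect_equal(w$mean, 2)
  expect_equal(w$se, 1 / sqrt(3), tolerance = 1e-6)
  f <- sm[sm$metric == "F_adh_pN", ]
  expect_equal(f$sd, 0)
  expect_equal(attr(sm, "no_binding_fraction"), 0)

  m$W_adh_aJ <- c(0, 0, 3)
  expect_equal(attr(summarize_curves(m), "no_binding_fraction"), 2 / 3)
})

test_that("batch analysis recovers generator truth", {
  g <- gen_force_curves(curve_recipe_preset("ca_1mM"), 25, seed = 77)
  mets <- analyze_curves(g$curves)
  ret <- mets[mets$segment == "retract", ]
  expect_equal(ret$n_events, g$truth$n_events)
  expect_lt(max(abs(ret$W_adh_aJ - g$truth$work_aJ) / g$truth$work_aJ), 0.05)
  expect_lt(max(abs(ret$onset_z_nm - g$truth$onset_nm)), 1)
  app <- mets[mets$segment == "approach", ]
  expect_lt(max(abs(app$jump_to_contact_z_nm - g$truth$jtc_nm)), 1)
})
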