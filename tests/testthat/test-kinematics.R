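test_that("cilium length is the longer of the two base-to-tip distances", {
  expect_equal(cilia_length(c(0, 0), c(5, 0), c(0, 5)), 5)
  expect_equal(cilia_length(c(0, 0), c(0, 0), c(0, 0)), 0)
  expect_equal(cilia_length(c(0, 0), c(3, 4), c(5, 0)), 5)
  # vectorised over rows
  p0 <- rbind(c(0, 0), c(1, 1))
  expect_equal(cilia_length(p0, rbind(c(5, 0), c(1, 4)), rbind(c(0, 5), c(1, 2))),
               c(5, 3))
  expect_error(cilia_length(c(0, 0), c(NA, 0), c(0, 1)), "non-finite")
})

test_that("beating angle follows the law of cosines, clamped into [0, pi]", {
  expect_equal(beating_angle(c(0, 0), c(5, 0), c(0, 5)), pi / 2)
  expect_equal(beating_angle(c(0, 0), c(5, 0), c(5, 0)), 0)
  expect_equal(beating_angle(c(0, 0), c(5, 0), c(3, 4)), acos(0.6))
  # collinear opposite arms: exactly pi, no NaN from rounding
  expect_equal(beating_angle(c(0, 0), c(1, 1), c(-2, -2)), pi)
  expect_error(beating_angle(c(0, 0), c(0, 0), c(1, 0)), "degenerate")
})

test_that("beating angle is invariant under rigid motion of the landmarks", {
  set.seed(11)
  for (i in 1:25) {
    p0 <- rnorm(2); p1 <- p0 + rnorm(2); p2 <- p0 + rnorm(2)
    if (all(p1 == p0) || all(p2 == p0)) next
    a0 <- beating_angle(p0, p1, p2)
    th <- runif(1, 0, 2 * pi); shift <- rnorm(2, sd = 10)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    a1 <- beating_angle(drop(rot %*% p0) + shift, drop(rot %*% p1) + shift,
                        drop(rot %*% p2) + shift)
    expect_equal(a1, a0, tolerance = 1e-9)
    expect_gte(a0, 0); expect_lte(a0, pi)
  }
})

test_that("global frequency is the reciprocal cycle duration", {
  expect_equal(global_frequency(0, 1), 1)
  expect_equal(global_frequency(frames_to_seconds(0, 355),
                                frames_to_seconds(355, 355)), 1)
  expect_equal(global_frequency(frames_to_seconds(0, 355),
                                frames_to_seconds(142, 355)), 2.5)
  expect_error(global_frequency(1, 1), "t5 must exceed t1")
})

test_that("stroke timings decompose the cycle and close to the period", {
  d <- stroke_timings(0, 0.1, 0.1, 0.3, 0.3)
  expect_equal(unlist(d), c(Dp = 0.1, Dr = 0.2, Ps = 0, Pr = 0, Pt = 0))
  f <- frames_to_seconds(c(0, 35, 40, 120, 142), 355)
  d2 <- stroke_timings(f[1], f[2], f[3], f[4], f[5])
  expect_equal(d2$Dp, 35 / 355); expect_equal(d2$Ps, 5 / 355)
  expect_equal(d2$Dr, 80 / 355); expect_equal(d2$Pr, 22 / 355)
  expect_equal(d2$Pt, 27 / 355)
  d3 <- stroke_timings(0, 0.25, 0.5, 0.75, 1.0)
  expect_equal(d3$Pt, 0.5)
  expect_equal(d3$Dp + d3$Dr + d3$Pt, 1 / global_frequency(0, 1))
  expect_error(stroke_timings(0, 0.2, 0.1, 0.3, 0.4), "invalid annotation")
})

test_that("timing closure Dp+Dr+Ps+Pr = t5-t1 = 1/fg holds on random annotations", {
  set.seed(21)
  for (i in 1:50) {
    t <- sort(c(0, cumsum(runif(4, 0, 0.2))))
    t <- t + runif(1, 0, 2)  # arbitrary origin
    if (t[2] <= t[1] || t[4] <= t[3]) next
    d <- stroke_timings(t[1], t[2], t[3], t[4], t[5])
    expect_equal(d$Dp + d$Dr + d$Ps + d$Pr, t[5] - t[1], tolerance = 1e-12)
    expect_equal(d$Dp + d$Dr + d$Ps + d$Pr,
                 1 / global_frequency(t[1], t[5]), tolerance = 1e-12)
    expect_equal(d$Pt, d$Ps + d$Pr)
  }
})

test_that("distance and area rates multiply out and obey dist = 2*area/Lc", {
  expect_equal(distance_per_second(5, acos(0.6), 8), 5 * acos(0.6) * 8)
  expect_equal(distance_per_second(5, 0.9273, 0), 0)
  expect_equal(distance_per_second(1, 1, 1), 1)
  expect_equal(area_per_second(5, acos(0.6), 8), (acos(0.6) / 2) * 25 * 8)
  expect_equal(area_per_second(5, 0, 8), 0)
  expect_equal(area_per_second(2, 1, 1), 2)
  set.seed(31)
  lc <- runif(20, 0.1, 10); an <- runif(20, 0, pi); fg <- runif(20, 0, 20)
  expect_equal(distance_per_second(lc, an, fg) * lc,
               2 * area_per_second(lc, an, fg), tolerance = 1e-12)
  expect_error(distance_per_second(-1, 1, 1), "invalid annotation")
})

test_that("distance rate is nondecreasing in each factor", {
  grid <- seq(0, 5, by = 0.5)
  expect_true(all(diff(distance_per_second(grid, 1, 2)) >= 0))
  expect_true(all(diff(distance_per_second(3, grid * pi / 5, 2)) >= 0))
  expect_true(all(diff(distance_per_second(3, 1, grid)) >= 0))
})

test_that("weighting scales by the beating fraction and rejects bad fractions", {
  expect_equal(weight_by_beating_fraction(50, 0.5), 25)
  expect_equal(weight_by_beating_fraction(37.09, 1), 37.09)
  expect_equal(weight_by_beating_fraction(37.09, 0), 0)
  expect_error(weight_by_beating_fraction(1, 1.2), "invalid score")
  expect_error(weight_by_beating_fraction(1, -0.1), "invalid score")
})

test_that("frame/second and pixel/micrometre conversions round-trip", {
  fr <- c(0, 1, 35, 142, 1799)
  expect_equal(seconds_to_frames(frames_to_seconds(fr, 355), 355), fr)
  px <- c(0, 1.5, 255)
  expect_equal((px * 0.13) / 0.13, px)
})

test_that("compute_cycle_parameters populates all 12 fields consistently", {
  ann <- make_annotation(p0 = c(0, 0), p1 = c(5, 0), p2 = c(3, 4),
                         ts = c(0, 0.05, 0.06, 0.12, 0.125))
  p <- compute_cycle_parameters(ann, fraction = 1)
  expect_equal(p$length_um, 5)
  expect_equal(p$angle_rad, acos(0.6))
  expect_equal(p$freq_hz, 8)
  expect_equal(p$dist_per_s_um, 5 * acos(0.6) * 8, tolerance = 1e-12)
  expect_equal(p$area_per_s_um2, (acos(0.6) / 2) * 25 * 8, tolerance = 1e-12)
  # spec worked example: Lc=5, angle=0.9273, fg=8 -> 37.09 um, 92.73 um2
  expect_equal(p$dist_per_s_um, 37.09, tolerance = 1e-3)
  expect_equal(p$area_per_s_um2, 92.73, tolerance = 1e-3)
  expect_equal(p$pause_total_s, p$pause_after_stroke_s + p$pause_after_recovery_s)
  expect_equal(p$dur_power_s + p$dur_recovery_s + p$pause_total_s,
               1 / p$freq_hz, tolerance = 1e-12)
})

test_that("unobserved cycles contribute zero rates but keep geometry", {
  ann <- make_annotation(ts = rep(NA_real_, 5), observed = FALSE)
  p <- compute_cycle_parameters(ann, fraction = 1)
  expect_equal(p$freq_hz, 0)
  expect_equal(p$dist_per_s_um, 0)
  expect_equal(p$weighted_dist_per_s_um, 0)
  expect_equal(p$length_um, 5)
  expect_gt(p$angle_rad, 0)
  # zero fraction wipes only the weighted rates
  ann2 <- make_annotation()
  p2 <- compute_cycle_parameters(ann2, fraction = 0)
  expect_gt(p2$dist_per_s_um, 0)
  expect_equal(p2$weighted_dist_per_s_um, 0)
  # coincident tip landmarks: angle 0 by convention, no error
  ann3 <- make_annotation(p1 = c(0, 0), p2 = c(0, 0), ts = rep(NA_real_, 5),
                          observed = FALSE)
  expect_equal(compute_cycle_parameters(ann3, 1)$angle_rad, 0)
})
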