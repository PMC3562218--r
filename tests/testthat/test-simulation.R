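test_that("beat model enforces timing closure and parameter ranges", {
  m <- beat_model(freq = 4, duty = c(0.3, 0.1, 0.5, 0.1))
  expect_equal(m$dur_power + m$pause_after_stroke + m$dur_recovery +
                 m$pause_after_recovery, 1 / 4, tolerance = 1e-12)
  expect_error(beat_model(angle_amplitude = 4), "configuration error")
  expect_error(beat_model(duty = c(0.5, 0.5, 0.5, 0.5)), "configuration error")
})

test_that("simulated trajectories are periodic, bounded and seed-deterministic", {
  m <- beat_model(base = c(10, 10), length = 6, angle_amplitude = pi / 3,
                  freq = 2, orientation = pi / 2)
  tr <- simulate_trajectory(m, duration = 1, fps = 100)
  # noise-free: exactly periodic with period 0.5 s = 50 frames
  expect_equal(tr$tip[1:50, ], tr$tip[51:100, ], tolerance = 1e-12)
  # tip stays on the circle of radius length
  r <- sqrt(rowSums((tr$tip - rep(c(10, 10), each = 100))^2))
  expect_equal(r, rep(6, 100), tolerance = 1e-9)
  # zero amplitude: immotile
  m0 <- beat_model(angle_amplitude = 0, freq = 2)
  tr0 <- simulate_trajectory(m0, 0.5, 100)
  expect_equal(max(dist(tr0$tip)), 0)
  # same seed, same noise
  mn <- beat_model(angular_noise_sd = 0.05, freq = 2)
  a <- simulate_trajectory(mn, 0.5, 100, seed = 3)
  b <- simulate_trajectory(mn, 0.5, 100, seed = 3)
  expect_identical(a$tip, b$tip)
})

test_that("annotating a noise-free trajectory recovers the model exactly", {
  m <- beat_model(base = c(12, 10), length = 6, angle_amplitude = pi / 2,
                  freq = 2.5, duty = c(0.25, 0.05, 0.6, 0.10),
                  orientation = pi / 2)
  tr <- simulate_trajectory(m, duration = 1, fps = 355)
  ann <- annotate_cycle(tr)
  expect_true(ann$cycle_observed)
  p <- compute_cycle_parameters(ann, fraction = 1)
  expect_equal(p$freq_hz, 2.5, tolerance = 1e-9)
  expect_equal(p$angle_rad, pi / 2, tolerance = 2 * pi / 180)
  expect_equal(p$length_um, 6, tolerance = 0.01)
  # recovered timings close by construction
  expect_equal(p$dur_power_s + p$dur_recovery_s + p$pause_total_s,
               1 / p$freq_hz, tolerance = 1e-12)
  # constant trajectory yields no cycle
  tr0 <- simulate_trajectory(beat_model(freq = 0), 0.2, 100)
  expect_false(annotate_cycle(tr0)$cycle_observed)
  # sub-cycle recordings yield no cycle rather than an error
  short <- simulate_trajectory(m, duration = 0.3, fps = 355)
  expect_false(annotate_cycle(short)$cycle_observed)
})

test_that("rendered frames place the brightest far pixel at the tip", {
  m <- beat_model(base = c(8, 7), length = 5, angle_amplitude = pi / 3,
                  freq = 4, orientation = pi / 4)
  tr <- simulate_trajectory(m, duration = 0.1, fps = 100)
  meta <- acquisition_meta(fps = 100, width = 128, height = 110)
  st <- render_stack(tr, meta, psf_sigma = 0.3, snr = Inf)
  expect_equal(dim(st), c(110, 128, 10))
  expect_gte(min(st), 0); expect_lte(max(st), 1)
  for (i in c(1, 5, 10)) {
    fr <- st[, , i]
    fg <- which(fr > 0.5 * max(fr), arr.ind = TRUE)
    d <- sqrt((fg[, 2] - 0.5 - 8 / 0.13)^2 + (fg[, 1] - 0.5 - 7 / 0.13)^2)
    far <- fg[which.max(d), ]
    tip_px <- tr$tip[i, ] / 0.13
    expect_lt(sqrt((far[2] - 0.5 - tip_px[1])^2 + (far[1] - 0.5 - tip_px[2])^2),
              1.5)
  }
  # zero-length cilium: one blurred spot, identical frames
  trz <- simulate_trajectory(beat_model(base = c(5, 5), length = 0, freq = 2),
                             0.05, 100)
  stz <- render_stack(trz, acquisition_meta(fps = 100, width = 80, height = 80))
  expect_equal(stz[, , 1], stz[, , dim(stz)[3]])
  # out-of-field geometry errors
  trx <- simulate_trajectory(beat_model(base = c(1, 1), length = 30, freq = 2),
                             0.05, 100)
  expect_error(render_stack(trx, acquisition_meta(width = 64, height = 64)),
               "geometry error")
})

test_that("simulate -> render -> track recovers the tip within half a pixel", {
  m <- beat_model(base = c(10, 9), length = 6, angle_amplitude = pi / 2,
                  freq = 2.5, duty = c(0.25, 0.05, 0.6, 0.10),
                  orientation = pi / 2)
  tr <- simulate_trajectory(m, duration = 0.45, fps = 355)
  meta <- acquisition_meta(width = 160, height = 140)
  st <- render_stack(tr, meta, psf_sigma = 0.3, snr = Inf)
  tk <- track_tip(st, base = c(10, 9), meta = meta)
  rms_px <- sqrt(mean(rowSums((tk$tip - tr$tip)^2))) / meta$pixel_size
  expect_lt(rms_px, 0.5)
  # blank frames are a tracking failure naming the frame
  blank <- array(0, dim = c(32, 32, 2))
  expect_error(track_tip(blank, c(1, 1)), "frame 1")
})

test_that("tracking is equivariant under a 180-degree stack rotation", {
  m <- beat_model(base = c(6, 5), length = 4, angle_amplitude = pi / 3,
                  freq = 4, orientation = pi / 4)
  tr <- simulate_trajectory(m, duration = 0.05, fps = 100)
  meta <- acquisition_meta(fps = 100, width = 96, height = 80)
  st <- render_stack(tr, meta, psf_sigma = 0.3, snr = Inf)
  rot <- st[rev(seq_len(dim(st)[1])), rev(seq_len(dim(st)[2])), , drop = FALSE]
  w_um <- meta$width * meta$pixel_size; h_um <- meta$height * meta$pixel_size
  tk <- track_tip(st, c(6, 5), meta = meta)
  tkr <- track_tip(rot, c(w_um - 6, h_um - 5), meta = meta)
  back <- cbind(w_um - tkr$tip[, 1], h_um - tkr$tip[, 2])
  expect_equal(back, tk$tip, tolerance = 0.05)
})

test_that("stacks survive a TIFF write/read round trip", {
  m <- beat_model(base = c(5, 5), length = 3, freq = 4)
  tr <- simulate_trajectory(m, 0.05, 100)
  st <- render_stack(tr, acquisition_meta(fps = 100, width = 72, height = 64))
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(path))
  write_stack(st, path)
  st2 <- read_stack(path)
  expect_equal(dim(st2), dim(st))
  expect_lt(max(abs(st2 - st)), 1 / 65535 + 1e-9)  # 16-bit quantisation
})

test_that("cohort generation is reproducible and respects its profiles", {
  a <- simulate_cohort(n_patients = 3, seed = 12)
  b <- simulate_cohort(n_patients = 3, seed = 12)
  expect_identical(a, b)
  expect_equal(nrow(a$clinical), 6)
  expect_equal(nrow(a$edges), 6 * 20)
  expect_equal(nrow(a$annotations), 6 * 10)
  # degenerate single-group profile pins the summary at the profile means
  pf <- default_profiles()["non_pcd_like"]
  pf$non_pcd_like$frac_beating["sd"] <- 0
  pf$non_pcd_like$length["sd"] <- 0
  pf$non_pcd_like$amplitude["sd"] <- 0
  pf$non_pcd_like$freq["sd"] <- 0
  coh <- simulate_cohort(n_patients = 1, profiles = pf, seed = 5)
  s <- summarize_cohort(coh$annotations, coh$edges)
  expect_equal(s$length_um_mean, 6)
  expect_equal(s$freq_hz_mean, 9)
  expect_equal(s$angle_rad_mean, 1.2)
  expect_equal(s$length_um_sd, 0)
  # group separation: empirical means fall on the expected sides
  coh2 <- simulate_cohort(n_patients = 8, seed = 31)
  s2 <- summarize_cohort(coh2$annotations, coh2$edges)
  wd <- s2$weighted_dist_per_s_um_mean
  is_pcd <- grepl("^pcd", s2$patient_id)
  expect_gt(min(wd[!is_pcd]), 30)
  expect_lt(max(wd[is_pcd]), 15)
})
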