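# run expr with a locally-seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Acquisition geometry of the high-speed recording
#'
#' Defaults mirror the reference recording set-up: 355 frames per second,
#' 1800 frames per movie, a 256 x 192 pixel field and 0.13 micrometre
#' pixels.
#'
#' @param fps Frame rate, frames per second.
#' @param pixel_size Pixel edge, micrometres.
#' @param width,height Field of view, pixels.
#' @param n_frames Frames per movie.
#' @return List of class \code{"cbp_meta"}.
#' @export
acquisition_meta <- function(fps = 355, pixel_size = 0.13,
                             width = 256L, height = 192L, n_frames = 1800L) {
  if (fps <= 0 || pixel_size <= 0)
    stop("fps and pixel_size must be > 0", call. = FALSE)
  structure(list(fps = fps, pixel_size = pixel_size,
                 width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames)),
            class = "cbp_meta")
}

#' Generative model of one beating cilium
#'
#' The tip dwells at the pre-power-stroke extreme for the pause after
#' recovery, sweeps linearly (constant angular velocity) through the beating
#' angle during the power stroke, dwells for the pause after stroke, and
#' sweeps back during the recovery stroke; the four phase durations sum to
#' one beat period. Per-frame Gaussian angular noise models tip jitter. The
#' \code{"circular"} pattern instead moves the tip on an ellipse about the
#' base with no dwells.
#'
#' @param base Base of the cilium, \code{c(x, y)} in micrometres (image
#'   convention: origin top-left, y increasing downward).
#' @param length Cilium length, micrometres.
#' @param angle_amplitude Beating angle swept between the two tip extremes,
#'   radians in \eqn{[0, \pi]}.
#' @param freq Global beat frequency, Hz. \code{freq = 0} gives an immotile
#'   cilium.
#' @param duty Fractions of the period spent in (power stroke, pause after
#'   stroke, recovery stroke, pause after recovery); must sum to 1.
#' @param orientation Direction of the beat midline, radians.
#' @param pattern Qualitative class tag: one of
#'   \code{"normal"}, \code{"stiff"}, \code{"virtually_immotile"},
#'   \code{"circular"}.
#' @param angular_noise_sd Per-frame angular jitter, radians.
#' @return List of class \code{"cbp_beat_model"} with the phase durations
#'   \code{dur_power}, \code{pause_after_stroke}, \code{dur_recovery},
#'   \code{pause_after_recovery} resolved in seconds.
#' @export
beat_model <- function(base = c(10, 10), length = 6, angle_amplitude = pi / 3,
                       freq = 8, duty = c(0.35, 0.05, 0.5, 0.10),
                       orientation = 0, pattern = "normal",
                       angular_noise_sd = 0) {
  if (angle_amplitude < 0 || angle_amplitude > pi)
    stop("configuration error: angle_amplitude must lie in [0, pi]",
         call. = FALSE)
  if (freq < 0 || length < 0 || angular_noise_sd < 0)
    stop("configuration error: length, freq and noise must be >= 0",
         call. = FALSE)
  if (length(duty) != 4L || any(duty < 0) || abs(sum(duty) - 1) > 1e-9)
    stop("configuration error: duty must be 4 nonnegative fractions summing to 1",
         call. = FALSE)
  pattern <- match.arg(pattern, PATTERN_LABELS)
  period <- if (freq > 0) 1 / freq else Inf
  structure(list(base = as.numeric(base), length = length,
                 angle_amplitude = angle_amplitude, freq = freq,
                 duty = duty,
                 dur_power = duty[1] * period,
                 pause_after_stroke = duty[2] * period,
                 dur_recovery = duty[3] * period,
                 pause_after_recovery = duty[4] * period,
                 orientation = orientation, pattern = pattern,
                 angular_noise_sd = angular_noise_sd),
            class = "cbp_beat_model")
}

#' Simulate the tip trajectory of a beating cilium
#'
#' Samples the generative model of \code{\link{beat_model}} at the frame
#' times \code{0, 1/fps, 2/fps, ...}. The phase at time zero is the dwell at
#' the pre-power-stroke extreme.
#'
#' @param model A \code{"cbp_beat_model"}.
#' @param duration Recording length, seconds.
#' @param fps Frame rate, frames per second.
#' @param seed Optional integer seed for the angular noise (the caller's RNG
#'   stream is restored afterwards).
#' @return List of class \code{"cbp_trajectory"}: \code{tip} (n x 2 matrix,
#'   micrometres), \code{times} (seconds), \code{fps}, \code{base}.
#' @export
simulate_trajectory <- function(model, duration, fps = 355, seed = NULL) {
  stopifnot(inherits(model, "cbp_beat_model"))
  if (duration <= 0 || fps <= 0)
    stop("configuration error: duration and fps must be > 0", call. = FALSE)
  n <- max(2L, as.integer(round(duration * fps)))
  t <- (seq_len(n) - 1L) / fps
  a <- model$angle_amplitude
  if (model$pattern == "circular" && model$freq > 0) {
    phase <- 2 * pi * model$freq * t
    ex <- model$length * cos(phase)
    ey <- (model$length / 2) * sin(phase)
    th <- model$orientation
    tip <- cbind(model$base[1] + ex * cos(th) - ey * sin(th),
                 model$base[2] + ex * sin(th) + ey * cos(th))
    theta <- NULL
  } else {
    if (model$freq > 0) {
      u <- t %% (1 / model$freq)
      b1 <- model$pause_after_recovery
      b2 <- b1 + model$dur_power
      b3 <- b2 + model$pause_after_stroke
      frac <- ifelse(u < b1, 0,
              ifelse(u < b2, (u - b1) / model$dur_power,
              ifelse(u < b3, 1, 1 - (u - b3) / model$dur_recovery)))
    } else {
      frac <- rep(0, n)
    }
    theta <- model$orientation - a / 2 + frac * a
    if (model$angular_noise_sd > 0)
      theta <- theta + with_local_seed(seed,
        stats::rnorm(n, 0, model$angular_noise_sd))
    tip <- cbind(model$base[1] + model$length * cos(theta),
                 model$base[2] + model$length * sin(theta))
  }
  structure(list(tip = tip, times = t, fps = fps, base = model$base),
            class = "cbp_trajectory")
}

#' Render a tip trajectory as a grayscale image stack
#'
#' Each frame draws the base-to-tip segment, convolves it with a Gaussian
#' point-spread function and adds Gaussian read-out noise; pixel values are
#' clamped to \eqn{[0, 1]}.
#'
#' @param traj A \code{"cbp_trajectory"}.
#' @param meta Acquisition geometry, see \code{\link{acquisition_meta}}.
#' @param psf_sigma Point-spread standard deviation, micrometres.
#' @param snr Peak signal-to-noise ratio; \code{Inf} for noise-free frames.
#' @param seed Optional integer seed for the read-out noise.
#' @return Numeric array \code{[height, width, n_frames]} with values in
#'   \eqn{[0, 1]}.
#' @export
render_stack <- function(traj, meta = acquisition_meta(), psf_sigma = 0.3,
                         snr = Inf, seed = NULL) {
  stopifnot(inherits(traj, "cbp_trajectory"))
  px <- meta$pixel_size
  pts <- rbind(traj$tip, traj$base)
  if (any(pts[, 1] < 0) || any(pts[, 2] < 0) ||
      any(pts[, 1] >= meta$width * px) || any(pts[, 2] >= meta$height * px))
    stop("geometry error: cilium leaves the field of view", call. = FALSE)
  n <- nrow(traj$tip)
  stack <- array(0, dim = c(meta$height, meta$width, n))
  sig_px <- psf_sigma / px
  for (i in seq_len(n)) {
    fr <- draw_segment_px(traj$base / px, traj$tip[i, ] / px,
                          meta$height, meta$width)
    if (sig_px > 0) {
      fr <- t(EBImage::gblur(t(fr), sigma = sig_px))
    }
    m <- max(fr)
    if (m > 0) fr <- fr / m
    stack[, , i] <- fr
  }
  if (is.finite(snr)) {
    if (snr <= 0) stop("snr must be > 0", call. = FALSE)
    noise <- with_local_seed(seed, stats::rnorm(length(stack), 0, 1 / snr))
    stack <- stack + noise
  }
  # clamp: blur convolution can leave tiny negative round-off
  stack[] <- pmin(1, pmax(0, stack))
  stack
}

# rasterise the segment a -> b (continuous 0-based pixel coordinates) into
# an h x w intensity image: points sampled at tenth-pixel steps are splatted
# bilinearly onto the four neighbouring pixel centres, so the pre-blur line
# is symmetric about the true segment (no staircase bias)
draw_segment_px <- function(a, b, h, w) {
  len <- sqrt(sum((b - a)^2))
  k <- max(2L, ceiling(len / 0.1) + 1L)
  s <- seq(0, 1, length.out = k)
  xs <- a[1] + s * (b[1] - a[1])
  ys <- a[2] + s * (b[2] - a[2])
  # nearest pixel-centre grid: centre of pixel (r, c) is at (c - 0.5, r - 0.5)
  x0 <- pmin(pmax(floor(xs - 0.5), 0), w - 2L)
  y0 <- pmin(pmax(floor(ys - 0.5), 0), h - 2L)
  fx <- pmin(pmax(xs - (x0 + 0.5), 0), 1)
  fy <- pmin(pmax(ys - (y0 + 0.5), 0), 1)
  fr <- matrix(0, h, w)
  idx <- function(r, c) (c - 1L) * h + r
  add <- function(r, c, wgt) {
    i <- idx(r, c)
    tab <- rowsum(wgt, i)
    fr[as.integer(rownames(tab))] <<- fr[as.integer(rownames(tab))] + tab[, 1]
  }
  add(y0 + 1L, x0 + 1L, (1 - fx) * (1 - fy))
  add(y0 + 1L, x0 + 2L, fx * (1 - fy))
  add(y0 + 2L, x0 + 1L, (1 - fx) * fy)
  add(y0 + 2L, x0 + 2L, fx * fy)
  fr
}

#' Track the cilium tip through an image stack
#'
#' Per frame, pixels brighter than \code{threshold} times the frame maximum
#' form the foreground; the tip is the foreground pixel farthest from the
#' base, refined to sub-pixel precision by the intensity-weighted centroid
#' of its 3 x 3 neighbourhood.
#'
#' @param stack Numeric array \code{[height, width, n_frames]}.
#' @param base Base position, \code{c(x, y)} micrometres.
#' @param threshold Foreground threshold as a fraction of the frame maximum.
#' @param meta Acquisition geometry (only \code{pixel_size} and \code{fps}
#'   are used).
#' @return A \code{"cbp_trajectory"} with tip positions in micrometres.
#' @export
track_tip <- function(stack, base, threshold = 0.5,
                      meta = acquisition_meta()) {
  if (length(dim(stack)) != 3L || dim(stack)[3] == 0L)
    stop("stack must be a nonempty [height, width, frames] array",
         call. = FALSE)
  px <- meta$pixel_size
  n <- dim(stack)[3]
  h <- dim(stack)[1]; w <- dim(stack)[2]
  bx <- base[1] / px; by <- base[2] / px  # continuous 0-based px coords
  tip <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    fr <- stack[, , i]
    m <- max(fr)
    if (m <= 0)
      stop(sprintf("tracking failure at frame %d: empty foreground", i),
           call. = FALSE)
    fg <- which(fr > threshold * m, arr.ind = TRUE)
    if (nrow(fg) == 0L)
      stop(sprintf("tracking failure at frame %d: empty foreground", i),
           call. = FALSE)
    cx <- fg[, 2] - 0.5; cy <- fg[, 1] - 0.5  # pixel centres, 0-based coords
    d2 <- (cx - bx)^2 + (cy - by)^2
    k <- which.max(d2)
    tip[i, ] <- refine_tip(fr, c(bx, by), c(cx[k], cy[k]),
                           threshold * m) * px
  }
  structure(list(tip = tip, times = (seq_len(n) - 1L) / meta$fps,
                 fps = meta$fps, base = as.numeric(base)),
            class = "cbp_trajectory")
}

# bilinear intensity lookup at continuous 0-based pixel coordinates
bilinear_at <- function(fr, x, y) {
  h <- nrow(fr); w <- ncol(fr)
  x <- pmin(pmax(x, 0), w - 1e-9); y <- pmin(pmax(y, 0), h - 1e-9)
  # pixel centres sit at integer+0.5; interpolate between the 4 neighbours
  x0 <- pmin(pmax(floor(x - 0.5), 0), w - 2L)
  y0 <- pmin(pmax(floor(y - 0.5), 0), h - 2L)
  fx <- pmin(pmax(x - (x0 + 0.5), 0), 1)
  fy <- pmin(pmax(y - (y0 + 0.5), 0), 1)
  v00 <- fr[cbind(y0 + 1L, x0 + 1L)]
  v10 <- fr[cbind(y0 + 1L, x0 + 2L)]
  v01 <- fr[cbind(y0 + 2L, x0 + 1L)]
  v11 <- fr[cbind(y0 + 2L, x0 + 2L)]
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

# sub-pixel tip from a coarse farthest-pixel guess: along the base->guess ray
# the blurred segment profile falls to half its ridge level exactly at the
# endpoint, so the tip radius is the outermost threshold crossing; the
# cross-track offset is the intensity centroid perpendicular to the ray
refine_tip <- function(fr, base, guess, level, iters = 3L) {
  est <- guess
  for (it in seq_len(iters)) {
    v <- est - base
    r0 <- sqrt(sum(v^2))
    if (r0 == 0) return(guess)
    u <- v / r0
    rs <- seq(max(0, r0 - 3), r0 + 3, by = 0.1)
    prof <- bilinear_at(fr, base[1] + rs * u[1], base[2] + rs * u[2])
    above <- which(prof >= level)
    if (!length(above)) return(est)
    j <- max(above)
    r_tip <- if (j < length(rs)) {
      # linear interpolation of the outermost crossing
      rs[j] + 0.1 * (prof[j] - level) / max(prof[j] - prof[j + 1], 1e-12)
    } else rs[j]
    nrm <- c(-u[2], u[1])
    mid <- base + (r_tip - 1) * u  # sample just inside the tip cap
    off <- seq(-6, 6, by = 0.25)   # window wide enough for the whole PSF
    w <- bilinear_at(fr, mid[1] + off * nrm[1], mid[2] + off * nrm[2])
    sh <- if (sum(w) > 0) sum(w * off) / sum(w) else 0
    est <- base + r_tip * u + sh * nrm
  }
  est
}

#' Write / read a stack as multi-page grayscale TIFF
#'
#' @param stack Numeric array \code{[height, width, n_frames]} in
#'   \eqn{[0, 1]}.
#' @param path Output file.
#' @return \code{read_stack} returns the \code{[height, width, n_frames]}
#'   array.
#' @export
write_stack <- function(stack, path) {
  frames <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) if (length(dim(f)) == 3L) f[, , 1] else f)
  array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
}

#' Auto-annotate the first complete beat cycle of a trajectory
#'
#' Computes the tip's angular position about the base, classifies each
#' inter-frame step as dwelling or sweeping (in either direction) and locates
#' the first complete dwell-power-dwell-recovery-dwell cycle. The five
#' time-points are the frame times bounding that cycle; the landmark
#' positions are the tip positions at the angular extremes. When no complete
#' cycle is present the annotation is returned with
#' \code{cycle_observed = FALSE}.
#'
#' @param traj A \code{"cbp_trajectory"}.
#' @param omega_eps Dwell threshold on the per-frame angular step, radians;
#'   \code{NULL} adapts it to 20\% of the 98th percentile of observed
#'   steps (robust to isolated tracking spikes).
#' @param smooth Odd window of a running-median filter applied to the
#'   angular position before differencing (1 disables it); suppresses
#'   tracking jitter without displacing ramp/dwell boundaries by more than
#'   one frame.
#' @param lag Frame lag of the angular-slope estimate used to classify
#'   dwell vs sweep; larger lags tolerate more tip jitter at the cost of
#'   blurring phase boundaries by up to half a lag.
#' @param min_run Minimum credible length, in frames, of a dwell or sweep;
#'   shorter runs of the dwell/sweep state sequence are merged into their
#'   longer neighbour before the cycle is located.
#' @param patient_id,cilium_id Identifiers attached to the annotation row.
#' @return One-row annotation data frame (micrometres / seconds), see
#'   \code{\link{validate_annotations}}.
#' @export
annotate_cycle <- function(traj, omega_eps = NULL, smooth = 5L, lag = 3L,
                           min_run = 5L, patient_id = "sim", cilium_id = 1L) {
  stopifnot(inherits(traj, "cbp_trajectory"))
  theta <- atan2(traj$tip[, 2] - traj$base[2], traj$tip[, 1] - traj$base[1])
  # unwrap so circular motion grows monotonically
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  theta <- cumsum(c(theta[1], d))
  if (smooth > 1L && length(theta) > smooth)
    theta <- stats::runmed(theta, smooth)
  n <- length(theta)
  lag <- min(lag, n - 1L)
  # lagged slope estimate: robust to tip jitter comparable to one frame step
  dth <- (theta[(1L + lag):n] - theta[1:(n - lag)]) / lag
  eps <- if (is.null(omega_eps))
    0.2 * stats::quantile(abs(dth), 0.98, names = FALSE) else omega_eps
  no_cycle <- function() annotation_row(patient_id, cilium_id,
                                        traj$base, traj$tip[1, ], traj$tip[1, ],
                                        rep(NA_real_, 5), FALSE)
  if (eps <= 0) return(no_cycle())
  state <- ifelse(abs(dth) <= eps, 0L, ifelse(dth > 0, 1L, -1L))
  state <- merge_short_runs(state, min_run)
  mv <- which(state != 0L)
  if (!length(mv)) return(no_cycle())
  dir <- state[mv[1L]]
  # runs of constant state; step i spans frames i -> i+1
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # locate: power run (dir), optional dwell, recovery run (-dir),
  # optional dwell, next power run
  pw <- which(r$values == dir)
  for (i in pw) {
    if (i == 1L) next  # need a boundary into the power stroke
    j <- i + 1L
    if (j <= length(r$values) && r$values[j] == 0L) j <- j + 1L
    if (j > length(r$values) || r$values[j] != -dir) next
    k <- j + 1L
    if (k <= length(r$values) && r$values[k] == 0L) k <- k + 1L
    if (k > length(r$values) || r$values[k] != dir) next
    f1 <- starts[i]        # frame index (1-based) at power-stroke start
    f2 <- ends[i] + 1L     # first frame at the post-power extreme
    f3 <- starts[j]        # recovery start
    f4 <- ends[j] + 1L     # first frame back at the pre-power extreme
    f5 <- starts[k]        # start of the next cycle
    ts <- traj$times[c(f1, f2, f3, f4, f5)]
    # landmarks: average the tip over the dwell adjacent to each extreme
    # (jitter averages out); fall back to the single extreme frame when the
    # cycle has no dwell there
    span <- f1:min(f5, n)
    fmin <- span[which.min(theta[span])]
    fmax <- span[which.max(theta[span])]
    ext1 <- if (dir > 0) fmin else fmax  # pre-power extreme
    ext2 <- if (dir > 0) fmax else fmin  # post-power extreme
    p1 <- dwell_mean_tip(traj$tip, r, starts, ends, i - 1L, lag, ext1)
    p2 <- if (j == i + 2L)
      dwell_mean_tip(traj$tip, r, starts, ends, i + 1L, lag, ext2)
    else traj$tip[ext2, ]
    return(annotation_row(patient_id, cilium_id, traj$base, p1, p2, ts, TRUE))
  }
  no_cycle()
}

# mean tip position over the interior of dwell run `idx` (frames trimmed by
# the slope lag at the leading edge); falls back to the extreme frame
dwell_mean_tip <- function(tip, r, starts, ends, idx, lag, fallback_frame) {
  if (idx < 1L || idx > length(r$values) || r$values[idx] != 0L)
    return(tip[fallback_frame, ])
  f <- (starts[idx] + lag):ends[idx]
  f <- f[f >= 1L & f <= nrow(tip)]
  if (length(f) < 1L) return(tip[fallback_frame, ])
  colMeans(tip[f, , drop = FALSE])
}

# absorb state runs shorter than min_run into the longer adjacent run
# (first and last runs are kept: they are truncated by the recording)
merge_short_runs <- function(state, min_run) {
  if (min_run <= 1L) return(state)
  repeat {
    r <- rle(state)
    k <- length(r$lengths)
    if (k <= 2L) return(state)
    short <- which(r$lengths < min_run)
    short <- short[short > 1L & short < k]
    if (!length(short)) return(state)
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- if (r$lengths[i - 1L] >= r$lengths[i + 1L])
      r$values[i - 1L] else r$values[i + 1L]
    state <- inverse.rle(r)
  }
}

annotation_row <- function(patient_id, cilium_id, p0, p1, p2, ts, observed) {
  data.frame(patient_id = patient_id, cilium_id = cilium_id,
             x0 = p0[1], y0 = p0[2], x1 = p1[1], y1 = p1[2],
             x2 = p2[1], y2 = p2[2],
             t1 = ts[1], t2 = ts[2], t3 = ts[3], t4 = ts[4], t5 = ts[5],
             cycle_observed = observed, stringsAsFactors = FALSE)
}

# exact annotation implied by a beat model (no rendering / tracking)
model_annotation <- function(model, patient_id = "sim", cilium_id = 1L) {
  a <- model$angle_amplitude
  th1 <- model$orientation - a / 2
  th2 <- model$orientation + a / 2
  p0 <- model$base
  p1 <- p0 + model$length * c(cos(th1), sin(th1))
  p2 <- p0 + model$length * c(cos(th2), sin(th2))
  observed <- model$freq > 0 && model$dur_power > 0 && model$dur_recovery > 0
  ts <- if (observed) {
    t1 <- 0
    t2 <- model$dur_power
    t3 <- t2 + model$pause_after_stroke
    t4 <- t3 + model$dur_recovery
    c(t1, t2, t3, t4, t4 + model$pause_after_recovery)
  } else rep(NA_real_, 5)
  annotation_row(patient_id, cilium_id, p0, p1, p2, ts, observed)
}

#' Group profiles for the synthetic cohort generator
#'
#' Two built-in profiles bracket the clinical spectrum: a non-PCD-like group
#' (nearly all edges beating, beating angle around 1.2 rad, frequency around
#' 9 Hz, weighted distance travelled per second around 60 micrometres) and a
#' PCD-like group (about a third of edges beating, small angle, slow beat,
#' weighted distance around 3 micrometres). Clinical margins (nasal NO
#' output, TEM percentage) are drawn to land in the corresponding
#' gold-standard regions.
#'
#' @return Named list of profile lists.
#' @export
default_profiles <- function() {
  list(
    non_pcd_like = list(
      frac_beating = c(mean = 0.95, sd = 0.05),
      length = c(mean = 6, sd = 0.5),
      amplitude = c(mean = 1.2, sd = 0.15),
      freq = c(mean = 9, sd = 1.5),
      dyskinesia = c(mean = 0.3, sd = 0.2),
      pattern_probs = c(normal = 0.9, virtually_immotile = 0,
                        stiff = 0.1, circular = 0),
      p_cycle_observed = 1,
      no_n = c(min = 150, max = 800),
      tem = c(min = 0, max = 15),
      same_defect = FALSE),
    pcd_like = list(
      frac_beating = c(mean = 0.35, sd = 0.10),
      length = c(mean = 6, sd = 0.5),
      amplitude = c(mean = 0.45, sd = 0.10),
      freq = c(mean = 3, sd = 0.8),
      dyskinesia = c(mean = 2.5, sd = 0.3),
      pattern_probs = c(normal = 0.05, virtually_immotile = 0.6,
                        stiff = 0.3, circular = 0.05),
      p_cycle_observed = 0.8,
      no_n = c(min = 0, max = 60),
      tem = c(min = 92, max = 100),
      same_defect = TRUE)
  )
}

rtrunc_norm <- function(n, mean, sd, lo = 0, hi = Inf) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

#' Simulate a synthetic patient cohort
#'
#' Draws, for each patient, 20 edge observations (beating score, pattern
#' label, dyskinesia score) and 10 per-cilium beat models whose exact
#' annotations are emitted in the standard schema, plus a clinical record
#' (nasal NO output, TEM percentage, defect homogeneity). Everything is
#' driven by a single RNG stream keyed by \code{seed}, so runs are
#' bit-reproducible.
#'
#' @param n_patients Number of patients per profile (recycled across
#'   profiles), or a vector with one count per profile.
#' @param profiles Named list of group profiles
#'   (see \code{\link{default_profiles}}).
#' @param seed Integer seed.
#' @return List with data frames \code{annotations}, \code{edges},
#'   \code{clinical} (the latter with a \code{profile} column).
#' @export
simulate_cohort <- function(n_patients = 20, profiles = default_profiles(),
                            seed = 1) {
  if (any(n_patients < 1)) stop("n_patients must be >= 1", call. = FALSE)
  n_patients <- rep_len(n_patients, length(profiles))
  with_local_seed(seed, {
    anns <- list(); edges <- list(); clin <- list()
    for (g in seq_along(profiles)) {
      pf <- profiles[[g]]
      gname <- names(profiles)[g]
      for (p in seq_len(n_patients[g])) {
        pid <- sprintf("%s_%02d", gname, p)
        f <- rtrunc_norm(1, pf$frac_beating["mean"], pf$frac_beating["sd"], 0, 1)
        sc <- sample(c(0, 0.5, 1), 20, replace = TRUE,
                     prob = c((1 - f)^2, 2 * f * (1 - f), f^2))
        lab <- sample(PATTERN_LABELS, 20, replace = TRUE,
                      prob = pf$pattern_probs[PATTERN_LABELS])
        dys <- rtrunc_norm(20, pf$dyskinesia["mean"], pf$dyskinesia["sd"], 0, 3)
        edges[[length(edges) + 1L]] <- data.frame(
          patient_id = pid, area_id = 1:20, beating_score = sc,
          pattern_label = lab, dyskinesia_score = dys,
          stringsAsFactors = FALSE)
        rows <- lapply(1:10, function(ci) {
          m <- beat_model(
            base = c(10, 10),
            length = rtrunc_norm(1, pf$length["mean"], pf$length["sd"], 1),
            angle_amplitude = rtrunc_norm(1, pf$amplitude["mean"],
                                          pf$amplitude["sd"], 0.01, pi),
            freq = if (stats::runif(1) < pf$p_cycle_observed)
              rtrunc_norm(1, pf$freq["mean"], pf$freq["sd"], 0.5) else 0,
            orientation = stats::runif(1, 0, 2 * pi))
          model_annotation(m, patient_id = pid, cilium_id = ci)
        })
        anns[[length(anns) + 1L]] <- do.call(rbind, rows)
        clin[[length(clin) + 1L]] <- data.frame(
          patient_id = pid,
          no_n_nl_min = stats::runif(1, pf$no_n["min"], pf$no_n["max"]),
          tem_pct_abnormal = stats::runif(1, pf$tem["min"], pf$tem["max"]),
          same_defect = pf$same_defect, profile = gname,
          stringsAsFactors = FALSE)
      }
    }
    list(annotations = do.call(rbind, anns),
         edges = do.call(rbind, edges),
         clinical = do.call(rbind, clin))
  })
}
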