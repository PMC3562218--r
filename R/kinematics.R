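# internal: coerce a point argument (length-2 vector or n x 2 matrix/data.frame)
# to an n x 2 numeric matrix
as_point_matrix <- function(p, arg = deparse(substitute(p))) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) {
    if (length(p) != 2L)
      stop(sprintf("'%s' must be a length-2 point or an n x 2 matrix", arg),
           call. = FALSE)
    p <- matrix(as.numeric(p), ncol = 2L)
  }
  p <- matrix(as.numeric(p), ncol = 2L,
              dimnames = list(NULL, c("x", "y")))
  if (any(!is.finite(p)))
    stop("invalid annotation: non-finite landmark coordinates", call. = FALSE)
  p
}

euclid <- function(a, b) sqrt(rowSums((a - b)^2))

#' Cilium length from the three beat-cycle landmarks
#'
#' The cilium length is taken as the larger of the two Euclidean distances
#' from the base \code{p0} to the tip positions before the active stroke
#' (\code{p1}) and before the recovery stroke (\code{p2}).
#'
#' @param p0,p1,p2 Landmark coordinates in micrometres: length-2 vectors
#'   \code{c(x, y)} or n x 2 matrices (one row per cilium).
#' @return Numeric vector of lengths in micrometres (>= 0).
#' @examples
#' cilia_length(c(0, 0), c(3, 4), c(5, 0))  # max(5, 5) = 5
#' @export
cilia_length <- function(p0, p1, p2) {
  p0 <- as_point_matrix(p0); p1 <- as_point_matrix(p1); p2 <- as_point_matrix(p2)
  pmax(euclid(p0, p1), euclid(p0, p2))
}

#' Beating angle at the ciliary base
#'
#' Angle subtended at the base \code{p0} by the two tip extreme positions
#' \code{p1} and \code{p2}, from the law of cosines. The cosine argument is
#' clamped to \eqn{[-1, 1]} so collinear landmarks do not produce NaN from
#' floating-point rounding.
#'
#' @inheritParams cilia_length
#' @return Angle(s) in radians, in \eqn{[0, \pi]}.
#' @examples
#' beating_angle(c(0, 0), c(5, 0), c(0, 5))  # pi/2
#' @export
beating_angle <- function(p0, p1, p2) {
  p0 <- as_point_matrix(p0); p1 <- as_point_matrix(p1); p2 <- as_point_matrix(p2)
  a <- euclid(p0, p1)
  b <- euclid(p0, p2)
  c2 <- rowSums((p1 - p2)^2)
  if (any(a == 0 | b == 0))
    stop("degenerate geometry: tip landmark coincides with the base",
         call. = FALSE)
  cosang <- (a^2 + b^2 - c2) / (2 * a * b)
  acos(pmin(1, pmax(-1, cosang)))
}

#' Global beat frequency
#'
#' Reciprocal of the full beat-cycle duration \code{t5 - t1}.
#'
#' @param t1,t5 Start of the cycle and start of the following cycle, seconds.
#' @return Frequency in Hz.
#' @export
global_frequency <- function(t1, t5) {
  if (any(!is.finite(t1)) || any(!is.finite(t5)) || any(t5 <= t1))
    stop("invalid annotation: t5 must exceed t1", call. = FALSE)
  1 / (t5 - t1)
}

#' Stroke and pause durations of one beat cycle
#'
#' From the five annotated time-points: power-stroke duration
#' \code{Dp = t2 - t1}, recovery duration \code{Dr = t4 - t3}, pause after
#' stroke \code{Ps = t3 - t2}, pause after recovery \code{Pr = t5 - t4}, and
#' total pause \code{Pt = Ps + Pr}. The four phase durations always sum to the
#' full cycle duration \code{t5 - t1}.
#'
#' @param t1,t2,t3,t4,t5 Time-points in seconds; must satisfy
#'   \code{t1 < t2 <= t3 < t4 <= t5}.
#' @return Data frame with columns \code{Dp}, \code{Dr}, \code{Ps}, \code{Pr},
#'   \code{Pt} (seconds).
#' @export
stroke_timings <- function(t1, t2, t3, t4, t5) {
  ok <- is.finite(t1) & is.finite(t2) & is.finite(t3) & is.finite(t4) &
    is.finite(t5) & (t1 < t2) & (t2 <= t3) & (t3 < t4) & (t4 <= t5)
  if (any(!ok))
    stop("invalid annotation: time-points must satisfy t1 < t2 <= t3 < t4 <= t5",
         call. = FALSE)
  ps <- t3 - t2
  pr <- t5 - t4
  data.frame(Dp = t2 - t1, Dr = t4 - t3, Ps = ps, Pr = pr, Pt = ps + pr)
}

#' Tip distance travelled per second
#'
#' The length of the arc swept by the cilium tip per unit time,
#' \code{Lc * angle * fg} (micrometres per second, reported per 1 s).
#'
#' @param lc Cilium length, micrometres.
#' @param angle Beating angle, radians.
#' @param fg Global frequency, Hz.
#' @return Distance in micrometres (per second).
#' @export
distance_per_second <- function(lc, angle, fg) {
  check_nonneg(lc, angle, fg)
  lc * angle * fg
}

#' Area swept per second
#'
#' The circular-sector area swept by the cilium per unit time,
#' \code{(angle / 2) * Lc^2 * fg}. Satisfies
#' \code{distance_per_second = 2 * area_per_second / Lc} whenever
#' \code{Lc > 0}.
#'
#' @inheritParams distance_per_second
#' @return Area in square micrometres (per second).
#' @export
area_per_second <- function(lc, angle, fg) {
  check_nonneg(lc, angle, fg)
  (angle / 2) * lc^2 * fg
}

check_nonneg <- function(...) {
  args <- list(...)
  nms <- vapply(substitute(list(...))[-1L], deparse, character(1))
  for (i in seq_along(args)) {
    if (any(!is.finite(args[[i]])) || any(args[[i]] < 0))
      stop(sprintf("invalid annotation: '%s' must be finite and >= 0", nms[i]),
           call. = FALSE)
  }
  invisible(NULL)
}

#' Weight a per-cilium rate by the beating-edge fraction
#'
#' Multiplies a rate (distance or area per second) by the patient's fraction
#' of beating ciliated edges, a dimensionless value in \eqn{[0, 1]}.
#'
#' @param value Rate(s) to weight.
#' @param fraction Beating-edge fraction(s) in \eqn{[0, 1]}.
#' @return \code{fraction * value}, same units as \code{value}.
#' @export
weight_by_beating_fraction <- function(value, fraction) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1))
    stop("invalid score: beating fraction must lie in [0, 1]", call. = FALSE)
  fraction * value
}

#' Convert video frame indices to seconds
#'
#' @param frame 0-based frame index (or vector).
#' @param fps Acquisition frame rate, frames per second (> 0).
#' @return Time in seconds.
#' @export
frames_to_seconds <- function(frame, fps) {
  if (any(fps <= 0)) stop("fps must be > 0", call. = FALSE)
  frame / fps
}

#' @rdname frames_to_seconds
#' @param t Time in seconds.
#' @export
seconds_to_frames <- function(t, fps) {
  if (any(fps <= 0)) stop("fps must be > 0", call. = FALSE)
  t * fps
}

#' Validate a table of beat-cycle annotations
#'
#' An annotation table holds one row per cilium, with landmark coordinates in
#' micrometres, time-points in seconds, and a \code{cycle_observed} flag for
#' cilia whose tip never completed an identifiable cycle.
#'
#' @param ann Data frame with columns \code{patient_id}, \code{cilium_id},
#'   \code{x0, y0, x1, y1, x2, y2} (micrometres), \code{t1 .. t5} (seconds)
#'   and logical \code{cycle_observed}.
#' @return The validated data frame, invisibly classed \code{"cbp_annotations"}.
#' @export
validate_annotations <- function(ann) {
  needed <- c("patient_id", "cilium_id", "x0", "y0", "x1", "y1", "x2", "y2",
              paste0("t", 1:5), "cycle_observed")
  miss <- setdiff(needed, names(ann))
  if (length(miss))
    stop("annotation table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- c("x0", "y0", "x1", "y1", "x2", "y2", paste0("t", 1:5))
  for (j in num) ann[[j]] <- as.numeric(ann[[j]])
  ann$cycle_observed <- as.logical(ann$cycle_observed)
  obs <- which(ann$cycle_observed)
  if (length(obs)) {
    o <- ann[obs, ]
    ok <- with(o, t1 < t2 & t2 <= t3 & t3 < t4 & t4 <= t5)
    if (any(!ok | is.na(ok)))
      stop("invalid annotation in row(s) ",
           paste(obs[!ok | is.na(ok)], collapse = ", "),
           ": time-points must satisfy t1 < t2 <= t3 < t4 <= t5",
           call. = FALSE)
  }
  class(ann) <- unique(c("cbp_annotations", class(ann)))
  invisible(ann)
}

#' Compute the twelve beat-cycle kinematic parameters
#'
#' For each annotated cilium, computes cilium length, beating angle, global
#' frequency, the four stroke/pause durations and total pause, the tip
#' distance travelled per second, the area swept per second, and the two
#' weighted rates (multiplied by the patient's beating-edge fraction).
#'
#' Cilia flagged \code{cycle_observed = FALSE} contribute zero frequency,
#' durations, distance and area by convention; their length and angle are
#' still computed from the landmarks when present.
#'
#' @param ann Annotation table (see \code{\link{validate_annotations}}).
#' @param fraction Beating-edge fraction in \eqn{[0, 1]}: a single value
#'   applied to all rows, or one value per row.
#' @return Data frame with one row per cilium: \code{patient_id},
#'   \code{cilium_id}, \code{length_um}, \code{angle_rad}, \code{freq_hz},
#'   \code{dur_power_s}, \code{dur_recovery_s}, \code{pause_after_stroke_s},
#'   \code{pause_after_recovery_s}, \code{pause_total_s}, \code{dist_per_s_um},
#'   \code{area_per_s_um2}, \code{weighted_dist_per_s_um},
#'   \code{weighted_area_per_s_um2}.
#' @examples
#' ann <- data.frame(patient_id = "p1", cilium_id = 1L,
#'                   x0 = 0, y0 = 0, x1 = 5, y1 = 0, x2 = 3, y2 = 4,
#'                   t1 = 0, t2 = 0.05, t3 = 0.06, t4 = 0.12, t5 = 0.125,
#'                   cycle_observed = TRUE)
#' compute_cycle_parameters(ann, fraction = 1)
#' @export
compute_cycle_parameters <- function(ann, fraction = 1) {
  ann <- validate_annotations(ann)
  n <- nrow(ann)
  if (length(fraction) == 1L) fraction <- rep(fraction, n)
  if (length(fraction) != n)
    stop("'fraction' must have length 1 or nrow(ann)", call. = FALSE)
  if (any(!is.finite(fraction)) || any(fraction < 0 | fraction > 1))
    stop("invalid score: beating fraction must lie in [0, 1]", call. = FALSE)

  p0 <- cbind(ann$x0, ann$y0); p1 <- cbind(ann$x1, ann$y1)
  p2 <- cbind(ann$x2, ann$y2)
  lc <- cilia_length(p0, p1, p2)
  # angle 0 by convention where a tip landmark coincides with the base
  # (flagged-immotile cilia)
  a <- euclid(p0, p1); b <- euclid(p0, p2)
  angle <- numeric(n)
  ok <- a > 0 & b > 0
  if (any(ok)) angle[ok] <- beating_angle(p0[ok, , drop = FALSE],
                                          p1[ok, , drop = FALSE],
                                          p2[ok, , drop = FALSE])

  fg <- numeric(n)
  dur <- data.frame(Dp = numeric(n), Dr = numeric(n), Ps = numeric(n),
                    Pr = numeric(n), Pt = numeric(n))
  obs <- ann$cycle_observed
  if (any(obs)) {
    fg[obs] <- global_frequency(ann$t1[obs], ann$t5[obs])
    dur[obs, ] <- stroke_timings(ann$t1[obs], ann$t2[obs], ann$t3[obs],
                                 ann$t4[obs], ann$t5[obs])
  }
  dist <- distance_per_second(lc, angle, fg)
  area <- area_per_second(lc, angle, fg)
  data.frame(
    patient_id = ann$patient_id,
    cilium_id = ann$cilium_id,
    length_um = lc,
    angle_rad = angle,
    freq_hz = fg,
    dur_power_s = dur$Dp,
    dur_recovery_s = dur$Dr,
    pause_after_stroke_s = dur$Ps,
    pause_after_recovery_s = dur$Pr,
    pause_total_s = dur$Pt,
    dist_per_s_um = dist,
    area_per_s_um2 = area,
    weighted_dist_per_s_um = weight_by_beating_fraction(dist, fraction),
    weighted_area_per_s_um2 = weight_by_beating_fraction(area, fraction),
    stringsAsFactors = FALSE
  )
}
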