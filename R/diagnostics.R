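#' Gold-standard PCD group assignment
#'
#' Partitions patients by the joint rule on transmission electron microscopy
#' (TEM) and nasal nitric-oxide output (NOn): PCD when more than 90% of cilia
#' are ultrastructurally abnormal, all sharing the same defect, and NOn is
#' below 100 nl/min; non-PCD when fewer than 20% of cilia are abnormal and
#' NOn is at least 100 nl/min; inconclusive otherwise (discordant TEM and
#' NOn results).
#'
#' @param no_n Nasal NO output, nl/min (>= 0).
#' @param tem_pct_abnormal Percentage of ultrastructurally abnormal cilia,
#'   in \eqn{[0, 100]}.
#' @param same_defect Logical: do all abnormal cilia share a single
#'   ultrastructural defect? Heterogeneous phenotypes are \code{FALSE}.
#' @return Factor with levels \code{PCD}, \code{non_PCD},
#'   \code{inconclusive}.
#' @examples
#' gold_standard_classify(c(15, 809, 93), c(100, 7, 21), c(TRUE, FALSE, TRUE))
#' @export
gold_standard_classify <- function(no_n, tem_pct_abnormal, same_defect) {
  if (any(!is.finite(no_n)) || any(no_n < 0))
    stop("no_n must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(tem_pct_abnormal)) ||
      any(tem_pct_abnormal < 0 | tem_pct_abnormal > 100))
    stop("tem_pct_abnormal must lie in [0, 100]", call. = FALSE)
  same_defect <- as.logical(same_defect)
  out <- rep("inconclusive", length(no_n))
  out[tem_pct_abnormal > 90 & same_defect & no_n < 100] <- "PCD"
  out[tem_pct_abnormal < 20 & no_n >= 100] <- "non_PCD"
  factor(out, levels = c("PCD", "non_PCD", "inconclusive"))
}

#' Empirical ROC curve for a diagnostic measurement
#'
#' Sweeps every candidate threshold (midpoints between adjacent distinct
#' pooled values, bracketed below the minimum and above the maximum) and
#' records sensitivity and specificity. With
#' \code{orientation = "lower"} a measurement strictly below the threshold is
#' called positive; with \code{"higher"}, strictly above. The AUC is the
#' trapezoidal area under the (FPR, TPR) polyline and equals the
#' Mann-Whitney U statistic (ties counted 0.5) divided by
#' \code{n_pos * n_neg}.
#'
#' @param pos Measurements from the positive (disease) group.
#' @param neg Measurements from the negative group.
#' @param orientation \code{"lower"} when low values indicate disease
#'   (e.g. weighted distance travelled per second), \code{"higher"} otherwise.
#' @return An object of class \code{"cbp_roc"}: list with \code{thresholds},
#'   \code{sensitivity}, \code{specificity}, \code{fpr}, \code{auc},
#'   \code{n_pos}, \code{n_neg}, \code{orientation}.
#' @export
roc_curve <- function(pos, neg, orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  pos <- as.numeric(pos); neg <- as.numeric(neg)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("insufficient data: both groups must be nonempty", call. = FALSE)
  if (any(!is.finite(pos)) || any(!is.finite(neg)))
    stop("measurements must be finite", call. = FALSE)
  v <- sort(unique(c(pos, neg)))
  span <- max(diff(range(v)), 1)
  thr <- if (length(v) > 1L) (v[-1L] + v[-length(v)]) / 2 else numeric(0)
  thr <- c(min(v) - 0.05 * span, thr, max(v) + 0.05 * span)
  if (orientation == "lower") {
    sens <- vapply(thr, function(c) mean(pos < c), numeric(1))
    spec <- vapply(thr, function(c) mean(neg >= c), numeric(1))
  } else {
    sens <- vapply(thr, function(c) mean(pos > c), numeric(1))
    spec <- vapply(thr, function(c) mean(neg <= c), numeric(1))
  }
  fpr <- 1 - spec
  # bracketing thresholds guarantee the sweep reaches (0,0) and (1,1)
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1L] + sens[o][-length(o)]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 fpr = fpr, auc = auc, n_pos = length(pos),
                 n_neg = length(neg), orientation = orientation,
                 pos = pos, neg = neg),
            class = "cbp_roc")
}

#' @export
print.cbp_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC: %d positive vs %d negative (%s values indicate disease)\n",
              x$n_pos, x$n_neg,
              if (x$orientation == "lower") "lower" else "higher"))
  cat(sprintf("AUC = %.4f over %d candidate thresholds\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' With \code{orientation = "lower"}, sensitivity is the fraction of positive
#' measurements strictly below the cutoff and specificity the fraction of
#' negative measurements at or above it (mirrored for \code{"higher"}).
#'
#' @param values Numeric measurements.
#' @param labels Logical (or 0/1) vector, \code{TRUE} for the positive group.
#' @param cutoff Decision threshold, same units as \code{values}.
#' @inheritParams roc_curve
#' @return Named numeric vector \code{c(sensitivity, specificity)}.
#' @export
sens_spec_at <- function(values, labels, cutoff,
                         orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  if (!is.finite(cutoff)) stop("cutoff must be finite", call. = FALSE)
  if (all(labels) || !any(labels))
    stop("undefined rate: need both positive and negative measurements",
         call. = FALSE)
  pos <- values[labels]; neg <- values[!labels]
  if (orientation == "lower")
    c(sensitivity = mean(pos < cutoff), specificity = mean(neg >= cutoff))
  else
    c(sensitivity = mean(pos > cutoff), specificity = mean(neg <= cutoff))
}

#' Named diagnostic cutoffs from an ROC curve
#'
#' Three operating points are extracted from the threshold sweep: the
#' balanced cutoff maximising Youden's J (sensitivity + specificity - 1),
#' the 100%-sensitivity cutoff (the operating point with sensitivity 1 and
#' maximal specificity) and the 100%-specificity cutoff (specificity 1 and
#' maximal sensitivity). For a measurement where low values indicate disease
#' the 100%-specificity cutoff lies at or below the 100%-sensitivity cutoff;
#' the interval between them is the diagnostic grey zone.
#'
#' @param roc A \code{"cbp_roc"} object from \code{\link{roc_curve}}.
#' @return Named numeric vector \code{c(balanced, sens100, spec100)}, in
#'   measurement units.
#' @export
find_named_cutoffs <- function(roc) {
  stopifnot(inherits(roc, "cbp_roc"))
  thr <- roc$thresholds; sens <- roc$sensitivity; spec <- roc$specificity
  j <- sens + spec - 1
  balanced <- thr[which.max(j)]
  s1 <- which(sens >= 1 - 1e-12)
  p1 <- which(spec >= 1 - 1e-12)
  if (!length(s1) || !length(p1))
    stop("degenerate ROC: cannot locate 100% operating points", call. = FALSE)
  sens100 <- thr[s1[which.max(spec[s1])]]
  spec100 <- thr[p1[which.max(sens[p1])]]
  c(balanced = balanced, sens100 = sens100, spec100 = spec100)
}

#' Three-zone diagnostic classification
#'
#' Places a patient's mean weighted measurement relative to the two
#' 100% cutoffs (low values indicating disease): strictly below the
#' 100%-specificity cutoff supports the PCD diagnosis, strictly above the
#' 100%-sensitivity cutoff excludes it, and values in between (boundaries
#' included) remain indeterminate.
#'
#' @param value Mean weighted measurement(s), e.g. weighted distance
#'   travelled per second in micrometres.
#' @param spec100 100%-specificity cutoff (lower bound of the grey zone).
#' @param sens100 100%-sensitivity cutoff (upper bound of the grey zone).
#' @return Factor with levels \code{pcd_supported}, \code{indeterminate},
#'   \code{pcd_excluded}.
#' @examples
#' classify_three_zone(c(5.7, 30.3, 76.0), spec100 = 10, sens100 = 51)
#' @export
classify_three_zone <- function(value, spec100, sens100) {
  if (!is.finite(spec100) || !is.finite(sens100) || spec100 > sens100)
    stop("configuration error: require spec100 <= sens100", call. = FALSE)
  out <- rep("indeterminate", length(value))
  out[value < spec100] <- "pcd_supported"
  out[value > sens100] <- "pcd_excluded"
  factor(out, levels = c("pcd_supported", "indeterminate", "pcd_excluded"))
}

#' Mann-Whitney U test between two groups
#'
#' The U statistic is counted pairwise as the number of pairs where the first
#' group's value exceeds the second's, with ties contributing 0.5; the
#' two-sided p-value comes from \code{\link[stats]{wilcox.test}} (normal
#' approximation with tie correction where ties are present). With this
#' convention \code{U / (n1 * n2)} equals the area under the empirical ROC
#' curve taking group \code{a} as positive with higher values indicating
#' disease.
#'
#' @param a,b Numeric samples.
#' @return Named numeric vector \code{c(U, p)}.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("insufficient data: both samples must be nonempty", call. = FALSE)
  gt <- outer(a, b, ">")
  eq <- outer(a, b, "==")
  u <- sum(gt) + 0.5 * sum(eq)
  p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                           correct = FALSE)$p.value)
  c(U = u, p = p)
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper over \code{\link[stats]{kruskal.test}}: tie-corrected H
#' statistic with a chi-square p-value on \code{k - 1} degrees of freedom.
#'
#' @param groups List of two or more numeric samples.
#' @return Named numeric vector \code{c(H, p, df)}.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L ||
      any(vapply(groups, length, integer(1)) == 0L))
    stop("insufficient data: need at least two nonempty groups", call. = FALSE)
  kt <- stats::kruskal.test(groups)
  c(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}
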