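#' Fit the ROC-cutoff diagnostic classifier
#'
#' Fits the empirical-ROC diagnostic rule for a single quantitative
#' beat-pattern parameter (typically the mean weighted distance travelled per
#' second) against a binary gold standard. The fit records the full ROC
#' sweep, its AUC, the Mann-Whitney comparison of the two groups and three
#' named operating points: the balanced (Youden-maximising) cutoff and the
#' two 100% cutoffs bounding the diagnostic grey zone. \code{predict} then
#' assigns new patients to the three zones (PCD supported / indeterminate /
#' PCD excluded).
#'
#' @param x Either a formula \code{value ~ group} with \code{data}, or a
#'   numeric vector of measurements.
#' @param ... Passed between methods.
#' @return An object of class \code{"cbp_classifier"}.
#' @seealso \code{\link{roc_curve}}, \code{\link{find_named_cutoffs}},
#'   \code{\link{classify_three_zone}}
#' @examples
#' cohort <- reference_cohort()
#' conclusive <- subset(cohort, group != "inconclusive")
#' fit <- cbp_classifier(weighted_dist_um ~ group, data = conclusive,
#'                       positive = "PCD")
#' coef(fit)
#' predict(fit, subset(cohort, group == "inconclusive")$weighted_dist_um,
#'         cutoffs = c(spec100 = 10, sens100 = 51))
#' @export
cbp_classifier <- function(x, ...) UseMethod("cbp_classifier")

#' @rdname cbp_classifier
#' @param data Data frame holding the formula variables.
#' @param positive Level of the grouping variable that marks the disease
#'   (positive) group.
#' @param orientation \code{"lower"} when low values indicate disease.
#' @export
cbp_classifier.formula <- function(x, data, positive,
                                   orientation = c("lower", "higher"), ...) {
  mf <- stats::model.frame(x, data)
  if (ncol(mf) != 2L)
    stop("formula must have the form value ~ group", call. = FALSE)
  values <- mf[[1L]]
  grp <- as.character(mf[[2L]])
  if (missing(positive)) positive <- sort(unique(grp))[1L]
  fit <- cbp_classifier.default(values, grp == positive,
                                orientation = orientation, ...)
  fit$call <- match.call()
  fit$positive <- positive
  fit
}

#' @rdname cbp_classifier
#' @param labels Logical (or 0/1) vector, \code{TRUE} for the disease group.
#' @export
cbp_classifier.default <- function(x, labels,
                                   orientation = c("lower", "higher"), ...) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  if (length(x) != length(labels))
    stop("'x' and 'labels' must have the same length", call. = FALSE)
  keep <- !is.na(x) & !is.na(labels)
  x <- x[keep]; labels <- labels[keep]
  if (all(labels) || !any(labels))
    stop("insufficient data: need both positive and negative measurements",
         call. = FALSE)
  roc <- roc_curve(x[labels], x[!labels], orientation = orientation)
  cutoffs <- find_named_cutoffs(roc)
  mw <- mann_whitney(x[labels], x[!labels])
  structure(list(call = match.call(), values = x, labels = labels,
                 orientation = orientation, positive = "positive",
                 roc = roc, auc = roc$auc, cutoffs = cutoffs, mw = mw),
            class = "cbp_classifier")
}

#' @export
print.cbp_classifier <- function(x, ...) {
  cat("ROC-cutoff diagnostic classifier\n")
  cat(sprintf("  %d positive vs %d negative measurements (%s values indicate disease)\n",
              x$roc$n_pos, x$roc$n_neg, x$orientation))
  cat(sprintf("  AUC = %.3f\n", x$auc))
  cat(sprintf("  cutoffs: balanced = %.3g, 100%% sensitivity = %.3g, 100%% specificity = %.3g\n",
              x$cutoffs["balanced"], x$cutoffs["sens100"], x$cutoffs["spec100"]))
  invisible(x)
}

#' @export
coef.cbp_classifier <- function(object, ...) object$cutoffs

#' @export
summary.cbp_classifier <- function(object, ...) {
  ss <- lapply(object$cutoffs, function(c)
    sens_spec_at(object$values, object$labels, c,
                 orientation = object$orientation))
  op <- do.call(rbind, ss)
  op <- cbind(cutoff = object$cutoffs, op, youden = op[, 1] + op[, 2] - 1)
  structure(list(call = object$call, auc = object$auc, operating = op,
                 mw = object$mw, n_pos = object$roc$n_pos,
                 n_neg = object$roc$n_neg, orientation = object$orientation),
            class = "summary.cbp_classifier")
}

#' @export
print.summary.cbp_classifier <- function(x, ...) {
  cat("ROC-cutoff diagnostic classifier\n\nCall: ")
  print(x$call)
  cat(sprintf("\n%d positive vs %d negative; %s values indicate disease\n",
              x$n_pos, x$n_neg, x$orientation))
  cat(sprintf("AUC = %.4f;  Mann-Whitney U = %.1f, p = %.3g\n\n",
              x$auc, x$mw["U"], x$mw["p"]))
  cat("Operating points:\n")
  print(round(x$operating, 4))
  invisible(x)
}

#' Three-zone predictions from a fitted classifier
#'
#' @param object A \code{"cbp_classifier"} fit.
#' @param newdata Numeric vector of measurements (or a data frame holding
#'   the response variable of the fitting formula).
#' @param cutoffs Optional named vector \code{c(spec100 = , sens100 = )}
#'   overriding the fitted cutoffs, e.g. externally established ones.
#' @param ... Ignored.
#' @return Factor of zones (\code{pcd_supported}, \code{indeterminate},
#'   \code{pcd_excluded}).
#' @export
predict.cbp_classifier <- function(object, newdata,
                                   cutoffs = coef(object)[c("spec100", "sens100")],
                                   ...) {
  if (missing(newdata)) newdata <- object$values
  if (is.data.frame(newdata)) {
    resp <- all.vars(object$call$x)[1L]
    if (!resp %in% names(newdata))
      stop("newdata must contain column '", resp, "'", call. = FALSE)
    newdata <- newdata[[resp]]
  }
  lo <- unname(cutoffs["spec100"]); hi <- unname(cutoffs["sens100"])
  if (object$orientation == "higher") {
    # mirror: high values indicate disease, so the supported zone is on top
    # (negating values and cutoffs maps it onto the lower-orientation rule)
    classify_three_zone(-newdata, spec100 = -lo, sens100 = -hi)
  } else {
    classify_three_zone(newdata, spec100 = lo, sens100 = hi)
  }
}

#' @export
plot.cbp_classifier <- function(x, ...) {
  o <- order(x$roc$fpr, x$roc$sensitivity)
  graphics::plot(x$roc$fpr[o], x$roc$sensitivity[o], type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  for (nm in names(x$cutoffs)) {
    ss <- sens_spec_at(x$values, x$labels, x$cutoffs[nm],
                       orientation = x$orientation)
    graphics::points(1 - ss["specificity"], ss["sensitivity"], pch = 19)
    graphics::text(1 - ss["specificity"], ss["sensitivity"],
                   labels = sprintf("%s (%.3g)", nm, x$cutoffs[nm]),
                   pos = 4, cex = 0.8)
  }
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}
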