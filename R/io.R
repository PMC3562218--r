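ANNOTATION_COLS <- c("patient_id", "cilium_id", "fps", "pixel_size_um",
                     "x0", "y0", "x1", "y1", "x2", "y2",
                     paste0("t", 1:5), "cycle_observed")

#' Read a beat-cycle annotation CSV
#'
#' The on-disk schema carries landmark coordinates in pixels and time-points
#' as 0-based frame indices, together with the per-recording frame rate and
#' pixel size; reading converts pixels to micrometres and frames to seconds.
#' Validation failures name the offending row.
#'
#' @param path CSV file with header columns \code{patient_id, cilium_id,
#'   fps, pixel_size_um, x0, y0, x1, y1, x2, y2, t1..t5, cycle_observed}.
#' @return Annotation data frame in micrometres / seconds
#'   (see \code{\link{validate_annotations}}).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(ANNOTATION_COLS, names(raw))
  if (length(miss))
    stop("parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  num <- setdiff(ANNOTATION_COLS, c("patient_id", "cilium_id", "cycle_observed"))
  for (j in num) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]) & raw[[j]] != "" &
                   !(j %in% paste0("t", 1:5)))
    if (length(bad))
      stop(sprintf("parse error in %s: row %d, field '%s' is not numeric",
                   path, bad[1L], j), call. = FALSE)
    raw[[j]] <- v
  }
  if (any(raw$fps <= 0, na.rm = TRUE) || any(raw$pixel_size_um <= 0, na.rm = TRUE))
    stop("parse error: fps and pixel_size_um must be > 0", call. = FALSE)
  out <- data.frame(
    patient_id = as.character(raw$patient_id),
    cilium_id = raw$cilium_id,
    x0 = raw$x0 * raw$pixel_size_um, y0 = raw$y0 * raw$pixel_size_um,
    x1 = raw$x1 * raw$pixel_size_um, y1 = raw$y1 * raw$pixel_size_um,
    x2 = raw$x2 * raw$pixel_size_um, y2 = raw$y2 * raw$pixel_size_um,
    t1 = raw$t1 / raw$fps, t2 = raw$t2 / raw$fps, t3 = raw$t3 / raw$fps,
    t4 = raw$t4 / raw$fps, t5 = raw$t5 / raw$fps,
    cycle_observed = as.logical(raw$cycle_observed),
    stringsAsFactors = FALSE)
  validate_annotations(out)
  out
}

#' Write annotations in the pixel / frame-index CSV schema
#'
#' Inverse of \code{\link{read_annotations}}: micrometres are divided by the
#' pixel size and seconds multiplied by the frame rate before writing.
#'
#' @param ann Annotation data frame (micrometres / seconds).
#' @param path Output CSV path.
#' @param fps Frame rate used to encode time-points as frame indices.
#' @param pixel_size Pixel edge in micrometres used to encode coordinates.
#' @export
write_annotations <- function(ann, path, fps = 355, pixel_size = 0.13) {
  validate_annotations(ann)
  out <- data.frame(
    patient_id = ann$patient_id, cilium_id = ann$cilium_id,
    fps = fps, pixel_size_um = pixel_size,
    x0 = ann$x0 / pixel_size, y0 = ann$y0 / pixel_size,
    x1 = ann$x1 / pixel_size, y1 = ann$y1 / pixel_size,
    x2 = ann$x2 / pixel_size, y2 = ann$y2 / pixel_size,
    t1 = ann$t1 * fps, t2 = ann$t2 * fps, t3 = ann$t3 * fps,
    t4 = ann$t4 * fps, t5 = ann$t5 * fps,
    cycle_observed = ann$cycle_observed)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edge-observation CSV
#'
#' @param path CSV with header \code{patient_id, area_id, beating_score,
#'   pattern_label, dyskinesia_score}.
#' @return Validated data frame of edge observations.
#' @export
read_edge_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  edges <- utils::read.csv(path, stringsAsFactors = FALSE)
  edges$patient_id <- as.character(edges$patient_id)
  validate_edges(edges)
  edges
}

#' Read a patient clinical TSV
#'
#' @param path Tab-separated file with header \code{patient_id, no_n_nl_min,
#'   tem_pct_abnormal, same_defect} and optional extra columns
#'   (\code{defect_label}, \code{group}, ...).
#' @return Data frame with \code{same_defect} coerced to logical.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  clin <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "no_n_nl_min", "tem_pct_abnormal", "same_defect")
  miss <- setdiff(needed, names(clin))
  if (length(miss))
    stop("parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  clin$patient_id <- as.character(clin$patient_id)
  clin$same_defect <- as.logical(clin$same_defect)
  clin
}

#' Bundled reference cohort of 34 patients investigated for PCD
#'
#' Patient-level measurements from a pilot cohort referred for suspected
#' primary ciliary dyskinesia: nasal NO output, TEM percentage of abnormal
#' cilia and defect label, the qualitative beat-pattern percentages and
#' dyskinesia score, and the two weighted quantitative parameters (distance
#' travelled and area swept per second). The \code{group} column is the
#' gold-standard partition recomputed from the NO/TEM columns with
#' \code{\link{gold_standard_classify}}.
#'
#' @return Data frame with one row per patient.
#' @export
reference_cohort <- function() {
  dir <- system.file("extdata", package = "ciliokin")
  clin <- read_clinical(file.path(dir, "reference_clinical.tsv"))
  bp <- utils::read.delim(file.path(dir, "reference_beat_pattern.tsv"),
                          stringsAsFactors = FALSE)
  bp$patient_id <- as.character(bp$patient_id)
  out <- merge(clin, bp, by = "patient_id", sort = FALSE)
  out <- out[order(as.integer(out$patient_id)), ]
  out$group <- gold_standard_classify(out$no_n_nl_min, out$tem_pct_abnormal,
                                      out$same_defect)
  rownames(out) <- NULL
  out
}

#' Run the full beat-pattern analysis pipeline
#'
#' Summarises every patient, applies the gold standard, compares the PCD and
#' non-PCD groups parameter by parameter (Mann-Whitney; Kruskal-Wallis when
#' the inconclusive group is also present), fits the ROC-cutoff classifier
#' on the patient-level mean weighted distance travelled per second and
#' assigns three-zone calls to the inconclusive patients.
#'
#' @param annotations Annotation data frame (micrometres / seconds), or a
#'   CSV path in the pixel / frame schema.
#' @param edges Edge-observation data frame or CSV path.
#' @param clinical Clinical data frame or TSV path.
#' @param cutoffs Optional named vector \code{c(spec100 = , sens100 = )}
#'   overriding the fitted zone cutoffs (e.g. externally established
#'   10 / 51 micrometre cutoffs).
#' @param parameter Summary column used for the classifier; default the mean
#'   weighted distance travelled per second.
#' @return List of class \code{"cbp_report"}: \code{summaries},
#'   \code{groups}, \code{group_tests}, \code{classifier}, \code{zones},
#'   \code{cutoffs_used}.
#' @export
run_full_analysis <- function(annotations, edges, clinical, cutoffs = NULL,
                              parameter = "weighted_dist_per_s_um_mean") {
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  if (is.character(edges)) edges <- read_edge_observations(edges)
  if (is.character(clinical)) clinical <- read_clinical(clinical)

  summ <- summarize_cohort(annotations, edges)
  orphans <- c(setdiff(summ$patient_id, clinical$patient_id),
               setdiff(clinical$patient_id, summ$patient_id))
  if (length(orphans))
    stop("consistency error: patient ids missing from a table: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  clinical <- clinical[match(summ$patient_id, clinical$patient_id), ]
  groups <- gold_standard_classify(clinical$no_n_nl_min,
                                   clinical$tem_pct_abnormal,
                                   clinical$same_defect)

  pcd <- summ[groups == "PCD", , drop = FALSE]
  non <- summ[groups == "non_PCD", , drop = FALSE]
  inc <- summ[groups == "inconclusive", , drop = FALSE]

  params <- grep("_mean$", names(summ), value = TRUE)
  tests <- NULL
  if (nrow(pcd) && nrow(non)) {
    tests <- do.call(rbind, lapply(params, function(pp) {
      mw <- mann_whitney(pcd[[pp]], non[[pp]])
      data.frame(parameter = sub("_mean$", "", pp), U = mw["U"], p = mw["p"])
    }))
    rownames(tests) <- NULL
  }

  fit <- NULL; zones <- NULL; used <- cutoffs
  if (nrow(pcd) && nrow(non)) {
    vals <- c(pcd[[parameter]], non[[parameter]])
    labs <- rep(c(TRUE, FALSE), c(nrow(pcd), nrow(non)))
    fit <- cbp_classifier(vals, labs, orientation = "lower")
    if (is.null(used)) used <- coef(fit)[c("spec100", "sens100")]
  }
  if (!is.null(used) && nrow(inc)) {
    zones <- data.frame(patient_id = inc$patient_id,
                        value = inc[[parameter]],
                        zone = classify_three_zone(inc[[parameter]],
                                                   used[["spec100"]],
                                                   used[["sens100"]]),
                        stringsAsFactors = FALSE)
  }
  structure(list(summaries = summ, groups = groups, group_tests = tests,
                 classifier = fit, zones = zones, cutoffs_used = used,
                 parameter = parameter),
            class = "cbp_report")
}

#' @export
print.cbp_report <- function(x, ...) {
  cat("Ciliary beat-pattern analysis report\n")
  cat(sprintf("  patients: %d (%s)\n", nrow(x$summaries),
              paste(sprintf("%s %d", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  if (!is.null(x$classifier))
    cat(sprintf("  classifier on %s: AUC = %.3f\n", x$parameter,
                x$classifier$auc))
  if (!is.null(x$cutoffs_used))
    cat(sprintf("  zone cutoffs: spec100 = %.3g, sens100 = %.3g\n",
                x$cutoffs_used[["spec100"]], x$cutoffs_used[["sens100"]]))
  if (!is.null(x$zones)) {
    cat("  three-zone calls for inconclusive patients:\n")
    tb <- table(x$zones$zone)
    cat(sprintf("    %s: %d\n", names(tb), tb), sep = "")
  }
  invisible(x)
}

#' Write a per-patient summary TSV in the reference table layout
#'
#' Columns mirror the published patient table: total / virtually-immotile /
#' stiff / circular abnormal-beating percentages, dyskinesia score, weighted
#' distance and weighted area.
#'
#' @param summaries Output of \code{\link{summarize_cohort}}.
#' @param path Output TSV path.
#' @export
write_summary_tsv <- function(summaries, path) {
  out <- data.frame(
    patient_id = summaries$patient_id,
    pct_abnormal_total = summaries$pct_abnormal,
    pct_virtually_immotile = summaries$pct_virtually_immotile,
    pct_stiff = summaries$pct_stiff,
    pct_circular = summaries$pct_circular,
    dyskinesia_score = summaries$mean_dyskinesia,
    weighted_dist_um = summaries$weighted_dist_per_s_um_mean,
    weighted_area_um2 = summaries$weighted_area_per_s_um2_mean)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
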