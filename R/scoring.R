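#' Recognised beat-pattern labels
#'
#' The four qualitative beat-pattern classes assigned per epithelial edge:
#' normal, virtually immotile, stiff, circular.
#' @export
PATTERN_LABELS <- c("normal", "virtually_immotile", "stiff", "circular")

validate_edges <- function(edges) {
  needed <- c("patient_id", "beating_score", "pattern_label", "dyskinesia_score")
  miss <- setdiff(needed, names(edges))
  if (length(miss))
    stop("edge table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(edges) == 0L)
    stop("insufficient data: no edge observations", call. = FALSE)
  if (!all(edges$beating_score %in% c(0, 0.5, 1)))
    stop("invalid score: beating_score must be one of 0, 0.5, 1", call. = FALSE)
  bad <- setdiff(unique(as.character(edges$pattern_label)), PATTERN_LABELS)
  if (length(bad))
    stop("invalid label: unknown pattern_label ", paste(bad, collapse = ", "),
         call. = FALSE)
  ds <- edges$dyskinesia_score
  if (any(!is.finite(ds)) || any(ds < 0 | ds > 3))
    stop("invalid score: dyskinesia_score must lie in [0, 3]", call. = FALSE)
  invisible(edges)
}

#' Fraction of beating ciliated edges
#'
#' Each of the (nominally 20) recorded epithelial areas is scored 1 when a
#' majority of cilia beat, 0.5 when about half beat and 0 when a minority
#' beat. The beating fraction is the sum of the scores divided by the number
#' of areas.
#'
#' @param edges Data frame of edge observations with at least columns
#'   \code{patient_id}, \code{beating_score}, \code{pattern_label},
#'   \code{dyskinesia_score} (one patient only).
#' @return Fraction in \eqn{[0, 1]}.
#' @export
beating_fraction <- function(edges) {
  validate_edges(edges)
  if (nrow(edges) != 20L)
    warning(sprintf("expected 20 edge areas, got %d", nrow(edges)),
            call. = FALSE)
  sum(edges$beating_score) / nrow(edges)
}

#' Per-label beat-pattern percentages
#'
#' Share of the recorded edges carrying each qualitative pattern label,
#' as percentages summing to 100, plus the total abnormal percentage
#' (100 minus the normal share).
#'
#' @inheritParams beating_fraction
#' @return Named numeric vector: \code{pct_normal},
#'   \code{pct_virtually_immotile}, \code{pct_stiff}, \code{pct_circular},
#'   \code{pct_abnormal}.
#' @export
pattern_percentages <- function(edges) {
  validate_edges(edges)
  lab <- factor(as.character(edges$pattern_label), levels = PATTERN_LABELS)
  pct <- 100 * as.numeric(table(lab)) / nrow(edges)
  names(pct) <- paste0("pct_", PATTERN_LABELS)
  c(pct, pct_abnormal = 100 - pct[["pct_normal"]])
}

#' Mean ciliary dyskinesia score
#'
#' Arithmetic mean over edges of the 0--3 dyskinesia grade (0 = coordinated
#' beating, 1--3 = dyskinetic beating graded by the extent of abnormal
#' beating along the edge).
#'
#' @inheritParams beating_fraction
#' @return Mean score in \eqn{[0, 3]}.
#' @export
mean_dyskinesia <- function(edges) {
  validate_edges(edges)
  mean(edges$dyskinesia_score)
}

#' Summarise one patient's observations
#'
#' Combines a patient's cilium annotations and edge observations into the
#' per-patient summary used for diagnosis: beating-edge fraction, pattern
#' percentages, mean dyskinesia score, and the mean and sample standard
#' deviation of each of the twelve kinematic parameters over the (nominally
#' ten) annotated cilia. Weighted rates are computed per cilium with the
#' patient's beating fraction, then averaged.
#'
#' @param ann Annotation table for one patient
#'   (see \code{\link{validate_annotations}}).
#' @param edges Edge-observation table for the same patient.
#' @return A one-row data frame: \code{patient_id}, \code{n_cilia},
#'   \code{n_edges}, \code{beating_fraction}, the pattern percentages,
#'   \code{mean_dyskinesia}, and \code{<param>_mean} / \code{<param>_sd}
#'   for each kinematic parameter.
#' @export
summarize_patient <- function(ann, edges) {
  if (nrow(ann) == 0L || nrow(edges) == 0L)
    stop("insufficient data: need at least one cilium and one edge",
         call. = FALSE)
  pid <- unique(as.character(ann$patient_id))
  if (length(pid) != 1L || !all(as.character(edges$patient_id) == pid))
    stop("summarize_patient expects observations from a single patient",
         call. = FALSE)
  if (nrow(ann) != 10L)
    warning(sprintf("patient %s: expected 10 cilia, got %d", pid, nrow(ann)),
            call. = FALSE)
  frac <- beating_fraction(edges)
  pars <- compute_cycle_parameters(ann, fraction = frac)
  num <- setdiff(names(pars), c("patient_id", "cilium_id"))
  mns <- vapply(pars[num], mean, numeric(1))
  sds <- vapply(pars[num], stats::sd, numeric(1))
  if (nrow(pars) == 1L) sds[] <- 0
  out <- data.frame(patient_id = pid, n_cilia = nrow(ann),
                    n_edges = nrow(edges), beating_fraction = frac,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(as.list(pattern_percentages(edges))),
               mean_dyskinesia = mean_dyskinesia(edges),
               as.data.frame(as.list(stats::setNames(mns, paste0(num, "_mean")))),
               as.data.frame(as.list(stats::setNames(sds, paste0(num, "_sd")))))
  rownames(out) <- NULL
  out
}

#' Summarise every patient in a cohort
#'
#' Applies \code{\link{summarize_patient}} to each patient present in both
#' the annotation and edge tables.
#'
#' @param ann Annotation table (all patients).
#' @param edges Edge-observation table (all patients).
#' @return Data frame with one row per patient.
#' @export
summarize_cohort <- function(ann, edges) {
  pa <- unique(as.character(ann$patient_id))
  pe <- unique(as.character(edges$patient_id))
  orphans <- c(setdiff(pa, pe), setdiff(pe, pa))
  if (length(orphans))
    stop("consistency error: patient ids present in only one table: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  out <- lapply(pa, function(p)
    summarize_patient(ann[as.character(ann$patient_id) == p, , drop = FALSE],
                      edges[as.character(edges$patient_id) == p, , drop = FALSE]))
  do.call(rbind, out)
}
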