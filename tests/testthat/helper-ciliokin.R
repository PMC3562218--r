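# one-row annotation in micrometres / seconds
make_annotation <- function(p0 = c(0, 0), p1 = c(5, 0), p2 = c(3, 4),
                            ts = c(0, 0.05, 0.06, 0.12, 0.125),
                            observed = TRUE, patient = "p1", cilium = 1L) {
  data.frame(patient_id = patient, cilium_id = cilium,
             x0 = p0[1], y0 = p0[2], x1 = p1[1], y1 = p1[2],
             x2 = p2[1], y2 = p2[2],
             t1 = ts[1], t2 = ts[2], t3 = ts[3], t4 = ts[4], t5 = ts[5],
             cycle_observed = observed, stringsAsFactors = FALSE)
}

# edge table with the given numbers of 1 / 0.5 / 0 beating scores
make_edges <- function(n1 = 20, nh = 0, n0 = 0, patient = "p1",
                       labels = "normal", dyskinesia = 0) {
  n <- n1 + nh + n0
  data.frame(patient_id = rep(patient, n), area_id = seq_len(n),
             beating_score = rep(c(1, 0.5, 0), c(n1, nh, n0)),
             pattern_label = rep_len(labels, n),
             dyskinesia_score = rep_len(dyskinesia, n),
             stringsAsFactors = FALSE)
}

# brute-force AUC oracle: P(pos beats neg) with ties counted half,
# in the stated orientation
auc_pairwise <- function(pos, neg, orientation = "lower") {
  if (orientation == "lower")
    mean(outer(pos, neg, "<") + 0.5 * outer(pos, neg, "=="))
  else
    mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}
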