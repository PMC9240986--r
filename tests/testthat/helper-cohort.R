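# Builders for tiny hand-specified cohorts, and the brute-force
# concordance oracle the c statistic is checked against.

record_defaults <- list(
  patient_id = "P1", age = 40L, sex = "male",
  arrival = "2021-07-01T10:00:00", pregnant = FALSE,
  alert = TRUE, attentive = TRUE, calm = TRUE, coherent = TRUE,
  months_backwards_pass = TRUE, gait = "stable_independent",
  spo2 = 97, resp_rate = 16, presentations = "non_urgent",
  admitted = FALSE, died_within_24h = FALSE, died_in_hospital = FALSE,
  day_of_death = NA_integer_)

# One patient row; unspecified fields take healthy defaults.
make_record <- function(...) {
  args <- list(...)
  rec <- record_defaults
  rec[names(args)] <- args
  as.data.frame(rec, stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  rows <- lapply(list(...), function(args) do.call(make_record, args))
  out <- do.call(rbind, rows)
  out$patient_id <- sprintf("P%d", seq_len(nrow(out)))
  out
}

# All-pairs concordance count: positives beating negatives, ties half.
brute_auc <- function(scores, outcomes) {
  pos <- scores[as.logical(outcomes)]
  neg <- scores[!as.logical(outcomes)]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}
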