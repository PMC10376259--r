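# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays within a desk-scale budget.

small_au_config <- function(seed = 1L, ...) {
  defaults <- list(n_subjects_per_class = 4L,
                   sessions_per_subject_range = c(1L, 2L),
                   frames_per_session = 512L,
                   seed = seed)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# deterministic toy sequences: two constant, linearly separable classes
toy_separable_sequences <- function(n_per_class = 5L, frames = 6L) {
  x <- c(lapply(seq_len(n_per_class),
                function(i) matrix(rep(c(1, 0), each = frames), frames, 2L)),
         lapply(seq_len(n_per_class),
                function(i) matrix(rep(c(0, 1), each = frames), frames, 2L)))
  list(x = x, y = rep(c("healthy", "dementia"), each = n_per_class))
}

# brute-force two-pass mean/variance, the clip-feature oracle
twopass_clip_oracle <- function(clip, ids, sample_var = FALSE) {
  m <- vapply(ids, function(id) sum(clip[, id]) / nrow(clip), numeric(1L))
  v <- vapply(ids, function(id) {
    d <- clip[, id] - m[[id]]
    sum(d^2) / (nrow(clip) - if (sample_var) 1L else 0L)
  }, numeric(1L))
  stats::setNames(c(m, v), c(paste0("m_", ids), paste0("v_", ids)))
}

# dense-grid brute force over voting thresholds, the sweep oracle
grid_sweep_oracle <- function(fractions, labels, grid = seq(0, 1, by = 0.01)) {
  stats <- t(vapply(grid, function(t) {
    dec <- ifelse(fractions > t, "dementia", "healthy")
    tp <- sum(dec == "dementia" & labels == "dementia")
    fp <- sum(dec == "dementia" & labels == "healthy")
    fn <- sum(dec == "healthy" & labels == "dementia")
    tn <- sum(dec == "healthy" & labels == "healthy")
    c(accuracy = (tp + tn) / length(labels),
      fpr = fp / (fp + tn), fnr = fn / (tp + fn))
  }, numeric(3L)))
  list(max_accuracy = max(stats[, "accuracy"]),
       min_eer_gap = min(abs(stats[, "fpr"] - stats[, "fnr"])))
}

derive_seed_for_test <- function(seed, ...) facescreen:::derive_seed(seed, ...)

# per-subject vote fractions for a synthetic prediction pattern
fraction_frame <- function(fractions, labels) {
  data.frame(fraction = fractions, label = labels, stringsAsFactors = FALSE)
}
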