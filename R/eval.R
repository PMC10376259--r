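feature_columns <- function(tab) {
  grep("^(m|v)_", names(tab), value = TRUE)
}

#' Leave-one-subject-out clip predictions
#'
#' One fold per subject: all of that subject's clips are held out, an
#' RBF-SVM is trained on the remaining subjects' clips, and the held-out
#' clips are predicted. Features are standardized with the training fold's
#' mean and standard deviation only, so no information from the held-out
#' subject reaches the model. Returns per-clip predictions plus each
#' subject's dementia-vote fraction p = (#clips predicted dementia)/(#clips).
#'
#' @param tab a clip-feature table (\code{\link{cohort_feature_table}}):
#'   columns \code{subject_id}, \code{label}, and \code{m_*}/\code{v_*}
#'   features.
#' @param C,gamma,tol SVM hyperparameters (see \code{\link{svm_rbf_train}}).
#' @return a \code{clip_prediction_set}: list with \code{clips} (data.table
#'   of per-clip predictions) and \code{subjects} (data.table with
#'   \code{subject_id}, \code{label}, \code{n_clips}, \code{fraction}).
#' @export
loso_clip_predictions <- function(tab, C = 1, gamma = "scale", tol = 1e-3) {
  tab <- data.table::as.data.table(tab)
  fcols <- feature_columns(tab)
  if (!length(fcols)) stop_fs("no m_*/v_* feature columns in the table")
  subj_lab <- unique(tab[, c("subject_id", "label")])
  if (anyDuplicated(subj_lab$subject_id))
    stop_fs("a subject_id carries two labels")
  counts <- table(subj_lab$label)
  if (length(counts) < 2L || any(counts < 2L))
    stop_fs("need >= 2 subjects per class for LOSO")
  X <- as.matrix(tab[, fcols, with = FALSE])
  pred <- character(nrow(tab))
  # fold order is by subject id, but each fold is independent of the others,
  # so permuting subjects cannot change any subject's predictions
  for (sid in sort(unique(tab$subject_id))) {
    hold <- tab$subject_id == sid
    ytr <- tab$label[!hold]
    if (length(unique(ytr)) < 2L)
      stop_fs("training fold for subject ", sid, " lacks a class")
    mu <- colMeans(X[!hold, , drop = FALSE])
    sdv <- apply(X[!hold, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    scale_rows <- function(M) sweep(sweep(M, 2L, mu, `-`), 2L, sdv, `/`)
    fit <- svm_rbf_train(scale_rows(X[!hold, , drop = FALSE]), ytr,
                         C = C, gamma = gamma, tol = tol)
    pred[hold] <- predict(fit, scale_rows(X[hold, , drop = FALSE]))
  }
  clips <- data.table::data.table(
    subject_id = tab$subject_id, session_id = tab$session_id,
    clip_index = tab$clip_index, label = tab$label, predicted = pred)
  subjects <- clips[, list(label = label[1L], n_clips = .N,
                           fraction = mean(predicted == "dementia")),
                    by = "subject_id"]
  data.table::setorder(subjects, subject_id)
  structure(list(clips = clips, subjects = subjects),
            class = "clip_prediction_set")
}

#' Subject decision by threshold voting
#'
#' A subject is declared dementia when the fraction of their clips predicted
#' as dementia strictly exceeds the threshold \code{t}; \code{t = 0.5}
#' recovers majority voting. With \code{polarity = "healthy"} the rule is
#' applied to the healthy fraction instead (subject healthy iff
#' \code{1 - p > t}), matching the alternative statement of the rule.
#' Note the strict inequality: at \code{t = 1} even \code{p = 1} votes
#' healthy under the dementia polarity.
#'
#' @param fraction dementia-vote fraction(s) p in [0, 1].
#' @param threshold t in [0, 1].
#' @param polarity \code{"dementia"} (default) or \code{"healthy"}.
#' @return character label(s).
#' @export
vote <- function(fraction, threshold, polarity = c("dementia", "healthy")) {
  polarity <- match.arg(polarity)
  if (any(fraction < 0 | fraction > 1) || threshold < 0 || threshold > 1)
    stop_fs("fractions and threshold must lie in [0, 1]")
  if (polarity == "dementia")
    ifelse(fraction > threshold, "dementia", "healthy")
  else
    ifelse(1 - fraction > threshold, "healthy", "dementia")
}

#' Sweep the voting threshold: max-accuracy and EER operating points
#'
#' Evaluates subject decisions over candidate thresholds (the sorted unique
#' vote fractions together with 0, 1 and the midpoints between consecutive
#' values — every achievable decision pattern is realized by one of these).
#' Reports per-threshold accuracy, recall, precision, FPR and FNR; the
#' max-accuracy entry (ties broken toward the smallest threshold); and the
#' equal-error-rate entry, the threshold minimizing |FPR - FNR| (exact
#' equality is generally unattainable with finitely many subjects). The
#' reported EER accuracy is the mean of the two class-wise accuracies at
#' that threshold, i.e. balanced accuracy, which is insensitive to class
#' imbalance.
#'
#' @param prediction_set a \code{\link{loso_clip_predictions}} result, or a
#'   data.frame with columns \code{fraction} and \code{label}.
#' @param polarity voting polarity, see \code{\link{vote}}.
#' @return a \code{threshold_sweep} object: \code{table} (per-threshold
#'   metrics), \code{best} (max-accuracy row), \code{eer} (EER row plus
#'   \code{eer_accuracy}).
#' @export
threshold_sweep <- function(prediction_set, polarity = "dementia") {
  subj <- if (inherits(prediction_set, "clip_prediction_set"))
    prediction_set$subjects else as.data.frame(prediction_set)
  if (!all(c("fraction", "label") %in% names(subj)))
    stop_fs("need per-subject columns `fraction` and `label`")
  if (length(unique(subj$label)) < 2L)
    stop_fs("threshold sweep needs both classes among subjects")
  fr <- subj$fraction
  u <- sort(unique(c(0, fr, 1)))
  cand <- sort(unique(c(u, (head(u, -1L) + tail(u, -1L)) / 2)))
  n_pos <- sum(subj$label == "dementia")
  n_neg <- sum(subj$label == "healthy")
  rows <- lapply(cand, function(t) {
    dec <- vote(fr, t, polarity)
    tp <- sum(dec == "dementia" & subj$label == "dementia")
    fp <- sum(dec == "dementia" & subj$label == "healthy")
    fn <- n_pos - tp
    tn <- n_neg - fp
    data.frame(threshold = t,
               accuracy = (tp + tn) / (n_pos + n_neg),
               recall = tp / n_pos,
               precision = if (tp + fp > 0) tp / (tp + fp) else 0,
               fpr = fp / n_neg, fnr = fn / n_pos)
  })
  tabres <- do.call(rbind, rows)
  best <- tabres[which.max(tabres$accuracy), ]       # ties -> smallest t
  eer_idx <- which.min(abs(tabres$fpr - tabres$fnr)) # ties -> smallest t
  eer <- tabres[eer_idx, ]
  eer$eer_accuracy <- ((1 - eer$fpr) + (1 - eer$fnr)) / 2
  structure(list(table = tabres, best = best, eer = eer,
                 polarity = polarity),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("threshold sweep over %d candidates (%s polarity)\n",
              nrow(x$table), x$polarity))
  cat(sprintf("max accuracy %.3f at t = %.3f (recall %.3f, precision %.3f)\n",
              x$best$accuracy, x$best$threshold, x$best$recall, x$best$precision))
  cat(sprintf("EER point t = %.3f: |FPR-FNR| = %.3f, EER accuracy %.3f\n",
              x$eer$threshold, abs(x$eer$fpr - x$eer$fnr), x$eer$eer_accuracy))
  invisible(x)
}

#' Subject-level classification metrics
#'
#' Standard confusion-matrix metrics with dementia as the positive class.
#' Precision of a predictor that never predicts dementia is reported as 0
#' with a warning. The EER accuracy is not recomputable from decisions at a
#' single threshold, so it is carried in from the sweep.
#'
#' @param decisions predicted subject labels.
#' @param labels true subject labels.
#' @param eer_accuracy optional EER accuracy from
#'   \code{\link{threshold_sweep}}.
#' @return a \code{metrics_report}: accuracy, recall, precision, f1,
#'   eer_accuracy.
#' @export
compute_metrics <- function(decisions, labels, eer_accuracy = NA_real_) {
  if (!length(decisions) || length(decisions) != length(labels))
    stop_fs("decisions and labels must be nonempty and aligned")
  tp <- sum(decisions == "dementia" & labels == "dementia")
  fp <- sum(decisions == "dementia" & labels == "healthy")
  fn <- sum(decisions == "healthy" & labels == "dementia")
  tn <- sum(decisions == "healthy" & labels == "healthy")
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("no dementia predictions: precision undefined, reporting 0",
            call. = FALSE)
    0
  }
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(accuracy = (tp + tn) / length(labels),
                 recall = recall, precision = precision, f1 = f1,
                 eer_accuracy = eer_accuracy),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f | recall %.3f | precision %.3f | F1 %.3f | EER accuracy %s\n",
              x$accuracy, x$recall, x$precision, x$f1,
              ifelse(is.na(x$eer_accuracy), "NA",
                     sprintf("%.3f", x$eer_accuracy))))
  invisible(x)
}

#' End-to-end AU-branch evaluation
#'
#' Convenience composition: clip-feature table -> LOSO clip predictions ->
#' threshold sweep -> metrics at the max-accuracy threshold. This mirrors
#' the published protocol, where the voting threshold is optimized on the
#' test predictions themselves; \code{nested = TRUE} instead selects each
#' subject's threshold on the remaining subjects' vote fractions (a
#' leakage-free variant) and reports metrics from those decisions.
#'
#' @param tab clip-feature table.
#' @param C,gamma SVM hyperparameters.
#' @param polarity voting polarity.
#' @param nested use nested threshold selection instead of sweep-on-test.
#' @return list with \code{predictions}, \code{sweep} (NULL when nested),
#'   \code{metrics}.
#' @export
evaluate_au_branch <- function(tab, C = 1, gamma = "scale",
                               polarity = "dementia", nested = FALSE) {
  preds <- loso_clip_predictions(tab, C = C, gamma = gamma)
  subj <- preds$subjects
  if (!nested) {
    sw <- threshold_sweep(preds, polarity)
    dec <- vote(subj$fraction, sw$best$threshold, polarity)
    metrics <- compute_metrics(dec, subj$label,
                               eer_accuracy = sw$eer$eer_accuracy)
    list(predictions = preds, sweep = sw, metrics = metrics)
  } else {
    dec <- vapply(seq_len(nrow(subj)), function(i) {
      inner <- threshold_sweep(subj[-i, ], polarity)
      vote(subj$fraction[i], inner$best$threshold, polarity)
    }, character(1L))
    metrics <- compute_metrics(dec, subj$label)
    list(predictions = preds, sweep = NULL, metrics = metrics)
  }
}
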