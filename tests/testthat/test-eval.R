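# perfectly separable by construction: the two classes' clip features sit in
# tight clusters 6 sd-units apart on every coordinate
separable_clip_table <- function(seed = 1L, n_per_class = 4L, clips = 4L) {
  set.seed(seed)
  rows <- list()
  for (lab in c("healthy", "dementia")) {
    mu <- if (lab == "dementia") 3 else 0
    for (i in seq_len(n_per_class)) {
      sid <- sprintf("%s%02d", toupper(substr(lab, 1L, 1L)), i)
      for (k in seq_len(clips)) {
        feat <- stats::setNames(as.list(rnorm(6L, mean = mu, sd = 0.1)),
                                c(paste0("m_AU0", 1:3), paste0("v_AU0", 1:3)))
        rows[[length(rows) + 1L]] <- c(
          list(subject_id = sid, session_id = paste0(sid, "_s01"),
               clip_index = k, label = lab), feat)
      }
    }
  }
  data.table::rbindlist(rows)
}

test_that("LOSO predicts separable clips perfectly with clean hygiene", {
  tab <- separable_clip_table()
  preds <- loso_clip_predictions(tab)
  expect_identical(preds$clips$predicted, preds$clips$label)
  # vote fractions are 0 or 1 in the separable case
  expect_true(all(preds$subjects$fraction %in% c(0, 1)))
  # fold order is irrelevant: permuting rows leaves per-subject results alone
  set.seed(2)
  perm <- tab[sample(nrow(tab)), ]
  preds2 <- loso_clip_predictions(perm)
  expect_identical(preds$subjects, preds2$subjects)
})

test_that("LOSO rejects degenerate cohorts", {
  tab <- separable_clip_table()
  # one subject with a unique label -> that fold's training set lacks a class
  solo <- tab[tab$subject_id %in% c(unique(tab$subject_id[tab$label == "healthy"])[1L],
                                    unique(tab$subject_id[tab$label == "dementia"])), ]
  expect_error(loso_clip_predictions(solo), "2 subjects")
  two_labels <- data.table::copy(tab)
  two_labels$label[1L] <- "dementia"
  expect_error(loso_clip_predictions(two_labels), "two labels")
})

test_that("vote applies a strict threshold with both polarities", {
  expect_identical(vote(0.3, 0.25), "dementia")   # worked example: 25% rule
  expect_identical(vote(0.5, 0.5), "healthy")     # strict inequality tie-break
  expect_identical(vote(1.0, 1.0), "healthy")     # documented boundary edge
  expect_identical(vote(0.0, 0.0), "healthy")
  expect_identical(vote(0.1, 0.0), "dementia")
  # healthy polarity: subject healthy iff healthy fraction exceeds t
  expect_identical(vote(0.3, 0.5, polarity = "healthy"), "healthy")
  expect_identical(vote(0.9, 0.5, polarity = "healthy"), "dementia")
  expect_error(vote(1.2, 0.5), "\\[0, 1\\]")
})

test_that("threshold sweep finds the separated and degenerate optima", {
  sw <- threshold_sweep(fraction_frame(c(0.0, 0.1, 0.8, 0.9),
                                       c("healthy", "healthy", "dementia", "dementia")))
  expect_equal(sw$best$accuracy, 1)
  expect_equal(sw$eer$eer_accuracy, 1)
  # identical fractions: best accuracy equals majority-class prevalence
  sw2 <- threshold_sweep(fraction_frame(rep(0.4, 5L),
                                        c("healthy", "healthy", "healthy",
                                          "dementia", "dementia")))
  expect_equal(sw2$best$accuracy, 3 / 5)
  expect_error(threshold_sweep(fraction_frame(0.5, "dementia")), "both classes")
})

test_that("threshold sweep agrees with dense-grid brute force", {
  set.seed(17)
  for (rep_ in 1:5) {
    fr <- round(runif(10L), 2L)   # fractions on the grid so the oracle is exact
    labels <- sample(rep(c("healthy", "dementia"), 5L))
    sw <- threshold_sweep(fraction_frame(fr, labels))
    oracle <- grid_sweep_oracle(fr, labels)
    expect_equal(sw$best$accuracy, oracle$max_accuracy)
    expect_equal(abs(sw$eer$fpr - sw$eer$fnr), oracle$min_eer_gap)
  }
})

test_that("recall is nonincreasing and specificity nondecreasing in t", {
  set.seed(23)
  fr <- runif(14L)
  labels <- sample(rep(c("healthy", "dementia"), 7L))
  sw <- threshold_sweep(fraction_frame(fr, labels))
  expect_true(all(diff(sw$table$recall) <= 1e-12))
  expect_true(all(diff(1 - sw$table$fpr) >= -1e-12))
})

test_that("compute_metrics implements the confusion-matrix definitions", {
  # perfect prediction
  m <- compute_metrics(c("dementia", "healthy"), c("dementia", "healthy"),
                       eer_accuracy = 1)
  expect_equal(unlist(m[c("accuracy", "recall", "precision", "f1")]),
               c(accuracy = 1, recall = 1, precision = 1, f1 = 1))
  # TP=5 FN=5 TN=9 FP=1 over 20 subjects
  labels <- c(rep("dementia", 10L), rep("healthy", 10L))
  decisions <- c(rep("dementia", 5L), rep("healthy", 5L),
                 rep("healthy", 9L), "dementia")
  m2 <- compute_metrics(decisions, labels)
  expect_equal(m2$recall, 0.5)
  expect_equal(m2$precision, 5 / 6)
  expect_equal(m2$accuracy, 0.7)
  expect_equal(m2$f1, 2 * (5 / 6) * 0.5 / (5 / 6 + 0.5))
  # degenerate predictor: no dementia calls
  expect_warning(m3 <- compute_metrics(rep("healthy", 4L),
                                       c("dementia", "dementia", "healthy", "healthy")),
                 "precision")
  expect_equal(m3$precision, 0)
  expect_equal(m3$recall, 0)
  expect_equal(m3$f1, 0)
  expect_error(compute_metrics(character(0L), character(0L)), "nonempty")
})

test_that("evaluate_au_branch reports sweep-on-test and nested variants", {
  tab <- separable_clip_table()
  res <- evaluate_au_branch(tab)
  expect_equal(res$metrics$accuracy, 1)
  expect_equal(res$metrics$eer_accuracy, 1)
  nested <- evaluate_au_branch(tab, nested = TRUE)
  expect_null(nested$sweep)
  expect_equal(nested$metrics$accuracy, 1)   # separable: nested also perfect
})
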