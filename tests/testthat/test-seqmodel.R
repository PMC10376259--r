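test_that("parameter count matches the closed form and tensor enumeration", {
  # published mesh-branch architecture: 16 inputs, hidden 32, 2 classes
  expect_identical(count_parameters(seq_model_config(16L)), 6466L)
  # smallest config by hand: 4*1*2 + 8 + 2 = 18
  expect_identical(
    count_parameters(seq_model_config(1L, hidden_dim = 1L, n_classes = 2L)),
    4L * 1L * 2L + 8L + 2L * 1L + 2L)
  # tensor-enumeration oracle on assorted configs
  for (dims in list(c(3L, 5L, 2L), c(16L, 32L, 2L), c(7L, 4L, 3L))) {
    cfg <- seq_model_config(dims[1L], hidden_dim = dims[2L], n_classes = dims[3L])
    params <- facescreen:::lstm_init(dims[1L], dims[2L], dims[3L])
    expect_identical(count_parameters(cfg),
                     as.integer(sum(vapply(params, length, integer(1L)))))
  }
  # consistency with the ~22.5M appearance-branch figure at hidden 1024
  big <- seq_model_config(4464L, hidden_dim = 1024L)
  expect_equal(count_parameters(big) / 1e6, 22.5, tolerance = 0.01)
})

test_that("analytic BPTT gradients match finite differences", {
  set.seed(31)
  d <- 3L; h <- 4L; cl <- 2L; B <- 2L; T_ <- 3L
  params <- facescreen:::lstm_init(d, h, cl)
  x <- array(rnorm(B * T_ * d), dim = c(B, T_, d))
  y <- c(1L, 2L)
  fwd <- facescreen:::lstm_forward(params, x, keep = TRUE)
  bwd <- facescreen:::lstm_backward(params, x, y, fwd)
  loss_at <- function(p) {
    f <- facescreen:::lstm_forward(p, x)
    P <- facescreen:::softmax_rows(f$logits)
    -mean(log(P[cbind(seq_len(B), y)]))
  }
  eps <- 1e-6
  for (nm in names(params)) {
    idx <- seq_len(min(6L, length(params[[nm]])))   # spot-check entries
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(bwd$grads[[nm]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("training separates a toy pair and is reproducible", {
  toy <- toy_separable_sequences()
  cfg <- seq_model_config(2L, epochs = 60L, seed = 1L)
  m <- train_sequence_classifier(toy$x, toy$y, cfg)
  # loss decreases monotonically over the first 10 epochs
  expect_true(all(diff(m$loss_log[1:10]) < 0))
  pred <- predict_subjectwise(m, toy$x)
  expect_equal(mean(pred$label == toy$y), 1)
  # score pairs normalize
  expect_equal(pred$score_healthy + pred$score_dementia, rep(1, length(toy$y)),
               tolerance = 1e-6)
  # identical inputs give identical scores
  expect_identical(pred$score_dementia[1L], pred$score_dementia[2L])
  # determinism given the seed
  m2 <- train_sequence_classifier(toy$x, toy$y, cfg)
  expect_identical(m$params, m2$params)
  # guards
  expect_error(train_sequence_classifier(toy$x, toy$y,
                                         seq_model_config(5L, epochs = 1L)),
               "width")
  expect_error(train_sequence_classifier(list(), character(0L), cfg), "empty")
  expect_error(predict_subjectwise(m, list(matrix(0, 4L, 3L))), "width")
})

test_that("reversed frame order is accepted and may change scores", {
  set.seed(8)
  x <- list(matrix(rnorm(40L), 20L, 2L))
  m <- train_sequence_classifier(toy_separable_sequences()$x,
                                 toy_separable_sequences()$y,
                                 seq_model_config(2L, epochs = 5L, seed = 2L))
  fwd <- predict_subjectwise(m, x)
  rev_ <- predict_subjectwise(m, list(x[[1L]][20:1, ]))
  expect_identical(nrow(fwd), 1L)
  expect_identical(nrow(rev_), 1L)   # order sensitivity permitted, not asserted
})

test_that("subject-disjoint splits are leak-free, balanced and seeded", {
  co <- generate_cohort(cohort_config(n_subjects_per_class = 10L,
                                      sessions_per_subject_range = c(1L, 3L),
                                      frames_per_session = 2L, seed = 5L))
  sp <- subject_disjoint_split(co, 0.3, seed = 9L)
  subj <- facescreen:::session_subjects(co)
  expect_length(intersect(subj[sp$train], subj[sp$test]), 0L)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(co$sessions))
  # 10+10 at 0.3 -> 3 test subjects per class
  test_labels <- co$subjects$label[match(sp$test_subjects, co$subjects$subject_id)]
  expect_identical(as.vector(table(test_labels)), c(3L, 3L))
  expect_identical(subject_disjoint_split(co, 0.3, seed = 9L)$test_subjects,
                   sp$test_subjects)
  expect_false(identical(subject_disjoint_split(co, 0.3, seed = 10L)$test_subjects,
                         sp$test_subjects))
  # impossible balance rejected
  tiny <- generate_cohort(cohort_config(n_subjects_per_class = 1L,
                                        frames_per_session = 2L,
                                        sessions_per_subject_range = c(1L, 1L)))
  expect_error(subject_disjoint_split(tiny, 0.5), "2 subjects")
})

test_that("frame_count_ablation truncates, matches full-length training, guards", {
  toy <- toy_separable_sequences(n_per_class = 6L, frames = 8L)
  subjects <- sprintf("S%02d", seq_along(toy$y))
  cfg <- seq_model_config(2L, epochs = 30L, seed = 3L)
  ab <- frame_count_ablation(toy$x, toy$y, subjects, c(1L, 8L), cfg,
                             test_fraction = 0.3, split_seed = 4L)
  expect_identical(ab$frames, c(1L, 8L))
  # n = full length reproduces direct training on the same split
  fake <- list(subjects = unique(data.frame(subject_id = subjects, label = toy$y)),
               sessions = lapply(subjects, function(s) list(subject_id = s)))
  class(fake) <- "cohort"
  sp <- subject_disjoint_split(fake, 0.3, seed = 4L)
  m <- train_sequence_classifier(toy$x[sp$train], toy$y[sp$train], cfg)
  acc <- mean(predict_subjectwise(m, toy$x[sp$test])$label == toy$y[sp$test])
  expect_identical(ab$accuracy[2L], acc)
  expect_error(frame_count_ablation(toy$x, toy$y, subjects, 9L, cfg), "exceeds")
})

test_that("label-shuffled training gives chance-level accuracy", {
  # no-signal calibration at unit-test scale: appearance streams with no
  # class effect, single frame; accuracy concentrates near 0.5 on a
  # balanced test set
  cfg <- cohort_config(n_subjects_per_class = 20L,
                       sessions_per_subject_range = c(1L, 3L),
                       frames_per_session = 2L, n_appearance_dims = 16L,
                       noise_sd = 0.5, streams = "appearance", seed = 13L)
  co <- generate_cohort(cfg)
  x <- lapply(co$sessions, `[[`, "appearance")
  y <- facescreen:::session_labels(co)
  subjects <- facescreen:::session_subjects(co)
  ab <- frame_count_ablation(x, y, subjects, 1L,
                             seq_model_config(16L, epochs = 40L, seed = 13L),
                             test_fraction = 0.4, split_seed = 13L)
  expect_gte(ab$accuracy, 0.4)
  expect_lte(ab$accuracy, 0.6)
})
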