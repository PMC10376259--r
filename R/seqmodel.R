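#' Configuration for the LSTM sequence classifier
#'
#' Defaults follow the published mesh-branch setup: hidden size 32, two
#' output classes, Adam with learning rate 0.001, cross-entropy loss. The
#' mesh branch feeds 16 PCA scores per frame (\code{input_dim = 16}); the
#' appearance branch feeds the raw 4464-dimensional descriptors. Published
#' epoch counts are 338 (full batch, mesh) and 110 (batch 64, appearance);
#' synthetic tests use far fewer.
#'
#' @param input_dim per-frame feature width.
#' @param hidden_dim LSTM hidden size (default 32).
#' @param n_classes number of output classes (default 2).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size \code{"full"} or a positive integer.
#' @param epochs training epochs.
#' @param seed integer seed controlling initialization and batch order.
#' @return a validated \code{seq_model_config}.
#' @export
seq_model_config <- function(input_dim, hidden_dim = 32L, n_classes = 2L,
                             learning_rate = 0.001, batch_size = "full",
                             epochs = 50L, seed = 1L) {
  cfg <- list(input_dim = check_count(input_dim, "input_dim"),
              hidden_dim = check_count(hidden_dim, "hidden_dim"),
              n_classes = check_count(n_classes, "n_classes", min = 2L),
              learning_rate = as.double(learning_rate),
              batch_size = batch_size,
              epochs = check_count(epochs, "epochs"),
              seed = check_count(seed, "seed", min = 0L))
  if (cfg$learning_rate <= 0) stop_fs("learning_rate must be > 0")
  if (!identical(batch_size, "full"))
    cfg$batch_size <- check_count(batch_size, "batch_size")
  structure(cfg, class = "seq_model_config")
}

#' Closed-form parameter count of the sequence classifier
#'
#' \code{4*h*(d + h) + 8*h + (h*c + c)} for input width \code{d}, hidden size
#' \code{h} and \code{c} classes: four gate stacks with input-to-hidden and
#' hidden-to-hidden weights plus two separate bias vectors, and a dense head
#' with bias. The mesh-branch default (d = 16, h = 32, c = 2) gives 6466.
#'
#' @param cfg a \code{\link{seq_model_config}}.
#' @return integer parameter count.
#' @export
count_parameters <- function(cfg) {
  d <- cfg$input_dim; h <- cfg$hidden_dim; c <- cfg$n_classes
  as.integer(4 * h * (d + h) + 8 * h + (h * c + c))
}

class_levels <- c("healthy", "dementia")

# Coerce a list of per-session T x d feature matrices (or a [B, T, d] array)
# into a [B, T, d] array, truncating unequal lengths to the batch minimum.
as_feature_array <- function(x, input_dim) {
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[3L] != input_dim)
      stop_fs(sprintf("feature width %d does not match input_dim %d",
                      dim(x)[3L], input_dim))
    return(x)
  }
  if (!is.list(x) || !length(x)) stop_fs("empty training set")
  widths <- vapply(x, ncol, integer(1L))
  if (any(widths != input_dim))
    stop_fs(sprintf("feature width %d does not match input_dim %d",
                    widths[widths != input_dim][1L], input_dim))
  T_ <- min(vapply(x, nrow, integer(1L)))
  arr <- array(NA_real_, dim = c(length(x), T_, input_dim))
  for (i in seq_along(x)) arr[i, , ] <- x[[i]][seq_len(T_), , drop = FALSE]
  arr
}

as_class_index <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (!all(y %in% class_levels))
    stop_fs("labels must be 'healthy' or 'dementia'")
  match(y, class_levels)
}

#' Train the LSTM sequence classifier
#'
#' Runs the recurrent network over each session's frame-feature sequence in
#' time order, feeds the final hidden state to a dense layer, and minimizes
#' cross-entropy with Adam. Training is deterministic given
#' \code{cfg$seed} on a fixed platform; the per-epoch mean training loss is
#' recorded in the returned model.
#'
#' @param x list of per-session frames x \code{input_dim} matrices, or a
#'   \code{[sessions, frames, input_dim]} array. Unequal sequence lengths are
#'   truncated to the batch minimum.
#' @param y session labels, \code{"healthy"} / \code{"dementia"}.
#' @param cfg a \code{\link{seq_model_config}}.
#' @param standardize standardize each input feature with the training set's
#'   per-feature mean and standard deviation (stored in the model and
#'   re-applied at prediction). Keeps optimization well-conditioned when
#'   feature scales are far from unit (e.g. PCA scores of normalized
#'   meshes); disable to feed raw features.
#' @return a \code{trained_seq_model}: parameters, config, input scaling and
#'   \code{loss_log} (per-epoch mean training loss).
#' @export
train_sequence_classifier <- function(x, y, cfg, standardize = TRUE) {
  if (!inherits(cfg, "seq_model_config")) stop_fs("`cfg` must be a seq_model_config")
  arr <- as_feature_array(x, cfg$input_dim)
  yi <- as_class_index(y)
  if (standardize) {
    flat <- matrix(arr, prod(dim(arr)[1:2]), dim(arr)[3L])
    center <- colMeans(flat)
    scl <- apply(flat, 2L, stats::sd)
    scl[scl == 0 | is.na(scl)] <- 1
  } else {
    center <- rep(0, cfg$input_dim)
    scl <- rep(1, cfg$input_dim)
  }
  for (j in seq_len(cfg$input_dim))
    arr[, , j] <- (arr[, , j] - center[j]) / scl[j]
  B <- dim(arr)[1L]
  if (length(yi) != B) stop_fs("length(y) must match the number of sessions")
  with_seed(cfg$seed, {
    params <- lstm_init(cfg$input_dim, cfg$hidden_dim, cfg$n_classes)
    opt <- adam_init(params)
    loss_log <- numeric(cfg$epochs)
    bs <- if (identical(cfg$batch_size, "full")) B else min(cfg$batch_size, B)
    for (ep in seq_len(cfg$epochs)) {
      ord <- if (bs < B) sample.int(B) else seq_len(B)
      losses <- c(); seen <- 0L
      for (start in seq(1L, B, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, B)]
        xb <- arr[idx, , , drop = FALSE]
        fwd <- lstm_forward(params, xb, keep = TRUE)
        bwd <- lstm_backward(params, xb, yi[idx], fwd)
        upd <- adam_step(params, bwd$grads, opt, cfg$learning_rate)
        params <- upd$params; opt <- upd$state
        losses <- c(losses, bwd$loss * length(idx)); seen <- seen + length(idx)
      }
      loss_log[ep] <- sum(losses) / seen
    }
    structure(list(params = params, config = cfg, loss_log = loss_log,
                   center = center, scale = scl),
              class = "trained_seq_model")
  })
}

#' Predict class scores per session
#'
#' Returns the softmax-normalized score pair (probability of belonging to
#' the healthy vs dementia class) and the argmax label for each session.
#'
#' @param model a \code{\link{train_sequence_classifier}} result.
#' @param x sessions as in \code{\link{train_sequence_classifier}}.
#' @return data.frame with columns \code{score_healthy}, \code{score_dementia},
#'   \code{label}.
#' @export
predict_subjectwise <- function(model, x) {
  if (!inherits(model, "trained_seq_model"))
    stop_fs("`model` must be a trained_seq_model")
  arr <- as_feature_array(x, model$config$input_dim)
  for (j in seq_len(model$config$input_dim))
    arr[, , j] <- (arr[, , j] - model$center[j]) / model$scale[j]
  fwd <- lstm_forward(model$params, arr, keep = FALSE)
  P <- softmax_rows(fwd$logits)
  data.frame(score_healthy = P[, 1L], score_dementia = P[, 2L],
             label = class_levels[max.col(P, ties.method = "first")],
             stringsAsFactors = FALSE)
}

#' Subject-disjoint, class-balanced train/test split
#'
#' Samples test subjects per class (counts differing by at most one across
#' classes) and places \emph{all} sessions of a test subject on the test
#' side, so no identity information leaks between sides.
#'
#' @param cohort a \code{\link{generate_cohort}} result.
#' @param test_fraction fraction of each class's subjects held out.
#' @param seed integer seed for the subject draw.
#' @return list with \code{train} and \code{test} integer session indices,
#'   plus \code{test_subjects}.
#' @export
subject_disjoint_split <- function(cohort, test_fraction = 0.3, seed = 1L) {
  subj <- cohort$subjects
  per_class <- split(subj$subject_id, subj$label)
  if (any(vapply(per_class, length, integer(1L)) < 2L))
    stop_fs("need >= 2 subjects per class for a subject-disjoint split")
  test_subjects <- with_seed(seed, {
    unlist(lapply(per_class, function(ids) {
      n_test <- max(1L, min(length(ids) - 1L, round(test_fraction * length(ids))))
      sample(ids, n_test)
    }), use.names = FALSE)
  })
  subjects <- session_subjects(cohort)
  test_idx <- which(subjects %in% test_subjects)
  list(train = setdiff(seq_along(cohort$sessions), test_idx),
       test = test_idx, test_subjects = sort(test_subjects))
}

#' Frame-count ablation for the sequence classifier
#'
#' For each requested frame count \code{n}, truncates every session's feature
#' sequence to its first \code{n} frames, trains the classifier on the
#' subject-disjoint training side, and reports test accuracy. With \code{n =
#' 1} the model degenerates to a feedforward classifier on single frames, so
#' the table shows how much the temporal context contributes (and, for
#' appearance features, how much a single frame alone can separate classes —
#' a bias warning sign).
#'
#' @param x per-session feature sequences (list of frames x d matrices).
#' @param y session labels.
#' @param subjects session subject ids (for the subject-disjoint split).
#' @param frame_counts integer vector of frame counts to test.
#' @param cfg a \code{\link{seq_model_config}}.
#' @param test_fraction,split_seed split parameters.
#' @return data.frame with columns \code{frames} and \code{accuracy}.
#' @export
frame_count_ablation <- function(x, y, subjects, frame_counts, cfg,
                                 test_fraction = 0.3, split_seed = 1L) {
  lens <- vapply(x, nrow, integer(1L))
  if (any(frame_counts > min(lens)))
    stop_fs(sprintf("frame count %d exceeds the shortest session (%d frames)",
                    max(frame_counts), min(lens)))
  # subject-disjoint split over the provided sessions
  uniq <- unique(data.frame(subject_id = subjects, label = y,
                            stringsAsFactors = FALSE))
  fake_cohort <- list(subjects = uniq,
                      sessions = lapply(subjects, function(s) list(subject_id = s)))
  class(fake_cohort) <- "cohort"
  sp <- subject_disjoint_split(fake_cohort, test_fraction, split_seed)
  out <- data.frame(frames = as.integer(frame_counts), accuracy = NA_real_)
  for (i in seq_along(frame_counts)) {
    n <- frame_counts[i]
    xt <- lapply(x, function(m) m[seq_len(n), , drop = FALSE])
    model <- train_sequence_classifier(xt[sp$train], y[sp$train], cfg)
    pred <- predict_subjectwise(model, xt[sp$test])
    out$accuracy[i] <- mean(pred$label == y[sp$test])
  }
  out
}
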