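#' Write an AU sequence as an extractor-style CSV
#'
#' One row per frame with columns \code{frame} (1-based index),
#' \code{timestamp} (seconds at the given frame rate), then one
#' \code{<AU>_r} intensity column per channel — the on-disk shape produced
#' by OpenFace-style extractors.
#'
#' @param seq numeric matrix, frames x channels, channel ids as column names.
#' @param path output path.
#' @param frame_rate frames per second for the timestamp column.
#' @return \code{path}, invisibly.
#' @export
write_au_csv <- function(seq, path, frame_rate = 30L) {
  if (!is.matrix(seq) || is.null(colnames(seq)))
    stop_fs("`seq` must be a matrix with AU ids as column names")
  dt <- data.table::data.table(frame = seq_len(nrow(seq)),
                               timestamp = (seq_len(nrow(seq)) - 1L) / frame_rate)
  # 17 significant digits: doubles survive the text round trip bit-exactly
  for (id in colnames(seq)) dt[[paste0(id, "_r")]] <- sprintf("%.17g", seq[, id])
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Read an extractor-style AU intensity CSV
#'
#' Maps intensity columns through \code{au_map} (channel id -> column name),
#' preserves frame order, ignores unrelated columns, and clips values to the
#' 0--5 intensity scale (with a warning giving the number of clipped cells).
#' Missing configured columns and non-numeric cells are rejected with the
#' offending column/row named.
#'
#' @param path CSV file with a header.
#' @param au_map named character vector mapping channel ids to column names;
#'   default the 17 standard ids mapped to \code{<id>_r}.
#' @return numeric matrix, frames x channels, channel ids as column names.
#' @export
read_au_csv <- function(path, au_map = NULL) {
  if (!file.exists(path)) stop_fs("file not found: ", path)
  if (is.null(au_map)) {
    ids <- openface_au_ids()
    au_map <- stats::setNames(paste0(ids, "_r"), ids)
  }
  dt <- data.table::fread(path, header = TRUE)
  missing <- setdiff(unname(au_map), names(dt))
  if (length(missing))
    stop_fs("missing AU columns: ", paste(missing, collapse = ", "))
  out <- matrix(NA_real_, nrow(dt), length(au_map),
                dimnames = list(NULL, names(au_map)))
  for (i in seq_along(au_map)) {
    col <- dt[[au_map[[i]]]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop_fs(sprintf("non-numeric value in column %s, row %d",
                      au_map[[i]], if (is.na(bad)) 1L else bad))
    }
    out[, i] <- as.double(col)
  }
  n_clip <- sum(out < 0 | out > 5)
  if (n_clip > 0) {
    warning(sprintf("%d AU values outside [0, 5] were clipped", n_clip),
            call. = FALSE)
    out[out < 0] <- 0
    out[out > 5] <- 5
  }
  out
}

#' Write a cohort to a directory layout
#'
#' Produces \code{metadata.csv} (subject_id, session_id, label, frames) and
#' one file per session and stream: AU sequences as extractor-style CSV
#' (\code{<session>_au.csv}), mesh sequences as wide CSV with
#' \code{x_<l>, y_<l>, z_<l>, v_<l>} columns, appearance sequences as plain
#' CSV. All files round-trip through \code{\link{read_cohort}}.
#'
#' @param cohort a \code{\link{generate_cohort}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- data.table::rbindlist(lapply(cohort$sessions, function(s)
    data.table::data.table(subject_id = s$subject_id, session_id = s$session_id,
                           label = s$label,
                           frames = nrow(s$au %||% s$appearance %||%
                                           matrix(nrow = dim(s$mesh)[1L], ncol = 0)))))
  data.table::fwrite(meta, file.path(dir, "metadata.csv"))
  for (s in cohort$sessions) {
    if (!is.null(s$au))
      write_au_csv(s$au, file.path(dir, paste0(s$session_id, "_au.csv")),
                   frame_rate = cohort$config$frame_rate)
    if (!is.null(s$mesh)) {
      L <- dim(s$mesh)[2L]
      flat <- matrix(aperm(s$mesh, c(1L, 3L, 2L)), nrow = dim(s$mesh)[1L])
      colnames(flat) <- as.vector(outer(c("x", "y", "z", "v"),
                                        seq_len(L), paste, sep = "_"))
      data.table::fwrite(data.table::as.data.table(flat),
                         file.path(dir, paste0(s$session_id, "_mesh.csv")))
    }
    if (!is.null(s$appearance)) {
      ap <- s$appearance
      colnames(ap) <- paste0("hog_", seq_len(ncol(ap)))
      data.table::fwrite(data.table::as.data.table(ap),
                         file.path(dir, paste0(s$session_id, "_appearance.csv")))
    }
  }
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort directory written by \code{\link{write_cohort}}
#'
#' @param dir cohort directory containing \code{metadata.csv}.
#' @return a \code{cohort} object (config not restored; sessions carry the
#'   streams found on disk).
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop_fs("no metadata.csv under ", dir)
  meta <- data.table::fread(meta_path, colClasses = list(
    character = c("subject_id", "session_id", "label")))
  sessions <- lapply(seq_len(nrow(meta)), function(i) {
    s <- list(subject_id = meta$subject_id[i], session_id = meta$session_id[i],
              label = meta$label[i])
    au_path <- file.path(dir, paste0(s$session_id, "_au.csv"))
    if (file.exists(au_path)) s$au <- read_au_csv(au_path)
    mesh_path <- file.path(dir, paste0(s$session_id, "_mesh.csv"))
    if (file.exists(mesh_path)) {
      flat <- as.matrix(data.table::fread(mesh_path))
      L <- ncol(flat) %/% 4L
      s$mesh <- aperm(array(flat, dim = c(nrow(flat), 4L, L)), c(1L, 3L, 2L))
      dimnames(s$mesh) <- list(NULL, NULL, c("x", "y", "z", "v"))
    }
    ap_path <- file.path(dir, paste0(s$session_id, "_appearance.csv"))
    if (file.exists(ap_path)) s$appearance <- as.matrix(data.table::fread(ap_path))
    class(s) <- "session"
    s
  })
  subjects <- meta[, list(label = label[1L], n_sessions = .N), by = "subject_id"]
  structure(list(sessions = sessions, subjects = subjects, config = NULL),
            class = "cohort")
}

run_config_fields <- list(
  cohort = c("n_subjects_per_class", "sessions_per_subject_range",
             "frames_per_session", "frame_rate", "n_landmarks", "n_au",
             "n_appearance_dims", "au_mean_shift", "au_var_scale",
             "mesh_motion_scale", "appearance_signal_dims",
             "appearance_signal_strength", "appearance_bias_strength",
             "noise_sd", "streams", "seed"),
  mesh = c("center_index", "pca_k"),
  seq = c("input_dim", "hidden_dim", "n_classes", "learning_rate",
          "batch_size", "epochs", "seed"),
  au = c("segment_len", "au_mode", "variance_estimator"),
  eval = c("C", "gamma", "polarity"),
  top = c("branches", "seed", "test_fraction"))

#' Build, read and write a run configuration
#'
#' A run configuration bundles the cohort, mesh, sequence-model, AU and
#' evaluation settings plus a single master seed into one JSON-serializable
#' object; unknown keys are rejected on read so typos fail loudly. All stage
#' seeds are derived from the master seed.
#'
#' @param branches which branches \code{\link{run_pipeline}} executes:
#'   subset of \code{c("au", "mesh")}.
#' @param cohort,mesh,seq,au,eval named lists overriding stage defaults.
#' @param seed master seed.
#' @param test_fraction subject fraction held out for the mesh branch.
#' @return a validated \code{run_config} list.
#' @export
run_config <- function(branches = "au", cohort = list(), mesh = list(),
                       seq = list(), au = list(), eval = list(), seed = 1L,
                       test_fraction = 0.3) {
  cfg <- list(
    branches = branches,
    seed = check_count(seed, "seed", min = 0L),
    test_fraction = test_fraction,
    cohort = utils::modifyList(list(seed = seed), cohort),
    mesh = utils::modifyList(list(center_index = 2L, pca_k = 16L), mesh),
    seq = utils::modifyList(list(hidden_dim = 32L, learning_rate = 0.001,
                                 batch_size = "full", epochs = 30L), seq),
    au = utils::modifyList(list(segment_len = 1024L, au_mode = "all17",
                                variance_estimator = "population"), au),
    eval = utils::modifyList(list(C = 1, gamma = "scale",
                                  polarity = "dementia"), eval))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  bad <- setdiff(cfg$branches, c("au", "mesh"))
  if (length(bad)) stop_fs("unknown branches: ", paste(bad, collapse = ", "))
  for (sec in c("cohort", "mesh", "seq", "au", "eval")) {
    unknown <- setdiff(names(cfg[[sec]]), run_config_fields[[sec]])
    if (length(unknown))
      stop_fs(sprintf("unknown keys in `%s` config: %s", sec,
                      paste(unknown, collapse = ", ")))
  }
  unknown <- setdiff(names(cfg),
                     c("branches", "seed", "test_fraction",
                       "cohort", "mesh", "seq", "au", "eval"))
  if (length(unknown))
    stop_fs("unknown top-level config keys: ", paste(unknown, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(cfg$cohort)) cfg$cohort <- as.list(cfg$cohort)
  validate_run_config(cfg)
}

log_msg <- function(stage, ...) {
  message(sprintf("[facescreen/%s] %s", stage, sprintf(...)))
}

#' Run an end-to-end pipeline from a configuration
#'
#' Generates the synthetic cohort, then executes the requested branches:
#' \itemize{
#'   \item \code{"au"}: clip featureization -> LOSO RBF-SVM -> threshold
#'     voting, writing the clip-feature table, per-subject fractions and a
#'     metric report;
#'   \item \code{"mesh"}: normalization -> PCA (fit on training frames only)
#'     -> LSTM on a subject-disjoint split, writing the PCA model and test
#'     accuracy.
#' }
#' All artifacts land under \code{out_dir}; \code{report.json} summarizes
#' the run and is byte-reproducible from the same config (a single
#' \code{generated_at} timestamp field aside).
#'
#' @param cfg a \code{\link{run_config}} (or path to one).
#' @param out_dir output directory.
#' @return the report, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "generate"
  report <- list(config = unclass(cfg), generated_at = format(Sys.time()))
  result <- tryCatch({
    streams <- c(if ("au" %in% cfg$branches) "au",
                 if ("mesh" %in% cfg$branches) "mesh")
    ccfg <- do.call(cohort_config,
                    utils::modifyList(cfg$cohort,
                                      list(streams = streams,
                                           seed = derive_seed(cfg$seed, 101L))))
    cohort <- generate_cohort(ccfg)
    log_msg(stage, "cohort: %d sessions, seed %d", length(cohort$sessions),
            ccfg$seed)
    if ("au" %in% cfg$branches) {
      stage <- "au"
      au_subset <- select_au_subset(cfg$au$au_mode,
                                    au_ids = openface_au_ids(ccfg$n_au))
      seg <- cfg$au$segment_len
      if (identical(seg, "all")) seg <- "all" else seg <- as.integer(seg)
      tab <- cohort_feature_table(cohort, seg, au_subset,
                                  variance = cfg$au$variance_estimator)
      write_feature_table(tab, file.path(out_dir, "au_clip_features.csv"))
      res <- evaluate_au_branch(tab, C = cfg$eval$C, gamma = cfg$eval$gamma,
                                polarity = cfg$eval$polarity)
      data.table::fwrite(res$predictions$subjects,
                         file.path(out_dir, "au_subject_fractions.csv"))
      report$au <- list(
        n_clips = nrow(tab),
        feature_width = length(feature_columns(tab)),
        best_threshold = res$sweep$best$threshold,
        max_accuracy = res$sweep$best$accuracy,
        metrics = unclass(res$metrics))
      log_msg(stage, "LOSO max accuracy %.3f, EER accuracy %.3f",
              res$sweep$best$accuracy, res$sweep$eer$eer_accuracy)
    }
    if ("mesh" %in% cfg$branches) {
      stage <- "mesh"
      sp <- subject_disjoint_split(cohort, cfg$test_fraction,
                                   seed = derive_seed(cfg$seed, 202L))
      feats <- lapply(cohort$sessions, function(s)
        normalize_sequence(s$mesh, cfg$mesh$center_index))
      pca <- fit_pca(do.call(rbind, feats[sp$train]), cfg$mesh$pca_k)
      write_pca_model(pca, file.path(out_dir, "pca_model.json"))
      red <- lapply(feats, function(f) transform_pca(pca, f))
      scfg <- do.call(seq_model_config,
                      utils::modifyList(cfg$seq,
                                        list(input_dim = cfg$mesh$pca_k,
                                             seed = derive_seed(cfg$seed, 303L))))
      labels <- session_labels(cohort)
      model <- train_sequence_classifier(red[sp$train], labels[sp$train], scfg)
      pred <- predict_subjectwise(model, red[sp$test])
      report$mesh <- list(
        pca_components = cfg$mesh$pca_k,
        cumulative_explained_variance =
          explained_variance_table(pca)$cumulative_explained_variance,
        n_parameters = count_parameters(scfg),
        test_accuracy = mean(pred$label == labels[sp$test]),
        final_training_loss = tail(model$loss_log, 1L))
      log_msg(stage, "test accuracy %.3f", report$mesh$test_accuracy)
    }
    report
  }, error = function(e) {
    report$incomplete <- TRUE
    report$failed_stage <- stage
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    stop_fs(sprintf("pipeline failed in stage '%s': %s", stage,
                    conditionMessage(e)))
  })
  jsonlite::write_json(result, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  log_msg("done", "report written to %s", file.path(out_dir, "report.json"))
  invisible(result)
}
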