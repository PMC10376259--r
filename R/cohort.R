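#' Configuration for the synthetic cohort generator
#'
#' Describes the statistical world the generator draws from. Defaults follow
#' the structure of clinical interview recordings: roughly 10-minute sessions
#' at 30 frames per second (18,000 frames), 478 face-mesh landmarks, 17
#' action-unit intensity channels on the 0--5 FACS scale, and 4464-dimensional
#' appearance (HOG-style) descriptors. Subjects contribute between
#' \code{sessions_per_subject_range[1]} and \code{sessions_per_subject_range[2]}
#' sessions, all sharing one binary label.
#'
#' The dementia class differs from the healthy baseline process by a per-AU
#' mean offset (\code{au_mean_shift}), a per-AU variance multiplier
#' (\code{au_var_scale}), a per-class mesh motion amplitude
#' (\code{mesh_motion_scale}), and optionally an appearance-space class signal
#' and/or a class-correlated constant "institutional bias" offset.
#'
#' @param n_subjects_per_class subjects per class (healthy / dementia).
#' @param sessions_per_subject_range integer \code{c(min, max)}; session counts
#'   are drawn uniformly from this range per subject.
#' @param frames_per_session frames per session (default 18000 = 10 min at
#'   30 FPS).
#' @param frame_rate frames per second (default 30).
#' @param n_landmarks mesh landmarks per frame (default 478).
#' @param n_au action-unit intensity channels (default 17).
#' @param n_appearance_dims appearance descriptor width (default 4464 =
#'   12 x 12 blocks x 31 orientation bins).
#' @param au_mean_shift numeric, length 1 or \code{n_au}: additive offset on
#'   the dementia class AU means (before clipping to [0, 5]).
#' @param au_var_scale numeric > 0, length 1 or \code{n_au}: multiplier on the
#'   dementia class AU variance.
#' @param mesh_motion_scale named numeric \code{c(healthy=, dementia=)}: mesh
#'   motion amplitude per class, in template coordinate units.
#' @param appearance_signal_dims leading appearance dimensions carrying the
#'   class signal.
#' @param appearance_signal_strength additive dementia-class offset on the
#'   signal dimensions (0 = no disease signal).
#' @param appearance_bias_strength additive dementia-class offset on all
#'   appearance dimensions, emulating environment-correlated (institutional)
#'   bias rather than disease signal (0 = unbiased).
#' @param noise_sd white-noise standard deviation added to every stream.
#' @param streams which feature streams \code{\link{generate_cohort}} fills:
#'   subset of \code{c("au", "mesh", "appearance")}. Default "au" only; mesh
#'   and appearance streams at paper-scale defaults are large, so request them
#'   explicitly (typically with reduced \code{frames_per_session}).
#' @param seed integer master seed; all per-subject/per-session substreams are
#'   derived from it.
#' @return a validated \code{cohort_config} object.
#' @export
cohort_config <- function(n_subjects_per_class = 10L,
                          sessions_per_subject_range = c(1L, 10L),
                          frames_per_session = 18000L,
                          frame_rate = 30L,
                          n_landmarks = 478L,
                          n_au = 17L,
                          n_appearance_dims = 4464L,
                          au_mean_shift = 0,
                          au_var_scale = 1,
                          mesh_motion_scale = c(healthy = 0.2, dementia = 0.2),
                          appearance_signal_dims = 8L,
                          appearance_signal_strength = 0,
                          appearance_bias_strength = 0,
                          noise_sd = 0.1,
                          streams = "au",
                          seed = 1L) {
  cfg <- list(
    n_subjects_per_class = check_count(n_subjects_per_class, "n_subjects_per_class"),
    sessions_per_subject_range = c(
      check_count(sessions_per_subject_range[1], "sessions_per_subject_range[min]"),
      check_count(sessions_per_subject_range[2], "sessions_per_subject_range[max]")),
    frames_per_session = check_count(frames_per_session, "frames_per_session"),
    frame_rate = check_count(frame_rate, "frame_rate"),
    n_landmarks = check_count(n_landmarks, "n_landmarks"),
    n_au = check_count(n_au, "n_au"),
    n_appearance_dims = check_count(n_appearance_dims, "n_appearance_dims"),
    au_mean_shift = rep_len(as.double(au_mean_shift), n_au),
    au_var_scale = rep_len(as.double(au_var_scale), n_au),
    mesh_motion_scale = mesh_motion_scale,
    appearance_signal_dims = check_count(appearance_signal_dims,
                                         "appearance_signal_dims", min = 0L),
    appearance_signal_strength = as.double(appearance_signal_strength),
    appearance_bias_strength = as.double(appearance_bias_strength),
    noise_sd = as.double(noise_sd),
    streams = streams,
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$sessions_per_subject_range[1] > cfg$sessions_per_subject_range[2])
    stop_fs("sessions_per_subject_range must satisfy min <= max")
  if (any(cfg$au_var_scale <= 0)) stop_fs("au_var_scale entries must be > 0")
  if (cfg$noise_sd < 0) stop_fs("noise_sd must be >= 0")
  if (is.null(names(cfg$mesh_motion_scale)))
    names(cfg$mesh_motion_scale) <- c("healthy", "dementia")
  if (!all(c("healthy", "dementia") %in% names(cfg$mesh_motion_scale)))
    stop_fs("mesh_motion_scale needs entries named 'healthy' and 'dementia'")
  if (any(cfg$mesh_motion_scale < 0)) stop_fs("mesh_motion_scale must be >= 0")
  bad <- setdiff(cfg$streams, c("au", "mesh", "appearance"))
  if (length(bad)) stop_fs("unknown streams: ", paste(bad, collapse = ", "))
  structure(cfg, class = "cohort_config")
}

# Healthy-baseline AU process parameters (fixed constants of the generator,
# documented in the methods vignette): channel means spread over the low end
# of the 0-5 FACS scale, common marginal sd, and strong frame-to-frame
# autocorrelation appropriate for 30 FPS muscle intensity.
au_baseline <- function(n_au) {
  list(mu = seq(0.8, 2.2, length.out = n_au), sd = 0.5, phi = 0.95)
}

# Stationary AR(1) draws: marginal sd `sd`, lag-1 correlation `phi`.
ar1_matrix <- function(n, k, sd, phi) {
  eps <- matrix(rnorm(n * k, sd = sd * sqrt(1 - phi^2)), n, k)
  x <- matrix(0, n, k)
  x[1L, ] <- rnorm(k, sd = sd)
  for (t in seq_len(n)[-1L]) x[t, ] <- phi * x[t - 1L, ] + eps[t, ]
  x
}

#' Generate one action-unit intensity sequence
#'
#' Draws a \code{frames_per_session x n_au} matrix of AU intensities clipped
#' to the 0--5 scale. The healthy baseline is a per-channel stationary AR(1)
#' signal plus white noise around fixed channel means; the dementia class
#' shifts each channel mean by \code{au_mean_shift} and multiplies the
#' stochastic part's variance by \code{au_var_scale} (shift and scale applied
#' before clipping, so realized moments deviate near the scale bounds).
#'
#' @param label \code{"healthy"} or \code{"dementia"}.
#' @param cfg a \code{\link{cohort_config}}.
#' @param seed integer seed for this sequence's substream.
#' @return numeric matrix, frames in rows, AU channels in columns (named with
#'   the OpenFace-style intensity channel ids).
#' @export
generate_au_sequence <- function(label, cfg, seed = cfg$seed) {
  check_label(label)
  base <- au_baseline(cfg$n_au)
  n <- cfg$frames_per_session
  with_seed(seed, {
    x <- ar1_matrix(n, cfg$n_au, base$sd, base$phi)
    if (cfg$noise_sd > 0)
      x <- x + matrix(rnorm(n * cfg$n_au, sd = cfg$noise_sd), n, cfg$n_au)
    mu <- base$mu
    if (label == "dementia") {
      x <- sweep(x, 2L, sqrt(cfg$au_var_scale), `*`)
      mu <- mu + cfg$au_mean_shift
    }
    x <- sweep(x, 2L, mu, `+`)
    x[x < 0] <- 0
    x[x > 5] <- 5
    colnames(x) <- openface_au_ids(cfg$n_au)
    x
  })
}

# Deterministic 478-point face template: Fibonacci lattice on an ellipsoid
# with face-like proportions (units are arbitrary "image" units).
mesh_template <- function(n_landmarks) {
  i <- seq_len(n_landmarks) - 0.5
  golden <- (1 + sqrt(5)) / 2
  theta <- acos(1 - 2 * i / n_landmarks)
  phi <- 2 * pi * i / golden
  cbind(x = 70 * sin(theta) * cos(phi),
        y = 90 * cos(theta),
        z = 60 * sin(theta) * sin(phi))
}

# Fixed per-landmark motion-mode directions: facial motion modes (jaw, brow,
# cheeks...) are shared anatomy, identical across subjects and sessions —
# only their phase and amplitude vary. Deterministic smooth fields over the
# template, so they are a constant of the generator like the template itself.
mesh_motion_modes <- function(n_landmarks, n_modes = 3L) {
  tpl <- mesh_template(n_landmarks) / 90
  modes <- vector("list", n_modes)
  for (m in seq_len(n_modes)) {
    dir <- cbind(sin(m * tpl[, 2] + m), cos(m * tpl[, 1] - m),
                 sin(m * (tpl[, 1] + tpl[, 3])))
    modes[[m]] <- dir / sqrt(rowSums(dir^2))
  }
  modes
}

#' Generate one face-mesh landmark sequence
#'
#' Frames are a fixed face template plus smooth sinusoidal motion along
#' three fixed anatomical mode fields shared by all subjects (frequencies
#' below 1.5 Hz, random phase per session, amplitude set by the class's
#' \code{mesh_motion_scale}) plus white noise, then subjected to a per-session
#' global translation and isotropic scale mimicking camera placement. The
#' motion substream is controlled by \code{seed}; the nuisance transform can
#' be supplied explicitly via \code{transform} (list with \code{translate},
#' length-3 numeric, and \code{scale}, positive scalar) so tests can vary the
#' camera while holding the face fixed.
#'
#' @inheritParams generate_au_sequence
#' @param transform \code{NULL} (draw from the seed's substream) or
#'   \code{list(translate =, scale =)}.
#' @return numeric array \code{[frames, n_landmarks, 4]} with coordinate slabs
#'   named \code{x, y, z, v}; visibility \code{v} is 1 everywhere.
#' @export
generate_mesh_sequence <- function(label, cfg, seed = cfg$seed,
                                   transform = NULL) {
  check_label(label)
  n <- cfg$frames_per_session
  L <- cfg$n_landmarks
  amp <- unname(cfg$mesh_motion_scale[[label]])
  tpl <- mesh_template(L)
  modes <- mesh_motion_modes(L)
  out <- with_seed(seed, {
    freqs <- c(0.3, 0.7, 1.3)                     # Hz, slow facial motion
    tt <- (seq_len(n) - 1L) / cfg$frame_rate
    frames <- array(rep(tpl, each = n), dim = c(n, L, 3L))
    for (m in seq_along(freqs)) {
      dir <- modes[[m]]
      phase <- runif(1L, 0, 2 * pi)
      wave <- amp * sin(2 * pi * freqs[m] * tt + phase) / length(freqs)
      for (a in 1:3)
        frames[, , a] <- frames[, , a] + outer(wave, dir[, a])
    }
    if (cfg$noise_sd > 0)
      frames <- frames + array(rnorm(n * L * 3L, sd = cfg$noise_sd),
                               dim = c(n, L, 3L))
    if (is.null(transform))
      transform <- list(translate = c(runif(2L, -200, 200), runif(1L, -50, 50)),
                        scale = runif(1L, 0.5, 2))
    for (a in 1:3)
      frames[, , a] <- frames[, , a] * transform$scale + transform$translate[a]
    frames
  })
  res <- array(1, dim = c(n, L, 4L), dimnames = list(NULL, NULL, c("x", "y", "z", "v")))
  res[, , 1:3] <- out
  res
}

#' Generate one appearance-descriptor sequence
#'
#' Emulates per-frame HOG-style descriptors: a fixed nonnegative base pattern
#' per dimension plus white noise, truncated at zero (gradient magnitudes are
#' nonnegative). The dementia class optionally receives (a) a persistent
#' offset \code{appearance_signal_strength} on the first
#' \code{appearance_signal_dims} dimensions — the stand-in for disease signal
#' — and/or (b) a constant offset \code{appearance_bias_strength} on every
#' dimension, the stand-in for environment-correlated institutional bias
#' (lighting/background differences between recording sites).
#'
#' @inheritParams generate_au_sequence
#' @return numeric matrix, frames x n_appearance_dims, all values >= 0.
#' @export
generate_appearance_sequence <- function(label, cfg, seed = cfg$seed) {
  check_label(label)
  n <- cfg$frames_per_session
  d <- cfg$n_appearance_dims
  base <- 0.3 + 0.2 * abs(sin(seq_len(d)))
  with_seed(seed, {
    x <- matrix(rnorm(n * d, sd = cfg$noise_sd), n, d)
    x <- sweep(x, 2L, base, `+`)
    if (label == "dementia") {
      ks <- min(cfg$appearance_signal_dims, d)
      if (ks > 0 && cfg$appearance_signal_strength != 0)
        x[, seq_len(ks)] <- x[, seq_len(ks)] + cfg$appearance_signal_strength
      if (cfg$appearance_bias_strength != 0)
        x <- x + cfg$appearance_bias_strength
    }
    x[x < 0] <- 0
    x
  })
}

#' Generate a full synthetic cohort
#'
#' Subjects are split evenly between the two classes; each subject draws a
#' session count uniformly from \code{sessions_per_subject_range}, and each
#' session draws the streams named in \code{cfg$streams}. All randomness is
#' derived from \code{cfg$seed} through per-subject/per-session substreams,
#' so the cohort is reproducible and earlier subjects' data do not change
#' when \code{n_subjects_per_class} grows.
#'
#' @param cfg a \code{\link{cohort_config}}.
#' @return a \code{cohort} object: list with \code{sessions} (list of
#'   \code{session} objects carrying \code{subject_id}, \code{session_id},
#'   \code{label} and the requested streams) and \code{subjects} (a
#'   \code{data.table} with one row per subject).
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) stop_fs("`cfg` must be a cohort_config")
  labels <- c("healthy", "dementia")
  sessions <- list()
  subj_rows <- list()
  for (ci in seq_along(labels)) {
    label <- labels[ci]
    for (si in seq_len(cfg$n_subjects_per_class)) {
      subject_id <- sprintf("%s%03d", toupper(substr(label, 1, 1)), si)
      n_sessions <- with_seed(
        derive_seed(cfg$seed, ci, si, 1L),
        sample(seq(cfg$sessions_per_subject_range[1],
                   cfg$sessions_per_subject_range[2]), 1L))
      subj_rows[[length(subj_rows) + 1L]] <-
        data.table::data.table(subject_id = subject_id, label = label,
                               n_sessions = n_sessions)
      for (vi in seq_len(n_sessions)) {
        sess <- list(subject_id = subject_id,
                     session_id = sprintf("%s_s%02d", subject_id, vi),
                     label = label)
        if ("au" %in% cfg$streams)
          sess$au <- generate_au_sequence(
            label, cfg, derive_seed(cfg$seed, ci, si, vi, 2L))
        if ("mesh" %in% cfg$streams)
          sess$mesh <- generate_mesh_sequence(
            label, cfg, derive_seed(cfg$seed, ci, si, vi, 3L))
        if ("appearance" %in% cfg$streams)
          sess$appearance <- generate_appearance_sequence(
            label, cfg, derive_seed(cfg$seed, ci, si, vi, 4L))
        class(sess) <- "session"
        sessions[[length(sessions) + 1L]] <- sess
      }
    }
  }
  structure(list(sessions = sessions,
                 subjects = data.table::rbindlist(subj_rows),
                 config = cfg),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects (%d healthy / %d dementia), %d sessions\n",
              nrow(x$subjects),
              sum(x$subjects$label == "healthy"),
              sum(x$subjects$label == "dementia"),
              length(x$sessions)))
  cat(sprintf("streams per session: %s; frames/session: %d\n",
              paste(x$config$streams, collapse = ", "),
              x$config$frames_per_session))
  invisible(x)
}

# Accessors used throughout the evaluation code.
session_labels <- function(cohort) {
  vapply(cohort$sessions, `[[`, character(1L), "label")
}
session_subjects <- function(cohort) {
  vapply(cohort$sessions, `[[`, character(1L), "subject_id")
}
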