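#' Standard action-unit intensity channel identifiers
#'
#' The 17 AU intensity channels emitted by the OpenFace-style extractor, in
#' their conventional order (AU01 inner brow raiser ... AU45 blink).
#'
#' @param n number of channels (default 17; other values label generically).
#' @return character vector of channel ids.
#' @export
openface_au_ids <- function(n = 17L) {
  ids <- c("AU01", "AU02", "AU04", "AU05", "AU06", "AU07", "AU09", "AU10",
           "AU12", "AU14", "AU15", "AU17", "AU20", "AU23", "AU25", "AU26",
           "AU45")
  if (n == length(ids)) ids else sprintf("AU%02d", seq_len(n))
}

# Printed indices of the channels with visible group differences in the
# source study's mean/variance comparison. Interpreted as 1-based positions
# within the 17-channel intensity ordering (see select_au_subset).
significant_au_positions <- c(2L, 4L, 5L, 7L, 8L, 9L, 10L, 12L, 14L, 15L, 16L)

#' Select the AU channel subset for featureization
#'
#' \code{"all17"} keeps every extracted intensity channel (feature length
#' 34 after mean+variance). \code{"significant11"} keeps the 11 channels
#' reported to differ visibly between groups; the published index set
#' \{2,4,5,7,8,9,10,12,14,15,16\} contains values that are not OpenFace AU
#' numbers, so it is interpreted through an explicit mapping, by default as
#' 1-based positions within the 17-channel ordering. Supply \code{index_map}
#' to impose a different interpretation.
#'
#' @param mode \code{"all17"} or \code{"significant11"}.
#' @param au_ids the channel universe (default the 17 standard ids).
#' @param index_map integer vector mapping printed indices to positions in
#'   \code{au_ids} (default identity: printed index k = k-th channel).
#' @return character vector of selected channel ids.
#' @export
select_au_subset <- function(mode = c("all17", "significant11"),
                             au_ids = openface_au_ids(),
                             index_map = seq_along(au_ids)) {
  mode <- match.arg(mode)
  if (mode == "all17") return(au_ids)
  pos <- index_map[significant_au_positions]
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > length(au_ids)))
    stop_fs("index_map does not cover the significant AU index set")
  au_ids[pos]
}

#' Segment a sequence into fixed-length clips
#'
#' Cuts consecutive, non-overlapping clips of exactly \code{segment_len}
#' frames from the start of the sequence; a trailing remainder shorter than
#' \code{segment_len} is discarded. \code{"all"} returns the whole sequence
#' as a single clip. An 18,000-frame session yields 17 clips at 1024 frames
#' and 35 at 512.
#'
#' @param seq numeric matrix, frames x channels.
#' @param segment_len positive integer or \code{"all"}.
#' @return list of clip matrices (possibly empty, with a warning, when
#'   \code{segment_len} exceeds the sequence length).
#' @export
segment_sequence <- function(seq, segment_len = 1024L) {
  if (!is.matrix(seq)) stop_fs("`seq` must be a frames x channels matrix")
  if (identical(segment_len, "all")) return(list(seq))
  segment_len <- check_count(segment_len, "segment_len")
  n_clips <- nrow(seq) %/% segment_len
  if (n_clips == 0L) {
    warning(sprintf("segment_len %d exceeds sequence length %d: no clips",
                    segment_len, nrow(seq)), call. = FALSE)
    return(list())
  }
  lapply(seq_len(n_clips), function(i)
    seq[((i - 1L) * segment_len + 1L):(i * segment_len), , drop = FALSE])
}

#' Clip-level mean/variance feature vector
#'
#' For each selected channel, the temporal mean and the temporal variance
#' over the clip, concatenated as all means (in \code{au_subset} order)
#' followed by all variances — 34 elements for the full 17-channel set. The
#' default variance is the population (divide-by-n) estimator; set
#' \code{variance = "sample"} for divide-by-(n-1).
#'
#' @param clip numeric matrix, frames x channels, with channel ids as column
#'   names.
#' @param au_subset channel ids to featurize (default: all columns).
#' @param variance \code{"population"} or \code{"sample"}.
#' @return named numeric vector \code{m_<id>..., v_<id>...}.
#' @export
clip_features <- function(clip, au_subset = colnames(clip),
                          variance = c("population", "sample")) {
  variance <- match.arg(variance)
  if (!is.matrix(clip) || nrow(clip) == 0L) stop_fs("`clip` must be a nonempty matrix")
  if (is.null(au_subset) || !length(au_subset)) stop_fs("empty AU subset")
  if (is.character(au_subset)) {
    missing <- setdiff(au_subset, colnames(clip))
    if (length(missing))
      stop_fs("AU channels not present in clip: ", paste(missing, collapse = ", "))
  }
  x <- clip[, au_subset, drop = FALSE]
  m <- colMeans(x)
  v <- colMeans(sweep(x, 2L, m, `-`)^2)
  if (variance == "sample") {
    if (nrow(x) < 2L) stop_fs("sample variance needs >= 2 frames")
    v <- v * nrow(x) / (nrow(x) - 1L)
  }
  ids <- if (is.character(au_subset)) au_subset else colnames(clip)[au_subset]
  stats::setNames(c(m, v), c(paste0("m_", ids), paste0("v_", ids)))
}

#' Cohort-wide clip feature table
#'
#' Segments every session's AU sequence and computes clip features, carrying
#' subject, session and label through — the input expected by
#' \code{\link{loso_clip_predictions}}.
#'
#' @param cohort a \code{\link{generate_cohort}} result whose sessions carry
#'   AU streams.
#' @param segment_len clip length in frames, or \code{"all"} (one clip per
#'   session).
#' @param au_subset channel ids (default all 17).
#' @param variance variance estimator, see \code{\link{clip_features}}.
#' @return \code{data.table}: \code{subject_id, session_id, clip_index,
#'   label}, then feature columns \code{m_*}/\code{v_*}.
#' @export
cohort_feature_table <- function(cohort, segment_len = 1024L,
                                 au_subset = NULL,
                                 variance = c("population", "sample")) {
  variance <- match.arg(variance)
  rows <- list()
  for (sess in cohort$sessions) {
    if (is.null(sess$au))
      stop_fs("session ", sess$session_id, " has no AU stream")
    if (is.null(au_subset)) au_subset <- colnames(sess$au)
    clips <- segment_sequence(sess$au, segment_len)
    for (ci in seq_along(clips)) {
      feat <- clip_features(clips[[ci]], au_subset, variance)
      rows[[length(rows) + 1L]] <- c(
        list(subject_id = sess$subject_id, session_id = sess$session_id,
             clip_index = ci, label = sess$label),
        as.list(feat))
    }
  }
  if (!length(rows)) stop_fs("no clips produced; segment_len too large?")
  data.table::rbindlist(rows)
}

#' Write a clip-feature table as CSV
#'
#' @param tab a \code{\link{cohort_feature_table}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(tab, path) {
  data.table::fwrite(tab, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  data.table::fread(path, colClasses = list(character = c("subject_id", "session_id", "label")))
}
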