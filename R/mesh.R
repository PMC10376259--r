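#' Recentre a mesh frame on a face-centre landmark
#'
#' Translates every landmark so that the landmark at \code{center_index}
#' lands exactly at the origin. Visibility values, if present as a fourth
#' coordinate column, are untouched. Translation is an isometry, so all
#' inter-landmark distances are preserved.
#'
#' @param frame numeric matrix, landmarks x 3 (x,y,z) or landmarks x 4
#'   (x,y,z,v).
#' @param center_index 1-based landmark index of the face centre. The default
#'   2 is the nose-tip vertex of the 478-point face-mesh topology.
#' @return frame of the same shape with the centre landmark at (0,0,0).
#' @export
center_frame <- function(frame, center_index = 2L) {
  if (!is.matrix(frame) || !ncol(frame) %in% c(3L, 4L))
    stop_fs("`frame` must be a landmarks x 3 or landmarks x 4 matrix")
  if (center_index < 1L || center_index > nrow(frame))
    stop_fs(sprintf("center_index %d out of range [1, %d]",
                    center_index, nrow(frame)))
  frame[, 1:3] <- sweep(frame[, 1:3, drop = FALSE], 2L,
                        frame[center_index, 1:3], `-`)
  frame
}

#' Rescale a centred mesh frame to the [-1, 1] cube
#'
#' Applies one isotropic scale factor to all three axes so that the largest
#' absolute coordinate becomes exactly 1; the mesh shape is unchanged (ratios
#' between coordinates are preserved). The frame must already be centred.
#'
#' @param frame numeric matrix, landmarks x 3 or landmarks x 4 (visibility
#'   column untouched).
#' @return rescaled frame with all coordinates in [-1, 1].
#' @export
rescale_frame <- function(frame) {
  if (!is.matrix(frame) || !ncol(frame) %in% c(3L, 4L))
    stop_fs("`frame` must be a landmarks x 3 or landmarks x 4 matrix")
  m <- max(abs(frame[, 1:3]))
  if (m == 0) stop_fs("all-zero frame: isotropic rescale is undefined")
  frame[, 1:3] <- frame[, 1:3] / m
  frame
}

#' Normalize a mesh sequence to a frame-feature matrix
#'
#' Each frame is independently recentred on \code{center_index} and
#' isotropically rescaled to [-1, 1]; the visibility channel is dropped.
#' With the default 478-landmark topology every frame yields
#' 478 x 3 = 1434 features. The result is invariant to any global
#' translation plus positive isotropic scaling of the input session (exactly
#' so when the transform arithmetic is exact, to ~1e-15 relative otherwise),
#' which is precisely the camera-placement nuisance the normalization is
#' meant to remove.
#'
#' @param seq mesh sequence: numeric array \code{[frames, landmarks, 3 or 4]}
#'   (as produced by \code{\link{generate_mesh_sequence}}) or a list of
#'   per-frame landmark matrices.
#' @param center_index 1-based face-centre landmark (default 2, nose tip).
#' @return numeric matrix, frames x (3 * landmarks); per frame the layout is
#'   x1,y1,z1,x2,y2,z2,...
#' @export
normalize_sequence <- function(seq, center_index = 2L) {
  if (is.array(seq) && length(dim(seq)) == 3L) {
    n <- dim(seq)[1L]
    frames <- lapply(seq_len(n), function(t) {
      f <- seq[t, , , drop = TRUE]
      dim(f) <- dim(seq)[2:3]
      f
    })
  } else if (is.list(seq)) {
    frames <- seq
  } else stop_fs("`seq` must be a [frames, landmarks, coords] array or a list of frames")
  if (!length(frames)) stop_fs("empty mesh sequence")
  L <- nrow(frames[[1L]])
  out <- matrix(NA_real_, length(frames), 3L * L)
  for (t in seq_along(frames)) {
    f <- tryCatch(rescale_frame(center_frame(frames[[t]], center_index)),
                  error = function(e)
                    stop_fs(sprintf("frame %d: %s", t, conditionMessage(e))))
    out[t, ] <- as.vector(t(f[, 1:3]))
  }
  out
}

#' Fit a PCA model on pooled training frames
#'
#' Components are the top-\code{k} right singular directions of the
#' mean-centred frame matrix; explained-variance ratios are computed against
#' the total variance of all columns. The sign of each component is fixed by
#' forcing its largest-magnitude entry nonnegative, making fits reproducible.
#' Fit PCA on training frames only and reuse the model for test frames to
#' avoid leakage.
#'
#' @param x numeric matrix, frames x features (e.g. the output of
#'   \code{\link{normalize_sequence}} pooled over training sessions).
#' @param k number of components, \code{1 <= k < nrow(x)} and
#'   \code{k <= ncol(x)}.
#' @return a \code{pca_model}: list with \code{mean} (length-p), \code{components}
#'   (k x p, orthonormal rows), \code{explained_variance_ratio} (length-k).
#' @export
fit_pca <- function(x, k) {
  if (!is.matrix(x)) x <- as.matrix(x)
  k <- check_count(k, "k")
  if (k >= nrow(x)) stop_fs("need more frames than components: k < nrow(x)")
  if (k > ncol(x)) stop_fs("k exceeds the feature dimension")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, `-`)
  sv <- svd(xc, nu = 0, nv = k)
  comps <- t(sv$v)
  for (i in seq_len(k)) {
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) comps[i, ] <- -comps[i, ]
  }
  total_var <- sum(xc^2) / (nrow(x) - 1L)
  evr <- (sv$d[seq_len(k)]^2 / (nrow(x) - 1L)) / total_var
  structure(list(mean = mu, components = comps,
                 explained_variance_ratio = evr),
            class = "pca_model")
}

#' Project frames onto a fitted PCA model
#'
#' @param model a \code{\link{fit_pca}} result.
#' @param x numeric matrix, frames x features, feature width matching the
#'   model's mean vector.
#' @return numeric matrix, frames x k scores.
#' @export
transform_pca <- function(model, x) {
  if (!inherits(model, "pca_model")) stop_fs("`model` must be a pca_model")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$mean))
    stop_fs(sprintf("feature width %d does not match model width %d",
                    ncol(x), length(model$mean)))
  sweep(x, 2L, model$mean, `-`) %*% t(model$components)
}

#' Cumulative explained-variance table
#'
#' One row per retained component count, with the cumulative fraction of
#' total frame variance explained — the standard report for choosing how many
#' components to keep.
#'
#' @param model a \code{\link{fit_pca}} result.
#' @return data.frame with columns \code{components} and
#'   \code{cumulative_explained_variance}.
#' @export
explained_variance_table <- function(model) {
  if (!inherits(model, "pca_model")) stop_fs("`model` must be a pca_model")
  data.frame(components = seq_along(model$explained_variance_ratio),
             cumulative_explained_variance = cumsum(model$explained_variance_ratio))
}

#' Serialize / restore a PCA model as portable JSON
#'
#' @param model a \code{pca_model}.
#' @param path file path.
#' @return \code{read_pca_model} returns the restored \code{pca_model};
#'   \code{write_pca_model} returns \code{path} invisibly.
#' @export
write_pca_model <- function(model, path) {
  if (!inherits(model, "pca_model")) stop_fs("`model` must be a pca_model")
  jsonlite::write_json(
    list(mean = model$mean,
         components = model$components,
         explained_variance_ratio = model$explained_variance_ratio),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.double(obj$mean),
                 components = matrix(as.double(obj$components),
                                     nrow = nrow(obj$components)),
                 explained_variance_ratio = as.double(obj$explained_variance_ratio)),
            class = "pca_model")
}
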