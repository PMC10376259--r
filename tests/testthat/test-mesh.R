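toy_frame <- function() {
  rbind(c(3, 2, 1),
        c(2, 1, 0),    # centre landmark
        c(0, 0, 0))
}

test_that("center_frame translates onto the chosen landmark", {
  f <- center_frame(toy_frame(), 2L)
  expect_equal(f[2L, ], c(0, 0, 0))
  expect_equal(f[1L, ], c(1, 1, 1))
  # translation is an isometry
  expect_equal(dist(f), dist(toy_frame()), ignore_attr = TRUE)
  # idempotent on a centred frame
  expect_identical(center_frame(f, 2L), f)
  # visibility untouched
  f4 <- cbind(toy_frame(), v = c(1, 0, 1))
  expect_equal(center_frame(f4, 2L)[, 4L], c(1, 0, 1), ignore_attr = TRUE)
  expect_error(center_frame(toy_frame(), 7L), "out of range")
})

test_that("rescale_frame applies one isotropic factor reaching max |coord| = 1", {
  f <- matrix(c(2, -1, 0.5, 0, 0, 0), 2L, 3L, byrow = TRUE)
  r <- rescale_frame(f)
  expect_equal(max(abs(r[, 1:3])), 1)
  expect_equal(r[1L, ], f[1L, ] / 2)            # halved: max |coord| was 2
  expect_identical(rescale_frame(r), r)         # idempotent
  # ratios between coordinates preserved (single scalar multiplier)
  expect_equal(r[1L, 2L] / r[1L, 1L], f[1L, 2L] / f[1L, 1L])
  expect_error(rescale_frame(matrix(0, 2L, 3L)), "all-zero")
})

test_that("normalize_sequence yields 1434 features per 478-landmark frame", {
  cfg <- small_au_config(frames_per_session = 3L, streams = "mesh")
  m <- generate_mesh_sequence("healthy", cfg, seed = 1L)
  nm <- normalize_sequence(m)
  expect_identical(dim(nm), c(3L, 1434L))
  expect_true(all(abs(nm) <= 1))
  # single-frame sequence
  one <- normalize_sequence(m[1L, , , drop = FALSE])
  expect_identical(dim(one), c(1L, 1434L))
  # frame index surfaces in error diagnostics
  bad <- m
  bad[2L, , 1:3] <- bad[2L, 2L, 1:3][col(matrix(0, dim(m)[2L], 3L))]
  expect_error(normalize_sequence(bad), "frame 2")
})

test_that("normalization removes global translation and isotropic scale", {
  cfg <- small_au_config(frames_per_session = 8L, n_landmarks = 60L,
                         noise_sd = 0.05, streams = "mesh")
  base <- generate_mesh_sequence("healthy", cfg, seed = 5L,
                                 transform = list(translate = c(0, 0, 0), scale = 1))
  ref <- normalize_sequence(base)
  # arbitrary real transforms: equality to floating-point rounding
  for (tr in list(list(translate = c(17.3, -4.2, 88.8), scale = 0.37),
                  list(translate = c(-120.5, 3.14, 0.2), scale = 2.9))) {
    moved <- base
    for (a in 1:3) moved[, , a] <- base[, , a] * tr$scale + tr$translate[a]
    expect_equal(normalize_sequence(moved), ref, tolerance = 1e-12)
  }
  # exactly representable transform arithmetic: bit-identical output
  grid <- round(base * 8) / 8                   # dyadic coordinates
  grid[, , 4L] <- 1
  ref_grid <- normalize_sequence(grid)
  exact <- grid
  for (a in 1:3) exact[, , a] <- grid[, , a] * 4 + c(10, -6, 2)[a]
  expect_identical(normalize_sequence(exact), ref_grid)
})

test_that("fit_pca matches a dense covariance eigen-decomposition", {
  set.seed(11)
  X <- matrix(rnorm(20L * 6L), 20L, 6L)
  p <- fit_pca(X, 5L)
  ev <- eigen(cov(X), symmetric = TRUE)
  expect_equal(p$explained_variance_ratio,
               (ev$values / sum(ev$values))[1:5], tolerance = 1e-10)
  # components equal eigenvectors up to the documented sign convention
  for (i in 1:5) {
    v <- ev$vectors[, i]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(p$components[i, ], v, tolerance = 1e-8)
  }
  # rows orthonormal
  expect_equal(p$components %*% t(p$components), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("rank-1 data is fully explained by one component", {
  set.seed(2)
  dir <- rnorm(8)
  X <- outer(rnorm(30), dir) + 3
  p <- fit_pca(X, 3L)
  expect_equal(p$explained_variance_ratio[1L], 1, tolerance = 1e-10)
})

test_that("transform_pca projects, reconstructs, and guards widths", {
  set.seed(4)
  X <- matrix(rnorm(40L * 7L), 40L, 7L)
  p <- fit_pca(X, 7L)
  # projecting the model mean gives zero scores
  expect_equal(as.vector(transform_pca(p, matrix(p$mean, 1L))), rep(0, 7L),
               tolerance = 1e-12)
  # full-rank round trip
  scores <- transform_pca(p, X)
  recon <- sweep(scores %*% p$components, 2L, p$mean, `+`)
  expect_equal(recon, X, tolerance = 1e-8, ignore_attr = TRUE)
  expect_identical(ncol(transform_pca(fit_pca(X, 5L), X)), 5L)
  expect_error(transform_pca(p, X[, 1:3]), "width")
  expect_error(fit_pca(X, 40L), "frames")
})

test_that("reconstruction error is nonincreasing in k", {
  set.seed(9)
  X <- matrix(rnorm(30L * 10L), 30L, 10L)
  errs <- vapply(1:9, function(k) {
    p <- fit_pca(X, k)
    recon <- sweep(transform_pca(p, X) %*% p$components, 2L, p$mean, `+`)
    sum((X - recon)^2)
  }, numeric(1L))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("explained_variance_table gives monotone cumulative prefix sums", {
  p <- structure(list(mean = numeric(3L), components = diag(3L),
                      explained_variance_ratio = c(0.6, 0.3, 0.1)),
                 class = "pca_model")
  tab <- explained_variance_table(p)
  expect_equal(tab$cumulative_explained_variance, c(0.6, 0.9, 1.0))
  expect_true(all(diff(tab$cumulative_explained_variance) >= 0))
  expect_lte(max(tab$cumulative_explained_variance), 1 + 1e-8)
})

test_that("PCA models survive a serialization round trip", {
  set.seed(21)
  X <- matrix(rnorm(25L * 6L), 25L, 6L)
  p <- fit_pca(X, 4L)
  path <- withr::local_tempfile(fileext = ".json")
  write_pca_model(p, path)
  q <- read_pca_model(path)
  expect_equal(q$mean, p$mean)
  expect_equal(q$components, p$components)
  expect_equal(q$explained_variance_ratio, p$explained_variance_ratio)
})
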