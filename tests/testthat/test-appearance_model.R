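# Dual-PCA appearance model: fitting, projection, synthesis.

rank1_shapes <- function() {
  base <- square_shape()
  v <- matrix(0, 5, 2); v[5, 2] <- 1   # move the centre point vertically
  lapply(c(-2, -1, 0, 1, 2), function(c) base + c * v)
}

test_that("a rank-1 shape family yields exactly one component", {
  # construct aligned shapes directly (bypassing GPA) so the closed-form
  # rank-1 oracle applies exactly
  shapes <- rank1_shapes()
  aligned <- structure(list(shapes = shapes,
                            mean_shape = Reduce(`+`, shapes) / 5,
                            transforms = NULL, iterations = 0L),
                       class = "aligned_shapes")
  sm <- fit_shape_model(aligned, variance_retained = 0.5)
  expect_equal(sm$n_components, 1L)
  # axis = +-unit direction of the construction
  v <- numeric(10); v[10] <- 1
  expect_equal(abs(sum(sm$axes[, 1] * v)), 1, tolerance = 1e-10)
  expect_equal(sm$sds[1], sd(c(-2, -1, 0, 1, 2)), tolerance = 1e-10)
})

test_that("identical shapes produce an empty model or an error per config", {
  s <- square_shape()
  aligned <- structure(list(shapes = list(s, s, s), mean_shape = s,
                            transforms = NULL, iterations = 0L),
                       class = "aligned_shapes")
  expect_error(fit_shape_model(aligned), "zero total variance")
  empty <- fit_shape_model(aligned, allow_empty = TRUE)
  expect_equal(empty$n_components, 0L)
})

test_that("rank-1 and identical texture families behave analogously", {
  pattern <- sin(seq_len(40))
  tex <- do.call(rbind, lapply(c(-1, 0, 2), function(c) 0.5 + c * 0.1 * pattern))
  tm <- fit_texture_model(tex, variance_retained = 0.9)
  expect_equal(tm$n_components, 1L)
  unit <- pattern / sqrt(sum(pattern^2))
  expect_equal(abs(sum(tm$axes[, 1] * unit)), 1, tolerance = 1e-10)
  same <- fit_texture_model(tex[c(1, 1, 1), ], allow_empty = TRUE)
  expect_equal(same$n_components, 0L)
  expect_error(fit_texture_model(tex[c(1, 1, 1), ]), "zero total variance")
})

test_that("three generative factors with variances 9:4:1 are recovered", {
  fit <- three_factor_fit()
  sm <- fit$model$shape_model
  expect_equal(sm$n_components, 3L)
  ratios <- sm$sds / sm$sds[3]
  expect_lt(max(abs(ratios / c(3, 2, 1) - 1)), 0.10)
})

test_that("PCA axes are orthonormal with non-increasing positive sds", {
  m <- three_factor_fit()$model
  for (pm in list(m$shape_model, m$texture_model)) {
    G <- crossprod(pm$axes)
    expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
    expect_true(all(pm$sds > 0))
    expect_true(all(diff(pm$sds) <= 1e-12))
    expect_true(all(diff(pm$var_explained) <= 1e-12))
    expect_lte(sum(pm$var_explained), 1 + 1e-12)
  }
})

test_that("training scores are standardized and uncorrelated", {
  m <- three_factor_fit()$model
  expect_lt(max(abs(colMeans(m$scores))), 1e-8)
  expect_lt(max(abs(apply(m$scores, 2, sd) - 1)), 1e-8)
  # shape scores mutually uncorrelated; texture scores mutually uncorrelated
  ns <- m$shape_model$n_components
  cs <- cor(m$scores[, 1:ns, drop = FALSE])
  expect_lt(max(abs(cs - diag(ns))), 1e-6)
  ct <- cor(m$scores[, -(1:ns), drop = FALSE])
  expect_lt(max(abs(ct - diag(ncol(ct)))), 1e-6)
})

test_that("textures of identically shaped faces equal the masked originals", {
  # constant-geometry faces: textures must reproduce the (warped) images;
  # constant-intensity images give exactly constant texture vectors
  s <- face_template()
  flat <- matrix(0.4, 64, 64)
  frame <- reference_frame(align_shapes(list(s, s + 1e-9))$mean_shape, 64, 64)
  tex <- extract_textures(list(flat, flat), list(s, s), frame)
  expect_equal(as.vector(tex), rep(0.4, length(tex)), tolerance = 1e-12)
})

test_that("similarity-transformed copies of a face give near-equal textures", {
  spec <- generative_spec(n_ratees = c(F = 2, M = 2))
  faces <- generate_faces(spec, n = 1, seed = 21)
  img <- faces$images[[1]]; lm1 <- faces$true_landmarks[[1]]
  # a second "photograph": same face, slightly rotated camera. Build the
  # transformed image by warping with a dense mesh over the full frame.
  ang <- 4 * pi / 180
  ctr <- c(31.5, 31.5)
  lm2 <- sweep(sweep(lm1, 2, ctr) %*% t(faceforge:::rotation_matrix(ang)),
               2, ctr, "+")
  tri <- triangulate(lm1)
  img2 <- warp_image(img, src = lm1, dst = lm2, tri = tri)
  frame <- reference_frame(align_shapes(list(lm1, lm2))$mean_shape, 64, 64)
  tex <- extract_textures(list(img, img2), list(lm1, lm2), frame)
  expect_lt(mean(abs(tex[1, ] - tex[2, ])), 0.02 * diff(range(img)))
})

test_that("the mean face projects to the zero component vector", {
  m <- three_factor_fit()$model
  syn <- synthesize_face(m)   # c = 0
  pr <- project_face(syn$image, syn$landmarks, m)
  expect_lt(max(abs(pr$standardized)), 1e-8)
})

test_that("synthesis then projection recovers the coefficients", {
  m <- three_factor_fit()$model
  ns <- m$shape_model$n_components; nt <- m$texture_model$n_components
  z <- numeric(ns + nt)
  z[1:3] <- c(2, -2, 1); z[ns + 1] <- 2
  syn <- synthesize_face(m, standardized = z)
  pr <- project_face(syn$image, syn$landmarks, m)
  set_idx <- c(1:3, ns + 1)
  rel <- abs(pr$standardized[set_idx] - z[set_idx]) / abs(z[set_idx])
  expect_lt(max(rel), 0.01)
  # unset leading texture components stay near zero in intensity units
  resid_tex <- (pr$texture_coeffs - z[ns + 1:nt] * m$texture_model$sds)
  expect_lt(max(abs(resid_tex)), 0.02)
})

test_that("opposite shape displacements land 4 sd apart along the axis", {
  m <- three_factor_fit()$model
  ns <- m$shape_model$n_components
  z_hi <- numeric(ns + m$texture_model$n_components); z_hi[2] <- 2
  z_lo <- -z_hi
  hi <- synthesize_face(m, standardized = z_hi)
  lo <- synthesize_face(m, standardized = z_lo)
  # landmark difference equals 4 sd_2 along axis 2, mapped to pixel frame
  d_aligned <- faceforge:::shape_to_vec(hi$landmarks - lo$landmarks) /
    m$frame$scale
  expected <- 4 * m$shape_model$sds[2] * m$shape_model$axes[, 2]
  expect_equal(d_aligned, expected, tolerance = 1e-10)
})

test_that("synthesis is deterministic and clips little at moderate range", {
  m <- three_factor_fit()$model
  ns <- m$shape_model$n_components
  z <- numeric(ns + m$texture_model$n_components)
  z[c(1, ns + 1)] <- c(2, 2)
  a <- synthesize_face(m, standardized = z)
  b <- synthesize_face(m, standardized = z)
  expect_identical(a$image, b$image)
  expect_lt(a$clip_fraction, 0.01)
  expect_true(all(a$image >= 0 & a$image <= 1))
})

test_that("full-retention shape model reconstructs training shapes exactly", {
  set.seed(77)
  shapes <- lapply(1:10, function(i) face_template() + matrix(rnorm(64, 0, 0.6), 32))
  aligned <- align_shapes(shapes)
  sm <- fit_shape_model(aligned, variance_retained = 1)
  for (i in c(1, 5, 10)) {
    x <- faceforge:::shape_to_vec(aligned$shapes[[i]]) -
      faceforge:::shape_to_vec(sm$mean_shape)
    recon <- drop(sm$axes %*% crossprod(sm$axes, x))
    expect_lt(max(abs(recon - x)), 1e-6)
  }
})

test_that("coefficient length mismatches and bad retention are rejected", {
  m <- three_factor_fit()$model
  expect_error(synthesize_face(m, shape_coeffs = 1), "length mismatch")
  expect_error(synthesize_face(m, standardized = 1:2), "length mismatch")
  expect_error(fit_texture_model(matrix(rnorm(20), 5), variance_retained = 0),
               "variance_retained")
  expect_error(fit_texture_model(matrix(rnorm(20), 5), variance_retained = 1.2),
               "variance_retained")
})

test_that("model serialization round-trips bit-exactly", {
  m <- three_factor_fit()$model
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m, m2)
  unlink(path)
})
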