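# The statistical appearance model: a PCA of Procrustes-aligned landmark
# shapes plus a PCA of shape-normalised ("shape-free") pixel textures.
# Faces are points in the resulting face-space; the standardized component
# scores are the predictors used throughout the rating analyses.

#' Principal component analysis by SVD of the centred data matrix
#'
#' Rows are observations, columns variables. Variances use the n-1 divisor.
#' Each axis is sign-anchored so that its largest-magnitude loading is
#' positive, making results deterministic across platforms. Components with
#' negligible variance (singular value below `1e-10` times the largest) are
#' dropped before the retention rule is applied.
#'
#' @param X numeric matrix, n x p.
#' @param variance_retained fraction of total variance to retain, in (0, 1].
#'   The smallest component count reaching it is kept.
#' @param allow_empty if the data have zero total variance, return an empty
#'   model (`TRUE`) or raise an error (`FALSE`, default).
#' @return list with `center`, `axes` (p x k, orthonormal columns), `sds`
#'   (length k, non-increasing), `var_explained` (per-component fractions).
#' @keywords internal
pca_fit <- function(X, variance_retained = 0.95, allow_empty = FALSE) {
  if (variance_retained <= 0 || variance_retained > 1)
    stop("variance_retained must be in (0, 1]")
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 observations")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0)
  keep <- sv$d > 1e-10 * max(sv$d, .Machine$double.eps)
  if (!any(keep)) {
    if (!allow_empty) stop("data have zero total variance")
    return(list(center = ctr, axes = matrix(0, ncol(X), 0),
                sds = numeric(0), var_explained = numeric(0)))
  }
  d <- sv$d[keep]
  V <- sv$v[, keep, drop = FALSE]
  vars <- d^2 / (n - 1)
  frac <- vars / sum(vars)
  k <- which(cumsum(frac) >= variance_retained - 1e-12)[1]
  V <- V[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry positive per axis
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(center = ctr, axes = V, sds = sqrt(vars[seq_len(k)]),
       var_explained = frac[seq_len(k)])
}

shape_to_vec <- function(shape) as.vector(t(shape))       # x1,y1,x2,y2,...
vec_to_shape <- function(v) matrix(v, ncol = 2, byrow = TRUE,
                                   dimnames = list(NULL, c("x", "y")))

#' Fit the shape PCA of an appearance model
#'
#' @param aligned an `aligned_shapes` object from [align_shapes()].
#' @param variance_retained fraction of shape variance to keep (default 0.95).
#' @param allow_empty behaviour when shapes are all identical; see [pca_fit()].
#' @return object of class `shape_model`: `mean_shape`, `axes`
#'   (2n x k), `sds` (aligned-frame units), `var_explained`, `n_components`.
#' @export
fit_shape_model <- function(aligned, variance_retained = 0.95,
                            allow_empty = FALSE) {
  if (!inherits(aligned, "aligned_shapes"))
    stop("aligned must come from align_shapes()")
  X <- do.call(rbind, lapply(aligned$shapes, shape_to_vec))
  p <- pca_fit(X, variance_retained, allow_empty)
  structure(list(mean_shape = vec_to_shape(p$center), axes = p$axes,
                 sds = p$sds, var_explained = p$var_explained,
                 n_components = length(p$sds)),
            class = "shape_model")
}

#' Fit the texture PCA of an appearance model
#'
#' @param textures matrix of shape-free texture vectors, one row per face
#'   (as produced by [extract_textures()]).
#' @param variance_retained fraction of texture variance to keep.
#' @param allow_empty behaviour for identical textures; see [pca_fit()].
#' @return object of class `texture_model`: `mean_texture`, `axes`, `sds`
#'   (intensity units), `var_explained`, `n_components`.
#' @export
fit_texture_model <- function(textures, variance_retained = 0.95,
                              allow_empty = FALSE) {
  p <- pca_fit(as.matrix(textures), variance_retained, allow_empty)
  structure(list(mean_texture = p$center, axes = p$axes, sds = p$sds,
                 var_explained = p$var_explained,
                 n_components = length(p$sds)),
            class = "texture_model")
}

#' Build the reference (shape-free) frame of a model
#'
#' Places the unit-size mean shape into a width x height pixel frame with a
#' margin, triangulates it, and precomputes the pixel-triangle warp map and
#' the pixel mask of the face interior.
#'
#' @param mean_shape mean shape in the aligned frame (unit centroid size).
#' @param width,height frame size in pixels.
#' @param margin fraction of the frame kept clear around the face.
#' @return list with `shape` (reference landmarks in pixel coordinates),
#'   `scale`, `offset` (the similarity placing aligned-frame coordinates
#'   into the frame), `tri`, `map`, `mask` (linear pixel indices),
#'   `width`, `height`.
#' @export
reference_frame <- function(mean_shape, width, height, margin = 0.05) {
  rng_x <- range(mean_shape[, 1]); rng_y <- range(mean_shape[, 2])
  s <- (1 - 2 * margin) * min((width - 1) / diff(rng_x),
                              (height - 1) / diff(rng_y))
  ref <- mean_shape * s
  off <- c((width - 1) / 2 - mean(range(ref[, 1])),
           (height - 1) / 2 - mean(range(ref[, 2])))
  ref <- sweep(ref, 2, off, "+")
  tri <- triangulate(ref)
  map <- warp_map(ref, tri, width, height)
  list(shape = ref, scale = s, offset = off, tri = tri, map = map,
       mask = sort(map$idx), width = as.integer(width),
       height = as.integer(height))
}

#' Extract shape-free textures by warping faces onto the reference frame
#'
#' Implements the shape-normalisation step: every image is warped from its
#' own landmarks onto the model's mean shape, and the pixels inside the face
#' mesh are collected into one vector per face, all with identical support.
#'
#' @param images list of grayscale matrices (or RGB arrays) in 0..1.
#' @param landmarks list of landmark shapes matching `images`.
#' @param frame reference frame from [reference_frame()].
#' @param interpolation passed to [warp_image()].
#' @return n x n_pixels matrix (n_pixels x channels for RGB, stacked).
#' @export
extract_textures <- function(images, landmarks, frame,
                             interpolation = "cubic") {
  if (length(images) != length(landmarks))
    stop("images and landmarks must have the same length")
  tex <- lapply(seq_along(images), function(i) {
    w <- warp_image(images[[i]], src = landmarks[[i]], dst = frame$shape,
                    tri = frame$tri, width = frame$width,
                    height = frame$height, interpolation = interpolation,
                    map = frame$map)
    if (length(dim(w)) == 2L) w <- w[frame$mask]
    else w <- as.vector(apply(w, 3, function(p) p[frame$mask]))
    # trim cubic resampling overshoot: textures live on the image scale
    pmin(pmax(w, 0), 1)
  })
  do.call(rbind, tex)
}

#' Build a gender-specific appearance model from images and landmarks
#'
#' Runs the full construction: generalized Procrustes alignment, shape PCA,
#' warping of all faces onto the mean shape, and texture PCA. One model is
#' fitted per gender because male and female facial composition differs
#' substantially; pass the pre-filtered faces of one gender.
#'
#' @param images list of grayscale matrices in 0..1.
#' @param landmarks list of matching landmark shapes.
#' @param gender label stored with the model ("F", "M", ...).
#' @param variance_retained PCA retention threshold for both PCAs
#'   (default 0.95; the resulting component counts depend on the data).
#' @param width,height reference-frame size; defaults to `frame_scale`
#'   times the first image's size.
#' @param frame_scale oversampling of the shape-free frame relative to the
#'   input images (default 3: textures are stored on a finer grid, which
#'   keeps the synthesis/projection resampling loss well below the
#'   component SDs).
#' @param interpolation warp interpolation mode ("cubic" default:
#'   Catmull-Rom loses least energy under the synthesis/projection double
#'   resampling; "bilinear" and "nearest" available).
#' @return object of class `appearance_model` with elements `gender`,
#'   `shape_model`, `texture_model`, `frame`, `aligned` (the GPA result),
#'   `scores` (training standardized scores), `variance_retained`.
#' @export
build_appearance_model <- function(images, landmarks, gender = "F",
                                   variance_retained = 0.95,
                                   width = NULL, height = NULL,
                                   frame_scale = 3,
                                   interpolation = "cubic") {
  if (length(images) != length(landmarks))
    stop("images and landmarks must have the same length")
  if (is.null(height)) height <- round(frame_scale * dim(images[[1]])[1])
  if (is.null(width)) width <- round(frame_scale * dim(images[[1]])[2])
  aligned <- align_shapes(landmarks)
  shape_model <- fit_shape_model(aligned, variance_retained)
  frame <- reference_frame(aligned$mean_shape, width, height)
  textures <- extract_textures(images, landmarks, frame, interpolation)
  texture_model <- fit_texture_model(textures, variance_retained)
  model <- structure(list(gender = gender, shape_model = shape_model,
                          texture_model = texture_model, frame = frame,
                          aligned = aligned,
                          variance_retained = variance_retained,
                          interpolation = interpolation),
                     class = "appearance_model")
  # training scores straight from the PCA decompositions (identical to
  # project_face on the training faces, without re-warping every image)
  S <- do.call(rbind, lapply(aligned$shapes, shape_to_vec))
  sc_s <- sweep(S, 2, shape_to_vec(shape_model$mean_shape)) %*% shape_model$axes
  sc_t <- sweep(textures, 2, texture_model$mean_texture) %*% texture_model$axes
  model$scores <- cbind(sweep(sc_s, 2, shape_model$sds, "/"),
                        sweep(sc_t, 2, texture_model$sds, "/"))
  colnames(model$scores) <- component_names(model)
  model
}

#' @export
print.appearance_model <- function(x, ...) {
  cat(sprintf(paste0("Appearance model (gender %s): %d shape + %d texture ",
                     "components (%.0f%% variance retained)\n"),
              x$gender, x$shape_model$n_components,
              x$texture_model$n_components, 100 * x$variance_retained))
  invisible(x)
}

#' Names of the concatenated model components
#'
#' @param model an `appearance_model`.
#' @return character vector `s1..s_k, t1..t_m` (shape then texture).
#' @export
component_names <- function(model) {
  c(sprintf("s%d", seq_len(model$shape_model$n_components)),
    sprintf("t%d", seq_len(model$texture_model$n_components)))
}

#' Project a face into an appearance model's component space
#'
#' The landmark shape is similarity-fitted onto the model's mean shape and
#' projected onto the shape axes; the image is warped onto the reference
#' frame and its masked pixels projected onto the texture axes.
#'
#' @param image grayscale matrix in 0..1.
#' @param landmarks landmark shape of the face.
#' @param model fitted `appearance_model`.
#' @return list with `shape_coeffs`, `texture_coeffs` (model units) and
#'   `standardized` (all coefficients divided by their component SD,
#'   concatenated shape-then-texture).
#' @export
project_face <- function(image, landmarks, model) {
  if (!inherits(model, "appearance_model")) stop("model must be fitted")
  sm <- model$shape_model; tm <- model$texture_model
  fit <- procrustes_fit(landmarks, sm$mean_shape)
  dv <- shape_to_vec(fit$aligned) - shape_to_vec(sm$mean_shape)
  shape_coeffs <- drop(crossprod(sm$axes, dv))
  tex <- extract_textures(list(image), list(landmarks), model$frame,
                          model$interpolation)[1, ]
  texture_coeffs <- drop(crossprod(tm$axes, tex - tm$mean_texture))
  list(shape_coeffs = shape_coeffs, texture_coeffs = texture_coeffs,
       standardized = c(shape_coeffs / sm$sds, texture_coeffs / tm$sds))
}

#' Synthesize a face image from component coefficients
#'
#' Reconstructs the texture in the mean-shape frame, reconstructs the
#' landmark shape, and warps the texture from the mean shape onto the
#' reconstructed shape. Deterministic; intensities are clipped to 0..1.
#'
#' @param model fitted `appearance_model`.
#' @param shape_coeffs,texture_coeffs coefficients in model units (lengths
#'   must match the component counts). Missing/zero gives the mean face.
#' @param standardized optionally, a single concatenated standardized score
#'   vector instead of the two raw-coefficient vectors.
#' @return list with `image` (height x width matrix), `landmarks` (the
#'   reconstructed shape in pixel coordinates), `clip_fraction` (share of
#'   mesh pixels clipped to 0..1).
#' @export
synthesize_face <- function(model, shape_coeffs = NULL, texture_coeffs = NULL,
                            standardized = NULL) {
  sm <- model$shape_model; tm <- model$texture_model
  if (!is.null(standardized)) {
    if (length(standardized) != sm$n_components + tm$n_components)
      stop("standardized score length mismatch")
    shape_coeffs <- standardized[seq_len(sm$n_components)] * sm$sds
    texture_coeffs <- standardized[-seq_len(sm$n_components)] * tm$sds
  }
  if (is.null(shape_coeffs)) shape_coeffs <- numeric(sm$n_components)
  if (is.null(texture_coeffs)) texture_coeffs <- numeric(tm$n_components)
  if (length(shape_coeffs) != sm$n_components)
    stop("shape coefficient length mismatch")
  if (length(texture_coeffs) != tm$n_components)
    stop("texture coefficient length mismatch")
  # reconstruct shape in the aligned frame, then place in the pixel frame
  v <- shape_to_vec(sm$mean_shape) +
    if (sm$n_components) drop(sm$axes %*% shape_coeffs) else 0
  shape_px <- sweep(vec_to_shape(v) * model$frame$scale, 2,
                    model$frame$offset, "+")
  tex <- tm$mean_texture +
    if (tm$n_components) drop(tm$axes %*% texture_coeffs) else 0
  clip_fraction <- mean(tex < 0 | tex > 1)
  tex <- pmin(pmax(tex, 0), 1)
  canvas <- matrix(0, model$frame$height, model$frame$width)
  canvas[model$frame$mask] <- tex
  # pad the texture a few pixels beyond the face hull so that bilinear
  # sampling at the mesh boundary never mixes in the background fill
  canvas <- extend_image(canvas, model$frame$mask, passes = 3L)
  img <- warp_image(canvas, src = model$frame$shape, dst = shape_px,
                    tri = model$frame$tri, width = model$frame$width,
                    height = model$frame$height,
                    interpolation = model$interpolation)
  dst_map <- warp_map(shape_px, model$frame$tri, model$frame$width,
                      model$frame$height)
  img <- extend_image(img, dst_map$idx, passes = 3L)
  list(image = pmin(pmax(img, 0), 1), landmarks = shape_px,
       clip_fraction = clip_fraction)
}

#' Save / load an appearance model
#'
#' The model container (means, axes, SDs, triangulation, mask, metadata) is
#' serialized with R's native format; the round-trip is bit-exact.
#'
#' @param model an `appearance_model`.
#' @param path file path.
#' @return `load_model` returns the model; `save_model` the path, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "appearance_model")) stop("not an appearance model file")
  model
}
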