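# Landmark geometry: Procrustes alignment, Delaunay triangulation and
# piecewise-affine image warping. These are the prerequisites of the
# appearance model: shapes must live in a common similarity-free frame
# before PCA, and textures must be resampled onto the mean shape.

#' Validate a landmark shape
#'
#' A landmark shape is an n x 2 numeric matrix of (x, y) coordinates in
#' pixels. Coordinates are continuous and 0-based: x runs rightwards along
#' columns, y downwards along rows, and (0, 0) is the centre of the top-left
#' pixel. Row order is semantic: row i is the same anatomical landmark in
#' every shape of a dataset.
#'
#' @param points numeric n x 2 matrix (n >= 3).
#' @return the validated matrix, invisibly classed for printing.
#' @export
as_landmark_shape <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("a landmark shape must be a numeric n x 2 matrix")
  if (nrow(points) < 3L)
    stop("a landmark shape needs at least 3 points")
  if (!all(is.finite(points)))
    stop("landmark coordinates must be finite")
  dimnames(points) <- list(NULL, c("x", "y"))
  points
}

centroid_size <- function(points) {
  ctr <- colMeans(points)
  sqrt(sum(sweep(points, 2, ctr)^2))
}

#' Optimal similarity fit of one shape onto a target
#'
#' Removes translation, uniform scale and rotation (no reflection) so that
#' the returned coordinates are as close to `target` as possible in the
#' least-squares sense. Used both inside the generalized Procrustes loop and
#' to place a new face into a fitted model's frame.
#'
#' @param shape,target n x 2 landmark matrices with matching rows.
#' @return list with `aligned` coordinates and the similarity `transform`
#'   (`scale`, `angle` in radians, `translation`) that maps the aligned
#'   coordinates back onto the original shape:
#'   `original = scale * aligned %*% t(R(angle)) + translation`.
#' @export
procrustes_fit <- function(shape, target) {
  shape <- as_landmark_shape(shape); target <- as_landmark_shape(target)
  if (nrow(shape) != nrow(target)) stop("point counts differ")
  ctr <- colMeans(shape)
  X <- sweep(shape, 2, ctr)
  sz <- sqrt(sum(X^2))
  if (sz < .Machine$double.eps) stop("degenerate shape: all points identical")
  X <- X / sz
  M <- sweep(target, 2, colMeans(target))
  # optimal rotation (no reflection) via SVD of the cross-covariance
  sv <- svd(crossprod(X, M))
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  Xr <- X %*% R
  # tangent-space scale: the aligned shape's projection onto the target is
  # exactly the target's squared norm, so displacements orthogonal to the
  # target survive projection unshrunk (the usual tangent projection of
  # statistical shape analysis)
  beta <- sum(M * M) / sum(Xr * M)
  aligned <- sweep(beta * Xr, 2, colMeans(target), "+")
  # invert: original = scale * (aligned - target centroid) %*% t(R) + ctr
  angle <- atan2(R[2, 1], R[1, 1])
  list(aligned = aligned,
       transform = list(scale = sz / beta, angle = angle,
                        translation = ctr, target_centroid = colMeans(target)))
}

#' Apply the inverse of a stored similarity transform
#'
#' Reconstructs original coordinates from aligned ones, i.e. undoes
#' [procrustes_fit()] / [align_shapes()].
#'
#' @param aligned n x 2 matrix in the aligned frame.
#' @param transform a transform as returned by [procrustes_fit()].
#' @return n x 2 matrix in the original frame.
#' @export
inverse_similarity <- function(aligned, transform) {
  R <- rotation_matrix(transform$angle)
  X <- sweep(aligned, 2, transform$target_centroid)
  sweep(transform$scale * X %*% t(R), 2, transform$translation, "+")
}

rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Generalized Procrustes alignment of a set of landmark shapes
#'
#' Iteratively removes translation, rotation and uniform scale from every
#' shape and re-estimates the mean until the mean stabilises. The mean shape
#' is renormalised to unit centroid size and zero centroid each iteration,
#' and finally rotated to best match the first input shape so the result
#' does not depend on input order (up to that fixed anchoring).
#'
#' @param shapes list of n x 2 landmark matrices, equal point counts.
#' @param tol convergence tolerance on the root-mean-square change of the
#'   mean shape between iterations.
#' @param max_iter iteration cap.
#' @return object of class `aligned_shapes`: list with `shapes` (aligned
#'   list), `mean_shape` (unit centroid size, centroid at origin),
#'   `transforms` (per shape, see [procrustes_fit()]) and `iterations`.
#' @export
align_shapes <- function(shapes, tol = 1e-8, max_iter = 100L) {
  if (!is.list(shapes) || length(shapes) < 2L)
    stop("need a list of at least 2 shapes")
  shapes <- lapply(shapes, as_landmark_shape)
  n_pts <- vapply(shapes, nrow, integer(1))
  if (length(unique(n_pts)) != 1L)
    stop("all shapes must have the same number of points")
  for (s in shapes)
    if (centroid_size(s) < .Machine$double.eps)
      stop("degenerate shape: all points identical")

  # initial frame: each shape centred and scaled to unit centroid size
  mean_shape <- local({
    X <- sweep(shapes[[1L]], 2, colMeans(shapes[[1L]]))
    X / sqrt(sum(X^2))
  })
  aligned <- shapes
  fits <- vector("list", length(shapes))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fits <- lapply(shapes, procrustes_fit, target = mean_shape)
    aligned <- lapply(fits, `[[`, "aligned")
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol || iter >= max_iter) break
  }
  # anchor orientation: rotate the mean onto the first shape's direction
  anchor <- procrustes_fit(shapes[[1L]], mean_shape)$transform$angle
  R <- rotation_matrix(-anchor)
  mean_shape <- mean_shape %*% t(R)
  fits <- lapply(shapes, procrustes_fit, target = mean_shape)
  aligned <- lapply(fits, `[[`, "aligned")
  mean_final <- Reduce(`+`, aligned) / length(aligned)
  structure(list(shapes = aligned,
                 mean_shape = mean_final,
                 transforms = lapply(fits, `[[`, "transform"),
                 iterations = iter),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf("Aligned landmark set: %d shapes x %d points (%d GPA iterations)\n",
              length(x$shapes), nrow(x$mean_shape), x$iterations))
  invisible(x)
}

#' Delaunay triangulation of a reference shape
#'
#' Computed once on a model's mean shape and reused for every warp so all
#' faces share the same mesh topology. Triangle rows are canonicalised
#' (vertex indices sorted within a row, rows in lexicographic order) so the
#' result is deterministic across platforms.
#'
#' @param reference n x 2 landmark matrix, n >= 3, not all collinear.
#' @return integer m x 3 matrix of landmark indices (class `triangulation`).
#' @export
triangulate <- function(reference) {
  reference <- as_landmark_shape(reference)
  # collinearity check: rank of centred coordinates
  ctr <- sweep(reference, 2, colMeans(reference))
  if (min(svd(ctr)$d) < 1e-9 * max(svd(ctr)$d))
    stop("points are collinear; cannot triangulate")
  dd <- deldir::deldir(reference[, 1], reference[, 2], suppressMsge = TRUE)
  tri <- deldir::triMat(dd)
  if (is.null(dim(tri))) tri <- matrix(tri, ncol = 3)
  tri <- matrix(t(apply(tri, 1, sort)), ncol = 3)
  tri <- tri[order(tri[, 1], tri[, 2], tri[, 3]), , drop = FALSE]
  storage.mode(tri) <- "integer"
  structure(tri, class = c("triangulation", "matrix"))
}

triangle_areas <- function(shape, tri) {
  a <- shape[tri[, 1], , drop = FALSE]
  b <- shape[tri[, 2], , drop = FALSE]
  c_ <- shape[tri[, 3], , drop = FALSE]
  0.5 * abs((b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
            (c_[, 1] - a[, 1]) * (b[, 2] - a[, 2]))
}

#' Precompute the pixel-to-triangle map for a warp destination
#'
#' For a fixed destination shape and mesh, records which output pixel falls
#' in which triangle and with which barycentric coordinates. Warping many
#' images onto the same destination (texture extraction onto the mean
#' shape) then reduces to one matrix product and a bilinear lookup each.
#'
#' @param dst destination landmark shape (pixel coordinates, 0-based).
#' @param tri triangulation from [triangulate()].
#' @param width,height output image size in pixels.
#' @return list with `idx` (linear pixel indices, column-major over a
#'   height x width matrix), `tri_id`, `bary` (N x 3), `width`, `height`.
#' @export
warp_map <- function(dst, tri, width, height) {
  dst <- as_landmark_shape(dst)
  if (max(tri) > nrow(dst)) stop("triangulation indices exceed point count")
  if (any(triangle_areas(dst, tri) < 1e-12))
    stop("degenerate triangle in destination shape")
  # pixel centres, 0-based
  xs <- rep(0:(width - 1L), each = height)
  ys <- rep(0:(height - 1L), times = width)
  assigned <- integer(0); tri_of <- integer(0); bary <- NULL
  taken <- logical(width * height)
  eps <- 1e-9
  for (t in seq_len(nrow(tri))) {
    p1 <- dst[tri[t, 1], ]; p2 <- dst[tri[t, 2], ]; p3 <- dst[tri[t, 3], ]
    xmin <- floor(min(p1[1], p2[1], p3[1])); xmax <- ceiling(max(p1[1], p2[1], p3[1]))
    ymin <- floor(min(p1[2], p2[2], p3[2])); ymax <- ceiling(max(p1[2], p2[2], p3[2]))
    cx <- max(0, xmin):min(width - 1L, xmax)
    cy <- max(0, ymin):min(height - 1L, ymax)
    if (!length(cx) || !length(cy)) next
    px <- rep(cx, each = length(cy)); py <- rep(cy, times = length(cx))
    lin <- px * height + py + 1L
    cand <- which(!taken[lin])
    if (!length(cand)) next
    px <- px[cand]; py <- py[cand]; lin <- lin[cand]
    det <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2])
    l2 <- ((px - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (py - p1[2])) / det
    l3 <- ((p2[1] - p1[1]) * (py - p1[2]) - (px - p1[1]) * (p2[2] - p1[2])) / det
    l1 <- 1 - l2 - l3
    inside <- l1 >= -eps & l2 >= -eps & l3 >= -eps
    if (!any(inside)) next
    lin <- lin[inside]
    taken[lin] <- TRUE
    assigned <- c(assigned, lin)
    tri_of <- c(tri_of, rep.int(t, length(lin)))
    bary <- rbind(bary, cbind(l1[inside], l2[inside], l3[inside]))
  }
  list(idx = assigned, tri_id = tri_of, bary = bary,
       width = as.integer(width), height = as.integer(height))
}

#' Sample an image at continuous coordinates
#'
#' Bilinear by default; "cubic" uses the Catmull-Rom kernel (lower blur
#' under repeated resampling, used by the appearance-model pipeline);
#' "nearest" picks the closest pixel.
#'
#' @param image height x width numeric matrix, values typically in 0..1.
#' @param x,y vectors of 0-based continuous coordinates.
#' @param interpolation "bilinear", "cubic" or "nearest".
#' @param fill value for samples outside the image support.
#' @return numeric vector of sampled intensities.
#' @export
sample_image <- function(image, x, y,
                         interpolation = c("bilinear", "cubic", "nearest"),
                         fill = 0) {
  interpolation <- match.arg(interpolation)
  h <- nrow(image); w <- ncol(image)
  out <- rep(fill, length(x))
  if (interpolation == "nearest") {
    xi <- round(x); yi <- round(y)
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    out[ok] <- image[cbind(yi[ok] + 1L, xi[ok] + 1L)]
    return(out)
  }
  if (interpolation == "cubic") {
    ok <- x >= -0.5 & x <= w - 0.5 & y >= -0.5 & y <= h - 0.5
    xc <- pmin(pmax(x[ok], 0), w - 1); yc <- pmin(pmax(y[ok], 0), h - 1)
    x0 <- floor(xc); y0 <- floor(yc)
    fx <- xc - x0; fy <- yc - y0
    cr <- function(t) {      # Catmull-Rom weights for offsets -1,0,1,2
      cbind(((-t + 2) * t - 1) * t / 2,
            ((3 * t - 5) * t * t + 2) / 2,
            ((-3 * t + 4) * t + 1) * t / 2,
            (t - 1) * t * t / 2)
    }
    wx <- cr(fx); wy <- cr(fy)
    acc <- numeric(length(xc))
    for (j in 1:4) {
      col <- pmin(pmax(x0 + j - 2L, 0), w - 1) + 1L
      rowacc <- numeric(length(xc))
      for (i in 1:4) {
        row <- pmin(pmax(y0 + i - 2L, 0), h - 1) + 1L
        rowacc <- rowacc + wy[, i] * image[cbind(row, col)]
      }
      acc <- acc + wx[, j] * rowacc
    }
    out[ok] <- acc
    return(out)
  }
  # clamp to the valid bilinear domain; warped landmarks can sit exactly on
  # the border, so allow a half-pixel tolerance before falling back to fill
  ok <- x >= -0.5 & x <= w - 0.5 & y >= -0.5 & y <= h - 0.5
  xc <- pmin(pmax(x[ok], 0), w - 1)
  yc <- pmin(pmax(y[ok], 0), h - 1)
  x0 <- pmin(floor(xc), w - 2); y0 <- pmin(floor(yc), h - 2)
  fx <- xc - x0; fy <- yc - y0
  i00 <- cbind(y0 + 1L, x0 + 1L); i01 <- cbind(y0 + 1L, x0 + 2L)
  i10 <- cbind(y0 + 2L, x0 + 1L); i11 <- cbind(y0 + 2L, x0 + 2L)
  out[ok] <- (1 - fy) * ((1 - fx) * image[i00] + fx * image[i01]) +
             fy * ((1 - fx) * image[i10] + fx * image[i11])
  out
}

#' Extend known pixel values outward by iterative dilation
#'
#' Each pass, every unknown pixel with at least one known 4-neighbour takes
#' the mean of its known neighbours. Used to pad a masked texture a few
#' pixels past the face hull so interpolation at the mesh boundary reads
#' face-like values instead of the background fill.
#'
#' @param image height x width matrix.
#' @param known linear indices of the pixels holding valid values.
#' @param passes number of one-pixel dilation passes.
#' @return the extended image matrix.
#' @export
extend_image <- function(image, known, passes = 3L) {
  h <- nrow(image); w <- ncol(image)
  K <- matrix(FALSE, h, w); K[known] <- TRUE
  for (p in seq_len(passes)) {
    acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
    shift <- function(M, dr, dc) {
      out <- matrix(0, h, w)
      rs <- max(1, 1 + dr):min(h, h + dr); cs <- max(1, 1 + dc):min(w, w + dc)
      out[rs, cs] <- M[rs - dr, cs - dc]
      out
    }
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      acc <- acc + shift(image * K, d[1], d[2])
      cnt <- cnt + shift(K + 0, d[1], d[2])
    }
    new <- !K & cnt > 0
    image[new] <- acc[new] / cnt[new]
    K <- K | new
  }
  image
}

#' Warp an image between two landmark configurations
#'
#' Piecewise-affine inverse warp: each output pixel inside the destination
#' mesh is mapped through its triangle's barycentric coordinates to the
#' corresponding source location and the source image is sampled there.
#' Pixels outside the destination mesh receive `fill`.
#'
#' @param image height x width matrix (grayscale) or height x width x 3
#'   array (RGB), intensities in 0..1.
#' @param src landmark shape of `image` (pixel coordinates).
#' @param dst landmark shape of the output frame.
#' @param tri shared triangulation ([triangulate()]).
#' @param width,height output size; defaults to the input size.
#' @param interpolation "bilinear" (default), "cubic" or "nearest".
#' @param fill intensity for pixels outside the destination mesh.
#' @param map optional precomputed [warp_map()] for `dst` (saves recomputing
#'   the pixel-triangle assignment when warping many images onto one frame).
#' @return warped image of size height x width (x 3 for RGB input).
#' @export
warp_image <- function(image, src, dst, tri,
                       width = NULL, height = NULL,
                       interpolation = c("bilinear", "cubic", "nearest"),
                       fill = 0, map = NULL) {
  interpolation <- match.arg(interpolation)
  src <- as_landmark_shape(src); dst <- as_landmark_shape(dst)
  if (nrow(src) != nrow(dst)) stop("src and dst point counts differ")
  gray <- length(dim(image)) == 2L
  h_in <- dim(image)[1]; w_in <- dim(image)[2]
  if (is.null(width)) width <- w_in
  if (is.null(height)) height <- h_in
  if (any(triangle_areas(src, tri) < 1e-12))
    stop("degenerate triangle in source shape")
  if (is.null(map)) map <- warp_map(dst, tri, width, height)
  # source coordinates for every mapped pixel
  sx <- map$bary[, 1] * src[tri[map$tri_id, 1], 1] +
        map$bary[, 2] * src[tri[map$tri_id, 2], 1] +
        map$bary[, 3] * src[tri[map$tri_id, 3], 1]
  sy <- map$bary[, 1] * src[tri[map$tri_id, 1], 2] +
        map$bary[, 2] * src[tri[map$tri_id, 2], 2] +
        map$bary[, 3] * src[tri[map$tri_id, 3], 2]
  if (gray) {
    out <- matrix(fill, height, width)
    out[map$idx] <- sample_image(image, sx, sy, interpolation, fill)
    out
  } else {
    out <- array(fill, c(height, width, dim(image)[3]))
    plane <- matrix(fill, height, width)
    for (ch in seq_len(dim(image)[3])) {
      plane[] <- fill
      plane[map$idx] <- sample_image(image[, , ch], sx, sy, interpolation, fill)
      out[, , ch] <- plane
    }
    out
  }
}
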