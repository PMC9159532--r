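#' Detection parameters for silver-enhanced nanogold beads
#'
#' @param diameter_range_nm (lo, hi) particle-diameter search band in nm,
#'   default the 10-20 nm band produced by silver enhancement
#' @param response_threshold minimum scale-normalized Laplacian-of-Gaussian
#'   response (on intensities scaled to [0, 1]); the default was calibrated
#'   on synthetic fixtures to sit between the membrane-ridge response and
#'   the weakest in-band bead response
#' @param min_separation_nm non-maximum-suppression radius
#' @param n_scales number of LoG scales spanning the diameter band
#' @return object of class `detection_params`
#' @export
detection_params <- function(diameter_range_nm = c(10, 20),
                             response_threshold = 0.12,
                             min_separation_nm = 12,
                             n_scales = 4L) {
  stopifnot(length(diameter_range_nm) == 2,
            diameter_range_nm[1] > 0,
            diameter_range_nm[1] < diameter_range_nm[2],
            response_threshold > 0, min_separation_nm > 0, n_scales >= 1)
  structure(list(diameter_range_nm = diameter_range_nm,
                 response_threshold = response_threshold,
                 min_separation_nm = min_separation_nm,
                 n_scales = as.integer(n_scales)),
            class = "detection_params")
}

# zero-sum scale-normalized LoG kernel (sigma in px); positive response for
# dark blobs when convolved with the image
.nlog_kernel <- function(sigma) {
  r <- max(2L, ceiling(3.5 * sigma))
  d <- (-r):r
  r2 <- outer(d^2, d^2, `+`)
  g <- exp(-r2 / (2 * sigma^2))
  k <- (r2 / sigma^2 - 2) * g        # sigma^2 * Laplacian of Gaussian, unnormalized
  k <- k / (2 * pi * sigma^2)
  k - mean(k)                         # exact zero response to constant background
}

#' Detect nanogold beads in every slice of a stack
#'
#' Per-slice multiscale dark-blob detection: scale-normalized
#' Laplacian-of-Gaussian responses at scales spanning the diameter band,
#' local maxima over position and scale, response thresholding, greedy
#' non-maximum suppression at `min_separation_nm`, and subpixel centroid
#' refinement by quadratic interpolation of the response peak. Deterministic
#' for fixed input.
#'
#' @param stack an `em_stack`
#' @param params a [detection_params()]
#' @return data.frame with columns slice, x_nm, y_nm, diameter_nm, score,
#'   sorted by slice then descending score
#' @export
detect_beads <- function(stack, params = detection_params()) {
  stopifnot(inherits(stack, "em_stack"))
  g <- stack$geometry
  lo_px <- params$diameter_range_nm[1] / g$dx_nm
  if (lo_px < 2) {
    stop("smallest search diameter spans < 2 pixels at this pixel size; ",
         "resample the stack or raise the diameter band")
  }
  diams <- seq(params$diameter_range_nm[1], params$diameter_range_nm[2],
               length.out = params$n_scales)
  sigmas <- diams / 2.3548 / g$dx_nm     # matched blob scale: FWHM = diameter
  kernels <- lapply(sigmas, .nlog_kernel)
  out <- list()
  for (k in seq_len(g$n_slices)) {
    img <- stack$intensities[, , k]
    resp <- lapply(kernels, function(kk)
      EBImage::filter2(img, kk, boundary = "replicate"))
    cand <- .scale_space_maxima(resp, params$response_threshold)
    if (!nrow(cand)) next
    cand <- .nms(cand, g, params$min_separation_nm)
    if (!nrow(cand)) next
    refined <- .refine_subpixel(cand, resp)
    refined <- .refine_centroid(img, refined, sigmas[cand$scale])
    out[[length(out) + 1L]] <- data.frame(
      slice = k - 1L,
      x_nm = (refined$col - 1) * g$dx_nm,
      y_nm = (refined$row - 1) * g$dy_nm,
      diameter_nm = diams[cand$scale],
      score = cand$score)
  }
  if (!length(out)) {
    return(data.frame(slice = integer(0), x_nm = numeric(0), y_nm = numeric(0),
                      diameter_nm = numeric(0), score = numeric(0)))
  }
  det <- do.call(rbind, out)
  det[order(det$slice, -det$score), , drop = FALSE]
}

# local maxima over 3x3 neighbourhood and adjacent scales, above threshold
.scale_space_maxima <- function(resp, threshold) {
  ns <- length(resp)
  nr <- nrow(resp[[1]]); nc <- ncol(resp[[1]])
  shift <- function(m, dr, dc) {
    out <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  rows <- integer(0); cols <- integer(0); scales <- integer(0); sc <- numeric(0)
  for (s in seq_len(ns)) {
    m <- resp[[s]]
    is_max <- m >= threshold
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      is_max <- is_max & (m > shift(m, dr, dc) |
                            (m == shift(m, dr, dc) & (dr > 0 | (dr == 0 & dc > 0))))
      if (!any(is_max)) break
    }
    if (s > 1) is_max <- is_max & (m >= resp[[s - 1]])
    if (s < ns) is_max <- is_max & (m > resp[[s + 1]])
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx)) {
      rows <- c(rows, idx[, 1]); cols <- c(cols, idx[, 2])
      scales <- c(scales, rep(s, nrow(idx))); sc <- c(sc, m[idx])
    }
  }
  data.frame(row = rows, col = cols, scale = scales, score = sc)
}

# greedy NMS in physical coordinates, strongest first
.nms <- function(cand, geometry, min_sep_nm) {
  o <- order(-cand$score)
  cand <- cand[o, , drop = FALSE]
  x <- (cand$col - 1) * geometry$dx_nm
  y <- (cand$row - 1) * geometry$dy_nm
  keep <- logical(nrow(cand))
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kx)) {
      if (min((kx - x[i])^2 + (ky - y[i])^2) < min_sep_nm^2) next
    }
    keep[i] <- TRUE
    kx <- c(kx, x[i]); ky <- c(ky, y[i])
  }
  cand[keep, , drop = FALSE]
}

# 3-point quadratic peak interpolation in row and column
.refine_subpixel <- function(cand, resp) {
  row <- cand$row; col <- cand$col
  rr <- as.numeric(row); cc <- as.numeric(col)
  for (i in seq_len(nrow(cand))) {
    m <- resp[[cand$scale[i]]]
    r <- row[i]; c <- col[i]
    if (r > 1 && r < nrow(m)) {
      den <- m[r - 1, c] - 2 * m[r, c] + m[r + 1, c]
      if (den < 0) rr[i] <- r + min(max(0.5 * (m[r - 1, c] - m[r + 1, c]) / den, -0.5), 0.5)
    }
    if (c > 1 && c < ncol(m)) {
      den <- m[r, c - 1] - 2 * m[r, c] + m[r, c + 1]
      if (den < 0) cc[i] <- c + min(max(0.5 * (m[r, c - 1] - m[r, c + 1]) / den, -0.5), 0.5)
    }
  }
  data.frame(row = rr, col = cc)
}

# iterative Gaussian-weighted centroid of the inverted intensity around each
# peak; sharpens localization beyond the quadratic response fit
.refine_centroid <- function(img, refined, sigma_px, n_iter = 3L) {
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_len(nrow(refined))) {
    x <- refined$col[i] - 1; y <- refined$row[i] - 1   # 0-based px coords
    s <- sigma_px[i]
    r <- ceiling(2.5 * s)
    for (it in seq_len(n_iter)) {
      c0 <- max(1L, floor(x) - r + 1L); c1 <- min(nc, floor(x) + r + 1L)
      r0 <- max(1L, floor(y) - r + 1L); r1 <- min(nr, floor(y) + r + 1L)
      win <- img[r0:r1, c0:c1]
      xs <- (c0:c1) - 1; ys <- (r0:r1) - 1
      w <- pmax(stats::quantile(win, 0.85) - win, 0)
      gx <- outer((ys - y)^2, (xs - x)^2, `+`)
      w <- w * exp(-gx / (2 * s^2))
      sw <- sum(w)
      if (sw <= 0) break
      nx <- sum(w * rep(xs, each = length(ys))) / sw
      ny <- sum(w * rep(ys, length(xs))) / sw
      x <- x + max(min(nx - x, 1.5), -1.5)
      y <- y + max(min(ny - y, 1.5), -1.5)
    }
    refined$col[i] <- x + 1; refined$row[i] <- y + 1
  }
  refined
}

#' Score detections against ground truth
#'
#' One-to-one greedy matching by ascending distance within the same slice:
#' candidate (detection, truth-bead) pairs closer than `match_radius_nm` are
#' accepted in order of distance, each bead and detection used at most once.
#' Precision with zero detections is reported as 0 by convention.
#'
#' @param detections data.frame from [detect_beads()]
#' @param truth a `ground_truth`
#' @param match_radius_nm maximum match distance (default 15 nm, about one
#'   bead diameter)
#' @return list with `precision`, `recall`, `pairs` (data.frame of matched
#'   detection row, truth row, distance)
#' @export
match_to_truth <- function(detections, truth, match_radius_nm = 15) {
  stopifnot(match_radius_nm > 0)
  tb <- truth_beads(truth)
  if (!nrow(tb)) {
    return(list(precision = if (nrow(detections)) 0 else 1,
                recall = 1, pairs = NULL))
  }
  if (!nrow(detections)) {
    return(list(precision = 0, recall = 0, pairs = NULL))
  }
  pairs <- list()
  used_d <- logical(nrow(detections)); used_t <- logical(nrow(tb))
  for (k in sort(unique(tb$slice))) {
    di <- which(detections$slice == k)
    ti <- which(tb$slice == k)
    if (!length(di) || !length(ti)) next
    dmat <- outer(detections$x_nm[di], tb$x_nm[ti], `-`)^2 +
      outer(detections$y_nm[di], tb$y_nm[ti], `-`)^2
    ok <- which(dmat <= match_radius_nm^2, arr.ind = TRUE)
    if (!nrow(ok)) next
    ord <- order(dmat[ok])
    for (j in ord) {
      a <- di[ok[j, 1]]; b <- ti[ok[j, 2]]
      if (used_d[a] || used_t[b]) next
      used_d[a] <- TRUE; used_t[b] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        detection = a, truth = b, dist_nm = sqrt(dmat[ok[j, 1], ok[j, 2]]))
    }
  }
  npairs <- length(pairs)
  list(precision = npairs / nrow(detections),
       recall = npairs / nrow(tb),
       pairs = if (npairs) do.call(rbind, pairs) else NULL)
}
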