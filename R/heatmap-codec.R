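# Gaussian-heatmap encoding of landmarks and edge-vector targets.
#
# Coordinate conventions: heatmap pixel centres sit at integer 1-based
# coordinates; landmark coordinates handed to the codec are already in
# heatmap pixel units (the detector maps between input and heatmap grids,
# see `input_to_heatmap`).

#' Codec configuration
#'
#' @param sigma Standard deviation of the target Gaussians, in heatmap
#'   pixels (default 2).
#' @param height,width Heatmap grid size.
#' @param truncation_radius Radius (heatmap pixels) beyond which the
#'   Gaussian is written as exactly 0; must be at least `3 * sigma`.
#' @param edges Two-column integer matrix of landmark index pairs defining
#'   the supervised edge set. The default chains the mechanical and
#'   anatomical axes and both joint lines, so every angle-defining segment
#'   appears: v1-v2, v2-v4, v4-v3, v4-v5, v7-v6, v7-v8, v7-v9, v9-v10,
#'   v4-v7.
#' @return A list of class `codec_config`.
#' @export
codec_config <- function(sigma = 2, height = 64, width = 32,
                         truncation_radius = 3 * sigma,
                         edges = default_edges()) {
  if (sigma <= 0) abort("`sigma` must be positive.",
                        class = "limbalign_config_error")
  if (truncation_radius < 3 * sigma)
    abort("`truncation_radius` must be >= 3 * sigma.",
          class = "limbalign_config_error")
  edges <- as.matrix(edges)
  stopifnot(ncol(edges) == 2L)
  structure(list(sigma = sigma, height = as.integer(height),
                 width = as.integer(width),
                 truncation_radius = truncation_radius, edges = edges),
            class = "codec_config")
}

#' Default supervised edge set
#' @return Two-column integer matrix of landmark index pairs.
#' @export
default_edges <- function() {
  cbind(a = c(1L, 2L, 4L, 4L, 7L, 7L, 7L, 9L, 4L),
        b = c(2L, 4L, 3L, 5L, 6L, 8L, 9L, 10L, 7L))
}

#' Encode landmarks as peak-normalised Gaussian heatmaps
#'
#' Channel `k` holds `exp(-((x - xk)^2 + (y - yk)^2) / (2 sigma^2))`
#' evaluated at pixel centres, truncated to 0 outside `truncation_radius`
#' and rescaled so the maximum over the channel is exactly 1. A landmark
#' whose nearest grid point falls outside the frame yields an all-zero
#' channel with `visible = FALSE` (never an error).
#'
#' @param landmarks K x 2 matrix of `(x, y)` landmark coordinates in
#'   heatmap pixel units.
#' @param config A [codec_config].
#' @return A list of class `heatmap_stack`: `values` (K x H x W array in
#'   `[0, 1]`), `visible` (logical K), `config`.
#' @export
encode_landmarks <- function(landmarks, config = codec_config()) {
  landmarks <- matrix(as.numeric(landmarks), ncol = 2)
  K <- nrow(landmarks)
  H <- config$height; W <- config$width
  vals <- array(0, dim = c(K, H, W))
  visible <- rep(TRUE, K)
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  for (k in seq_len(K)) {
    p <- landmarks[k, ]
    if (round(p[1]) < 1 || round(p[1]) > W || round(p[2]) < 1 ||
        round(p[2]) > H || anyNA(p)) {
      visible[k] <- FALSE
      next
    }
    d2 <- (xs - p[1])^2 + (ys - p[2])^2
    g <- exp(-d2 / (2 * config$sigma^2))
    g[d2 > config$truncation_radius^2] <- 0
    vals[k, , ] <- g / max(g)
  }
  structure(list(values = vals, visible = visible, config = config),
            class = "heatmap_stack")
}

#' Decode heatmaps to landmark coordinates
#'
#' Per channel, the argmax pixel (first in row-major scan order on ties,
#' i.e. scanning y then x) refined by a quarter-pixel shift toward the
#' larger of the two neighbours in each axis, with the channel maximum as
#' confidence. An all-zero channel decodes to `NA` coordinates with
#' confidence 0.
#'
#' @param stack A `heatmap_stack` (or a bare K x H x W array).
#' @param refine Apply the quarter-pixel refinement (default) or return the
#'   bare argmax.
#' @return Tibble with columns `x`, `y`, `confidence`, `detected`.
#' @export
decode_heatmaps <- function(stack, refine = TRUE) {
  vals <- if (inherits(stack, "heatmap_stack")) stack$values else stack
  stopifnot(length(dim(vals)) == 3L)
  K <- dim(vals)[1]; H <- dim(vals)[2]; W <- dim(vals)[3]
  out <- matrix(NA_real_, K, 3)
  for (k in seq_len(K)) {
    ch <- matrix(vals[k, , ], H, W)
    m <- max(ch)
    if (m <= 0) { out[k, ] <- c(NA, NA, 0); next }
    # row-major scan order: first by y (row), then x within the row
    hits <- which(ch == m, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    y0 <- hits[1, 1]; x0 <- hits[1, 2]
    x <- x0; y <- y0
    if (refine) {
      left  <- if (x0 > 1) ch[y0, x0 - 1] else -Inf
      right <- if (x0 < W) ch[y0, x0 + 1] else -Inf
      if (right > left) x <- x + 0.25 else if (left > right) x <- x - 0.25
      up   <- if (y0 > 1) ch[y0 - 1, x0] else -Inf
      down <- if (y0 < H) ch[y0 + 1, x0] else -Inf
      if (down > up) y <- y + 0.25 else if (up > down) y <- y - 0.25
    }
    out[k, ] <- c(x, y, m)
  }
  tibble(x = out[, 1], y = out[, 2], confidence = out[, 3],
         detected = out[, 3] > 0)
}

#' Encode inter-landmark edges as normalised vectors
#'
#' For edge `(a, b)`, `vector = (p_b - p_a) / ||p_b - p_a||`. Degenerate
#' edges (length below 1e-9) yield the zero vector and are flagged, never
#' thrown.
#'
#' @param landmarks K x 2 coordinate matrix.
#' @param edges Two-column index matrix (defaults to [default_edges]).
#' @return Tibble with columns `a`, `b`, `vx`, `vy`, `degenerate`.
#' @export
encode_edges <- function(landmarks, edges = default_edges()) {
  landmarks <- matrix(as.numeric(landmarks), ncol = 2)
  edges <- as.matrix(edges)
  stopifnot(max(edges) <= nrow(landmarks), min(edges) >= 1)
  d <- landmarks[edges[, 2], , drop = FALSE] -
    landmarks[edges[, 1], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  deg <- len < 1e-9
  v <- d / ifelse(deg, 1, len)
  v[deg, ] <- 0
  tibble(a = edges[, 1], b = edges[, 2], vx = v[, 1], vy = v[, 2],
         degenerate = deg)
}
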