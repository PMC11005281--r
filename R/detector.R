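# Two-branch landmark detector: Gaussian-heatmap regression head plus an
# edge-vector constraint head over a shared two-stream multi-resolution
# backbone (parallel high/low-resolution convolution streams with repeated
# cross-resolution fusion, in the high-resolution-network style, scaled to
# desk size through `backbone_width`).

#' Detector configuration
#'
#' Defaults follow the reference training protocol (640 x 320 input at
#' 0.79 mm/pixel, 200 epochs, batch 32, learning rate 1e-3 stepped down
#' tenfold at epochs 120 and 170); tests and desk-scale runs override them
#' with a smaller frame and schedule.
#'
#' @param input_height,input_width Model input frame (pixels); both must be
#'   divisible by the backbone stride (8).
#' @param target_spacing_mm Isotropic pixel spacing images are resampled to
#'   (mm/pixel).
#' @param backbone_width Channel multiplier of the high-resolution stream
#'   (the low-resolution stream gets twice this).
#' @param epochs,batch_size Optimisation schedule.
#' @param lr_initial Initial Adam learning rate.
#' @param lr_steps Epochs (strictly increasing, < `epochs`) at which the
#'   rate drops by `lr_factor`.
#' @param lr_factor Multiplicative drop at each step.
#' @param edge_loss_weight Weight of the edge-vector MSE term (>= 0; the
#'   edge branch is a training-time constraint only and is unused at
#'   inference).
#' @param heatmap_peak_weight Foreground emphasis `c` of the heatmap loss:
#'   each pixel's squared error is weighted `1 + c * target`, so `c = 0`
#'   is the plain mean-squared error. Target blobs cover well under 2% of
#'   the heatmap area; without emphasis their gradient contribution is
#'   diluted by the background and short schedules leave channels for
#'   appearance-poor landmarks unformed.
#' @param sigma Gaussian sigma of the target heatmaps (heatmap pixels).
#' @param heatmap_stride Output stride of the heatmap head, 1 or 2. Stride
#'   2 halves the head cost; stride 1 halves the decode quantisation floor,
#'   which matters for angles measured over short joint lines.
#' @param detection_threshold Minimum peak confidence for a landmark to
#'   count as detected.
#' @param augment Named logical toggles: `flip` (horizontal mirror, turning
#'   the limb into its contralateral counterpart with landmark identities
#'   preserved), `rotate` (within +/- 5 degrees),
#'   `intensity` (+/- 10% scaling), `noise` (mild additive Gaussian).
#' @param frame_mode Only `"per_side"` is supported: each limb is cropped
#'   and measured separately, with one 10-channel heatmap stack per limb.
#' @param seed Seed controlling initialisation and the training stream.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(input_height = 640L, input_width = 320L,
                            target_spacing_mm = 0.79,
                            backbone_width = 8L,
                            epochs = 200L, batch_size = 32L,
                            lr_initial = 1e-3, lr_steps = c(120L, 170L),
                            lr_factor = 0.1,
                            edge_loss_weight = 0.1,
                            heatmap_peak_weight = 20,
                            sigma = 2, detection_threshold = 0.3,
                            heatmap_stride = 2L,
                            augment = c(flip = TRUE, rotate = TRUE,
                                        intensity = TRUE, noise = TRUE),
                            frame_mode = "per_side",
                            seed = 1L) {
  if (input_height %% 8L != 0L || input_width %% 8L != 0L)
    abort("Input dimensions must be divisible by the backbone stride (8).",
          class = "limbalign_config_error")
  if (length(lr_steps) && (is.unsorted(lr_steps, strictly = TRUE) ||
                           any(lr_steps >= epochs) || any(lr_steps < 1)))
    abort("`lr_steps` must be strictly increasing and below `epochs`.",
          class = "limbalign_config_error")
  if (edge_loss_weight < 0)
    abort("`edge_loss_weight` must be >= 0.", class = "limbalign_config_error")
  if (!heatmap_stride %in% c(1L, 2L))
    abort("`heatmap_stride` must be 1 or 2.", class = "limbalign_config_error")
  if (!identical(frame_mode, "per_side"))
    abort("Only `frame_mode = \"per_side\"` is supported.",
          class = "limbalign_config_error")
  structure(list(
    input_height = as.integer(input_height),
    input_width = as.integer(input_width),
    target_spacing_mm = target_spacing_mm,
    backbone_width = as.integer(backbone_width),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    lr_initial = lr_initial, lr_steps = as.integer(lr_steps),
    lr_factor = lr_factor, edge_loss_weight = edge_loss_weight,
    heatmap_peak_weight = heatmap_peak_weight,
    sigma = sigma, detection_threshold = detection_threshold,
    heatmap_stride = as.integer(heatmap_stride),
    augment = augment, frame_mode = frame_mode, seed = as.integer(seed),
    n_landmarks = 10L, edges = default_edges()),
    class = "detector_config")
}

heatmap_dims <- function(config)
  c(config$input_height %/% config$heatmap_stride,
    config$input_width %/% config$heatmap_stride)

# input-frame coordinate -> heatmap-grid coordinate (pixel-centre aligned),
# and back.
input_to_heatmap <- function(x, stride = 2L) (x - 0.5) / stride + 0.5
heatmap_to_input <- function(x, stride = 2L) (x - 0.5) * stride + 0.5

#' Resample an image to the model frame
#'
#' Bilinear resize to the configured isotropic spacing, aspect ratio
#' preserved, centred with padding in the target frame, then standardised
#' to zero mean / unit variance. When `spacing_mm` is `NA` (portable-photo
#' mode) the image is scaled to fill the frame instead. The returned
#' metadata is an exact invertible affine between original and model pixel
#' coordinates.
#'
#' @param image Numeric H x W matrix (grayscale, any intensity range) or an
#'   H x W x C array (channels are averaged).
#' @param spacing_mm Pixel spacing of `image`, or `NA` when unknown.
#' @param config A [detector_config].
#' @return List: `tensor` (input_height x input_width standardised matrix),
#'   `meta` (scale `f`, offsets `ox`/`oy`, `out_spacing_mm`).
#' @export
preprocess_image <- function(image, spacing_mm = NA_real_,
                             config = detector_config()) {
  if (length(dim(image)) == 3L) image <- apply(image, c(1, 2), mean)
  if (!is.matrix(image) || nrow(image) < 2L || ncol(image) < 2L)
    abort("`image` must be a numeric matrix with at least 2 x 2 pixels.",
          class = "limbalign_preprocess_error")
  if (max(image) - min(image) < 1e-12)
    abort("Constant image: nothing to detect.",
          class = "limbalign_preprocess_error")
  H <- nrow(image); W <- ncol(image)
  th <- config$input_height; tw <- config$input_width
  fit <- min(th / H, tw / W)
  f <- if (is.na(spacing_mm)) fit else min(spacing_mm / config$target_spacing_mm, fit)
  ox <- (tw - W * f) / 2
  oy <- (th - H * f) / 2
  # output pixel (x, y) samples input at ((x - 0.5 - ox)/f + 0.5, ...)
  A <- diag(c(1 / f, 1 / f))
  b <- c((-0.5 - ox) / f + 0.5, (-0.5 - oy) / f + 0.5)
  out <- warp_affine(image, A, b, out_h = th, out_w = tw, fill = min(image))
  out <- (out - mean(out)) / stats::sd(out)
  list(tensor = out,
       meta = list(f = f, ox = ox, oy = oy,
                   out_spacing_mm = if (is.na(spacing_mm)) NA_real_
                                    else spacing_mm / f))
}

#' Map coordinates between the original and model frames
#'
#' @param xy n x 2 matrix (or length-2 vector) of `(x, y)` coordinates.
#' @param meta Metadata returned by [preprocess_image].
#' @return Transformed n x 2 matrix.
#' @export
to_model_frame <- function(xy, meta) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  cbind((xy[, 1] - 0.5) * meta$f + 0.5 + meta$ox,
        (xy[, 2] - 0.5) * meta$f + 0.5 + meta$oy)
}

#' @rdname to_model_frame
#' @export
from_model_frame <- function(xy, meta) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  cbind((xy[, 1] - 0.5 - meta$ox) / meta$f + 0.5,
        (xy[, 2] - 0.5 - meta$oy) / meta$f + 0.5)
}

#' Build an untrained two-branch detector
#'
#' Three parallel streams (strides 2, 4 and 8 with widths w, 2w, 4w) with
#' two cross-resolution fusion exchanges per stage boundary, a heatmap head
#' on the high-resolution stream (one channel per landmark, output stride
#' 2) and an edge-vector head (one normalised 2-vector per configured
#' edge) on the pooled coarsest stream. The coarse stream gives the
#' receptive field needed to place landmarks defined by long-range
#' geometry, such as diaphysis centres. Seeded He-normal initialisation.
#'
#' @param config A [detector_config].
#' @return List of class `detector_model` with `params`, `config`.
#' @export
build_detector <- function(config = detector_config()) {
  w1 <- config$backbone_width; w2 <- 2L * w1; w4 <- 4L * w1
  K <- config$n_landmarks; E <- nrow(config$edges)
  params <- with_seed(config$seed, list(
    stem = he_conv(w1, 3L, 3L),   # image + two coordinate-encoding channels
    hr0 = he_conv(w1, w1, 3L),
    down0 = he_conv(w2, w1, 3L),
    down1 = he_conv(w4, w2, 3L),
    hr_1 = he_conv(w1, w1, 3L), md_1 = he_conv(w2, w2, 3L),
    lo_1 = he_conv(w4, w4, 3L),
    upm_1 = he_conv(w1, w2, 1L), upl_1 = he_conv(w2, w4, 1L),
    dnm_1 = he_conv(w2, w1, 3L), dnl_1 = he_conv(w4, w2, 3L),
    hr_2 = he_conv(w1, w1, 3L), md_2 = he_conv(w2, w2, 3L),
    lo_2 = he_conv(w4, w4, 3L),
    upm_2 = he_conv(w1, w2, 1L), upl_2 = he_conv(w2, w4, 1L),
    dnm_2 = he_conv(w2, w1, 3L), dnl_2 = he_conv(w4, w2, 3L),
    headh1 = he_conv(w2, w1, 3L),
    headh2 = he_conv(K, w2, 1L),
    heade1 = he_conv(w4, w4, 3L),
    edge = he_dense(2L * E, w4)))
  structure(list(params = params, config = config), class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model> width %d, %d landmarks, %d edges, %s parameters%s\n",
              x$config$backbone_width, x$config$n_landmarks,
              nrow(x$config$edges), format(n_params(x$params), big.mark = ","),
              if (is.null(x$records)) " (untrained)" else ""))
  invisible(x)
}

# Stack standardised image matrices into the (3, H, W, N) input tensor:
# channel 1 the image, channels 2-3 normalised x/y coordinate encodings.
# Convolutions are translation-equivariant, so absolute position along a
# homogeneous diaphysis is otherwise invisible at desk-scale depth; the
# coordinate channels supply it explicitly.
make_input_tensor <- function(tensors) {
  H <- nrow(tensors[[1]]); W <- ncol(tensors[[1]]); N <- length(tensors)
  x <- array(0, c(3L, H, W, N))
  cx <- matrix(seq_len(W) / W - 0.5, H, W, byrow = TRUE)
  cy <- matrix(seq_len(H) / H - 0.5, H, W)
  for (i in seq_len(N)) {
    x[1, , , i] <- tensors[[i]]
    x[2, , , i] <- cx
    x[3, , , i] <- cy
  }
  x
}

# Forward pass. x: (3, H, W, N). Returns heatmaps (K, H/2, W/2, N), edge
# vectors (2E, N) and, when `keep` is TRUE, the caches for backprop.
detector_forward <- function(params, x, keep = FALSE, hm_stride = 2L) {
  cc <- list()
  s <- conv_fwd(x, params$stem, stride = 2L);    a_stem <- relu_fwd(s$out)
  h0 <- conv_fwd(a_stem, params$hr0);            hr <- relu_fwd(h0$out)
  d0 <- conv_fwd(hr, params$down0, stride = 2L); md <- relu_fwd(d0$out)
  d1 <- conv_fwd(md, params$down1, stride = 2L); lo <- relu_fwd(d1$out)
  cc$s <- s; cc$h0 <- h0; cc$d0 <- d0; cc$d1 <- d1
  for (st in 1:2) {
    nm <- function(base) paste0(base, "_", st)
    hb_c <- conv_fwd(hr, params[[nm("hr")]]); hb <- relu_fwd(hb_c$out)
    mb_c <- conv_fwd(md, params[[nm("md")]]); mb <- relu_fwd(mb_c$out)
    lb_c <- conv_fwd(lo, params[[nm("lo")]]); lb <- relu_fwd(lb_c$out)
    upm_c <- conv_fwd(mb, params[[nm("upm")]])
    upl_c <- conv_fwd(lb, params[[nm("upl")]])
    dnm_c <- conv_fwd(hb, params[[nm("dnm")]], stride = 2L)
    dnl_c <- conv_fwd(mb, params[[nm("dnl")]], stride = 2L)
    hr_pre <- hb + upsample2_fwd(upm_c$out)
    md_pre <- mb + upsample2_fwd(upl_c$out) + dnm_c$out
    lo_pre <- lb + dnl_c$out
    hr <- relu_fwd(hr_pre); md <- relu_fwd(md_pre); lo <- relu_fwd(lo_pre)
    cc[[nm("stage")]] <- list(hb_c = hb_c, mb_c = mb_c, lb_c = lb_c,
                              upm_c = upm_c, upl_c = upl_c,
                              dnm_c = dnm_c, dnl_c = dnl_c,
                              hr_pre = hr_pre, md_pre = md_pre,
                              lo_pre = lo_pre)
  }
  hr_head <- if (hm_stride == 1L) upsample2_fwd(hr) else hr
  hh_c <- conv_fwd(hr_head, params$headh1); hh <- relu_fwd(hh_c$out)
  hm_c <- conv_fwd(hh, params$headh2)
  eh_c <- conv_fwd(lo, params$heade1); eh <- relu_fwd(eh_c$out)
  g <- gap_fwd(eh)
  ev <- dense_fwd(g, params$edge)
  cc$hh_c <- hh_c; cc$hm_c <- hm_c; cc$eh_c <- eh_c
  cc$eh <- eh; cc$g <- g
  list(heatmaps = hm_c$out, edges = ev, cache = if (keep) cc else NULL)
}

# Backward pass from head gradients; returns the gradient list.
detector_backward <- function(params, cc, d_hm, d_ev, hm_stride = 2L) {
  gr <- list()
  de <- dense_bwd(d_ev, params$edge, cc$g)
  gr$edge <- list(W = de$dW, b = de$db)
  d_eh <- relu_bwd(gap_bwd(de$dx, dim(cc$eh)), cc$eh_c$out)
  be <- conv_bwd(d_eh, params$heade1, cc$eh_c$cache)
  gr$heade1 <- list(W = be$dW, b = be$db)
  d_lo <- be$dx

  bm <- conv_bwd(d_hm, params$headh2, cc$hm_c$cache)
  gr$headh2 <- list(W = bm$dW, b = bm$db)
  bh <- conv_bwd(relu_bwd(bm$dx, cc$hh_c$out), params$headh1, cc$hh_c$cache)
  gr$headh1 <- list(W = bh$dW, b = bh$db)
  d_hr <- if (hm_stride == 1L) upsample2_bwd(bh$dx) else bh$dx
  d_md <- NULL

  for (st in 2:1) {
    nm <- function(base) paste0(base, "_", st)
    sc <- cc[[nm("stage")]]
    d_hr_pre <- relu_bwd(d_hr, sc$hr_pre)
    d_md_pre <- if (is.null(d_md)) array(0, dim(sc$md_pre)) else
      relu_bwd(d_md, sc$md_pre)
    d_lo_pre <- relu_bwd(d_lo, sc$lo_pre)
    bupm <- conv_bwd(upsample2_bwd(d_hr_pre), params[[nm("upm")]],
                     sc$upm_c$cache)
    gr[[nm("upm")]] <- list(W = bupm$dW, b = bupm$db)
    bupl <- conv_bwd(upsample2_bwd(d_md_pre), params[[nm("upl")]],
                     sc$upl_c$cache)
    gr[[nm("upl")]] <- list(W = bupl$dW, b = bupl$db)
    bdnm <- conv_bwd(d_md_pre, params[[nm("dnm")]], sc$dnm_c$cache)
    gr[[nm("dnm")]] <- list(W = bdnm$dW, b = bdnm$db)
    bdnl <- conv_bwd(d_lo_pre, params[[nm("dnl")]], sc$dnl_c$cache)
    gr[[nm("dnl")]] <- list(W = bdnl$dW, b = bdnl$db)
    d_hb <- d_hr_pre + bdnm$dx
    d_mb <- d_md_pre + bupm$dx + bdnl$dx
    d_lb <- d_lo_pre + bupl$dx
    bhb <- conv_bwd(relu_bwd(d_hb, sc$hb_c$out), params[[nm("hr")]],
                    sc$hb_c$cache)
    gr[[nm("hr")]] <- list(W = bhb$dW, b = bhb$db)
    bmb <- conv_bwd(relu_bwd(d_mb, sc$mb_c$out), params[[nm("md")]],
                    sc$mb_c$cache)
    gr[[nm("md")]] <- list(W = bmb$dW, b = bmb$db)
    blb <- conv_bwd(relu_bwd(d_lb, sc$lb_c$out), params[[nm("lo")]],
                    sc$lb_c$cache)
    gr[[nm("lo")]] <- list(W = blb$dW, b = blb$db)
    d_hr <- bhb$dx; d_md <- bmb$dx; d_lo <- blb$dx
  }
  bd1 <- conv_bwd(relu_bwd(d_lo, cc$d1$out), params$down1, cc$d1$cache)
  gr$down1 <- list(W = bd1$dW, b = bd1$db)
  d_md <- d_md + bd1$dx
  bd0 <- conv_bwd(relu_bwd(d_md, cc$d0$out), params$down0, cc$d0$cache)
  gr$down0 <- list(W = bd0$dW, b = bd0$db)
  d_hr <- d_hr + bd0$dx
  bh0 <- conv_bwd(relu_bwd(d_hr, cc$h0$out), params$hr0, cc$h0$cache)
  gr$hr0 <- list(W = bh0$dW, b = bh0$db)
  bs <- conv_bwd(relu_bwd(bh0$dx, cc$s$out), params$stem, cc$s$cache)
  gr$stem <- list(W = bs$dW, b = bs$db)
  gr
}
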