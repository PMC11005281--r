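# Training loop and inference for the two-branch detector.

# Preprocess one (image, landmarks) pair into the model frame.
prepare_sample <- function(image, landmarks, config) {
  pp <- preprocess_image(image, landmarks$spacing_mm, config)
  list(tensor = pp$tensor, meta = pp$meta,
       xy = to_model_frame(landmarks$xy, pp$meta), side = landmarks$side)
}

augment_sample <- function(tensor, xy, config) {
  W <- ncol(tensor); H <- nrow(tensor)
  aug <- config$augment
  if (isTRUE(aug[["flip"]]) && stats::runif(1) < 0.5) {
    # mirroring turns a right limb into a left limb; lateral structures stay
    # lateral, so landmark identities are unchanged — only coordinates move
    tensor <- tensor[, W:1, drop = FALSE]
    xy[, 1] <- W + 1 - xy[, 1]
  }
  if (isTRUE(aug[["rotate"]])) {
    ang <- stats::runif(1, -5, 5)
    ctr <- c((W + 1) / 2, (H + 1) / 2)
    R <- rot2(ang)
    xy <- t(R %*% (t(xy) - ctr) + ctr)
    tensor <- warp_affine(tensor, t(R), as.numeric(ctr - t(R) %*% ctr),
                          fill = min(tensor))
  }
  if (isTRUE(aug[["intensity"]])) tensor <- tensor * stats::runif(1, 0.9, 1.1)
  if (isTRUE(aug[["noise"]]))
    tensor <- tensor + matrix(stats::rnorm(H * W, 0, 0.05), H, W)
  list(tensor = tensor, xy = xy)
}

# Heatmap + edge targets for a batch of model-frame landmark matrices.
make_targets <- function(xys, config) {
  hd <- heatmap_dims(config)
  K <- config$n_landmarks; E <- nrow(config$edges); n <- length(xys)
  cdc <- codec_config(sigma = config$sigma, height = hd[1], width = hd[2])
  hm <- array(0, c(K, hd[1], hd[2], n))
  ev <- matrix(0, 2L * E, n)
  for (i in seq_len(n)) {
    st <- encode_landmarks(input_to_heatmap(xys[[i]], config$heatmap_stride),
                            cdc)
    hm[, , , i] <- st$values
    e <- encode_edges(xys[[i]], config$edges)
    ev[, i] <- as.numeric(rbind(e$vx, e$vy))
  }
  list(heatmaps = hm, edges = ev)
}

lr_at_epoch <- function(config, epoch)
  config$lr_initial * config$lr_factor^sum(epoch > config$lr_steps)

#' Train the two-branch detector
#'
#' Minimises mean-squared heatmap error plus `edge_loss_weight` times the
#' mean-squared error between predicted and target normalised edge vectors,
#' with Adam and the stepped learning-rate schedule of the config. All
#' randomness (initialisation, shuffling, augmentation) runs on the seeded
#' stream, so identical configs give identical loss curves.
#'
#' @param samples List of training samples; each needs an `image` matrix
#'   and a `landmarks` [limb_landmarks] (phantom samples from
#'   [render_phantom] work directly).
#' @param config A [detector_config].
#' @param val_samples Optional held-out samples; per-epoch mean radial
#'   error (model-frame pixels) is logged for them.
#' @param verbose Print per-epoch progress.
#' @return A `detector_model` with trained `params` and a `records` tibble
#'   (`epoch`, `train_loss`, `validation_mre`, `lr`).
#' @export
train_detector <- function(samples, config = detector_config(),
                           val_samples = NULL, verbose = FALSE) {
  if (length(samples) == 0) abort("Empty training set.")
  model <- build_detector(config)
  prep <- lapply(samples, function(s) prepare_sample(s$image, s$landmarks, config))
  vprep <- if (length(val_samples))
    lapply(val_samples, function(s) prepare_sample(s$image, s$landmarks, config))
  H <- config$input_height; W <- config$input_width
  n <- length(prep)
  state <- adam_init(model$params)
  params <- model$params
  records <- vector("list", config$epochs)

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at_epoch(config, epoch)
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1, n, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
        nb <- length(idx)
        tensors <- vector("list", nb)
        xys <- vector("list", nb)
        for (i in seq_len(nb)) {
          a <- augment_sample(prep[[idx[i]]]$tensor, prep[[idx[i]]]$xy, config)
          tensors[[i]] <- a$tensor
          xys[[i]] <- a$xy
        }
        x <- make_input_tensor(tensors)
        tg <- make_targets(xys, config)
        fw <- detector_forward(params, x, keep = TRUE,
                               hm_stride = config$heatmap_stride)
        r_hm <- fw$heatmaps - tg$heatmaps
        r_ev <- fw$edges - tg$edges
        wt <- 1 + config$heatmap_peak_weight * tg$heatmaps
        loss <- mean(wt * r_hm^2) + config$edge_loss_weight * mean(r_ev^2)
        if (!is.finite(loss))
          abort(sprintf(
            "Non-finite loss at epoch %d, batch starting at sample %d.",
            epoch, b0), class = "limbalign_training_error")
        d_hm <- 2 * wt * r_hm / length(r_hm)
        d_ev <- config$edge_loss_weight * 2 * r_ev / length(r_ev)
        gr <- detector_backward(params, fw$cache, d_hm, d_ev,
                                config$heatmap_stride)
        upd <- adam_step(params, gr, state, lr)
        params <- upd$params; state <- upd$state
        losses <- c(losses, loss)
      }
      vmre <- if (length(val_samples)) {
        err <- vapply(vprep, function(p) {
          dec <- decode_batch(params, p$tensor, config)
          mean(sqrt(rowSums((dec[, c("x", "y")] - p$xy)^2)))
        }, 1)
        mean(err)
      } else NA_real_
      records[[epoch]] <- tibble(epoch = epoch, train_loss = mean(losses),
                                 validation_mre = vmre, lr = lr)
      if (verbose)
        cat(sprintf("epoch %3d  loss %.5f  val MRE %s\n", epoch, mean(losses),
                    ifelse(is.na(vmre), "-", sprintf("%.2f px", vmre))))
    }
  })
  model$params <- params
  model$records <- dplyr::bind_rows(records)
  model
}

# Forward + decode one model-frame tensor; coordinates in model-frame pixels.
decode_batch <- function(params, tensor, config) {
  x <- make_input_tensor(list(tensor))
  fw <- detector_forward(params, x, hm_stride = config$heatmap_stride)
  hm <- fw$heatmaps[, , , 1, drop = FALSE]
  dim(hm) <- dim(fw$heatmaps)[1:3]
  dec <- decode_heatmaps(hm)
  m <- as.matrix(dec[, c("x", "y")])
  m <- heatmap_to_input(m, config$heatmap_stride)
  cbind(x = m[, 1], y = m[, 2], confidence = dec$confidence)
}

#' Detect landmarks on one image
#'
#' Runs preprocessing, the forward pass, heatmap decoding and the inverse
#' coordinate mapping. The joint counts as not detected when any
#' landmark's peak confidence falls below the configured threshold; low
#' confidence is reported, never thrown.
#'
#' @param image Numeric image matrix (grayscale `[0, 1]` or any range).
#' @param model A trained `detector_model`.
#' @param spacing_mm Pixel spacing, or `NA` for portable-photo images of
#'   unknown scale.
#' @return Tibble with one row per landmark (`landmark`, `x`, `y` in
#'   original image pixels, `confidence`, `detected`) and attribute
#'   `joint_detected`.
#' @export
predict_landmarks <- function(image, model, spacing_mm = NA_real_) {
  config <- model$config
  pp <- preprocess_image(image, spacing_mm, config)
  dec <- decode_batch(model$params, pp$tensor, config)
  xy <- from_model_frame(dec[, c("x", "y")], pp$meta)
  out <- tibble(landmark = landmark_names(), x = xy[, 1], y = xy[, 2],
                confidence = dec[, "confidence"],
                detected = dec[, "confidence"] >= config$detection_threshold)
  attr(out, "joint_detected") <- all(out$detected)
  out
}

#' Predicted landmarks as a measurable limb
#'
#' @param prediction Output of [predict_landmarks].
#' @param side `"left"` or `"right"`.
#' @param spacing_mm Pixel spacing to record.
#' @return A [limb_landmarks], or `NULL` when the joint was not detected or
#'   the predicted geometry is invalid (failed detection is a value, not an
#'   exception).
#' @export
prediction_to_limb <- function(prediction, side, spacing_mm = NA_real_) {
  if (!isTRUE(attr(prediction, "joint_detected"))) return(NULL)
  tryCatch(
    limb_landmarks(prediction[, c("landmark", "x", "y")], side = side,
                   spacing_mm = spacing_mm),
    error = function(e) {
      warn(paste("Predicted landmarks do not form a valid limb:",
                 conditionMessage(e)))
      NULL
    })
}
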