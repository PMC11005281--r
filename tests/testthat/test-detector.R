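test_that("preprocessing resamples to the target spacing and inverts exactly", {
  cfg <- detector_config(input_height = 640L, input_width = 320L)
  # identity case: image already at target size and spacing
  set.seed(1)
  img <- matrix(stats::runif(640 * 320), 640, 320)
  pp <- preprocess_image(img, spacing_mm = 0.79, cfg)
  expect_equal(pp$meta$f, 1)
  expect_equal(to_model_frame(c(37.5, 200.25), pp$meta), rbind(c(37.5, 200.25)))
  expect_equal(abs(mean(pp$tensor)), 0, tolerance = 1e-9)
  expect_equal(stats::sd(pp$tensor), 1, tolerance = 1e-9)

  # a 2021 x 1011 half-frame crop at 0.2 mm/px lands on the 0.79 mm grid
  img2 <- matrix(stats::runif(2021 * 40), 2021, 40) # thin stand-in, same height
  pp2 <- preprocess_image(img2, spacing_mm = 0.2, cfg)
  expect_equal(pp2$meta$f, 0.2 / 0.79, tolerance = 1e-12)
  expect_equal(pp2$meta$out_spacing_mm, 0.79, tolerance = 1e-12)

  # affine round trip to 1e-9 px
  set.seed(2)
  pts <- cbind(stats::runif(50, 1, 2021), stats::runif(50, 1, 40))
  back <- from_model_frame(to_model_frame(pts, pp2$meta), pp2$meta)
  expect_lt(max(abs(back - pts)), 1e-9)

  expect_error(preprocess_image(matrix(1, 50, 50), 1, cfg),
               class = "limbalign_preprocess_error")
  expect_error(preprocess_image(matrix(1, 1, 1), 1, cfg),
               class = "limbalign_preprocess_error")
})

test_that("configuration invariants are enforced", {
  expect_error(detector_config(input_height = 130L),
               class = "limbalign_config_error")
  expect_error(detector_config(lr_steps = c(170L, 120L)),
               class = "limbalign_config_error")
  expect_error(detector_config(lr_steps = c(250L)),
               class = "limbalign_config_error")
  expect_error(detector_config(edge_loss_weight = -1),
               class = "limbalign_config_error")
  expect_error(detector_config(frame_mode = "full_frame"),
               class = "limbalign_config_error")
  cfg <- detector_config()
  expect_equal(c(cfg$input_height, cfg$input_width), c(640L, 320L))
  expect_equal(cfg$target_spacing_mm, 0.79)
  expect_equal(cfg$lr_initial, 1e-3)
  expect_equal(cfg$lr_steps, c(120L, 170L))
  expect_equal(limbalign:::lr_at_epoch(cfg, 1), 1e-3)
  expect_equal(limbalign:::lr_at_epoch(cfg, 121), 1e-4)
  expect_equal(limbalign:::lr_at_epoch(cfg, 171), 1e-5)
})

test_that("the network honours its shape contract and determinism", {
  cfg <- detector_config(input_height = 32L, input_width = 16L,
                         backbone_width = 4L, seed = 2L)
  model <- build_detector(cfg)
  x <- limbalign:::make_input_tensor(lapply(1:3, function(i)
    matrix(stats::rnorm(32 * 16), 32, 16)))
  fw <- limbalign:::detector_forward(model$params, x)
  expect_equal(dim(fw$heatmaps), c(10, 16, 8, 3))
  expect_equal(dim(fw$edges), c(2 * nrow(cfg$edges), 3))
  # evaluation passes are bitwise identical
  fw2 <- limbalign:::detector_forward(model$params, x)
  expect_identical(fw$heatmaps, fw2$heatmaps)
  expect_identical(fw$edges, fw2$edges)
  # doubling the width strictly increases the parameter count
  m2 <- build_detector(detector_config(input_height = 32L, input_width = 16L,
                                       backbone_width = 8L))
  expect_gt(limbalign:::n_params(m2$params),
            limbalign:::n_params(model$params))
  # same seed, same initial weights
  m3 <- build_detector(cfg)
  expect_identical(model$params, m3$params)
})

test_that("backpropagation matches central finite differences", {
  cfg <- detector_config(input_height = 8L, input_width = 8L,
                         backbone_width = 2L, seed = 3L)
  p <- build_detector(cfg)$params
  set.seed(4)
  # nudge biases off zero so no pre-activation sits exactly on the ReLU kink
  for (nm in names(p)) p[[nm]]$b <- p[[nm]]$b +
      stats::runif(length(p[[nm]]$b), 0.01, 0.05)
  x <- array(stats::rnorm(3 * 64), c(3, 8, 8, 1))
  E <- nrow(cfg$edges)
  t_hm <- array(stats::runif(10 * 16), c(10, 4, 4, 1))
  t_ev <- matrix(stats::runif(2 * E), 2 * E, 1)
  lossfn <- function(pp) {
    fw <- limbalign:::detector_forward(pp, x)
    mean((fw$heatmaps - t_hm)^2) + 0.1 * mean((fw$edges - t_ev)^2)
  }
  fw <- limbalign:::detector_forward(p, x, keep = TRUE)
  gr <- limbalign:::detector_backward(
    p, fw$cache, 2 * (fw$heatmaps - t_hm) / length(t_hm),
    0.1 * 2 * (fw$edges - t_ev) / length(t_ev))
  eps <- 1e-6
  for (nm in names(p)) for (f in c("W", "b")) {
    arr <- p[[nm]][[f]]
    idx <- sample(length(arr), min(6, length(arr)))
    for (i in idx) {
      p2 <- p; p2[[nm]][[f]][i] <- p2[[nm]][[f]][i] + eps
      p3 <- p; p3[[nm]][[f]][i] <- p3[[nm]][[f]][i] - eps
      num <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
      expect_equal(gr[[nm]][[f]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("an oracle network that emits the encoded truth round-trips", {
  # full predict path fidelity: preprocess -> (oracle heatmaps) -> decode ->
  # inverse mapping recovers the landmarks to the decode bound
  cfg <- detector_config(input_height = 128L, input_width = 64L)
  sp <- sample_phantom_specs(1, desk_cohort(), seed = 21)
  s <- render_phantom(sp)
  pp <- preprocess_image(s$image, sp$spacing_mm, cfg)
  xy_model <- to_model_frame(s$landmarks$xy, pp$meta)
  hd <- limbalign:::heatmap_dims(cfg)
  st <- encode_landmarks(limbalign:::input_to_heatmap(xy_model),
                         codec_config(sigma = cfg$sigma, height = hd[1],
                                      width = hd[2]))
  dec <- decode_heatmaps(st)
  back <- from_model_frame(
    limbalign:::heatmap_to_input(cbind(dec$x, dec$y)), pp$meta)
  err <- sqrt(rowSums((back - s$landmarks$xy)^2))
  # 0.5 heatmap px bound, times stride 2, over the preprocess scale factor
  expect_lt(max(err), 0.5 * 2 / pp$meta$f + 1e-9)
})

test_that("mirroring a limb preserves landmark identities and angles", {
  # a mirrored right limb is a left limb whose lateral structures are still
  # lateral: same labels, same angles under the flipped side label
  lm <- limb_from_angles(-6, side = "right", image_height = 128,
                         image_width = 64)
  xy <- lm$xy
  xy[, 1] <- 64 + 1 - xy[, 1]
  a <- measure_limb(limb_landmarks(xy, "left", 1))
  expect_equal(a$hka, -6, tolerance = 1e-9)
  expect_equal(a$mldfa, measure_limb(lm)$mldfa, tolerance = 1e-9)
})

test_that("a short training run is seed-deterministic and reduces the loss", {
  cohort <- phantom_cohort(image_height = 64, image_width = 32,
                           spacing_mm = 5.5, noise_sd = 0.02)
  specs <- sample_phantom_specs(12, cohort, seed = 15)
  samples <- lapply(seq_len(12), function(i) render_phantom(specs[i, ]))
  cfg <- detector_config(input_height = 64L, input_width = 32L,
                         backbone_width = 2L, epochs = 4L, batch_size = 6L,
                         lr_steps = integer(0), seed = 6L)
  fit1 <- train_detector(samples[1:10], cfg, val_samples = samples[11:12])
  fit2 <- train_detector(samples[1:10], cfg)
  expect_equal(tidy(fit1)$train_loss, tidy(fit2)$train_loss)
  r <- tidy(fit1)
  expect_lt(r$train_loss[4], r$train_loss[1])
  expect_true(all(is.finite(r$train_loss)))
  expect_true(all(is.finite(r$validation_mre)))
  expect_equal(glance(fit1)$epochs_trained, 4L)
  # edge_loss_weight = 0 reduces to pure heatmap regression and still runs
  cfg0 <- detector_config(input_height = 64L, input_width = 32L,
                          backbone_width = 2L, epochs = 2L, batch_size = 6L,
                          edge_loss_weight = 0, lr_steps = integer(0),
                          seed = 6L)
  fit0 <- train_detector(samples[1:6], cfg0)
  expect_true(all(is.finite(tidy(fit0)$train_loss)))
})

test_that("prediction output respects the detection threshold contract", {
  cfg <- detector_config(input_height = 32L, input_width = 16L,
                         backbone_width = 2L, seed = 2L,
                         detection_threshold = 1e6)  # unreachable on purpose
  model <- build_detector(cfg)
  img <- matrix(stats::runif(64 * 32), 64, 32)
  pred <- predict_landmarks(img, model, spacing_mm = NA)
  expect_equal(nrow(pred), 10)
  expect_false(any(pred$detected))
  expect_false(isTRUE(attr(pred, "joint_detected")))
  expect_null(prediction_to_limb(pred, "right"))
})
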