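# Synthetic AP long-leg radiograph phantoms with exactly known landmarks.
#
# The generator is the package's study-condition module: every rendered
# sample carries analytic ground-truth landmarks whose measured angles
# reproduce the generating parameters to < 0.01 degrees, which ties the
# phantom and geometry modules together as mutual tests.

# direction vector at angle `a` (radians) from the down-vertical, measured
# toward +x (the canonical medial direction); y increases downward.
dirv <- function(a) c(sin(a), cos(a))

rot2 <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Joint-line closure identity of the planar limb model
#'
#' In any planar limb whose joint lines are rigid line segments, the five
#' alignment angles are over-determined: the joint line convergence angle is
#' fixed by the other three line-to-line relations,
#' `JCLA = mMPTA - mLDFA - HKA` (all in the package's sign conventions).
#' The phantom generator therefore samples HKA, AMA, mLDFA and mMPTA and
#' derives JCLA from this identity.
#'
#' @param hka,mldfa,mmpta Angles in degrees.
#' @return JCLA in degrees (positive = medial convergence).
#' @export
jcla_closure <- function(hka, mldfa, mmpta) mmpta - mldfa - hka

#' Construct limb landmarks analytically from alignment angles
#'
#' Places the ten landmarks of a stylized planar limb so that
#' [measure_limb] recovers `hka`, `ama`, `mldfa` and `mmpta` exactly (and
#' JCLA equals [jcla_closure] of the three line angles). The limb is built
#' in a canonical medial-right frame and mirrored for the left side.
#'
#' @param hka Hip-knee-ankle angle in degrees (negative = varus).
#' @param ama Anatomical-mechanical angle in degrees (unsigned).
#' @param mldfa,mmpta Mechanical lateral distal femoral / medial proximal
#'   tibial angles in degrees.
#' @param side `"left"` or `"right"`.
#' @param image_height,image_width Frame size in pixels the limb is scaled to.
#' @param spacing_mm Pixel spacing recorded on the landmark set.
#' @param limb_frac Fraction of the frame height spanned hip-to-ankle.
#' @param condyle_frac Condyle/plateau half-width as a fraction of frame
#'   height.
#' @return A [limb_landmarks] object.
#' @examples
#' measure_limb(limb_from_angles(hka = -8, side = "left"))
#' @export
limb_from_angles <- function(hka, ama = 6, mldfa = 88, mmpta = 87,
                             side = c("right", "left"),
                             image_height = 440, image_width = 220,
                             spacing_mm = NA_real_,
                             limb_frac = 0.86, condyle_frac = 0.052) {
  side <- match.arg(side)
  rad <- pi / 180
  h <- hka * rad
  af <- h / 2          # femoral mechanical axis tilt (HKA = af - at)
  at <- -h / 2
  gap <- 0.016 * image_height
  L <- limb_frac * image_height
  lf <- lt <- (L - gap) / 2
  cw <- condyle_frac * image_height

  knee <- c(image_width / 2, image_height * (1 - limb_frac) / 2 + lf)
  v4 <- knee
  v7 <- knee + c(0, gap)
  v1 <- v4 - lf * dirv(af)
  v10 <- v7 + lt * dirv(at)
  v2 <- v4 - 0.55 * lf * dirv(af - ama * rad)     # shaft lateral of mech axis
  jf <- dirv(af + pi + mldfa * rad)               # femoral joint line, lateral dir
  v3 <- v4 + cw * jf
  v5 <- v4 - cw * jf
  td <- dirv(at + mmpta * rad)                    # tibial joint line, medial dir
  v8 <- v7 + cw * td
  v6 <- v7 - cw * td
  v9 <- v7 + 0.5 * lt * dirv(at)

  xy <- rbind(v1, v2, v3, v4, v5, v6, v7, v8, v9, v10)
  rownames(xy) <- landmark_names()
  if (side == "left") xy[, 1] <- image_width + 1 - xy[, 1]
  limb_landmarks(xy, side = side, spacing_mm = spacing_mm)
}

#' Neutral reference limb
#'
#' A symmetric limb (vertical mechanical axes, horizontal parallel joint
#' lines when all defaults are kept) used in examples and tests.
#'
#' @inheritParams limb_from_angles
#' @param ... Passed to [limb_from_angles].
#' @return A [limb_landmarks] object.
#' @export
neutral_limb <- function(hka = 0, ama = 6, mldfa = 90, mmpta = 90,
                         side = "right", ...) {
  limb_from_angles(hka = hka, ama = ama, mldfa = mldfa, mmpta = mmpta,
                   side = side, ...)
}

#' Cohort parameters for the phantom sampler
#'
#' Defaults emulate a knee-osteoarthritis surgical cohort: alignment class
#' mixture 54.5% varus / 30.7% neutral / 14.8% valgus, HKA uniform within
#' the class band (varus -12..-2, neutral -2..2, valgus 2..12 degrees), AMA
#' normal around 6 degrees, and mLDFA/mMPTA normal around centers that
#' shift with HKA (`bone_share` per bone) so that the derived JCLA keeps a
#' physiologic joint-line share of the deformity.
#'
#' @param weights Named mixture weights over `varus`, `neutral`, `valgus`;
#'   must sum to 1.
#' @param hka_bands 3 x 2 matrix of HKA band limits (rows varus/neutral/
#'   valgus).
#' @param ama_mean,ama_sd AMA distribution (degrees).
#' @param mldfa_center,mmpta_center Neutral-limb centers (degrees).
#' @param angle_sd Standard deviation of mLDFA and mMPTA (degrees).
#' @param bone_share Fraction of HKA expressed in each bone's joint-line
#'   angle (0 = all deformity intra-articular).
#' @param prosthesis_prob Probability a limb carries a knee prosthesis.
#' @param left_prob Probability of a left-side limb.
#' @param image_height,image_width Rendered frame size (pixels).
#' @param spacing_mm Pixel spacing written to ground truth (mm/pixel).
#' @param noise_sd Additive intensity noise (image in `[0, 1]`).
#' @param capture_degradation `"none"` (plain radiograph) or `"photo"`
#'   (portable-device capture emulation: small angle-preserving similarity
#'   jitter, vignetting, extra sensor noise).
#' @return A list of class `phantom_cohort`.
#' @export
phantom_cohort <- function(weights = c(varus = 0.545, neutral = 0.307,
                                       valgus = 0.148),
                           hka_bands = rbind(varus = c(-12, -2),
                                             neutral = c(-2, 2),
                                             valgus = c(2, 12)),
                           ama_mean = 6, ama_sd = 1,
                           mldfa_center = 88, mmpta_center = 87,
                           angle_sd = 1, bone_share = 0.35,
                           prosthesis_prob = 0.25, left_prob = 0.5,
                           image_height = 440, image_width = 220,
                           spacing_mm = 0.8, noise_sd = 0.03,
                           capture_degradation = c("none", "photo")) {
  if (length(weights) != 3L || is.null(names(weights)) ||
      !setequal(names(weights), c("varus", "neutral", "valgus")) ||
      any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    abort("`weights` must be nonnegative varus/neutral/valgus weights summing to 1.",
          class = "limbalign_config_error")
  capture_degradation <- match.arg(capture_degradation)
  structure(as.list(environment()), class = "phantom_cohort")
}

#' Sample phantom specifications from a cohort
#'
#' Draws the alignment class with the cohort mixture weights, HKA uniformly
#' within the class band, AMA / mLDFA / mMPTA from the cohort normals, and
#' derives JCLA from [jcla_closure]. Each spec carries its own render seed,
#' so a dataset is fully reproducible from the returned table.
#'
#' @param n Number of specs.
#' @param cohort A [phantom_cohort].
#' @param seed Integer seed for the sampling stream.
#' @return A tibble with one row per phantom: the five true angles, `side`,
#'   `has_prosthesis`, frame size, noise, degradation mode and `seed`.
#' @export
sample_phantom_specs <- function(n, cohort = phantom_cohort(), seed = 1L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    cls <- sample(c("varus", "neutral", "valgus"), n, replace = TRUE,
                  prob = cohort$weights[c("varus", "neutral", "valgus")])
    b <- cohort$hka_bands[cls, , drop = FALSE]
    hka <- stats::runif(n, b[, 1], b[, 2])
    ama <- pmin(pmax(stats::rnorm(n, cohort$ama_mean, cohort$ama_sd), 2), 12)
    mldfa <- pmin(pmax(stats::rnorm(n, cohort$mldfa_center -
                                      cohort$bone_share * hka, cohort$angle_sd),
                       80), 96)
    mmpta <- pmin(pmax(stats::rnorm(n, cohort$mmpta_center +
                                      cohort$bone_share * hka, cohort$angle_sd),
                       78), 96)
    tibble(
      phantom_id = sprintf("phantom_%04d", seq_len(n)),
      alignment_true = factor(cls, levels = c("varus", "neutral", "valgus")),
      hka_true = hka,
      jcla_true = jcla_closure(hka, mldfa, mmpta),
      ama_true = ama, mldfa_true = mldfa, mmpta_true = mmpta,
      side = sample(c("left", "right"), n, replace = TRUE,
                    prob = c(cohort$left_prob, 1 - cohort$left_prob)),
      has_prosthesis = stats::runif(n) < cohort$prosthesis_prob,
      image_height = cohort$image_height, image_width = cohort$image_width,
      spacing_mm = cohort$spacing_mm, noise_sd = cohort$noise_sd,
      capture_degradation = cohort$capture_degradation,
      seed = sample.int(.Machine$integer.max, n))
  })
}

# distance from every pixel centre to segment a-b (vectorized over pixels)
seg_dist <- function(px, py, a, b) {
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  l2 <- dx^2 + dy^2
  t <- if (l2 < 1e-12) rep(0, length(px)) else
    pmin(pmax(((px - a[1]) * dx + (py - a[2]) * dy) / l2, 0), 1)
  sqrt((px - (a[1] + t * dx))^2 + (py - (a[2] + t * dy))^2)
}

# anti-aliased solid of given radius around a segment
paint <- function(canvas, px, py, a, b, radius, level) {
  d <- seg_dist(px, py, a, b)
  cov <- pmin(pmax(radius - d + 0.5, 0), 1)
  pmax(canvas, level * cov)
}

# bilinear sampling of image `img` (H x W, y = row) at points (x, y);
# out-of-frame samples take the `fill` value.
bilinear_sample <- function(img, x, y, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  get <- function(xx, yy) {
    ok <- xx >= 1 & xx <= W & yy >= 1 & yy <= H
    v <- rep(fill, length(xx))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  (1 - fx) * (1 - fy) * get(x0, y0) + fx * (1 - fy) * get(x0 + 1, y0) +
    (1 - fx) * fy * get(x0, y0 + 1) + fx * fy * get(x0 + 1, y0 + 1)
}

# Affine warp: output pixel (x, y) takes the value of input point A %*% (x, y) + b.
# Pixel centres are 1-based integers in both frames.
warp_affine <- function(img, A, b, out_h = nrow(img), out_w = ncol(img),
                        fill = 0) {
  g <- expand.grid(x = seq_len(out_w), y = seq_len(out_h))
  src <- cbind(g$x, g$y) %*% t(A)
  vals <- bilinear_sample(img, src[, 1] + b[1], src[, 2] + b[2], fill = fill)
  matrix(vals, nrow = out_h, ncol = out_w, byrow = TRUE)
}

#' Render one phantom radiograph
#'
#' Draws the limb of a phantom spec as smooth capsule/disc silhouettes
#' (femoral shaft and head, condylar arcs whose lowest points realise
#' v3/v5, tibial plateau through v6/v8, tibial shaft, ankle) over a soft
#' tissue background, optionally replaces the condylar margins by a
#' high-intensity knee prosthesis, adds intensity noise, and for
#' `capture_degradation = "photo"` applies an angle-preserving similarity
#' jitter (<= 2 degrees), vignetting and extra sensor noise. The jitter is
#' reapplied to the ground-truth landmarks, so the returned landmarks stay
#' exact and their measured angles equal the spec angles.
#'
#' @param spec One row of [sample_phantom_specs] (or an equivalent named
#'   list).
#' @return A list of class `phantom_sample`: `image` (H x W matrix in
#'   `[0, 1]`), `landmarks` (a [limb_landmarks]) and `spec`.
#' @export
render_phantom <- function(spec) {
  spec <- as.list(spec)
  if (!is.null(spec$alignment_true)) spec$alignment_true <- as.character(spec$alignment_true)
  H <- spec$image_height; W <- spec$image_width
  lm <- limb_from_angles(hka = spec$hka_true, ama = spec$ama_true,
                         mldfa = spec$mldfa_true, mmpta = spec$mmpta_true,
                         side = spec$side, image_height = H, image_width = W,
                         spacing_mm = spec$spacing_mm)
  xy <- lm$xy
  margin <- 0.04 * H
  if (any(xy[, 1] < margin) || any(xy[, 1] > W - margin) ||
      any(xy[, 2] < margin) || any(xy[, 2] > H - margin))
    abort("Phantom geometry exceeds the frame; use a larger image.",
          class = "limbalign_frame_error")

  px <- rep(seq_len(W), each = H)   # column-major over (y, x)
  py <- rep(seq_len(H), times = W)
  rs <- 0.016 * H                   # shaft radius
  rc <- 0.026 * H                   # condyle radius
  rh <- 0.030 * H                   # femoral head radius
  bone <- 0.75; tissue <- 0.22

  v <- function(k) xy[k, ]
  img <- rep(0.04, H * W)
  img <- paint(img, px, py, v("v1"), v("v10"), 3.2 * rs, tissue)
  # femoral diaphysis runs through its own centre landmark v2 (the
  # mechanical axis v1->v4 is a chord of the bent femur, not the shaft)
  img <- paint(img, px, py, v("v1"), v("v2"), rs, bone)
  img <- paint(img, px, py, v("v2"), v("v4") + c(0, 0.02 * H), rs, bone)
  img <- paint(img, px, py, v("v7"), v("v10"), rs, bone)
  # chiral anatomy: the fibula flanks the tibia laterally and the greater
  # trochanter sits lateral of the femoral head — without them a limb
  # image carries no lateral/medial cue and the detection task would be
  # ill-posed (every real AP radiograph shows both)
  cw <- sqrt(sum((v("v6") - v("v8"))^2)) / 2
  lat_t <- v("v6") - v("v8"); lat_t <- lat_t / sqrt(sum(lat_t^2))
  fib_top <- v("v6") + 0.5 * cw * lat_t + c(0, 0.05 * H)
  fib_bot <- v("v10") + 1.6 * rs * lat_t + c(0, -0.01 * H)
  img <- paint(img, px, py, fib_top, fib_bot, 0.45 * rs, bone - 0.06)
  lat_f <- v("v3") - v("v5"); lat_f <- lat_f / sqrt(sum(lat_f^2))
  img <- paint(img, px, py, v("v1") + 1.2 * rh * lat_f + c(0, 0.2 * rh),
               v("v1") + 1.2 * rh * lat_f + c(0, 0.2 * rh), 0.75 * rh, bone)
  img <- paint(img, px, py, v("v1"), v("v1"), rh, bone + 0.05)
  img <- paint(img, px, py, v("v10"), v("v10"), 1.4 * rs, bone)
  if (isTRUE(spec$has_prosthesis)) {
    # femoral component over the condylar margins, tibial tray + stem
    img <- paint(img, px, py, v("v3") - c(0, rc), v("v5") - c(0, rc),
                 rc, 1.0)
    jn <- v("v8") - v("v6"); jn <- jn / sqrt(sum(jn^2))
    dn <- c(-jn[2], jn[1]); if (dn[2] < 0) dn <- -dn   # downward normal
    img <- paint(img, px, py, v("v6") + 0.45 * rc * dn,
                 v("v8") + 0.45 * rc * dn, 0.5 * rc, 1.0)
    img <- paint(img, px, py, v("v7"), v("v7") + c(0, 0.06 * H), 0.5 * rs, 1.0)
  } else {
    img <- paint(img, px, py, v("v3") - c(0, rc), v("v3") - c(0, rc), rc, bone)
    img <- paint(img, px, py, v("v5") - c(0, rc), v("v5") - c(0, rc), rc, bone)
    jn <- v("v8") - v("v6"); jn <- jn / sqrt(sum(jn^2))
    dn <- c(-jn[2], jn[1]); if (dn[2] < 0) dn <- -dn
    img <- paint(img, px, py, v("v6") + 0.6 * rc * dn,
                 v("v8") + 0.6 * rc * dn, 0.62 * rc, bone)
  }
  img <- matrix(img, nrow = H, ncol = W)   # (y, x)

  with_seed(spec$seed %||% 0L, {
    img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sd %||% 0), H, W)
    if (identical(spec$capture_degradation, "photo")) {
      ang <- stats::runif(1, -2, 2)
      sc <- stats::runif(1, 0.97, 1.03)
      sh <- stats::runif(2, -0.01, 0.01) * H
      ctr <- c((W + 1) / 2, (H + 1) / 2)
      R <- rot2(ang)
      # forward map: p' = sc * R %*% (p - ctr) + ctr + sh
      xy2 <- t(sc * R %*% (t(xy) - ctr) + ctr + sh)
      Ainv <- t(R) / sc
      binv <- ctr - Ainv %*% (ctr + sh)
      img <- warp_affine(img, Ainv, as.numeric(binv), fill = 0.04)
      yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
      r2 <- ((xx - ctr[1])^2 + (yy - ctr[2])^2) / sum((c(W, H) / 2)^2)
      img <- img * (1 - 0.30 * r2)
      img <- img + matrix(stats::rnorm(H * W, 0, 0.02), H, W)
      rownames(xy2) <- rownames(xy)
      lm <- limb_landmarks(xy2, side = lm$side, spacing_mm = lm$spacing_mm)
    }
    img <- pmin(pmax(img, 0), 1)
  })
  structure(list(image = img, landmarks = lm, spec = spec),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %dx%d %s limb, HKA %.2f deg%s\n",
              nrow(x$image), ncol(x$image), x$landmarks$side,
              x$spec$hka_true,
              if (isTRUE(x$spec$has_prosthesis)) " (prosthesis)" else ""))
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Renders `n` phantoms, writing one PNG per sample, a long-format
#' ground-truth landmark CSV (`landmarks.csv`, schema of [read_landmarks]),
#' a true-angle table (`angles.csv`) and a JSON manifest holding every spec
#' and seed, from which the dataset can be regenerated byte-identically.
#'
#' @param n Number of phantoms (>= 1).
#' @param dir Output directory (created if missing).
#' @param cohort A [phantom_cohort].
#' @param seed Master seed.
#' @return Invisibly, the manifest tibble (with an `image` column of file
#'   names).
#' @export
make_phantom_dataset <- function(n, dir, cohort = phantom_cohort(), seed = 1L) {
  if (n < 1) abort("`n` must be >= 1.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- sample_phantom_specs(n, cohort, seed = seed)
  specs$image <- paste0(specs$phantom_id, ".png")
  lms <- vector("list", n)
  for (i in seq_len(n)) {
    s <- render_phantom(specs[i, ])
    png::writePNG(s$image, file.path(dir, specs$image[i]))
    lms[[i]] <- dplyr::mutate(as_tibble(s$landmarks),
                              image_id = specs$phantom_id[i], .before = 1)
  }
  readr::write_csv(dplyr::bind_rows(lms), file.path(dir, "landmarks.csv"))
  readr::write_csv(
    specs[, c("phantom_id", "side", "alignment_true", "hka_true", "jcla_true",
              "ama_true", "mldfa_true", "mmpta_true", "has_prosthesis")],
    file.path(dir, "angles.csv"))
  jsonlite::write_json(list(seed = seed, n = n, specs = specs),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(specs)
}

#' Load phantom samples described by a dataset manifest
#'
#' @param dir Directory written by [make_phantom_dataset].
#' @return List of `phantom_sample`-like lists with `image`, `landmarks`,
#'   `spec`.
#' @export
load_phantom_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  specs <- as_tibble(man$specs)
  lmtab <- readr::read_csv(file.path(dir, "landmarks.csv"),
                           show_col_types = FALSE)
  purrr::map(seq_len(nrow(specs)), function(i) {
    sub <- lmtab[lmtab$image_id == specs$phantom_id[i], ]
    list(image = png::readPNG(file.path(dir, specs$image[i])),
         landmarks = limb_landmarks(sub[, c("landmark", "x", "y")],
                                    side = sub$side[1],
                                    spacing_mm = sub$spacing_mm[1]),
         spec = as.list(specs[i, ]))
  })
}
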