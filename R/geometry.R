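#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

#' Names of the ten lower-limb landmarks
#'
#' The landmark schema used throughout the package, ordered proximal to
#' distal: `v1` centre of the femoral head; `v2` centre of the femoral
#' diaphysis; `v3` lowest point of the lateral femoral condyle (or
#' prosthesis); `v4` centre of the knee joint on the femoral side; `v5`
#' lowest point of the medial femoral condyle; `v6` lowest point of the
#' lateral tibial plateau; `v7` centre of the knee joint on the tibial side;
#' `v8` lowest point of the medial tibial plateau; `v9` centre of the tibial
#' diaphysis; `v10` centre of the ankle joint.
#'
#' @return Character vector of length ten.
#' @export
landmark_names <- function() paste0("v", 1:10)

#' Construct the landmark set of one lower limb
#'
#' Bundles the ten named landmarks of a single limb with its side label and
#' pixel spacing. Coordinates are in image pixels with `y` increasing
#' downward (the usual raster convention).
#'
#' @param xy Numeric 10 x 2 matrix of `(x, y)` coordinates with rows named
#'   `v1`..`v10` (or in that order), or a data frame with columns
#'   `landmark`, `x`, `y`.
#' @param side `"left"` or `"right"` (the patient's side).
#' @param spacing_mm Physical size of one pixel in millimetres. May be `NA`
#'   for images of unknown spacing (angles are scale-invariant and remain
#'   valid; radial errors are then reported in pixels only).
#' @return An object of class `limb_landmarks`.
#' @examples
#' lm <- neutral_limb()
#' measure_limb(lm)
#' @export
limb_landmarks <- function(xy, side, spacing_mm = NA_real_) {
  if (is.data.frame(xy)) {
    stopifnot(all(c("landmark", "x", "y") %in% names(xy)))
    m <- as.matrix(xy[match(landmark_names(), xy$landmark), c("x", "y")])
    rownames(m) <- landmark_names()
    xy <- m
  }
  xy <- as.matrix(xy)
  if (nrow(xy) != 10L || ncol(xy) != 2L)
    abort("`xy` must be a 10 x 2 coordinate matrix (landmarks v1..v10).")
  if (is.null(rownames(xy))) rownames(xy) <- landmark_names()
  xy <- xy[landmark_names(), , drop = FALSE]
  colnames(xy) <- c("x", "y")
  storage.mode(xy) <- "double"
  if (anyNA(xy) || any(!is.finite(xy)))
    abort("All ten landmarks must be present with finite coordinates.")
  side <- match.arg(side, c("left", "right"))
  if (!is.na(spacing_mm) && spacing_mm <= 0)
    abort("`spacing_mm` must be positive (or NA when unknown).")
  if (!(xy["v1", "y"] < xy["v4", "y"] && xy["v4", "y"] < xy["v10", "y"]))
    abort(paste0(
      "Landmark ordering violated: the femoral head (v1) must lie above the ",
      "knee (v4), which must lie above the ankle (v10); y increases downward."))
  structure(list(xy = xy, side = side, spacing_mm = as.numeric(spacing_mm)),
            class = "limb_landmarks")
}

#' @export
print.limb_landmarks <- function(x, ...) {
  cat("<limb_landmarks> side:", x$side,
      " spacing:", if (is.na(x$spacing_mm)) "unknown" else
        paste0(x$spacing_mm, " mm/px"), "\n")
  print(round(x$xy, 2))
  invisible(x)
}

#' @export
as_tibble.limb_landmarks <- function(x, ...) {
  # hoist fields out of tibble's data mask: a column is named `x`
  xy <- x$xy; side <- x$side; spacing <- x$spacing_mm
  tibble(landmark = rownames(xy), x = xy[, "x"], y = xy[, "y"],
         side = side, spacing_mm = spacing)
}

# Medial direction along +x for the right limb, -x for the left: on an AP
# radiograph (viewed as facing the patient) the patient's right limb sits on
# the image left, its medial side toward the image centre.
side_sign <- function(side) if (side == "right") 1 else -1

#' Signed planar angle between two direction vectors
#'
#' The angle rotating `u` onto `v`, in degrees, in `(-180, 180]`. The sign is
#' positive when the rotation from `u` to `v` turns the `+x` axis toward the
#' `+y` axis (in the image frame used throughout, `x` right / `y` down).
#' Magnitude equals `acos` of the normalised dot product.
#'
#' @param u,v Numeric length-2 vectors; must be nonzero.
#' @return Signed angle in degrees.
#' @examples
#' signed_angle_between(c(0, 1), c(1, 1)) # -45
#' @export
signed_angle_between <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  stopifnot(length(u) == 2L, length(v) == 2L)
  if (!all(is.finite(c(u, v))))
    abort("Direction vectors must be finite.", class = "limbalign_geometry_error")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    abort("Zero-length direction vector: invalid geometry.",
          class = "limbalign_geometry_error")
  cr <- u[1] * v[2] - u[2] * v[1]
  dt <- u[1] * v[1] + u[2] * v[2]
  atan2(cr, dt) * 180 / pi
}

# Unsigned angle in [0, 180] between two vectors.
unsigned_angle <- function(u, v) abs(signed_angle_between(u, v))

axis_vector <- function(lm, from, to) {
  d <- lm$xy[to, ] - lm$xy[from, ]
  if (sqrt(sum(d^2)) < 1e-9)
    abort(sprintf("Degenerate axis %s->%s: coincident landmarks.", from, to),
          class = "limbalign_geometry_error")
  d
}

# Loud failure on side/coordinate mismatch: for the right limb medial is +x,
# so the medial condyle v5 (plateau v8) must sit at larger x than the lateral
# v3 (v6); mirrored for the left. A mislabeled side would otherwise silently
# flip mLDFA/mMPTA and the HKA sign.
check_side_consistency <- function(lm) {
  s <- side_sign(lm$side)
  ok_f <- s * (lm$xy["v5", "x"] - lm$xy["v3", "x"]) > 0
  ok_t <- s * (lm$xy["v8", "x"] - lm$xy["v6", "x"]) > 0
  if (!ok_f || !ok_t)
    abort(paste0(
      "Side label '", lm$side, "' is inconsistent with the lateral/medial ",
      "x-ordering of the ", if (!ok_f) "femoral condyle (v3/v5)" else
        "tibial plateau (v6/v8)",
      " landmarks; refusing to measure a possibly mislabeled limb."),
      class = "limbalign_side_error")
  invisible(lm)
}

#' Compute the five clinical alignment angles of one limb
#'
#' Axis constructions: femoral mechanical axis `v1 -> v4`, tibial mechanical
#' axis `v7 -> v10`, femoral anatomical axis `v2 -> v4`, femoral joint line
#' `v3 -> v5` (lateral to medial), tibial joint line `v6 -> v8`.
#'
#' Sign conventions (all angles in degrees, computed in the image frame,
#' `y` down):
#' * **HKA**: signed angle between the femoral and tibial mechanical axes;
#'   0 for a perfectly aligned limb, negative for varus (knee apex lateral,
#'   i.e. the tibial axis deviated toward the medial side relative to the
#'   femoral axis), positive for valgus. The side label resolves which image
#'   direction is medial.
#' * **JCLA**: signed angle between the femoral and tibial joint lines,
#'   positive when the lines converge medially (open laterally). Set
#'   `jcla_signed = FALSE` for the absolute-value convention.
#' * **AMA**: unsigned angle between the femoral anatomical and mechanical
#'   axes.
#' * **mLDFA**: lateral angle between the femoral mechanical axis and the
#'   femoral joint line (90 for a neutral symmetric limb).
#' * **mMPTA**: medial angle between the tibial mechanical axis and the
#'   tibial joint line.
#'
#' @param landmarks A [limb_landmarks] object.
#' @param jcla_signed Keep the sign of JCLA (default) or report `|JCLA|`.
#' @return An `alignment_angles` object: a named list with elements `hka`,
#'   `jcla`, `ama`, `mldfa`, `mmpta`, `side` and `class` (see
#'   [classify_alignment]).
#' @examples
#' measure_limb(neutral_limb(hka = -5))
#' @export
measure_limb <- function(landmarks, jcla_signed = TRUE) {
  stopifnot(inherits(landmarks, "limb_landmarks"))
  check_side_consistency(landmarks)
  lm <- landmarks
  s <- side_sign(lm$side)

  fem_mech <- axis_vector(lm, "v1", "v4")
  tib_mech <- axis_vector(lm, "v7", "v10")
  fem_anat <- axis_vector(lm, "v2", "v4")
  fem_joint <- axis_vector(lm, "v3", "v5")   # lateral -> medial
  tib_joint <- axis_vector(lm, "v6", "v8")

  hka <- s * signed_angle_between(fem_mech, tib_mech)
  jcla <- -s * signed_angle_between(fem_joint, tib_joint)
  if (!jcla_signed) jcla <- abs(jcla)
  ama <- unsigned_angle(fem_anat, fem_mech)
  mldfa <- unsigned_angle(-fem_mech, -fem_joint)  # up-axis vs lateral joint dir
  mmpta <- unsigned_angle(tib_mech, tib_joint)    # down-axis vs medial joint dir

  alignment_angles(hka = hka, jcla = jcla, ama = ama,
                   mldfa = mldfa, mmpta = mmpta, side = lm$side)
}

#' Bundle the five alignment angles
#'
#' Validates the physiologic bounds (|HKA| and |JCLA| below 90, AMA in
#' `[0, 90)`, mLDFA and mMPTA in `(0, 180)`).
#'
#' @param hka,jcla,ama,mldfa,mmpta Angles in degrees (see [measure_limb] for
#'   the sign conventions).
#' @param side `"left"` or `"right"`.
#' @return An `alignment_angles` object.
#' @export
alignment_angles <- function(hka, jcla, ama, mldfa, mmpta, side = "right") {
  vals <- c(hka = hka, jcla = jcla, ama = ama, mldfa = mldfa, mmpta = mmpta)
  if (any(!is.finite(vals)))
    abort("Alignment angles must be finite.", class = "limbalign_geometry_error")
  if (abs(hka) >= 90 || abs(jcla) >= 90 || ama < 0 || ama >= 90 ||
      mldfa <= 0 || mldfa >= 180 || mmpta <= 0 || mmpta >= 180)
    abort("Alignment angles outside physiologic bounds.",
          class = "limbalign_geometry_error")
  structure(list(hka = hka, jcla = jcla, ama = ama, mldfa = mldfa,
                 mmpta = mmpta, side = match.arg(side, c("left", "right")),
                 class_ = classify_alignment(hka)),
            class = "alignment_angles")
}

#' @export
print.alignment_angles <- function(x, ...) {
  cat(sprintf(
    "<alignment_angles> %s limb [%s]\n  HKA %7.2f  JCLA %6.2f  AMA %5.2f  mLDFA %6.2f  mMPTA %6.2f\n",
    x$side, x$class_, x$hka, x$jcla, x$ama, x$mldfa, x$mmpta))
  invisible(x)
}

#' @export
as_tibble.alignment_angles <- function(x, ...) {
  tibble(side = x$side, hka = x$hka, jcla = x$jcla, ama = x$ama,
         mldfa = x$mldfa, mmpta = x$mmpta, alignment = x$class_)
}

#' Classify limb alignment from the HKA angle
#'
#' Boundary-inclusive thresholds: varus when HKA <= -2 degrees, valgus when
#' HKA >= +2 degrees, neutral in between.
#'
#' @param hka Numeric vector of HKA angles in degrees (varus negative).
#' @return Factor with levels `varus`, `neutral`, `valgus`.
#' @examples
#' classify_alignment(c(-3, -2, 0, 2.5))
#' @export
classify_alignment <- function(hka) {
  if (any(!is.finite(hka))) abort("HKA must be finite.")
  factor(ifelse(hka <= -2, "varus", ifelse(hka >= 2, "valgus", "neutral")),
         levels = c("varus", "neutral", "valgus"))
}

#' Measure alignment angles for a table of landmarks
#'
#' Data-frame-first interface over [measure_limb]: takes a long landmark
#' table (one row per landmark) and returns one row of angles per limb.
#' Limbs with missing or degenerate landmarks are skipped with a warning
#' rather than failing the whole table.
#'
#' @param landmarks Data frame with columns `image_id`, `side`, `landmark`
#'   (`v1`..`v10`), `x`, `y` and optionally `spacing_mm`.
#' @param jcla_signed Passed to [measure_limb].
#' @return A tibble with columns `image_id`, `side`, the five angles,
#'   `alignment`, and `n_skipped` limbs recorded in the `"n_skipped"`
#'   attribute.
#' @export
measure_limbs <- function(landmarks, jcla_signed = TRUE) {
  stopifnot(is.data.frame(landmarks))
  req <- c("image_id", "side", "landmark", "x", "y")
  if (!all(req %in% names(landmarks)))
    abort(paste("Landmark table must have columns:", paste(req, collapse = ", ")))
  if (!"spacing_mm" %in% names(landmarks)) landmarks$spacing_mm <- NA_real_
  keys <- dplyr::distinct(landmarks, .data$image_id, .data$side)
  skipped <- 0L
  rows <- purrr::pmap(keys, function(image_id, side) {
    sub <- landmarks[landmarks$image_id == image_id & landmarks$side == side, ]
    res <- tryCatch({
      if (!setequal(sub$landmark, landmark_names()))
        abort(paste("missing landmarks:",
                    paste(setdiff(landmark_names(), sub$landmark), collapse = ",")))
      lm <- limb_landmarks(sub[, c("landmark", "x", "y")], side = side,
                           spacing_mm = sub$spacing_mm[[1]])
      ang <- measure_limb(lm, jcla_signed = jcla_signed)
      dplyr::bind_cols(tibble(image_id = image_id), as_tibble(ang))
    }, error = function(e) {
      warn(sprintf("Skipping limb %s/%s: %s", image_id, side, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) skipped <<- skipped + 1L
    res
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble(image_id = character(), side = character(), hka = double(),
                  jcla = double(), ama = double(), mldfa = double(),
                  mmpta = double(), alignment = factor(character(),
                    levels = c("varus", "neutral", "valgus")))
  attr(out, "n_skipped") <- skipped
  out
}
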