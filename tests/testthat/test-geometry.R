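test_that("signed angle matches the arctangent oracle and its conventions", {
  expect_equal(signed_angle_between(c(0, 1), c(0, 1)), 0)
  expect_equal(abs(signed_angle_between(c(0, 1), c(1, 0))), 90)
  # sign convention: rotation taking +x toward +y is positive
  expect_equal(signed_angle_between(c(1, 0), c(0, 1)), 90)
  expect_equal(signed_angle_between(c(0, 1), c(sin(5 * pi / 180),
                                               cos(5 * pi / 180))), -5,
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:1000) {
    u <- stats::rnorm(2); v <- stats::rnorm(2)
    expect_equal(signed_angle_between(u, v), angle_oracle(u, v),
                 tolerance = 1e-10)
  }
  expect_error(signed_angle_between(c(0, 0), c(1, 0)),
               class = "limbalign_geometry_error")
})

test_that("a neutral symmetric limb measures as perfectly aligned", {
  for (side in c("right", "left")) {
    a <- measure_limb(manual_neutral_limb(side))
    expect_equal(a$hka, 0)
    expect_equal(a$jcla, 0)
    expect_equal(a$ama, 0)
    expect_equal(a$mldfa, 90)
    expect_equal(a$mmpta, 90)
    expect_equal(as.character(a$class_), "neutral")
  }
})

test_that("rotating the tibial axis medially produces varus of that angle", {
  # rotation-matrix oracle applied to the neutral fixture: moving the ankle
  # toward the medial side (+x for the right limb, so a negative angle in
  # the helper's +x-toward-+y convention) is the bow-legged pattern
  lm <- manual_neutral_limb("right")
  xy <- lm$xy
  xy["v10", ] <- rotate_about(xy["v10", , drop = FALSE], xy["v7", ], -5)
  a <- measure_limb(limb_landmarks(xy, "right", 1))
  expect_equal(a$hka, -5, tolerance = 1e-9)
  expect_equal(as.character(a$class_), "varus")
  # mirrored limb, mirrored rotation: same varus
  lm_l <- manual_neutral_limb("left")
  xy <- lm_l$xy
  xy["v10", ] <- rotate_about(xy["v10", , drop = FALSE], xy["v7", ], 5)
  expect_equal(measure_limb(limb_landmarks(xy, "left", 1))$hka, -5,
               tolerance = 1e-9)
  # and the lateral rotation is knock-kneed: valgus, positive HKA
  xy <- lm$xy
  xy["v10", ] <- rotate_about(xy["v10", , drop = FALSE], xy["v7", ], 5)
  expect_equal(measure_limb(limb_landmarks(xy, "right", 1))$hka, 5,
               tolerance = 1e-9)
})

test_that("AMA equals the construction angle of the anatomical axis", {
  lm <- manual_neutral_limb("right")
  xy <- lm$xy
  # construct v2 by rotating a point on the mechanical axis by 6 deg about v4
  xy["v2", ] <- rotate_about(xy["v2", , drop = FALSE], xy["v4", ], 6)
  expect_equal(measure_limb(limb_landmarks(xy, "right", 1))$ama, 6,
               tolerance = 1e-9)
})

test_that("joint-line tilts move mLDFA, mMPTA and JCLA coherently", {
  lm <- manual_neutral_limb("right")
  xy <- lm$xy
  # tilt the femoral joint line by 3 deg about the knee centre
  xy[c("v3", "v5"), ] <- rotate_about(xy[c("v3", "v5"), ], xy["v4", ], 3)
  a <- measure_limb(limb_landmarks(xy, "right", 1))
  expect_equal(a$mldfa, 87, tolerance = 1e-9)
  expect_equal(a$mmpta, 90, tolerance = 1e-9)
  # femoral line now drops toward medial: the joint converges medially
  expect_equal(a$jcla, 3, tolerance = 1e-9)
  expect_equal(a$jcla, jcla_closure(a$hka, a$mldfa, a$mmpta),
               tolerance = 1e-9)
})

test_that("alignment classification applies inclusive +/- 2 degree bounds", {
  expect_equal(as.character(classify_alignment(c(-3, -2, -1.999, 0, 1.999, 2, 3))),
               c("varus", "varus", "neutral", "neutral", "neutral",
                 "valgus", "valgus"))
  expect_error(classify_alignment(NaN))
})

test_that("angles are invariant to mirror, rigid rotation and scale", {
  set.seed(7)
  for (i in 1:25) {
    lm <- limb_from_angles(hka = stats::runif(1, -12, 12),
                           ama = stats::runif(1, 3, 9),
                           mldfa = stats::runif(1, 84, 92),
                           mmpta = stats::runif(1, 83, 91),
                           side = sample(c("left", "right"), 1))
    a <- unlist(measure_limb(lm)[c("hka", "jcla", "ama", "mldfa", "mmpta")])

    # mirror + side flip
    xy <- lm$xy; xy[, 1] <- -xy[, 1]
    side2 <- if (lm$side == "left") "right" else "left"
    am <- unlist(measure_limb(limb_landmarks(xy, side2, 1))[names(a)])
    expect_lt(max(abs(a - am)), 1e-9)

    # rigid rotation
    th <- stats::runif(1, -10, 10)
    xyr <- rotate_about(lm$xy, c(0, 0), th)
    ar <- unlist(measure_limb(limb_landmarks(xyr, lm$side, 1))[names(a)])
    expect_lt(max(abs(a - ar)), 1e-9)

    # scale
    s <- stats::runif(1, 0.2, 5)
    as_ <- unlist(measure_limb(limb_landmarks(lm$xy * s, lm$side, 1))[names(a)])
    expect_lt(max(abs(a - as_)), 1e-9)
  }
})

test_that("degenerate and inconsistent landmark sets fail loudly", {
  lm <- manual_neutral_limb("right")
  xy <- lm$xy
  xy["v1", ] <- xy["v4", ] - c(0, 1e-12)   # collapse the femoral axis
  expect_error(measure_limb(limb_landmarks(xy, "right", 1)),
               class = "limbalign_geometry_error")
  # mislabeled side must not silently flip mLDFA/mMPTA
  expect_error(measure_limb(limb_landmarks(manual_neutral_limb("right")$xy,
                                           "left", 1)),
               class = "limbalign_side_error")
  expect_error(limb_landmarks(lm$xy, "right", spacing_mm = -1))
  bad <- lm$xy; bad["v1", 2] <- 300   # femoral head below the ankle
  expect_error(limb_landmarks(bad, "right", 1))
})

test_that("measure_limbs processes tables and skips malformed limbs", {
  tab <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(manual_neutral_limb("right")), image_id = "a"),
    dplyr::mutate(as_tibble(limb_from_angles(-6, side = "left")),
                  image_id = "b"))
  out <- measure_limbs(tab)
  expect_equal(nrow(out), 2)
  expect_equal(out$hka, c(0, -6), tolerance = 1e-9)
  expect_equal(attr(out, "n_skipped"), 0)
  # drop v3 from one limb: that limb is skipped with a warning, other kept
  tab2 <- tab[!(tab$image_id == "a" & tab$landmark == "v3"), ]
  expect_warning(out2 <- measure_limbs(tab2), "v3")
  expect_equal(out2$image_id, "b")
  expect_equal(attr(out2, "n_skipped"), 1)
})
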