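# Shared fixtures and independent oracles.

# A neutral symmetric limb written out coordinate-by-coordinate (independent
# of limb_from_angles): vertical collinear mechanical axes, horizontal
# parallel joint lines, anatomical axis on the mechanical axis.
manual_neutral_limb <- function(side = "right") {
  xy <- rbind(
    v1 = c(50, 0), v2 = c(50, 50), v3 = c(40, 100), v4 = c(50, 100),
    v5 = c(60, 100), v6 = c(40, 105), v7 = c(50, 105), v8 = c(60, 105),
    v9 = c(50, 155), v10 = c(50, 205))
  if (side == "left") xy[, 1] <- 100 - xy[, 1]
  limb_landmarks(xy, side = side, spacing_mm = 1)
}

# rotate points about a centre (independent rotation-matrix oracle; positive
# angle turns +x toward +y, i.e. toward medial for a right limb near vertical)
rotate_about <- function(xy, centre, deg) {
  a <- deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  t(R %*% (t(xy) - centre) + centre)
}

# arctangent-based oracle for the signed angle between two vectors
angle_oracle <- function(u, v) {
  d <- (atan2(v[2], v[1]) - atan2(u[2], u[1])) * 180 / pi
  d <- ((d + 180) %% 360) - 180
  if (d == -180) d <- 180
  d
}

# brute-force Pearson statistic, written directly from sum((O-E)^2 / E)
chisq_brute <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# small phantom cohort rendered at detector desk scale
desk_cohort <- function(...)
  phantom_cohort(image_height = 128, image_width = 64, spacing_mm = 2.75,
                 noise_sd = 0.03, ...)
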