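test_that("mre is the arithmetic mean and rejects empty input", {
  expect_equal(mre(c(0, 0, 0)), 0)
  expect_equal(mre(c(1, 2, 6)), 3)
  expect_error(mre(numeric(0)), class = "limbalign_stat_error")
  expect_error(mre(c(1, -1)), class = "limbalign_stat_error")
  expect_error(mre(c(1, NA)), class = "limbalign_stat_error")
})

test_that("mre scales linearly with unit conversion via pixel spacing", {
  set.seed(5)
  ref <- matrix(stats::runif(20, 0, 100), 10, 2)
  pred <- ref + matrix(stats::rnorm(20), 10, 2)
  r_px <- radial_errors(ref, pred)
  r_mm <- radial_errors(ref, pred, spacing_mm = 0.79)
  expect_equal(mre(r_mm), 0.79 * mre(r_px))
  expect_equal(mre(r_px + 3), mre(r_px) + 3)  # translation equivariance
})

test_that("the published per-landmark errors average to the printed means", {
  tab <- clinical_landmark_mre()
  expect_equal(nrow(tab), 20)
  expect_equal(mre(tab$mre[tab$dataset == "validation"]), 2.778,
               tolerance = 5e-4)
  expect_equal(mre(tab$mre[tab$dataset == "test"]), 2.447, tolerance = 5e-4)
})

test_that("agreement reproduces hand-computed reference cases", {
  # identical series
  a <- agreement(c(1, 2, 3), c(1, 2, 3))
  expect_equal(a$mad, 0)
  expect_equal(unname(a$ad), c(1, 1))
  expect_equal(c(a$loa_low, a$bias, a$loa_high), c(0, 0, 0))

  # two-point case: differences +1 and -1
  b <- agreement(c(0, 0), c(1, -1))
  expect_equal(b$bias, 0)
  expect_equal(b$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(b$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(b$mad, 1)
  expect_equal(b$mad_sd, 0)

  # constant offset: zero spread, LoA collapse onto the bias
  d <- agreement(c(5, 6, 7), c(5.5, 6.5, 7.5))
  expect_equal(c(d$loa_low, d$bias, d$loa_high), c(0.5, 0.5, 0.5))

  expect_error(agreement(1:3, 1:2), class = "limbalign_stat_error")
  expect_error(agreement(numeric(0), numeric(0)),
               class = "limbalign_stat_error")
})

test_that("AD fractions use strict thresholds and are monotone", {
  # |difference| exactly 1 must NOT count as deviation < 1 degree
  r <- agreement(c(0, 0, 0, 0), c(1, 0.99, -1, 1.5))
  expect_equal(unname(r$ad["ad_lt_1"]), 0.25)
  expect_equal(unname(r$ad["ad_lt_2"]), 1)
  set.seed(31)
  d <- stats::rnorm(200)
  r2 <- agreement(rep(0, 200), d, thresholds = c(0.5, 1, 2, 4))
  expect_true(all(diff(unname(r2$ad)) >= 0))
  # LoA width is exactly 2 * 1.96 * sd
  expect_equal(r2$loa_high - r2$loa_low, 2 * 1.96 * stats::sd(d))
})

test_that("agreement machinery matches the analytic normal-deviate rate", {
  set.seed(97)
  ref <- stats::runif(400, -10, 10)
  pred <- ref + stats::rnorm(400, 0, 0.5)
  r <- agreement(ref, pred)
  expect_lt(abs(r$ad[["ad_lt_1"]] - (2 * stats::pnorm(2) - 1)), 0.02)
})

test_that("pearson chi-square matches brute force and printed subgroups", {
  tabs <- subgroup_count_matrices()
  expect_length(tabs, 8)
  printed <- c(native_alignment = 0.975, native_sex = 3.771,
               native_bmi = 0.552, native_age = 0.537,
               prosthesis_alignment = 3.511, prosthesis_sex = 1.024,
               prosthesis_bmi = 0.752, prosthesis_age = 0.001)
  for (nm in names(printed)) {
    res <- pearson_chi_square(tabs[[nm]])
    expect_equal(round(res$statistic, 3), unname(printed[nm]))
    expect_equal(res$statistic, chisq_brute(tabs[[nm]]), tolerance = 1e-10)
    expect_equal(res$df, nrow(tabs[[nm]]) - 1L)
    # row permutation invariance
    perm <- sample(nrow(tabs[[nm]]))
    expect_equal(pearson_chi_square(tabs[[nm]][perm, ])$statistic,
                 res$statistic, tolerance = 1e-10)
  }
  # identical row proportions give exactly zero
  expect_equal(pearson_chi_square(rbind(c(10, 20), c(30, 60)))$statistic, 0,
               tolerance = 1e-12)
  expect_error(pearson_chi_square(rbind(c(0, 0), c(1, 2))),
               class = "limbalign_stat_error")
  expect_error(pearson_chi_square(matrix(1:3, 1)),
               class = "limbalign_stat_error")
})

test_that("evaluate_angles joins tables and reports per angle", {
  ref <- tibble::tibble(image_id = c("a", "b", "c"), side = "right",
                        hka = c(-5, 0, 3), jcla = c(1, 0, -1))
  pred <- ref
  pred$hka <- pred$hka + c(0.5, -0.5, 0.5)
  out <- evaluate_angles(ref, pred)
  expect_equal(out$angle, c("hka", "jcla"))
  expect_equal(out$mad[out$angle == "hka"], 0.5)
  expect_equal(out$ad_lt_1[out$angle == "hka"], 1)
  expect_equal(out$mad[out$angle == "jcla"], 0)
  bad <- pred; bad$image_id <- c("x", "y", "z")
  expect_error(evaluate_angles(ref, bad), class = "limbalign_stat_error")
})

test_that("subgroup chi-square cross-tabulates accuracy correctly", {
  set.seed(13)
  df <- tibble::tibble(
    hka_ref = stats::runif(200, -10, 10),
    grp = sample(c("A", "B"), 200, replace = TRUE))
  df$hka_pred <- df$hka_ref + stats::rnorm(200, 0, 0.7)
  out <- subgroup_chi_square(df, "hka_ref", "hka_pred", groups = "grp")
  tb <- attr(out, "tables")$grp
  expect_equal(sum(tb), 200)
  expect_equal(out$statistic, chisq_brute(unclass(tb)), tolerance = 1e-10)
  expect_equal(out$df, 1L)
})
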