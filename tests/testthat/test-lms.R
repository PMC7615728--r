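test_that("lms_value matches the Box-Cox formula and its limits", {
  # Z = 0 returns the median for any valid parameters
  expect_equal(lms_value(-1.3, 150, 0.05, 0), 150)
  expect_equal(lms_value(0, 92.3, 0.11, 0), 92.3)
  # L = 1 reduces to M * (1 + S*Z)
  expect_equal(lms_value(1, 100, 0.04, 2), 108)
  # direct evaluation of the formula for a negative power
  expect_equal(lms_value(-0.5, 150, 0.05, 1), 150 * (1 - 0.025)^(-2))
  # L -> 0 converges to the log-normal limit
  expect_equal(lms_value(1e-8, 120, 0.05, 1.7),
               120 * exp(0.05 * 1.7), tolerance = 1e-6)
  # strictly increasing in Z
  z <- seq(-2.5, 2.5, length.out = 41)
  v <- lms_value(-1.2, 150, 0.04, z)
  expect_true(all(diff(v) > 0))
})

test_that("lms_value rejects invalid parameters and implausible deviates", {
  expect_error(lms_value(1, -5, 0.05, 0), "M must be positive")
  expect_error(lms_value(1, 100, 0, 0), "S must be positive")
  # 1 + L*S*Z <= 0: L=2, S=0.5, Z=-1 gives 0
  expect_error(lms_value(2, 100, 0.5, -1), "implausible")
})

test_that("lms_quantile is the normal-deviate quantile of the LMS model", {
  expect_equal(lms_quantile(-0.7, 134, 0.043, 0.5), 134)  # median
  expect_equal(lms_quantile(1, 100, 0.04, pnorm(1)), 104)
  expect_equal(lms_quantile(-0.5, 150, 0.05, 0.01),
               lms_value(-0.5, 150, 0.05, qnorm(0.01)))
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(lms_quantile(-1, 150, 0.04, p)) > 0))
  expect_error(lms_quantile(1, 100, 0.04, 0), "in \\(0, 1\\)")
})

test_that("load_lms_table parses the CDC dialect and validates rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Sex,Agemos,L,M,S,P3,P50",
               "1,24.5,1.2,86.5,0.041,80,86.5",
               "1,36.5,1.1,94.8,0.042,88,94.8",
               "2,24.5,1.0,85.2,0.040,79,85.2"), path)
  tab <- load_lms_table(path, "stature")
  expect_s3_class(tab, "lms_table")
  expect_equal(nrow(tab), 3)
  expect_equal(levels(tab$sex), c("male", "female"))
  expect_equal(attr(tab, "measure"), "stature")
  # extra percentile columns ignored, sexes decoded
  expect_equal(sum(tab$sex == "female"), 1)

  # rows below 24 months are dropped
  writeLines(c("Sex,Agemos,L,M,S", "1,12,1,75,0.04", "1,36,1,95,0.04"), path)
  expect_equal(nrow(load_lms_table(path, "stature")), 1)

  # non-positive M is a parse error naming the row
  writeLines(c("Sex,Agemos,L,M,S", "1,24,1,86,0.04", "1,36,1,0,0.04"), path)
  expect_error(load_lms_table(path, "stature"), "row\\(s\\) 2")
  # missing column
  writeLines(c("Sex,Agemos,L,M", "1,24,1,86"), path)
  expect_error(load_lms_table(path, "stature"), "no S column")
})

test_that("builtin fallback table is well-formed for both measures", {
  for (measure in c("stature", "weight")) {
    tab <- builtin_lms_table(measure)
    expect_equal(sort(unique(tab$age_months)), 24:240)
    expect_setequal(as.character(unique(tab$sex)), c("male", "female"))
    expect_true(all(tab$S > 0))
    for (s in c("male", "female")) {
      expect_true(all(diff(tab$M[tab$sex == s]) > 0))
    }
  }
  # youngest stature median near typical 2-year-old stature
  st <- builtin_lms_table("stature")
  m24 <- st$M[st$age_months == 24]
  expect_true(all(m24 > 80 & m24 < 92))
})

test_that("simulate_growth allocates groups evenly and reproducibly", {
  th <- toy_lms_table()
  tw <- toy_lms_table(measure = "weight")
  # exact divisibility: 2 per group
  tab <- simulate_growth(12, th, tw, seed = 1)
  expect_equal(nrow(tab), 12)
  expect_true(all(table(tab$sex, tab$age_months) == 2))
  # remainder: group sizes differ by at most 1 and do not depend on the seed
  t1 <- simulate_growth(20, th, tw, seed = 1)
  t2 <- simulate_growth(20, th, tw, seed = 99)
  g1 <- table(t1$sex, t1$age_months)
  expect_true(max(g1) - min(g1) <= 1)
  expect_equal(table(t2$sex, t2$age_months), g1)
  # same seed is bit-identical
  expect_identical(simulate_growth(50, th, tw, seed = 7),
                   simulate_growth(50, th, tw, seed = 7))
})

test_that("simulated records respect the growth-model contracts", {
  th <- toy_lms_table()
  tw <- toy_lms_table(measure = "weight")
  tab <- simulate_growth(600, th, tw, seed = 3)
  expect_true(all(tab$height_cm > 0))
  expect_true(all(tab$height_cm == round(tab$height_cm)))
  expect_true(all(tab$weight_kg > 0))
  expect_identical(tab$log_weight, log(tab$weight_kg))
  expect_equal(tab$id, seq_len(600))
  # group medians track the LMS median parameter
  med <- tapply(tab$height_cm, tab$age_months, median)
  expect_true(all(diff(med[order(as.numeric(names(med)))]) > 0))
  expect_error(simulate_growth(10, th[0, ], tw), "empty")
})

test_that("builtin-table cohort reproduces the study-scale height profile", {
  tab <- simulate_growth(5000, builtin_lms_table("stature"),
                         builtin_lms_table("weight"), seed = 2024)
  expect_equal(nrow(tab), 5000)
  # pooled height median and MAD near the published descriptive profile
  expect_gt(median(tab$height_cm), 138)
  expect_lt(median(tab$height_cm), 158)
  expect_gt(mad(tab$height_cm), 28)
  expect_lt(mad(tab$height_cm), 38)
  # ages and both sexes fully covered
  expect_equal(range(tab$age_months), c(24, 240))
})
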