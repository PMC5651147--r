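# ICC(2,1), mean absolute difference, and the simulated-examiner harness.

test_that("identical rater columns give ICC exactly 1 with a degenerate interval", {
  set.seed(71)
  a <- runif(25, 10, 60)
  res <- icc_absolute_agreement(cbind(a, a))
  expect_equal(res$icc, 1)
  expect_equal(res$ci_low, 1)
  expect_equal(res$ci_high, 1)
  expect_equal(res$variant, "ICC(2,1)")
})

test_that("independent noise around a common constant gives ICC near zero", {
  set.seed(72)
  iccs <- replicate(20, {
    icc_absolute_agreement(cbind(rnorm(200, 20, 3), rnorm(200, 20, 3)))$icc
  })
  expect_lt(abs(mean(iccs)), 0.15)
  x <- cbind(rnorm(200, 20, 3), rnorm(200, 20, 3))
  res <- icc_absolute_agreement(x)
  expect_lte(res$ci_low, res$icc)
  expect_gte(res$ci_high, res$icc)
})

test_that("ICC matches the closed-form variance ratio under a components model", {
  # subjects sd 10, error sd 2: ICC = 100 / (100 + 4)
  set.seed(73)
  iccs <- replicate(500, {
    subj <- rnorm(30, 40, 10)
    x <- cbind(subj + rnorm(30, 0, 2), subj + rnorm(30, 0, 2))
    icc_absolute_agreement(x)$icc
  })
  expect_lt(abs(mean(iccs) - 100 / 104), 0.05)
})

test_that("ICC point estimate agrees with lme4 variance components", {
  skip_if_not_installed("lme4")
  set.seed(74)
  n <- 150; k <- 3
  subj <- rnorm(n, 30, 8)
  rater <- rnorm(k, 0, 2)
  x <- outer(subj, rep(1, k)) + outer(rep(1, n), rater) +
    matrix(rnorm(n * k, 0, 3), n, k)
  res <- icc_absolute_agreement(x)
  df <- data.frame(y = as.vector(x),
                   s = factor(rep(seq_len(n), k)),
                   r = factor(rep(seq_len(k), each = n)))
  fit <- lme4::lmer(y ~ (1 | s) + (1 | r), data = df,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vs <- vc$vcov[vc$grp == "s"]; vr <- vc$vcov[vc$grp == "r"]
  ve <- vc$vcov[vc$grp == "Residual"]
  expect_lt(abs(res$icc - vs / (vs + vr + ve)), 0.02)
})

test_that("ICC is invariant to common shifts and positive rescalings", {
  set.seed(75)
  x <- cbind(rnorm(40, 30, 9), rnorm(40, 30, 9) )
  x[, 2] <- 0.7 * x[, 1] + 0.3 * x[, 2]
  base <- icc_absolute_agreement(x)$icc
  expect_equal(icc_absolute_agreement(x + 12)$icc, base, tolerance = 1e-10)
  expect_equal(icc_absolute_agreement(2.5 * x)$icc, base, tolerance = 1e-10)
})

test_that("zero between-subject variance reports undefined, not zero", {
  x <- matrix(rep(c(10, 12, 11), each = 5), nrow = 5)  # identical rows
  res <- icc_absolute_agreement(x)
  expect_true(is.na(res$icc))
  expect_match(res$note, "undefined")
})

test_that("measurement tables reject missing cells and degenerate sizes", {
  expect_error(measurement_table(matrix(1:3, ncol = 1)), "at least 2")
  x <- matrix(runif(10), 5, 2); x[2, 1] <- NA
  expect_error(measurement_table(x), "missing")
})

test_that("MAD matches hand arithmetic and an element-wise loop oracle", {
  expect_equal(mean_absolute_difference(c(10, 20), c(12, 16)), 3)
  expect_equal(mean_absolute_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(mean_absolute_difference(1:3, 1:4), "lengths differ")
  set.seed(76)
  for (rep in 1:20) {
    a <- runif(15, 0, 50); b <- runif(15, 0, 50)
    acc <- 0
    for (i in seq_along(a)) acc <- acc + abs(a[i] - b[i])
    expect_equal(mean_absolute_difference(a, b), acc / length(a))
  }
})

test_that("MAD satisfies the triangle inequality", {
  set.seed(77)
  for (rep in 1:50) {
    a <- runif(10, 0, 50); b <- runif(10, 0, 50); c <- runif(10, 0, 50)
    expect_lte(mean_absolute_difference(a, c),
               mean_absolute_difference(a, b) +
                 mean_absolute_difference(b, c) + 1e-12)
  }
})

test_that("noise-free examiner sessions are identical: ICC 1, MAD 0", {
  m <- fixture_model()
  rgs <- fixture_radiographs(4)
  s1 <- simulate_examiner_session(rgs, m, click_noise_sd = 0, seed = 1)
  s2 <- simulate_examiner_session(rgs, m, click_noise_sd = 0, seed = 2)
  expect_equal(as.vector(s1), as.vector(s2))
  rep0 <- reliability_study(rgs, m, "intraobserver", sessions = 2,
                            click_noise_sd = 0, seed = 5)
  expect_equal(rep0$icc, 1)
  expect_equal(rep0$mad, 0)
})

test_that("sessions are reproducible bit-for-bit under a fixed seed", {
  m <- fixture_model()
  rgs <- fixture_radiographs(3)
  s1 <- simulate_examiner_session(rgs, m, click_noise_sd = 5, seed = 9)
  s2 <- simulate_examiner_session(rgs, m, click_noise_sd = 5, seed = 9)
  expect_identical(s1, s2)
  s3 <- simulate_examiner_session(rgs, m, click_noise_sd = 5, seed = 10)
  expect_false(identical(as.vector(s1), as.vector(s3)))
})

test_that("the study report's MAD is definitionally consistent with its table", {
  m <- fixture_model()
  rgs <- fixture_radiographs(4)
  rep1 <- reliability_study(rgs, m, "intraobserver", sessions = 2,
                            click_noise_sd = 4, seed = 6)
  tab <- rep1$table$values
  expect_equal(rep1$mad, mean_absolute_difference(tab[, 1], tab[, 2]))
  expect_lte(rep1$ci_low, rep1$icc)
  expect_gte(rep1$ci_high, rep1$icc)
})

test_that("more click noise never improves mean ICC", {
  m <- fixture_model()
  rgs <- fixture_radiographs(6)
  mean_icc <- function(sd) {
    mean(vapply(1:8, function(r) {
      reliability_study(rgs, m, "intraobserver", 2, sd, seed = 100 + r)$icc
    }, numeric(1)))
  }
  low <- mean_icc(2); high <- mean_icc(10)
  expect_gte(low, high - 0.01)
})
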