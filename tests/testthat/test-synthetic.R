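test_that("daily admitted counts honour the published range and mean", {
  obs <- generate_observed(year_days = 365, seed = 12)
  cnt <- obs$daily$admitted
  expect_true(all(cnt >= 28 & cnt <= 79))

  # analytic mean of the truncated normal N(52, 28) on [28, 79]
  a <- (28 - 52) / 28; b <- (79 - 52) / 28
  mu_trunc <- 52 + 28 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  sd_trunc <- 28 * sqrt(1 + (a * dnorm(a) - b * dnorm(b)) /
                          (pnorm(b) - pnorm(a)) -
                          ((dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a)))^2)
  expect_lt(abs(mean(cnt) - mu_trunc), 4 * sd_trunc / sqrt(365) + 0.5)

  # annual scale lands near the published ~19k admissions
  expect_gt(nrow(obs$patients), 15000)
  expect_lt(nrow(obs$patients), 25000)
  expect_identical(nrow(obs$patients), sum(cnt))
})

test_that("per-patient durations carry the observed moments", {
  obs <- generate_observed(year_days = 365, seed = 2)
  tab <- table1_moments()
  for (i in seq_len(nrow(tab))) {
    x <- obs$patients[[paste0("d_", tab$name[i])]]
    expect_true(all(x > 0))
    expect_lt(abs(mean(x) - tab$mean[i]),
              4 * tab$sd[i] / sqrt(length(x)) + 1e-4)
  }
  # total PET is exactly the row sum of the seven stage durations
  dmat <- as.matrix(obs$patients[paste0("d_", tab$name)])
  expect_equal(obs$patients$total_pet, rowSums(dmat))
})

test_that("generation is byte-identical under a fixed seed", {
  o1 <- generate_observed(year_days = 30, seed = 77)
  o2 <- generate_observed(year_days = 30, seed = 77)
  expect_identical(o1$patients, o2$patients)
  expect_identical(o1$daily, o2$daily)
  o3 <- generate_observed(year_days = 30, seed = 78)
  expect_false(identical(o1$daily, o3$daily))
})

test_that("CSV export round-trips losslessly", {
  obs <- generate_observed(year_days = 20, seed = 5)
  path <- file.path(tempdir(), "obs_test.csv")
  on.exit(unlink(c(path, sub("\\.csv$", "_daily.csv", path))), add = TRUE)
  export_observed(obs, path)
  back <- read_observed(path)
  tab <- table1_moments()
  for (nm in paste0("d_", tab$name))
    expect_identical(back$patients[[nm]], obs$patients[[nm]])
  expect_identical(back$patients$admission_date, obs$patients$admission_date)
  expect_equal(back$patients$total_pet, obs$patients$total_pet,
               tolerance = 1e-9)
  expect_identical(back$daily$admitted, obs$daily$admitted)
  expect_identical(nrow(back$patients), nrow(obs$patients))
})

test_that("monthly totals stay inside the published sanity bounds", {
  obs <- generate_observed(year_days = 365, seed = 9)
  months <- format(obs$daily$date, "%Y-%m")
  monthly <- tapply(obs$daily$admitted, months, sum)
  # published monthly range 707-1331 (median 955); allow generator slack
  expect_gt(min(monthly), 600)
  expect_lt(max(monthly), 2000)
})
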