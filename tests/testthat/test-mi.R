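test_that("imputing a complete cohort returns identical copies", {
  d <- sim_ph(60, seed = 61)
  mi <- impute_cohort(d, m = 3, seed = 1)
  expect_length(mi, 3L)
  for (k in 1:3) expect_equal(as.data.frame(mi[[k]]), as.data.frame(d))
})

test_that("imputation is reproducible and respects the mask size", {
  d <- simulate_cohort(transplant_scenario(288), seed = 62)
  dm <- mask_missing(d, "creatinine", 0.0625, "MCAR", seed = 7)
  expect_equal(sum(is.na(dm$creatinine)), 18L)      # 6.25% of 288
  mi1 <- impute_cohort(dm, m = 5, seed = 99)
  mi2 <- impute_cohort(dm, m = 5, seed = 99)
  expect_length(mi1, 5L)
  for (k in 1:5) {
    expect_false(anyNA(mi1[[k]]$creatinine))
    expect_equal(mi1[[k]]$creatinine, mi2[[k]]$creatinine)
  }
  # imputed values are on a plausible scale
  imputed <- mi1[[1]]$creatinine[is.na(dm$creatinine)]
  expect_true(all(imputed > min(d$creatinine) - 3 * sd(d$creatinine)))
  expect_true(all(imputed < max(d$creatinine) + 3 * sd(d$creatinine)))
  expect_error(impute_cohort(mask_missing(d, "cmv", 0.99, "MCAR",
                                          seed = 1)),
               NA) # high missingness still imputes
  # a fully missing column cannot be imputed
  dbad <- d; dbad$creatinine <- NA_real_
  expect_error(impute_cohort(dbad, m = 2, seed = 1), "fully missing")
})

test_that("MAR masking depends on its driver", {
  d <- simulate_cohort(transplant_scenario(400), seed = 63)
  dm <- mask_missing(d, "creatinine", 0.3, "MAR", driver = "event",
                     seed = 11)
  rate1 <- mean(is.na(dm$creatinine[dm$event == 1]))
  rate0 <- mean(is.na(dm$creatinine[dm$event == 0]))
  expect_gt(rate1 - rate0, 0.1)
})

test_that("Rubin pooling reproduces the textbook arithmetic", {
  mkfit <- function(est, v) {
    structure(list(coefficients = c(x = est), var = matrix(v, 1, 1),
                   n = 100L), class = "cox_efron")
  }
  pooled <- pool_rubin(list(mkfit(1, 1), mkfit(3, 1)))
  tab <- pooled$coefficients
  expect_equal(tab$estimate, 2)
  expect_equal(tab$W, 1)
  expect_equal(tab$B, 2)
  expect_equal(tab$total_var, 1 + (1 + 1 / 2) * 2)   # T = W + (1+1/m)B = 4
  # identical fits: between-variance exactly zero
  pooled0 <- pool_rubin(list(mkfit(1.5, 2), mkfit(1.5, 2), mkfit(1.5, 2)))
  expect_equal(pooled0$coefficients$B, 0)
  expect_equal(pooled0$coefficients$total_var, pooled0$coefficients$W)
  # m = 1 returns the fit unchanged
  single <- mkfit(1, 1)
  expect_identical(pool_rubin(list(single)), single)
  # mismatched specifications fail
  bad <- structure(list(coefficients = c(y = 1), var = matrix(1, 1, 1),
                        n = 100L), class = "cox_efron")
  expect_error(pool_rubin(list(mkfit(1, 1), bad)), "mismatched")
})

test_that("imputed-data fits pool close to the complete-data fit", {
  d <- simulate_cohort(transplant_scenario(288), seed = 64)
  full <- cox_efron(Surv(time, event) ~ creatinine + cmv, d)
  dm <- mask_missing(d, "creatinine", 0.0625, "MCAR", seed = 13)
  mi <- impute_cohort(dm, m = 5, seed = 21)
  fits <- lapply(mi, function(di) {
    cox_efron(Surv(time, event) ~ creatinine + cmv, di)
  })
  pooled <- pool_rubin(fits)
  tab <- pooled$coefficients
  for (k in seq_len(nrow(tab))) {
    expect_lt(abs(tab$estimate[k] - coef(full)[[tab$coefficient[k]]]),
              2 * sqrt(tab$total_var[k]))
  }
  expect_true(all(tab$total_var >= tab$W))
})

test_that("Gray-model tests pool by the D2 rule", {
  d <- simulate_cohort(transplant_scenario(288), seed = 65)
  dm <- mask_missing(d, "creatinine", 0.0625, "MCAR", seed = 3)
  mi <- impute_cohort(dm, m = 3, seed = 5)
  fits <- lapply(mi, function(di) {
    pctvc(Surv(time, event) ~ tv(ventilator) + creatinine, di, df = 2,
          K = 3)
  })
  pooled <- pool_rubin(fits)
  expect_s3_class(pooled, "pooled_fit")
  tt <- pooled$tests
  expect_true(all(c("overall", "nonproportionality") %in% tt$hypothesis))
  expect_true(all(tt$p >= 0 & tt$p <= 1))
})
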