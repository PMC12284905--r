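small_params <- function(...) model_params(K = 600, P0 = 20, ...)

test_that("campaigns are seed-reproducible and aggregate per-day summaries", {
  p <- small_params(omega0 = 0.5, sigma_fm = 0.98, sigma_md = 0.02,
                    sigma_total = 1, mu = 0.018)
  c1 <- run_one_year(p, replicates = 3, base_seed = 77)
  c2 <- run_one_year(p, replicates = 3, base_seed = 77)
  expect_identical(c1$daily, c2$daily) # bit-identical under the same seed
  c3 <- run_one_year(p, replicates = 3, base_seed = 78)
  expect_false(identical(c1$daily, c3$daily))
  expect_equal(nrow(c1$daily), 3 * p$T)
  expect_equal(nrow(c1$summary), p$T)
  expect_named(c1$final,
               c("rep", "pop_size", "inf_freq_female", "inf_freq_all",
                 "mf_ratio", "suppressor_freq", "n_created",
                 "deaths_age_0_3", "deaths_total"))
  # omega0 = 0 stays flat zero
  c0 <- run_one_year(small_params(), replicates = 2, base_seed = 1)
  expect_true(all(c0$daily$inf_freq_all == 0))
})

test_that("without drive, infection decays by (1-mu) per realized generation", {
  p <- small_params(omega0 = 0.5, mu = 0.018)
  camp <- run_one_year(p, replicates = 10, base_seed = 31)
  fin <- mean(camp$final$inf_freq_female)
  expect_lt(fin, 0.5) # decay, no drive
  # realized generation interval = egg-weighted mean mother age (longer than
  # the 11-day female maturity in an overlapping-generation population)
  g <- with(camp$daily, sum(mean_mother_age * n_eggs, na.rm = TRUE) /
              sum(n_eggs, na.rm = TRUE))
  expect_gt(g, 11)
  expect_lt(g, 18)
  pred <- 0.5 * (1 - p$mu)^(p$T / g)
  expect_lt(abs(fin - pred), 0.03)
})

test_that("the final-frequency surface rises with CI strength and initial frequency", {
  p <- small_params(sigma_fm = 0.98, sigma_md = 0.02, sigma_total = 1,
                    mu = 0.018)
  surf <- final_frequency_surface(p, c(0, 1), c(0, 0.5, 1),
                                  replicates = 3, base_seed = 5)
  expect_equal(dim(surf), c(2, 3))
  expect_equal(unname(surf[, "0"]), c(0, 0)) # omega0 = 0 column
  expect_gt(surf["1", "0.5"], surf["0", "0.5"]) # CI drives
  expect_true(all(surf[, "1"] > 0.8)) # near-fixation start stays high
})

test_that("paired CI-type arms share seeds and report the FM-vs-MD contrast", {
  p <- small_params(mu = 0.018)
  ct <- ci_type_contrast(p, omega0 = 0.25, sigma_total = 1,
                         replicates = 6, base_seed = 9)
  expect_equal(ct$fm$params$sigma_fm, 1)
  expect_equal(ct$md$params$sigma_md, 1)
  expect_equal(ct$fm$base_seed, ct$md$base_seed)
  expect_true(is.finite(ct$final_gap))
  # MD converts CI eggs to males: its sex-ratio peak must exceed FM's
  expect_gt(ct$peak_mf["md"], ct$peak_mf["fm"])
  # optional grid contrast: paired surfaces, difference = MD - FM,
  # regimes coincide without CI
  ctg <- ci_type_contrast(p, replicates = 2, base_seed = 9,
                          sigma_grid = c(0, 1), omega_grid = c(0.25, 1))
  expect_equal(dim(ctg$difference), c(2, 2))
  expect_equal(unname(ctg$difference["0", ]), c(0, 0), tolerance = 0.1)
  expect_equal(ctg$difference, ctg$md_surface - ctg$fm_surface)
})

test_that("multi-year chains track suppressor and infection frequencies with carryover", {
  p <- small_params(omega0 = 1, mu = 0.2) # fast loss for a cheap check
  res <- run_multi_year(p, years = 4, replicates = 2, carryover = "full",
                        base_seed = 3)
  expect_equal(nrow(res), 8)
  expect_true(all(res$inf_freq_female >= 0 & res$inf_freq_female <= 1))
  # frequencies decline year over year under strong imperfect transmission
  m <- tapply(res$inf_freq_female, res$year, mean)
  expect_true(all(diff(m) <= 0))
})

test_that("persistence times report loss years and censor unfinished chains", {
  p <- small_params(omega0 = 1, mu = 0.25)
  res <- persistence_times(p, max_years = 12, replicates = 4, base_seed = 41)
  expect_true(all(!res$censored))
  expect_true(all(res$years >= 1 & res$years <= 12))
  # mu = 0: no loss channel, all censored
  p0 <- small_params(omega0 = 1, mu = 0)
  res0 <- persistence_times(p0, max_years = 2, replicates = 2, base_seed = 1)
  expect_true(all(res0$censored))
  expect_true(all(res0$years == 2))
})

test_that("gamma MLE recovers parameters from synthetic draws and handles edge cases", {
  set.seed(99)
  x <- rgamma(500, shape = 4, scale = 3)
  fit <- fit_gamma_mle(x)
  expect_equal(fit$mean, 12, tolerance = 0.1 * 12) # within 10% of the truth
  expect_equal(fit$shape, 4, tolerance = 1)
  expect_false(fit$degenerate)
  # censored entries are excluded with a warning
  df <- data.frame(years = c(x[1:50], 100, 100),
                   censored = c(rep(FALSE, 50), TRUE, TRUE))
  expect_warning(fit2 <- fit_gamma_mle(df), "censored")
  expect_equal(fit2$n, 50)
  # constant sample: degenerate point-mass limit, not an error
  fitc <- fit_gamma_mle(rep(7, 10))
  expect_true(fitc$degenerate)
  expect_equal(fitc$mean, 7)
  expect_true(is.infinite(fitc$shape))
  expect_error(fit_gamma_mle(5), "at least 2")
  expect_error(fit_gamma_mle(data.frame(years = c(3, 3), censored = TRUE)))
})

test_that("the moving-average fecundity threshold finds the first F reaching omega0", {
  Fs <- seq(0.001, 0.1, length.out = 50)
  # frequencies step from 0.1 to 0.9 at F = 0.05
  freqs <- ifelse(Fs < 0.05, 0.1, 0.9)
  fc <- wolbsim:::fc_from_samples(Fs, freqs, omega0 = 0.5, window = 10)
  expect_true(fc$reached)
  expect_gte(fc$Fc, 0.05)
  expect_lt(fc$Fc, 0.07) # within half a window of the true step
  # all frequencies above omega0: threshold is the smallest sampled F
  fc2 <- wolbsim:::fc_from_samples(Fs, rep(0.8, 50), 0.5, 10)
  expect_equal(fc2$Fc, Fs[1])
  fc0 <- wolbsim:::fc_from_samples(c(0, Fs), rep(0.8, 51), 0.5, 10)
  expect_equal(fc0$Fc, 0) # condition already holds at F = 0
  # never satisfied
  fc3 <- wolbsim:::fc_from_samples(Fs, rep(0.1, 50), 0.5, 10)
  expect_false(fc3$reached)
  expect_error(wolbsim:::fc_from_samples(Fs[1:5], rep(1, 5), 0.5, 10),
               "window")
})

test_that("relative RMSE matches closed forms and rejects bad observation tables", {
  days <- 1:150
  sim <- 0.5 + 0.002 * days
  obs_days <- c(20, 60, 100)
  expect_equal(relative_rmse(days, sim, obs_days, 0.5 + 0.002 * obs_days), 0)
  # constant offset d on constant level y -> 100 d / y
  expect_equal(relative_rmse(days, rep(0.45, 150), c(10, 50), c(0.5, 0.5)),
               100 * 0.05 / 0.5)
  set.seed(2)
  noisy <- 0.5 + 0.002 * obs_days + rnorm(3, 0, 0.05)
  expect_gt(relative_rmse(days, sim, obs_days, noisy), 0)
  expect_error(relative_rmse(days, sim, numeric(0), numeric(0)), "non-empty")
  expect_error(relative_rmse(days, sim, c(10, 200), c(0.5, 0.5)), "range")
  expect_equal(relative_rmse(days, rep(0.45, 150), c(10, 50), c(0.4, 0.6),
                             normalizer = "range"),
               100 * sqrt(mean(c(0.05, 0.15)^2)) / 0.2)
})

test_that("suppressor-flow bookkeeping separates the two CI outcomes", {
  # female-mortality CI destroys suppressor alleles carried by CI-killed
  # eggs; male-development CI retains them (the mechanism behind the faster
  # spread of suppressors under MD)
  mk <- function(fm, md)
    model_params(K = 600, P0 = 20, omega0 = 0.5, mu = 0.018,
                 sigma_fm = fm, sigma_md = md, sigma_total = 1,
                 suppressor_init_freq = 0.5)
  cf <- run_one_year(mk(1, 0), replicates = 5, base_seed = 7800)
  cm <- run_one_year(mk(0, 1), replicates = 5, base_seed = 7800)
  expect_gt(mean(cf$daily$supp_lost_in_ci), 0.02)
  expect_equal(mean(cm$daily$supp_lost_in_ci), 0) # no FM deaths under MD
  expect_gt(mean(cm$daily$newborn_supp_from_ci), 0.02)
})

test_that("Sd stability table pairs simulated long-run frequencies with the closed form", {
  p <- small_params(omega0 = 0.6, mu = 0.02)
  res <- sd_stability_check(p, c(0.05, 0.1), years = 3, replicates = 2,
                            base_seed = 11)
  expect_equal(res$Sd, c(0.05, 0.1))
  expect_equal(res$predicted[1], stable_infection_freq(0.05, 0.02)$omega)
  expect_true(all(res$simulated >= 0 & res$simulated <= 1))
  expect_warning(sd_stability_check(small_params(sigma_fm = 0.5, sigma_md = 0,
                                                 sigma_total = 0.5,
                                                 omega0 = 0.5),
                                    0.05, years = 1, replicates = 1),
                 "sigma_total = 0")
})
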