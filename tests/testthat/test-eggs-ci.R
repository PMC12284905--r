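ref_traits <- list(M = 11, Mp = 16, D = 20, eggsM = 1, eggsMp = 10)

test_that("oviposition schedule is piecewise linear between maturity, peak and death", {
  expect_equal(expected_eggs(11, ref_traits), 1)   # eggs at maturity
  expect_equal(expected_eggs(16, ref_traits), 10)  # eggs at the peak
  expect_equal(expected_eggs(13, ref_traits), 4.6) # 1 + (13-11)/(16-11)*9
  expect_equal(expected_eggs(9, ref_traits), 0)    # juvenile
  expect_equal(expected_eggs(18, ref_traits), 5)   # 10*(20-18)/(20-16)
  expect_equal(expected_eggs(20, ref_traits), 0)   # death age
  # continuity at the peak and linearity of both branches
  ages <- seq(11, 19.99, by = 0.01)
  e <- expected_eggs(ages, ref_traits)
  expect_true(all(diff(e[ages < 16]) > 0))
  expect_true(all(diff(e[ages >= 16]) < 0))
  expect_equal(expected_eggs(16 - 1e-9, ref_traits), 10, tolerance = 1e-6)
})

test_that("realized egg counts are non-negative integers centered on the expectation", {
  set.seed(1)
  expect_true(all(draw_egg_count(rep(0, 1000)) >= 0))
  x <- draw_egg_count(rep(10, 5000))
  expect_equal(mean(x), 10, tolerance = 0.05)
  x <- draw_egg_count(rep(4.6, 5000))
  expect_true(all(x %in% 0:10))
  expect_equal(mean(x), 4.6, tolerance = 0.1) # rounds toward ~5 eggs
  expect_true(mean(x %in% 4:5) > 0.8)
})

test_that("additive suppression: each sperm-borne allele removes 1/L of both CI components", {
  eff <- effective_ci(1, 0, 2, 5)
  expect_equal(eff$theta, 0.40)            # worked two-suppressor example
  eff <- effective_ci(0.98, 0.02, 0, 5)    # Beis, no suppression
  expect_equal(eff$theta, 0.02)
  expect_equal(eff$sigma_md_eff, 0.02)
  eff <- effective_ci(0.7, 0.3, 5, 5)      # full suppression
  expect_equal(eff$theta, 1)
  expect_equal(eff$sigma_md_eff, 0)
  expect_error(effective_ci(1, 0, 6, 5), "\\[0, L\\]")
  # strict additivity across all counts
  for (s in 0:5) {
    eff <- effective_ci(0.9, 0.1, s, 5)
    expect_equal(eff$theta, 1 - 0.9 * (1 - s / 5))
    expect_equal(eff$sigma_md_eff, 0.1 * (1 - s / 5))
  }
})

test_that("hatch rate of incompatible crosses matches 1 - sigma_fm(1 - s/L) for every suppressor count", {
  # theta oracle: simulate >= 1e4 fertilized eggs per suppressor count
  p <- model_params(sigma_fm = 1, sigma_md = 0, sigma_total = 1)
  set.seed(42)
  for (s in 0:5) {
    st <- make_state(600, p, age = 16, infected = FALSE,
                     sperm_inf = TRUE, sperm_s = s)
    ovi <- produce_offspring(st, p)
    n_fert <- sum(ovi$newborn$female) + ovi$n_ci_killed
    expect_gt(n_fert, 1e4 * 0.4) # enough eggs for a tight binomial check
    hatch <- sum(ovi$newborn$female) / n_fert
    theta <- 1 - 1 * (1 - s / 5)
    se <- sqrt(max(theta * (1 - theta), 0.25 / n_fert) / n_fert)
    expect_lt(abs(hatch - theta), max(4 * se, 0.01))
  }
})

test_that("every egg resolves to exactly one fate (dead, male or female)", {
  set.seed(11)
  for (i in 1:10) {
    fm <- runif(1)
    md <- runif(1, 0, 1 - fm)
    p <- model_params(sigma_fm = fm, sigma_md = md, sigma_total = fm + md,
                      mu = runif(1, 0, 0.05), Sd = runif(1, 0, 0.2),
                      F = runif(1, 0, 0.1))
    st <- make_state(80, p, age = 14, infected = c(TRUE, FALSE),
                     sperm_inf = c(FALSE, TRUE), sperm_s = sample(0:5, 1))
    ovi <- produce_offspring(st, p)
    nb <- ovi$newborn
    n_out <- ovi$n_ci_killed + sum(nb$female) + sum(!nb$female)
    expect_identical(n_out, ovi$n_eggs)
  }
})

test_that("extreme CI regimes produce the stated egg fates", {
  p_fm <- model_params(sigma_fm = 1, sigma_md = 0, sigma_total = 1)
  set.seed(5)
  st <- make_state(100, p_fm, age = 16, infected = FALSE, sperm_inf = TRUE)
  ovi <- produce_offspring(st, p_fm)
  expect_true(all(!ovi$newborn$female))  # only unfertilized-egg males hatch
  expect_gt(ovi$n_ci_killed, 0)

  p_md <- model_params(sigma_fm = 0, sigma_md = 1, sigma_total = 1)
  ovi <- produce_offspring(st, p_md)
  expect_identical(ovi$n_ci_killed, 0L)  # all fertilized eggs develop as males
  expect_true(all(!ovi$newborn$female))

  # sigma_fm = 0.9 / sigma_md = 0.1: deaths ~90% of fertilized eggs,
  # male development ~10% of the survivors
  p_mix <- model_params(sigma_fm = 0.9, sigma_md = 0.1, sigma_total = 1)
  st <- make_state(2000, p_mix, age = 16, infected = FALSE, sperm_inf = TRUE)
  ovi <- produce_offspring(st, p_mix)
  nb <- ovi$newborn
  n_unfert_male <- round(ovi$n_eggs * 0.2)
  # fertilized eggs = CI-killed + hatched females + MD-converted males
  death_rate <- ovi$n_ci_killed / (ovi$n_ci_killed + sum(nb$female) +
                                     (sum(!nb$female) - n_unfert_male))
  expect_equal(death_rate, 0.9, tolerance = 0.02)
})

test_that("maternal transmission and fecundity effects act on infected mothers only", {
  set.seed(3)
  p <- model_params(mu = 0)
  st <- make_state(200, p, age = 14, infected = TRUE, sperm_inf = TRUE)
  ovi <- produce_offspring(st, p)
  expect_true(all(ovi$newborn$infected)) # mu = 0: no loss channel
  p2 <- model_params(mu = 0.3)
  ovi <- produce_offspring(st, p2)
  expect_equal(mean(ovi$newborn$infected), 0.7, tolerance = 0.03)
  # uninfected mothers never transmit
  st0 <- make_state(200, p2, age = 14, infected = FALSE)
  ovi <- produce_offspring(st0, p2)
  expect_true(all(!ovi$newborn$infected))
  # fecundity effect: egg output of infected mothers scales by 1 + F
  pf <- model_params(F = 0.10)
  o1 <- produce_offspring(make_state(3000, pf, age = 16, infected = TRUE), pf)
  o0 <- produce_offspring(make_state(3000, pf, age = 16, infected = FALSE), pf)
  expect_equal(o1$n_eggs / o0$n_eggs, 1.10, tolerance = 0.02)
})

test_that("sex-allocation distortion shifts the brood toward females in infected mothers", {
  set.seed(9)
  p <- model_params(Sd = 0.1) # alpha = 0.5
  st <- make_state(2000, p, age = 16, infected = TRUE, sperm_inf = TRUE)
  ovi <- produce_offspring(st, p)
  # fertilized share: lam + alpha (1 - lam) = 0.9
  expect_equal(mean(ovi$newborn$female), 0.9, tolerance = 0.01)
  st0 <- make_state(2000, p, age = 16, infected = FALSE)
  ovi0 <- produce_offspring(st0, p)
  expect_equal(mean(ovi0$newborn$female), 0.8, tolerance = 0.01)
})

test_that("offspring haplotypes recombine freely from the maternal pair", {
  set.seed(13)
  p <- model_params()
  st <- make_state(500, p, age = 16)
  st$pop$hm[] <- 1L # heterozygous at every locus
  st$pop$hp[] <- 0L
  ovi <- produce_offspring(st, p)
  nb <- ovi$newborn
  # each oocyte locus takes the active allele with probability 1/2
  expect_equal(mean(nb$hm), 0.5, tolerance = 0.02)
  # males carry no paternal genome
  expect_true(all(nb$hp[!nb$female, ] == 0))
  # daughters carry the sperm haplotype (all zero here) as paternal
  expect_true(all(nb$hp[nb$female, ] == 0))
})
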