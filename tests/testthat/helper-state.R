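# Construct small, fully specified populations for unit tests.

beis_params <- function(mu = 0.018, omega0 = 0.5, ...) {
  model_params(sigma_fm = 0.98, sigma_md = 0.02, sigma_total = 1,
               mu = mu, omega0 = omega0, ...)
}

# A hand-built state of `n` mated adult females with controlled infection and
# sperm attributes, plus optionally `n_males` mature males.
make_state <- function(n, params = model_params(), age = 13,
                       infected = FALSE, mated = TRUE,
                       sperm_inf = FALSE, sperm_s = 0,
                       hap = 0L, n_males = 0, male_infected = FALSE,
                       male_hap = 0L) {
  L <- as.integer(params$L)
  pop <- wolbsim:::.cohort(n + n_males, L)
  fem <- c(rep(TRUE, n), rep(FALSE, n_males))
  pop$female <- fem
  pop$age <- rep(age, n + n_males)
  pop$infected <- c(rep_len(infected, n), rep_len(male_infected, n_males))
  pop$D <- rep(params$D_mean, n + n_males)
  pop$M <- c(rep(params$M_female_mean, n), rep(params$M_male_mean, n_males))
  pop$Mp[fem] <- params$Mp_mean
  pop$eggsM[fem] <- params$eggsM_mean
  pop$eggsMp[fem] <- params$eggsMp_mean
  pop$hm <- matrix(rep_len(as.integer(hap), (n + n_males) * L),
                   n + n_males, L)
  pop$hp <- pop$hm
  pop$hp[!fem, ] <- 0L
  if (n_males > 0)
    pop$hm[!fem, ] <- matrix(rep_len(as.integer(male_hap), n_males * L),
                             n_males, L)
  pop$mated <- c(rep_len(mated, n), rep(FALSE, n_males))
  sperm <- matrix(0L, n + n_males, L)
  if (sperm_s > 0)
    sperm[seq_len(n), seq_len(sperm_s)] <- 1L
  pop$sperm_h <- sperm
  pop$sperm_inf <- c(rep_len(sperm_inf, n), rep(FALSE, n_males))
  st <- list(day = 0L, year = 1L, A = (params$K - n) / max(n, 1),
             r = 0.05, pop = pop, n_created = n + n_males,
             deaths_by_age = numeric(64), extinct = FALSE)
  class(st) <- "wolb_state"
  st
}
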