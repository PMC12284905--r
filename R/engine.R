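# Core daily life cycle of the individual-based model.
#
# The living population is held in struct-of-arrays form: parallel vectors and
# L-column 0/1 matrices, one row per individual. All per-day operations
# (mating, oviposition, egg-fate resolution, mortality, aging) are vectorized
# across individuals; a replicate draws all randomness from R's global RNG,
# seeded once per replicate.

# allocate an empty cohort of n individuals with L suppressor loci
.cohort <- function(n, L) {
  list(female    = logical(n),
       age       = numeric(n),
       infected  = logical(n),
       hm        = matrix(0L, n, L),  # maternal haplotype
       hp        = matrix(0L, n, L),  # paternal haplotype (females only)
       D         = numeric(n),
       M         = numeric(n),
       Mp        = rep(NA_real_, n),
       eggsM     = rep(NA_real_, n),
       eggsMp    = rep(NA_real_, n),
       mated     = logical(n),
       sperm_h   = matrix(0L, n, L),
       sperm_inf = logical(n))
}

.cohort_size <- function(pop) length(pop$female)

.cohort_subset <- function(pop, keep) {
  pop$hm <- pop$hm[keep, , drop = FALSE]
  pop$hp <- pop$hp[keep, , drop = FALSE]
  pop$sperm_h <- pop$sperm_h[keep, , drop = FALSE]
  for (f in c("female", "age", "infected", "D", "M", "Mp", "eggsM",
              "eggsMp", "mated", "sperm_inf"))
    pop[[f]] <- pop[[f]][keep]
  pop
}

.cohort_bind <- function(a, b) {
  if (.cohort_size(b) == 0L) return(a)
  if (.cohort_size(a) == 0L) return(b)
  a$hm <- rbind(a$hm, b$hm)
  a$hp <- rbind(a$hp, b$hp)
  a$sperm_h <- rbind(a$sperm_h, b$sperm_h)
  for (f in c("female", "age", "infected", "D", "M", "Mp", "eggsM",
              "eggsMp", "mated", "sperm_inf"))
    a[[f]] <- c(a[[f]], b[[f]])
  a
}

# female life-history traits with M < Mp < D enforced by redraw
.draw_female_traits <- function(n, p) {
  D  <- stats::rnorm(n, p$D_mean, p$trait_sd)
  M  <- stats::rnorm(n, p$M_female_mean, p$trait_sd)
  Mp <- stats::rnorm(n, p$Mp_mean, p$trait_sd)
  bad <- which(!(M < Mp & Mp < D))
  while (length(bad)) {
    D[bad]  <- stats::rnorm(length(bad), p$D_mean, p$trait_sd)
    M[bad]  <- stats::rnorm(length(bad), p$M_female_mean, p$trait_sd)
    Mp[bad] <- stats::rnorm(length(bad), p$Mp_mean, p$trait_sd)
    bad <- bad[!(M[bad] < Mp[bad] & Mp[bad] < D[bad])]
  }
  list(D = D, M = M, Mp = Mp,
       eggsM  = stats::rnorm(n, p$eggsM_mean, p$trait_sd),
       eggsMp = stats::rnorm(n, p$eggsMp_mean, p$trait_sd))
}

.draw_male_traits <- function(n, p) {
  D <- stats::rnorm(n, p$D_mean, p$trait_sd)
  M <- stats::rnorm(n, p$M_male_mean, p$trait_sd)
  bad <- which(!(M < D))
  while (length(bad)) {
    D[bad] <- stats::rnorm(length(bad), p$D_mean, p$trait_sd)
    M[bad] <- stats::rnorm(length(bad), p$M_male_mean, p$trait_sd)
    bad <- bad[!(M[bad] < D[bad])]
  }
  list(D = D, M = M)
}

#' Initialize a population of founding adult females
#'
#' Creates `P0` adult females at their individual maturity age. Exactly
#' `round(omega0 * P0)` of them are infected (random assignment). Every founder
#' is pre-inseminated: her stored sperm carries the infection state of a male
#' of her own line (donor infected iff she is infected, mirroring within-line
#' matings of the founding cultures) and suppressor alleles drawn i.i.d.
#' Bernoulli(`suppressor_init_freq`), as are her own haplotypes. The logistic
#' mortality constants are set to `A = (K - P0)/P0` and `r = log(A)/r_half_day`
#' so the population target reaches `K/2` at day `r_half_day`.
#'
#' @param params a [model_params()] object.
#' @return an object of class `wolb_state`: the population on day 0.
#' @examples
#' set.seed(1)
#' st <- init_population(model_params(omega0 = 0.5))
#' st$A # 99 for K = 5000, P0 = 50
#' @export
init_population <- function(params) {
  p <- validate_params(params)
  n <- as.integer(p$P0)
  if (n <= 0) stop("P0 must be positive", call. = FALSE)
  L <- as.integer(p$L)
  pop <- .cohort(n, L)
  tr <- .draw_female_traits(n, p)
  pop$female <- rep(TRUE, n)
  pop$D <- tr$D; pop$M <- tr$M; pop$Mp <- tr$Mp
  pop$eggsM <- tr$eggsM; pop$eggsMp <- tr$eggsMp
  pop$age <- tr$M # founders enter as newly molted adults
  n_inf <- as.integer(round(p$omega0 * n))
  inf <- rep(FALSE, n)
  inf[sample.int(n, n_inf)] <- TRUE
  pop$infected <- inf
  q <- p$suppressor_init_freq
  pop$hm <- matrix(stats::rbinom(n * L, 1L, q), n, L)
  pop$hp <- matrix(stats::rbinom(n * L, 1L, q), n, L)
  pop$mated <- rep(TRUE, n)
  pop$sperm_h <- matrix(stats::rbinom(n * L, 1L, q), n, L)
  pop$sperm_inf <- inf # within-line virtual mates
  A <- (p$K - n) / n
  r <- if (A > 1) log(A) / p$r_half_day else 0
  state <- list(day = 0L, year = 1L, A = A, r = r, pop = pop,
                n_created = n, deaths_by_age = numeric(64), extinct = FALSE)
  class(state) <- "wolb_state"
  state
}

#' @export
print.wolb_state <- function(x, ...) {
  n <- .cohort_size(x$pop)
  cat(sprintf("<wolb_state> day %d of year %d: %d individuals (%d female), %.1f%% infected\n",
              x$day, x$year, n, sum(x$pop$female),
              if (n) 100 * mean(x$pop$infected) else 0))
  invisible(x)
}

#' Expected daily oviposition as a function of female age
#'
#' Piecewise-linear fecundity schedule: rises from `eggsM` at maturity `M` to
#' `eggsMp` at the peak `Mp`, then declines linearly to 0 at the natural death
#' age `D`; zero outside `[M, D)`.
#'
#' @param age age in days (vectorized).
#' @param traits list (or data frame) with numeric elements `M`, `Mp`, `D`,
#'   `eggsM`, `eggsMp`, recycled against `age`.
#' @return expected eggs per day.
#' @examples
#' tr <- list(M = 11, Mp = 16, D = 20, eggsM = 1, eggsMp = 10)
#' expected_eggs(c(9, 11, 13, 16, 18), tr)
#' @export
expected_eggs <- function(age, traits) {
  M <- traits$M; Mp <- traits$Mp; D <- traits$D
  eM <- traits$eggsM; eMp <- traits$eggsMp
  rising  <- age >= M & age < Mp
  falling <- age >= Mp & age < D
  out <- numeric(length(age))
  out[rising] <- ((eMp * (age - M) + eM * (Mp - age)) / (Mp - M))[rising]
  out[falling] <- (eMp * (D - age) / (D - Mp))[falling] # eggs at D are 0
  out
}

#' Realized daily egg count
#'
#' Draws the actual number of eggs laid: `Normal(expected, sd)` rounded to the
#' nearest integer and clamped below at zero.
#'
#' @param expected expected eggs/day (vectorized).
#' @param sd standard deviation of the daily draw (default 0.5).
#' @return non-negative integer counts.
#' @export
draw_egg_count <- function(expected, sd = 0.5) {
  pmax(0L, as.integer(round(stats::rnorm(length(expected), expected, sd))))
}

#' Effective CI strength under additive polygenic suppression
#'
#' Each active suppressor allele carried by the fertilizing male reduces both
#' CI components by a fraction `1/L`, strictly additively and without
#' epistasis. With `s` active alleles the hatch probability of a fertilized
#' egg in an incompatible cross is `theta = 1 - sigma_fm * (1 - s/L)` and the
#' male-development probability of a hatched egg is
#' `sigma_md_eff = sigma_md * (1 - s/L)`.
#'
#' @param sigma_fm,sigma_md CI component strengths.
#' @param s number of active suppressor alleles on the sperm haplotype
#'   (vectorized), between 0 and `L`.
#' @param L suppressor loci per haploid genome.
#' @return list with elements `theta` and `sigma_md_eff`.
#' @examples
#' effective_ci(1, 0, 2, 5)$theta # 0.40
#' @export
effective_ci <- function(sigma_fm, sigma_md, s, L) {
  if (any(s < 0 | s > L)) stop("suppressor count must lie in [0, L]", call. = FALSE)
  rel <- 1 - s / L
  list(theta = 1 - sigma_fm * rel, sigma_md_eff = sigma_md * rel)
}

#' Mate all virgin adult females
#'
#' Each virgin adult female (age at or above her maturity) is paired with a
#' uniformly random mature male; his haplotype and infection state are stored
#' as her sperm for life (first-male sperm precedence). Males may fertilize
#' any number of females. With no mature male present, females stay virgin and
#' are retried the next day.
#'
#' @param state a `wolb_state`.
#' @return the updated state.
#' @export
mate_virgins <- function(state) {
  pop <- state$pop
  virgins <- which(pop$female & !pop$mated & pop$age >= pop$M)
  if (!length(virgins)) return(state)
  males <- which(!pop$female & pop$age >= pop$M)
  if (!length(males)) return(state)
  mates <- males[sample.int(length(males), length(virgins), replace = TRUE)]
  pop$sperm_h[virgins, ] <- pop$hm[mates, , drop = FALSE]
  pop$sperm_inf[virgins] <- pop$infected[mates]
  pop$mated[virgins] <- TRUE
  state$pop <- pop
  state
}

# Resolve one day of oviposition for the given mothers (indices into the
# population). Returns the newborn cohort plus per-day bookkeeping.
#
# Egg fate order: base count -> fecundity duplication (F) -> fertilization
# (lambda) -> Sd extra fertilization (alpha) -> maternal transmission (1 - mu)
# -> oocyte haplotype (free recombination) -> CI resolution.
.oviposit <- function(state, params, mothers) {
  p <- params
  pop <- state$pop
  L <- as.integer(p$L)
  empty <- list(newborn = .cohort(0L, L), n_laid_mothers = 0L,
                ci_cross_frac = 0, newborn_supp_from_ci = 0,
                supp_lost_in_ci = 0, n_eggs = 0L, n_ci_killed = 0L,
                mean_mother_age = NA_real_)
  if (!length(mothers)) return(empty)

  E <- expected_eggs(pop$age[mothers],
                     list(M = pop$M[mothers], Mp = pop$Mp[mothers],
                          D = pop$D[mothers], eggsM = pop$eggsM[mothers],
                          eggsMp = pop$eggsMp[mothers]))
  n_base <- draw_egg_count(E)
  m_inf <- pop$infected[mothers]
  n_tot <- n_base
  if (p$F > 0 && any(m_inf)) # each egg of an infected female may spawn an extra one
    n_tot[m_inf] <- n_base[m_inf] +
      stats::rbinom(sum(m_inf), n_base[m_inf], p$F)
  laid <- n_tot > 0L
  if (!any(laid)) return(empty)

  mi <- rep(mothers, n_tot)              # mother of each egg
  ne <- length(mi)
  minf <- pop$infected[mi]
  sperm_inf <- pop$sperm_inf[mi]

  fert <- stats::runif(ne) < p$lam
  if (p$Sd > 0) {                        # sex-allocation distortion
    alpha <- alpha_from_sd(p$Sd, p$lam)
    gain <- !fert & minf & (stats::runif(ne) < alpha)
    fert <- fert | gain
  }
  egg_inf <- minf & (stats::runif(ne) < 1 - p$mu)

  # oocyte haplotype: each locus takes one of the mother's alleles at random
  pick <- matrix(stats::runif(ne * L) < 0.5, ne, L)
  oo <- pop$hm[mi, , drop = FALSE]
  hp_m <- pop$hp[mi, , drop = FALSE]
  oo[!pick] <- hp_m[!pick]
  sperm <- pop$sperm_h[mi, , drop = FALSE]

  incomp_cross <- !minf & sperm_inf      # uninfected mother, infected sperm
  exposed <- if (p$ci_rescue_scope == "egg_level") !egg_inf & sperm_inf
             else incomp_cross
  ci_egg <- fert & exposed
  s <- .rowSums(sperm, ne, L)
  eff <- effective_ci(p$sigma_fm, p$sigma_md, s, L)
  dies <- ci_egg & (stats::runif(ne) >= eff$theta)
  md_male <- ci_egg & !dies & (stats::runif(ne) < eff$sigma_md_eff)

  female_off <- fert & !dies & !md_male
  keep <- !dies
  nk <- sum(keep)

  nb <- .cohort(nk, L)
  nb$female <- female_off[keep]
  nb$age <- numeric(nk)
  nb$infected <- egg_inf[keep]           # CI eggs are uninfected by construction
  nb$hm <- oo[keep, , drop = FALSE]
  hp <- matrix(0L, nk, L)
  fem <- nb$female
  if (any(fem)) {
    sp_keep <- sperm[keep, , drop = FALSE]
    hp[fem, ] <- sp_keep[fem, , drop = FALSE]
  }
  nb$hp <- hp
  if (any(fem)) {
    tr <- .draw_female_traits(sum(fem), p)
    nb$D[fem] <- tr$D; nb$M[fem] <- tr$M; nb$Mp[fem] <- tr$Mp
    nb$eggsM[fem] <- tr$eggsM; nb$eggsMp[fem] <- tr$eggsMp
  }
  if (any(!fem)) {
    tr <- .draw_male_traits(sum(!fem), p)
    nb$D[!fem] <- tr$D; nb$M[!fem] <- tr$M
  }

  # -- per-day bookkeeping -------------------------------------------------
  moth_laid <- mothers[laid]
  ci_mothers <- (!pop$infected & pop$sperm_inf)[moth_laid]
  alleles_per_egg <- .rowSums(oo, ne, L) + ifelse(fert, s, 0L)
  nb_alleles <- .rowSums(oo[keep, , drop = FALSE], nk, L) +
    ifelse(female_off[keep], s[keep], 0L)
  from_ci <- incomp_cross[keep]
  tot_nb_alleles <- sum(nb_alleles)
  lost_alleles <- sum(alleles_per_egg[dies])
  compat_alleles <- sum(alleles_per_egg[!incomp_cross])

  list(newborn = nb,
       n_laid_mothers = length(moth_laid),
       ci_cross_frac = mean(ci_mothers),
       newborn_supp_from_ci = if (tot_nb_alleles > 0)
         sum(nb_alleles[from_ci]) / tot_nb_alleles else 0,
       supp_lost_in_ci = if (compat_alleles > 0 && lost_alleles > 0)
         lost_alleles / compat_alleles else 0,
       n_eggs = ne, n_ci_killed = sum(dies),
       # realized generation interval: egg-weighted age of mothers
       mean_mother_age = mean(pop$age[mi]))
}

#' Offspring of mated adult females for one day
#'
#' Resolves one oviposition event for the selected mothers: realized egg
#' count, fecundity duplication in infected females (`F`), fertilization
#' (`lam`), extra Sd fertilization (`alpha = Sd/(1-lam)`), maternal
#' transmission (`1 - mu`), free recombination of the oocyte haplotype, and CI
#' resolution. Fertilized eggs of an incompatible cross die with probability
#' `1 - theta`; survivors develop as haploid males (maternal genome only) with
#' probability `sigma_md_eff`, else as uninfected diploid females.
#'
#' @param state a `wolb_state`.
#' @param params the [model_params()] in force.
#' @param mothers indices of the ovipositing females; defaults to every mated
#'   adult female alive. Virgin females do not oviposit.
#' @return list with the newborn cohort (`newborn`) and per-day bookkeeping:
#'   `ci_cross_frac` (fraction of laying mothers in an incompatible cross),
#'   `newborn_supp_from_ci`, `supp_lost_in_ci`, `n_eggs`, `n_ci_killed`.
#' @export
produce_offspring <- function(state, params, mothers = NULL) {
  pop <- state$pop
  if (is.null(mothers))
    mothers <- which(pop$female & pop$mated & pop$age >= pop$M &
                     pop$age < pop$D)
  .oviposit(state, params, mothers)
}

#' Daily logistic mortality fraction
#'
#' Proportion of the population that dies at the end of day `t` so that total
#' population size tracks the logistic curve `K / (1 + A * exp(-r t))`:
#' `psi = (Pt - target) / Pt`, clamped to `[0, 1]` (no deaths while the
#' population is below target).
#'
#' @param Pt total population size (eggs + juveniles + adults).
#' @param t day within the season.
#' @param K carrying capacity.
#' @param A,r logistic constants (see [init_population()]).
#' @return the death proportion `psi` in [0, 1].
#' @export
mortality_fraction <- function(Pt, t, K, A, r) {
  if (Pt <= 0) return(0)
  target <- K / (1 + A * exp(-r * t))
  min(1, max(0, (Pt - target) / Pt))
}

#' Apply random mortality and aging
#'
#' Removes a proportion `psi` of the population uniformly at random
#' (irrespective of age, sex or infection status), then increments all ages by
#' one day and removes individuals that reached their natural death age `D`.
#' With `mortality_mode = "fixed"` exactly `round(psi * Pt)` individuals are
#' removed (lower variance); `"bernoulli"` kills each individual independently
#' with probability `psi`.
#'
#' @param state a `wolb_state`.
#' @param psi death proportion in [0, 1].
#' @param params the [model_params()] in force.
#' @return the updated state (death-age tallies accumulated).
#' @export
apply_mortality_and_aging <- function(state, psi, params) {
  pop <- state$pop
  n <- .cohort_size(pop)
  if (n == 0L) return(state)
  if (psi > 0) {
    if (params$mortality_mode == "bernoulli") {
      dead <- which(stats::runif(n) < psi)
    } else {
      k <- as.integer(round(psi * n))
      dead <- if (k > 0L) sample.int(n, k) else integer(0)
    }
    if (length(dead)) {
      state$deaths_by_age <- .tally_ages(state$deaths_by_age, pop$age[dead])
      pop <- .cohort_subset(pop, -dead)
    }
  }
  pop$age <- pop$age + 1
  old <- pop$age >= pop$D
  if (any(old)) {
    state$deaths_by_age <- .tally_ages(state$deaths_by_age, pop$age[old])
    pop <- .cohort_subset(pop, !old)
  }
  state$pop <- pop
  if (.cohort_size(pop) == 0L) state$extinct <- TRUE
  state
}

.tally_ages <- function(tally, ages) {
  idx <- pmin(floor(ages), length(tally) - 1L) + 1L
  t2 <- tabulate(idx, nbins = length(tally))
  tally + t2
}

#' Population observables for one day
#'
#' Infection frequencies (females, males, all), male:female ratio, suppressor
#' allele frequency and population size over the living individuals, plus the
#' day's cross and suppressor-flow statistics when oviposition bookkeeping is
#' supplied. Frequencies over empty categories are 0 by convention.
#'
#' @param state a `wolb_state`.
#' @param ovi oviposition bookkeeping as returned by [produce_offspring()], or
#'   `NULL` (cross statistics reported as 0).
#' @param psi the death proportion applied that day.
#' @return a one-row `data.frame` (a `DailyRecord`).
#' @export
measure <- function(state, ovi = NULL, psi = 0) {
  pop <- state$pop
  n <- .cohort_size(pop)
  nf <- sum(pop$female)
  nm <- n - nf
  adult <- pop$age >= pop$M
  naf <- sum(adult & pop$female)
  nam <- sum(adult) - naf
  n_inf_f <- sum(pop$infected & pop$female)
  n_inf_m <- sum(pop$infected) - n_inf_f
  L <- ncol(pop$hm)
  supp <- if (n > 0) {
    (sum(pop$hm) + sum(pop$hp[pop$female, , drop = FALSE])) /
      (L * (n + nf))
  } else 0
  data.frame(day = state$day, year = state$year, pop_size = n,
             inf_freq_female = if (nf) n_inf_f / nf else 0,
             inf_freq_male = if (nm) n_inf_m / nm else 0,
             inf_freq_all = if (n) (n_inf_f + n_inf_m) / n else 0,
             mf_ratio = if (nf) nm / nf else 0,
             mf_ratio_adult = if (naf) nam / naf else 0,
             ci_cross_frac = if (is.null(ovi)) 0 else ovi$ci_cross_frac,
             psi = psi,
             suppressor_freq = supp,
             newborn_supp_from_ci = if (is.null(ovi)) 0 else ovi$newborn_supp_from_ci,
             supp_lost_in_ci = if (is.null(ovi)) 0 else ovi$supp_lost_in_ci,
             n_born = if (is.null(ovi)) 0L else
               .cohort_size(ovi$newborn),
             n_eggs = if (is.null(ovi)) 0L else ovi$n_eggs,
             mean_mother_age = if (is.null(ovi)) NA_real_ else
               ovi$mean_mother_age)
}

#' Advance the population by one day
#'
#' Runs one full daily cycle in order: mating of virgins, oviposition by every
#' mated adult female (newborn eggs join at age 0), logistic mortality on the
#' post-reproduction total, aging and natural death, and measurement on the
#' survivors. An empty population is absorbing and records zeros.
#'
#' @param state a `wolb_state`.
#' @param params the [model_params()] in force.
#' @return list with elements `state` and `record` (one-row data frame).
#' @export
step_day <- function(state, params) {
  t <- state$day + 1L
  if (.cohort_size(state$pop) == 0L) {
    state$day <- t
    rec <- measure(state, NULL, 0)
    rec$day <- t
    return(list(state = state, record = rec))
  }
  state <- mate_virgins(state)
  ovi <- produce_offspring(state, params)
  nb <- ovi$newborn
  n_nb <- .cohort_size(nb)
  if (n_nb > 0L) state$pop <- .cohort_bind(state$pop, nb)
  state$n_created <- state$n_created + ovi$n_eggs
  if (ovi$n_ci_killed > 0L) # CI-killed eggs die at age 0
    state$deaths_by_age <- .tally_ages(state$deaths_by_age,
                                       numeric(ovi$n_ci_killed))
  Pt <- .cohort_size(state$pop)
  psi <- mortality_fraction(Pt, t, params$K, state$A, state$r)
  state <- apply_mortality_and_aging(state, psi, params)
  state$day <- t
  list(state = state, record = measure(state, ovi, psi))
}

#' Run one reproductive season
#'
#' Iterates [step_day()] for `params$T` days (default 150, about 14 host
#' generations) from a fresh or supplied starting population.
#'
#' @param params a [model_params()] object.
#' @param state optional starting `wolb_state`; a new population is initialized
#'   when `NULL`.
#' @return list of class `wolb_season` with the final `state` and `daily`, a
#'   data frame of per-day records.
#' @examples
#' set.seed(42)
#' p <- model_params(K = 500, P0 = 20, omega0 = 0.5,
#'                   sigma_fm = 0.98, sigma_md = 0.02, sigma_total = 1,
#'                   mu = 0.018)
#' season <- run_season(p)
#' tail(season$daily$inf_freq_female, 1)
#' @export
run_season <- function(params, state = NULL) {
  p <- validate_params(params)
  if (is.null(state)) state <- init_population(p)
  days <- as.integer(p$T)
  recs <- vector("list", days)
  for (t in seq_len(days)) {
    out <- step_day(state, p)
    state <- out$state
    recs[[t]] <- out$record
  }
  res <- list(state = state, daily = do.call(rbind, recs))
  class(res) <- "wolb_season"
  res
}

#' @export
print.wolb_season <- function(x, ...) {
  last <- x$daily[nrow(x$daily), ]
  cat(sprintf("<wolb_season> %d days; final: %d individuals, infection %.3f (females), m:f %.3f\n",
              nrow(x$daily), last$pop_size, last$inf_freq_female, last$mf_ratio))
  invisible(x)
}

#' Start the next reproductive season
#'
#' Resets the day counter, recomputes the logistic constant `A` from the new
#' season's founding size (the growth rate `r` is kept from the first season
#' whenever the founders already number `K/2` or more) and optionally applies
#' the carryover regime: `"full"` keeps the entire population (no drift at the
#' transition), `"subsample"` keeps a uniform random subset of size `P0`
#' (periodic bottleneck, injecting drift). Ages and states carry over.
#'
#' @param state a `wolb_state` at the end of a season.
#' @param params the [model_params()] in force.
#' @param carryover `"full"` or `"subsample"`.
#' @return the state ready for the next season.
#' @export
next_season <- function(state, params, carryover = c("full", "subsample")) {
  carryover <- match.arg(carryover)
  pop <- state$pop
  n <- .cohort_size(pop)
  if (carryover == "subsample" && n > params$P0) {
    keep <- sample.int(n, as.integer(params$P0))
    pop <- .cohort_subset(pop, keep)
    n <- .cohort_size(pop)
  }
  state$pop <- pop
  state$day <- 0L
  state$year <- state$year + 1L
  if (n > 0L) {
    A <- max(0, (params$K - n) / n)
    state$A <- A
    if (A > 1) state$r <- log(A) / params$r_half_day
  }
  state
}
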