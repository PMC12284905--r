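# Experiment harness: replicated campaigns over the individual-based model,
# comparisons against the deterministic recursions, multi-year coevolution
# runs, persistence-time and fecundity-threshold analyses.
#
# Seed discipline: replicate i of a campaign with base seed s is seeded with
# s + i (grid campaigns advance the base seed by `replicates` per cell), so a
# campaign is bit-reproducible from its base seed alone.

#' Replicated one-season campaign
#'
#' Runs `replicates` independent one-season simulations and aggregates the
#' daily records.
#'
#' @param params a [model_params()] object.
#' @param replicates number of independent runs (the reference analyses use
#'   100).
#' @param base_seed integer; replicate `i` uses seed `base_seed + i`.
#' @return list of class `wolb_campaign` with `daily` (per-replicate records,
#'   column `rep`), `summary` (per-day mean and sd of the main observables)
#'   and `final` (one row per replicate: end-of-season state).
#' @examples
#' \donttest{
#' p <- model_params(K = 500, P0 = 20, omega0 = 0.5,
#'                   sigma_fm = 0.98, sigma_md = 0.02, sigma_total = 1,
#'                   mu = 0.018)
#' camp <- run_one_year(p, replicates = 3, base_seed = 1)
#' head(camp$summary)
#' }
#' @export
run_one_year <- function(params, replicates = 100, base_seed = 1) {
  stopifnot(replicates >= 1)
  daily <- vector("list", replicates)
  final <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    set.seed(base_seed + i)
    season <- run_season(params)
    d <- season$daily
    d$rep <- i
    daily[[i]] <- d
    last <- d[nrow(d), ]
    dd <- season$state$deaths_by_age
    final[[i]] <- data.frame(
      rep = i, pop_size = last$pop_size,
      inf_freq_female = last$inf_freq_female,
      inf_freq_all = last$inf_freq_all,
      mf_ratio = last$mf_ratio,
      suppressor_freq = last$suppressor_freq,
      n_created = season$state$n_created,
      deaths_age_0_3 = sum(dd[1:4]),
      deaths_total = sum(dd))
  }
  daily <- do.call(rbind, daily)
  vars <- c("pop_size", "inf_freq_female", "inf_freq_male", "inf_freq_all",
            "mf_ratio", "mf_ratio_adult", "ci_cross_frac", "suppressor_freq",
            "newborn_supp_from_ci", "supp_lost_in_ci")
  agg_mean <- stats::aggregate(daily[vars], by = list(day = daily$day), mean)
  agg_sd <- stats::aggregate(daily[vars], by = list(day = daily$day),
                             stats::sd)
  names(agg_sd)[-1] <- paste0(names(agg_sd)[-1], "_sd")
  out <- list(daily = daily,
              summary = merge(agg_mean, agg_sd, by = "day"),
              final = do.call(rbind, final),
              params = params, replicates = replicates,
              base_seed = base_seed)
  class(out) <- "wolb_campaign"
  out
}

#' @export
print.wolb_campaign <- function(x, ...) {
  cat(sprintf("<wolb_campaign> %d replicates x %d days; mean final infection (females) %.3f\n",
              x$replicates, max(x$summary$day), mean(x$final$inf_freq_female)))
  invisible(x)
}

#' Mean end-of-season infection frequency over a CI-strength x initial-frequency grid
#'
#' For each combination of total CI strength and initial infection frequency,
#' runs a replicated one-season campaign (FM:MD proportions held fixed) and
#' records the mean end-of-season female infection frequency.
#'
#' @param params base [model_params()]; `sigma_*` and `omega0` are overwritten
#'   per cell.
#' @param sigma_grid,omega_grid numeric vectors in [0, 1].
#' @param replicates replicates per cell.
#' @param base_seed integer; cells consume consecutive seed blocks.
#' @param fm_prop FM share of total CI (default from `params`, 0.98:0.02 in
#'   the Beis parametrization).
#' @return matrix of mean final female infection frequency, rows indexed by
#'   `sigma_grid`, columns by `omega_grid`.
#' @export
final_frequency_surface <- function(params, sigma_grid, omega_grid,
                                    replicates = 20, base_seed = 1,
                                    fm_prop = NULL) {
  stopifnot(all(sigma_grid >= 0 & sigma_grid <= 1),
            all(omega_grid >= 0 & omega_grid <= 1))
  if (is.null(fm_prop))
    fm_prop <- if (params$sigma_total > 0)
      params$sigma_fm / params$sigma_total else 1
  out <- matrix(NA_real_, length(sigma_grid), length(omega_grid),
                dimnames = list(sigma_total = sigma_grid, omega0 = omega_grid))
  seed <- base_seed
  for (i in seq_along(sigma_grid)) {
    for (j in seq_along(omega_grid)) {
      p <- scale_ci(params, sigma_grid[i], fm_prop)
      p$omega0 <- omega_grid[j]
      finals <- numeric(replicates)
      for (k in seq_len(replicates)) {
        set.seed(seed + k)
        s <- run_season(p)
        finals[k] <- s$daily$inf_freq_female[nrow(s$daily)]
      }
      seed <- seed + replicates
      out[i, j] <- mean(finals)
    }
  }
  out
}

#' Deterministic-recursion inflation relative to the individual-based model
#'
#' Computes, cell by cell over a CI-strength x initial-frequency grid, the
#' difference between the final female infection frequency of the
#' deterministic recursions and the mean final frequency of the
#' individual-based model (recursion minus IBM; positive values mean the
#' deterministic model overestimates the drive of CI).
#'
#' @inheritParams final_frequency_surface
#' @param generations recursion generations, default `floor(T/11)`.
#' @return list with `mean_difference` (grid average), `difference` (matrix),
#'   `ibm` and `recursion` (the two surfaces), and `argmax`, the (sigma,
#'   omega) cell of maximal divergence.
#' @export
ibm_vs_recursion_bias <- function(params, sigma_grid, omega_grid,
                                  replicates = 20, base_seed = 1,
                                  generations = NULL, fm_prop = NULL) {
  if (is.null(generations)) generations <- days_to_generations(params$T)
  if (is.null(fm_prop))
    fm_prop <- if (params$sigma_total > 0)
      params$sigma_fm / params$sigma_total else 1
  ibm <- final_frequency_surface(params, sigma_grid, omega_grid,
                                 replicates, base_seed, fm_prop)
  rp <- recursion_params(F = params$F,
                         alpha = if (params$Sd > 0)
                           alpha_from_sd(params$Sd, params$lam) else 0,
                         lam = params$lam, mu = params$mu,
                         sigma_total = 1, sigma_md = 1 - fm_prop)
  rec <- invasion_surface_recursion(rp, sigma_grid, omega_grid, generations,
                                    md_prop = 1 - fm_prop)
  diff <- rec - ibm
  am <- which(diff == max(diff), arr.ind = TRUE)[1, ]
  list(mean_difference = mean(diff), difference = diff, ibm = ibm,
       recursion = rec,
       argmax = c(sigma_total = sigma_grid[am[1]], omega0 = omega_grid[am[2]]))
}

#' Contrast of the two haplodiploid CI outcomes
#'
#' Pairs a strict female-mortality regime (`sigma_fm = sigma_total`,
#' `sigma_md = 0`) with a strict male-development regime (`sigma_md =
#' sigma_total`, `sigma_fm = 0`) at a focal cell, using identical replicate
#' seeds in both arms, and reports the paired final-frequency difference plus
#' the per-day mean cross-frequency and sex-ratio diagnostics of each arm.
#'
#' @param params base [model_params()].
#' @param omega0,sigma_total focal cell (defaults at the point of maximal
#'   divergence between the regimes: 0.25 and 1.0).
#' @param replicates paired replicates.
#' @param base_seed integer; the same seeds are used in both arms.
#' @param sigma_grid,omega_grid optional grids; when supplied, two paired
#'   final-frequency surfaces (strict FM and strict MD) are computed and
#'   their cell-wise difference (MD minus FM) returned as `difference`.
#' @return list with `fm`, `md` (each a `wolb_campaign` at the focal cell),
#'   `final_gap` (mean FM final frequency minus mean MD final frequency),
#'   `peak_mf` (named vector: seasonal maximum of the per-day mean
#'   male:female ratio in each arm), and — with grids — `difference` plus the
#'   `fm_surface`/`md_surface` matrices.
#' @export
ci_type_contrast <- function(params, omega0 = 0.25, sigma_total = 1,
                             replicates = 100, base_seed = 1,
                             sigma_grid = NULL, omega_grid = NULL) {
  pf <- params; pf$omega0 <- omega0
  pf <- scale_ci(pf, sigma_total, fm_prop = 1)
  pm <- params; pm$omega0 <- omega0
  pm <- scale_ci(pm, sigma_total, fm_prop = 0)
  fm <- run_one_year(pf, replicates, base_seed)
  md <- run_one_year(pm, replicates, base_seed)
  out <- list(fm = fm, md = md,
              final_gap = mean(fm$final$inf_freq_female) -
                mean(md$final$inf_freq_female),
              peak_mf = c(fm = max(fm$summary$mf_ratio),
                          md = max(md$summary$mf_ratio)))
  if (!is.null(sigma_grid) && !is.null(omega_grid)) {
    sf <- final_frequency_surface(params, sigma_grid, omega_grid,
                                  replicates, base_seed, fm_prop = 1)
    sm <- final_frequency_surface(params, sigma_grid, omega_grid,
                                  replicates, base_seed, fm_prop = 0)
    out$fm_surface <- sf
    out$md_surface <- sm
    out$difference <- sm - sf
  }
  out
}

#' Multi-year simulation with season carryover
#'
#' Chains reproductive seasons: at each year transition either the full
#' population is carried over (no drift injection; the next season starts at
#' carrying capacity) or a random subsample of size `P0` founds the next
#' season (periodic bottleneck).
#'
#' @param params a [model_params()] object.
#' @param years number of seasons to chain.
#' @param replicates independent replicate chains.
#' @param carryover `"full"` or `"subsample"`.
#' @param base_seed integer; replicate `i` uses `base_seed + i`.
#' @param stop_when_lost end a replicate early once no infected individual is
#'   left at a season's end (remaining years are recorded as lost).
#' @return data frame with one row per (replicate, year): `rep`, `year`,
#'   `pop_size`, `inf_freq_female`, `inf_freq_all`, `suppressor_freq`,
#'   `lost` (no infected individuals at season end).
#' @export
run_multi_year <- function(params, years, replicates = 1,
                           carryover = c("full", "subsample"),
                           base_seed = 1, stop_when_lost = FALSE) {
  carryover <- match.arg(carryover)
  stopifnot(years >= 1)
  rows <- vector("list", replicates * years)
  k <- 0L
  for (i in seq_len(replicates)) {
    set.seed(base_seed + i)
    state <- NULL
    lost <- FALSE
    for (y in seq_len(years)) {
      if (!lost || !stop_when_lost) {
        season <- run_season(params, state)
        state <- next_season(season$state, params, carryover)
        last <- season$daily[nrow(season$daily), ]
        n_inf <- sum(season$state$pop$infected)
        lost <- lost || n_inf == 0L
        row <- data.frame(rep = i, year = y, pop_size = last$pop_size,
                          inf_freq_female = last$inf_freq_female,
                          inf_freq_all = last$inf_freq_all,
                          suppressor_freq = last$suppressor_freq,
                          lost = n_inf == 0L)
      } else {
        row <- data.frame(rep = i, year = y, pop_size = NA_integer_,
                          inf_freq_female = 0, inf_freq_all = 0,
                          suppressor_freq = NA_real_, lost = TRUE)
      }
      k <- k + 1L
      rows[[k]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Years until infection loss
#'
#' Runs multi-year chains without CI (`sigma_total = 0` expected) and records,
#' per replicate, the first year at whose end no infected individual remains.
#' Replicates still infected at `max_years` are censored.
#'
#' @param params a [model_params()] object (typically `sigma_total = 0`,
#'   `omega0 = 1`).
#' @param max_years censoring horizon.
#' @param replicates independent chains.
#' @param carryover `"full"` (no drift at transitions) or `"subsample"`.
#' @param base_seed integer seed base.
#' @return data frame with `rep`, `years` (year of loss, or `max_years` when
#'   censored) and `censored`.
#' @export
persistence_times <- function(params, max_years = 100, replicates = 100,
                              carryover = c("full", "subsample"),
                              base_seed = 1) {
  carryover <- match.arg(carryover)
  out <- data.frame(rep = seq_len(replicates), years = NA_real_,
                    censored = FALSE)
  for (i in seq_len(replicates)) {
    set.seed(base_seed + i)
    state <- NULL
    lost_year <- NA_real_
    for (y in seq_len(max_years)) {
      season <- run_season(params, state)
      if (sum(season$state$pop$infected) == 0L) { lost_year <- y; break }
      state <- next_season(season$state, params, carryover)
    }
    if (is.na(lost_year)) {
      out$years[i] <- max_years
      out$censored[i] <- TRUE
    } else out$years[i] <- lost_year
  }
  out
}

#' Gamma fit of persistence times by maximum likelihood
#'
#' Fits a gamma distribution to (uncensored) persistence times. Censored
#' observations are excluded with a warning. A degenerate constant sample is
#' reported as the point-mass limit (`shape = Inf`, `scale = 0`) rather than
#' an error.
#'
#' @param times positive persistence times (years), or the data frame returned
#'   by [persistence_times()].
#' @param censored optional logical vector marking censored entries.
#' @return list of class `wolb_gamma_fit` with `shape`, `scale`, `mean`
#'   (`shape * scale`), `loglik`, `n` and `degenerate`.
#' @export
fit_gamma_mle <- function(times, censored = NULL) {
  if (is.data.frame(times)) {
    censored <- times$censored
    times <- times$years
  }
  if (!is.null(censored) && any(censored)) {
    warning(sprintf("excluding %d censored observation(s) from the gamma fit",
                    sum(censored)))
    times <- times[!censored]
  }
  times <- as.numeric(times)
  if (length(times) < 2) stop("need at least 2 uncensored observations",
                              call. = FALSE)
  if (any(times <= 0)) stop("persistence times must be positive", call. = FALSE)
  if (stats::sd(times) < sqrt(.Machine$double.eps)) {
    fit <- list(shape = Inf, scale = 0, mean = mean(times), loglik = NA_real_,
                n = length(times), degenerate = TRUE)
  } else {
    fd <- MASS::fitdistr(times, "gamma")
    shape <- unname(fd$estimate["shape"])
    rate <- unname(fd$estimate["rate"])
    fit <- list(shape = shape, scale = 1 / rate, mean = shape / rate,
                loglik = fd$loglik, n = length(times), degenerate = FALSE)
  }
  class(fit) <- "wolb_gamma_fit"
  fit
}

#' @export
print.wolb_gamma_fit <- function(x, ...) {
  cat(sprintf("<wolb_gamma_fit> shape %.3g, scale %.3g, mean %.3g (n = %d%s)\n",
              x$shape, x$scale, x$mean, x$n,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

# moving-average threshold over (F, final frequency) samples: first F whose
# trailing window mean reaches omega0
fc_from_samples <- function(F_values, final_freqs, omega0, window = 10) {
  stopifnot(length(F_values) == length(final_freqs))
  if (length(F_values) < window)
    stop("need at least `window` samples", call. = FALSE)
  ord <- order(F_values)
  Fs <- F_values[ord]
  fr <- final_freqs[ord]
  ma <- stats::filter(fr, rep(1 / window, window), sides = 1)
  hit <- which(!is.na(ma) & ma >= omega0)
  if (!length(hit)) return(list(Fc = NA_real_, reached = FALSE,
                                F_sorted = Fs, moving_avg = as.numeric(ma)))
  idx <- hit[1]
  # condition satisfied from the earliest measurable point -> the smallest
  # sampled F (0 when 0 itself was sampled: no fecundity benefit required)
  Fc <- if (idx == window && all(fr[seq_len(window)] >= omega0))
    Fs[1] else Fs[idx]
  list(Fc = Fc, reached = TRUE, F_sorted = Fs, moving_avg = as.numeric(ma))
}

#' Fecundity threshold for stable infection after CI loss
#'
#' Samples fecundity effects `F` uniformly on `[0, f_max]`, measures the
#' infection frequency after `years` seasons for each sample (one chain per
#' sample, full carryover), orders the samples by `F` and smooths with a
#' trailing moving average of `window` observations. The threshold `Fc` is the
#' smallest `F` at which the smoothed infection frequency reaches the initial
#' frequency `omega0`; 0 when the condition already holds without any
#' fecundity benefit, `NA` (not reached) when it is never satisfied.
#'
#' @param params a [model_params()] object (`sigma_total = 0`, `omega0 = 0.5`
#'   in the reference analysis).
#' @param n_samples number of uniform `F` draws (must be at least `window`).
#' @param years seasons per sample chain.
#' @param window trailing moving-average lag (default 10 observations).
#' @param f_max upper end of the sampled `F` range (default 0.10).
#' @param base_seed integer seed base.
#' @return list with `Fc`, `reached`, and the per-sample table `samples`
#'   (columns `F`, `final_freq`).
#' @export
fecundity_threshold <- function(params, n_samples = 100, years = 100,
                                window = 10, f_max = 0.10, base_seed = 1) {
  if (n_samples < window)
    stop("n_samples must be at least `window`", call. = FALSE)
  set.seed(base_seed)
  Fs <- sort(stats::runif(n_samples, 0, f_max))
  finals <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    p <- params
    p$F <- Fs[i]
    res <- run_multi_year(p, years = years, replicates = 1,
                          carryover = "full", base_seed = base_seed * 1000 + i,
                          stop_when_lost = TRUE)
    finals[i] <- res$inf_freq_female[nrow(res)]
  }
  fc <- fc_from_samples(Fs, finals, params$omega0, window)
  list(Fc = fc$Fc, reached = fc$reached,
       samples = data.frame(F = Fs, final_freq = finals),
       moving_avg = fc$moving_avg)
}

#' Simulated long-run frequencies against the closed-form Sd prediction
#'
#' For each sex-allocation distortion value, runs multi-year chains after CI
#' loss and tabulates the simulated long-run mean infection frequency next to
#' the stable polymorphic frequency predicted by the closed form
#' `(Sd - mu(1+Sd))/Sd`.
#'
#' @param params a [model_params()] object with `sigma_total = 0`.
#' @param sd_grid sex-allocation distortion values (each at most `1 - lam`).
#' @param years seasons per chain.
#' @param replicates chains per Sd value.
#' @param base_seed integer seed base.
#' @return data frame with `Sd`, `predicted` (clamped closed form, 0 when not
#'   maintainable), `simulated` (mean end frequency across replicates) and
#'   `simulated_sd`.
#' @export
sd_stability_check <- function(params, sd_grid, years = 20, replicates = 10,
                               base_seed = 1) {
  if (params$sigma_total != 0)
    warning("sd_stability_check is meant for the CI-loss regime (sigma_total = 0)")
  rows <- lapply(seq_along(sd_grid), function(i) {
    p <- params
    p$Sd <- sd_grid[i]
    validate_params(p)
    res <- run_multi_year(p, years = years, replicates = replicates,
                          carryover = "full",
                          base_seed = base_seed + (i - 1) * replicates,
                          stop_when_lost = TRUE)
    fin <- res$inf_freq_female[res$year == years]
    pred <- if (sd_grid[i] > 0) {
      sf <- stable_infection_freq(sd_grid[i], params$mu)
      if (sf$maintainable) sf$omega else 0
    } else 0
    data.frame(Sd = sd_grid[i], predicted = pred, simulated = mean(fin),
               simulated_sd = stats::sd(fin))
  })
  do.call(rbind, rows)
}

#' Relative root-mean-squared error against observed infection frequencies
#'
#' Linearly interpolates a simulated mean infection-frequency series to the
#' observation days and reports the RMSE relative to a normalizer (by default
#' the mean of the observed frequencies), as a percentage.
#'
#' @param sim_days,sim_freq simulated day grid and mean frequencies.
#' @param obs_days,obs_freq observed day/frequency records; observation days
#'   must fall within the simulated range.
#' @param normalizer `"mean"` (default), `"range"` or `"final"` value of the
#'   observations.
#' @return relative RMSE in percent.
#' @examples
#' relative_rmse(1:10, rep(0.5, 10), c(2, 5), c(0.4, 0.6)) # 20
#' @export
relative_rmse <- function(sim_days, sim_freq, obs_days, obs_freq,
                          normalizer = c("mean", "range", "final")) {
  normalizer <- match.arg(normalizer)
  if (!length(obs_days) || length(obs_days) != length(obs_freq))
    stop("observed table must be non-empty with matching day/frequency columns",
         call. = FALSE)
  if (min(obs_days) < min(sim_days) || max(obs_days) > max(sim_days))
    stop("observation days must lie within the simulated range", call. = FALSE)
  sim_at <- stats::approx(sim_days, sim_freq, xout = obs_days)$y
  rmse <- sqrt(mean((sim_at - obs_freq)^2))
  denom <- switch(normalizer,
                  mean = mean(obs_freq),
                  range = diff(range(obs_freq)),
                  final = obs_freq[length(obs_freq)])
  if (denom == 0) stop("normalizer of the observed series is zero", call. = FALSE)
  100 * rmse / denom
}
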