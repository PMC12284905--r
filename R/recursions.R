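# Deterministic companion model: coupled recursions for infection frequencies
# among females (f) and males (m) in an infinite haplodiploid population with
# discrete generations, and the closed-form sex-allocation-distortion algebra
# for persistence after CI loss.

#' One step of the deterministic infection-frequency recursions
#'
#' Advances the female (`f`) and male (`m`) infection frequencies by one host
#' generation under total CI strength `sigma_total` (male-development
#' component `sigma_md`), imperfect transmission `mu`, fecundity effect `F`
#' and per-egg extra fertilization `alpha` (sex-allocation distortion):
#'
#' \deqn{f' = \frac{f(1+F)(1+\alpha(1-\lambda))(1-\mu)}
#'   {f(1+F)(1+\alpha(1-\lambda)) + (1-f)(1-\sigma_{tot} m)}}
#' \deqn{m' = \frac{f(1+F)(1-\mu)(1-\lambda)(1-\alpha)}
#'   {f(1+F)(1-\lambda)(1-\alpha) +
#'    (1-f)\left[(1-\lambda)+\lambda\sigma_{md} m\right]}}
#'
#' Cytoplasmic incompatibility is rescued at the female level: all eggs of an
#' infected mother are protected, including the fraction `mu` that fails to
#' inherit the infection, matching the default rescue scope of the
#' individual-based model. In the `sigma_total = 0`, `F = 0` limit the female
#' recursion collapses to `f' = f(1+Sd)(1-mu) / (f(1+Sd) + 1 - f)` with
#' `1 + Sd = 1 + alpha(1-lam)`.
#'
#' @param f,m infection frequencies among females and males, in [0, 1].
#' @param p named list with `F`, `alpha`, `lam`, `mu`, `sigma_total`,
#'   `sigma_md` (see [recursion_params()]).
#' @return list with the updated `f` and `m`.
#' @export
recursion_step <- function(f, m, p) {
  up <- 1 + p$alpha * (1 - p$lam)      # Sd uplift of the female egg share
  wf <- f * (1 + p$F) * up
  num_f <- wf * (1 - p$mu)
  den_f <- wf + (1 - f) * (1 - p$sigma_total * m)
  unfert <- (1 - p$lam) * (1 - p$alpha) # male egg share of infected females
  num_m <- f * (1 + p$F) * (1 - p$mu) * unfert
  den_m <- f * (1 + p$F) * unfert +
    (1 - f) * ((1 - p$lam) + p$lam * p$sigma_md * m)
  f2 <- if (den_f > 0) num_f / den_f else 0
  m2 <- if (den_m > 0) num_m / den_m else 0
  list(f = min(1, max(0, f2)), m = min(1, max(0, m2)))
}

#' Parameters of the deterministic recursions
#'
#' @param F fecundity effect of infection.
#' @param alpha per-egg extra fertilization probability (`Sd/(1-lam)`); see
#'   [alpha_from_sd()].
#' @param lam baseline fertilization proportion.
#' @param mu imperfect maternal transmission rate.
#' @param sigma_total,sigma_md total and male-development CI strengths.
#' @return a named list usable with [recursion_step()].
#' @export
recursion_params <- function(F = 0, alpha = 0, lam = 0.8, mu = 0,
                             sigma_total = 0, sigma_md = 0) {
  for (v in c(F, alpha, lam, mu, sigma_total, sigma_md))
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("recursion parameters must be probabilities in [0, 1]", call. = FALSE)
  if (sigma_md > sigma_total + 1e-12)
    stop("sigma_md cannot exceed sigma_total", call. = FALSE)
  list(F = F, alpha = alpha, lam = lam, mu = mu,
       sigma_total = sigma_total, sigma_md = sigma_md)
}

#' Iterate the deterministic recursions
#'
#' @param f0,m0 initial infection frequencies among females and males.
#' @param p parameters from [recursion_params()].
#' @param n number of generations (one generation is taken as 11 days of the
#'   individual-based model; see [days_to_generations()]).
#' @return data frame with columns `generation`, `f`, `m`, including the
#'   initial state at generation 0.
#' @examples
#' p <- recursion_params(mu = 0.018, sigma_total = 1, sigma_md = 0.02)
#' iterate_recursions(0.5, 0.5, p, 9)
#' @export
iterate_recursions <- function(f0, m0, p, n) {
  stopifnot(n >= 0, f0 >= 0, f0 <= 1, m0 >= 0, m0 <= 1)
  f <- numeric(n + 1); m <- numeric(n + 1)
  f[1] <- f0; m[1] <- m0
  if (n > 0) for (i in seq_len(n)) {
    st <- recursion_step(f[i], m[i], p)
    f[i + 1] <- st$f; m[i + 1] <- st$m
  }
  data.frame(generation = 0:n, f = f, m = m)
}

#' Map days of the individual-based model to recursion generations
#'
#' One host generation is 11 days (age at female maturity); remainder days are
#' not fractionally iterated.
#'
#' @param days number of days.
#' @param generation_days days per generation (default 11).
#' @return integer number of whole generations, `floor(days/generation_days)`.
#' @export
days_to_generations <- function(days, generation_days = 11) {
  as.integer(floor(days / generation_days))
}

#' Minimum sex-allocation distortion maintaining a given infection frequency
#'
#' After CI loss (`sigma_total = 0`, `F = 0`), the female recursion has
#' `omega0` as a fixed point iff `Sd = mu / (1 - mu - omega0)`; this is the
#' weakest distortion that stably maintains infection at `omega0` against
#' imperfect transmission. Defined only for `mu + omega0 < 1`.
#'
#' @param mu imperfect transmission rate.
#' @param omega0 infection frequency to maintain, in (0, 1).
#' @return the threshold `Sd`.
#' @examples
#' sd_threshold(0.02, 0.5) # ~0.0417
#' @export
sd_threshold <- function(mu, omega0) {
  stopifnot(mu >= 0, omega0 > 0)
  if (mu + omega0 >= 1)
    stop("sd_threshold is defined only for mu + omega0 < 1", call. = FALSE)
  mu / (1 - mu - omega0)
}

#' Stable polymorphic infection frequency under sex-allocation distortion
#'
#' Inverse of [sd_threshold()]: the infection frequency stably maintained by a
#' distortion `Sd` with imperfect transmission `mu`, after CI loss:
#' `omega = (Sd - mu (1 + Sd)) / Sd`. A non-positive raw value means the
#' infection cannot be maintained.
#'
#' @param Sd sex-allocation distortion, strictly positive.
#' @param mu imperfect transmission rate.
#' @return list with `omega` (clamped to [0, 1]), the unclamped `raw`, and
#'   `maintainable` (`FALSE` when `raw <= 0`).
#' @examples
#' stable_infection_freq(0.05, 0.02)$omega # 0.58
#' @export
stable_infection_freq <- function(Sd, mu) {
  if (Sd <= 0) stop("stable_infection_freq requires Sd > 0", call. = FALSE)
  stopifnot(mu >= 0, mu <= 1)
  raw <- (Sd - mu * (1 + Sd)) / Sd
  list(omega = min(1, max(0, raw)), raw = raw, maintainable = raw > 0)
}

#' Final infection frequency of the recursions over a parameter grid
#'
#' Iterates the recursions for each combination of total CI strength and
#' initial frequency, holding the FM:MD proportions fixed, and returns the
#' final female infection frequency.
#'
#' @param p base parameters from [recursion_params()]; `sigma_total` and
#'   `sigma_md` are overwritten cell by cell keeping their proportion.
#' @param sigma_grid,omega_grid numeric vectors in [0, 1].
#' @param n generations per cell.
#' @param md_prop MD share of total CI; defaults to the proportion in `p`
#'   (0 when `p$sigma_total` is 0).
#' @return matrix of final `f`, rows indexed by `sigma_grid`, columns by
#'   `omega_grid`.
#' @export
invasion_surface_recursion <- function(p, sigma_grid, omega_grid, n,
                                       md_prop = NULL) {
  stopifnot(all(sigma_grid >= 0 & sigma_grid <= 1),
            all(omega_grid >= 0 & omega_grid <= 1))
  if (is.null(md_prop))
    md_prop <- if (p$sigma_total > 0) p$sigma_md / p$sigma_total else 0
  out <- matrix(NA_real_, length(sigma_grid), length(omega_grid),
                dimnames = list(sigma_total = sigma_grid, omega0 = omega_grid))
  for (i in seq_along(sigma_grid)) {
    pi <- p
    pi$sigma_total <- sigma_grid[i]
    pi$sigma_md <- sigma_grid[i] * md_prop
    for (j in seq_along(omega_grid)) {
      tr <- iterate_recursions(omega_grid[j], omega_grid[j], pi, n)
      out[i, j] <- tr$f[nrow(tr)]
    }
  }
  out
}
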