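#' Model parameters for the haplodiploid Wolbachia simulator
#'
#' Builds and validates the full parameter set of the individual-based model.
#' Defaults correspond to the spider-mite (*Tetranychus urticae*) life history
#' used to parameterize the model: a 150-day reproductive season, carrying
#' capacity 5000, 50 founding adult females, maturity at 11 (females) / 10
#' (males) days, oviposition peaking at age 16 with 10 expected eggs/day, death
#' at age 20, and 80% of eggs fertilized.
#'
#' @param T days in one reproductive season.
#' @param K carrying capacity (total individuals: eggs + juveniles + adults).
#' @param P0 number of founding adult females.
#' @param D_mean mean age (days) of natural death.
#' @param M_female_mean,M_male_mean mean maturity ages (days).
#' @param Mp_mean mean age of peak oviposition (days).
#' @param eggsM_mean expected eggs/day at maturity.
#' @param eggsMp_mean expected eggs/day at the oviposition peak.
#' @param trait_sd standard deviation of per-individual trait draws.
#' @param lam baseline proportion of eggs fertilized (female-destined), lambda.
#' @param mu imperfect maternal transmission rate: an egg of an infected mother
#'   fails to inherit the infection with probability `mu`.
#' @param L number of suppressor loci per haploid genome.
#' @param sigma_fm,sigma_md,sigma_total female-mortality, male-development and
#'   total cytoplasmic-incompatibility strengths; `sigma_fm + sigma_md` must
#'   equal `sigma_total`.
#' @param F relative fecundity increase of infected females (probability that
#'   each oviposited egg spawns one additional egg).
#' @param Sd sex-allocation distortion: population-level excess of fertilized
#'   (female-destined) eggs in infected females; must not exceed `1 - lam`.
#' @param omega0 initial infection frequency among founding females.
#' @param suppressor_init_freq initial frequency of active suppressor alleles.
#' @param r_half_day day at which the logistic population target reaches `K/2`.
#' @param ci_rescue_scope `"female_level"` (all eggs of an uninfected female
#'   inseminated by an infected male face CI) or `"egg_level"` (eggs that did
#'   not inherit the infection face CI even in infected mothers).
#' @param mortality_mode `"fixed"` (remove exactly `round(psi * Pt)`
#'   individuals) or `"bernoulli"` (each individual dies independently with
#'   probability `psi`).
#' @param seed optional RNG seed stored with the parameters; campaign runners
#'   derive per-replicate seeds from it.
#'
#' @return an object of class `wolb_params` (a named list).
#' @examples
#' p <- model_params(sigma_fm = 0.98, sigma_md = 0.02, sigma_total = 1,
#'                   mu = 0.018, omega0 = 0.5)
#' p$lam
#' @export
model_params <- function(T = 150, K = 5000, P0 = 50,
                         D_mean = 20, M_female_mean = 11, M_male_mean = 10,
                         Mp_mean = 16, eggsM_mean = 1, eggsMp_mean = 10,
                         trait_sd = 0.5, lam = 0.8, mu = 0, L = 5,
                         sigma_fm = 0, sigma_md = 0, sigma_total = 0,
                         F = 0, Sd = 0, omega0 = 0,
                         suppressor_init_freq = 0, r_half_day = 60,
                         ci_rescue_scope = c("female_level", "egg_level"),
                         mortality_mode = c("fixed", "bernoulli"),
                         seed = NULL) {
  p <- list(T = T, K = K, P0 = P0, D_mean = D_mean,
            M_female_mean = M_female_mean, M_male_mean = M_male_mean,
            Mp_mean = Mp_mean, eggsM_mean = eggsM_mean,
            eggsMp_mean = eggsMp_mean, trait_sd = trait_sd, lam = lam,
            mu = mu, L = L, sigma_fm = sigma_fm, sigma_md = sigma_md,
            sigma_total = sigma_total, F = F, Sd = Sd, omega0 = omega0,
            suppressor_init_freq = suppressor_init_freq,
            r_half_day = r_half_day,
            ci_rescue_scope = match.arg(ci_rescue_scope),
            mortality_mode = match.arg(mortality_mode),
            seed = seed)
  class(p) <- "wolb_params"
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks range, consistency (`sigma_fm + sigma_md = sigma_total`,
#' `Sd <= 1 - lam`, `P0 <= K`) and positivity constraints, with a specific
#' message for each violation.
#'
#' @param p a `wolb_params` object (or plain named list with the same fields).
#' @return `p`, invisibly classed as `wolb_params`, if valid; otherwise an error.
#' @export
validate_params <- function(p) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in c("T", "K", "P0", "D_mean", "M_female_mean", "M_male_mean",
              "Mp_mean", "eggsM_mean", "eggsMp_mean", "trait_sd", "lam",
              "mu", "L", "sigma_fm", "sigma_md", "sigma_total", "F", "Sd",
              "omega0", "suppressor_init_freq", "r_half_day"))
    stop_if(!num1(p[[f]]), sprintf("parameter '%s' must be a finite number", f))
  for (f in c("lam", "mu", "sigma_fm", "sigma_md", "sigma_total", "F",
              "omega0", "suppressor_init_freq"))
    stop_if(p[[f]] < 0 || p[[f]] > 1,
            sprintf("parameter '%s' must lie in [0, 1] (got %g)", f, p[[f]]))
  for (f in c("T", "K", "P0", "D_mean", "M_female_mean", "M_male_mean",
              "Mp_mean", "L", "r_half_day"))
    stop_if(p[[f]] <= 0, sprintf("parameter '%s' must be strictly positive", f))
  stop_if(abs(p$sigma_fm + p$sigma_md - p$sigma_total) > 1e-8,
          sprintf("sigma_fm + sigma_md must equal sigma_total (%g + %g != %g)",
                  p$sigma_fm, p$sigma_md, p$sigma_total))
  stop_if(p$lam >= 1 && p$Sd > 0,
          "Sd requires lam < 1 (no unfertilized eggs to distort)")
  stop_if(p$Sd < 0 || p$Sd > 1 - p$lam + 1e-12,
          sprintf("Sd must lie in [0, 1 - lam] = [0, %g] (got %g): alpha = Sd/(1-lam) must be a probability",
                  1 - p$lam, p$Sd))
  stop_if(p$P0 > p$K, "P0 must not exceed the carrying capacity K")
  stop_if(p$P0 >= p$K, "P0 = K leaves no room for logistic growth (A = 0, r undefined)")
  stop_if(!(p$M_female_mean < p$Mp_mean && p$Mp_mean < p$D_mean),
          "trait means must satisfy M (female) < Mp < D")
  if (!inherits(p, "wolb_params")) class(p) <- "wolb_params"
  invisible(p)
}

#' @export
print.wolb_params <- function(x, ...) {
  cat("<wolb_params>\n")
  cat(sprintf("  season T=%g days, K=%g, P0=%g founding females\n", x$T, x$K, x$P0))
  cat(sprintf("  CI: sigma_fm=%g sigma_md=%g (total %g), rescue scope %s\n",
              x$sigma_fm, x$sigma_md, x$sigma_total, x$ci_rescue_scope))
  cat(sprintf("  transmission mu=%g, Sd=%g, F=%g, lambda=%g, L=%d loci\n",
              x$mu, x$Sd, x$F, x$lam, as.integer(x$L)))
  cat(sprintf("  omega0=%g, suppressor init freq=%g\n",
              x$omega0, x$suppressor_init_freq))
  invisible(x)
}

#' Rescale total CI strength keeping the FM:MD proportions
#'
#' The two CI outcome strengths always sum to the total. When the total is
#' varied, their relative proportions are held constant: e.g. moving from
#' `sigma_total = 1` with `sigma_fm = 0.9` to `sigma_total = 0.5` gives
#' `sigma_fm = 0.45`, `sigma_md = 0.05`.
#'
#' @param p a `wolb_params` object.
#' @param sigma_total new total CI strength in [0, 1].
#' @param fm_prop optional FM proportion of total CI in [0, 1]; defaults to the
#'   proportion implied by `p` (0.5 when `p$sigma_total` is 0).
#' @return `p` with rescaled `sigma_fm`, `sigma_md`, `sigma_total`.
#' @examples
#' p <- model_params(sigma_fm = 0.9, sigma_md = 0.1, sigma_total = 1)
#' scale_ci(p, 0.5)[c("sigma_fm", "sigma_md")]
#' @export
scale_ci <- function(p, sigma_total, fm_prop = NULL) {
  stopifnot(sigma_total >= 0, sigma_total <= 1)
  if (is.null(fm_prop)) {
    fm_prop <- if (p$sigma_total > 0) p$sigma_fm / p$sigma_total else 0.5
  }
  stopifnot(fm_prop >= 0, fm_prop <= 1)
  p$sigma_total <- sigma_total
  p$sigma_fm <- sigma_total * fm_prop
  p$sigma_md <- sigma_total * (1 - fm_prop)
  validate_params(p)
  p
}

#' Per-egg extra fertilization probability implied by sex-allocation distortion
#'
#' Sex-allocation distortion `Sd` is a population-level quantity: the expected
#' excess of fertilized (female-destined) eggs in broods of infected females.
#' Inside the simulator each still-unfertilized egg of an infected female is
#' fertilized with probability `alpha = Sd / (1 - lam)`.
#'
#' @param Sd sex-allocation distortion, at most `1 - lam`.
#' @param lam baseline fertilization proportion, strictly below 1.
#' @return the probability `alpha` in [0, 1].
#' @examples
#' alpha_from_sd(0.05, 0.8) # 0.25
#' @export
alpha_from_sd <- function(Sd, lam) {
  if (any(lam >= 1)) stop("alpha_from_sd requires lam < 1", call. = FALSE)
  if (any(Sd < 0)) stop("Sd must be non-negative", call. = FALSE)
  if (any(Sd > 1 - lam + 1e-12))
    stop(sprintf("Sd must not exceed 1 - lam = %g (alpha would exceed 1)",
                 1 - lam), call. = FALSE)
  pmin(Sd / (1 - lam), 1)
}
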