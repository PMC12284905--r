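---
title: "Modelling Wolbachia infection dynamics in haplodiploid hosts"
author: "wolbsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Wolbachia infection dynamics in haplodiploid hosts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolbsim)
```

## The biological problem

*Wolbachia* and related maternally transmitted endosymbionts spread through
arthropod populations by manipulating host reproduction. In haplodiploid
hosts such as the spider mite *Tetranychus urticae* — where unfertilized eggs
develop into haploid males and fertilized eggs into diploid females —
cytoplasmic incompatibility (CI) between infected males and uninfected
females takes two forms: the fertilized (female-destined) egg dies
(female-mortality CI, strength $\sigma_{fm}$) or develops into a viable
haploid male carrying only the maternal genome (male-development CI,
$\sigma_{md}$). `wolbsim` implements a daily, individual-based model (IBM) of
these dynamics, together with its deterministic companion recursions, to ask
how long an infection persists once CI is lost — through host suppressor
evolution or symbiont *cif* gene decay — and how sex-allocation distortion
(Sd) and fecundity effects (F) of infection modulate that persistence.

## The individual-based model

**Individuals and life history.** Each individual carries a sex, an age in
days, an infection flag, and per-individual life-history traits drawn at
birth from normal distributions (`trait_sd`, default 0.5 days): natural death
age $D$ (mean 20), maturity $M$ (11 for females, 10 for males), oviposition
peak $M_p$ (16) and the expected egg outputs at maturity and peak (1 and 10
eggs/day). Draws are redone until $M < M_p < D$; ages are compared against
these real-valued thresholds without rounding. Females are diploid at $L = 5$
biallelic suppressor loci (allele 1 = active suppressor), males haploid.

**Oviposition.** The expected daily output of an adult female of age $x$
follows a tent function: it rises linearly from $\mathrm{Eggs}_M$ at maturity
to $\mathrm{Eggs}_{M_p}$ at the peak, then falls linearly to zero at $D$
(the output at $D$ is pinned to 0, the only choice that makes the schedule
continuous and non-negative at both ends). The realized daily count is
$\mathcal{N}(\mathrm{Eggs}_x, 0.5)$ rounded and clamped at zero.

**Mating.** Virgin adult females pair with a uniformly random mature male;
his haplotype and infection state are stored for life (first-male sperm
precedence), and males can inseminate any number of females. Founding
females enter the simulation pre-inseminated by a virtual male of their own
infection state — mirroring within-line matings used to found experimental
populations — so CI crosses only arise in the first daughter generation.
Never-mated females do not oviposit (the daily cycle is mate-then-lay; the
model does not let virgins lay unfertilized male eggs).

**Egg fate.** For each egg of an infected female, in order: with probability
$F$ an extra egg is produced; the egg is fertilized with probability
$\lambda$ (0.8); a still-unfertilized egg of an infected female is fertilized
with probability $\alpha = S_d/(1-\lambda)$, which makes $S_d$ the
population-level excess of daughters; the infection is inherited with
probability $1-\mu$; the oocyte haplotype is assembled locus by locus from
the mother's two alleles (free recombination). Fertilized eggs of an
incompatible cross — an uninfected female inseminated by an infected male —
hatch with probability $\theta = 1 - \sigma_{fm}(1 - s/L)$, where $s$ is the
number of active suppressors on the stored sperm haplotype (suppression is
strictly additive, no epistasis); hatched CI eggs develop as haploid males
with probability $\sigma_{md}(1-s/L)$ and as uninfected diploid females
otherwise. The two CI components always satisfy
$\sigma_{fm} + \sigma_{md} = \sigma_{total}$, and rescaling the total keeps
their proportions.

**Rescue scope.** By default all eggs of an infected mother are protected
from CI (`ci_rescue_scope = "female_level"`), including the fraction $\mu$
that fails to inherit the infection. The alternative `"egg_level"` exposes
those uninfected eggs to CI. We default to the female level because (i) CI
rescue is a property of the egg cytoplasm provisioned by the mother and
(ii) only this reading reproduces the published behaviour of the companion
deterministic model (below).

**Density regulation.** Population growth is capped by removing, at the end
of each day $t$, a uniformly random fraction
$\psi_t = \max\{0, (P_t - K/(1+Ae^{-rt}))/P_t\}$ of all individuals,
irrespective of age, sex or infection — so the sex ratio is shaped only by
$\lambda$ and CI. $A = (K-P_0)/P_0$ and $r = \ln(A)/60$ place the logistic
half-point at day 60. By default exactly $\mathrm{round}(\psi_t P_t)$
individuals are removed (lower variance); a Bernoulli per-individual mode is
available. When a later season starts at or above $K/2$ ($A \le 1$), $r$ is
kept from the first season and the clamp does the work; the logistic target
is then effectively $K$.

**Season structure.** A reproductive year is 150 days. Multi-year runs chain
seasons with either the full population carried over (no drift at the
transition; the next season starts at carrying capacity) or a random
subsample of size $P_0$ (a periodic bottleneck that injects drift). Ages and
all states are retained through the transition; the day counter and $A$ are
reset.

## The deterministic companion model

With discrete generations and an infinite population, the female and male
infection frequencies follow

$$f' = \frac{f(1+F)(1+\alpha(1-\lambda))(1-\mu)}
  {f(1+F)(1+\alpha(1-\lambda)) + (1-f)(1-\sigma_{total}\, m)}, \qquad
m' = \frac{f(1+F)(1-\mu)(1-\lambda)(1-\alpha)}
  {f(1+F)(1-\lambda)(1-\alpha) + (1-f)\left[(1-\lambda) +
  \lambda \sigma_{md}\, m\right]}.$$

The denominators count the surviving female- and male-destined eggs:
uninfected mothers lose a fraction $\sigma_{total} m$ of their daughters to
CI (or see them converted, $\lambda\sigma_{md} m$ extra sons), while all
eggs of infected mothers are protected (female-level rescue, consistent with
the IBM default). We adopted this parenthesization of the recursions after
checking it against three independent anchors: the no-CI limit
$f' = f(1+S_d)(1-\mu)/(f(1+S_d)+1-f)$, absorbing fixation under perfect
transmission, and the published nine-generation endpoint of the
Beis-parametrized invasion ($\approx 98\%$), which the alternative
egg-level parse misses by two points. One recursion step is one host
generation, conventionally 11 days (female maturity); a season of 150 days
maps to $\lfloor 150/11 \rfloor = 13$ generations.

Setting $\sigma_{total} = 0$ and $F = 0$, the stationarity condition of $f$
gives closed forms used throughout the persistence analyses: the minimum
distortion maintaining a frequency $\omega_0$ is
$S_d = \mu/(1-\mu-\omega_0)$ (defined for $\mu + \omega_0 < 1$), and
conversely a non-zero $S_d$ stably maintains
$\omega_0 = (S_d - \mu(1+S_d))/S_d$ — with a non-positive value meaning the
infection cannot be maintained. The two maps are algebraic inverses, which
the test suite verifies on a $(\mu, \omega_0)$ lattice.

## Generation time in an overlapping-generation population

The 11-day generation convention is useful for comparing with the
recursions, but the *realized* generation interval of the IBM is the
egg-weighted mean age of mothers, which the daily records expose
(`mean_mother_age`). Because oviposition continues to age 20 while random
mortality thins older cohorts, that interval settles around 14 days. The
neutral-decay oracle in the test suite therefore checks the transmission law
$f_{t+1} = f_t(1-\mu)$ per *realized* generation; at an 11-day convention
the deterministic map slightly overstates how fast a neutral infection
decays.

## Observables

Each day the simulator records, over living individuals: population size,
infection frequencies (females, males, all), male:female ratio (all
individuals and adults only), active-suppressor allele frequency, the
fraction of that day's laying (inseminated) females whose cross is
incompatible (`ci_cross_frac`), the applied $\psi_t$, and two
suppressor-flow statistics: the share of newborn suppressor alleles that
derive from CI crosses, and the suppressor alleles destroyed by
female-mortality CI that day relative to those transmitted through
compatible crosses. Frequencies over empty categories are 0 by convention;
an emptied population is absorbing and keeps recording zeros.

The early-life mortality summary reported by the demographic analyses is the
age-at-death distribution: the fraction of *deaths* occurring at ages 0–3
days (about 62–63% under default parameters). Survivors at season end are
not part of that denominator.

## Experiment harness

* `run_one_year()` — replicated single seasons with per-day mean/sd
  summaries (reference analyses use 100 replicates).
* `final_frequency_surface()` / `invasion_surface_recursion()` /
  `ibm_vs_recursion_bias()` — mean final infection frequency over a
  $(\sigma_{total}, \omega_0)$ grid, and the cell-wise inflation of the
  deterministic endpoint over the IBM mean. Default grids are 11×11 on
  $[0,1]^2$ and configurable; the divergence is largest at strong CI and low
  initial frequencies.
* `ci_type_contrast()` — strict FM vs strict MD regimes at a focal cell
  (default $\omega_0 = 0.25$, $\sigma_{total} = 1$, the point of maximal
  divergence), with identical replicate seeds in both arms so the contrast
  is paired.
* `run_multi_year()`, `persistence_times()`, `fit_gamma_mle()` — chained
  seasons, years-to-loss (loss = no infected individual at a season's end;
  chains alive at the horizon are reported censored and excluded from the
  gamma fit, with a warning), and a gamma maximum-likelihood fit of the
  persistence-time distribution.
* `fecundity_threshold()` — the smallest fecundity benefit $F_c$ whose
  trailing 10-observation moving average of 100-year final frequencies
  (samples ordered by $F$) reaches $\omega_0$; ties resolve to the first
  qualifying index, and a window that qualifies immediately reports the
  smallest sampled $F$ (0 if 0 was sampled).
* `sd_stability_check()` — simulated long-run frequencies next to the
  closed-form prediction.
* `relative_rmse()` — RMSE of a simulated mean trajectory against a
  day/frequency observation table, normalized by default to the mean
  observed frequency (range- and final-value normalizations are available;
  the choice matters and is therefore explicit).

All campaign randomness derives from one base seed (replicate $i$ uses
`base_seed + i`; grid cells consume consecutive blocks), so any result is
bit-reproducible from its manifest.

## Problem sizes used in the packaged checks

The packaged tests and the acceptance script run the single-season analyses
at the reference scale ($K = 5000$, 100 replicates). The long-horizon
analyses are run at a reduced scale chosen once: persistence and
fecundity-threshold checks use $K = 600$, $P_0 = 20$, 10–20 chains and
horizons of 12–60 years, where only orderings and orders of magnitude are
asserted — a bottlenecked population loses rare infections faster, so
absolute persistence times at reduced $K$ sit below the full-scale values
(the reference persistence analysis at $K = 5000$, 100 chains and a
multi-century horizon is an overnight job reproducible with
`persistence_times()` / `fecundity_threshold()` at default parameters).
Suppressor-coevolution orderings over many years are likewise exercised
through their daily flow statistics (allele gain/loss through CI crosses)
rather than multi-decade fixation times.

## Numerical conventions and degenerate inputs

* $\psi_t$ is clamped to $[0,1]$; populations below target see no random
  mortality.
* Egg counts and the initial infected count use deterministic rounding
  (`round(omega0 * P0)` infected founders, matching a pooled experimental
  design rather than a Bernoulli draw).
* $S_d \le 1-\lambda$ is enforced so $\alpha$ stays a probability; $P_0 = K$
  is rejected ($A = 0$ leaves $r$ undefined).
* Closed-form frequencies outside $[0,1]$ are reported as explicit
  not-maintainable/capped states, never silently saturated.
* Empty categories (no males, no laying females, no newborn suppressors)
  report frequency 0; the gamma fit of a constant sample reports the
  point-mass limit instead of erroring.

## What the synthetic scenarios do and do not show

All inputs are generated by the simulator itself from the spider-mite
parameterization; no field data ship with the package. Passing checks show
internal consistency (egg-fate bookkeeping, suppression algebra, logistic
regulation, transmission law) and agreement with the deterministic
companion model in its limits — they do not validate the life-history
parameterization against other host species, temperature regimes, seasonal
diapause, spatial structure, horizontal transmission or multi-variant
(bidirectional) CI, none of which are modelled. Model-to-data comparison is
supported through `relative_rmse()` on user-supplied day/frequency tables.

## A worked example

```{r example, eval = FALSE}
p <- model_params(sigma_fm = 0.98, sigma_md = 0.02, sigma_total = 1,
                  mu = 0.018, omega0 = 0.5)
camp <- run_one_year(p, replicates = 100, base_seed = 1)
# infection frequency among females at day 100
mean(camp$daily$inf_freq_female[camp$daily$day == 100])
# peak of the mean daily CI-cross frequency and sex ratio
max(camp$summary$ci_cross_frac)
max(camp$summary$mf_ratio)
```

Under this parameterization the invasion from a 50% founding frequency
reaches ~90% infected females within 100 days, the CI-cross frequency peaks
near day 14–15 at ~25%, and the population sex ratio transiently peaks near
33% before returning to the natural 25% as the infection approaches
fixation.
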