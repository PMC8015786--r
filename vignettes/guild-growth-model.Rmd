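---
title: "A guild-pooled Bayesian state-space model of fish population growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A guild-pooled Bayesian state-space model of fish population growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Long-term trawl surveys count fish of many species at a handful of sites,
year after year. Species-by-species trend models ignore that trophically
similar species respond to the same food-web changes; collapsing species
into functional feeding guilds throws away the taxonomic signal. This
package implements the intermediate: a multi-species state-space model in
which every species keeps its own latent abundance trajectory, but the
annual growth rates of species within a guild are partially pooled through a
guild-level distribution, and the guild-level mean growth can be regressed
on an ecosystem covariate (here, annual zooplankton dry-weight biomass) for
the years the covariate record exists.

## The model

**Process layer.** Let $n_{s,t}$ be log abundance of species $s$ in year
$t$ ($t = 1, \dots, T$). Abundance follows exponential growth,

$$n_{s,t+1} = n_{s,t} + \lambda_{f,s,t},$$

where $\lambda_{f,s,t}$ is the annual log-growth increment of species $s$
in guild $f$. The growth model has two regimes, split by whether the
transition's *origin year* falls inside the covariate record:

$$\lambda_{f,s,t} \sim
  \begin{cases}
  \mathrm{Normal}(\bar\lambda_f,\ \sigma_{\lambda,f}) & \text{origin before the covariate record} \\
  \mathrm{Normal}(\alpha_f + \beta_f X_t,\ \sigma_{\lambda,f}) & \text{origin within it,}
  \end{cases}$$

with $X_t$ the covariate z-score in the origin year. $\bar\lambda_f$ is the
guild mean log-growth rate (0 means a stable population),
$\sigma_{\lambda,f}$ the guild process SD (how differently species and
years within the guild grow), $\alpha_f$ the expected growth at mean
covariate biomass (z-score 0), and $\beta_f$ the change in growth per 1 SD
of covariate biomass. The initial states $n_{s,1}$ are free parameters.

A deliberate reading choice: exponential growth is often written
multiplicatively, $N_{t+1} = N_t \lambda_t$. Because the observation layer
exponentiates $n_{s,t}$, the priors centre growth at 0, and the reported
growth summaries treat 0 as "stable", we implement the process additively
on the log scale with $\lambda$ a log-growth increment. If one instead read
$\lambda$ as a finite rate with $\lambda = 1$ meaning stability, every
growth summary would shift by a constant; nothing else in the machinery
changes.

**Observation layer.** Each sampling event $i$ (one hour of trawling at one
site) yields a count $y_{i,s}$ per species:

$$y_{i,s} \sim \mathrm{Poisson}(\mu_{i,s}), \qquad
  \mu_{i,s} = \exp\!\big(n_{s,t(i)} + \gamma_{s,\mathrm{site}(i)} + \varepsilon_{i,s}\big).$$

$\gamma_{s,k} \sim \mathrm{Normal}(0, \sigma_{s,\mathrm{site}})$ is a
species-specific site effect (drawn once per species-site) and
$\varepsilon_{i,s} \sim \mathrm{Normal}(0, \sigma_s)$ an observation-level
term that makes the marginal count Poisson-lognormal, i.e. overdispersed:
$\mathrm{Var}(y) = \mu + \mu^2(e^{\sigma_s^2} - 1) > \mu$ whenever
$\sigma_s > 0$. Both scale parameters are per-species; a `pool_sigma`
switch shares them across species for sensitivity checks.

**Priors.** Normal(0, 2) — SD 2 — on $\bar\lambda_f$, $\alpha_f$,
$\beta_f$ and $n_{s,1}$; half-Cauchy(0, 2) on every SD
($\sigma_{\lambda,f}$, $\sigma_s$, $\sigma_{s,\mathrm{site}}$), the
standard weakly-informative choice for hierarchical scale parameters. On
the log scale these are diffuse: a growth increment of ±2 is a 7-fold
annual change.

**Latent states are derived, not free.** Given $n_{s,1}$ and the
$\lambda$ draws, the trajectory is deterministic
($n_{s,t} = n_{s,1} + \sum_{u<t} \lambda_{s,u}$). The joint posterior
therefore factorizes as prior × process × observation, which
`joint_log_posterior()` computes exactly as that sum — the decomposition is
checked against an independently coded monolithic oracle in the tests.

## Fitting and diagnostics

`fit_ssm()` samples the posterior with JAGS. The default protocol is 3
chains of 5,000 iterations each with the first 2,000 per chain discarded
(adaptation plus burn-in), keeping 9,000 draws. Chain $c$ is seeded with
`seed + c`, so a fit is bit-reproducible under a fixed backend. Initial
values start every latent state at the species' log mean count and all
effects at 0 — diffuse-prior inits can place $\exp(n)$ astronomically far
from the data and stall the sampler. The per-event $\varepsilon$ draws are
not monitored (one node per observation row; no reported quantity needs
them); all other parameters are saved.

Convergence is assessed with the classic split potential-scale-reduction
statistic: each chain is halved and
$\hat R = \sqrt{((N-1)/N\,W + B/N)/W}$ is computed over the half-chains,
with the conventional threshold 1.1. A rank-normalized variant is available
behind a flag (`split_rhat(x, rank_normalize = TRUE)`), but the classic form is the
default to match common practice for this model family. Draws that are all
identical define $\hat R = 1$ with a warning (zero variance carries no
evidence against convergence for a point-mass posterior). Posterior
summaries are medians and equal-tailed 95% credible intervals (quantiles by
linear interpolation of order statistics, R's type 7); equal-tailed rather
than HPD intervals because that is what the reported-quantity conventions
imply, and type 7 because no other convention is stated anywhere in the
quantities we mirror.

## Data conventions

* **Effort.** One hour of trawling per sampling event; a survey file
  without an effort column defaults to 1.0 h per row.
* **Annual CPUE** pools all sites and months within a year: total catch
  divided by total trawl hours. Per-species summaries (mean, sample SD,
  type-7 quartiles, maximum of the annual values) follow from that. A
  species-year with no rows in a sampled year is a zero catch over that
  year's effort, not missing data.
* **Covariate standardization** uses the sample SD (divisor $n-1$) over
  the covariate years; z-scores are checked to have mean 0 and unit SD to
  1e-10. A constant covariate series is rejected as degenerate rather than
  silently producing 0/0.
* **Regime bookkeeping.** Transition $t \to t+1$ belongs to regime 2 iff
  its origin year $t$ lies inside the covariate record. The final survey
  year has a state but no outgoing transition, so a covariate record ending
  one year before the survey still covers every regime-2 transition; a
  covariate year with no following survey year is an error.

## The synthetic-data generator

The simulator draws from exactly the generative model above — the
distributional match between the simulator and the density functions is
itself a test (mean simulated log-density against an exact entropy
summation). Its default configuration is the study design the package
targets: 10 species in guilds of 4 (benthic invertivore), 3 (general
invertivore) and 3 (planktivore); 33 annual states; sites growing
2 → 3 → 4 over three eras with 6 events per site-year in the dense eras
(twice-monthly summer sampling) and 1 in the sparse final era; a covariate
record spanning the last 19 transition origins, simulated as a declining
linear trend (45,000 − 1,800/yr, in µg DW/m³) with lognormal noise
(sdlog 0.3), giving an annual mean near 29,000–30,000 µg DW/m³ with SD of
order 15,000 — the magnitude of the zooplankton record it emulates. True
guild parameters default to stable pre-covariate growth
($\bar\lambda_f = 0$), mildly negative intercepts ($\alpha_f = -0.1$),
covariate slopes of realistic magnitude (−0.07 benthic, −0.19 general
invertivore, +0.22 planktivore), process SDs (0.5, 0.25, 0.6) that make the
general invertivores the most stable guild, per-species overdispersion SD 1
and site-effect SD 0.5, and initial log-abundances spanning the observed
range of species commonness (≈0.7 to ≈550 fish/h).

One integer seed determines everything, through fixed per-component
sub-streams (covariate, growth draws, site effects, event noise) so that
adding species never perturbs the covariate draws. Growth draws are made
species-major for the same reason.

What the simulator does *not* emulate: spatial correlation between sites,
within-season dynamics (the process ticks annually; monthly events are
exchangeable replicates of the same annual state), species interactions,
and any bound on abundance — a random walk with guild-scale process SD can
wander to larger counts over 33 years than a real bounded population would.
Passing recovery tests therefore demonstrates that the *inference machinery*
is calibrated for data generated by the assumed model, not that the model
is adequate for any particular real survey.

## Design choices that were genuinely open

* **Per-year species draws.** The guild equation indexes $\lambda$ by
  species *and* year, so each species-year gets an independent draw around
  the guild mean (default). A variant with a time-constant species offset
  (`lambda_structure = "species_constant"`) is available but not default.
* **Chain arithmetic.** "15,000 total iterations split between three
  chains, first 2,000 of each discarded, 9,000 saved" is only
  self-consistent as 5,000 iterations per chain − 2,000 warmup = 3,000
  saved × 3 chains; that is the default.
* **Overflow guard.** Simulated events whose Poisson mean exceeds a cap
  (default 1e8) are flagged with NA counts and a warning instead of being
  silently truncated; the model-fit layer refuses flagged rows upstream.
* **Half-Cauchy via truncation.** Implemented (and sampled in JAGS) as the
  positive half of Cauchy(0, 2); the log-density adds log 2 to the full
  Cauchy density on the positive axis.

## Problem sizes used by the tests and the acceptance script

The calibration study runs 20 simulate–fit replicates of a 5-species /
3-guild / 15-year / 2-site design with 3 × 1,500-iteration chains — small
enough to run at desk scale, large enough that nominal 95% intervals can be
checked for ≥ 80% empirical coverage (≥ 90% containment of zero for null
slopes). The acceptance script simulates the full 10-species / 33-year
design (≈ 4,700 observation rows) and refits it with 3 × 3,000-iteration
chains, reporting the guild slope and process-SD medians plus the protocol
bookkeeping from a separate full-protocol run on the small design. Those
sizes are the package's chosen desk-scale defaults; the model itself has no
size limits beyond memory.

## Known limitations

* The sampler is single-backend (JAGS). The density functions are
  backend-independent and tested against oracles, so adding a second
  backend is mechanical, but cross-backend agreement is not itself tested.
* Short chains on the full design can leave $\hat R$ above 1.1 for the
  process SDs (they mix slowest); the pipeline fails loudly in that case
  unless `allow_unconverged = TRUE`.
* No model-comparison machinery (WAIC/LOO) and no alternative count
  distributions: the Poisson-lognormal observation model is the only one
  implemented.
* Counts far into the overdispersed tail (simulated populations drifting
  to ~10⁶ per event) are legitimate under the model but slow the sampler;
  the overflow cap exists to keep the generator honest rather than to
  model gear saturation.
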