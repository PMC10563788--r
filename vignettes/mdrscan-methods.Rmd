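---
title: "Methods: mixture density regression for selection scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixture density regression for selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`mdrscan` models the per-window summary of a haplotype-based selection scan
— the z-scored natural log of the window mean absolute integrated haplotype
score (iHS) — as a two-component Gaussian mixture with covariate-dependent
mixing. For window $j$ with standardized covariates $x_j$ and response
$Y_j$:

$$p_j = \sigma\!\left(a + \textstyle\sum_i b_i x_{ij}\right), \qquad
P(Y_j) = p_j\,\mathcal{N}(Y_j \mid \mu_1, \sigma_1) +
         (1 - p_j)\,\mathcal{N}(Y_j \mid \mu_0, \sigma_0),$$

with the ordering constraint $\mu_1 > \mu_0$. The upper component is
interpreted as enriched in recent positive selection: incomplete sweeps
inflate |iHS| over extended regions, producing the heavy right tail that a
single Gaussian cannot capture. The logistic gate lets each genomic factor
shift a window's odds of belonging to that component without assuming any
linear effect on the bulk of the distribution — the key difference from
ordinary regression, which dilutes localized selection signals across the
whole genome.

Assumptions worth keeping in mind: component responses are Gaussian after
the log transform; covariate effects are linear on the logit scale; windows
are treated as independent, although gene-centered windows physically
overlap (an optional greedy non-overlap filter exists for a robustness
check, at a large cost in sample size); and two components suffice — the
model is not a general mixture-of-experts.

## Fitting

Parameters $(a, b, \mu_0, \sigma_0, \mu_1, \sigma_1)$ are estimated jointly
by maximizing the summed log mixture likelihood with L-BFGS-B. The
optimizer works on the unconstrained vector
$\theta = (a, b, \mu_0, \log\sigma_0, \delta, \log\sigma_1)$ with
$\mu_1 = \mu_0 + e^{\delta}$: positivity of both scales and the component
ordering hold by construction, so label switching cannot occur and no box
constraints are needed. Gradients are analytic; the gating part has the
familiar mixture-of-experts form $\partial\ell/\partial a = \sum_j (r_j -
p_j)$ where $r_j$ is the posterior responsibility of the upper component.
All density work is done in log space (log-sum-exp), so observations far in
one tail never underflow.

Initialization puts $\mu_0$ at the 40th and $\mu_1$ at the 90th percentile
of $Y$, both scales at $\mathrm{SD}(Y)$, $a = \mathrm{logit}(0.25)$ and
$b = 0$ — a robust starting point for right-heavy responses. The first
start is deterministic; `restarts - 1` further starts (default 5 total)
jitter $\theta$ with seeded Gaussian noise of SD 0.3, and the best log
likelihood wins with ties going to the earliest start. Convergence uses a
relative log-likelihood tolerance of 1e-9 and a projected-gradient
tolerance of 1e-6 with at most 2,000 iterations; all are configurable
through `mdr_fit_config()`. On the well-separated synthetic datasets used
for validation one or two starts already reach the optimum; the larger
default guards real, messier data.

### Degeneracy reporting

When the response is effectively a single Gaussian the gate parameters
$(a, b)$ are unidentifiable, and a mixture fit can "converge" to spurious
structure. `fit_mdr()` therefore compares every fit with the closed-form
single-Gaussian maximum likelihood and flags it `degenerate` (with a
warning) when any of three conditions holds: the components collapsed
(relative mean separation and log SD ratio both under 1%), the
log-likelihood gain fails to pay for the mixture's $k + 3$ extra parameters
(an AIC margin), or the gate blew up into a hard threshold (any
|slope| or |intercept| above 30 on standardized covariates — a fitted
mixing probability that flips between 0 and 1 within a tiny fraction of a
covariate SD, the classic spurious spike of mixture regressions). The flag
never alters estimates; it marks them as not interpretable.

### Testing covariates

Each covariate is tested by a likelihood-ratio test against the nested
model with that column removed and every remaining parameter free. The
nested fit warm-starts from the full solution (dropped slope removed) and
is then fully re-optimized, with jittered restarts as a safety net. The
statistic $2(\ell_{\text{full}} - \ell_{\text{null}})$ is clipped at zero
(numerical noise can push it slightly negative) and referred to
$\chi^2_1$. The intercept can optionally be tested the same way against a
model with $a = 0$. Raw p-values are the primary report, matching how such
scans are usually tabulated; a Benjamini–Hochberg column is available
behind a flag, off by default. Nested-model testing of a boundary-free
slope satisfies the regularity conditions for the $\chi^2_1$ reference; the
suite checks calibration empirically (below).

## Preprocessing conventions

Choices the upstream literature leaves open are fixed and documented here;
each is also encoded in exactly one function.

* **Coordinates.** 0-based half-open `[start, end)` everywhere internally;
  BED is read natively. Window membership of a SNP is half-open: a SNP at
  `start` is inside, at `end` outside.
* **Windows.** Centered at `floor((gene_start + gene_end) / 2)`, fixed
  sizes 50/100/200/500/1,000 kb; windows may overlap each other. Windows
  truncated at chromosome ends are kept and flagged (exclusion is a
  config flag); densities then refer to the truncated extent.
* **iHS standardization.** SNPs with minor allele frequency ≤ 0.05 are
  dropped (strict inequality, with a 1e-9 guard so decimal thresholds like
  a derived frequency of 0.95 behave exactly). Retained SNPs fall into 50
  derived-allele-frequency bins — derived, because iHS is polarized by the
  derived allele; the column mapping is configurable for runs whose
  frequency column is minor-allele. Bins are computed genome-wide, never
  per chromosome or window. Standardization is `(raw - bin mean) / bin SD`
  with the sample (n−1) SD convention, used consistently everywhere. Bins
  with fewer than 2 SNPs (configurable) or zero SD are dropped with a
  logged count.
* **Response.** Natural log of the window mean |standardized iHS|, then
  z-scored over the rows that actually enter the model (after complete-case
  filtering). The log base only rescales the response and is absorbed by
  the z-score; it is fixed at e and documented for reproducibility.
* **Recombination.** Window rate = genetic distance between the window
  edges over physical distance (cM/Mb). Edge cM positions come from linear
  interpolation between the two flanking map points, each required within
  50 kb of the edge; otherwise the window has no rate and is excluded
  (complete case). SNP genetic positions would use the same rule with a
  1,000 kb search. No extrapolation beyond the map ends.
* **Densities.** Interval tracks are merged before measuring; density =
  covered non-gap bases / non-gap window length, undefined (and excluded)
  when a window is entirely assembly gap. Scored tracks (conserved
  elements, DNaseI, ChIP-seq) are thresholded to a target genome fraction
  — 4.17% for conserved elements, 10% for regulatory tracks — taking the
  smallest score whose coverage stays at or below the budget, ties kept
  together; when one experiment set's threshold is reused for its tissue
  subsets, the config's `threshold_from` expresses that.
* **GC content.** (G+C)/(A+C+G+T); ambiguous bases leave the denominator,
  an all-ambiguous window is undefined.
* **Gene covariates.** Expression enters as log2(TPM + 1) — the pseudocount
  handles TPM = 0 and is configurable; PPIs as log2(count + 1); VIP
  distance as the edge-to-edge gap to the nearest same-chromosome
  virus-interacting gene (0 on overlap or for a VIP itself; a
  center-to-center alternative sits behind a flag; no VIP on the
  chromosome gives a missing value).
* **Local recombination around regulatory elements.** Elements intersecting
  the window are flanked by 5 kb, merged, clipped to the window; the rate
  between consecutive map points inside those regions is averaged with
  physical-span weights, and the number of map points used is reported
  alongside. Span weighting makes the uniform-map case exact and is the
  natural discretization of the average local rate; the point count lets a
  model downweight windows with sparse map coverage.
* **Missing data.** Complete-case: a window missing any covariate is
  excluded, with per-reason counts reported and written next to the
  feature table. Local-recombination columns are diagnostic by default and
  join the complete-case filter only on request.

## The synthetic generators

`simulate_mdr_dataset()` draws from the model's exact generative process:
standard-normal covariates (optionally correlated through a Gaussian
copula, to emulate co-varying genomic factors such as GC and
recombination), the sigmoid gate, a Bernoulli component label, and the
labelled Gaussian. Its default truth is genome-scan-like: 16 covariate
slopes and intercept −1.43 taken from a published human scan in 1,000 kb
windows, with component parameters $(\mu_0, \sigma_0, \mu_1, \sigma_1) =
(-0.4, 0.8, 0.8, 1.1)$ — values chosen so the marginal response is
approximately standardized (as a z-scored response must be) and the implied
mean gate probability is near one third, matching the magnitudes such scans
report. `recovery_true_params()` is the separate truth used for the
parameter-recovery study: 16 slopes spanning magnitudes 0–1.5 with several
straddling 0.15. The distinction matters because the strongest genome-scan
slope (recombination, −2.44) has an observed-information standard error of
about 0.1 at n = 20,000 — a recovery study under that truth would measure
the information limit, not estimator quality, so the recovery truth keeps
all slope standard errors well below the 0.1 accuracy bar.

`simulate_toy_genome()` writes a complete input set (FASTA, gene and scalar
tables, genetic map, interval tracks, iHS scores) for a 2 × 5 Mb genome
with ~55 genes — small enough that the whole feature pipeline runs in
seconds — together with a ground-truth feature table computed *by
construction*: naive loops and per-base occupancy vectors, deliberately
independent of the pipeline's interval algebra and vectorized
interpolation. Planted structure gives closed-form expectations (a
piecewise-uniform map with rates 2/0.5/1.5 cM/Mb, a 300 kb map desert that
must cost some windows their rate, one window swallowed by an assembly gap,
an N-run in the sequence, SNP frequencies spanning the MAF filter). The
suite requires pipeline output to equal this ground truth bit for bit.

What the generators do **not** emulate: linkage disequilibrium between
windows (windows are drawn independently), demography and drift (no
population history enters the generator), real marginal distributions of
covariates (standard normal instead of the skewed empirical ones), or any
failure of the mixture model itself. Passing tests therefore demonstrate
correctness of the estimator and pipeline under the model's own
assumptions, not that the model is adequate for any particular real
dataset — forward population-genetic simulation is explicitly out of scope.

## Validation problem sizes

The validation studies use 25 replicates of n = 20,000 windows with 16
covariates for parameter recovery, and 1,000 replicates of n = 2,000
windows (three true covariates plus one appended standard-normal null
column) for likelihood-ratio calibration, where the α = 0.05 rejection
rate is required to fall in [0.03, 0.07]. These sizes give the studies
enough resolution to detect meaningful bias or miscalibration while
keeping the full suite to a couple of minutes; recovery fits use two
optimizer starts, which on these well-separated datasets reach the same
optimum as the five-start default.

## Known limitations

* Two components only; a genome with qualitatively distinct sweep classes
  would need a richer mixture, which is out of scope.
* The $\chi^2_1$ reference is asymptotic; at a few hundred windows the
  test may be conservative or liberal — the calibration study covers
  n = 2,000, not tiny inputs.
* The score-threshold search recomputes merged coverage per candidate
  score, which is quadratic in the number of distinct scores; fine for
  annotation-track scales, not for millions of distinct scores.
* `summarize_windows()` and several per-window feature loops are linear
  scans per window; genome-scale inputs (tens of thousands of windows,
  millions of SNPs) are better served by chromosome-wise chunking, which
  the window/SNP layout supports but the current code does not implement.
* Ancestral-allele polarization, EHH/iHS computation itself, and liftOver
  between assemblies are out of scope; the package consumes scan output.
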