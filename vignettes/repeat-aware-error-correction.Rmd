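---
title: "Repeat-aware detection and correction of short-read errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-aware detection and correction of short-read errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readem)
library(dplyr)
```

## The problem

Classical kmer-spectrum error detection counts how often each length-$k$
substring $x_l$ occurs across a read set ($Y_l$) and declares kmers with
$Y_l < M$ erroneous. This works when every genuine kmer is sampled at a
roughly constant depth, because misreads are rare and their products have
counts near zero. Repeat-rich genomes break the assumption: a kmer that
occurs hundreds of times in the genome generates the *same* misread over
and over, so an erroneous kmer one substitution away from a high-copy
repeat can easily be observed more often than a genuine single-copy kmer.
No count threshold can separate the two classes.

`readem` addresses this by estimating, for every observed kmer, the
expected number of **attempts** $T_l$ to read it — attempts that produced
the kmer correctly plus attempts at neighboring kmers that were misread
into it. On the attempt scale an erroneous kmer drops back toward zero no
matter how often it was (mis)observed, because its count is re-attributed
to the repeat that generated it.

## The model

Let $R$ be $N$ reads of length $L$ and $Y = (Y_1, \dots, Y_{|R^k|})$ the
observed counts over the distinct kmers. Substitution errors are modeled
either uniformly, with per-base rate $p_e$ and misread probability

$$p_e(x_m, x_l) = \left(\frac{p_e}{3}\right)^{d}(1 - p_e)^{k - d}, \qquad
d = d_H(x_m, x_l),$$

or position-specifically through $k$ stochastic $4\times4$ tables
$q_i(\alpha, \beta)$, giving the (asymmetric) product
$p_e(x_m, x_l) = \prod_i q_i(x_m[i], x_l[i])$. Because errors are rare,
only sources within Hamming distance $d_{\max}$ (default 1) are
considered, and kmers never observed in the data are dropped from the
neighborhoods; the surviving misread weights of each source are
renormalized over the observed targets in its ball. The counts then follow
a multinomial whose cell probabilities mix over each kmer's neighborhood
$\mathcal N_l$, with observed log likelihood (up to an additive constant)

$$\ell(T \mid Y) = \sum_l Y_l \log \sum_{m \in \mathcal N_l}
T_m\, p_e(x_m, x_l).$$

An EM algorithm maximizes this directly on the attempt scale: the E step
splits each $Y_l$ over $\mathcal N_l$ proportionally to
$T_m\,p_e(x_m, x_l)$, and the M step sums each source's shares. The
iteration starts at $T = Y$, conserves $\sum_l T_l = \sum_l Y_l$ exactly,
and increases the likelihood monotonically. Estimates that reach zero stay
at zero; detection treats $T = 0$ as the strongest evidence of error.

Detection itself is a strict threshold: $x_l$ is called erroneous when its
statistic falls below $M$, applied either to $T$ (this method) or to $Y$
(the classical baseline the package keeps for comparison).

```{r toy}
reads <- c(rep("AAA", 500), rep("AAC", 6))
sp <- build_spectrum(reads, k = 3)
rows <- build_neighbor_rows(sp, uniform_error_model(0.01), d_max = 1)
fit <- run_em(sp, rows)
tidy(fit)
```

The satellite kmer `AAC` keeps its observed count of 6 but only about
4.4 expected attempts at the default tolerance (tightening `tol` reaches
the exact constrained maximum-likelihood value of about 4.6, which a grid
search over the one free parameter confirms): part of its observations
are explained as misreads of the 500-copy repeat `AAA`. At realistic
coverages the drop is far more dramatic, since genuine kmers sit near the
coverage constant.

## Correction

For each base of a read, every covering window $x_l$ (up to $k$ of them)
supplies a posterior over the true base at its in-window position $t$:

$$p_t(b \mid x_l) \propto \sum_{m \in \mathcal N_l,\, x_m[t] = b}
T_m\, p_e(x_m, x_l),$$

with the attempt estimates standing in for the unknown genomic
occupancies. The covering windows' posteriors are averaged (they are not
independent, so averaging rather than multiplying is deliberate) and the
base is rewritten to the argmax when that differs from the observed base.
Three design points are worth making explicit, as the choice was open:

* **Single pass.** Posteriors are computed from the original read;
  corrections are not re-fed into overlapping windows, which would make
  the result depend on sweep order.
* **Ties keep the observed base** — the conservative choice.
* **No candidate filtering.** All neighbors contribute to the posterior,
  including the observed kmer itself. A consequence is that corrections
  succeed where the true source carries substantial attempt mass (repeat
  contexts) and abstain in single-copy contexts, where the observed
  kmer's own mass dominates. This matches the method's purpose: it is a
  *repeat-aware* corrector, and the evaluation below shows exactly that
  profile.
* **Liberal pre-filter.** Only reads containing at least one kmer with
  $T$ below a liberal threshold (by default $3M$) enter correction;
  everything else passes through unchanged and provably identical to a
  full run.

## Choosing the threshold

The histogram of $T$ is multi-modal: a spike near zero (erroneous kmers)
and peaks near $g \cdot c$ for genomic occurrence $g = 1, 2, \dots$,
where $c = N(L - k + 1)/(|G| - k + 1)$ is the coverage constant. The
`fit_mixture()` module models it as

$$\pi_0\,\mathrm{Gamma}(\alpha, \beta)
+ \sum_{g=1}^{G} \pi_g\, \mathcal N(\mu_g, \sigma_g^2)
+ \pi_{G+1}\,\mathrm{Uniform}(\min T, \max T),$$

where hypothesizing Gamma-distributed Poisson intensities for the attempt
counts makes each occurrence class negative binomial, approximated by a
normal with mean $\mu_g = g\mu p/(1-p)$ and variance $g\mu p/(1-p)^2$;
the uniform absorbs the few kmers with occurrence beyond $G$. The number
of classes $G$ is chosen by BIC, and kmers whose posterior membership in
the gamma component exceeds 0.5 are classified erroneous. Numerical
choices:

* The normal block is reparametrized by the unit mean $m = \mu p/(1-p)$
  and unit variance $v = m/(1-p)$, for which the weighted maximum
  likelihood M step is closed form; $\alpha$ comes from a bracketed 1-D
  root of the digamma equation, and $\hat\beta = \hat\alpha / $ the
  gamma-weighted mean.
* The gamma mean is capped at $m/2$: the error component must sit below
  the occurrence-1 class, otherwise a flexible gamma can silently absorb
  a normal peak and the labels lose their meaning.
* Initialization is deterministic but multi-start: candidate unit means
  (the main density peak plus upper quantiles) are each run briefly and
  the best likelihood is polished to convergence. A single start is
  unreliable when erroneous kmers are the majority class, which is the
  usual situation at high coverage.
* $T \le 10^{-8}$ is assigned to the gamma component outright, avoiding
  $\log 0$; the fit is otherwise pure EM with a monotone likelihood.

The headline detection results in this package use optimal-threshold
sweeps against simulator truth rather than estimated thresholds, so the
mixture is a convenience for real data, not a dependency of the
benchmarks.

## The simulator

Because repeat-rich regions cannot be reliably mapped or assembled, only
simulation provides unambiguous ground truth. `generate_genome()` builds
an iid background at a maize-like composition (A 28%, C 23%, G 22%,
T 27%) and embeds repeat families — one random unit per family, copied
`multiplicity` times at uniformly chosen non-overlapping positions, the
units drawn from the same composition. `simulate_reads()` samples
forward-strand substrings uniformly and passes every base through the
substitution model (constant rate, or one $4\times4$ matrix per read
position such as `ramped_read_profile()`, whose rates rise toward the 3'
end as on real instruments). Indels, quality strings, GC-coverage bias,
paired ends and reverse-strand sampling are deliberately out of scope;
passing tests therefore demonstrate correctness of the method under its
own model, not robustness to artifacts the model excludes (indels in
particular would be seen as bursts of substitutions).

The bundled desk-scale presets emulate three repeat regimes on 100 kb
genomes at 80x coverage of 36 bp reads:

| preset | repeat span | families (unit length, multiplicity) |
|--------|-------------|--------------------------------------|
| `D1-small` | 20% | (100, 200) |
| `D2-small` | 50% | (50, 400), (150, 200) |
| `D3-small` | 80% | (50, 400), (150, 200), (300, 100) |

These are 1/10-scale versions of the full-size recipes (1 Mb, e.g.
(1000, 200) or (500, 400) + (1500, 200) + (3000, 100)). The scaling
preserves **multiplicities** and shrinks unit lengths, because the
phenomenon under study depends on per-kmer occupancy: an erroneous kmer
adjacent to an $\alpha$-copy repeat is observed about
$\alpha c \cdot p_e/3 \cdot (1-p_e)^{k-1}$ times, and only when that is
comparable to the clean-kmer depth $c$ does count thresholding actually
fail. Dividing multiplicities instead would make the scaled problem
trivially easy and the comparison meaningless.

## Parameters that matter

| parameter | default | meaning |
|-----------|---------|---------|
| `k` | 13 | kmer length (bases). Large enough that the 4^k space dwarfs the spectrum, small enough that every read yields many windows; codes stay exact up to k = 26. |
| `d_max` | 1 | neighborhood radius (substitutions). Rows stay at most 3k + 1 wide; 2 is supported for small spectra. |
| `p_e` | 0.006 | uniform per-base substitution rate, a typical short-read figure. |
| `tol`, `max_iter` | 1e-6, 100 | EM stops when the relative log-likelihood change drops below `tol`. |
| threshold grid | `0:ceiling(max Y)` | integer sweep, comparable across Y and T. |
| `liberal_threshold` | `3 * M` | correction pre-filter. |
| `tau` | 0.5 | posterior cutoff for the mixture classifier. |

## What the benchmarks compute

`scripts/acceptance.R` and the calibration test suite rerun the full
pipeline at the preset scales: simulate, count, build neighborhoods, run
the EM, sweep every integer threshold on both $Y$ and $T$ against the
truth ($\alpha_l = 0$ defines an erroneous kmer type), and compare the
sweep minima. On `D3-small` with a matched uniform model, thresholding
$T$ removes ~99% of the minimum wrong predictions achievable with $Y$;
with a deliberately misspecified positional model (simulation under a
ramped read-position profile, inference under a diagonal-perturbed
kmer-position model spanning roughly 0.96–0.995) the reduction is still
~54%. Correction on the same recipe reaches a gain around 0.69 with
specificity 1.00 at `d_max = 1` and collapses to zero at `d_max = 0`,
quantifying how much of the benefit comes from modeling the misread
neighborhood. On `D1-small` the no-intercept regression of $T_l$ on
$\alpha_l c$ over genome-present kmers has slope within 5% of one. Each
run takes seconds to a couple of minutes on one core; the problem sizes
(100 kb genomes, ~220k reads, ~150-400k distinct kmers) were chosen so
the whole suite stays desk-scale while keeping the occupancy statistics
of the full-size recipes.

## Known limitations

* The positional model is indexed by *kmer* position, while real error
  rates vary by *read* position; the collapse `profile_to_kmer_model()`
  averages over window offsets, so a sharp 3'-end gradient is flattened.
  This mismatch is inherent to the kmer-level formulation.
* Correction abstains on errors in single-copy context (see above), so
  base-level sensitivity tracks the repeat fraction of the genome.
* The neighborhood ignores unobserved kmers; their occupancy must be
  small (or they would have been observed), but the renormalization
  slightly inflates attempt estimates for kmers with mostly-unobserved
  balls.
* Quality scores are read but ignored; insertion and deletion errors are
  not modeled.
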