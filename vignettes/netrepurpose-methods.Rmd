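---
title: "Methods: network-proximity drug repurposing with Bayesian dose-response evidence"
author: "netrepurpose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-proximity drug repurposing with Bayesian dose-response evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrepurpose)
```

# Overview

`netrepurpose` implements a network-pharmacology screen for drug
repurposing against a disease gene module, followed by three layers of
evidence: a clinical-phase *rediscovery rate* that validates the ranking
computationally, a Bayesian dose-response model that grades experimental
evidence with Bayes factors, and an enumeration of short mechanistic paths
that makes candidate rankings interpretable. A synthetic-data generator
with planted ground truth makes every stage testable end to end without
external databases. This vignette records the models, the tunable
parameters, the numerical choices, and the limitations.

# The drug-target network

Drug-target pairs are retained when the mean pActivity — the negative
base-10 logarithm of the molar activity concentration, averaged over all
measurements for the pair — is at least 5, which corresponds to a mean
activity of 10 µM or better. Raw activity values are assumed to be in nM
(the common convention of public bioactivity repositories); the unit is an
argument of `filter_drug_targets()` because upstream exports differ. All
measurements for a pair enter the mean, including duplicates: the averaged
statistic is defined over measurements, not over distinct assays. Gene
identifiers are treated as case-sensitive symbols with no alias
resolution; identifier harmonisation belongs upstream of this package.

# Network proximity

For a drug with target set $T$ and a disease gene set $S$ in an
interactome with shortest-path distance $d(s,t)$, the *closest* proximity
measure is

$$d(S, T) = \frac{1}{|T|} \sum_{t \in T} \min_{s \in S} d(s, t),$$

the average hop distance from each target to its nearest disease gene.
Distances are unweighted; the interactome carries no edge confidence
scores. Design choices worth recording:

* **Unreachable targets.** A target with no path to any disease gene
  contributes $\infty$, making the drug's proximity $\infty$ (ranked
  last). A `drop` mode that averages only over reachable targets exists
  for disconnected interactomes, but infinity is the default because
  silently dropping targets changes $|T|$ and flatters polypharmacology.
* **No permutation z-score.** Proximity is reported as the raw distance;
  no degree-preserving randomisation is applied. Raw distances are
  monotone in the evidence the screen actually uses (rank within a gene
  set), and the rank aggregation downstream is invariant to any monotone
  per-column transformation.
* **Ties.** Ranks within a gene-set column are strict permutations; tied
  distances are broken lexicographically by drug identifier. Average
  ranks would be friendlier to a single-column reading, but the
  Markov-chain aggregation downstream consumes strict orders, and a
  deterministic tie rule keeps reruns byte-identical. The rule is recorded
  in the screen's JSON metadata.
* Disease genes absent from the interactome are dropped with a message
  (proximity is undefined for them); an empty intersection is an error.

# Rank aggregation

Per-gene-set rankings are aggregated with the classical Markov-chain
schemes. From the current item $u$, a candidate $v$ is proposed uniformly;
among input lists ranking both items, let $f$ be the fraction preferring
$v$ over $u$. MC1 moves if $f > 0$, MC2 if $f > 1/2$, MC3 with
probability $f$. Lists enter with uniform weight. The chain is mixed with
a teleportation weight of 0.05 — large enough to guarantee ergodicity on
every instance we generate, small enough not to flatten the stationary
distribution — and the consensus orders items by stationary probability,
computed by power iteration to an $L_\infty$ tolerance of $10^{-10}$.
Borda (mean rank) is included as a deterministic baseline.

Algorithm selection follows the mean *modified Kendall distance* between
each candidate consensus and the input lists: pairwise disagreements over
the union of two top-$k$ lists, with pairs whose relative order one list
leaves undetermined contributing a penalty $p$ (default 0.5, the neutral
value), normalised to $[0, 1]$. Ties in the selection are resolved by the
fixed precedence MC3 > MC2 > MC1 > Borda, reflecting that MC3 uses the
most information per pair. With strongly correlated input rankings all
four algorithms often coincide — visible in this package's own synthetic
runs — which is itself a useful robustness signal.

# Rediscovery rate

For an indication $i$, let $\bar\phi_{T_k}(i)$ be the mean maximum
clinical phase (0 = never investigated, 4 = approved) over the top-$k$
consensus drugs, and $\bar\phi_{B_l}(i)$ the same over the bottom-$l$.
The rediscovery rate is their ratio

$$r_l(k, i) = \bar\phi_{T_k}(i) / \bar\phi_{B_l}(i).$$

Values above 1 mean the screen concentrates clinically investigated drugs
near the top. Pairs absent from the phase table count as phase 0, the
"never investigated" reading; a zero bottom mean flags the rate undefined
rather than infinite. The bottom-set size defaults to 1808 when the
consensus is long enough and to $\lfloor n/3 \rfloor$ otherwise, and
multi-indication reports include only indications with at least 100 drugs
at phase ≥ 1 (both configurable). The rate is reported descriptively,
without a significance test: under the null the expected ratio is
approximately $1 + \mathrm{CV}^2(\bar\phi_{B_l})$ (about 1.01 at the test
suite's sizes), which the null-calibration test budget of ±0.05 absorbs.

# Bayesian dose-response model

For one drug-assay pair with bioactivity $y$ observed at concentrations
$x$ (log10 µM), the model is

$$y \sim \mathcal{N}(\mu,\; \sigma \mu), \qquad
  \mu = y_1 + \frac{y_0 - y_1}{1 + e^{k (x - EC_{50})}},$$

a four-parameter logistic mean with noise *proportional to the mean* —
multiplicative error being the norm for plate-based bioactivity readouts —
and the prior on the fold change $FC = y_1 / y_0$

$$FC \sim \Gamma(\alpha = 5, \beta = 5),$$

whose mean of 1 encodes "no effect" as the prior expectation. Choices and
defaults:

* **Axis.** $x = \log_{10}$(concentration in µM) by default: doses span
  decades, and only on a log axis does the logistic recover $y_0$ as the
  zero-dose asymptote ($x \to -\infty$) with $k > 0$. A raw-axis mode
  exists for narrow dose ranges.
* **Parameterisation.** $y_0$ and $FC$ are sampled and $y_1 = FC \cdot
  y_0$ derived, which places the Gamma prior directly on the quantity of
  interest and, with $y_0 > 0$, keeps $\mu$ in the interval
  $(\min(y_0,y_1), \max(y_0,y_1))$, strictly positive — so $\sigma\mu$ is
  a valid scale everywhere in the parameter space.
* **Other priors** (weakly informative defaults; only the $FC$ prior is
  part of the analysis design): $y_0 \sim \mathcal{N}^+(\bar
  y_{\text{lowest dose}},\, 3\,\mathrm{sd}(y))$ truncated at zero,
  $k \sim \mathcal{N}^+(0, 5)$, $EC_{50} \sim U(\min x - 1, \max x + 1)$,
  $\sigma \sim \mathcal{N}^+(0, 0.5)$. For calibration studies the
  data-driven $y_0$ location must be replaced by fixed numbers so the
  generating and fitted priors coincide (`dr_priors(y0_loc=, y0_scale=)`).
* **Standardisation.** Each dataset is scaled so 10 units equal one
  sample standard deviation (scaling only, no centring — centring would
  break the positivity of $\mu$); the factor is stored and inverted by
  `destandardize_bioactivity()`.
* **Sampling.** Gibbs/slice sampling via JAGS: 4 chains × 1,000 kept
  draws after 1,000 adaptation plus 1,000 burn-in iterations. The
  conditional one-parameter updates mix slowly along the correlated
  $(y_0, FC, EC_{50})$ ridge typical of three-dose designs, so draws are
  thinned 80:1 by default (`sampler_config(thin=)`); chain RNG seeds
  derive deterministically from the configured seed, making fits exactly
  reproducible.
* **Diagnostics.** Fits are excluded, not reinterpreted, when any
  parameter has $\hat R > 1.01$, effective sample size < 400, or Monte
  Carlo standard error above 10% of the posterior standard deviation.
  Three-dose designs leave $EC_{50}$ and $k$ weakly identified, so
  occasional exclusions are expected behaviour, mirroring the
  inspect-and-exclude practice the analysis models; a longer chain
  (larger `thin`) typically clears a marginal fit.

## Hypotheses and evidence

The hypothesis partition places the protective/neutral/adverse boundaries
at the 0.2 and 0.8 quantiles of the $\Gamma(5,5)$ prior — the unique
symmetric-in-prior-mass choice giving the three hypotheses prior
probabilities (0.2, 0.6, 0.2). For assays where benefit means a decreased
readout, protective is $FC < q_{0.2}$; for increase-benefit assays the
outer intervals swap; the closed neutral interval takes boundary values.
Posterior probabilities are the fractions of posterior $FC$ samples in
each interval, and the Bayes factor is the *posterior odds*

$$BF = P(H_{\text{protective}} \mid D) / P(H_{\text{neutral}} \mid D),$$

reported as $2\ln BF$ (natural log) and graded on the conventional bands:
≤ 2 none, (2, 6] moderate, (6, 10] strong, > 10 very strong. Because the
prior odds are 1/3 rather than 1, the prior-odds-corrected factor
($3 \times BF$) is reported alongside. With finite samples a posterior
wholly outside the neutral interval yields $BF = \infty$ (flagged with a
caveat), and a posterior with no mass in either hypothesis yields an
undefined $BF$ (`NaN`, graded `NA`) — an entirely adverse posterior is
not evidence of protection.

# Mechanistic paths

Paths have the grammar drug →¹ target →² mediator →³ disease gene, the
drug-target link counting as the first edge. Enumeration returns all
simple paths of 1–3 edges; mediators that are themselves disease genes
are excluded from 3-edge paths by default since those routes already
appear as 2-edge paths. The mediator summary counts, for every (target,
mediator) pair seen in a 3-edge path, the *distinct* disease genes of
each gene set adjacent to the mediator — invariant to path multiplicity —
and the fraction of the set, the tabular form of a mediator-by-gene-set
heatmap. No expression or tissue filter is applied to mediators.

# Synthetic study conditions

The generator's defaults define the conditions under which the package
tests itself (chosen once, at desk scale):

* Interactome: 1,000 genes by preferential attachment, 3 edges per new
  gene. Preferential attachment is used deliberately: proximity methods
  are degree-sensitive, and honest testing requires the heavy-tailed
  degrees of real interactomes (a property the test suite verifies
  against same-size uniform random graphs). The generator does not match
  the real interactome's size; a full-size run is a parameter change, not
  a code change.
* Disease module: 30 genes grown by snowball sampling, hence connected
  (real disease modules are locally clustered rather than scattered).
* Drugs: 100, 3 targets each. With probability `proximity_signal` a
  drug's targets are sampled within distance 1 of the module (closest
  proximity ≤ 1 by construction); otherwise uniformly.
* Clinical phases: with probability `phase_signal` the deterministic map
  proximal → 4, distal → 1; otherwise Binomial(4, ½) noise. The two
  extremes give an exact null (`phase_signal = 0`, expected rate 1) and
  an exact closed form (`phase_signal = 1`, rate 4 under the planted
  ordering) used by the calibration tests.
* Dose-response: 3 concentrations (1, 3, 10 µM — the dosing pattern of
  the motivating assays) × 5 replicates, truth fold changes 0.3 / 1.0 /
  2.0 in both benefit directions, $y_0 = 100$, $k = 3$, $EC_{50} =
  \log_{10} 3$, $\sigma = 0.05$. The values 0.3 and 2.0 are
  quantile-symmetric displacements under the $\Gamma(5,5)$ prior (≈1.5%
  tail mass on each side).

What the generator does **not** emulate: literature and curation biases
of real drug-target data, edge noise and study bias of real interactomes,
correlated assay batch effects, or indication structure across diseases.
Passing tests demonstrate the *computations* are correct and calibrated
under the stated model, not that the biological conclusions of any real
screen are.

# Test and calibration design

Problem sizes in the test suite are chosen for desk-scale runs: oracle
cross-checks on ≤ 50-node graphs (exact agreement with hand-rolled BFS
and exhaustive DFS), eigenvector checks on ≤ 10-state chains
($L_\infty \le 10^{-8}$), 200 null redraws for the rediscovery rate, and
for the dose-response model 200 simulation-based-calibration replicates
at 3 doses × 3 replicates (rank-uniformity of the true fold change within
the posterior, chi-square at 0.01, using 19 evenly spaced posterior draws
per replicate to blunt autocorrelation) plus 50-replicate
detection/false-positive rate checks. Calibration fits use 2 chains × 500
kept draws (thin 4), enough for interval and hypothesis-mass statistics;
single-fit inference keeps the heavier defaults above.

# Known limitations

* Proximity is unweighted and unnormalised; hub-heavy target sets are not
  penalised relative to a random-target baseline.
* The aggregation implements uniform list weights only; weighting gene
  sets by evidence quality would require a different transition rule.
* Three-dose designs identify the fold change far better than $EC_{50}$
  or $k$; posterior summaries for the latter two mostly return the prior,
  and the slice sampler needs heavy thinning on their ridge.
* The Bayes factor here is a posterior-odds summary, not a marginal
  likelihood ratio; with the (0.2, 0.6, 0.2) prior masses the two differ
  by a factor of 3, which the report carries explicitly.
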