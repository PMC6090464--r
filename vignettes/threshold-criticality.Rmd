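---
title: "Threshold criticality in functional connectivity networks: methods"
author: "critnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold criticality in functional connectivity networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critnet)
```

## The question the package addresses

Resting-state functional connectomes are summarized as symmetric matrices
$(w_{ij})$ of correlation weights between brain regions, $|w_{ij}| \le 1$,
zero diagonal. Thresholding such a matrix at a cut-off $w_t$ and keeping
the connections with $|w_{ij}| > w_t$ produces a family of binary networks
indexed by the threshold. critnet tracks three readouts of that family —

1. the mutual information carried by a one-step ternary signal-transfer
   model on the thresholded network,
2. the topology of the binarized graph (largest connected component
   fraction and transitivity), and
3. the goodness of a bounded power-law model of the surviving weight
   magnitudes, scored against an exponentially truncated power law,

— and asks whether the three exhibit their critical behavior at the same
threshold. Coincidence of those transitions is the signature, reported for
real connectome ensembles, that information-transfer optimality,
small-world topology and self-organized criticality of the weight
statistics are facets of a single phenomenon.

## The threshold rule

For each matrix the cut-off is parameterized as

$$ w_t = \langle |w| \rangle + n\,\sigma_{|w|}, $$

with the mean and standard deviation taken over the $N(N-1)/2$
off-diagonal upper-triangle $|w_{ij}|$ values of that subject, so the same
$n$ adapts to inter-individual differences in overall connectivity.
Choices fixed here, because the rule itself does not prescribe them:

* $\sigma_{|w|}$ is the **population** standard deviation (divisor $N_p$,
  not $N_p - 1$), so `computeThreshold()` is a closed deterministic
  function of the matrix;
* each undirected weight is counted **once** (upper triangle); counting
  both triangles would leave the mean unchanged but alter nothing else —
  the convention is fixed for reproducibility of $\sigma$;
* binarization uses the **strict** inequality $|w_{ij}| > w_t$; ties are
  excluded;
* the default sweep grid is $n \in [-2, 4]$ in steps of $0.1$. The lower
  end anchors the stepwise clustering difference at $n = -2$; the upper
  end and the step are artifact choices that cover the full percolation
  collapse of the ensembles considered here.

Negative weights (anti-correlated regions) survive thresholding by
magnitude and keep their sign in the retained-weight matrix.

## The transfer model and its mutual information

A stimulus $S = (s_1,\dots,s_N)$, $s_i \in \{-1, 0, +1\}$, drives each
node through its retained connections:

$$ r_{s,j} = \sum_i a_{ij} w_{ij} s_i, \qquad
   r_j = \begin{cases} +1 & r_{s,j} > w_t \\
                       -1 & r_{s,j} < -w_t \\
                       0 & |r_{s,j}| \le w_t. \end{cases} $$

Stimulus entries are independent with $P(+1) = P(-1) = p$ (the activation
density) and $P(0) = 1 - 2p$. Design decisions:

* **Single synchronous step.** The response is read out once; there is no
  recurrent iteration, no avalanche dynamics, no refractory state. The
  transfer rule defines $R$ directly from $S$ with no time index, and
  that literal reading is implemented.
* **The response threshold equals the edge cut-off.** A boundary drive
  $|r_{s,j}| = w_t$ maps to the silent state.
* **Degenerate negative thresholds.** On the default grid $w_t$ can be
  negative at $n = -2$ (mean minus two standard deviations). The ternary
  rule is then contradictory as printed (the $+1$ and $-1$ conditions
  overlap), so propagation clamps the response threshold to
  $\tau = \max(w_t, 0)$. Binarization keeps the strict rule unchanged
  (every nonzero weight survives a negative cut-off).

Information transfer between stimulus node $i$ and response node $j$ is
the mutual information in nats,
$m(i,j) = H(s_i) + H(r_j) - H(s_i, r_j)$, averaged in two levels:
$\langle m(j)\rangle = \sum_{i \ne j} m(i,j)/(N-1)$ over stimulus nodes
and $m = \sum_j \langle m(j)\rangle / N$ over the network.

* The divisor $N-1$ forces the all-ordered-pairs reading: $m(i,j)$ is
  computed for every ordered pair, adjacent or not. An
  adjacency-restricted variant (same divisor) is available behind the
  `pairs = "adjacent"` flag for sensitivity analysis.
* Estimation is **plug-in** (maximum likelihood) from the empirical joint
  of 1000 Monte-Carlo trials per cell by default, with no bias
  correction: comparisons are relative across thresholds, and the
  plug-in bias ($\approx$ (occupied cells $-$ 1)/2T nats) is shared along
  a curve. Marginals are taken from the same joint table as the joint
  entropy, which guarantees $m(i,j) \ge 0$ for every pair in every run.
* `exactNetworkMI()` enumerates all $3^N$ stimulus configurations (capped
  at $N = 10$, 59 049 configurations) and serves as the oracle for the
  Monte-Carlo path; the test suite verifies convergence of the estimator
  to the oracle as the trial count grows.
* Values of the pairwise matrix below $10^{-12}$ nats are snapped to zero:
  they are floating-point residue of exactly independent pairs.

## Weight-distribution models

On the bounded range $|w| \le 1$ a pure power law is ill-defined, so the
scale-free model is a power law in the complement $\tilde w = 1 - |w|$:

$$ p(|w|) = (\gamma + 1)\,(1 - |w|)^{\gamma}, \qquad \gamma > -1 . $$

Fitted to the weights surviving a threshold, the model is renormalized to
the conditional density on $(w_t, 1]$ — the only coherent reading when the
data are the $|w_{ij}| > w_t$ values — and the MLE is closed form:

$$ \hat\gamma = \frac{-n}{\sum_k \ln\frac{1 - |w_k|}{1 - w_t}} - 1 . $$

The comparator is the exponentially truncated power law
$p(x) \propto x^{\alpha - 1} e^{-x/x_c}$, fitted by numerical maximum
likelihood over $\alpha \in (-10, 10]$, $x_c \in (10^{-3}, 10^3]$, with
the normalization constant evaluated on the bounded domain (incomplete
gamma function for $\alpha > 0$, quadrature otherwise). The exponential is
implemented as *decaying*: a growing exponential is not the truncation
the comparator literature defines, and the decaying form is the only one
that makes $x_c$ a cut-off. The complement-variable fit
(`variable = "wtilde"`) is available since the literature is ambiguous
about which variable the comparator should be applied to.

Both fits are scored by the Kolmogorov–Smirnov distance
$D = \sup_w |P_e(w) - P(w)|$, evaluated at **both sides of every
empirical step** (for a step function against a continuous model CDF the
supremum occurs at a step edge). Numerical conventions: values exactly
equal to 1 are nudged to $1 - 10^{-12}$ (rather than dropped, keeping the
sample size consistent across models) with a warning; fewer than 10
surviving values is an error; a negative $w_t$ clamps the fit domain to
$[0, 1]$. No goodness-of-fit p-values are computed — distance comparison
is the model-selection criterion.

A practical caveat the test suite quantifies: on strongly truncated
domains (e.g. $(0.3, 1]$ with $\gamma = 10$) the two-parameter truncated
power law can reproduce the conditional boundary-power density within
sampling error at $n = 5000$, so KS discrimination is only reliable on
the full domain, and it weakens as $\gamma$ grows (at $w_t = 0$,
measured win rates for the true model fall from 100% at
$\gamma \in \{2, 5\}$ to roughly 95% at $\gamma = 10$ and 82% at
$\gamma = 20$). The families genuinely overlap there; this is a property
of the models, not of the fitting code.

## The synthetic ensemble generator

`generateEnsemble()` makes the pipeline testable without external data.
It emulates the statistical structure the analysis assumes — a clustered
strong-edge skeleton inside correlation-like symmetric matrices whose
magnitudes follow the boundary-power law — not the physiology behind it.
Construction: one Watts–Strogatz ring lattice (degree `backboneDegree`,
rewiring probability `rewireProb`) is the shared backbone; boundary-power
magnitudes are drawn for *all* region pairs, with the top
`backboneQuantile` fraction of the backbone receiving the largest
magnitudes and the displaced large magnitudes landing on random
non-backbone pairs; signs are independent and equiprobable; each subject
is the shared base matrix plus zero-mean Gaussian noise (sd `noiseSd`),
clamped to $[-1, 1]$ (clamping is counted and reported rather than
resampled, keeping the generator a closed form of its seed).

Defaults, chosen once as the study conditions:

| parameter | default | rationale |
|---|---|---|
| `nRegions` | 100 | ensemble scale of the reference analysis, scaled to desk runtimes |
| `nSubjects` | 20 | enough for stable ensemble means at that scale |
| `gamma` | 10 | steep boundary-power weights, the regime the exponent-recovery checks use |
| `backboneDegree` | 6 | ring transitivity $3(k-2)/(4(k-1)) = 0.6$, a strongly clustered skeleton |
| `rewireProb` | 0.1 | the classic small-world regime: high clustering, short paths |
| `backboneQuantile` | 0.9 | a mostly-pure strong backbone with some strong shortcuts |
| `noiseSd` | 0.02 | about a quarter of the mean $|w|$ ($1/(\gamma+2) \approx 0.083$): visible inter-subject variability without destroying the backbone |

All randomness flows from the single `seed` through a documented
splitting scheme (a 31-bit fold of the master seed and the cell indices,
`critnet:::deriveSeed`), so every subject, every sweep cell and every
figure analogue is exactly reproducible; re-running a sweep with the same
master seed reproduces the table byte for byte.

What the generator does **not** emulate — and therefore what passing
tests do and do not show — matters for interpreting ensemble-level
results. Its degree structure is homogeneous: every node sits on the same
ring backbone, so nodes lose their last edge, and the largest component
fragments, only when the mean degree has fallen to order one. In real
correlation matrices the weight geometry is strongly heterogeneous and
component fragmentation begins while the mean degree is still high. Two
consequences observed in this package's own sweeps of the default
ensemble:

* the network mutual information of the one-step model peaks where the
  mean degree is near $1/(2p)$ — every surviving edge is a deterministic
  relay when its source is the only active neighbour, so the per-node
  information scales like $d\,e^{-2pd}$ in the degree $d$ — which at
  $p = 0.01$, $N = 100$ is the half-dense regime ($n \approx 0$), far
  below the percolation threshold ($n \approx 3$);
* consequently the three critical points (mutual-information peak,
  transitivity drop, KS minimum) do **not** co-locate on this generator
  at $p = 0.01$, and the $p = 0.1$ information peak (sitting in the
  sparse relay regime where the stimulus entropy, 0.64 nats, is larger)
  narrowly exceeds the $p = 0.01$ peak. The co-location reported for
  real connectomes is a property of their heterogeneous weight geometry
  that this minimal generator does not reproduce.

The generator's noise model is likewise an artifact decision: real
connectivity matrices carry structured acquisition noise concentrated in
the small-$|w|$ body; additive Gaussian noise with clamping is the
simplest stand-in, and it is the reason the truncated power law can
out-fit the boundary-power model at low thresholds on synthetic data
(the free exponent absorbs the noise-folded mass near zero).

## The sweep and critical-point localization

`runSweep()` iterates subjects over the $(n, p)$ grid: per subject and
threshold it computes $w_t$, the binarized topology and the distribution
fits (threshold-level quantities are shared across $p$), then the
Monte-Carlo mutual information per activation density, appends the
stepwise clustering change $\Delta C(i) = C(i) - C(i+1)$, and averages
every metric across subjects per $(n, p)$ cell (per-quantity averages,
not per-subject critical points). Cells whose fit fails — typically fewer
than 10 surviving weights at high thresholds — are recorded in the
result's failure log and averaged around, not fatal.

`locateCriticalPoint()` reports the argmax of the ensemble-mean mutual
information, the argmax of $\Delta C$ and the argmin of the
boundary-power KS distance, with ties broken toward smaller $n$ (fixed,
documented), boundary extrema flagged as non-peaks, distances between the
three locations expressed in grid steps (the grid spacing is a
configuration choice, so absolute-$n$ statements would not transfer), and
the percolation transition region reported as the $n$-range where the
ensemble-mean component fraction lies strictly between 0.05 and 0.95.

Problem sizes used throughout the package's own checks: the ensemble
sweeps run 20 subjects of 100 regions over 61 thresholds and three
activation densities at 1000 trials per cell; oracle comparisons use
networks of up to 8 nodes at up to $10^5$ trials; distribution-fit
recovery uses 5000 draws. These sizes give stable ensemble means and
sub-percent oracle agreement at interactive runtimes.

## Known limitations

* One-step propagation only; no cascade or time-resolved measures, so
  "information transfer" here is single-hop and the component structure
  influences it only through local degrees.
* Plug-in entropies bias every $m(i,j)$ upward by a term that depends on
  the occupied joint cells; curves are comparable across thresholds, but
  absolute values at small $p$ and few trials are bias-dominated.
* KS model selection loses power between overlapping families on
  truncated domains (quantified above).
* The synthetic generator reproduces the percolation transition and the
  transitivity plateau-then-drop, but not the co-location of the three
  critical transitions seen in real connectome ensembles; analyses of
  that coincidence need real data through `readConnectivityMatrix()`.
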