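# critnet

Criticality analysis of thresholded functional connectivity networks.

Resting-state functional connectomes arrive as symmetric matrices
(w_ij) of signed correlation weights between N brain regions. Keeping
only the connections with |w_ij| strictly above a cut-off

    w_t = <|w|> + n * sigma_|w|

and sweeping the multiplier n turns one weighted matrix into a family of
binary networks. critnet is for researchers who want to ask, on such a
family, whether three different readouts go critical at the same
threshold:

1. **Information transfer.** A one-step ternary transfer model: a random
   stimulus S with entries +1/-1 (each with activation density p) or 0
   drives each node j through its retained connections,
   r_sj = sum_i a_ij w_ij s_i, and the response is +1, -1 or 0 as the
   drive exceeds w_t, falls below -w_t, or lies between. Transfer is
   scored by the mutual information m(i,j) = H(s_i) + H(r_j) - H(s_i,r_j)
   in nats, averaged per node (<m(j)> = sum_i m(i,j)/(N-1)) and over the
   network (m = mean_j <m(j)>), estimated from Monte-Carlo trials with an
   exact enumeration oracle for small networks.
2. **Topology.** Largest-connected-component fraction (the percolation
   order parameter) and the global transitivity C = 3 triangles /
   connected triples, with its stepwise change Delta C(i) = C(i) - C(i+1)
   along the sweep.
3. **Weight statistics.** A maximum-likelihood fit of the boundary-power
   model p(|w|) = (gamma+1)(1-|w|)^gamma — a power law in 1-|w| adapted to
   the bounded correlation range, renormalized to the surviving domain
   (w_t, 1], with closed-form MLE — against an exponentially truncated
   power law p(x) proportional to x^(alpha-1) e^(-x/x_c), both scored by
   the Kolmogorov-Smirnov distance D = sup |P_e - P|.

A synthetic small-world connectome generator (boundary-power magnitudes
on a rewired ring-lattice backbone, per-subject noise) makes every stage
testable without external data, and a sweep orchestrator runs the whole
(n, p) grid over a matrix ensemble, averages across subjects, localizes
the critical points and renders the standard curve families. The methods
vignette (`vignettes/threshold-criticality.Rmd`) documents every model
choice, default and limitation.

## Worked example

```r
library(critnet)

## a 5-subject synthetic ensemble of 60-region matrices
spec <- ensembleSpec(nRegions = 60, nSubjects = 5, seed = 42)
mats <- generateEnsemble(spec)
mats[[1]]
#> ConnectivityMatrix 'sim001': 60 x 60 regions
#>   |w| mean 0.0851, sd 0.0787, max 0.4606

## sweep thresholds and activation densities
cfg <- sweepConfig(input = mats, nGrid = seq(-2, 4, by = 0.5),
                   pValues = c(0.001, 0.01, 0.1), nTrials = 1000,
                   masterSeed = 42)
res <- runSweep(cfg)
res
#> SweepResult: 195 subject rows, 39 ensemble rows
#>   8 cells skipped a distribution fit (see @failures)

locateCriticalPoint(res, 0.01)
#> Critical point summary at p = 0.01
#>   argmax m:        n = -1.5
#>   argmax Delta C:  n = -1
#>   argmin KS (boundary power): n = -2 (grid boundary, non-peak)
#>   grid-step distances: |MI-dC| = 1, |MI-KS| = 1, |dC-KS| = 2
#>   lcc at MI peak = 1.000; percolation transition n in [2.5, 3.5]

## one subject, two standard deviations above the mean weight
net <- binarize(mats[[1]], computeThreshold(mats[[1]], 2))
net
#> ThresholdedNetwork: 60 nodes, 99 edges at w_t = 0.242486

v <- abs(weights(mats[[1]])[upper.tri(weights(mats[[1]]))])
fitBoundaryPower(v[v > wt(net)], wt(net))
#> DistributionFit 'boundary_power' on 99 values above w_t = 0.242486
#>   params: gamma = 10.7449
#>   logLik = 180.802, KS distance = 0.0724997
```

Reading the numbers: the mutual-information argmax, the transitivity-drop
argmax and the KS argmin are each located on the threshold grid, with
their mutual distances in grid steps; the percolation transition region
is where the ensemble-mean largest-component fraction falls between 0.95
and 0.05. The fitted gamma near the generator's exponent (10) on 99
surviving weights shows the boundary-power recovery at work. On this
homogeneous synthetic ensemble the information peak sits below the
percolation region — the vignette discusses why that co-location is a
property of real connectomes' heterogeneous weight geometry rather than
of the minimal generator.

`writeSweepTable(res, "sweep.csv")` serializes the per-subject and
ensemble rows with a fixed header; `plotCurves(res, "mi_vs_n", "mi.pdf")`
(and six sibling kinds) renders the curve families. A thin command-line
front end with `simulate`, `sweep`, `fit` and `report` subcommands lives
at `inst/scripts/critnet-cli.R`.

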