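# Synthetic connectome ensembles: boundary-power weight magnitudes on a
# clustered (Watts-Strogatz) strong-edge backbone, plus per-subject noise.
# Every downstream stage of the pipeline is testable against these without
# external data.

#' Sample from the boundary-power magnitude distribution
#'
#' Draws |w| magnitudes from p(|w|) = (gamma + 1) (1 - |w|)^gamma on
#' \[0, 1\], the bounded-support power law in the complement 1 - |w|,
#' via the inverse CDF x = 1 - (1 - u)^(1 / (gamma + 1)).
#'
#' @param gamma exponent, must exceed -1 for normalizability.
#' @param count number of draws.
#' @param seed optional integer seed; when given, draws are reproducible and
#'   the caller's RNG state is untouched.
#' @return numeric vector of magnitudes in \[0, 1).
#' @examples
#' mean(sampleBoundaryPower(0, 1e4, seed = 1)) # gamma = 0 is uniform
#' @export
sampleBoundaryPower <- function(gamma, count, seed = NULL) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= -1)
    stop("'gamma' must be a single number greater than -1")
  draw <- function() {
    u <- stats::runif(count)
    1 - (1 - u)^(1 / (gamma + 1))
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Sample from the exponentially truncated power law
#'
#' Draws from the density proportional to x^(alpha - 1) exp(-x / xc)
#' restricted to (lower, upper\], via the truncated-gamma inverse CDF.
#' Used as the comparator data generator when discriminating the two
#' distribution models.
#'
#' @param alpha power-law exponent; must be positive for this sampler.
#' @param xc exponential truncation scale, positive.
#' @param count number of draws.
#' @param lower,upper support bounds, 0 <= lower < upper.
#' @param seed optional integer seed.
#' @return numeric vector in (lower, upper\].
#' @export
sampleTruncatedPowerLaw <- function(alpha, xc, count, lower = 0, upper = 1,
                                    seed = NULL) {
  if (alpha <= 0) stop("this sampler requires alpha > 0")
  if (xc <= 0) stop("'xc' must be positive")
  if (lower < 0 || upper <= lower) stop("need 0 <= lower < upper")
  draw <- function() {
    flo <- stats::pgamma(lower, shape = alpha, scale = xc)
    fhi <- stats::pgamma(upper, shape = alpha, scale = xc)
    u <- flo + stats::runif(count) * (fhi - flo)
    stats::qgamma(u, shape = alpha, scale = xc)
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Construct an EnsembleSpec
#'
#' Defaults describe the study conditions used throughout: 20 subjects of
#' 100 regions, steep boundary-power weights (gamma = 10), a degree-6
#' ring-lattice backbone rewired with probability 0.1 (the classic
#' small-world regime), 90 percent of the top weight magnitudes routed to
#' backbone edges, and per-subject Gaussian weight noise of sd 0.02.
#'
#' @param nRegions,nSubjects,gamma,backboneDegree,rewireProb
#'   see [EnsembleSpec-class].
#' @param backboneQuantile,noiseSd,seed see [EnsembleSpec-class].
#' @return a validated [EnsembleSpec-class].
#' @export
ensembleSpec <- function(nRegions = 100, nSubjects = 20, gamma = 10,
                         backboneDegree = 6, rewireProb = 0.1,
                         backboneQuantile = 0.9, noiseSd = 0.02, seed = 1) {
  new("EnsembleSpec", nRegions = nRegions, nSubjects = nSubjects,
      gamma = gamma, backboneDegree = backboneDegree,
      rewireProb = rewireProb, backboneQuantile = backboneQuantile,
      noiseSd = noiseSd, seed = seed)
}

#' Generate a synthetic connectivity-matrix ensemble
#'
#' Builds one base matrix shared by the ensemble and perturbs it per
#' subject:
#' \enumerate{
#'   \item a ring lattice of degree `backboneDegree`, each edge rewired to a
#'     random non-neighbor with probability `rewireProb` (Watts-Strogatz),
#'     forms the strong-edge backbone;
#'   \item |w| magnitudes for all region pairs are drawn from the
#'     boundary-power law; a fraction `backboneQuantile` of the backbone
#'     edges receives the largest magnitudes, the displaced large
#'     magnitudes land on random non-backbone pairs, and the remaining
#'     magnitudes are spread over the remaining pairs;
#'   \item each pair gets an independent, equiprobable sign;
#'   \item each subject adds zero-mean Gaussian noise of sd `noiseSd` and
#'     entries are clamped to \[-1, 1\] (clamping events are reported).
#' }
#' Sweeping the threshold upward over such matrices first strips the weak
#' random edges, then fragments the clustered backbone, producing a
#' largest-component percolation transition and a transitivity
#' plateau-then-drop.
#'
#' @param spec an [EnsembleSpec-class].
#' @return list of [ConnectivityMatrix-class] objects, one per subject.
#' @examples
#' mats <- generateEnsemble(ensembleSpec(nRegions = 30, nSubjects = 2))
#' @export
generateEnsemble <- function(spec) {
  stopifnot(is(spec, "EnsembleSpec"))
  validObject(spec)
  N <- as.integer(spec@nRegions)
  k <- as.integer(spec@backboneDegree)
  M <- N * (N - 1L) / 2L

  base <- withSeed(deriveSeed(spec@seed, 1L), {
    g <- igraph::sample_smallworld(1, N, k / 2L, spec@rewireProb,
                                   loops = FALSE, multiple = FALSE)
    bbMask <- matrix(FALSE, N, N)
    el <- igraph::as_edgelist(g, names = FALSE)
    bbMask[el] <- TRUE
    bbMask <- bbMask | t(bbMask)

    ut <- which(upper.tri(bbMask))
    bb <- ut[bbMask[ut]]
    nb <- ut[!bbMask[ut]]
    nBB <- length(bb)

    mags <- sampleBoundaryPower(spec@gamma, M)
    ord <- order(mags, decreasing = TRUE)
    strong <- mags[ord[seq_len(nBB)]]
    weak <- mags[ord[-seq_len(nBB)]]

    nTop <- min(nBB, max(1L, round(spec@backboneQuantile * nBB)))
    bbStrong <- resample(bb, nTop)
    bbWeak <- setdiff(bb, bbStrong)
    nbStrong <- if (nTop < nBB) resample(nb, nBB - nTop) else integer(0)
    nbWeak <- setdiff(nb, nbStrong)

    w <- matrix(0, N, N)
    strongPerm <- resample(strong)
    w[bbStrong] <- strongPerm[seq_len(nTop)]
    if (length(nbStrong)) w[nbStrong] <- strongPerm[-seq_len(nTop)]
    weakPerm <- resample(weak)
    w[bbWeak] <- weakPerm[seq_along(bbWeak)]
    w[nbWeak] <- weakPerm[length(bbWeak) + seq_along(nbWeak)]

    w[ut] <- w[ut] * sample(c(-1, 1), M, replace = TRUE)
    w
  })

  mats <- vector("list", spec@nSubjects)
  clamped <- 0L
  for (s in seq_len(spec@nSubjects)) {
    ws <- withSeed(deriveSeed(spec@seed, 2L, s), {
      ut <- which(upper.tri(base))
      noise <- if (spec@noiseSd > 0)
        stats::rnorm(length(ut), 0, spec@noiseSd) else 0
      v <- base[ut] + noise
      nClamp <- sum(v > 1 | v < -1)
      v <- pmin(pmax(v, -1), 1)
      m <- matrix(0, N, N)
      m[ut] <- v
      attr(m, "nClamp") <- nClamp
      m
    })
    clamped <- clamped + attr(ws, "nClamp")
    attr(ws, "nClamp") <- NULL
    ws <- ws + t(ws)
    mats[[s]] <- ConnectivityMatrix(ws, subjectId = sprintf("sim%03d", s))
  }
  if (clamped > 0)
    message(sprintf("generateEnsemble: clamped %d noisy entries to [-1, 1]",
                    clamped))
  mats
}

#' Generate random ternary stimulus vectors
#'
#' Each entry is +1 with probability p, -1 with probability p, and 0
#' otherwise, independently across regions and trials (equal chance of
#' positive and negative activation).
#'
#' @param nRegions number of regions N.
#' @param p activation density, in (0, 0.5).
#' @param nTrials number of stimulus vectors.
#' @param seed integer seed; same seed, same stimuli.
#' @return integer matrix with `nRegions` rows and `nTrials` columns, one
#'   stimulus vector per column.
#' @export
generateSignals <- function(nRegions, p, nTrials, seed) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 0.5)
    stop("'p' must lie strictly between 0 and 0.5")
  stopifnot(nRegions >= 1, nTrials >= 1)
  withSeed(seed, {
    u <- stats::runif(nRegions * nTrials)
    s <- integer(nRegions * nTrials)
    s[u < p] <- 1L
    s[u >= p & u < 2 * p] <- -1L
    matrix(s, nrow = nRegions, ncol = nTrials)
  })
}
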