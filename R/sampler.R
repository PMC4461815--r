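#' Conditional distribution of one site given its interacting partners
#'
#' The single-site Gibbs conditional: for state s at the given site,
#' \deqn{P(s) \propto \exp\{-\beta \sum_{o} [U_o(s, A_{site+o}) + U_o(A_{site-o}, s)]\}}
#' where the sum runs over the spec's offsets and their negations with
#' cyclic wrapping. At beta = 0 the conditional is uniform over states.
#'
#' @param site integer (row, col), 1-based.
#' @param config H x W integer matrix of states.
#' @param spec a [TextureSetSpec-class].
#' @param beta inverse temperature, >= 0.
#' @return probability vector of length \code{nStates(spec)} summing to 1.
#' @export
conditionalDistribution <- function(site, config, spec, beta) {
  .checkConfig(config, spec)
  H <- nrow(config); W <- ncol(config)
  p <- site[1L]; q <- site[2L]
  if (p < 1L || p > H || q < 1L || q > W)
    stop("site out of range")
  ns <- spec@nStates
  e <- numeric(ns)
  for (i in seq_len(nrow(spec@offsets))) {
    dy <- spec@offsets[i, 1L]; dx <- spec@offsets[i, 2L]
    U <- spec@potentials[[i]]
    sp <- config[((p - 1L + dy) %% H) + 1L, ((q - 1L + dx) %% W) + 1L]
    sm <- config[((p - 1L - dy) %% H) + 1L, ((q - 1L - dx) %% W) + 1L]
    e <- e + U[, sp + 1L] + U[sm + 1L, ]
  }
  w <- exp(-beta * (e - min(e)))
  w / sum(w)
}

#' Partition lattice sites into non-interacting colour groups
#'
#' Returns the four-group parity partition -- sub-grids with (even, even),
#' (even, odd), (odd, even) and (odd, odd) 0-based coordinates, updated in
#' that fixed order -- whenever no offset (or its wrap-around on the given
#' lattice) connects two sites of the same group. Otherwise a valid
#' colouring is computed by greedy colouring of the offset-interaction
#' graph. In every returned partition no two sites of one group interact,
#' so each group can be resampled in parallel.
#'
#' @param spec a [TextureSetSpec-class].
#' @return H x W integer matrix of 1-based colour labels with attribute
#'   \code{scheme} ("parity" or "greedy").
#' @export
colorClasses <- function(spec) {
  H <- spec@latticeShape[1L]; W <- spec@latticeShape[2L]
  off <- spec@offsets
  for (i in seq_len(nrow(off))) {
    if (off[i, 1L] %% H == 0L && off[i, 2L] %% W == 0L)
      stop(sprintf("offset (%d,%d) wraps onto the site itself on a %d x %d lattice",
                   off[i, 1L], off[i, 2L], H, W))
  }
  p <- matrix(rep(0:(H - 1L), W), H, W)
  q <- matrix(rep(0:(W - 1L), each = H), H, W)
  parity <- 2L * (p %% 2L) + (q %% 2L) + 1L
  if (.validColoring(parity, off)) {
    attr(parity, "scheme") <- "parity"
    return(parity)
  }
  colors <- .greedyColoring(H, W, off)
  stopifnot(.validColoring(colors, off))
  attr(colors, "scheme") <- "greedy"
  colors
}

# TRUE when no offset connects two equal colours anywhere on the torus
.validColoring <- function(colors, off) {
  for (i in seq_len(nrow(off))) {
    shifted <- .shiftBy(colors, off[i, 1L], off[i, 2L])
    if (any(colors == shifted)) return(FALSE)
  }
  TRUE
}

# greedy graph colouring of the offset-interaction graph in raster order
.greedyColoring <- function(H, W, off) {
  n <- H * W
  # 0-based neighbour site indices (offsets and negations), column-major
  nbrs <- vector("list", n)
  pp <- rep(0:(H - 1L), W); qq <- rep(0:(W - 1L), each = H)
  idx <- function(p, q) (p %% H) + (q %% W) * H
  nb <- matrix(0L, n, 2L * nrow(off))
  for (i in seq_len(nrow(off))) {
    dy <- off[i, 1L]; dx <- off[i, 2L]
    nb[, 2L * i - 1L] <- idx(pp + dy, qq + dx)
    nb[, 2L * i] <- idx(pp - dy, qq - dx)
  }
  colors <- integer(n)  # 0 = unassigned
  for (s in seq_len(n)) {
    used <- colors[nb[s, ] + 1L]
    col <- 1L
    while (col %in% used) col <- col + 1L
    colors[s] <- col
  }
  matrix(colors, H, W)
}

# colour matrix -> list of 0-based site index vectors in group order
.groupIndices <- function(colors) {
  ord <- sort(unique(as.vector(colors)))
  lapply(ord, function(g) which(as.vector(colors) == g) - 1L)
}

#' One chromatic Gibbs sweep
#'
#' Updates every colour group once, in the fixed partition order; within a
#' group all sites are resampled simultaneously from
#' [conditionalDistribution()] evaluated against the pre-update state of the
#' other groups. Uses R's RNG stream (seed with \code{set.seed} for
#' reproducibility).
#'
#' @param config H x W integer matrix of states.
#' @param spec a [TextureSetSpec-class].
#' @param beta inverse temperature.
#' @param colors optional colour matrix from [colorClasses()] (recomputed if
#'   missing).
#' @return the updated configuration.
#' @export
gibbsSweep <- function(config, spec, beta, colors = NULL) {
  .checkConfig(config, spec)
  if (is.null(colors)) colors <- colorClasses(spec)
  out <- .gibbsChain(config, spec@offsets, spec@potentials, beta,
                     spec@nStates, .groupIndices(colors),
                     0L, 1L, 1L)
  attr(out, "final")
}

#' Sample equilibrium lattices from the Boltzmann distribution
#'
#' Initialises i.i.d. uniform from the seed, runs \code{burnIn} chromatic
#' Gibbs sweeps, then keeps every \code{thin}-th of \code{nSweeps} further
#' sweeps. Reproducible: the same seed yields an identical sample list.
#'
#' @param spec a [TextureSetSpec-class].
#' @param beta inverse temperature, >= 0.
#' @param nSamples number of lattices to return (equivalently
#'   \code{nSweeps = nSamples * thin}).
#' @param burnIn sweeps discarded before sampling; default 2000.
#' @param thin keep every thin-th sweep; default 5.
#' @param seed integer seed, or NULL to continue the current RNG stream.
#' @return list of H x W integer matrices.
#' @export
sampleTexture <- function(spec, beta, nSamples, burnIn = 2000L, thin = 5L,
                          seed = NULL) {
  stopifnot(beta >= 0, nSamples >= 0, burnIn >= 0, thin >= 1)
  validateTextureSet(spec)
  if (!is.null(seed)) set.seed(seed)
  H <- spec@latticeShape[1L]; W <- spec@latticeShape[2L]
  init <- matrix(sample.int(spec@nStates, H * W, replace = TRUE) - 1L, H, W)
  colors <- colorClasses(spec)
  keep <- .gibbsChain(init, spec@offsets, spec@potentials, beta,
                      spec@nStates, .groupIndices(colors),
                      as.integer(burnIn), as.integer(nSamples * thin),
                      as.integer(thin))
  lapply(seq_len(nrow(keep)), function(i) matrix(keep[i, ], H, W))
}

# flat sample matrix (n x H*W) version used by the simulation loops
.sampleTextureFlat <- function(spec, beta, nSamples, burnIn = 2000L,
                               thin = 5L, seed = NULL) {
  stopifnot(beta >= 0, nSamples >= 0, burnIn >= 0, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  H <- spec@latticeShape[1L]; W <- spec@latticeShape[2L]
  init <- matrix(sample.int(spec@nStates, H * W, replace = TRUE) - 1L, H, W)
  colors <- colorClasses(spec)
  .gibbsChain(init, spec@offsets, spec@potentials, beta, spec@nStates,
              .groupIndices(colors), as.integer(burnIn),
              as.integer(nSamples * thin), as.integer(thin))
}

#' Exact Boltzmann distribution on a tiny lattice
#'
#' Enumerates all \code{nStates^(H*W)} configurations, computing
#' \eqn{P(I) = \exp(-\beta U(I)) / Z} with the partition function
#' \eqn{Z = \sum_I \exp(-\beta U(I))}. Intended as an exact oracle for the
#' Gibbs sampler; refuses lattices with more than \code{maxConfigs}
#' configurations.
#'
#' @param spec a [TextureSetSpec-class] with a tiny lattice.
#' @param beta inverse temperature.
#' @param maxConfigs enumeration cap (default 1e6).
#' @return list with \code{states} (nConfig x H*W matrix, column-major
#'   flattening; row i is configuration id i under the mixed-radix code
#'   \code{1 + sum(s_j * nStates^(j-1))}), \code{energy}, \code{prob} and
#'   \code{logZ}.
#' @export
enumerateBoltzmann <- function(spec, beta, maxConfigs = 1e6) {
  validateTextureSet(spec)
  H <- spec@latticeShape[1L]; W <- spec@latticeShape[2L]
  n <- H * W; ns <- spec@nStates
  if (ns^n > maxConfigs)
    stop(sprintf("lattice too large to enumerate: %d^%d configurations", ns, n))
  states <- as.matrix(expand.grid(rep(list(0:(ns - 1L)), n),
                                  KEEP.OUT.ATTRS = FALSE))
  dimnames(states) <- NULL
  storage.mode(states) <- "integer"
  # column-major site order: site j at (row, col) = ((j-1) %% H, (j-1) %/% H)
  pp <- (seq_len(n) - 1L) %% H
  qq <- (seq_len(n) - 1L) %/% H
  energy <- numeric(nrow(states))
  for (i in seq_len(nrow(spec@offsets))) {
    dy <- spec@offsets[i, 1L]; dx <- spec@offsets[i, 2L]
    U <- spec@potentials[[i]]
    partner <- ((pp + dy) %% H) + ((qq + dx) %% W) * H + 1L
    for (j in seq_len(n))
      energy <- energy + U[cbind(states[, j] + 1L, states[, partner[j]] + 1L)]
  }
  lw <- -beta * energy
  m <- max(lw)
  logZ <- m + log(sum(exp(lw - m)))
  list(states = states, energy = energy, prob = exp(lw - logZ), logZ = logZ)
}

# mixed-radix configuration ids (1-based) for flat sample rows, matching the
# row order of enumerateBoltzmann()$states
.configIds <- function(flat, nStates) {
  radix <- nStates^(seq_len(ncol(flat)) - 1L)
  as.vector(flat %*% radix) + 1
}

#' Generate a distractor lattice
#'
#' "uniform": i.i.d. uniform states (the distractor distribution of the
#' standard experiments). "permuted": a uniformly random rearrangement of
#' the target's entries, which preserves the marginal amplitude counts
#' exactly (and hence the luminance distribution) while destroying the
#' geometric relationships between amplitudes.
#'
#' @param spec a [TextureSetSpec-class].
#' @param mode "uniform" or "permuted".
#' @param target required for "permuted": the target configuration.
#' @return H x W integer matrix.
#' @export
makeDistractor <- function(spec, mode = c("uniform", "permuted"),
                           target = NULL) {
  mode <- match.arg(mode)
  H <- spec@latticeShape[1L]; W <- spec@latticeShape[2L]
  if (mode == "uniform") {
    matrix(sample.int(spec@nStates, H * W, replace = TRUE) - 1L, H, W)
  } else {
    if (is.null(target))
      stop("permuted mode requires a target configuration")
    .checkConfig(target, spec)
    matrix(sample(as.vector(target)), H, W)
  }
}

#' Chi-squared goodness of fit of sampled configurations to exact
#' probabilities
#'
#' Pearson chi-squared test of observed configuration counts against a
#' vector of exact cell probabilities. Cells with expected count below
#' \code{minExpected} are pooled (smallest first) into a single cell so the
#' asymptotic reference distribution is trustworthy.
#'
#' @param observed integer vector of per-cell counts.
#' @param prob exact cell probabilities (same length, summing to 1).
#' @param minExpected pooling threshold (default 5).
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{nPooled}.
#' @export
gofChisq <- function(observed, prob, minExpected = 5) {
  stopifnot(length(observed) == length(prob))
  n <- sum(observed)
  expected <- n * prob
  ord <- order(expected)
  # pool the smallest cells until every remaining cell (and the pooled cell
  # itself) has expected count >= minExpected
  npool <- 0L
  if (any(expected < minExpected)) {
    csum <- cumsum(expected[ord])
    npool <- max(which(expected[ord] < minExpected))
    while (npool < length(ord) && csum[npool] < minExpected)
      npool <- npool + 1L
  }
  if (npool > 0L) {
    low <- ord[seq_len(npool)]
    obs <- c(observed[-low], sum(observed[low]))
    exp_ <- c(expected[-low], sum(expected[low]))
  } else {
    obs <- observed
    exp_ <- expected
  }
  stat <- sum((obs - exp_)^2 / exp_)
  df <- length(obs) - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       nPooled = npool)
}
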