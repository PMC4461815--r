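# ---- statistic primitives ---------------------------------------------

# per-state blob counts of a configuration (vector of length nStates)
.lumCounts <- function(config, nStates) {
  tabulate(as.vector(config) + 1L, nbins = nStates)
}

# flattened joint-state contingencies, one nStates^2 block per offset.
# Within a block the (s, t) cell -- site state s, partner state t at the
# offset -- sits at index s + nStates * t + 1 (column-major over (s, t)).
.pairCounts <- function(config, spec) {
  ns <- spec@nStates
  out <- numeric(0L)
  for (i in seq_len(nrow(spec@offsets))) {
    Ashift <- .shiftBy(config, spec@offsets[i, 1L], spec@offsets[i, 2L])
    code <- as.vector(config) + ns * as.vector(Ashift) + 1L
    out <- c(out, tabulate(code, nbins = ns * ns))
  }
  out
}

#' Luminance statistic of a lattice
#'
#' The 3-dimensional (generally nStates-dimensional) vector of per-state
#' blob counts. Invariant under any spatial rearrangement of the blobs, so
#' a permuted distractor has exactly the target's statistic.
#'
#' @param config H x W integer matrix of states.
#' @param nStates number of amplitude levels (default 3).
#' @return a [QuadrantStatistic-class] of kind "luminance".
#' @export
luminanceStatistic <- function(config, nStates = 3L) {
  v <- .lumCounts(config, nStates)
  new("QuadrantStatistic", kind = "luminance", values = as.numeric(v),
      nStates = as.integer(nStates), nSites = length(config))
}

#' Pair (sufficient) statistic of a lattice
#'
#' For each interacting offset, the 3 x 3 contingency of joint states over
#' all sites with cyclic wrapping, flattened column-major; the full vector
#' has 9 entries per offset and each offset's counts sum to H*W. This is
#' the sufficient statistic of the Boltzmann model: the energy is the
#' linear functional \eqn{U(I) = \sum_o \langle counts_o, U_o \rangle}.
#'
#' @param config H x W integer matrix of states.
#' @param spec a [TextureSetSpec-class].
#' @return a [QuadrantStatistic-class] of kind "pair".
#' @export
pairStatistic <- function(config, spec) {
  .checkConfig(config, spec)
  new("QuadrantStatistic", kind = "pair",
      values = .pairCounts(config, spec),
      nStates = spec@nStates, nSites = length(config))
}

# ---- Gabor channel energy ---------------------------------------------

#' Construct a Gabor quadrature-pair specification
#'
#' @param sigma envelope width, degrees.
#' @param freq spatial frequency, cycles/degree.
#' @param theta orientation, degrees in [0, 180).
#' @param pixelScale pixels per degree (default 120).
#' @return a [GaborSpec-class].
#' @export
gaborSpec <- function(sigma, freq, theta, pixelScale = 120) {
  new("GaborSpec", sigma = sigma, freq = freq, theta = theta,
      pixelScale = pixelScale)
}

#' Gabor filter parameters used with the builtin texture sets
#'
#' A small table of quadrature-pair parameters (sigma in degrees, frequency
#' in cycles/degree, orientation in degrees) appropriate for blob grids at
#' the default rendering geometry, one row per builtin set.
#'
#' @param pixelScale pixels per degree for sampling the filters.
#' @param blobSpacing blob grid spacing in degrees (sets the pattern
#'   fundamentals the filters are tuned to).
#' @return named list of [GaborSpec-class] objects.
#' @export
builtinGabors <- function(pixelScale = 120, blobSpacing = 4.84 / 32) {
  f0 <- 1 / blobSpacing             # blob-grid frequency
  list(
    # ordered potts state is a uniform blob field: tune to the blob grid
    potts = gaborSpec(0.085, f0, 45, pixelScale),
    # checkerboard fundamental: diagonal, sqrt(2)/(2 * spacing)
    checkerboard = gaborSpec(0.085, sqrt(2) / 2 * f0, 45, pixelScale),
    # horizontal stripes of period 2 rows: vertical variation
    stripe = gaborSpec(0.085, f0 / 2, 90, pixelScale)
  )
}

#' Sampled quadrature-pair Gabor kernels
#'
#' Kernels are sampled at \code{pixelScale} and truncated at +/- 3 sigma.
#' The odd (sine) kernel is antisymmetric on the symmetric grid, so its DC
#' response is exactly zero by construction.
#'
#' @param gabor a [GaborSpec-class].
#' @return list with matrices \code{even} and \code{odd}.
#' @export
gaborKernels <- function(gabor) {
  ps <- gabor@pixelScale
  h <- ceiling(3 * gabor@sigma * ps)
  px <- (-h):h
  x <- matrix(rep(px, each = length(px)), length(px)) / ps  # columns
  y <- matrix(rep(px, length(px)), length(px)) / ps         # rows
  env <- exp(-(x^2 + y^2) / (2 * gabor@sigma^2))
  th <- gabor@theta * pi / 180
  phase <- 2 * pi * gabor@freq * (x * cos(th) + y * sin(th))
  list(even = env * cos(phase), odd = env * sin(phase))
}

# FFT of the complex kernel (even + 1i*odd) zero-padded to P1 x P2,
# memoised per (padded size, gabor parameters)
.kernelFFT <- function(gabor, P1, P2) {
  key <- sprintf("kfft:%g:%g:%g:%g:%d:%d", gabor@sigma, gabor@freq,
                 gabor@theta, gabor@pixelScale, P1, P2)
  hit <- .cacheGet(key)
  if (!is.null(hit)) return(hit)
  k <- gaborKernels(gabor)
  K <- matrix(0 + 0i, P1, P2)
  K[seq_len(nrow(k$even)), seq_len(ncol(k$even))] <- k$even + 1i * k$odd
  .cacheSet(key, list(fft = stats::fft(K), half = (nrow(k$even) - 1L) %/% 2L))
}

#' Channel energy map of an image
#'
#' \deqn{M = (I * G_{odd})^2 + (I * G_{even})^2}
#' where * is convolution with the quadrature pair of [gaborKernels()].
#' Computed by FFT with zero padding at the borders; the returned map has
#' the image's size and is everywhere >= 0.
#'
#' @param image 2-D numeric luminance array, larger than the truncated
#'   kernel.
#' @param gabor a [GaborSpec-class].
#' @return numeric matrix M, same size as \code{image}.
#' @export
channelEnergyMap <- function(image, gabor) {
  stopifnot(is.matrix(image))
  k <- gaborKernels(gabor)
  if (nrow(image) < nrow(k$even) || ncol(image) < ncol(k$even))
    stop("image smaller than the truncated Gabor kernel")
  P1 <- stats::nextn(nrow(image) + nrow(k$even) - 1L, c(2, 3, 5))
  P2 <- stats::nextn(ncol(image) + ncol(k$even) - 1L, c(2, 3, 5))
  kf <- .kernelFFT(gabor, P1, P2)
  Ipad <- matrix(0, P1, P2)
  Ipad[seq_len(nrow(image)), seq_len(ncol(image))] <- image
  C <- stats::fft(stats::fft(Ipad) * kf$fft, inverse = TRUE) / (P1 * P2)
  h <- kf$half
  rows <- h + seq_len(nrow(image))
  cols <- h + seq_len(ncol(image))
  Re(C[rows, cols])^2 + Im(C[rows, cols])^2
}

#' Integrated channel energy of one display quadrant
#'
#' Sum of the channel energy map over a quadrant. By default the map is
#' computed on the quadrant's own sub-image independently (zero padding at
#' its borders), which removes cross-border contamination between
#' quadrants; \code{composed = TRUE} instead computes the map on the whole
#' display and sums the quadrant's pixels.
#'
#' @param display 2-D luminance image (composed display, or a single
#'   texture when \code{quadrant} covers it).
#' @param quadrant 1 = top-left, 2 = top-right, 3 = bottom-left,
#'   4 = bottom-right.
#' @param gabor a [GaborSpec-class].
#' @param composed compute the map on the composed display (default FALSE).
#' @return scalar energy >= 0.
#' @export
quadrantEnergy <- function(display, quadrant, gabor, composed = FALSE) {
  if (!quadrant %in% 1:4) stop("quadrant must be in 1..4")
  hr <- nrow(display) %/% 2L
  hc <- ncol(display) %/% 2L
  rows <- if (quadrant %in% c(1L, 2L)) seq_len(hr) else hr + seq_len(nrow(display) - hr)
  cols <- if (quadrant %in% c(1L, 3L)) seq_len(hc) else hc + seq_len(ncol(display) - hc)
  if (composed) {
    M <- channelEnergyMap(display, gabor)
    sum(M[rows, cols])
  } else {
    sum(channelEnergyMap(display[rows, cols, drop = FALSE], gabor))
  }
}

# total channel energy of a single texture image (the per-quadrant decision
# variable when quadrant maps are computed independently)
.textureEnergy <- function(image, gabor) {
  sum(channelEnergyMap(image, gabor))
}

# ---- density models and decision rules --------------------------------

#' Fit a density model to statistic samples
#'
#' "kde": product-Gaussian-kernel density with per-dimension bandwidths.
#' The default bandwidth rule is Scott's multivariate rule-of-thumb
#' \eqn{h_j = s_j n^{-1/(d+4)}}; \code{bw = "oversmooth"} instead uses the
#' deliberately wide \eqn{h_j = 2 s_j}, appropriate when the fitted
#' densities feed a likelihood-ratio decision over high-dimensional count
#' statistics: in the smooth limit the product-kernel log ratio converges
#' to the correct (mean-difference) discriminant instead of being dominated
#' by nearest-sample noise. "gaussian": diagonal-covariance moment fit. A
#' zero-variance dimension has its bandwidth (or sd) floored at a small
#' positive epsilon, with a warning.
#'
#' @param x numeric vector (1-D) or n x d matrix of statistic samples.
#' @param kind "kde" or "gaussian".
#' @param bw "scott", "oversmooth", or a numeric vector of per-dimension
#'   bandwidths (KDE only; in whitened units when \code{whiten = TRUE}).
#' @param whiten pre-whiten by the sample covariance (KDE only), so the
#'   kernel respects the correlations between dimensions; near-degenerate
#'   covariance eigenvalues are floored.
#' @param epsilon floor for degenerate dimensions (default 1e-6).
#' @return a [DensityModel-class].
#' @export
fitDensity <- function(x, kind = c("kde", "gaussian"), bw = "scott",
                       whiten = FALSE, epsilon = 1e-6) {
  kind <- match.arg(kind)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(x))) stop("samples must be finite")
  d <- ncol(x)
  n <- nrow(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance dimension(s); bandwidth floored at %g",
                    sum(sds == 0), epsilon))
    sds[sds == 0] <- epsilon
  }
  if (kind == "gaussian") {
    return(new("DensityModel", kind = "gaussian", samples = matrix(0, 0L, d),
               bandwidths = numeric(0L), mean = colMeans(x), sd = sds,
               whiten = matrix(0, 0L, 0L), center = numeric(0L),
               logJac = 0, trainingN = n, dims = d))
  }
  Wm <- matrix(0, 0L, 0L)
  center <- numeric(0L)
  logJac <- 0
  kdeSds <- sds
  if (whiten) {
    center <- colMeans(x)
    xc <- sweep(x, 2L, center)
    eg <- eigen(crossprod(xc) / (n - 1), symmetric = TRUE)
    lam <- pmax(eg$values, epsilon * max(eg$values, epsilon))
    Wm <- eg$vectors %*% diag(1 / sqrt(lam), d)
    logJac <- -0.5 * sum(log(lam))
    x <- xc %*% Wm
    kdeSds <- rep(1, d)  # unit variance by construction
  }
  h <- if (is.numeric(bw)) {
    rep_len(bw, d)
  } else if (identical(bw, "oversmooth")) {
    2 * kdeSds
  } else {
    kdeSds * n^(-1 / (d + 4))
  }
  if (any(h <= 0)) stop("bandwidths must be positive")
  new("DensityModel", kind = "kde", samples = x, bandwidths = h,
      mean = numeric(0L), sd = numeric(0L),
      whiten = Wm, center = center, logJac = logJac,
      trainingN = n, dims = d)
}

#' Log density of a fitted model at one or more points
#'
#' KDE evaluation uses a numerically safe log-sum-exp over training
#' samples, so heavily underflowing points still return finite values where
#' possible.
#'
#' @param model a [DensityModel-class].
#' @param x numeric vector (one point) or m x d matrix of points.
#' @return numeric vector of log densities.
#' @export
logDensity <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = model@dims)
  if (ncol(x) != model@dims)
    stop(sprintf("points have %d dims; model expects %d", ncol(x), model@dims))
  m <- nrow(x)
  if (model@kind == "gaussian") {
    L <- matrix(stats::dnorm(x, rep(model@mean, each = m),
                             rep(model@sd, each = m), log = TRUE), m)
    return(rowSums(L))
  }
  if (nrow(model@whiten) > 0L)
    x <- sweep(x, 2L, model@center) %*% model@whiten
  n <- model@trainingN
  h <- model@bandwidths
  # L[i, j] = sum over dims of log K_h(x_i - X_j)
  L <- matrix(0, m, n)
  for (j in seq_len(model@dims)) {
    D <- outer(x[, j], model@samples[, j], "-") / h[j]
    L <- L - 0.5 * D * D
  }
  L <- L - sum(log(h)) - model@dims * 0.5 * log(2 * pi)
  mx <- apply(L, 1L, max)
  mx + log(rowSums(exp(L - mx))) - log(n) + model@logJac
}

#' Evaluate a fitted density
#'
#' @param model a [DensityModel-class].
#' @param x point or m x d matrix of points.
#' @return density values, >= 0.
#' @export
evalDensity <- function(model, x) exp(logDensity(model, x))

#' Maximum-likelihood 4AFC decision
#'
#' Given the four per-quadrant statistics, chooses the quadrant q
#' maximising \eqn{f_t(s_q) \prod_{q' \ne q} f_d(s_{q'})}, equivalently the
#' quadrant with the largest per-quadrant log likelihood ratio
#' \eqn{\log f_t(s_q) - \log f_d(s_q)}. Ties (including the fully
#' uninformative case where all ratios are equal or undefined) are broken
#' uniformly at random.
#'
#' @param stats 4 x d matrix of statistics (one row per quadrant), or a
#'   list of 4 [QuadrantStatistic-class] objects of one kind.
#' @param targetDensity,distractorDensity fitted [DensityModel-class]s.
#' @return chosen quadrant index in 1..4.
#' @export
decide4AFC <- function(stats, targetDensity, distractorDensity) {
  if (is.list(stats)) {
    kinds <- vapply(stats, function(s) s@kind, character(1L))
    if (length(unique(kinds)) != 1L)
      stop("all four statistics must have the same kind")
    stats <- do.call(rbind, lapply(stats, function(s) s@values))
  }
  if (nrow(stats) != 4L) stop("need exactly 4 quadrant statistics")
  sc <- logDensity(targetDensity, stats) - logDensity(distractorDensity, stats)
  .argmaxTie(sc)
}

# argmax with uniform tie-breaking; NaN/-Inf scores never win unless all
# scores are uninformative, in which case the choice is uniform
.argmaxTie <- function(sc) {
  sc[is.nan(sc)] <- -Inf
  mx <- max(sc)
  if (!is.finite(mx)) return(sample.int(length(sc), 1L))
  tol <- 1e-9 * max(1, abs(mx))
  cand <- which(sc >= mx - tol)
  if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
}

#' Exact maximum-likelihood (minimum-energy) 4AFC rule
#'
#' For targets drawn at inverse temperature beta > 0 and i.i.d. uniform
#' distractors, the log likelihood ratio of any configuration is
#' \eqn{-\beta U(I) + const}, so the exact maximum-likelihood choice is the
#' quadrant with minimal energy. At beta = 0 the target and distractor
#' distributions coincide and the rule is undefined: NA is returned with a
#' warning and the caller must fall back to chance.
#'
#' @param configs list of 4 lattice configurations (quadrant order).
#' @param spec a [TextureSetSpec-class].
#' @param beta inverse temperature of the target distribution.
#' @return chosen quadrant in 1..4, or NA when beta = 0.
#' @export
analyticIdealDecide <- function(configs, spec, beta) {
  if (beta <= 0) {
    warning("analytic ideal rule undefined at beta = 0 (distributions identical)")
    return(NA_integer_)
  }
  e <- vapply(configs, latticeEnergy, numeric(1L), spec = spec)
  .argmaxTie(-e)
}
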