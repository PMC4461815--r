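setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' TextureSetSpec: interaction rules defining a texture set
#'
#' A texture set is a shift-invariant pairwise Markov random field on a
#' cyclic H x W lattice of \code{nStates}-valued amplitude indices. Each
#' interacting pair is given by a displacement offset (dy, dx) together with
#' an \code{nStates} x \code{nStates} potential matrix; the global energy of
#' a lattice configuration is the sum of potentials over all sites and
#' offsets. Offsets never contain both a displacement and its negation, so
#' each unordered pair is counted exactly once.
#'
#' @slot name identifier for the set.
#' @slot nStates number of amplitude levels (3 in the canonical sets).
#' @slot offsets integer matrix with columns (dy, dx), one row per
#'   interacting pair; 0-based displacements, row increasing downward.
#' @slot potentials list of \code{nStates} x \code{nStates} numeric matrices
#'   (dimensionless energies), one per offset row. Entry \code{[s+1, t+1]}
#'   is the energy of a site in state \code{s} whose partner at the offset
#'   is in state \code{t}.
#' @slot latticeShape integer (H, W).
#' @slot betaGrid strictly increasing non-negative inverse temperatures at
#'   which the set is typically sampled.
#' @slot groundStateTile optional small periodic matrix of state indices
#'   whose tiling is the canonical minimum-energy pattern, or NULL.
#'
#' @seealso [textureSetSpec()], [builtinSpecs()], [latticeEnergy()]
#' @export
setClass("TextureSetSpec",
  representation(
    name = "character",
    nStates = "integer",
    offsets = "matrix",
    potentials = "list",
    latticeShape = "integer",
    betaGrid = "numeric",
    groundStateTile = "matrixOrNULL"
  )
)

setValidity("TextureSetSpec", function(object) {
  ns <- object@nStates
  if (length(ns) != 1L || is.na(ns) || ns < 2L)
    return("nStates must be a single integer >= 2")
  off <- object@offsets
  if (!is.numeric(off) || ncol(off) != 2L)
    return("offsets must be a matrix with columns (dy, dx)")
  if (nrow(off) < 1L)
    return("at least one offset is required")
  if (any(off != round(off)))
    return("offsets must be integer displacements")
  for (i in seq_len(nrow(off))) {
    if (all(off[i, ] == 0L))
      return("offset (0,0) is not allowed")
  }
  key <- paste(off[, 1L], off[, 2L])
  negkey <- paste(-off[, 1L], -off[, 2L])
  if (anyDuplicated(key))
    return("duplicate offset present")
  if (any(negkey %in% key))
    return("offset and its negation both present (each unordered pair is counted once)")
  if (length(object@potentials) != nrow(off))
    return("need exactly one potential matrix per offset")
  for (i in seq_along(object@potentials)) {
    U <- object@potentials[[i]]
    if (!is.matrix(U) || !identical(dim(U), c(ns, ns)) &&
        !identical(dim(U), as.integer(c(ns, ns))))
      return(sprintf("potential %d must be a %d x %d matrix", i, ns, ns))
    if (!all(is.finite(U)))
      return(sprintf("potential %d contains non-finite values", i))
  }
  sh <- object@latticeShape
  if (length(sh) != 2L || any(is.na(sh)) || any(sh < 1L))
    return("latticeShape must be two positive integers (H, W)")
  bg <- object@betaGrid
  if (length(bg)) {
    if (any(bg < 0))
      return("betaGrid values must be >= 0")
    if (length(bg) > 1L && any(diff(bg) <= 0))
      return("betaGrid must be strictly increasing")
  }
  tile <- object@groundStateTile
  if (!is.null(tile)) {
    if (any(tile != round(tile)) || any(tile < 0) || any(tile >= ns))
      return("groundStateTile entries must be state indices in [0, nStates)")
    if (sh[1L] %% nrow(tile) != 0L || sh[2L] %% ncol(tile) != 0L)
      return("groundStateTile dimensions must divide the lattice shape")
  }
  TRUE
})

#' OrderStatistic: order parameter of a lattice configuration
#'
#' The order parameter is the mean of an order field: a per-site measure in
#' [0, 1] of how consistent the site's interacting pairs are with the global
#' symmetry of the set's ground states. It equals 1 exactly on ground-state
#' configurations and approaches a set-specific baseline on i.i.d. uniform
#' lattices.
#'
#' @slot value mean of the field, in [0, 1].
#' @slot baseline expected value under i.i.d. uniform states.
#' @slot baselineSE Monte Carlo standard error of the baseline (0 when the
#'   baseline is analytic).
#' @slot field H x W matrix of local conformance values in [0, 1].
#' @seealso [orderParameter()], [conformanceField()]
#' @export
setClass("OrderStatistic",
  representation(value = "numeric", baseline = "numeric",
                 baselineSE = "numeric", field = "matrix")
)

setValidity("OrderStatistic", function(object) {
  if (length(object@value) != 1L || object@value < -1e-9 || object@value > 1 + 1e-9)
    return("value must be a scalar in [0, 1]")
  if (abs(object@value - mean(object@field)) > 1e-8)
    return("value must equal the mean of the field")
  if (any(object@field < -1e-9 | object@field > 1 + 1e-9))
    return("field entries must lie in [0, 1]")
  TRUE
})

#' QuadrantStatistic: an observer's per-quadrant decision statistic
#'
#' @slot kind one of "luminance" (3-vector of per-state blob counts),
#'   "pair" (9 counts per interacting offset, a flattened 3 x 3 joint-state
#'   contingency), "order" (scalar order parameter) or "channel_energy"
#'   (scalar integrated Gabor energy).
#' @slot values numeric vector of the statistic.
#' @slot nStates number of amplitude states (count statistics only).
#' @slot nSites number of lattice sites (count statistics only).
#' @seealso [luminanceStatistic()], [pairStatistic()]
#' @export
setClass("QuadrantStatistic",
  representation(kind = "character", values = "numeric",
                 nStates = "integer", nSites = "integer")
)

setValidity("QuadrantStatistic", function(object) {
  k <- object@kind
  if (!k %in% c("luminance", "pair", "order", "channel_energy"))
    return("unknown statistic kind")
  v <- object@values
  if (k == "luminance") {
    if (any(v < 0)) return("luminance counts must be >= 0")
    if (length(object@nSites) == 1L && abs(sum(v) - object@nSites) > 1e-8)
      return("luminance counts must sum to the number of sites")
  }
  if (k == "pair") {
    if (any(v < 0)) return("pair counts must be >= 0")
    d <- object@nStates^2
    if (length(v) %% d != 0L)
      return("pair statistic length must be a multiple of nStates^2")
    if (length(object@nSites) == 1L) {
      per <- matrix(v, nrow = d)
      if (any(abs(colSums(per) - object@nSites) > 1e-8))
        return("pair counts must sum to the number of sites per offset")
    }
  }
  if (k %in% c("order", "channel_energy") && length(v) != 1L)
    return(sprintf("%s statistic must be scalar", k))
  TRUE
})

#' DensityModel: fitted density for an observer statistic
#'
#' Either a product-Gaussian-kernel KDE (per-dimension rule-of-thumb
#' bandwidths) or a diagonal Gaussian moment fit.
#'
#' @slot kind "kde" or "gaussian".
#' @slot samples training sample matrix (KDE only; stored in whitened
#'   coordinates when a whitening transform is present).
#' @slot bandwidths per-dimension kernel bandwidths (KDE only; whitened
#'   units when whitening is on).
#' @slot mean,sd per-dimension moments (Gaussian only).
#' @slot whiten d x d whitening transform (0 x 0 when not used); evaluation
#'   points x are mapped to \code{(x - center) \%*\% whiten}.
#' @slot center centring vector for the whitening transform.
#' @slot logJac log-Jacobian of the whitening transform (added to log
#'   densities so they remain proper in the original coordinates).
#' @slot trainingN number of training samples.
#' @slot dims dimensionality of the support.
#' @seealso [fitDensity()], [logDensity()]
#' @export
setClass("DensityModel",
  representation(kind = "character", samples = "matrix",
                 bandwidths = "numeric", mean = "numeric", sd = "numeric",
                 whiten = "matrix", center = "numeric", logJac = "numeric",
                 trainingN = "integer", dims = "integer")
)

setValidity("DensityModel", function(object) {
  if (!object@kind %in% c("kde", "gaussian")) return("kind must be kde or gaussian")
  if (object@kind == "kde") {
    if (ncol(object@samples) != object@dims) return("sample dims mismatch")
    if (length(object@bandwidths) != object@dims) return("bandwidth dims mismatch")
    if (any(object@bandwidths <= 0)) return("bandwidths must be positive")
    if (nrow(object@whiten) > 0L &&
        (nrow(object@whiten) != object@dims ||
         length(object@center) != object@dims))
      return("whitening transform dims mismatch")
  } else {
    if (length(object@mean) != object@dims || length(object@sd) != object@dims)
      return("moment dims mismatch")
    if (any(object@sd <= 0)) return("sd must be positive")
  }
  TRUE
})

#' GaborSpec: quadrature-pair Gabor filter parameters
#'
#' The even and odd filters are
#' \deqn{G_{even}(x,y) = e^{-(x^2+y^2)/2\sigma^2} \cos(2\pi f (x\cos\theta + y\sin\theta))}
#' and the sine analogue; the channel energy map is
#' \eqn{M = (I * G_{odd})^2 + (I * G_{even})^2}.
#'
#' @slot sigma envelope width in degrees of visual angle.
#' @slot theta orientation in degrees, in [0, 180).
#' @slot freq spatial frequency in cycles/degree.
#' @slot pixelScale pixels per degree used to sample the filter.
#' @seealso [gaborSpec()], [channelEnergyMap()]
#' @export
setClass("GaborSpec",
  representation(sigma = "numeric", theta = "numeric", freq = "numeric",
                 pixelScale = "numeric")
)

setValidity("GaborSpec", function(object) {
  if (object@sigma <= 0) return("sigma must be > 0")
  if (object@freq <= 0) return("freq must be > 0")
  if (object@theta < 0 || object@theta >= 180) return("theta must be in [0, 180)")
  if (object@pixelScale <= 0) return("pixelScale must be > 0")
  TRUE
})

#' RenderSpec: geometry and luminance mapping for stimulus rendering
#'
#' Lattice configurations are rendered as grids of circularly symmetric
#' Gaussian blobs added to a uniform background. Defaults follow the
#' constant-stimuli experimental geometry: blob sigma 1.5 arcmin, quadrant
#' images 4.84 degrees across (32 blobs), amplitudes (26, 56, 91) cd/m^2 on
#' a 14 cd/m^2 background, normalised by 100 cd/m^2.
#'
#' @slot blobSigma blob Gaussian sigma, degrees (default 1.5/60).
#' @slot blobSpacing distance between blob grid centres, degrees.
#' @slot amplitudeMap strictly increasing peak added luminances for states
#'   0, 1, 2 (normalised units).
#' @slot background background luminance (normalised units).
#' @slot pixelScale pixels per degree.
#' @slot layout "attached" (quadrants abut, forming one 64 x 64 blob grid)
#'   or "gapped" (quadrant centres at an eccentricity from fixation).
#' @slot eccentricity centre-to-fixation distance for the gapped layout,
#'   degrees.
#' @seealso [renderSpec()], [renderTexture()], [composeDisplay()]
#' @export
setClass("RenderSpec",
  representation(blobSigma = "numeric", blobSpacing = "numeric",
                 amplitudeMap = "numeric", background = "numeric",
                 pixelScale = "numeric", layout = "character",
                 eccentricity = "numeric")
)

setValidity("RenderSpec", function(object) {
  if (object@blobSigma <= 0 || object@blobSpacing <= 0 || object@pixelScale <= 0)
    return("blobSigma, blobSpacing and pixelScale must be positive")
  if (any(diff(object@amplitudeMap) <= 0))
    return("amplitudeMap must be strictly increasing")
  if (any(object@amplitudeMap <= 0))
    return("amplitudeMap must be positive")
  if (object@pixelScale * object@blobSigma < 2)
    return("pixelScale too coarse: blob sigma must span >= 2 pixels")
  if (!object@layout %in% c("attached", "gapped"))
    return("layout must be 'attached' or 'gapped'")
  TRUE
})

#' PsychometricCurve: proportion correct vs inverse temperature
#'
#' @slot betaGrid increasing inverse temperatures.
#' @slot pCorrect proportion of correct 4AFC responses per beta.
#' @slot nTrials trials per beta (pCorrect * nTrials is integral).
#' @slot se binomial standard errors per beta.
#' @slot observerId observer identifier.
#' @slot mode "uniform_distractor" or "permuted_distractor".
#' @seealso [performanceCurve()], [estimateThreshold()], [chi2Compare()]
#' @export
setClass("PsychometricCurve",
  representation(betaGrid = "numeric", pCorrect = "numeric",
                 nTrials = "integer", se = "numeric",
                 observerId = "character", mode = "character")
)

setValidity("PsychometricCurve", function(object) {
  n <- length(object@betaGrid)
  if (length(object@pCorrect) != n || length(object@nTrials) != n ||
      length(object@se) != n)
    return("betaGrid, pCorrect, nTrials and se must have equal length")
  if (n > 1L && any(diff(object@betaGrid) <= 0))
    return("betaGrid must be strictly increasing")
  if (any(object@pCorrect < 0 | object@pCorrect > 1))
    return("pCorrect must lie in [0, 1]")
  k <- object@pCorrect * object@nTrials
  if (any(abs(k - round(k)) > 1e-6))
    return("pCorrect * nTrials must be integral (counts recoverable)")
  if (!object@mode %in% c("uniform_distractor", "permuted_distractor"))
    return("mode must be uniform_distractor or permuted_distractor")
  TRUE
})

#' Observer: a trained theoretical observer for one (set, beta, mode)
#'
#' Bundles the statistic kind, the fitted target and distractor densities,
#' and any auxiliary objects (ground-state orbit, render and Gabor
#' parameters) needed to compute the statistic on new lattices.
#'
#' @slot kind one of "luminance", "ideal", "ideal_analytic", "order",
#'   "channel_energy".
#' @slot specName texture set the observer was trained on.
#' @slot beta inverse temperature of the target distribution.
#' @slot mode distractor mode trained against.
#' @slot targetDensity,distractorDensity fitted [DensityModel-class]s
#'   (absent for the analytic Ideal rule).
#' @slot aux list of auxiliaries (orbit, renderSpec, gabor).
#' @seealso [trainObserver()], [observerStatistic()], [simulateTrial()]
#' @export
setClass("Observer",
  representation(kind = "character", specName = "character", beta = "numeric",
                 mode = "character", targetDensity = "ANY",
                 distractorDensity = "ANY", aux = "list")
)

setValidity("Observer", function(object) {
  kinds <- c("luminance", "ideal", "ideal_analytic", "order", "channel_energy")
  if (!object@kind %in% kinds)
    return(paste("kind must be one of", paste(kinds, collapse = ", ")))
  TRUE
})
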