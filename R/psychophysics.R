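# small deterministic string hash (FNV-style, kept below 2^31) used to
# derive per-condition seeds from a master seed
.hash32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- ((h * 16777619) %% 2147483647 + b) %% 2147483647
  as.integer(h)
}

.deriveSeed <- function(seed, ...) {
  (as.integer(seed) + .hash32(paste(..., sep = "|"))) %% 2147483647L
}

# compute an observer-kind statistic matrix (one row per lattice) from a
# flat sample matrix (n x H*W)
.statMatrix <- function(flat, kind, spec, aux) {
  H <- spec@latticeShape[1L]; W <- spec@latticeShape[2L]
  n <- nrow(flat)
  asMat <- function(i) matrix(flat[i, ], H, W)
  switch(kind,
    luminance = t(vapply(seq_len(n), function(i)
      .lumCounts(asMat(i), spec@nStates), numeric(spec@nStates))),
    ideal = t(vapply(seq_len(n), function(i)
      .pairCounts(asMat(i), spec),
      numeric(spec@nStates^2 * nrow(spec@offsets)))),
    order = matrix(vapply(seq_len(n), function(i)
      mean(conformanceField(asMat(i), spec, aux$orbit)), numeric(1L)),
      ncol = 1L),
    channel_energy = matrix(vapply(seq_len(n), function(i)
      .textureEnergy(renderTexture(asMat(i), aux$renderSpec), aux$gabor),
      numeric(1L)), ncol = 1L),
    stop("no statistic for kind ", kind)
  )
}

#' Statistic of one lattice under a trained observer
#'
#' @param observer an [Observer-class].
#' @param config lattice configuration.
#' @param spec the [TextureSetSpec-class] the observer was trained on.
#' @return numeric statistic vector.
#' @export
observerStatistic <- function(observer, config, spec) {
  flat <- matrix(as.vector(config), nrow = 1L)
  kind <- if (observer@kind == "ideal_analytic") "ideal" else observer@kind
  as.vector(.statMatrix(flat, kind, spec, observer@aux))
}

#' Train a theoretical observer for one (set, beta, mode) condition
#'
#' Draws \code{nTrain} equilibrium target lattices at beta and \code{nTrain}
#' distractor lattices (i.i.d. uniform, or random permutations of the
#' targets in permuted mode), computes the observer's statistic on each,
#' and fits target and distractor densities: a product-kernel KDE for the
#' multidimensional Luminance and Ideal statistics, a two-moment Gaussian
#' for the scalar Order and Channel energy statistics. The analytic Ideal
#' rule ("ideal_analytic") needs no training.
#'
#' @param spec a [TextureSetSpec-class].
#' @param beta inverse temperature of the target distribution.
#' @param kind "luminance", "ideal", "ideal_analytic", "order" or
#'   "channel_energy".
#' @param mode "uniform" or "permuted" distractors.
#' @param nTrain training samples; the conventional budgets are 1000 (100
#'   for the channel energy observer).
#' @param seed integer seed.
#' @param renderSpec,gabor rendering geometry and filter for the channel
#'   energy observer (defaults: [renderSpec()] at 80 px/degree and the
#'   builtin filter for the set).
#' @param burnIn,thin sampler settings for the training chain.
#' @return an [Observer-class].
#' @export
trainObserver <- function(spec, beta, kind = c("ideal", "luminance", "order",
                                               "channel_energy",
                                               "ideal_analytic"),
                          mode = c("uniform", "permuted"),
                          nTrain = NULL,
                          seed = NULL, renderSpec = NULL, gabor = NULL,
                          burnIn = 2000L, thin = 5L) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (is.null(nTrain))
    nTrain <- if (kind == "channel_energy") 100L else 1000L
  validateTextureSet(spec)
  aux <- .observerAux(kind, spec, renderSpec, gabor)
  if (kind == "ideal_analytic") {
    return(new("Observer", kind = kind, specName = spec@name, beta = beta,
               mode = mode, targetDensity = NULL, distractorDensity = NULL,
               aux = aux))
  }
  if (!is.null(seed)) set.seed(seed)
  targets <- .sampleTextureFlat(spec, beta, nTrain, burnIn = burnIn,
                                thin = thin)
  distractors <- .distractorFlat(spec, mode, targets)
  statKind <- kind
  dens <- if (kind %in% c("order", "channel_energy")) "gaussian" else "kde"
  st <- .statMatrix(targets, statKind, spec, aux)
  sd_ <- .statMatrix(distractors, statKind, spec, aux)
  if (dens == "kde") {
    pair <- .fitKdePair(st, sd_)
  } else {
    pair <- list(target = suppressWarnings(fitDensity(st, "gaussian")),
                 distractor = suppressWarnings(fitDensity(sd_, "gaussian")))
  }
  new("Observer", kind = kind, specName = spec@name, beta = beta,
      mode = mode, targetDensity = pair$target,
      distractorDensity = pair$distractor, aux = aux)
}

# KDE pair for the count statistics (luminance, pair counts) feeding the
# likelihood-ratio decision: both classes share one whitening transform
# built from the pooled within-class covariance, and use the oversmoothed
# bandwidth (2 in whitened units). With a shared kernel covariance the
# smooth-limit log ratio is the Fisher linear discriminant, which for these
# exponential-family sufficient statistics is the exact decision direction;
# per-class transforms would leave a noisy quadratic residual instead.
.fitKdePair <- function(st, sd_, h = 2, epsilon = 1e-6) {
  d <- ncol(st)
  center <- colMeans(rbind(st, sd_))
  Sig <- (stats::cov(st) + stats::cov(sd_)) / 2
  eg <- eigen(Sig, symmetric = TRUE)
  lam <- pmax(eg$values, epsilon * max(eg$values, epsilon))
  Wm <- eg$vectors %*% diag(1 / sqrt(lam), d)
  logJac <- -0.5 * sum(log(lam))
  mk <- function(s) {
    new("DensityModel", kind = "kde",
        samples = sweep(s, 2L, center) %*% Wm,
        bandwidths = rep(h, d), mean = numeric(0L), sd = numeric(0L),
        whiten = Wm, center = center, logJac = logJac,
        trainingN = nrow(s), dims = d)
  }
  list(target = mk(st), distractor = mk(sd_))
}

.observerAux <- function(kind, spec, rspec, gabor) {
  aux <- list()
  if (kind == "order") aux$orbit <- groundStateOrbit(spec)
  if (kind == "channel_energy") {
    if (is.null(rspec)) rspec <- renderSpec(pixelScale = 80)
    if (is.null(gabor)) {
      gb <- builtinGabors(rspec@pixelScale, rspec@blobSpacing)
      gabor <- if (spec@name %in% names(gb)) gb[[spec@name]] else gb[[1L]]
    }
    aux$renderSpec <- rspec
    aux$gabor <- gabor
  }
  aux
}

# flat matrix of distractor lattices matching a flat target matrix
.distractorFlat <- function(spec, mode, targets) {
  n <- nrow(targets)
  m <- ncol(targets)
  if (mode == "uniform") {
    matrix(sample.int(spec@nStates, n * m, replace = TRUE) - 1L, n, m)
  } else {
    t(apply(targets, 1L, sample))
  }
}

#' Simulate one 4AFC trial
#'
#' Draws one target lattice at beta (unless supplied), three distractors
#' according to the mode, assigns the target to a random quadrant, computes
#' the observer's statistics and decides by maximum likelihood
#' ([decide4AFC()], or the minimum-energy rule for the analytic Ideal
#' observer, falling back to chance at beta = 0).
#'
#' @param spec a [TextureSetSpec-class].
#' @param beta inverse temperature.
#' @param observer a trained [Observer-class] for (spec, beta, mode).
#' @param mode "uniform" or "permuted".
#' @param target optional pre-sampled target lattice.
#' @param burnIn,thin sampler settings when the target must be drawn.
#' @return logical: was the target quadrant chosen?
#' @export
simulateTrial <- function(spec, beta, observer, mode = c("uniform", "permuted"),
                          target = NULL, burnIn = 2000L, thin = 5L) {
  mode <- match.arg(mode)
  if (observer@kind != "ideal_analytic") {
    if (is.null(observer@targetDensity))
      stop("observer is untrained")
    if (observer@mode != mode)
      stop(sprintf("observer was trained for %s distractors", observer@mode))
  }
  if (is.null(target))
    target <- sampleTexture(spec, beta, 1L, burnIn = burnIn, thin = thin)[[1L]]
  configs <- vector("list", 4L)
  tq <- sample.int(4L, 1L)
  configs[[tq]] <- target
  for (q in setdiff(1:4, tq))
    configs[[q]] <- makeDistractor(spec, mode, target = target)
  if (observer@kind == "ideal_analytic") {
    ch <- if (beta > 0) analyticIdealDecide(configs, spec, beta)
          else sample.int(4L, 1L)
  } else {
    kind <- observer@kind
    stats <- do.call(rbind, lapply(configs, function(cf)
      .statMatrix(matrix(as.vector(cf), 1L), kind, spec, observer@aux)))
    ch <- decide4AFC(stats, observer@targetDensity, observer@distractorDensity)
  }
  identical(as.integer(ch), as.integer(tq))
}

#' Simulate a psychometric curve for one observer
#'
#' For each beta on the grid: trains the observer (\code{nTrain} samples),
#' then simulates \code{nTrials} 4AFC trials (one equilibrium chain
#' provides the targets; distractors follow the mode) and records the
#' fraction of correct maximum-likelihood responses with its binomial
#' standard error. Per-condition seeds are derived from the master seed and
#' a hash of (set, observer, beta), so each curve is independently
#' reproducible.
#'
#' @param spec a [TextureSetSpec-class].
#' @param observer observer kind (see [trainObserver()]).
#' @param betaGrid inverse temperatures; defaults to the spec's grid.
#' @param nTrials simulated trials per beta (convention: 1000; 100 for the
#'   channel energy observer).
#' @param nTrain training samples per beta.
#' @param mode "uniform" or "permuted" distractors.
#' @param seed master seed.
#' @param renderSpec,gabor channel-energy rendering geometry and filter.
#' @param burnIn,thin sampler settings.
#' @return a [PsychometricCurve-class].
#' @export
performanceCurve <- function(spec, observer = "ideal",
                             betaGrid = spec@betaGrid,
                             nTrials = if (observer == "channel_energy") 100L else 1000L,
                             nTrain = if (observer == "channel_energy") 100L else 1000L,
                             mode = c("uniform", "permuted"), seed = 1L,
                             renderSpec = NULL, gabor = NULL,
                             burnIn = 2000L, thin = 5L) {
  mode <- match.arg(mode)
  stopifnot(length(betaGrid) >= 1L)
  kind <- observer
  pc <- numeric(length(betaGrid))
  for (bi in seq_along(betaGrid)) {
    beta <- betaGrid[bi]
    set.seed(.deriveSeed(seed, spec@name, kind, signif(beta, 10L), mode))
    if (kind == "ideal_analytic") {
      targets <- .sampleTextureFlat(spec, beta, nTrials, burnIn = burnIn,
                                    thin = thin)
      pc[bi] <- .runTrialsAnalytic(targets, spec, beta, mode)
    } else {
      obs <- trainObserver(spec, beta, kind, mode, nTrain = nTrain,
                           seed = NULL, renderSpec = renderSpec,
                           gabor = gabor, burnIn = burnIn, thin = thin)
      targets <- .sampleTextureFlat(spec, beta, nTrials, burnIn = burnIn,
                                    thin = thin)
      pc[bi] <- .runTrials(targets, spec, mode, obs)
    }
  }
  k <- round(pc * nTrials)
  new("PsychometricCurve", betaGrid = as.numeric(betaGrid),
      pCorrect = k / nTrials, nTrials = rep(as.integer(nTrials),
                                            length(betaGrid)),
      se = sqrt(pmax(k / nTrials * (1 - k / nTrials), 0) / nTrials),
      observerId = kind,
      mode = paste0(mode, "_distractor"))
}

# fraction correct over trials for a density-based observer; target and the
# three distractor statistics are evaluated in one batch for speed
.runTrials <- function(targets, spec, mode, obs) {
  n <- nrow(targets)
  kind <- obs@kind
  d1 <- .distractorFlat(spec, mode, targets)
  d2 <- .distractorFlat(spec, mode, targets)
  d3 <- .distractorFlat(spec, mode, targets)
  S <- rbind(.statMatrix(targets, kind, spec, obs@aux),
             .statMatrix(d1, kind, spec, obs@aux),
             .statMatrix(d2, kind, spec, obs@aux),
             .statMatrix(d3, kind, spec, obs@aux))
  llr <- logDensity(obs@targetDensity, S) - logDensity(obs@distractorDensity, S)
  correct <- logical(n)
  for (i in seq_len(n)) {
    sc <- llr[c(i, n + i, 2L * n + i, 3L * n + i)]
    correct[i] <- .argmaxTie(sc) == 1L
  }
  mean(correct)
}

.runTrialsAnalytic <- function(targets, spec, beta, mode) {
  n <- nrow(targets)
  H <- spec@latticeShape[1L]; W <- spec@latticeShape[2L]
  if (beta <= 0) {
    # distributions identical: exact chance by construction
    return(mean(sample.int(4L, n, replace = TRUE) == 1L))
  }
  correct <- logical(n)
  for (i in seq_len(n)) {
    tg <- matrix(targets[i, ], H, W)
    cfgs <- list(tg,
                 makeDistractor(spec, mode, target = tg),
                 makeDistractor(spec, mode, target = tg),
                 makeDistractor(spec, mode, target = tg))
    e <- vapply(cfgs, latticeEnergy, numeric(1L), spec = spec)
    correct[i] <- .argmaxTie(-e) == 1L
  }
  mean(correct)
}

#' Threshold of a psychometric curve
#'
#' Smallest beta at which the curve crosses the criterion level (default
#' 62.5% correct, halfway between 4AFC chance and perfect), found by linear
#' interpolation in log beta between adjacent grid points (beta typically
#' spans orders of magnitude); a segment starting at beta = 0 is
#' interpolated linearly in beta instead. Returns NA (with attribute
#' \code{reason}) when the curve never reaches the level.
#'
#' @param curve a [PsychometricCurve-class].
#' @param level criterion proportion correct, strictly between 0.25 and 1.
#' @return the threshold beta, or NA if undefined.
#' @export
estimateThreshold <- function(curve, level = 0.625) {
  stopifnot(level > 0.25, level < 1)
  b <- curve@betaGrid
  p <- curve@pCorrect
  if (p[1L] >= level) {
    if (p[1L] == level) return(b[1L])
    # already above criterion at the smallest beta
    return(structure(b[1L], note = "at or above level from the first grid point"))
  }
  for (i in seq_len(length(b) - 1L)) {
    if (p[i + 1L] == level) return(b[i + 1L])
    if (p[i] < level && p[i + 1L] > level) {
      w <- (level - p[i]) / (p[i + 1L] - p[i])
      if (b[i] <= 0)
        return(b[i] + w * (b[i + 1L] - b[i]))
      return(exp(log(b[i]) + w * (log(b[i + 1L]) - log(b[i]))))
    }
  }
  structure(NA_real_, reason = "curve never reaches the criterion level")
}

#' Chi-squared comparison of two psychometric curves
#'
#' At each beta the two observed proportions are compared by the pooled
#' two-proportion chi-squared statistic (the Pearson statistic of the 2 x 2
#' correct/incorrect table); contributions are summed over the grid. The
#' degrees of freedom default to the number of beta levels and are
#' configurable.
#'
#' @param curveA,curveB [PsychometricCurve-class]s on the same beta grid.
#' @param dof degrees of freedom for the reference distribution (default:
#'   number of grid points).
#' @return list with \code{chi2}, \code{dof} and \code{p}.
#' @export
chi2Compare <- function(curveA, curveB, dof = NULL) {
  if (!isTRUE(all.equal(curveA@betaGrid, curveB@betaGrid)))
    stop("curves must share the same beta grid")
  if (is.null(dof)) dof <- length(curveA@betaGrid)
  k1 <- round(curveA@pCorrect * curveA@nTrials); n1 <- curveA@nTrials
  k2 <- round(curveB@pCorrect * curveB@nTrials); n2 <- curveB@nTrials
  phat <- (k1 + k2) / (n1 + n2)
  denom <- phat * (1 - phat) * (1 / n1 + 1 / n2)
  contrib <- ifelse(denom > 0, (k1 / n1 - k2 / n2)^2 / denom, 0)
  chi2 <- sum(contrib)
  list(chi2 = chi2, dof = dof,
       p = stats::pchisq(chi2, dof, lower.tail = FALSE))
}

#' Paired comparison of the KDE-based and analytic Ideal observers
#'
#' Runs the same simulated 4AFC trials -- identical target and distractor
#' lattices -- through both Ideal decision rules: the KDE likelihood-ratio
#' rule trained on \code{nTrain} samples, and the exact minimum-energy
#' rule. Pairing removes between-rule Monte Carlo noise, so the difference
#' column measures implementation agreement directly.
#'
#' @param spec a [TextureSetSpec-class].
#' @param betaGrid inverse temperatures.
#' @param nTrials paired trials per beta.
#' @param nTrain KDE training samples per beta.
#' @param mode distractor mode.
#' @param seed master seed.
#' @param burnIn,thin sampler settings.
#' @return data.frame with beta, pKDE, pAnalytic, diff, n.
#' @export
idealAgreement <- function(spec, betaGrid, nTrials = 1000L, nTrain = 1000L,
                           mode = c("uniform", "permuted"), seed = 1L,
                           burnIn = 2000L, thin = 5L) {
  mode <- match.arg(mode)
  H <- spec@latticeShape[1L]; W <- spec@latticeShape[2L]
  out <- data.frame(beta = betaGrid, pKDE = NA_real_, pAnalytic = NA_real_)
  for (bi in seq_along(betaGrid)) {
    beta <- betaGrid[bi]
    set.seed(.deriveSeed(seed, spec@name, "ideal_agreement",
                         signif(beta, 10L), mode))
    obs <- trainObserver(spec, beta, "ideal", mode, nTrain = nTrain,
                         burnIn = burnIn, thin = thin)
    targets <- .sampleTextureFlat(spec, beta, nTrials, burnIn = burnIn,
                                  thin = thin)
    d1 <- .distractorFlat(spec, mode, targets)
    d2 <- .distractorFlat(spec, mode, targets)
    d3 <- .distractorFlat(spec, mode, targets)
    S <- rbind(.statMatrix(targets, "ideal", spec, obs@aux),
               .statMatrix(d1, "ideal", spec, obs@aux),
               .statMatrix(d2, "ideal", spec, obs@aux),
               .statMatrix(d3, "ideal", spec, obs@aux))
    llr <- logDensity(obs@targetDensity, S) -
      logDensity(obs@distractorDensity, S)
    # energy is a linear functional of the pair statistic
    uvec <- unlist(lapply(spec@potentials, as.vector))
    en <- as.vector(S %*% uvec)
    okK <- logical(nTrials); okA <- logical(nTrials)
    for (i in seq_len(nTrials)) {
      sel <- c(i, nTrials + i, 2L * nTrials + i, 3L * nTrials + i)
      okK[i] <- .argmaxTie(llr[sel]) == 1L
      if (beta > 0) okA[i] <- .argmaxTie(-en[sel]) == 1L
    }
    out$pKDE[bi] <- mean(okK)
    # at beta = 0 the minimum-energy rule is undefined and the analytic
    # observer is chance by definition: report its exact value
    out$pAnalytic[bi] <- if (beta > 0) mean(okA) else 0.25
  }
  out$diff <- out$pKDE - out$pAnalytic
  out$n <- nTrials
  out
}
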