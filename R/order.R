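# all permutations of 0:(n-1); n is small (number of states)
.statePermutations <- function(n) {
  if (n == 1L) return(list(0L))
  perms <- list()
  for (p in .statePermutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      perms[[length(perms) + 1L]] <- append(p, n - 1L, after = pos)
    }
  }
  perms
}

# state permutations that leave every potential matrix invariant,
# i.e. relabelings under which the energy of any configuration is unchanged
.symmetryPermutations <- function(spec) {
  ns <- spec@nStates
  keep <- list()
  for (perm in .statePermutations(ns)) {
    idx <- perm + 1L
    ok <- all(vapply(spec@potentials, function(U) {
      isTRUE(all.equal(U[idx, idx], U, tolerance = 1e-12))
    }, logical(1L)))
    if (ok) keep[[length(keep) + 1L]] <- perm
  }
  keep
}

# energies of all periodic tilings with a th x tw tile (tile dims must
# divide the lattice); returns the minimum over all n_states^(th*tw) tiles
.minTilingEnergy <- function(spec, th, tw, maxTiles = 2e5) {
  ns <- spec@nStates
  if (ns^(th * tw) > maxTiles)
    stop("tile period too large for exhaustive ground-state verification")
  H <- spec@latticeShape[1L]; W <- spec@latticeShape[2L]
  n <- th * tw
  tiles <- as.matrix(expand.grid(rep(list(0:(ns - 1L)), n),
                                 KEEP.OUT.ATTRS = FALSE))
  dimnames(tiles) <- NULL
  pp <- (seq_len(n) - 1L) %% th
  qq <- (seq_len(n) - 1L) %/% th
  e <- numeric(nrow(tiles))
  for (i in seq_len(nrow(spec@offsets))) {
    # offsets wrap on the full lattice; since th | H and tw | W they reduce
    # to (dy mod th, dx mod tw) on the tile
    dy <- spec@offsets[i, 1L] %% th
    dx <- spec@offsets[i, 2L] %% tw
    U <- spec@potentials[[i]]
    partner <- ((pp + dy) %% th) + ((qq + dx) %% tw) * th + 1L
    for (j in seq_len(n))
      e <- e + U[cbind(tiles[, j] + 1L, tiles[, partner[j]] + 1L)]
  }
  scale <- (H / th) * (W / tw)
  list(tiles = tiles, energy = e * scale, min = min(e) * scale)
}

#' Ground-state orbit of a texture set
#'
#' All distinct minimum-energy full-lattice configurations obtainable as
#' cyclic translations of the set's ground-state tile, together with the
#' state relabelings that leave every potential matrix (and hence the
#' energy) invariant. All members have equal energy; by default that energy
#' is verified to be minimal among all periodic tilings with the tile's
#' period (exhaustive enumeration).
#'
#' @param spec a [TextureSetSpec-class] with \code{groundStateTile} set, or
#'   \code{searchPeriod} given.
#' @param searchPeriod when the spec has no tile, exhaustively search square
#'   tiles up to this period (kept small; the search is exponential in the
#'   tile area).
#' @param verify check minimality against all same-period tilings
#'   (default TRUE).
#' @return list of H x W integer matrices, each a ground state.
#' @export
groundStateOrbit <- function(spec, searchPeriod = NULL, verify = TRUE) {
  validateTextureSet(spec)
  key <- paste0("orbit:", .specKey(spec), ":", verify)
  hit <- .cacheGet(key)
  if (!is.null(hit)) return(hit)
  tile <- spec@groundStateTile
  if (is.null(tile)) {
    if (is.null(searchPeriod))
      stop("spec has no groundStateTile and no searchPeriod was given")
    srch <- .minTilingEnergy(spec, searchPeriod, searchPeriod)
    best <- which(srch$energy <= srch$min + 1e-9)
    tiles <- lapply(best, function(i)
      matrix(srch$tiles[i, ], searchPeriod, searchPeriod))
  } else {
    tiles <- list(tile)
  }
  perms <- .symmetryPermutations(spec)
  members <- list()
  seen <- character()
  for (tl in tiles) {
    th <- nrow(tl); tw <- ncol(tl)
    for (perm in perms) {
      for (dy in 0:(th - 1L)) {
        for (dx in 0:(tw - 1L)) {
          shifted <- .shiftBy(tl, dy, dx)
          conf <- matrix(unlist(perm)[shifted + 1L], th, tw)
          full <- .tileToLattice(conf, spec@latticeShape)
          k <- paste(full, collapse = ",")
          if (!k %in% seen) {
            seen <- c(seen, k)
            members[[length(members) + 1L]] <- full
          }
        }
      }
    }
  }
  e <- vapply(members, latticeEnergy, numeric(1L), spec = spec)
  members <- members[e <= min(e) + 1e-9]
  if (verify && !is.null(tile)) {
    chk <- .minTilingEnergy(spec, nrow(tile), ncol(tile))
    if (min(e) > chk$min + 1e-9)
      stop("groundStateTile is not minimal among same-period tilings")
  }
  .cacheSet(key, members)
  members
}

.specKey <- function(spec) {
  paste(spec@name, spec@nStates,
        paste(spec@offsets, collapse = ","),
        paste(signif(unlist(spec@potentials), 12L), collapse = ","),
        paste(spec@latticeShape, collapse = ","), sep = "|")
}

# per-offset logical nStates x nStates matrices marking the joint states
# realised by the ground-state orbit; because the orbit is closed under
# cyclic translation the allowed set is site-independent
.allowedJointStates <- function(spec, orbit = NULL) {
  key <- paste0("allowed:", .specKey(spec))
  hit <- .cacheGet(key)
  if (!is.null(hit)) return(hit)
  if (is.null(orbit)) orbit <- groundStateOrbit(spec)
  ns <- spec@nStates
  allowed <- lapply(seq_len(nrow(spec@offsets)), function(i) {
    M <- matrix(FALSE, ns, ns)
    for (Tm in orbit) {
      Ts <- .shiftBy(Tm, spec@offsets[i, 1L], spec@offsets[i, 2L])
      M[unique(cbind(as.vector(Tm) + 1L, as.vector(Ts) + 1L))] <- TRUE
    }
    M
  })
  .cacheSet(key, allowed)
}

#' Local order field of a configuration
#'
#' For each site, the fraction of its interacting pairs (the site with each
#' offset partner, in both directions) whose joint state is one realised by
#' the ground-state orbit at that relative offset. Entries lie in [0, 1];
#' the field is identically 1 on orbit members and shifts along with cyclic
#' translations of the configuration.
#'
#' @param config H x W integer matrix of states.
#' @param spec a [TextureSetSpec-class].
#' @param orbit optional precomputed [groundStateOrbit()] result.
#' @return H x W numeric matrix of local conformance values.
#' @export
conformanceField <- function(config, spec, orbit = NULL) {
  .checkConfig(config, spec)
  allowed <- .allowedJointStates(spec, orbit)
  nOff <- nrow(spec@offsets)
  acc <- matrix(0, nrow(config), ncol(config))
  for (i in seq_len(nOff)) {
    dy <- spec@offsets[i, 1L]; dx <- spec@offsets[i, 2L]
    M <- allowed[[i]]
    Ap <- .shiftBy(config, dy, dx)     # partner at +offset
    Am <- .shiftBy(config, -dy, -dx)   # partner at -offset
    acc <- acc + M[matrix(c(as.vector(config) + 1L, as.vector(Ap) + 1L),
                          ncol = 2L)]
    acc <- acc + M[matrix(c(as.vector(Am) + 1L, as.vector(config) + 1L),
                          ncol = 2L)]
  }
  acc / (2 * nOff)
}

#' Analytic or Monte Carlo baseline of the order parameter
#'
#' Expected order parameter of an i.i.d. uniform lattice. Analytically this
#' is the mean over offsets of (number of allowed joint states) / nStates^2
#' (the field is an average of indicator variables, each with that success
#' probability under independent uniform states). A Monte Carlo estimate
#' with standard error is returned when \code{nMC > 0}.
#'
#' @param spec a [TextureSetSpec-class].
#' @param nMC Monte Carlo replicates (0 = analytic).
#' @return list with \code{baseline} and \code{se} (0 for analytic).
#' @export
orderBaseline <- function(spec, nMC = 0L) {
  allowed <- .allowedJointStates(spec)
  if (nMC <= 0L) {
    b <- mean(vapply(allowed, function(M) sum(M) / length(M), numeric(1L)))
    return(list(baseline = b, se = 0))
  }
  H <- spec@latticeShape[1L]; W <- spec@latticeShape[2L]
  vals <- vapply(seq_len(nMC), function(i) {
    u <- matrix(sample.int(spec@nStates, H * W, replace = TRUE) - 1L, H, W)
    mean(conformanceField(u, spec))
  }, numeric(1L))
  list(baseline = mean(vals), se = stats::sd(vals) / sqrt(nMC))
}

#' Order parameter of a configuration
#'
#' The mean of the local order field: a scalar in [0, 1] measuring the
#' average conformance of local configurations to the global symmetry of
#' the set's ground states. Equals 1 exactly on ground-state
#' configurations; on i.i.d. uniform lattices its expectation is the
#' analytic baseline (1/3 for the ferromagnetic Potts set). The baseline is
#' reported alongside, not subtracted.
#'
#' @param config H x W integer matrix of states.
#' @param spec a [TextureSetSpec-class].
#' @param orbit optional precomputed [groundStateOrbit()] result.
#' @return an [OrderStatistic-class].
#' @export
orderParameter <- function(config, spec, orbit = NULL) {
  field <- conformanceField(config, spec, orbit)
  base <- orderBaseline(spec)
  new("OrderStatistic", value = mean(field), baseline = base$baseline,
      baselineSE = base$se, field = field)
}
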