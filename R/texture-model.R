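#' Construct a texture set specification
#'
#' A texture set defines a Boltzmann distribution
#' \eqn{P(I) = \exp(-\beta U(I)) / Z} over lattices \eqn{I} of amplitude
#' indices, where the energy \eqn{U(I)} sums a pairwise potential over every
#' site and every interacting offset, with cyclic boundary conditions.
#'
#' @param name identifier.
#' @param offsets list of integer (dy, dx) pairs, or an n x 2 matrix. Each
#'   unordered interacting pair appears once: an offset and its negation
#'   must not both be present.
#' @param potentials list of nStates x nStates numeric matrices, same order
#'   as \code{offsets}. Entry \code{[s+1, t+1]} is the energy contributed by
#'   a site in state s with its partner (at the offset) in state t.
#' @param nStates number of amplitude levels; default 3.
#' @param latticeShape integer (H, W); default c(32, 32).
#' @param betaGrid non-negative, strictly increasing inverse temperatures.
#' @param groundStateTile optional periodic matrix of state indices whose
#'   tiling is the canonical minimum-energy configuration; its dimensions
#'   must divide the lattice shape.
#' @return a validated [TextureSetSpec-class].
#' @examples
#' U <- -diag(3)  # ferromagnetic: matching neighbours lower the energy
#' sp <- textureSetSpec("potts", list(c(0, 1), c(1, 0)), list(U, U),
#'                      betaGrid = c(0, 0.5, 1))
#' @export
textureSetSpec <- function(name, offsets, potentials, nStates = 3L,
                           latticeShape = c(32L, 32L),
                           betaGrid = numeric(),
                           groundStateTile = NULL) {
  if (is.list(offsets))
    offsets <- do.call(rbind, lapply(offsets, as.integer))
  offsets <- matrix(as.integer(offsets), ncol = 2L,
                    dimnames = list(NULL, c("dy", "dx")))
  potentials <- lapply(potentials, function(U) {
    U <- as.matrix(U)
    storage.mode(U) <- "double"
    U
  })
  if (!is.null(groundStateTile)) {
    groundStateTile <- as.matrix(groundStateTile)
    storage.mode(groundStateTile) <- "integer"
  }
  new("TextureSetSpec", name = as.character(name),
      nStates = as.integer(nStates), offsets = offsets,
      potentials = potentials, latticeShape = as.integer(latticeShape),
      betaGrid = as.numeric(betaGrid), groundStateTile = groundStateTile)
}

#' Validate a texture set specification
#'
#' Checks every invariant of [TextureSetSpec-class] (no (0,0) offset, no
#' offset together with its negation, finite square potentials, strictly
#' increasing non-negative beta grid, tile dividing the lattice) and raises
#' an error naming the first violated one.
#'
#' @param spec a [TextureSetSpec-class].
#' @return the spec, invisibly, if valid.
#' @export
validateTextureSet <- function(spec) {
  stopifnot(is(spec, "TextureSetSpec"))
  msg <- validObject(spec, test = TRUE)
  if (is.character(msg)) stop(msg, call. = FALSE)
  invisible(spec)
}

# check a lattice configuration against a spec
.checkConfig <- function(config, spec) {
  if (!is.matrix(config))
    stop("lattice configuration must be a matrix of state indices")
  sh <- spec@latticeShape
  if (nrow(config) != sh[1L] || ncol(config) != sh[2L])
    stop(sprintf("configuration shape %d x %d does not match spec lattice %d x %d",
                 nrow(config), ncol(config), sh[1L], sh[2L]))
  if (any(config < 0L | config >= spec@nStates))
    stop("configuration entries must be state indices in [0, nStates)")
  invisible(config)
}

# cyclic shift of a matrix by an offset (dy, dx): entry [p,q] of the result
# is A[(p+dy) mod H, (q+dx) mod W] -- the partner state at each site
.shiftBy <- function(A, dy, dx) {
  H <- nrow(A); W <- ncol(A)
  rows <- ((seq_len(H) - 1L + dy) %% H) + 1L
  cols <- ((seq_len(W) - 1L + dx) %% W) + 1L
  A[rows, cols, drop = FALSE]
}

#' Total energy of a lattice configuration
#'
#' \deqn{U(I) = \sum_{(p,q)} \sum_o U_o(A_{p,q}, A_{(p,q)+o})}
#' with cyclic wrapping; each unordered interacting pair contributes once.
#' The energy does not depend on beta and is invariant under cyclic
#' translations of the configuration.
#'
#' @param config H x W integer matrix of states in [0, nStates).
#' @param spec a [TextureSetSpec-class].
#' @return scalar energy (dimensionless).
#' @export
latticeEnergy <- function(config, spec) {
  .checkConfig(config, spec)
  e <- 0
  for (i in seq_len(nrow(spec@offsets))) {
    Ashift <- .shiftBy(config, spec@offsets[i, 1L], spec@offsets[i, 2L])
    U <- spec@potentials[[i]]
    e <- e + sum(U[cbind(as.vector(config) + 1L, as.vector(Ashift) + 1L)])
  }
  e
}

#' Builtin example texture sets
#'
#' Three canonical sets with known ground states, spanning the qualitative
#' regimes of the framework:
#' \describe{
#'   \item{potts}{3-state ferromagnetic Potts model: matching nearest
#'     neighbours (horizontal and vertical) lower the energy; ground states
#'     are the three uniform lattices. Its ordered state is a field of
#'     blobs with uniform amplitudes, so permuted distractors are
#'     indistinguishable from it.}
#'   \item{checkerboard}{antiferromagnetic pairing of states 0 and 2:
#'     a (0,2)/(2,0) nearest-neighbour pair lowers the energy; ground states
#'     are the two phase-shifted checkerboards.}
#'   \item{stripe}{anisotropic set: horizontal neighbours prefer to match,
#'     vertical neighbours prefer the (0,2) alternation; ground states are
#'     the two phase-shifted horizontal stripe patterns.}
#' }
#' All sets use 3 states, a 32 x 32 lattice, offsets \{(0,1), (1,0)\} and a
#' populated \code{groundStateTile}.
#'
#' @param latticeShape lattice (H, W) for all returned sets. Sets whose
#'   ground-state tile does not divide the requested shape (the period-2
#'   sets on odd lattices) are omitted.
#' @return named list of validated [TextureSetSpec-class] objects.
#' @export
builtinSpecs <- function(latticeShape = c(32L, 32L)) {
  nn <- list(c(0L, 1L), c(1L, 0L))
  grid <- c(0, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.6, 0.8, 1)
  Uferro <- -diag(3)
  # -1 when the pair of states is {0, 2}
  Ualt <- matrix(0, 3L, 3L); Ualt[1L, 3L] <- Ualt[3L, 1L] <- -1
  defs <- list(
    potts = list(pot = list(Uferro, Uferro), tile = matrix(0L, 1L, 1L)),
    checkerboard = list(pot = list(Ualt, Ualt),
                        tile = matrix(c(0L, 2L, 2L, 0L), 2L, 2L)),
    stripe = list(pot = list(Uferro, Ualt), tile = matrix(c(0L, 2L), 2L, 1L))
  )
  specs <- list()
  for (nm in names(defs)) {
    d <- defs[[nm]]
    if (latticeShape[1L] %% nrow(d$tile) != 0L ||
        latticeShape[2L] %% ncol(d$tile) != 0L) next
    specs[[nm]] <- validateTextureSet(
      textureSetSpec(nm, nn, d$pot, latticeShape = latticeShape,
                     betaGrid = grid, groundStateTile = d$tile))
  }
  specs
}

# expand a periodic tile to the full lattice of a spec
.tileToLattice <- function(tile, shape) {
  H <- shape[1L]; W <- shape[2L]
  tile[((seq_len(H) - 1L) %% nrow(tile)) + 1L,
       ((seq_len(W) - 1L) %% ncol(tile)) + 1L, drop = FALSE]
}
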