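# shared fixtures: tiny texture sets and brute-force oracles

ferroU <- function() -diag(3)

# ferromagnetic Potts on a small lattice
smallPotts <- function(shape = c(4L, 4L)) {
  builtinSpecs(shape)$potts
}

# a spec with asymmetric potentials and mixed offsets, for oracle checks
asymSpec <- function(shape = c(4L, 4L)) {
  set.seed(99)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  pots <- lapply(offs, function(o) matrix(round(rnorm(9), 3), 3, 3))
  textureSetSpec("asym", offs, pots, latticeShape = shape)
}

randomConfig <- function(spec) {
  sh <- latticeShape(spec)
  matrix(sample.int(nStates(spec), prod(sh), replace = TRUE) - 1L,
         sh[1L], sh[2L])
}

# naive double-loop energy: every site, every offset, cyclic wrapping
bruteEnergy <- function(config, spec) {
  H <- nrow(config); W <- ncol(config)
  off <- offsets(spec); pots <- potentials(spec)
  e <- 0
  for (p in 0:(H - 1L)) for (q in 0:(W - 1L)) {
    for (i in seq_len(nrow(off))) {
      pp <- (p + off[i, 1L]) %% H
      qq <- (q + off[i, 2L]) %% W
      e <- e + pots[[i]][config[p + 1L, q + 1L] + 1L,
                         config[pp + 1L, qq + 1L] + 1L]
    }
  }
  e
}

# naive per-offset joint-state counting
brutePairCounts <- function(config, spec) {
  H <- nrow(config); W <- ncol(config)
  off <- offsets(spec); ns <- nStates(spec)
  out <- numeric(0)
  for (i in seq_len(nrow(off))) {
    tab <- matrix(0, ns, ns)
    for (p in 0:(H - 1L)) for (q in 0:(W - 1L)) {
      pp <- (p + off[i, 1L]) %% H
      qq <- (q + off[i, 2L]) %% W
      s <- config[p + 1L, q + 1L]; t <- config[pp + 1L, qq + 1L]
      tab[s + 1L, t + 1L] <- tab[s + 1L, t + 1L] + 1L
    }
    out <- c(out, as.vector(tab))
  }
  out
}

rollMatrix <- function(A, dy, dx) {
  H <- nrow(A); W <- ncol(A)
  A[((seq_len(H) - 1L - dy) %% H) + 1L, ((seq_len(W) - 1L - dx) %% W) + 1L,
    drop = FALSE]
}
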