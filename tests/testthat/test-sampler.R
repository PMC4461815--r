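test_that("conditional distribution matches the closed form", {
  sp <- builtinSpecs()$potts
  cfg <- matrix(0L, 32, 32)
  # beta = 0: uniform regardless of neighbourhood
  expect_equal(conditionalDistribution(c(5, 9), cfg, sp, 0), rep(1 / 3, 3))
  # all four partners in state 0, ferromagnetic U = -1 on match, beta = 1:
  # P(0) = e^4 / (e^4 + 2)
  p <- conditionalDistribution(c(2, 2), cfg, sp, 1)
  expect_equal(p[1], exp(4) / (exp(4) + 2), tolerance = 1e-12)
  expect_equal(p[2], 2 / (2 * (exp(4) + 2)), tolerance = 1e-12)
  expect_equal(sum(p), 1)
  expect_error(conditionalDistribution(c(0, 1), cfg, sp, 1), "range")

  # permuting state labels in both potential and neighbourhood permutes the
  # output identically
  asp <- asymSpec()
  set.seed(3)
  cfg4 <- randomConfig(asp)
  perm <- c(1L, 2L, 0L); idx <- perm + 1L
  permSpec <- textureSetSpec("p", lapply(seq_len(nrow(offsets(asp))),
                                         function(i) offsets(asp)[i, ]),
                             lapply(potentials(asp), function(U) {
                               V <- U; V[idx, idx] <- U; V
                             }),
                             latticeShape = latticeShape(asp))
  relab <- matrix(perm[cfg4 + 1L], 4, 4)
  p1 <- conditionalDistribution(c(2, 3), cfg4, asp, 0.7)
  p2 <- conditionalDistribution(c(2, 3), relab, permSpec, 0.7)
  expect_equal(p2[idx], p1, tolerance = 1e-12)
})

test_that("colour classes never place interacting sites in one group", {
  sp <- textureSetSpec("nn4", list(c(0, 1), c(1, 0), c(1, 1), c(1, -1)),
                       rep(list(ferroU()), 4), latticeShape = c(8L, 8L))
  colors <- colorClasses(sp)
  expect_identical(attr(colors, "scheme"), "parity")
  expect_equal(sort(unique(as.vector(colors))), 1:4)

  # (0,2) preserves both parities: a different valid colouring is returned
  sp2 <- textureSetSpec("wide", list(c(0, 1), c(0, 2)),
                        rep(list(ferroU()), 2), latticeShape = c(8L, 8L))
  colors2 <- colorClasses(sp2)
  expect_identical(attr(colors2, "scheme"), "greedy")

  # defining property, checked exhaustively on 8x8
  for (s in list(sp, sp2)) {
    cl <- colorClasses(s)
    off <- offsets(s)
    for (i in seq_len(nrow(off))) {
      shifted <- rollMatrix(cl, off[i, 1], off[i, 2])
      expect_true(all(cl != shifted))
    }
  }
  # an offset that wraps onto the site itself cannot be coloured
  spBad <- textureSetSpec("wrap", list(c(0, 4)), list(ferroU()),
                          latticeShape = c(4L, 4L))
  expect_error(colorClasses(spBad), "itself")
})

test_that("gibbs sweeps are deterministic under a seed and preserve the state space", {
  sp <- builtinSpecs()$potts
  cfg <- matrix(0L, 32, 32)
  set.seed(21); a <- gibbsSweep(cfg, sp, 0.4)
  set.seed(21); b <- gibbsSweep(cfg, sp, 0.4)
  expect_identical(a, b)
  expect_identical(dim(a), dim(cfg))
  expect_true(all(a %in% 0:2))

  # beta = 0: each site independently uniform; pool many sweeps
  set.seed(22)
  counts <- numeric(3)
  for (i in 1:20) {
    s <- gibbsSweep(cfg, sp, 0)
    counts <- counts + tabulate(s + 1L, 3)
  }
  n <- sum(counts)
  se <- sqrt(1 / 3 * 2 / 3 / n)
  expect_true(all(abs(counts / n - 1 / 3) < 3 * se))
})

test_that("sampleTexture is reproducible and hits the disorder/order limits", {
  sp <- builtinSpecs()$potts
  s1 <- sampleTexture(sp, 0.3, 5, burnIn = 100, seed = 8)
  s2 <- sampleTexture(sp, 0.3, 5, burnIn = 100, seed = 8)
  expect_identical(s1, s2)

  freq <- tabulate(unlist(sampleTexture(sp, 0, 50, burnIn = 10, seed = 9)) + 1L, 3)
  n <- sum(freq)
  se <- sqrt(1 / 3 * 2 / 3 / n)
  expect_true(all(abs(freq / n - 1 / 3) < 3 * se))

  # deep in the ordered phase the order parameter is near 1
  ordered <- sampleTexture(sp, 5, 10, burnIn = 2000, seed = 10)
  m <- mean(vapply(ordered, function(x) orderValue(orderParameter(x, sp)),
                   numeric(1)))
  expect_gt(m, 0.9)
})

test_that("exact enumeration is a valid probability table", {
  sp2 <- builtinSpecs(c(2L, 2L))$potts
  en <- enumerateBoltzmann(sp2, 0)
  expect_equal(nrow(en$states), 81)
  expect_equal(en$prob, rep(1 / 81, 81))
  expect_equal(sum(enumerateBoltzmann(sp2, 0.8)$prob), 1)
  expect_error(enumerateBoltzmann(builtinSpecs(c(8L, 8L))$potts, 0.5),
               "too large")

  # probabilities are invariant under cyclic translation: row i of the
  # enumeration is configuration id i, so index by the rolled ids
  en <- enumerateBoltzmann(sp2, 0.6)
  rolled <- t(apply(en$states, 1, function(s) {
    as.vector(rollMatrix(matrix(s, 2, 2), 1, 0))
  }))
  idsR <- ordtex:::.configIds(rolled, 3L)
  expect_equal(en$prob, en$prob[idsR], tolerance = 1e-12)
})

test_that("gibbs samples match exact enumeration on a tiny lattice", {
  sp2 <- builtinSpecs(c(2L, 2L))$potts
  en <- enumerateBoltzmann(sp2, 0.7)
  flat <- ordtex:::.sampleTextureFlat(sp2, 0.7, 2e4, burnIn = 500,
                                      thin = 10, seed = 31)
  counts <- tabulate(ordtex:::.configIds(flat, 3L), nbins = 81)
  gof <- gofChisq(counts, en$prob)
  expect_gt(gof$p.value, 0.001)

  # mean energy agrees with the exact Boltzmann mean within Monte Carlo error
  sampled <- en$energy[ordtex:::.configIds(flat, 3L)]
  exactMean <- sum(en$prob * en$energy)
  se <- sd(sampled) / sqrt(length(sampled))  # thinned draws ~ independent
  expect_lt(abs(mean(sampled) - exactMean), 5 * se)
})

test_that("distractors have the required marginals", {
  sp <- builtinSpecs()$potts
  set.seed(41)
  target <- randomConfig(sp)
  perm <- makeDistractor(sp, "permuted", target = target)
  expect_identical(sort(as.vector(perm)), sort(as.vector(target)))
  expect_error(makeDistractor(sp, "permuted"), "target")

  set.seed(42); p1 <- makeDistractor(sp, "permuted", target = target)
  set.seed(42); p2 <- makeDistractor(sp, "permuted", target = target)
  expect_identical(p1, p2)

  set.seed(43)
  counts <- numeric(3)
  for (i in 1:30) counts <- counts + tabulate(makeDistractor(sp, "uniform") + 1L, 3)
  n <- sum(counts)
  se <- sqrt(1 / 3 * 2 / 3 / n)
  expect_true(all(abs(counts / n - 1 / 3) < 3 * se))
})
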