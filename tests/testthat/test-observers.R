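test_that("luminance statistic counts states and ignores geometry", {
  cfg <- matrix(0L, 32, 32)
  st <- luminanceStatistic(cfg)
  expect_equal(statValues(st), c(1024, 0, 0))
  sp <- builtinSpecs()$potts
  set.seed(3)
  target <- randomConfig(sp)
  perm <- makeDistractor(sp, "permuted", target = target)
  expect_equal(statValues(luminanceStatistic(perm)),
               statValues(luminanceStatistic(target)))
})

test_that("pair statistic matches brute force and reconstructs the energy", {
  sp <- builtinSpecs()$potts
  st <- pairStatistic(matrix(0L, 32, 32), sp)
  v <- statValues(st)
  expect_equal(v[1], 1024)          # (0,0) cell of the first offset
  expect_equal(v[10], 1024)         # (0,0) cell of the second offset
  expect_equal(sum(v), 2048)

  asp <- asymSpec()
  set.seed(23)
  for (i in 1:5) {
    cfg <- randomConfig(asp)
    v <- statValues(pairStatistic(cfg, asp))
    expect_equal(v, brutePairCounts(cfg, asp))
    # energy is a linear functional of the pair counts
    uvec <- unlist(lapply(potentials(asp), as.vector))
    expect_equal(sum(v * uvec), latticeEnergy(cfg, asp))
  }
})

test_that("channel energy map responds selectively to matched gratings", {
  g <- gaborSpec(sigma = 0.085, freq = 6.87, theta = 22.5, pixelScale = 80)
  k <- gaborKernels(g)
  expect_equal(sum(k$odd), 0)              # exact zero DC by antisymmetry
  expect_equal(dim(k$even), dim(k$odd))

  zero <- matrix(0, 200, 200)
  expect_equal(channelEnergyMap(zero, g), zero)
  expect_error(channelEnergyMap(matrix(0, 10, 10), g), "smaller")

  grating <- function(theta, n = 200, ps = 80, f = 6.87) {
    x <- outer(rep(1, n), seq_len(n)) / ps
    y <- outer(seq_len(n), rep(1, n)) / ps
    th <- theta * pi / 180
    sin(2 * pi * f * (x * cos(th) + y * sin(th)))
  }
  M <- channelEnergyMap(grating(22.5), g)
  expect_true(all(M >= 0))
  # away from a 3-sigma border margin the energy of a matched grating is
  # spatially uniform: the quadrature pair is phase invariant
  margin <- ceiling(3 * 0.085 * 80)
  interior <- M[(margin + 1):(200 - margin), (margin + 1):(200 - margin)]
  expect_lt((max(interior) - min(interior)) / median(interior), 0.01)

  Mo <- channelEnergyMap(grating(112.5), g)
  expect_gt(sum(M) / sum(Mo), 10)
})

test_that("channel energy map commutes with quarter-turn rotations", {
  g0 <- gaborSpec(0.085, 6.87, 30, 80)
  g90 <- gaborSpec(0.085, 6.87, 120, 80)
  set.seed(31)
  img <- matrix(runif(150 * 150), 150, 150)
  M0 <- channelEnergyMap(img, g0)
  # rotate image by 90 degrees, filter with the rotated orientation,
  # rotate the map back
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  unrot <- function(m) t(m[nrow(m):1, , drop = FALSE])
  M90 <- unrot(channelEnergyMap(rot90(img), g90))
  expect_equal(M90, M0, tolerance = 1e-6)
})

test_that("quadrant energies are exchange symmetric", {
  g <- gaborSpec(0.1, 5, 45, 60)
  expect_equal(sapply(1:4, function(q) quadrantEnergy(matrix(0, 120, 120), q, g)),
               rep(0, 4))
  set.seed(7)
  a <- matrix(runif(60 * 60), 60, 60)
  b <- matrix(runif(60 * 60), 60, 60)
  d1 <- rbind(cbind(a, b), cbind(b, a))
  d2 <- rbind(cbind(b, a), cbind(a, b))   # quadrants 1<->2 and 3<->4 swapped
  e1 <- sapply(1:4, function(q) quadrantEnergy(d1, q, g))
  e2 <- sapply(1:4, function(q) quadrantEnergy(d2, q, g))
  expect_equal(e1[c(2, 1, 4, 3)], e2)
  # identical textures in all quadrants: four equal energies
  d3 <- rbind(cbind(a, a), cbind(a, a))
  e3 <- sapply(1:4, function(q) quadrantEnergy(d3, q, g))
  expect_equal(max(e3) - min(e3), 0)
  expect_error(quadrantEnergy(d1, 5, g), "quadrant")
})

test_that("density fits recover known densities and handle degeneracy", {
  set.seed(11)
  x <- rnorm(10000)
  kde <- fitDensity(x, "kde")
  expect_lt(abs(evalDensity(kde, 0) - dnorm(0)) / dnorm(0), 0.1)
  # the fitted density integrates to ~1 on a 1-D grid
  grid <- seq(-5, 5, by = 0.01)
  expect_equal(sum(evalDensity(kde, matrix(grid)) * 0.01), 1, tolerance = 0.02)
  expect_true(all(evalDensity(kde, matrix(seq(-10, 10, 0.5))) >= 0))

  gs <- fitDensity(cbind(rnorm(5000, 2, 3), rnorm(5000, -1, 0.5)), "gaussian")
  expect_equal(gs@mean, c(2, -1), tolerance = 0.2)
  expect_equal(gs@sd, c(3, 0.5), tolerance = 0.2)

  expect_warning(const <- fitDensity(rep(1, 50), "kde"), "zero-variance")
  expect_true(is.finite(logDensity(const, 1)))
  expect_gt(evalDensity(const, 1), evalDensity(const, 2))
  expect_error(fitDensity(1, "kde"), "2 samples")
  expect_error(fitDensity(c(1, NA), "kde"), "finite")
})

test_that("whitened KDE respects correlations and stays a proper density", {
  set.seed(12)
  z <- rnorm(4000)
  x <- cbind(z + rnorm(4000, sd = 0.1), z)   # strongly correlated pair
  m <- fitDensity(x, "kde", whiten = TRUE)
  # density must be much higher on the ridge than off it
  expect_gt(logDensity(m, c(1, 1)), logDensity(m, c(1, -1)) + 5)
})

test_that("the 4AFC rule reproduces chance, certainty, and the mAFC integral", {
  set.seed(13)
  ref <- fitDensity(rnorm(500), "kde")
  # identical densities and identical statistics: pure tie-breaking
  same <- matrix(0.3, 4, 1)
  picks <- replicate(4000, decide4AFC(same, ref, ref))
  expect_lt(abs(mean(picks == 1) - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))

  # disjoint supports: always correct
  ft <- fitDensity(rnorm(200, 50, 0.1), "gaussian")
  fd <- fitDensity(rnorm(200, 0, 0.1), "gaussian")
  for (i in 1:20) {
    stats <- matrix(c(50, 0, 0, 0) + rnorm(4, 0, 0.1), 4, 1)
    expect_equal(decide4AFC(stats, ft, fd), 1L)
  }

  # N(d', 1) target vs N(0, 1) distractors: proportion correct equals
  # integral of phi(x - d') Phi(x)^3 dx
  dprime <- 1.5
  pc <- integrate(function(x) dnorm(x - dprime) * pnorm(x)^3, -Inf, Inf)$value
  ft <- new("DensityModel", kind = "gaussian", samples = matrix(0, 0, 1),
            bandwidths = numeric(0), mean = dprime, sd = 1,
            whiten = matrix(0, 0, 0), center = numeric(0), logJac = 0,
            trainingN = 1000L, dims = 1L)
  fd <- new("DensityModel", kind = "gaussian", samples = matrix(0, 0, 1),
            bandwidths = numeric(0), mean = 0, sd = 1,
            whiten = matrix(0, 0, 0), center = numeric(0), logJac = 0,
            trainingN = 1000L, dims = 1L)
  set.seed(14)
  n <- 4000
  sim <- replicate(n, {
    stats <- matrix(c(rnorm(1, dprime), rnorm(3)), 4, 1)
    decide4AFC(stats, ft, fd) == 1L
  })
  expect_lt(abs(mean(sim) - pc), 3 * sqrt(pc * (1 - pc) / n))
  expect_error(decide4AFC(matrix(0, 3, 1), ft, fd), "4 quadrant")
})

test_that("the analytic ideal rule picks the minimum-energy quadrant", {
  sp <- builtinSpecs()$potts
  ground <- groundStateOrbit(sp)[[1]]
  set.seed(15)
  for (i in 1:25) {
    pos <- sample.int(4, 1)
    arr <- replicate(4, makeDistractor(sp, "uniform"), simplify = FALSE)
    arr[[pos]] <- ground
    expect_equal(analyticIdealDecide(arr, sp, 0.5), pos)
  }
  expect_warning(res <- analyticIdealDecide(list(ground, ground, ground, ground),
                                            sp, 0), "undefined")
  expect_true(is.na(res))
})
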