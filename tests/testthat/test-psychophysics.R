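test_that("single trials are at chance when target and distractors coincide", {
  sp <- builtinSpecs(c(8L, 8L))$potts
  obs <- trainObserver(sp, 0, "order", "uniform", nTrain = 200, seed = 51,
                       burnIn = 50, thin = 1)
  set.seed(52)
  correct <- replicate(400, {
    target <- makeDistractor(sp, "uniform")  # beta = 0 target is uniform
    simulateTrial(sp, 0, obs, "uniform", target = target)
  })
  expect_lt(abs(mean(correct) - 0.25), 3 * sqrt(0.25 * 0.75 / 400))

  # seeded runs are reproducible
  target <- makeDistractor(sp, "uniform")
  set.seed(53); r1 <- simulateTrial(sp, 0, obs, "uniform", target = target)
  set.seed(53); r2 <- simulateTrial(sp, 0, obs, "uniform", target = target)
  expect_identical(r1, r2)

  # an untrained density observer is rejected
  fake <- new("Observer", kind = "luminance", specName = "potts", beta = 0,
              mode = "uniform", targetDensity = NULL,
              distractorDensity = NULL, aux = list())
  expect_error(simulateTrial(sp, 0, fake, "uniform", target = target),
               "untrained")
})

test_that("permuted distractors force the luminance observer to chance", {
  # the luminance statistic of a permuted distractor equals the target's,
  # so every trial is a 4-way tie regardless of beta
  sp <- builtinSpecs(c(8L, 8L))$potts
  cv <- performanceCurve(sp, "luminance", betaGrid = c(0.3, 1),
                         nTrials = 500, nTrain = 120, mode = "permuted",
                         seed = 54, burnIn = 200, thin = 2)
  for (p in pCorrect(cv)) {
    expect_lt(abs(p - 0.25), 3 * sqrt(0.25 * 0.75 / 500))
  }
})

test_that("performance curves carry recoverable counts and standard errors", {
  sp <- builtinSpecs(c(8L, 8L))$potts
  cv <- performanceCurve(sp, "ideal_analytic", betaGrid = c(0, 0.5, 1.5),
                         nTrials = 200, seed = 55, burnIn = 200, thin = 2)
  expect_s4_class(cv, "PsychometricCurve")
  k <- pCorrect(cv) * nTrials(cv)
  expect_equal(k, round(k))
  expect_equal(curveSE(cv), sqrt(pCorrect(cv) * (1 - pCorrect(cv)) / 200))
  df <- as.data.frame(cv)
  expect_named(df, c("observer", "mode", "beta", "n", "k", "p", "se"))
  # deep order: the exact rule is near perfect
  expect_gt(pCorrect(cv)[3], 0.9)
  expect_lt(abs(pCorrect(cv)[1] - 0.25), 3 * sqrt(0.25 * 0.75 / 200))
})

test_that("threshold extraction follows log-beta interpolation", {
  mk <- function(beta, p, n = 1000) {
    new("PsychometricCurve", betaGrid = beta, pCorrect = round(p * n) / n,
        nTrials = rep(as.integer(n), length(beta)),
        se = sqrt(p * (1 - p) / n), observerId = "test",
        mode = "uniform_distractor")
  }
  # level 0.625 halfway between 0.50 and 0.75: geometric mean of the betas
  cv <- mk(c(0.3, 0.5), c(0.5, 0.75))
  expect_equal(as.numeric(estimateThreshold(cv)), sqrt(0.15), tolerance = 1e-10)
  # flat chance curve: undefined
  flat <- mk(c(0.1, 0.5, 1), rep(0.25, 3))
  expect_true(is.na(estimateThreshold(flat)))
  # a grid point exactly at the level is returned as-is
  exact <- mk(c(0.1, 0.2, 0.4), c(0.25, 0.625, 0.9))
  expect_equal(as.numeric(estimateThreshold(exact)), 0.2)
  expect_error(estimateThreshold(cv, level = 0.2))
})

test_that("thresholds are recovered from a synthetic logistic curve", {
  beta0 <- 0.3   # true 62.5%-correct point
  grid <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)
  p <- 0.25 + 0.75 * plogis((log(grid) - log(beta0)) / 0.4)
  n <- 10000
  cv <- new("PsychometricCurve", betaGrid = grid, pCorrect = round(p * n) / n,
            nTrials = rep(as.integer(n), length(grid)),
            se = sqrt(p * (1 - p) / n), observerId = "logistic",
            mode = "uniform_distractor")
  thr <- estimateThreshold(cv)
  # within the grid interval containing the true threshold
  expect_gt(thr, 0.2)
  expect_lt(thr, 0.4)
})

test_that("chi-squared curve comparison matches the pooled 2x2 statistic", {
  mk <- function(k, n = 1000) {
    new("PsychometricCurve", betaGrid = seq_along(k), pCorrect = k / n,
        nTrials = rep(as.integer(n), length(k)), se = sqrt(k / n * (1 - k / n) / n),
        observerId = "x", mode = "uniform_distractor")
  }
  a <- mk(c(300, 500, 900))
  expect_equal(chi2Compare(a, a), list(chi2 = 0, dof = 3, p = 1))

  # one level differing 900/1000 vs 500/1000: hand-computed pooled statistic
  b <- mk(c(300, 500, 500))
  phat <- (900 + 500) / 2000
  hand <- (0.9 - 0.5)^2 / (phat * (1 - phat) * (2 / 1000))
  cc <- chi2Compare(a, b)
  expect_equal(cc$chi2, hand)
  expect_equal(cc$p, pchisq(hand, 3, lower.tail = FALSE))
  # symmetry and configurable dof
  expect_equal(chi2Compare(b, a)$chi2, cc$chi2)
  expect_equal(chi2Compare(a, b, dof = 9)$dof, 9)
  wrong <- mk(c(300, 500))
  expect_error(chi2Compare(a, wrong), "grid")
})

test_that("derived seeds make curves independently reproducible", {
  sp <- builtinSpecs(c(8L, 8L))$potts
  c1 <- performanceCurve(sp, "ideal_analytic", betaGrid = c(0.4, 0.8),
                         nTrials = 100, seed = 77, burnIn = 100, thin = 1)
  c2 <- performanceCurve(sp, "ideal_analytic", betaGrid = c(0.4, 0.8),
                         nTrials = 100, seed = 77, burnIn = 100, thin = 1)
  expect_identical(pCorrect(c1), pCorrect(c2))
  # a single beta recomputed alone gives the same value as within the grid
  c3 <- performanceCurve(sp, "ideal_analytic", betaGrid = 0.8,
                         nTrials = 100, seed = 77, burnIn = 100, thin = 1)
  expect_identical(pCorrect(c3), pCorrect(c1)[2])
})
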