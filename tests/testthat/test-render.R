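test_that("rendered blobs have the mapped peak amplitudes and total luminance", {
  rs <- renderSpec(pixelScale = 80)
  sp <- builtinSpecs(c(8L, 8L))$potts
  cfg0 <- matrix(0L, 8, 8)
  img <- renderTexture(cfg0, rs)
  side <- round(8 * rs@blobSpacing * 80)
  expect_equal(dim(img), c(side, side))
  cell <- rs@blobSpacing * 80
  # peak added luminance at each blob centre ~ a1 (discretisation tolerance)
  for (p in c(1, 4, 8)) for (q in c(1, 5)) {
    cy <- round((p - 0.5) * cell); cx <- round((q - 0.5) * cell)
    patch <- img[max(1, cy - 2):min(side, cy + 2),
                 max(1, cx - 2):min(side, cx + 2)]
    # the nearest pixel centre can sit 0.5 px off the blob centre in each
    # axis: attenuation up to exp(-0.25/(2 sigma^2)) ~ 6% at sigma = 2 px
    expect_equal(max(patch) - rs@background, rs@amplitudeMap[1],
                 tolerance = 0.08)
  }
  # total added luminance ~ sum over blobs of amplitude * 2 pi sigma^2
  set.seed(61)
  cfg <- randomConfig(sp)
  img2 <- renderTexture(cfg, rs)
  sig <- rs@blobSigma * 80
  expected <- sum(rs@amplitudeMap[cfg + 1L]) * 2 * pi * sig^2
  measured <- sum(img2) - rs@background * length(img2)
  expect_equal(measured, expected, tolerance = 0.01)
  # deterministic
  expect_identical(img2, renderTexture(cfg, rs))
  # too-coarse pixel scale violates the sigma >= 2 px invariant
  expect_error(renderSpec(pixelScale = 20), "coarse")
})

test_that("attached displays tile four quadrants and record the target", {
  rs <- renderSpec(pixelScale = 80)
  sp <- builtinSpecs(c(8L, 8L))$potts
  set.seed(62)
  imgs <- replicate(4, renderTexture(randomConfig(sp), rs), simplify = FALSE)
  res <- composeDisplay(imgs[[1]], imgs[2:4], rs, targetQuadrant = 3)
  expect_equal(res$manifest$targetQuadrant, 3L)
  n <- nrow(imgs[[1]])
  expect_equal(dim(res$image), c(2 * n, 2 * n))
  expect_equal(res$image[n + seq_len(n), seq_len(n)], imgs[[1]])
  expect_error(composeDisplay(imgs[[1]], imgs[2:3], rs), "3")

  # random placement is uniform over the four quadrants
  set.seed(63)
  qs <- replicate(400, composeDisplay(imgs[[1]], imgs[2:4], rs)$manifest$targetQuadrant)
  expect_gt(chisq.test(tabulate(qs, 4))$p.value, 0.001)
})

test_that("gapped displays centre quadrants at the configured eccentricity", {
  rs <- renderSpec(pixelScale = 80, layout = "gapped", eccentricity = 2)
  sp <- builtinSpecs(c(8L, 8L))$potts
  set.seed(64)
  imgs <- replicate(4, renderTexture(randomConfig(sp), rs), simplify = FALSE)
  res <- composeDisplay(imgs[[1]], imgs[2:4], rs, targetQuadrant = 1)
  expect_equal(res$manifest$layout, "gapped")
  expect_true(all(dim(res$image) > dim(imgs[[1]])))
  # the display contains each quadrant image exactly, on uniform background
  n <- nrow(imgs[[1]])
  off <- 2 / sqrt(2) * 80
  half <- ceiling(off + n / 2) + 1
  r0 <- round(half - off - n / 2); c0 <- round(half - off - n / 2)
  expect_equal(res$image[r0 + seq_len(n), c0 + seq_len(n)], imgs[[1]])
  expect_equal(res$image[1, 1], rs@background)
})

test_that("render-then-measure preserves the luminance ordering", {
  rs <- renderSpec(pixelScale = 80)
  sp <- builtinSpecs(c(8L, 8L))$potts
  set.seed(65)
  cfgs <- replicate(4, randomConfig(sp), simplify = FALSE)
  latticeLum <- sapply(cfgs, function(cf) sum(rs@amplitudeMap[cf + 1L]))
  imageLum <- sapply(cfgs, function(cf) sum(renderTexture(cf, rs)))
  expect_equal(order(latticeLum), order(imageLum))
})

test_that("images and archives round-trip through disk", {
  rs <- renderSpec(pixelScale = 80)
  sp <- builtinSpecs(c(8L, 8L))$potts
  set.seed(66)
  img <- renderTexture(randomConfig(sp), rs)
  path <- file.path(tempdir(), "tex.png")
  writeImagePNG(img, path, maxLuminance = 1.2)
  expect_true(file.exists(path))
  back <- png::readPNG(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back * 1.2 - img)), 1.2 / 255)  # 8-bit quantisation

  samples <- sampleTexture(sp, 0.4, 6, burnIn = 100, seed = 67)
  base <- file.path(tempdir(), "arch")
  writeSampleArchive(samples, base, sp, 0.4, seed = 67, burnIn = 100, thin = 5)
  arch <- readSampleArchive(base)
  expect_identical(arch$samples, samples)
  expect_equal(arch$meta$beta, 0.4)
  expect_equal(arch$meta$spec, "potts")

  rpath <- file.path(tempdir(), "render.yaml")
  writeRenderSpec(rs, rpath)
  rs2 <- readRenderSpec(rpath)
  expect_equal(rs2@blobSigma, rs@blobSigma)
  expect_equal(rs2@amplitudeMap, rs@amplitudeMap)
  expect_equal(rs2@layout, rs@layout)
})
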