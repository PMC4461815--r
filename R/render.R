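#' Construct a render specification
#'
#' Defaults follow the constant-stimuli geometry: 32-blob quadrants 4.84
#' degrees across (blob spacing 4.84/32 degrees), blob sigma 1.5 arcmin,
#' amplitudes (26, 56, 91) cd/m^2 on a 14 cd/m^2 background normalised by
#' 100 cd/m^2, and 120 px/degree so the blob sigma spans 3 pixels.
#'
#' @param blobSigma blob Gaussian sigma, degrees (default 1.5/60).
#' @param blobSpacing centre-to-centre blob distance, degrees.
#' @param amplitudeMap increasing peak added luminances for the states.
#' @param background background luminance.
#' @param pixelScale pixels per degree.
#' @param layout "attached" or "gapped".
#' @param eccentricity quadrant-centre eccentricity for the gapped layout,
#'   degrees (default 4).
#' @return a [RenderSpec-class].
#' @export
renderSpec <- function(blobSigma = 1.5 / 60, blobSpacing = 4.84 / 32,
                       amplitudeMap = c(0.26, 0.56, 0.91),
                       background = 0.14, pixelScale = 120,
                       layout = c("attached", "gapped"),
                       eccentricity = 4) {
  layout <- match.arg(layout)
  new("RenderSpec", blobSigma = blobSigma, blobSpacing = blobSpacing,
      amplitudeMap = amplitudeMap, background = background,
      pixelScale = pixelScale, layout = layout, eccentricity = eccentricity)
}

#' Render a lattice as a Gaussian-blob luminance image
#'
#' Each lattice site becomes a circularly symmetric Gaussian blob at the
#' centre of its grid cell, added to the uniform background; the blob's
#' peak added luminance is \code{amplitudeMap[state + 1]}. Blob stamps are
#' truncated at +/- 4 sigma so the truncated mass (< 0.04%) is negligible
#' against the analytic Gaussian integral. Rendering is deterministic.
#'
#' @param config H x W integer matrix of states.
#' @param rspec a [RenderSpec-class].
#' @return numeric luminance matrix of side
#'   \code{round(H * blobSpacing * pixelScale)}.
#' @export
renderTexture <- function(config, rspec) {
  stopifnot(is(rspec, "RenderSpec"))
  msg <- validObject(rspec, test = TRUE)
  if (is.character(msg)) stop(msg, call. = FALSE)
  H <- nrow(config); W <- ncol(config)
  ps <- rspec@pixelScale
  cell <- rspec@blobSpacing * ps         # pixels per lattice cell
  nr <- round(H * cell); nc <- round(W * cell)
  sig <- rspec@blobSigma * ps            # blob sigma in pixels
  hw <- ceiling(4 * sig)
  img <- matrix(rspec@background, nr, nc)
  amps <- rspec@amplitudeMap
  for (p in seq_len(H)) {
    cy <- (p - 0.5) * cell               # blob centre, pixel units
    ry <- max(1L, floor(cy - hw)):min(nr, ceiling(cy + hw))
    gy <- exp(-((ry - 0.5) - cy)^2 / (2 * sig^2))
    for (q in seq_len(W)) {
      cx <- (q - 0.5) * cell
      rx <- max(1L, floor(cx - hw)):min(nc, ceiling(cx + hw))
      gx <- exp(-((rx - 0.5) - cx)^2 / (2 * sig^2))
      img[ry, rx] <- img[ry, rx] + amps[config[p, q] + 1L] * outer(gy, gx)
    }
  }
  img
}

#' Compose a four-quadrant 4AFC display
#'
#' "attached": the four images abut without overlap, forming one doubled
#' blob grid (64 x 64 blobs for 32 x 32 inputs) around the central fixation
#' point. "gapped": the four images are placed on a uniform background with
#' their centres at the configured eccentricity from fixation, along the
#' diagonals.
#'
#' @param targetImg rendered target image.
#' @param distractorImgs list of 3 rendered distractor images, same size.
#' @param rspec a [RenderSpec-class].
#' @param targetQuadrant 1 = top-left, 2 = top-right, 3 = bottom-left,
#'   4 = bottom-right; drawn uniformly at random when NULL.
#' @return list with \code{image} and \code{manifest} (layout, target
#'   quadrant, image size).
#' @export
composeDisplay <- function(targetImg, distractorImgs, rspec,
                           targetQuadrant = NULL) {
  stopifnot(length(distractorImgs) == 3L)
  dims <- vapply(c(list(targetImg), distractorImgs), dim, integer(2L))
  if (any(dims != dims[, 1L]))
    stop("all four images must have the same size")
  if (is.null(targetQuadrant)) targetQuadrant <- sample.int(4L, 1L)
  stopifnot(targetQuadrant %in% 1:4)
  imgs <- vector("list", 4L)
  imgs[[targetQuadrant]] <- targetImg
  imgs[setdiff(1:4, targetQuadrant)] <- distractorImgs
  nr <- nrow(targetImg); nc <- ncol(targetImg)
  if (rspec@layout == "attached") {
    display <- rbind(cbind(imgs[[1L]], imgs[[2L]]),
                     cbind(imgs[[3L]], imgs[[4L]]))
  } else {
    ps <- rspec@pixelScale
    off <- rspec@eccentricity / sqrt(2) * ps   # diagonal placement
    half <- ceiling(off + max(nr, nc) / 2) + 1L
    side <- 2L * half
    display <- matrix(rspec@background, side, side)
    centers <- rbind(c(-off, -off), c(-off, off), c(off, -off), c(off, off))
    for (qd in 1:4) {
      r0 <- round(half + centers[qd, 1L] - nr / 2)
      c0 <- round(half + centers[qd, 2L] - nc / 2)
      display[r0 + seq_len(nr), c0 + seq_len(nc)] <- imgs[[qd]]
    }
  }
  list(image = display,
       manifest = list(layout = rspec@layout,
                       targetQuadrant = as.integer(targetQuadrant),
                       quadrantSize = c(nr, nc),
                       displaySize = dim(display)))
}

#' Export a luminance image to 8-bit PNG
#'
#' @param image numeric luminance matrix.
#' @param path output file path.
#' @param maxLuminance white point; defaults to the image maximum.
#' @return the path, invisibly.
#' @export
writeImagePNG <- function(image, path, maxLuminance = NULL) {
  if (is.null(maxLuminance)) maxLuminance <- max(image)
  if (maxLuminance <= 0) maxLuminance <- 1
  png::writePNG(pmin(pmax(image / maxLuminance, 0), 1), path)
  invisible(path)
}

#' Export a luminance image to TIFF
#'
#' @inheritParams writeImagePNG
#' @export
writeImageTIFF <- function(image, path, maxLuminance = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  if (is.null(maxLuminance)) maxLuminance <- max(image)
  if (maxLuminance <= 0) maxLuminance <- 1
  tiff::writeTIFF(pmin(pmax(image / maxLuminance, 0), 1), path)
  invisible(path)
}
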