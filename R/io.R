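# serialise a spec to the plain-list config schema (offsets as [dy,dx]
# lists, potentials as row-major nested lists in offset order)
.specToList <- function(spec) {
  out <- list(
    name = spec@name,
    n_states = spec@nStates,
    lattice_shape = as.integer(spec@latticeShape),
    offsets = lapply(seq_len(nrow(spec@offsets)), function(i)
      as.integer(spec@offsets[i, ])),
    potentials = lapply(spec@potentials, function(U)
      lapply(seq_len(nrow(U)), function(r) as.numeric(U[r, ]))),
    beta_grid = as.numeric(spec@betaGrid)
  )
  if (!is.null(spec@groundStateTile)) {
    tl <- spec@groundStateTile
    out$ground_state_tile <- lapply(seq_len(nrow(tl)), function(r)
      as.integer(tl[r, ]))
  }
  out
}

.specFromList <- function(x) {
  pots <- lapply(x$potentials, function(rows)
    do.call(rbind, lapply(rows, as.numeric)))
  tile <- if (!is.null(x$ground_state_tile))
    do.call(rbind, lapply(x$ground_state_tile, as.integer)) else NULL
  textureSetSpec(name = x$name,
                 offsets = lapply(x$offsets, as.integer),
                 potentials = pots,
                 nStates = x$n_states,
                 latticeShape = as.integer(unlist(x$lattice_shape)),
                 betaGrid = as.numeric(unlist(x$beta_grid)),
                 groundStateTile = tile)
}

#' Read / write texture set configuration files
#'
#' Texture sets round-trip losslessly through YAML (.yaml/.yml) or JSON
#' config files with keys \code{name}, \code{n_states},
#' \code{lattice_shape}, \code{offsets} (list of [dy, dx]),
#' \code{potentials} (row-major matrices, same order as the offsets),
#' \code{beta_grid} and optional \code{ground_state_tile}.
#'
#' @param spec a [TextureSetSpec-class].
#' @param path config file path; the extension selects the format.
#' @return \code{readTextureSet} returns a validated
#'   [TextureSetSpec-class]; \code{writeTextureSet} returns the path,
#'   invisibly.
#' @export
writeTextureSet <- function(spec, path) {
  validateTextureSet(spec)
  x <- .specToList(spec)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname writeTextureSet
#' @export
readTextureSet <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  validateTextureSet(.specFromList(x))
}

#' Read / write render specification config files
#'
#' @param rspec a [RenderSpec-class].
#' @param path config file path (YAML or JSON by extension).
#' @return the path (write) or a [RenderSpec-class] (read).
#' @export
writeRenderSpec <- function(rspec, path) {
  x <- list(blob_sigma_deg = rspec@blobSigma,
            blob_spacing_deg = rspec@blobSpacing,
            amplitude_map = as.numeric(rspec@amplitudeMap),
            background = rspec@background,
            pixel_scale = rspec@pixelScale,
            layout = rspec@layout,
            eccentricity_deg = rspec@eccentricity)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname writeRenderSpec
#' @export
readRenderSpec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  renderSpec(blobSigma = x$blob_sigma_deg, blobSpacing = x$blob_spacing_deg,
             amplitudeMap = as.numeric(unlist(x$amplitude_map)),
             background = x$background, pixelScale = x$pixel_scale,
             layout = x$layout, eccentricity = x$eccentricity_deg)
}

#' Write / read a sample archive
#'
#' Samples are stored as a gzip-compressed CSV of flattened (column-major)
#' integer lattices, one row per sample, together with a JSON sidecar
#' recording the set name, lattice shape, beta, seed and sweep settings, so
#' observer training and testing sets are reproducible artifacts.
#'
#' @param samples list of lattice matrices (as from [sampleTexture()]).
#' @param basePath path without extension; \code{<basePath>.csv.gz} and
#'   \code{<basePath>.json} are written.
#' @param spec the [TextureSetSpec-class] the samples were drawn from.
#' @param beta,seed,burnIn,thin sampling metadata recorded in the sidecar.
#' @return \code{basePath}, invisibly.
#' @export
writeSampleArchive <- function(samples, basePath, spec, beta,
                               seed = NA_integer_, burnIn = NA_integer_,
                               thin = NA_integer_) {
  flat <- do.call(rbind, lapply(samples, as.vector))
  con <- gzfile(paste0(basePath, ".csv.gz"), "w")
  utils::write.table(flat, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  close(con)
  meta <- list(spec = spec@name, lattice_shape = as.integer(spec@latticeShape),
               n_states = spec@nStates, beta = beta, n_samples = length(samples),
               seed = seed, burn_in = burnIn, thin = thin,
               package_version = as.character(utils::packageVersion("ordtex")))
  jsonlite::write_json(meta, paste0(basePath, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(basePath)
}

#' @rdname writeSampleArchive
#' @export
readSampleArchive <- function(basePath) {
  meta <- jsonlite::read_json(paste0(basePath, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(gzfile(paste0(basePath, ".csv.gz")),
                                      sep = ",", header = FALSE))
  dimnames(flat) <- NULL
  storage.mode(flat) <- "integer"
  H <- meta$lattice_shape[1L]; W <- meta$lattice_shape[2L]
  samples <- lapply(seq_len(nrow(flat)), function(i) matrix(flat[i, ], H, W))
  list(samples = samples, meta = meta)
}

#' Write a psychometric curve to CSV
#'
#' Columns: observer, mode, beta, n, k, p, se.
#'
#' @param curve a [PsychometricCurve-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeCurveCSV <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
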