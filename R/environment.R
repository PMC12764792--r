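#' Specification for the synthetic five-layer environment
#'
#' Describes a synthetic landscape emulating the structure of the real
#' raster stack the simulator is designed for: three bioclimatic layers that
#' are nearly uniform at the micro scale of the workspace, and two soil
#' layers whose spatial patchiness restricts where plants can live. Each
#' layer is a smoothed Gaussian random field with a given mean, amplitude
#' (its standard deviation across the grid) and spatial correlation length.
#'
#' The default means and amplitudes are loosely styled on February solar
#' radiation (kJ m-2 day-1), isothermality (\%), annual precipitation (mm),
#' available soil water capacity (v\%) and soil organic carbon (g kg-1), and
#' are calibrated jointly with the default tolerance limits of [simConfig()]
#' so that the area suitable for the founding diploid genotypes is a
#' contiguous minority of the workspace supporting a quasi-equilibrium
#' census on the order of a thousand plants.
#'
#' @param width,height grid dimensions in patches.
#' @param means,amplitudes,corLengths numeric(5) per-layer field mean,
#'   standard deviation, and correlation length in patches. Amplitude 0
#'   gives a perfectly uniform layer.
#' @param trends numeric(5) radial trend slopes (units per patch of
#'   distance from the grid centre). Real soil maps carry large-scale
#'   gradients on top of their patchiness; the radial trend makes
#'   environmental dissimilarity grow with distance from the founder
#'   region, so the suitable area is a bounded core and "distant" optima
#'   are genuinely different. 0 gives a stationary layer.
#' @param patchArea patch area in m^2.
#' @return a list with class \code{"SyntheticEnvSpec"}.
#' @export
syntheticEnvSpec <- function(width = 100L, height = 100L,
                             means = c(180, 55, 1100, 15, 9),
                             amplitudes = c(0.35, 0.10, 2.0, 0.55, 0.35),
                             corLengths = c(60, 60, 60, 15, 15),
                             trends = c(0, 0, 0, 0.100, 0.065),
                             patchArea = 0.25) {
  if (any(corLengths <= 0)) stop("correlation lengths must be positive")
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative")
  if (width < 1 || height < 1) stop("grid dimensions must be positive")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         means = means, amplitudes = amplitudes, corLengths = corLengths,
         trends = trends, patchArea = patchArea),
    class = "SyntheticEnvSpec"
  )
}

# Smooth unit-variance Gaussian random field by circular FFT convolution of
# white noise with a Gaussian kernel (sd = correlation length).
.gaussianField <- function(nx, ny, corLength) {
  w <- matrix(rnorm(nx * ny), nx, ny)
  dx <- pmin(0:(nx - 1), nx - 0:(nx - 1))
  dy <- pmin(0:(ny - 1), ny - 0:(ny - 1))
  kern <- exp(-outer(dx^2, dy^2, "+") / (2 * corLength^2))
  kern <- kern / sum(kern)
  sm <- Re(fft(fft(w) * fft(kern), inverse = TRUE)) / (nx * ny)
  (sm - mean(sm)) / sd(sm)
}

#' Generate a synthetic environment
#'
#' Builds an [EnvironmentGrid-class] from a [syntheticEnvSpec()]. Each layer
#' is a smoothed Gaussian random field re-centred so that the average over
#' the central founder block equals the layer mean; founders placed centrally
#' therefore sit near the field optimum, and the suitable region is a
#' contiguous patchy subset of the grid determined mainly by the two
#' short-correlation soil layers. The same spec and seed always reproduce
#' the identical grid.
#'
#' @param spec a \code{SyntheticEnvSpec}; defaults to [syntheticEnvSpec()].
#' @param seed integer seed controlling the fields.
#' @return an [EnvironmentGrid-class]
#' @export
generateSyntheticEnvironment <- function(spec = syntheticEnvSpec(),
                                         seed = 1L) {
  stopifnot(inherits(spec, "SyntheticEnvSpec"))
  nx <- spec$width; ny <- spec$height
  cx <- floor(nx / 2); cy <- floor(ny / 2)
  blk <- 10L  # half-side of the central re-centring window
  xs <- max(1L, cx - blk + 1L):min(nx, cx + blk)
  ys <- max(1L, cy - blk + 1L):min(ny, cy + blk)
  trends <- if (is.null(spec$trends)) rep(0, 5) else spec$trends
  rad <- sqrt(outer((seq_len(nx) - 1 - cx)^2, (seq_len(ny) - 1 - cy)^2,
                    "+"))
  layers <- withr::with_seed(as.integer(seed), {
    arr <- array(0, dim = c(nx, ny, 5))
    for (i in 1:5) {
      base <- spec$means[i] + trends[i] * rad
      if (spec$amplitudes[i] == 0) {
        arr[, , i] <- base
      } else {
        z <- .gaussianField(nx, ny, spec$corLengths[i])
        z <- z - mean(z[xs, ys])
        arr[, , i] <- base + spec$amplitudes[i] * z
      }
    }
    arr
  })
  new("EnvironmentGrid", width = nx, height = ny, layers = layers,
      patchArea = spec$patchArea,
      layerNames = c("bioclim-1", "bioclim-2", "bioclim-3",
                     "soil-1", "soil-2"))
}

# Bilinear resampling of a matrix to new dimensions, grids aligned by the
# cell centres of the shared extent; values outside are edge-clamped.
.bilinearResample <- function(m, nxOut, nyOut) {
  nx <- nrow(m); ny <- ncol(m)
  coord <- function(nOut, nIn) {
    x <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5
    pmin(pmax(x, 0), nIn - 1)
  }
  xs <- coord(nxOut, nx); ys <- coord(nyOut, ny)
  x0 <- pmin(floor(xs), nx - 2); x1 <- x0 + 1; fx <- xs - x0
  if (nx == 1) { x0 <- x1 <- rep(0, nxOut); fx <- rep(0, nxOut) }
  y0 <- pmin(floor(ys), ny - 2); y1 <- y0 + 1; fy <- ys - y0
  if (ny == 1) { y0 <- y1 <- rep(0, nyOut); fy <- rep(0, nyOut) }
  out <- matrix(0, nxOut, nyOut)
  for (j in seq_len(nyOut)) {
    c0 <- m[, y0[j] + 1]; c1 <- m[, y1[j] + 1]
    col <- c0 * (1 - fy[j]) + c1 * fy[j]
    out[, j] <- col[x0 + 1] * (1 - fx) + col[x1 + 1] * fx
  }
  out
}

.loadOneLayer <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF layers requires the 'tiff' package")
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] != 1L) stop("raster must be single-band: ", path)
      img <- img[, , 1]
    }
    img
  } else {
    as.matrix(read.csv(path, header = FALSE))
  }
}

#' Load an environment from five raster layers
#'
#' Reads five co-registered single-band layers (plain CSV grid dumps, or
#' single-band TIFF if the \pkg{tiff} package is available), optionally
#' crops them to a pixel window, and bilinearly resamples each to the target
#' grid. Files are row-major with the first row at the top of the map;
#' layers are given in V1..V5 order. Non-finite cells (nodata) are an error:
#' mask them upstream or dump to CSV with explicit values.
#'
#' @param paths character(5) file paths, in layer order V1..V5.
#' @param window NULL for the full extent, or a list/vector with elements
#'   \code{rowMin,rowMax,colMin,colMax} (1-based source pixel indices).
#' @param target integer(2): output width and height in patches.
#' @param patchArea patch area in m^2.
#' @return an [EnvironmentGrid-class]
#' @export
loadRasterEnvironment <- function(paths, window = NULL,
                                  target = c(100L, 100L),
                                  patchArea = 0.25) {
  if (length(paths) != 5L) stop("exactly five layer files are required")
  nxOut <- as.integer(target[1]); nyOut <- as.integer(target[2])
  arr <- array(0, dim = c(nxOut, nyOut, 5))
  for (i in 1:5) {
    m <- .loadOneLayer(paths[i])
    if (!is.null(window)) {
      w <- as.list(window)
      if (w$rowMin < 1 || w$rowMax > nrow(m) ||
          w$colMin < 1 || w$colMax > ncol(m))
        stop("window outside raster extent for layer ", i)
      m <- m[w$rowMin:w$rowMax, w$colMin:w$colMax, drop = FALSE]
    }
    # file rows run north->south; flip to the lower-left-origin convention
    # and transpose so the first array index is x.
    m <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
    r <- .bilinearResample(m, nxOut, nyOut)
    if (!all(is.finite(r)))
      stop("non-finite values after resampling layer ", i)
    arr[, , i] <- r
  }
  new("EnvironmentGrid", width = nxOut, height = nyOut, layers = arr,
      patchArea = patchArea,
      layerNames = paste0("layer-", 1:5))
}

#' Dump each environment layer to CSV
#'
#' Writes one CSV per layer (row-major, first row at the top of the map),
#' the inverse of what [loadRasterEnvironment()] reads.
#'
#' @param grid an [EnvironmentGrid-class]
#' @param prefix path prefix; files are \code{<prefix>_V<i>.csv}
#' @return the five file paths, invisibly
#' @export
writeEnvironmentCsv <- function(grid, prefix) {
  paths <- character(5)
  for (i in 1:5) {
    m <- t(envLayers(grid)[, , i])       # rows = y
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # first row = top
    paths[i] <- paste0(prefix, "_V", i, ".csv")
    write.table(m, paths[i], sep = ",", row.names = FALSE,
                col.names = FALSE)
  }
  invisible(paths)
}

#' Draw the seasonal factor of one generation
#'
#' One global Gaussian multiplier (mean 1, default sd 1e-3) applied to the
#' three bioclimatic layers for a whole generation; every patch in that
#' generation sees the same value.
#'
#' @param sd standard deviation of the draw.
#' @return a positive scalar
#' @export
drawSeasonalFactor <- function(sd = 1e-3) {
  max(rnorm(1L, mean = 1, sd = sd), .Machine$double.eps)
}

#' Effective value of one environmental variable
#'
#' The seasonal factor multiplies only the bioclimatic layers (V1-V3);
#' soil layers (V4-V5) are returned unchanged.
#'
#' @param grid an [EnvironmentGrid-class]
#' @param patch integer(2), 0-based patch coordinates (x, y)
#' @param i layer index in 1..5
#' @param sv seasonal factor for the generation
#' @export
effectiveVariable <- function(grid, patch, i, sv = 1) {
  if (!(i %in% 1:5)) stop("layer index must be in 1..5")
  v <- envLayers(grid)[patch[1] + 1L, patch[2] + 1L, i]
  if (i <= 3L) v * sv else v
}

#' Map of patches ecologically suitable for a genotype
#'
#' A patch is suitable for a genotype iff every per-variable deviation from
#' the adaptive optimum is at most the cytotype's tolerance limit
#' (equivalently, every fitness component is at least 0.5). This hard
#' boundary is what gates seed establishment.
#'
#' @param grid an [EnvironmentGrid-class]
#' @param ia numeric(5) adaptive optimum
#' @param config a [SimConfig-class] supplying the limits
#' @param ploidy 2, 3 or 4 (tetraploids use the limit multiplier)
#' @param sv seasonal factor (default 1)
#' @return logical width x height matrix
#' @export
suitabilityMap <- function(grid, ia, config, ploidy = 2L, sv = 1) {
  .suitability(grid, ia, config, ploidy, sv)
}

.suitability <- function(grid, ia, config, ploidy = 2L, sv = 1) {
  p <- config@params
  lim <- p$limits * if (ploidy == 4L) p$limitMultiplier4x else 1
  ok <- matrix(TRUE, gridWidth(grid), gridHeight(grid))
  for (i in 1:5) {
    v <- envLayers(grid)[, , i]
    if (i <= 3L) v <- v * sv
    ok <- ok & (abs(ia[i] - v) <= lim[i])
  }
  ok
}

#' Maximum possible range of the founder population
#'
#' The founder population's optimum is a range of values, one genotype per
#' founder-block patch; the population's potential distribution is the
#' union of the patches suitable for any of those genotypes. This is the
#' boundary to overlay on establishment density maps (the maximal diploid
#' distribution).
#'
#' @inheritParams suitabilityMap
#' @param ploidy cytotype evaluated (tetraploids use the limit multiplier)
#' @return logical width x height matrix
#' @export
founderRangeMap <- function(grid, config = simConfig(), ploidy = 2L) {
  p <- config@params
  nx <- gridWidth(grid); ny <- gridHeight(grid)
  half <- p$founderBlock %/% 2L
  cx <- nx %/% 2L; cy <- ny %/% 2L
  xs <- max(0L, cx - half):min(nx - 1L, cx + half - 1L)
  ys <- max(0L, cy - half):min(ny - 1L, cy + half - 1L)
  ok <- matrix(FALSE, nx, ny)
  for (x in xs) for (y in ys)
    ok <- ok | .suitability(grid, envLayers(grid)[x + 1L, y + 1L, ],
                            config, ploidy)
  ok
}
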