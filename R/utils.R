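# Internal numerical helpers shared across modules.

#' Convert a Gaussian FWHM to its standard deviation
#'
#' @param fwhm Full width at half maximum (any length unit).
#' @return Standard deviation in the same unit (FWHM = 2*sqrt(2*ln 2)*sigma).
#' @export
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Normalised 1D Gaussian taps, truncated at ~4 sigma.
gaussianTaps <- function(sigmaVox) {
  if (sigmaVox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigmaVox^2))
  k / sum(k)
}

# n x n convolution matrix for the taps. edge = "zero" gives a symmetric
# (self-adjoint) operator; edge = "reflect" folds mass back at the borders so
# every column sums to 1 (total image mass is preserved exactly).
convolutionMatrix1d <- function(n, sigmaVox, edge = c("zero", "reflect")) {
  edge <- match.arg(edge)
  taps <- gaussianTaps(sigmaVox)
  r <- (length(taps) - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (o in seq_along(taps)) {
    off <- o - r - 1L
    w <- taps[o]
    for (j in seq_len(n)) {
      i <- j + off
      if (edge == "reflect") {
        # mirror about the half-sample boundary: ... c b a | a b c ...
        while (i < 1L || i > n) {
          if (i < 1L) i <- 1L - i
          if (i > n) i <- 2L * n + 1L - i
        }
      }
      if (i >= 1L && i <= n) B[i, j] <- B[i, j] + w
    }
  }
  B
}

# Separable 2D Gaussian blur of a values matrix; B1 acts on rows, B2 on columns.
blurValues <- function(values, B1, B2) {
  if (is.null(B1)) return(values)
  B1 %*% values %*% t(B2)
}

# Evaluate expr with the global RNG seeded to `seed`, restoring the previous
# RNG state afterwards so library code does not clobber user streams.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

stopIfNot2dGrid <- function(dim) {
  if (length(dim) != 2L) stop("only 2D voxel grids are supported", call. = FALSE)
}

# Voxel-centre physical coordinates (mm), centred on the grid.
gridCoordinates <- function(dim, spacing) {
  x <- (seq_len(dim[1]) - (dim[1] + 1) / 2) * spacing[1]
  y <- (seq_len(dim[2]) - (dim[2] + 1) / 2) * spacing[2]
  list(x = x, y = y,
       X = matrix(x, dim[1], dim[2]),
       Y = matrix(y, dim[1], dim[2], byrow = TRUE))
}
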