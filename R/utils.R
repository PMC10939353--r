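# Internal helpers shared across the pipeline. Coordinate convention used
# everywhere: positions are (row, col), 0-based, with pixel centres at
# integer coordinates; matrix element [i, j] covers the unit square centred
# on (i - 1, j - 1). Distances convert to nm via pixel_size_nm.

#' Evaluate code with a temporarily seeded RNG
#'
#' Runs `code` with the generator seeded at `seed` and restores the caller's
#' RNG state afterwards, so seeded pipeline stages do not disturb the
#' session. A `NULL` seed runs the code against the current RNG state.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic per-stage sub-seed, kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 99991 * as.numeric(k)) %% 2147483629L)
}

# Bilinear sample of a matrix at fractional 0-based (row, col) positions.
# Positions outside the grid are clamped to the border.
bilinear_sample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(rows, 0), nr - 1)
  c <- pmin(pmax(cols, 0), nc - 1)
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  fr <- r - r0; fc <- c - c0
  i0 <- r0 + 1; j0 <- c0 + 1
  img[cbind(i0, j0)]         * (1 - fr) * (1 - fc) +
    img[cbind(i0 + 1, j0)]     * fr       * (1 - fc) +
    img[cbind(i0, j0 + 1)]     * (1 - fr) * fc +
    img[cbind(i0 + 1, j0 + 1)] * fr       * fc
}

# Row/column weight matrix mapping a coarse grid (block size s, block centres
# at 0-based coordinates (i-1)*s + (s-1)/2) back onto the full grid by linear
# interpolation; used to enlarge the shrunken rolling-ball background.
upsample_weights <- function(n_full, n_small, s) {
  centres <- (seq_len(n_small) - 1) * s + (s - 1) / 2
  x <- seq_len(n_full) - 1
  W <- matrix(0, n_full, n_small)
  idx <- findInterval(x, centres)
  for (k in seq_len(n_full)) {
    i <- idx[k]
    if (i <= 0) {
      W[k, 1] <- 1
    } else if (i >= n_small) {
      W[k, n_small] <- 1
    } else {
      t <- (x[k] - centres[i]) / (centres[i + 1] - centres[i])
      W[k, i] <- 1 - t
      W[k, i + 1] <- t
    }
  }
  W
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
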