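`%||%` <- function(a, b) if (is.null(a)) b else a

stop_uexm <- function(msg, class) {
  stop(structure(class = c(class, "uexm_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_uexm(sprintf("`%s` must be a single positive number", name),
              "uexm_validation_error")
  invisible(x)
}

assert_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_uexm(sprintf("`%s` must be a single non-negative number", name),
              "uexm_validation_error")
  invisible(x)
}

#' Separable Gaussian blur of a matrix
#'
#' Convolves a matrix with an isotropic Gaussian kernel (truncated at three
#' standard deviations). Border kernels are renormalized so that a constant
#' image is preserved exactly and structure never wraps around the canvas.
#'
#' @param m numeric matrix.
#' @param sigma_px Gaussian standard deviation in pixels; `0` returns the
#'   input unchanged.
#' @return blurred matrix of the same dimensions.
#' @keywords internal
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma_px)))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  blur_1d <- function(n) {
    # n x n banded convolution matrix with row renormalization at the edges
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      w <- k[j - i + r + 1L]
      K[i, j] <- w / sum(w)
    }
    K
  }
  Kr <- blur_1d(nrow(m))
  Kc <- blur_1d(ncol(m))
  Kr %*% m %*% t(Kc)
}

# mean-pool an (ny*ss) x (nx*ss) matrix down to ny x nx
pool_mean <- function(m, ss) {
  if (ss == 1L) return(m)
  ny <- nrow(m) / ss
  nx <- ncol(m) / ss
  a <- array(m, dim = c(ss, ny, ss, nx))
  out <- apply(a, c(2L, 4L), mean)
  matrix(out, ny, nx)
}

# bilinear interpolation of matrix `m` at continuous (x = column, y = row)
# coordinates; pixel centers sit at integer coordinates
bilinear <- function(m, x, y) {
  nx <- ncol(m); ny <- nrow(m)
  if (any(x < 1 | x > nx | y < 1 | y > ny))
    stop_uexm("sample point outside the image", "uexm_validation_error")
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  m[cbind(y0, x0)]         * (1 - fx) * (1 - fy) +
    m[cbind(y0, x0 + 1)]   * fx       * (1 - fy) +
    m[cbind(y0 + 1, x0)]   * (1 - fx) * fy +
    m[cbind(y0 + 1, x0 + 1)] * fx     * fy
}
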