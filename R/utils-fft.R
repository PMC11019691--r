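# Fourier helpers shared by the optics, simulator and reconstruction code.
# Convention: frequencies in cycles/nm, DC at the array centre after
# fftshift(); unshifted layout is used internally for speed.

#' Discrete Fourier frequencies
#'
#' Frequencies associated with the unshifted FFT layout, in cycles per
#' `d` units (the numpy `fftfreq` convention).
#'
#' @param n Number of samples.
#' @param d Sample spacing (e.g. nm per pixel).
#' @return Numeric vector of length `n`.
#' @export
fft_freq <- function(n, d = 1) {
  stopifnot(n >= 1, d > 0)
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq_len(floor(n / 2)) - floor(n / 2) - 1L)
  k / (n * d)
}

#' Shift DC to the array centre (and back)
#'
#' `fftshift()` moves the zero-frequency element of a vector or matrix to
#' the centre; `ifftshift()` is its exact inverse (they differ for odd
#' lengths).
#'
#' @param x Numeric or complex vector or matrix.
#' @return Array of the same shape.
#' @export
fftshift <- function(x) {
  sh <- function(n) {
    p <- ceiling(n / 2)
    c(seq.int(p + 1L, n), seq_len(p))
  }
  if (is.matrix(x)) x[sh(nrow(x)), sh(ncol(x)), drop = FALSE] else x[sh(length(x))]
}

#' @rdname fftshift
#' @export
ifftshift <- function(x) {
  sh <- function(n) {
    p <- floor(n / 2)
    c(seq.int(p + 1L, n), seq_len(p))
  }
  if (is.matrix(x)) x[sh(nrow(x)), sh(ncol(x)), drop = FALSE] else x[sh(length(x))]
}

# 2D forward / inverse FFT (inverse is normalized).
fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Circular convolution of an image with a kernel whose origin sits at the
# array centre (kernel and image must have identical dimensions).
conv2_centered <- function(img, kernel_centered) {
  Re(ifft2(fft2(img) * fft2(ifftshift(kernel_centered))))
}

# round half away from zero, as values are printed in reports
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate the DTFT of a real-space field q at a continuous frequency
# k = c(ky, kx) in cycles/nm: sum_x q(x) exp(-2i*pi*k.x).
dtft_at <- function(q, k, px) {
  ny <- nrow(q); nx <- ncol(q)
  y <- (seq_len(ny) - 1) * px
  x <- (seq_len(nx) - 1) * px
  ey <- exp(-2i * pi * k[1] * y)
  ex <- exp(-2i * pi * k[2] * x)
  as.complex(crossprod(ey, q %*% ex))[1]
}

# Run `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the
# package go through this so that generators are pure functions of seed.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
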