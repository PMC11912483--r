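#' Boys function
#'
#' Evaluates the Boys function \eqn{F_m(T) = \int_0^1 x^{2m} e^{-T x^2} dx}
#' for all orders `0..m` at a single argument `T`. This is the radial kernel
#' of every Coulomb-type Gaussian integral in the package.
#'
#' Small arguments use the convergent ascending series at the highest order
#' followed by stable downward recursion; large arguments use the asymptotic
#' complete-integral value at order zero followed by upward recursion (stable
#' there because the exponential term is negligible).
#'
#' @param m maximum order (non-negative integer).
#' @param T argument, `T >= 0`.
#' @return numeric vector of length `m + 1` holding `F_0(T) .. F_m(T)`.
#' @examples
#' boys(0, 0)           # 1
#' boys(3, 0)           # 1, 1/3, 1/5, 1/7
#' boys(2, 1.5)
#' @export
boys <- function(m, T) {
  m <- as.integer(m)
  stopifnot(m >= 0L, length(T) == 1L)
  if (!is.finite(T) || T < 0) stop("boys(): T must be a finite non-negative number")
  if (T < 1e-14) return(1 / (2 * seq(0L, m) + 1))
  out <- numeric(m + 1L)
  eT <- exp(-T)
  if (T <= 45) {
    # ascending series at top order: F_m(T) = e^-T sum_k (2T)^k / (2m+1)(2m+3)...(2m+2k+1)
    term <- 1 / (2 * m + 1)
    s <- term
    k <- 1L
    repeat {
      term <- term * 2 * T / (2 * m + 2 * k + 1)
      s <- s + term
      if (term < s * 1e-17 || k > 400L) break
      k <- k + 1L
    }
    out[m + 1L] <- eT * s
    if (m > 0L) for (j in m:1) out[j] <- (2 * T * out[j + 1L] + eT) / (2 * j - 1)
  } else {
    out[1L] <- 0.5 * sqrt(pi / T)
    if (m > 0L) for (j in 1:m) out[j + 1L] <- ((2 * j - 1) * out[j] - eT) / (2 * T)
  }
  out
}
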