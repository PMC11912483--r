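# McMurchie-Davidson machinery: E-coefficients, Hermite Coulomb R-integrals,
# and the generic electron-repulsion contraction between two "Hermite
# distributions" (a screened shell pair or a single auxiliary shell, stored as
# its surviving primitives with precomputed Hermite-to-spherical E matrices).
#
# R-integral convention: the table holds R^0_{tuv}(p, PQ) seeded by
# R^n_{000} = (-2p)^n F_n(p |PQ|^2); the 2 pi^{5/2} / (p q sqrt(p+q)) charge
# prefactor and the (-1)^{t+u+v} ket parity are applied in eri_dist(), never
# inside the table.

#' McMurchie-Davidson E-coefficients (one dimension)
#'
#' Hermite expansion coefficients of a primitive Cartesian Gaussian product:
#' \eqn{x_A^i x_B^j e^{-a x_A^2} e^{-b x_B^2} = e^{-\mu X_{AB}^2} \sum_t
#' E_t^{ij} \Lambda_t(x - P)}. The Gaussian-product prefactor is folded into
#' `E[1,1,1]`, so the expansion is exact term by term.
#'
#' @param la,lb maximum Cartesian powers on each side.
#' @param a,b primitive exponents (`b = 0` with `AB = 0` gives the expansion
#'   of a single Gaussian over Hermite functions at its own center).
#' @param AB scalar displacement `A - B` along this dimension.
#' @return array `E[i+1, j+1, t+1]`, `t = 0..la+lb`.
#' @export
hermite_E1d <- function(la, lb, a, b, AB) {
  p <- a + b
  mu <- a * b / p
  ntot <- la + lb
  E <- array(0, dim = c(la + 1L, lb + 1L, ntot + 2L)) # one spare t slot
  E[1L, 1L, 1L] <- exp(-mu * AB * AB)
  XPA <- -b * AB / p
  XPB <- a * AB / p
  if (la > 0L) for (i in 1:la) for (t in 0:(i)) {
    E[i + 1L, 1L, t + 1L] <-
      (if (t > 0L) E[i, 1L, t] / (2 * p) else 0) +
      XPA * E[i, 1L, t + 1L] +
      (t + 1) * E[i, 1L, t + 2L]
  }
  if (lb > 0L) for (j in 1:lb) for (i in 0:la) for (t in 0:(i + j)) {
    E[i + 1L, j + 1L, t + 1L] <-
      (if (t > 0L) E[i + 1L, j, t] / (2 * p) else 0) +
      XPB * E[i + 1L, j, t + 1L] +
      (t + 1) * E[i + 1L, j, t + 2L]
  }
  E[, , seq_len(ntot + 1L), drop = FALSE]
}

#' Hermite Coulomb integrals R^0_{tuv}
#'
#' Auxiliary McMurchie-Davidson table of repulsion integrals over Hermite
#' Gaussians, complete for all `t+u+v <= nmax`, seeded by Boys values
#' \eqn{R^n_{000} = (-2p)^n F_n(p |PQ|^2)}.
#'
#' @param nmax maximum total Hermite order.
#' @param p effective exponent (for an ERI this is `p q / (p + q)`).
#' @param PQ displacement 3-vector between the two Hermite centers.
#' @return 3-d array indexed `[t+1, u+1, v+1]`.
#' @export
hermite_R3d <- function(nmax, p, PQ) {
  T <- p * sum(PQ * PQ)
  Fm <- boys(nmax, T)
  X <- PQ[1]; Y <- PQ[2]; Z <- PQ[3]
  dims <- rep(nmax + 1L, 3L)
  prev <- NULL
  for (n in nmax:0) {
    cur <- array(0, dims)
    cur[1L, 1L, 1L] <- (-2 * p)^n * Fm[n + 1L]
    smax <- nmax - n
    if (smax > 0L) for (s in 1:smax) {
      idx <- monomials(s)
      for (r in seq_len(nrow(idx))) {
        t <- idx[r, 1L]; u <- idx[r, 2L]; v <- idx[r, 3L]
        if (t > 0L) {
          val <- X * prev[t, u + 1L, v + 1L] +
            (if (t > 1L) (t - 1) * prev[t - 1L, u + 1L, v + 1L] else 0)
        } else if (u > 0L) {
          val <- Y * prev[1L, u, v + 1L] +
            (if (u > 1L) (u - 1) * prev[1L, u - 1L, v + 1L] else 0)
        } else {
          val <- Z * prev[1L, 1L, v] +
            (if (v > 1L) (v - 1) * prev[1L, 1L, v - 1L] else 0)
        }
        cur[t + 1L, u + 1L, v + 1L] <- val
      }
    }
    prev <- cur
  }
  prev
}

# ---- generic ERI over two Hermite distributions ------------------------------

#' Electron-repulsion block between two Hermite distributions
#'
#' A "Hermite distribution" is a screened shell pair or a single (auxiliary)
#' shell, stored as its surviving primitives, each carrying the total exponent
#' `p`, the Gaussian-product center `P`, the total angular momentum `lsum`,
#' and the E matrix mapping Hermite indices to contracted spherical function
#' (pairs). This one contraction implements the 2-, 3- and 4-index repulsion
#' integrals: `eri_dist(K, L)` for the metric, `eri_dist(K, pair)` for the
#' three-index block, `eri_dist(pairPQ, pairRS)` for the four-index block.
#'
#' @param d1,d2 Hermite distributions (see [build_shell_pairs()] /
#'   [aux_dist()]).
#' @return matrix `d1$nfun x d2$nfun` of repulsion integrals in Hartree.
#' @export
eri_dist <- function(d1, d2) {
  .eri_dist_cpp(d1$prims, d1$nfun, d2$prims, d2$nfun)
}

# reference R implementation of the same contraction (kept as an in-package
# cross-check of the compiled kernel on tiny cases)
eri_dist_ref <- function(d1, d2) {
  out <- matrix(0, d1$nfun, d2$nfun)
  for (p1 in d1$prims) {
    h1 <- hermite_indices(p1$lsum)
    for (p2 in d2$prims) {
      h2 <- hermite_indices(p2$lsum)
      xi <- p1$p * p2$p / (p1$p + p2$p)
      Rt <- hermite_R3d(p1$lsum + p2$lsum, xi, p1$P - p2$P)
      tt <- outer(h1[, 1L], h2[, 1L], `+`) + 1L
      uu <- outer(h1[, 2L], h2[, 2L], `+`) + 1L
      vv <- outer(h1[, 3L], h2[, 3L], `+`) + 1L
      Rmat <- matrix(Rt[cbind(c(tt), c(uu), c(vv))], nrow(h1), nrow(h2))
      sgn <- (-1)^(h2[, 1L] + h2[, 2L] + h2[, 3L])
      pref <- 2 * pi^2.5 / (p1$p * p2$p * sqrt(p1$p + p2$p))
      out <- out + pref * crossprod(p1$E, Rmat %*% (p2$E * sgn))
    }
  }
  out
}

# ---- multipole moments of a Hermite distribution -----------------------------

# 1-d moments of Hermite Gaussians about an arbitrary center:
# M[t+1, e+1] = (pi/p)^{-1/2} * int Lambda_t(x - P) (x - C)^e dx
mom1d <- function(tmax, emax, p, X) {
  M <- matrix(0, tmax + 1L, emax + 1L)
  M[1L, 1L] <- 1
  if (emax > 0L) for (e in 1:emax) for (t in 0:min(tmax, e)) {
    M[t + 1L, e + 1L] <-
      (if (t > 0L) t * M[t, e] else 0) +
      X * M[t + 1L, e] +
      (if (e > 1L) (e - 1) / (2 * p) * M[t + 1L, e - 1L] else 0)
  }
  M
}

# transform stacked Cartesian moments (monomials of degree 0..L, ordered as
# hermite_indices(L)) to packed real scaled solid harmonics l = 0..L
solid_from_cart <- function(L) {
  key <- paste0("sfc", L)
  cache_get(key, function() {
    nm <- nrow(hermite_indices(L))
    out <- matrix(0, (L + 1L)^2, nm)
    off <- 0L
    for (l in 0:L) {
      nb <- nrow(monomials(l))
      out[lm_index(l, -l):lm_index(l, l), off + seq_len(nb)] <- solid_coef_real(l)
      off <- off + nb
    }
    out
  })
}

#' Multipole moments of a Hermite distribution
#'
#' Real scaled solid-harmonic multipole moments about an arbitrary center of
#' every contracted function (pair) carried by the distribution, resolved per
#' function: column `j` holds the moments of function (pair) `j`. Terminating
#' expansions terminate exactly: a primitive pair at its Gaussian-product
#' point and any one-center pair at that center vanish identically above the
#' sum of the angular momenta; a single auxiliary shell at its own center is
#' nonzero only at its own `l`.
#'
#' @param dist Hermite distribution (see [eri_dist()]).
#' @param C expansion center, 3-vector Bohr.
#' @param L maximum multipole order.
#' @return matrix `(L+1)^2 x dist$nfun`.
#' @export
dist_multipoles <- function(dist, C, L) {
  if (L > L_ABS_MAX) stop("multipole order ", L, " exceeds the supported cap of ", L_ABS_MAX)
  mono <- hermite_indices(L)
  cart <- matrix(0, nrow(mono), dist$nfun)
  for (pr in dist$prims) {
    h <- hermite_indices(pr$lsum)
    Mx <- mom1d(pr$lsum, L, pr$p, pr$P[1] - C[1])
    My <- mom1d(pr$lsum, L, pr$p, pr$P[2] - C[2])
    Mz <- mom1d(pr$lsum, L, pr$p, pr$P[3] - C[3])
    CM <- Mx[h[, 1L] + 1L, mono[, 1L] + 1L, drop = FALSE] *
      My[h[, 2L] + 1L, mono[, 2L] + 1L, drop = FALSE] *
      Mz[h[, 3L] + 1L, mono[, 3L] + 1L, drop = FALSE]
    cart <- cart + (pi / pr$p)^1.5 * crossprod(CM, pr$E)
  }
  solid_from_cart(L) %*% cart
}

# absolute cap on any multipole order (scaled harmonics stay finite here)
L_ABS_MAX <- 44L
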