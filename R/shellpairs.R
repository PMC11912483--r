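# Screened shell pairs with Gaussian-product-theorem primitive centers,
# weighted contracted pair centers, walker-scan extents, Schwarz bounds and
# precomputed Hermite-to-spherical E matrices.

# E matrix of one primitive pair: rows = hermite_indices(la+lb),
# cols = (mu, nu) spherical pairs with mu (bra shell) slow
prim_pair_E <- function(la, lb, a, b, AB, weight) {
  Ex <- hermite_E1d(la, lb, a, b, AB[1])
  Ey <- hermite_E1d(la, lb, a, b, AB[2])
  Ez <- hermite_E1d(la, lb, a, b, AB[3])
  h <- hermite_indices(la + lb)
  ca <- monomials(la); cb <- monomials(lb)
  Ecart <- matrix(0, nrow(h), nrow(ca) * nrow(cb))
  cc <- 0L
  for (ia in seq_len(nrow(ca))) for (ib in seq_len(nrow(cb))) {
    cc <- cc + 1L
    Ecart[, cc] <- Ex[ca[ia, 1L] + 1L, cb[ib, 1L] + 1L, h[, 1L] + 1L] *
      Ey[ca[ia, 2L] + 1L, cb[ib, 2L] + 1L, h[, 2L] + 1L] *
      Ez[ca[ia, 3L] + 1L, cb[ib, 3L] + 1L, h[, 3L] + 1L]
  }
  weight * Ecart %*% t(kronecker(sph_transform(la), sph_transform(lb)))
}

#' Screened shell pairs
#'
#' Forms all unique unordered shell pairs `I <= J` that survive primitive
#' Gaussian-product prescreening, with the exponent-weighted contracted pair
#' center, the walker-scan extent, the Schwarz bound
#' \eqn{K_{IJ} = \sqrt{\max |(IJ|IJ)|}} and per-primitive-pair E matrices.
#' A primitive pair survives when its product prefactor
#' \eqn{|d_k d_l| \exp(-ab R_{AB}^2/(a+b))} reaches `threshold`; the number
#' of surviving pairs grows linearly with chain length at fixed threshold.
#'
#' @param sys `bupo_system`.
#' @param threshold primitive prescreen threshold (> 0).
#' @param T_sphere extent threshold for the walker scan.
#' @return list of shell pairs (class `bupo_pairs`), each carrying
#'   `I`, `J`, centers, primitive list, weighted center `P`, `extent`,
#'   Schwarz bound `K` and function offsets.
#' @export
build_shell_pairs <- function(sys, threshold = 1e-12, T_sphere = 1e-6) {
  stopifnot(threshold > 0)
  shells <- sys$shells
  ns <- length(shells)
  pairs <- list()
  for (I in seq_len(ns)) for (J in I:ns) {
    shI <- shells[[I]]; shJ <- shells[[J]]
    AB <- shI$center - shJ$center
    R2 <- sum(AB * AB)
    surv <- list()
    wsum <- 0; Pw <- c(0, 0, 0)
    for (k in seq_along(shI$exps)) for (l in seq_along(shJ$exps)) {
      a <- shI$exps[k]; b <- shJ$exps[l]
      pref <- exp(-a * b / (a + b) * R2)
      w <- abs(shI$coefs[k] * shJ$coefs[l]) * pref
      if (w < threshold) next
      P <- (a * shI$center + b * shJ$center) / (a + b)
      wsum <- wsum + w
      Pw <- Pw + w * P
      weight <- shI$coefs[k] * radial_norm(a, shI$l) *
        shJ$coefs[l] * radial_norm(b, shJ$l)
      surv[[length(surv) + 1L]] <- list(
        p = a + b, P = P, lsum = shI$l + shJ$l,
        E = prim_pair_E(shI$l, shJ$l, a, b, AB, weight)
      )
    }
    if (!length(surv)) next
    pr <- list(
      I = I, J = J, la = shI$l, lb = shJ$l,
      A = shI$center, B = shJ$center,
      nI = shI$nf, nJ = shJ$nf, nfun = shI$nf * shJ$nf,
      offI = shI$offset, offJ = shJ$offset,
      prims = surv, P = Pw / wsum
    )
    ext <- walker_extent(pr, shI, shJ, T_sphere)
    pr$extent <- ext$extent
    pr$extent_flagged <- ext$flagged
    pr$K <- sqrt(max(abs(eri_dist(pr, pr))))
    pairs[[length(pairs) + 1L]] <- pr
  }
  structure(pairs, class = "bupo_pairs")
}

#' @export
print.bupo_pairs <- function(x, ...) {
  cat(length(x), "screened shell pairs; mean extent",
      round(mean(vapply(x, `[[`, 0, "extent")), 3), "Bohr\n")
  invisible(x)
}

# scatter a per-pair (mu,nu) block into / gather from a full AO matrix
pair_block_indices <- function(pr) {
  mu <- rep(pr$offI + seq_len(pr$nI), each = pr$nJ)
  nu <- rep(pr$offJ + seq_len(pr$nJ), times = pr$nI)
  cbind(mu, nu)
}

# density vector over a pair's (mu,nu) columns, with the factor 2 for I != J
# so that contraction over unique pairs equals the full double sum
pair_density <- function(pr, D) {
  idx <- pair_block_indices(pr)
  d <- D[idx]
  if (pr$I != pr$J) d <- 2 * d
  d
}
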