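# Real-space extents of shells and shell pairs.
#
# The production near-field/far-field gate uses the walker-scan pair extent:
# two virtual walkers start outside the single-shell spheres S(I), S(J) on the
# line connecting the two centers and scan inward in 0.01 Bohr steps until the
# axial bound on the pair magnitude first exceeds T_sphere; the extent is the
# larger distance of the two stop points from the weighted pair center, floored
# at 2 Bohr.  Two literature extents (primitive-pair closed form and its
# contracted-pair generalization) are provided as comparison baselines only.

WALKER_STEP <- 0.01   # Bohr, fixed scan increment (bit-stable extents)
EXTENT_FLOOR <- 2.0   # Bohr, extents below this are not allowed

# Radial envelope bound of a contracted shell:
#   sum_k |c_k N_k| sqrt((2l+1)/4pi) r^l e^{-a_k r^2}
# an upper bound on |basis function| at distance r from the center in any
# direction, since every normalized real spherical harmonic is bounded by
# sqrt((2l+1)/4pi) on the unit sphere (addition theorem).
shell_envelope <- function(shell, r) {
  w <- abs(shell$coefs) * radial_norm(shell$exps, shell$l) *
    sqrt((2 * shell$l + 1) / (4 * pi))
  colSums(w * exp(-outer(shell$exps, r * r))) * r^shell$l
}

#' Single-shell sphere radius (chain-of-spheres style)
#'
#' Outermost radius beyond which the shell's radial envelope
#' \eqn{\sum_k |c_k| r^l e^{-\alpha_k r^2}} is guaranteed below `T_sphere`,
#' found by outward bracketing and bisection. The guarantee is one-sided:
#' the envelope stays below `T_sphere` for every larger radius.
#'
#' @param shell a shell record (fields `l`, `exps`, `coefs`).
#' @param T_sphere positive threshold.
#' @return radius in Bohr.
#' @export
cosx_radius <- function(shell, T_sphere = 1e-6) {
  stopifnot(T_sphere > 0)
  # beyond the envelope's last term peak (r = sqrt(l/(2a)) for the most
  # diffuse primitive) the envelope decays monotonically
  r_peak <- if (shell$l > 0L) sqrt(shell$l / (2 * min(shell$exps))) else 0
  if (shell_envelope(shell, r_peak) >= T_sphere) {
    lo <- r_peak
    hi <- max(1, 2 * r_peak)
    while (shell_envelope(shell, hi) >= T_sphere) hi <- hi * 2
  } else {
    # envelope below threshold at the outermost peak: outermost crossing (if
    # any) lies inside [0, r_peak]
    grid <- seq(0, max(r_peak, 1e-8), length.out = 256L)
    above <- shell_envelope(shell, grid) >= T_sphere
    if (!any(above)) return(0)
    lo <- grid[max(which(above))]
    hi <- r_peak
  }
  for (it in 1:200) {
    mid <- 0.5 * (lo + hi)
    if (shell_envelope(shell, mid) >= T_sphere) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  hi
}

#' Walker-scan shell-pair extent
#'
#' Places the two shells on the z-axis (B at the origin, A at `R_AB`), starts
#' one walker at `R_AB + S(A)` scanning in `-z` and one at `-S(B)` scanning in
#' `+z` (step 0.01 Bohr), and stops each at the first point where the axial
#' pair-magnitude bound exceeds `T_sphere`. The extent is the larger distance
#' of the two stop points from the weighted pair center, never below 2 Bohr.
#' Extents defined this way shrink with growing intercenter distance once the
#' shells stop overlapping.
#'
#' @param pair shell pair (needs the weighted center `P`).
#' @param shI,shJ the two shell records.
#' @param T_sphere positive threshold.
#' @return list with `extent` (Bohr), `method = "walker"`, scan diagnostics
#'   `z_min`, `z_max`, and `flagged` (TRUE when the pair magnitude never
#'   reached `T_sphere` and the 2 Bohr floor was used).
#' @export
walker_extent <- function(pair, shI, shJ, T_sphere = 1e-6) {
  stopifnot(T_sphere > 0)
  Rab <- vnorm(shI$center - shJ$center)
  SA <- cosx_radius(shI, T_sphere)
  SB <- cosx_radius(shJ, T_sphere)
  # axial coordinate: B at 0, A at Rab; pair center projected on the axis
  Cz <- if (Rab > 0) sum((pair$P - shJ$center) * (shI$center - shJ$center)) / Rab else 0
  gamma_bound <- function(z) {
    shell_envelope(shI, abs(z - Rab)) * shell_envelope(shJ, abs(z))
  }
  nmax <- ceiling((Rab + SA + SB) / WALKER_STEP) + 4L
  scan <- function(z0, step) {
    z <- z0 + step * (seq_len(nmax) - 1L)
    hit <- which(gamma_bound(z) > T_sphere)
    if (length(hit)) z[hit[1L]] else NA_real_
  }
  z_hi <- scan(Rab + SA, -WALKER_STEP)
  z_lo <- scan(-SB, +WALKER_STEP)
  flagged <- is.na(z_hi) || is.na(z_lo)
  ext <- if (flagged) EXTENT_FLOOR else max(abs(z_hi - Cz), abs(z_lo - Cz))
  list(extent = max(ext, EXTENT_FLOOR), method = "walker",
       z_min = z_lo, z_max = z_hi, flagged = flagged || ext < EXTENT_FLOOR)
}

#' Literature primitive-pair extent
#'
#' Closed-form extent of a primitive s-type Gaussian product,
#' \eqn{\sqrt{-\ln\tau/(a+b)}}: comparison baseline only, never used by the
#' production near-field/far-field gate.
#'
#' @param a,b primitive exponents.
#' @param tau accuracy parameter (typically 1e-4 .. 1e-6).
#' @return extent in Bohr.
#' @export
baseline_extent_primitive <- function(a, b, tau = 1e-6) {
  stopifnot(tau > 0, tau < 1)
  sqrt(-log(tau) / (a + b))
}

#' Literature contracted-pair extent
#'
#' Contracted generalization of [baseline_extent_primitive()]: the maximum over primitive
#' pairs of the primitive extent plus the displacement of the primitive
#' Gaussian-product center from the contracted pair center. The construction
#' carries no product screening, so when the shell records are supplied the
#' maximum runs over the full primitive grid (the literature definition);
#' otherwise only the pair's surviving primitives are available. Grows with
#' intercenter distance (the behavior the walker extent corrects);
#' comparison baseline only, never used by the production gate.
#'
#' @param pair shell pair (primitive list and weighted center `P`).
#' @param tau accuracy parameter.
#' @param shI,shJ the two shell records (optional; enables the full
#'   primitive grid).
#' @return extent in Bohr.
#' @export
baseline_extent_contracted <- function(pair, tau = 1e-6, shI = NULL, shJ = NULL) {
  best <- 0
  if (!is.null(shI) && !is.null(shJ)) {
    for (a in shI$exps) for (b in shJ$exps) {
      P <- (a * shI$center + b * shJ$center) / (a + b)
      best <- max(best, vnorm(P - pair$P) + sqrt(-log(tau) / (a + b)))
    }
  } else {
    for (pr in pair$prims) {
      best <- max(best, vnorm(pr$P - pair$P) + sqrt(-log(tau) / pr$p))
    }
  }
  best
}

#' Auxiliary-shell extent
#'
#' For a single auxiliary shell the extent is simply its own sphere radius,
#' which is rigorous. Shells whose extent exceeds `diffuse_cutoff` are flagged
#' diffuse (routed to the throwaway bubble by the hierarchy builder).
#'
#' @param shell auxiliary shell record.
#' @param T_sphere positive threshold.
#' @param diffuse_cutoff Bohr.
#' @return list with `extent` and `diffuse`.
#' @export
aux_extent <- function(shell, T_sphere = 1e-6, diffuse_cutoff = 20) {
  ext <- cosx_radius(shell, T_sphere)
  list(extent = ext, diffuse = ext > diffuse_cutoff)
}

#' Tabulate extents for every pair
#'
#' Walker, primitive-pair-baseline and contracted-baseline extents per shell
#' pair, ready for the comparison study (one row per pair).
#'
#' @param pairs `bupo_pairs`.
#' @param sys `bupo_system` the pairs were built from.
#' @param T_sphere,tau thresholds for walker and baseline extents.
#' @return data.frame with columns `I`, `J`, `R_AB`, `walker`,
#'   `baseline_prim`, `baseline_contr`.
#' @export
extent_table <- function(pairs, sys, T_sphere = 1e-6, tau = 1e-6) {
  rows <- lapply(pairs, function(pr) {
    shI <- sys$shells[[pr$I]]; shJ <- sys$shells[[pr$J]]
    e26 <- max(vapply(pr$prims, function(x) {
      baseline_extent_primitive(x$p / 2, x$p / 2, tau)
    }, 0))
    data.frame(I = pr$I, J = pr$J, R_AB = vnorm(shI$center - shJ$center),
               walker = pr$extent, baseline_prim = e26,
               baseline_contr = baseline_extent_contracted(pr, tau, shI, shJ))
  })
  do.call(rbind, rows)
}
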