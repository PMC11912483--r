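# Synthetic benchmark systems: quasi-linear/helical chains of repeated units
# with a compact contracted s/p orbital basis and a matching uncontracted
# auxiliary basis, plus seeded density generators and the convergence-study
# harness. The chains emulate the shape of polypeptide benchmark systems at
# desk scale: long, quasi-one-dimensional molecules are the best case for a
# linear-scaling Coulomb algorithm and make scaling behavior measurable with
# a few dozen atoms.

#' Synthetic chain geometries
#'
#' Deterministic chain of `units` repeated units. `"linear"` units are single
#' heavy atoms on the z axis; `"peptide"` units are 4 heavy atoms plus 2
#' hydrogens arranged off-axis, each successive unit twisted about the chain
#' axis (a crude helix). Length grows linearly with `units`.
#'
#' @param units number of repeat units (>= 1).
#' @param unit `"linear"` or `"peptide"`.
#' @param spacing per-unit rise along the chain axis, Bohr.
#' @param element heavy-atom element symbol for linear chains.
#' @param twist helical twist per unit, degrees (peptide units).
#' @return `bupo_atoms`.
#' @export
make_chain <- function(units, unit = c("linear", "peptide"), spacing = NULL,
                       element = "X", twist = 100) {
  unit <- match.arg(unit)
  stopifnot(units >= 1L)
  if (unit == "linear") {
    spacing <- spacing %||% 3.0
    stopifnot(spacing > 0)
    atoms(rep(element, units),
          cbind(0, 0, spacing * (seq_len(units) - 1L)))
  } else {
    spacing <- spacing %||% 2.8
    stopifnot(spacing > 0)
    local <- rbind(
      c(2.0, 0.0, 0.00), c(1.4, 1.4, 0.70), c(0.0, 2.0, 1.40),
      c(-1.4, 1.4, 2.10), c(2.9, 0.0, 0.35), c(0.0, 2.9, 1.75)
    )
    el_unit <- c("X", "X", "X", "X", "H", "H")
    th <- twist * pi / 180
    pos <- NULL; el <- character(0)
    for (u in seq_len(units)) {
      a <- th * (u - 1L)
      Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
      p <- local %*% t(Rz)
      p[, 3] <- p[, 3] + spacing * (u - 1L)
      pos <- rbind(pos, p)
      el <- c(el, el_unit)
    }
    atoms(el, pos)
  }
}

#' Compact synthetic orbital and auxiliary bases
#'
#' The orbital basis gives every heavy atom `X` a contracted s and a valence
#' p shell; hydrogen gets one contracted s. The auxiliary basis is
#' uncontracted with angular momenta up to twice the orbital maximum per
#' element (fit completeness heuristic): s,p,d on `X`, s on H. Exponents are
#' fixed and chosen so typical walker extents sit in the few-Bohr range at
#' bond-length spacings, mirroring production Gaussian bases; every generated
#' system is fully reproducible.
#'
#' @param kind `"ao"` or `"aux"`.
#' @return `bupo_basis`.
#' @export
toy_basis <- function(kind = c("ao", "aux")) {
  kind <- match.arg(kind)
  if (kind == "ao") {
    basis_set(list(
      X = list(
        list(l = 0L, exps = c(8.0, 1.4), coefs = c(0.45, 0.65)),
        list(l = 1L, exps = 0.45, coefs = 1)
      ),
      H = list(
        list(l = 0L, exps = c(1.8, 0.35), coefs = c(0.4, 0.75))
      )
    ))
  } else {
    basis_set(list(
      X = list(
        list(l = 0L, exps = 1.1, coefs = 1),
        list(l = 1L, exps = 0.8, coefs = 1),
        list(l = 2L, exps = 0.7, coefs = 1)
      ),
      H = list(
        list(l = 0L, exps = 0.7, coefs = 1)
      )
    ))
  }
}

#' Synthetic density matrices
#'
#' `"sad"` builds a superposition-of-atomic-guesses density: diagonal, each
#' atom's electron count spread evenly over its basis functions (equal
#' occupation within every shell, which makes the density exactly invariant
#' under rigid rotations of the geometry). `"random_spd"` builds a seeded
#' random symmetric positive semi-definite matrix with the trace normalized
#' to the total electron count.
#'
#' @param sys `bupo_system`.
#' @param mode `"sad"` or `"random_spd"`.
#' @param seed integer seed (random mode).
#' @return symmetric `nbf x nbf` matrix.
#' @export
make_density <- function(sys, mode = c("sad", "random_spd"), seed = 1L) {
  mode <- match.arg(mode)
  nel_atom <- ELEMENT_Z[sys$atoms$element]
  if (mode == "sad") {
    d <- numeric(sys$nbf)
    for (ia in seq_len(nrow(sys$atoms))) {
      idx <- unlist(lapply(sys$shells, function(sh) {
        if (sh$atom == ia) sh$offset + seq_len(sh$nf) else integer(0)
      }))
      d[idx] <- nel_atom[ia] / length(idx)
    }
    diag(d, nrow = sys$nbf)
  } else {
    set.seed(seed)
    A <- matrix(stats::rnorm(sys$nbf^2), sys$nbf)
    D <- tcrossprod(A) / sys$nbf
    D * (sum(nel_atom) / sum(diag(D)))
  }
}

#' Multipole-parameter convergence study
#'
#' Re-runs the RI-BUPO-J build along a grid of one configuration parameter,
#' everything else fixed, measuring the Coulomb-energy error against the
#' analytic Split-RI-J result on the same inputs. Output is plot-ready.
#'
#' @param param one of `"Lmax_step1"`, `"Lincr1_step1"`, `"Lmax_step2"`,
#'   `"Lincr1_step2"`, `"Lincr2"`, `"TargetDim1"`.
#' @param grid numeric vector of parameter values.
#' @param sys `bupo_system`.
#' @param D density matrix.
#' @param cfg base configuration.
#' @return data.frame with columns `value`, `energy_error` (Hartree,
#'   signed), `abs_error`, and near/far-field batch percentages.
#' @export
convergence_study <- function(param, grid, sys, D, cfg = bupo_config()) {
  stopifnot(param %in% c("Lmax_step1", "Lincr1_step1", "Lmax_step2",
                         "Lincr1_step2", "Lincr2", "TargetDim1"))
  eng <- bupo_engine(sys, cfg)
  E_ref <- split_rij_J(eng, D)$energy
  rows <- lapply(grid, function(v) {
    if (param == "TargetDim1") {
      cfg2 <- cfg; cfg2$TargetDim1 <- as.integer(v)
      eng2 <- bupo_engine(sys, cfg2)
    } else {
      eng2 <- eng
      eng2$cfg[[param]] <- as.integer(v)
    }
    res <- rbupo_J(eng2, D)
    st <- res$stats
    data.frame(value = v, energy_error = res$energy - E_ref,
               abs_error = abs(res$energy - E_ref),
               pct_nf = sum(st$nf) / sum(st$nf + st$ff + st$skipped) * 100,
               pct_ff = sum(st$ff) / sum(st$nf + st$ff + st$skipped) * 100)
  })
  do.call(rbind, rows)
}
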