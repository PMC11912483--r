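# Basis-set ingestion and shell construction.
#
# Text format (documented in the README, round-trips bit-exactly):
#   element H
#   s  13.0 0.032828  2.0 0.231204  0.44 0.817226
#   element X
#   s  16.0 0.35  2.5 0.65
#   p  1.0 1.0
# One line per shell: angular momentum letter (s p d f g h) or integer,
# followed by exponent/coefficient pairs.  Coefficients are understood with
# respect to unit-normalized primitives and are renormalized on input so the
# stored contraction gives unit self-overlap for every basis function.

L_LETTERS <- c(s = 0L, p = 1L, d = 2L, f = 3L, g = 4L, h = 5L)

# contracted self-overlap matrix between unit-normalized primitives of equal l
prim_overlap <- function(l, exps) {
  outer(exps, exps, function(a, b) (2 * sqrt(a * b) / (a + b))^(l + 1.5))
}

# renormalize contraction coefficients to unit self-overlap
normalize_contraction <- function(l, exps, coefs) {
  S <- prim_overlap(l, exps)
  coefs / sqrt(drop(crossprod(coefs, S %*% coefs)))
}

# radial norm of a primitive solid-harmonic Gaussian, split so that the
# angular part is carried by the (alpha-independent) spherical transform
radial_norm <- function(alpha, l) {
  1 / sqrt(gamma(l + 1.5) / (2 * (2 * alpha)^(l + 1.5)))
}

# Cartesian -> real spherical transform for shell l, including the angular
# normalization 1/sqrt(A_lm); rows m = -l..l, columns monomials(l)
sph_transform <- function(l) {
  key <- paste0("tsph", l)
  cache_get(key, function() {
    solid_coef_real(l) / sqrt(solid_angular_norm(l))
  })
}

#' Read a plain-text basis set
#'
#' @param path basis file path.
#' @return named list (per element) of shells, each a list with fields `l`,
#'   `exps` (descending), `coefs` (renormalized to unit self-overlap);
#'   class `bupo_basis`.
#' @export
read_basis <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  cur <- NULL
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1L]]
    if (tolower(tok[1L]) == "element") {
      cur <- tok[2L]
      out[[cur]] <- out[[cur]] %||% list()
    } else {
      if (is.null(cur)) stop("read_basis(): shell line before any 'element' header")
      l <- if (tolower(tok[1L]) %in% names(L_LETTERS)) {
        L_LETTERS[[tolower(tok[1L])]]
      } else suppressWarnings(as.integer(tok[1L]))
      if (is.na(l) || l < 0L) stop("read_basis(): bad angular momentum in line: ", ln)
      if (l > L_SHELL_MAX) stop("read_basis(): angular momentum ", l, " above supported cap ", L_SHELL_MAX)
      vals <- suppressWarnings(as.numeric(tok[-1L]))
      if (anyNA(vals) || length(vals) == 0L || length(vals) %% 2L != 0L) {
        stop("read_basis(): expected exponent/coefficient pairs in line: ", ln)
      }
      exps <- vals[seq(1L, length(vals), by = 2L)]
      coefs <- vals[seq(2L, length(vals), by = 2L)]
      if (any(exps <= 0)) stop("read_basis(): non-positive exponent in line: ", ln)
      ord <- order(exps, decreasing = TRUE)
      exps <- exps[ord]; coefs <- coefs[ord]
      out[[cur]] <- c(out[[cur]], list(list(
        l = l, exps = exps, coefs = normalize_contraction(l, exps, coefs)
      )))
    }
  }
  structure(out, class = "bupo_basis")
}

#' @rdname read_basis
#' @param basis `bupo_basis` object.
#' @export
write_basis <- function(basis, path) {
  lines <- character(0)
  for (el in names(basis)) {
    lines <- c(lines, paste("element", el))
    for (sh in basis[[el]]) {
      lines <- c(lines, paste(
        names(L_LETTERS)[sh$l + 1L],
        paste(sprintf("%.17g %.17g", sh$exps, sh$coefs), collapse = "  ")
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# in-memory basis constructor (used by the synthetic generators)
basis_set <- function(per_element) {
  out <- lapply(per_element, function(shells) {
    lapply(shells, function(sh) {
      ord <- order(sh$exps, decreasing = TRUE)
      list(l = sh$l, exps = sh$exps[ord],
           coefs = normalize_contraction(sh$l, sh$exps[ord], sh$coefs[ord]))
    })
  })
  structure(out, class = "bupo_basis")
}

#' Assemble a molecular system
#'
#' Instantiates the per-element basis on every atom, producing the shell
#' list, function offsets, and (when an auxiliary basis is given) the
#' auxiliary shell list with rigorous single-shell extents.
#'
#' @param atoms `bupo_atoms` object.
#' @param basis orbital basis (`bupo_basis`).
#' @param aux auxiliary (fitting) basis, or NULL.
#' @param T_sphere extent threshold used for auxiliary-shell extents.
#' @param diffuse_cutoff auxiliary extent (Bohr) above which a shell is
#'   flagged diffuse and routed to the throwaway bubble.
#' @return list of class `bupo_system`.
#' @export
build_system <- function(atoms, basis, aux = NULL, T_sphere = 1e-8,
                         diffuse_cutoff = 20) {
  missing_el <- setdiff(unique(atoms$element), names(basis))
  if (length(missing_el)) stop("no basis for element(s): ", paste(missing_el, collapse = ", "))
  shells <- list(); off <- 0L
  for (ia in seq_len(nrow(atoms))) {
    for (sh in basis[[atoms$element[ia]]]) {
      shells[[length(shells) + 1L]] <- list(
        atom = ia, l = sh$l, exps = sh$exps, coefs = sh$coefs,
        center = c(atoms$x[ia], atoms$y[ia], atoms$z[ia]),
        nf = 2L * sh$l + 1L, offset = off
      )
      off <- off + 2L * sh$l + 1L
    }
  }
  sys <- list(atoms = atoms, shells = shells, nbf = off, aux_shells = NULL, naux = 0L)
  if (!is.null(aux)) {
    missing_el <- setdiff(unique(atoms$element), names(aux))
    if (length(missing_el)) stop("no auxiliary basis for element(s): ", paste(missing_el, collapse = ", "))
    ash <- list(); aoff <- 0L
    for (ia in seq_len(nrow(atoms))) {
      for (sh in aux[[atoms$element[ia]]]) {
        ext <- cosx_radius(sh, T_sphere)
        ash[[length(ash) + 1L]] <- list(
          atom = ia, l = sh$l, exps = sh$exps, coefs = sh$coefs,
          center = c(atoms$x[ia], atoms$y[ia], atoms$z[ia]),
          nf = 2L * sh$l + 1L, offset = aoff,
          extent = ext, diffuse = ext > diffuse_cutoff
        )
        aoff <- aoff + 2L * sh$l + 1L
      }
    }
    sys$aux_shells <- ash
    sys$naux <- aoff
  }
  class(sys) <- "bupo_system"
  sys
}

#' @export
print.bupo_system <- function(x, ...) {
  cat("bupo_system:", nrow(x$atoms), "atoms,", length(x$shells), "shells,",
      x$nbf, "basis functions")
  if (x$naux > 0L) cat(",", length(x$aux_shells), "aux shells,", x$naux, "aux functions")
  cat("\n")
  invisible(x)
}

#' Hermite distribution of a single (auxiliary) shell
#'
#' Packs a shell record into the Hermite-distribution form consumed by
#' [eri_dist()] and [dist_multipoles()]: one primitive entry per contraction
#' primitive, each with the exponent, the center, and the E matrix mapping
#' Hermite indices to the shell's spherical functions.
#'
#' @param shell shell record (fields `l`, `exps`, `coefs`, `center`).
#' @return Hermite distribution (list with `prims`, `nfun`, `center`, `l`).
#' @export
aux_dist <- function(shell) {
  l <- shell$l
  h <- hermite_indices(l)
  cart <- monomials(l)
  Ts <- sph_transform(l)
  prims <- vector("list", length(shell$exps))
  for (k in seq_along(shell$exps)) {
    a <- shell$exps[k]
    Ex <- hermite_E1d(l, 0L, a, 0, 0)
    Ecart <- matrix(0, nrow(h), nrow(cart))
    for (cc in seq_len(nrow(cart))) {
      Ecart[, cc] <- Ex[cart[cc, 1L] + 1L, 1L, h[, 1L] + 1L] *
        Ex[cart[cc, 2L] + 1L, 1L, h[, 2L] + 1L] *
        Ex[cart[cc, 3L] + 1L, 1L, h[, 3L] + 1L]
    }
    w <- shell$coefs[k] * radial_norm(a, l)
    prims[[k]] <- list(p = a, P = shell$center, lsum = l, E = w * Ecart %*% t(Ts))
  }
  list(prims = prims, nfun = 2L * l + 1L, center = shell$center, l = l)
}
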