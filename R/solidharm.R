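# Real scaled solid harmonics.
#
# The whole multipole machinery runs over *scaled* solid harmonics
#   Rt_l^m(r) = r^l P_l^m(cos th) e^{i m phi} / (l+m)!
#             = R_l^m(r) / sqrt((l+m)!(l-m)!)          (Racah-normalized R)
#   It_l^m(r) = (l-m)! P_l^m(cos th) e^{i m phi} / r^{l+1}
# With this symmetric scaling the solid-harmonic addition theorem is
# coefficient-free, so the translation matrix entries are themselves scaled
# regular solids of the displacement, and coefficient magnitudes stay bounded
# to very high order (no factorial growth).  Real forms are obtained through
# the standard unitary complex-to-real transform; interaction and translation
# matrices are assembled once as real matrices so that all contractions are
# plain real matrix products.

# flat index of (l, m) in a packed l = 0..L, m = -l..l vector
lm_index <- function(l, m) l * l + l + m + 1L

# ---- complex value recursions ------------------------------------------------

# scaled regular solids Rt_l^m(r) for l = 0..L, packed (l,m); complex vector
regular_complex <- function(L, r) {
  x <- r[1]; y <- r[2]; z <- r[3]
  rr <- x * x + y * y + z * z
  out <- complex(length.out = (L + 1L)^2)
  out[1L] <- 1 + 0i
  if (L == 0L) return(out)
  xy <- complex(real = x, imaginary = y)
  diag_val <- 1 + 0i
  for (l in 1:L) {
    diag_val <- diag_val * (-xy / (2 * l))
    out[lm_index(l, l)] <- diag_val
    out[lm_index(l, -l)] <- (-1)^l * Conj(diag_val)
    for (m in 0:(l - 1L)) {
      r1 <- out[lm_index(l - 1L, m)]
      r2 <- if (m <= l - 2L) out[lm_index(l - 2L, m)] else 0 + 0i
      v <- ((2 * l - 1) * z * r1 - rr * r2) / ((l + m) * (l - m))
      out[lm_index(l, m)] <- v
      if (m > 0L) out[lm_index(l, -m)] <- (-1)^m * Conj(v)
    }
  }
  out
}

# scaled irregular solids It_l^m(r) for l = 0..L, packed (l,m); complex vector
irregular_complex <- function(L, r) {
  x <- r[1]; y <- r[2]; z <- r[3]
  rr <- x * x + y * y + z * z
  if (rr == 0) stop("irregular solid harmonics undefined at the origin")
  out <- complex(length.out = (L + 1L)^2)
  out[1L] <- 1 / sqrt(rr) + 0i
  if (L == 0L) return(out)
  xy <- complex(real = x, imaginary = y)
  diag_val <- out[1L]
  for (l in 1:L) {
    diag_val <- diag_val * (-(2 * l - 1) * xy / rr)
    out[lm_index(l, l)] <- diag_val
    out[lm_index(l, -l)] <- (-1)^l * Conj(diag_val)
    for (m in 0:(l - 1L)) {
      i1 <- out[lm_index(l - 1L, m)]
      i2 <- if (m <= l - 2L) out[lm_index(l - 2L, m)] else 0 + 0i
      v <- ((2 * l - 1) * z * i1 - ((l - 1)^2 - m^2) * i2) / rr
      out[lm_index(l, m)] <- v
      if (m > 0L) out[lm_index(l, -m)] <- (-1)^m * Conj(v)
    }
  }
  out
}

# ---- complex <-> real transform ---------------------------------------------

# unitary block U_l with X_l = U_l %*% Rt_l (columns/rows ordered m = -l..l);
# rows -m are sine components, row 0 the zonal one, rows +m cosine components.
u_block <- function(l) {
  key <- paste0("ublock", l)
  cache_get(key, function() {
    n <- 2L * l + 1L
    U <- matrix(0 + 0i, n, n)
    U[l + 1L, l + 1L] <- 1 + 0i
    if (l > 0L) for (m in 1:l) {
      ip <- l + 1L + m   # row/col of +m
      im <- l + 1L - m   # row/col of -m
      s <- (-1)^m / sqrt(2)
      U[ip, ip] <- s
      U[ip, im] <- 1 / sqrt(2)
      U[im, ip] <- complex(imaginary = -1) * s
      U[im, im] <- complex(imaginary = 1) / sqrt(2)
    }
    U
  })
}

# apply per-l U blocks to a packed complex (l,m) vector -> real vector
complex_to_real_vec <- function(v, L) {
  out <- numeric((L + 1L)^2)
  for (l in 0:L) {
    idx <- lm_index(l, -l):lm_index(l, l)
    w <- u_block(l) %*% v[idx]
    out[idx] <- Re(w)
  }
  out
}

#' Real scaled regular solid harmonics at a point
#'
#' Evaluates the packed vector of real scaled regular solid harmonics
#' \eqn{X_{lm}(r)}, `l = 0..L`, `m = -l..l` (sine components at negative m,
#' cosine at positive m). The multipole moment of a unit point charge at
#' displacement `r` from the expansion center is exactly this vector.
#'
#' @param L maximum order.
#' @param r 3-vector, Bohr.
#' @return numeric vector of length `(L+1)^2`.
#' @export
regular_solid_real <- function(L, r) {
  complex_to_real_vec(regular_complex(L, r), L)
}

# ---- Cartesian coefficient tables -------------------------------------------

# complex scaled regular solids of degree l as polynomials over the monomials
# of total degree l; rows m = 0..l, columns ordered like monomials(l)
solid_poly_complex <- function(l) {
  key <- paste0("spolyc", l)
  cache_get(key, function() {
    mono_pos <- function(n) {
      mm <- monomials(n)
      idx <- new.env(parent = emptyenv())
      for (r in seq_len(nrow(mm))) assign(paste(mm[r, ], collapse = ","), r, envir = idx)
      function(t, u, v) get(paste(c(t, u, v), collapse = ","), envir = idx)
    }
    if (l == 0L) return(matrix(1 + 0i, 1L, 1L))
    prev <- solid_poly_complex(l - 1L)     # rows m=0..l-1, degree l-1
    prev2 <- if (l >= 2L) solid_poly_complex(l - 2L) else NULL
    ml <- monomials(l); posl <- mono_pos(l)
    ml1 <- monomials(l - 1L)
    out <- matrix(0 + 0i, l + 1L, nrow(ml))
    # m = l (diagonal): Rt_l^l = Rt_{l-1}^{l-1} * ( -(x+iy) / (2l) )
    for (c1 in seq_len(nrow(ml1))) {
      co <- prev[l, c1]  # row index l = m=l-1
      if (co == 0) next
      t <- ml1[c1, 1L]; u <- ml1[c1, 2L]; v <- ml1[c1, 3L]
      out[l + 1L, posl(t + 1L, u, v)] <- out[l + 1L, posl(t + 1L, u, v)] - co / (2 * l)
      out[l + 1L, posl(t, u + 1L, v)] <- out[l + 1L, posl(t, u + 1L, v)] - complex(imaginary = 1) * co / (2 * l)
    }
    # vertical recursion for m = 0..l-1
    for (m in 0:(l - 1L)) {
      acc <- complex(length.out = nrow(ml))
      for (c1 in seq_len(nrow(ml1))) {       # (2l-1) z * Rt_{l-1}^m
        co <- prev[m + 1L, c1]
        if (co == 0) next
        acc[posl(ml1[c1, 1L], ml1[c1, 2L], ml1[c1, 3L] + 1L)] <-
          acc[posl(ml1[c1, 1L], ml1[c1, 2L], ml1[c1, 3L] + 1L)] + (2 * l - 1) * co
      }
      if (m <= l - 2L) {                     # - r^2 * Rt_{l-2}^m
        ml2 <- monomials(l - 2L)
        for (c1 in seq_len(nrow(ml2))) {
          co <- prev2[m + 1L, c1]
          if (co == 0) next
          t <- ml2[c1, 1L]; u <- ml2[c1, 2L]; v <- ml2[c1, 3L]
          acc[posl(t + 2L, u, v)] <- acc[posl(t + 2L, u, v)] - co
          acc[posl(t, u + 2L, v)] <- acc[posl(t, u + 2L, v)] - co
          acc[posl(t, u, v + 2L)] <- acc[posl(t, u, v + 2L)] - co
        }
      }
      out[m + 1L, ] <- acc / ((l + m) * (l - m))
    }
    out
  })
}

#' Cartesian coefficients of real scaled solid harmonics
#'
#' Returns the coefficient matrix `C` with `C[m_idx, mono_idx]` such that
#' \eqn{X_{lm}(x,y,z) = \sum_{tuv} C x^t y^u z^v} over the monomials of
#' total degree `l` (ordering of [monomials()]). Rows are ordered
#' `m = -l..l`.
#'
#' @param l angular momentum.
#' @return real matrix `(2l+1) x ((l+1)(l+2)/2)`.
#' @export
solid_coef_real <- function(l) {
  key <- paste0("spolyr", l)
  cache_get(key, function() {
    pc <- solid_poly_complex(l)
    out <- matrix(0, 2L * l + 1L, ncol(pc))
    out[l + 1L, ] <- Re(pc[1L, ])
    if (l > 0L) for (m in 1:l) {
      out[l + 1L + m, ] <- (-1)^m * sqrt(2) * Re(pc[m + 1L, ])
      out[l + 1L - m, ] <- (-1)^m * sqrt(2) * Im(pc[m + 1L, ])
    }
    out
  })
}

# angular self-integrals  A_lm = int |x_lm(rhat)|^2 dOmega  (per m, vector)
solid_angular_norm <- function(l) {
  key <- paste0("sangn", l)
  cache_get(key, function() {
    co <- solid_coef_real(l)
    mm <- monomials(l)
    n <- nrow(mm)
    smom <- matrix(0, n, n)
    for (a in seq_len(n)) for (b in a:n) {
      s <- sphere_moment(mm[a, 1L] + mm[b, 1L], mm[a, 2L] + mm[b, 2L], mm[a, 3L] + mm[b, 3L])
      smom[a, b] <- s; smom[b, a] <- s
    }
    rowSums((co %*% smom) * co)
  })
}

# ---- interaction and translation matrices -----------------------------------

#' Multipole interaction tensor
#'
#' Real interaction matrix `T` coupling two real scaled solid-harmonic
#' multipole vectors: the (approximate) Coulomb interaction of two
#' non-overlapping distributions is `t(M_P) %*% T %*% M_Q`.  Entries decay
#' as \eqn{|P-Q|^{-l-l'-1}}.
#'
# apply the complex-to-real transform on both sides of a complex (2l1+1) x
# (2l2+1) block, i.e. Re(conj(U_l1) %*% blk %*% t(Conj(U_l2))), exploiting the
# two-nonzeros-per-row structure of U (O(size) instead of two matmuls)
real_block <- function(blk, l1, l2) {
  A <- blk
  if (l1 > 0L) for (m in 1:l1) {
    pm <- l1 + 1L + m; mm <- l1 + 1L - m
    s <- (-1)^m
    top <- blk[pm, ]; bot <- blk[mm, ]
    A[pm, ] <- (s * top + bot) / sqrt(2)
    A[mm, ] <- 1i * (s * top - bot) / sqrt(2)
  }
  out <- A
  if (l2 > 0L) for (m in 1:l2) {
    pm <- l2 + 1L + m; mm <- l2 + 1L - m
    s <- (-1)^m
    rgt <- A[, pm]; lft <- A[, mm]
    out[, pm] <- (s * rgt + lft) / sqrt(2)
    out[, mm] <- 1i * (s * rgt - lft) / sqrt(2)
  }
  Re(out)
}

# cached flat-index matrix idx[m1+l1+1, m2+l2+1] = lm_index(l1+l2, m1+m2)
ti_index <- function(l1, l2) {
  key <- paste0("tiidx", l1, "_", l2)
  cache_get(key, function() {
    outer(-l1:l1, -l2:l2, function(m1, m2) lm_index(l1 + l2, m1 + m2))
  })
}

# cached index/mask for the translation block (l <- lp): entry (m, mp) picks
# lm_index(l - lp, m - mp) where |m - mp| <= l - lp, else 0
tr_index <- function(l, lp) {
  key <- paste0("tridx", l, "_", lp)
  cache_get(key, function() {
    dm <- outer(-l:l, -lp:lp, `-`)
    idx <- lm_index(l - lp, dm)
    idx[abs(dm) > l - lp] <- NA_integer_
    idx
  })
}

#' @param P,Q expansion centers (3-vectors, Bohr), `P != Q`.
#' @param L,Lp maximum orders of the bra/ket multipole vectors.
#' @return real matrix `(L+1)^2 x (Lp+1)^2`.
#' @export
interaction_tensor <- function(P, Q, L, Lp) {
  .interaction_tensor_cpp(P, Q, as.integer(L), as.integer(Lp))
}

#' Multipole translation matrix
#'
#' Real matrix `W` that moves a real multipole vector expanded about `from`
#' to an expansion about `to`: `M_new = W %*% M_old`.  `W` is lower
#' triangular in `l` with identity diagonal blocks, so zero displacement
#' gives the identity; choosing `Lto > Lfrom` performs an up-translation.
#'
#' @param from,to old and new expansion centers (3-vectors, Bohr).
#' @param Lfrom order of the incoming vector.
#' @param Lto order of the translated vector, `Lto >= Lfrom`.
#' @return real matrix `(Lto+1)^2 x (Lfrom+1)^2`.
#' @export
translation_matrix <- function(from, to, Lfrom, Lto = Lfrom) {
  stopifnot(Lto >= Lfrom)
  .translation_matrix_cpp(from, to, as.integer(Lfrom), as.integer(Lto))
}
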