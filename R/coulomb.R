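# Coulomb builders: classic RI-J, Hermite-basis Split-RI-J, the two-step
# linear-scaling RI-BUPO-J, and the non-RI BUPO-J variant (four-index near
# field) that doubles as a second oracle family.

#' Far-field allowedness gate
#'
#' Decides whether the multipole approximation may couple an object (center +
#' extent) to a bubble (center + radius). In the default `"ratio"` reading
#' the interaction is allowed iff
#' `|C_obj - C_bub| >= R_allow * (extent + radius)` (boundary inclusive);
#' the `"offset"` reading requires an additive clearance of `R_allow` Bohr
#' beyond touching. `R_allow = Inf` disables the far field entirely.
#'
#' @param obj_center,obj_extent object sphere.
#' @param bub_center,bub_radius bubble sphere.
#' @param R_allow safety factor (>= 1 guarantees a convergent expansion).
#' @param mode `"ratio"` or `"offset"`.
#' @return logical.
#' @export
mp_allowed <- function(obj_center, obj_extent, bub_center, bub_radius,
                       R_allow = 1, mode = "ratio") {
  d <- vnorm(obj_center - bub_center)
  if (mode == "ratio") d >= R_allow * (obj_extent + bub_radius)
  else d - obj_extent - bub_radius >= R_allow
}

#' Pivoted-Cholesky fit solve
#'
#' Solves `M x = g` for the auxiliary-basis density with a pivoted Cholesky
#' factorization, dropping pivots below `tol` relative to the largest
#' (robust against a nearly overcomplete fitting basis).
#'
#' @param M symmetric positive (semi-)definite metric.
#' @param g right-hand side vector.
#' @param tol relative pivot drop tolerance.
#' @return solution vector.
#' @export
solve_fit <- function(M, g, tol = 1e-12) {
  n <- nrow(M)
  ch <- tryCatch(suppressWarnings(chol(M, pivot = TRUE, tol = 0)),
                 error = function(e) stop("solve_fit(): metric is not positive semi-definite: ", conditionMessage(e)))
  piv <- attr(ch, "pivot")
  r <- attr(ch, "rank") %||% n
  d <- diag(ch)^2
  if (d[1L] <= 0) stop("solve_fit(): metric is not positive semi-definite (largest pivot ", d[1L], ")")
  # rows beyond the factorization rank are not meaningful; additionally drop
  # pivots below the relative tolerance
  r <- min(r, sum(d[seq_len(r)] > tol * d[1L]))
  if (r == 0L) {
    stop("solve_fit(): metric is not positive semi-definite (no positive pivot)")
  }
  R <- ch[seq_len(r), seq_len(r), drop = FALSE]
  x <- numeric(n)
  x[piv[seq_len(r)]] <- backsolve(R, forwardsolve(t(R), g[piv[seq_len(r)]]))
  res <- max(abs(M %*% x - g))
  if (res > 1e-8 * max(abs(g), 1)) {
    stop("solve_fit(): metric is not positive semi-definite within tolerance ",
         "(residual ", format(res, digits = 3), ", smallest kept pivot ",
         format(d[r], digits = 3), ")")
  }
  x
}

# ---- engine -----------------------------------------------------------------

#' Precompute the integral/bubble infrastructure for a system
#'
#' Builds screened shell pairs, auxiliary Hermite distributions, the
#' positive-definite two-index metric, cached Schwarz factors, and the
#' density-independent bubble hierarchy skeletons (shell-pair bubbles by
#' balanced k-means; auxiliary bubbles atomic or k-means). Objects whose
#' extent exceeds the diffuse cutoff go to the always-near-field throwaway
#' bubble. Every Coulomb builder runs off one engine.
#'
#' @param sys `bupo_system` with an auxiliary basis.
#' @param cfg `bupo_config`.
#' @return list of class `bupo_engine`.
#' @export
bupo_engine <- function(sys, cfg = bupo_config()) {
  stopifnot(inherits(sys, "bupo_system"))
  pairs <- build_shell_pairs(sys, cfg$prescreen, cfg$T_sphere)
  eng <- list(sys = sys, cfg = cfg, pairs = pairs,
              nbf = sys$nbf, naux = sys$naux)
  if (!is.null(sys$aux_shells)) {
    auxd <- lapply(sys$aux_shells, aux_dist)
    eng$auxd <- auxd
    eng$aux_off <- vapply(sys$aux_shells, `[[`, 0L, "offset")
    eng$aux_l <- vapply(sys$aux_shells, `[[`, 0L, "l")
    eng$aux_centers <- do.call(rbind, lapply(sys$aux_shells, `[[`, "center"))
    eng$aux_extents <- vapply(sys$aux_shells, `[[`, 0, "extent")
    # metric and per-shell Schwarz factors sqrt(max |(K|K)|)
    M <- matrix(0, sys$naux, sys$naux)
    nK <- length(auxd)
    sqrtKK <- numeric(nK)
    for (i in seq_len(nK)) {
      ii <- eng$aux_off[i] + seq_len(sys$aux_shells[[i]]$nf)
      for (j in i:nK) {
        jj <- eng$aux_off[j] + seq_len(sys$aux_shells[[j]]$nf)
        blk <- eri_dist(auxd[[i]], auxd[[j]])
        M[ii, jj] <- blk
        M[jj, ii] <- t(blk)
        if (j == i) sqrtKK[i] <- sqrt(max(abs(blk)))
      }
    }
    eng$M <- M
    eng$sqrtKK <- sqrtKK
    # auxiliary bubble skeleton
    diffuse <- vapply(sys$aux_shells, `[[`, TRUE, "diffuse")
    eng$aux_throwaway <- which(diffuse)
    keep <- which(!diffuse)
    if (length(keep)) {
      if (cfg$aux_bubbles == "atomic") {
        byatom <- split(keep, vapply(sys$aux_shells[keep], `[[`, 0L, "atom"))
        l1 <- lapply(byatom, function(g) {
          make_bubble(1L, g, eng$aux_centers, eng$aux_extents)
        })
      } else {
        l1 <- kmeans_bubbles(eng$aux_centers[keep, , drop = FALSE],
                             eng$aux_extents[keep], cfg$TargetDim1, cfg$seed)
        l1 <- lapply(l1, function(b) { b$members <- keep[b$members]; b })
        # recompute spheres in global indexing
        l1 <- lapply(l1, function(b) make_bubble(1L, b$members, eng$aux_centers, eng$aux_extents))
      }
      eng$aux_hier <- build_hierarchy(l1, cfg$TargetDim2, cfg$max_levels)
    }
  }
  # shell-pair bubble skeleton
  pc <- do.call(rbind, lapply(pairs, `[[`, "P"))
  pe <- vapply(pairs, `[[`, 0, "extent")
  eng$pair_centers <- pc
  eng$pair_extents <- pe
  pdiff <- which(pe > cfg$diffuse_cutoff)
  eng$pair_throwaway <- pdiff
  pkeep <- setdiff(seq_along(pairs), pdiff)
  if (length(pkeep)) {
    l1 <- kmeans_bubbles(pc[pkeep, , drop = FALSE], pe[pkeep],
                         cfg$TargetDim1, cfg$seed)
    l1 <- lapply(l1, function(b) {
      b$members <- pkeep[b$members]
      make_bubble(1L, b$members, pc, pe)
    })
    eng$pair_hier <- build_hierarchy(l1, cfg$TargetDim2, cfg$max_levels)
  }
  class(eng) <- "bupo_engine"
  eng
}

#' @export
print.bupo_engine <- function(x, ...) {
  cat("bupo_engine:", x$nbf, "basis /", x$naux, "aux functions,",
      length(x$pairs), "shell pairs,",
      if (!is.null(x$pair_hier)) x$pair_hier$nlevels else 0, "pair-bubble levels\n")
  invisible(x)
}

# density-weighted multipoles + PKMAX for the shell-pair hierarchy
fill_pair_hierarchy <- function(eng, D, Lmax, Lincr_sched, T_screen) {
  pairs <- eng$pairs
  moments <- lapply(pairs, function(pr) dist_multipoles(pr, pr$P, Lmax))
  weights <- lapply(pairs, pair_density, D = D)
  pk <- vapply(seq_along(pairs), function(i) {
    idx <- pair_block_indices(pairs[[i]])
    pairs[[i]]$K * max(abs(D[idx]))
  }, 0)
  h <- aggregate_bottom_multipoles(eng$pair_hier, moments, eng$pair_centers,
                                   weights, pk, Lmax, T_screen)
  up_translate(h, Lincr_sched, T_screen)
}

# aux-density-weighted multipoles + Schwarz factors for the aux hierarchy
fill_aux_hierarchy <- function(eng, cK, Lincr_sched, T_screen) {
  sh <- eng$sys$aux_shells
  moments <- lapply(seq_along(sh), function(k) {
    dist_multipoles(eng$auxd[[k]], sh[[k]]$center, sh[[k]]$l)
  })
  weights <- lapply(seq_along(sh), function(k) {
    cK[eng$aux_off[k] + seq_len(sh[[k]]$nf)]
  })
  pk <- vapply(seq_along(sh), function(k) {
    eng$sqrtKK[k] * max(abs(weights[[k]]))
  }, 0)
  Lbot <- max(eng$aux_l)
  h <- aggregate_bottom_multipoles(eng$aux_hier, moments, eng$aux_centers,
                                   weights, pk, Lbot, T_screen)
  up_translate(h, Lincr_sched, T_screen)
}

new_stats <- function() list(nf = 0L, ff = 0L, skipped = 0L)

stats_row <- function(stage, st) {
  tot <- st$nf + st$ff + st$skipped
  data.frame(stage = stage, nf = st$nf, ff = st$ff, skipped = st$skipped,
             pct_nf = if (tot) 100 * st$nf / tot else NA_real_,
             pct_ff = if (tot) 100 * st$ff / tot else NA_real_,
             pct_skipped = if (tot) 100 * st$skipped / tot else NA_real_)
}

bupo_result <- function(J, D, stats, method) {
  J <- 0.5 * (J + t(J))   # enforce exact symmetry of the accumulated matrix
  structure(list(J = J, energy = 0.5 * sum(D * J), stats = stats,
                 method = method), class = "bupo_jresult")
}

#' @export
print.bupo_jresult <- function(x, ...) {
  cat(x$method, "Coulomb build: energy", format(x$energy, digits = 12), "Eh\n")
  if (!is.null(x$stats) && nrow(x$stats)) print(x$stats, row.names = FALSE)
  invisible(x)
}

# ---- analytic builders ------------------------------------------------------

#' Classic RI-J Coulomb build
#'
#' Three-step density fitting: project the density onto the auxiliary basis
#' (`g_K = sum_{munu} D (K|munu)`), solve the metric equations for the
#' auxiliary density, and assemble `J = sum_K c_K (K|munu)`. All three-index
#' blocks are evaluated analytically.
#'
#' @param eng `bupo_engine`.
#' @param D symmetric density-like matrix (AO basis).
#' @return `bupo_jresult` with the Coulomb matrix, energy
#'   `1/2 tr(D J)`, and batch statistics.
#' @export
rij_J <- function(eng, D) {
  pairs <- eng$pairs
  g <- numeric(eng$naux)
  blocks <- vector("list", length(pairs))
  for (ip in seq_along(pairs)) {
    pr <- pairs[[ip]]
    d <- pair_density(pr, D)
    B <- matrix(0, eng$naux, pr$nfun)
    for (k in seq_along(eng$auxd)) {
      B[eng$aux_off[k] + seq_len(eng$auxd[[k]]$nfun), ] <-
        eri_dist(eng$auxd[[k]], pr)
    }
    blocks[[ip]] <- B
    g <- g + drop(B %*% d)
  }
  cK <- solve_fit(eng$M, g)
  J <- matrix(0, eng$nbf, eng$nbf)
  for (ip in seq_along(pairs)) {
    pr <- pairs[[ip]]
    v <- drop(crossprod(blocks[[ip]], cK))
    idx <- pair_block_indices(pr)
    J[idx] <- v
    if (pr$I != pr$J) J[idx[, 2:1, drop = FALSE]] <- v
  }
  st <- new_stats(); st$nf <- 2L * length(pairs) * length(eng$auxd)
  bupo_result(J, D, rbind(stats_row("step1", st)[0, ], stats_row("total", st)), "RI-J")
}

#' Split-RI-J Coulomb build (Hermite basis)
#'
#' Numerically identical to [rij_J()], but the rate-determining contractions
#' run in the Hermite-Gaussian basis: the density is transformed with the
#' pair E matrices, the auxiliary vector and the Hermite Coulomb matrix are
#' formed through Hermite repulsion integrals, and results are back
#' transformed at the end.
#'
#' @inheritParams rij_J
#' @return `bupo_jresult`.
#' @export
split_rij_J <- function(eng, D) {
  pairs <- eng$pairs
  # Hermite-basis density per pair primitive
  dh <- lapply(pairs, function(pr) {
    d <- pair_density(pr, D)
    lapply(pr$prims, function(pp) {
      h <- hermite_indices(pp$lsum)
      sgn <- (-1)^(h[, 1L] + h[, 2L] + h[, 3L])
      list(p = pp$p, P = pp$P, lsum = pp$lsum, v = sgn * drop(pp$E %*% d))
    })
  })
  g <- numeric(eng$naux)
  for (k in seq_along(eng$auxd)) {
    dk <- eng$auxd[[k]]
    acc <- 0
    for (pk in dk$prims) {
      hk <- hermite_indices(pk$lsum)
      gh <- numeric(nrow(hk))
      for (ip in seq_along(pairs)) for (ph in dh[[ip]]) {
        gh <- gh + .rvec_contract_cpp(pk$p, pk$P, pk$lsum,
                                      ph$p, ph$P, ph$lsum, ph$v)
      }
      acc <- acc + drop(crossprod(pk$E, gh))
    }
    g[eng$aux_off[k] + seq_len(dk$nfun)] <- acc
  }
  cK <- solve_fit(eng$M, g)
  # Hermite auxiliary density
  ch <- lapply(seq_along(eng$auxd), function(k) {
    dk <- eng$auxd[[k]]
    ckseg <- cK[eng$aux_off[k] + seq_len(dk$nfun)]
    lapply(dk$prims, function(pk) {
      h <- hermite_indices(pk$lsum)
      sgn <- (-1)^(h[, 1L] + h[, 2L] + h[, 3L])
      list(p = pk$p, P = pk$P, lsum = pk$lsum, v = sgn * drop(pk$E %*% ckseg))
    })
  })
  J <- matrix(0, eng$nbf, eng$nbf)
  for (ip in seq_along(pairs)) {
    pr <- pairs[[ip]]
    v <- numeric(pr$nfun)
    for (pp in pr$prims) {
      hp <- hermite_indices(pp$lsum)
      Jt <- numeric(nrow(hp))
      for (k in seq_along(eng$auxd)) for (pc in ch[[k]]) {
        Jt <- Jt + .rvec_contract_cpp(pp$p, pp$P, pp$lsum,
                                      pc$p, pc$P, pc$lsum, pc$v)
      }
      v <- v + drop(crossprod(pp$E, Jt))
    }
    idx <- pair_block_indices(pr)
    J[idx] <- v
    if (pr$I != pr$J) J[idx[, 2:1, drop = FALSE]] <- v
  }
  st <- new_stats(); st$nf <- 2L * length(pairs) * length(eng$auxd)
  bupo_result(J, D, stats_row("total", st), "Split-RI-J")
}

# exact auxiliary vector / exact J assembly (shared by the mixed-mode builds)
exact_g <- function(eng, D) {
  g <- numeric(eng$naux)
  for (pr in eng$pairs) {
    d <- pair_density(pr, D)
    for (k in seq_along(eng$auxd)) {
      g[eng$aux_off[k] + seq_len(eng$auxd[[k]]$nfun)] <-
        g[eng$aux_off[k] + seq_len(eng$auxd[[k]]$nfun)] +
        drop(eri_dist(eng$auxd[[k]], pr) %*% d)
    }
  }
  g
}

exact_J_from_c <- function(eng, cK) {
  J <- matrix(0, eng$nbf, eng$nbf)
  for (pr in eng$pairs) {
    v <- numeric(pr$nfun)
    for (k in seq_along(eng$auxd)) {
      v <- v + drop(crossprod(eri_dist(eng$auxd[[k]], pr),
                              cK[eng$aux_off[k] + seq_len(eng$auxd[[k]]$nfun)]))
    }
    idx <- pair_block_indices(pr)
    J[idx] <- v
    if (pr$I != pr$J) J[idx[, 2:1, drop = FALSE]] <- v
  }
  J
}

# ---- RI-BUPO-J --------------------------------------------------------------

# step-1 settings resolved from cfg (or the reduced incremental set)
step1_settings <- function(cfg, reduced = FALSE) {
  if (reduced) list(Lmax = cfg$incr_Lmax_step1,
                    sched = c(cfg$incr_Lincr1_step1, cfg$incr_Lincr2))
  else list(Lmax = cfg$Lmax_step1, sched = c(cfg$Lincr1_step1, cfg$Lincr2))
}

#' RI-BUPO-J step 1: auxiliary vector with far-field multipoles
#'
#' For every auxiliary shell the shell-pair bubble hierarchy is descended
#' from the top. A bubble subtree is Schwarz-skipped when
#' `PKMAX * sqrt(max(K|K)) < Thresh`; an allowed bubble contributes through
#' one real multipole contraction (first-allowed-ancestor wins, descendants
#' excluded); surviving bottom-level pairs are evaluated analytically
#' (three-index integrals contracted with the pair density).
#'
#' @param eng `bupo_engine`.
#' @param D density (or difference-density) matrix.
#' @param settings list with `Lmax` and `sched` (up-translation schedule);
#'   default from the config.
#' @param audit collect the per-auxiliary-shell classification of every pair
#'   (for the double-counting audit).
#' @return list with `g`, `stats`, and optionally `audit`.
#' @export
bupo_step1 <- function(eng, D, settings = NULL, audit = FALSE) {
  cfg <- eng$cfg
  s <- settings %||% step1_settings(cfg)
  h <- if (!is.null(eng$pair_hier)) {
    fill_pair_hierarchy(eng, D, s$Lmax, s$sched, cfg$T_screen)
  }
  st <- new_stats()
  g <- numeric(eng$naux)
  aud <- if (audit) vector("list", length(eng$auxd)) else NULL
  pk_pair <- vapply(seq_along(eng$pairs), function(i) {
    idx <- pair_block_indices(eng$pairs[[i]])
    eng$pairs[[i]]$K * max(abs(D[idx]))
  }, 0)
  for (k in seq_along(eng$auxd)) {
    dk <- eng$auxd[[k]]
    kseg <- eng$aux_off[k] + seq_len(dk$nfun)
    MK <- dist_multipoles(dk, dk$center, dk$l)   # exact, terminates at l_K
    sKK <- eng$sqrtKK[k]
    handled_ff <- integer(0); handled_nf <- integer(0); handled_skip <- integer(0)
    visit <- function(lev, bi) {
      b <- h$levels[[lev]][[bi]]
      if (b$pkmax * sKK < cfg$Thresh) {
        st$skipped <<- st$skipped + 1L
        if (audit) handled_skip <<- c(handled_skip, collect_members(h, lev, bi))
        return(invisible())
      }
      if (mp_allowed(dk$center, eng$sys$aux_shells[[k]]$extent,
                     b$center, b$radius, cfg$R_allow, cfg$R_allow_mode)) {
        Tm <- interaction_tensor(dk$center, b$center, dk$l, b$L)
        g[kseg] <<- g[kseg] + drop(crossprod(MK, Tm %*% b$M))
        st$ff <<- st$ff + 1L
        if (audit) {
          mem <- collect_members(h, lev, bi)
          handled_ff <<- c(handled_ff, mem)
        }
        return(invisible())
      }
      if (lev == 1L) {
        for (ip in b$members) {
          pr <- eng$pairs[[ip]]
          if (pk_pair[ip] * sKK < cfg$Thresh) {
            st$skipped <<- st$skipped + 1L
          } else {
            g[kseg] <<- g[kseg] + drop(eri_dist(dk, pr) %*% pair_density(pr, D))
            st$nf <<- st$nf + 1L
          }
          if (audit) handled_nf <<- c(handled_nf, ip)
        }
      } else {
        for (ci in b$members) visit(lev - 1L, ci)
      }
    }
    if (!is.null(eng$pair_hier)) {
      top <- h$nlevels
      for (bi in seq_along(h$levels[[top]])) visit(top, bi)
    }
    for (ip in eng$pair_throwaway) {   # throwaway bubble: always near field
      pr <- eng$pairs[[ip]]
      if (pk_pair[ip] * sKK < cfg$Thresh) {
        st$skipped <- st$skipped + 1L
      } else {
        g[kseg] <- g[kseg] + drop(eri_dist(dk, pr) %*% pair_density(pr, D))
        st$nf <- st$nf + 1L
      }
      if (audit) handled_nf <- c(handled_nf, ip)
    }
    if (audit) aud[[k]] <- list(ff = handled_ff, nf = handled_nf,
                                skipped = handled_skip)
  }
  list(g = g, stats = st, audit = aud)
}

# all bottom-level object indices under a bubble
collect_members <- function(h, lev, bi) {
  b <- h$levels[[lev]][[bi]]
  if (lev == 1L) return(b$members)
  unlist(lapply(b$members, function(ci) collect_members(h, lev - 1L, ci)))
}

#' RI-BUPO-J step 2: Coulomb assembly with far-field multipoles
#'
#' The auxiliary-basis density is expanded in a second bubble hierarchy
#' (atomic bubbles by default: exact terminating bottom-level expansions,
#' up-translated with a large first increment). Each shell pair expands its
#' own multipoles (contracted center by default, or exact per-primitive) and
#' descends the auxiliary hierarchy; allowed bubbles contribute via real
#' multipole contractions, surviving auxiliary shells analytically.
#'
#' @param eng `bupo_engine`.
#' @param cK auxiliary-basis density (from [solve_fit()]).
#' @param settings list with `Lmax` (pair expansion order) and `sched`;
#'   default from the config.
#' @param audit collect per-pair auxiliary classifications.
#' @return list with `J` (symmetric AO matrix contribution), `stats`,
#'   optionally `audit`.
#' @export
bupo_step2 <- function(eng, cK, settings = NULL, audit = FALSE) {
  cfg <- eng$cfg
  s <- settings %||% list(Lmax = cfg$Lmax_step2,
                          sched = c(cfg$Lincr1_step2, cfg$Lincr2))
  h <- if (!is.null(eng$aux_hier)) {
    fill_aux_hierarchy(eng, cK, s$sched, cfg$T_screen)
  }
  st <- new_stats()
  J <- matrix(0, eng$nbf, eng$nbf)
  aud <- if (audit) vector("list", length(eng$pairs)) else NULL
  ck_shell_max <- vapply(seq_along(eng$auxd), function(k) {
    max(abs(cK[eng$aux_off[k] + seq_len(eng$auxd[[k]]$nfun)]))
  }, 0)
  for (ip in seq_along(eng$pairs)) {
    pr <- eng$pairs[[ip]]
    prim_moms <- NULL
    Mp <- NULL
    if (cfg$step2_pair_multipoles == "contracted") {
      Mp <- dist_multipoles(pr, pr$P, s$Lmax)
    } else {
      prim_moms <- lapply(pr$prims, function(pp) {
        d1 <- list(prims = list(pp), nfun = pr$nfun)
        list(P = pp$P, M = dist_multipoles(d1, pp$P, pp$lsum), L = pp$lsum)
      })
    }
    v <- numeric(pr$nfun)
    handled_ff <- integer(0); handled_nf <- integer(0); handled_skip <- integer(0)
    visit <- function(lev, bi) {
      b <- h$levels[[lev]][[bi]]
      if (pr$K * b$pkmax < cfg$Thresh) {
        st$skipped <<- st$skipped + 1L
        if (audit) handled_skip <<- c(handled_skip, collect_members(h, lev, bi))
        return(invisible())
      }
      if (mp_allowed(pr$P, pr$extent, b$center, b$radius,
                     cfg$R_allow, cfg$R_allow_mode)) {
        if (is.null(prim_moms)) {
          Tm <- interaction_tensor(pr$P, b$center, s$Lmax, b$L)
          v <<- v + drop(crossprod(Mp, Tm %*% b$M))
        } else {
          for (pm in prim_moms) {
            Tm <- interaction_tensor(pm$P, b$center, pm$L, b$L)
            v <<- v + drop(crossprod(pm$M, Tm %*% b$M))
          }
        }
        st$ff <<- st$ff + 1L
        if (audit) handled_ff <<- c(handled_ff, collect_members(h, lev, bi))
        return(invisible())
      }
      if (lev == 1L) {
        for (k in b$members) {
          if (pr$K * eng$sqrtKK[k] * ck_shell_max[k] < cfg$Thresh) {
            st$skipped <<- st$skipped + 1L
          } else {
            kseg <- eng$aux_off[k] + seq_len(eng$auxd[[k]]$nfun)
            v <<- v + drop(crossprod(eri_dist(eng$auxd[[k]], pr), cK[kseg]))
            st$nf <<- st$nf + 1L
          }
          if (audit) handled_nf <<- c(handled_nf, k)
        }
      } else {
        for (ci in b$members) visit(lev - 1L, ci)
      }
    }
    if (!is.null(eng$aux_hier)) {
      top <- h$nlevels
      for (bi in seq_along(h$levels[[top]])) visit(top, bi)
    }
    for (k in eng$aux_throwaway) {   # diffuse auxiliaries: always near field
      if (pr$K * eng$sqrtKK[k] * ck_shell_max[k] < cfg$Thresh) {
        st$skipped <- st$skipped + 1L
      } else {
        kseg <- eng$aux_off[k] + seq_len(eng$auxd[[k]]$nfun)
        v <- v + drop(crossprod(eri_dist(eng$auxd[[k]], pr), cK[kseg]))
        st$nf <- st$nf + 1L
      }
      if (audit) handled_nf <- c(handled_nf, k)
    }
    idx <- pair_block_indices(pr)
    J[idx] <- v
    if (pr$I != pr$J) J[idx[, 2:1, drop = FALSE]] <- v
    if (audit) aud[[ip]] <- list(ff = handled_ff, nf = handled_nf,
                                 skipped = handled_skip)
  }
  list(J = J, stats = st, audit = aud)
}

#' RI-BUPO-J Coulomb build
#'
#' The full two-step linear-scaling build: multipole-accelerated auxiliary
#' vector (step 1), pivoted-Cholesky fit solve, multipole-accelerated
#' Coulomb assembly (step 2). Either step can be switched to its analytic
#' counterpart for error-decomposition studies.
#'
#' @param eng `bupo_engine`.
#' @param D symmetric density-like matrix.
#' @param use_mp_step1,use_mp_step2 use the multipole far field in the
#'   respective step (`FALSE` = fully analytic step).
#' @param reduced use the reduced-accuracy incremental settings.
#' @return `bupo_jresult`.
#' @export
rbupo_J <- function(eng, D, use_mp_step1 = TRUE, use_mp_step2 = TRUE,
                    reduced = FALSE) {
  cfg <- eng$cfg
  if (use_mp_step1) {
    s1 <- bupo_step1(eng, D, step1_settings(cfg, reduced))
    g <- s1$g; st1 <- s1$stats
  } else {
    g <- exact_g(eng, D)
    st1 <- new_stats(); st1$nf <- length(eng$pairs) * length(eng$auxd)
  }
  cK <- solve_fit(eng$M, g)
  if (use_mp_step2) {
    s2 <- bupo_step2(eng, cK)
    J <- s2$J; st2 <- s2$stats
  } else {
    J <- exact_J_from_c(eng, cK)
    st2 <- new_stats(); st2$nf <- length(eng$pairs) * length(eng$auxd)
  }
  stats <- rbind(stats_row("step1", st1), stats_row("step2", st2))
  bupo_result(J, D, stats, "RI-BUPO-J")
}

#' BUPO-J Coulomb build (non-RI, four-index near field)
#'
#' The small-scale non-fitted variant: each shell pair descends the
#' density-weighted shell-pair hierarchy; allowed bubbles contribute via
#' multipoles, surviving pairs through analytic four-index integrals with
#' standard Schwarz prescreening. Refused above the configured basis-size
#' cap; with the far field disabled it reproduces the exact four-index
#' Coulomb matrix, so it doubles as a second oracle family.
#'
#' @inheritParams rij_J
#' @return `bupo_jresult`.
#' @export
bupoJ_fullJ <- function(eng, D) {
  cfg <- eng$cfg
  if (eng$nbf > cfg$eri4_cap) {
    stop("bupoJ_fullJ(): ", eng$nbf, " basis functions exceed the four-index cap of ", cfg$eri4_cap)
  }
  s <- step1_settings(cfg)
  h <- if (!is.null(eng$pair_hier)) {
    fill_pair_hierarchy(eng, D, s$Lmax, s$sched, cfg$T_screen)
  }
  pk_pair <- vapply(seq_along(eng$pairs), function(i) {
    idx <- pair_block_indices(eng$pairs[[i]])
    eng$pairs[[i]]$K * max(abs(D[idx]))
  }, 0)
  st <- new_stats()
  J <- matrix(0, eng$nbf, eng$nbf)
  for (ib in seq_along(eng$pairs)) {
    bra <- eng$pairs[[ib]]
    Mb <- dist_multipoles(bra, bra$P, s$Lmax)
    v <- numeric(bra$nfun)
    visit <- function(lev, bi) {
      b <- h$levels[[lev]][[bi]]
      if (bra$K * b$pkmax < cfg$Thresh) {
        st$skipped <<- st$skipped + 1L
        return(invisible())
      }
      if (mp_allowed(bra$P, bra$extent, b$center, b$radius,
                     cfg$R_allow, cfg$R_allow_mode)) {
        Tm <- interaction_tensor(bra$P, b$center, s$Lmax, b$L)
        v <<- v + drop(crossprod(Mb, Tm %*% b$M))
        st$ff <<- st$ff + 1L
        return(invisible())
      }
      if (lev == 1L) {
        for (ik in b$members) {
          ket <- eng$pairs[[ik]]
          if (bra$K * pk_pair[ik] < cfg$Thresh) {
            st$skipped <<- st$skipped + 1L
          } else {
            v <<- v + drop(eri_dist(bra, ket) %*% pair_density(ket, D))
            st$nf <<- st$nf + 1L
          }
        }
      } else {
        for (ci in b$members) visit(lev - 1L, ci)
      }
    }
    if (!is.null(eng$pair_hier)) {
      top <- h$nlevels
      for (bi in seq_along(h$levels[[top]])) visit(top, bi)
    }
    for (ik in eng$pair_throwaway) {
      ket <- eng$pairs[[ik]]
      if (bra$K * pk_pair[ik] < cfg$Thresh) st$skipped <- st$skipped + 1L
      else {
        v <- v + drop(eri_dist(bra, ket) %*% pair_density(ket, D))
        st$nf <- st$nf + 1L
      }
    }
    idx <- pair_block_indices(bra)
    J[idx] <- v
    if (bra$I != bra$J) J[idx[, 2:1, drop = FALSE]] <- v
  }
  bupo_result(J, D, stats_row("total", st), "BUPO-J")
}

#' Exact four-index Coulomb matrix (oracle)
#'
#' Brute-force `J = sum (munu|kappatau) D` over all screened shell pairs,
#' no multipoles, no Schwarz skipping. Small systems only.
#'
#' @inheritParams rij_J
#' @return `bupo_jresult`.
#' @export
exact_J <- function(eng, D) {
  if (eng$nbf > eng$cfg$eri4_cap) {
    stop("exact_J(): ", eng$nbf, " basis functions exceed the four-index cap")
  }
  J <- matrix(0, eng$nbf, eng$nbf)
  for (bra in eng$pairs) {
    v <- numeric(bra$nfun)
    for (ket in eng$pairs) {
      v <- v + drop(eri_dist(bra, ket) %*% pair_density(ket, D))
    }
    idx <- pair_block_indices(bra)
    J[idx] <- v
    if (bra$I != bra$J) J[idx[, 2:1, drop = FALSE]] <- v
  }
  bupo_result(J, D, stats_row("total", new_stats()), "exact four-index")
}

#' Density-fit residual diagnostic
#'
#' Self-repulsion of the fitting error,
#' \eqn{(\rho - \tilde\rho | \rho - \tilde\rho) = (\rho|\rho) - g^T c}:
#' non-negative, and exactly twice the Coulomb-energy error of the RI
#' approximation. Needs the four-index oracle, so small systems only.
#'
#' @inheritParams rij_J
#' @return scalar residual (Hartree).
#' @export
fit_residual <- function(eng, D) {
  g <- exact_g(eng, D)
  cK <- solve_fit(eng$M, g)
  rho_rho <- 2 * exact_J(eng, D)$energy
  rho_rho - sum(g * cK)
}

# ---- incremental / full build driver ----------------------------------------

#' SCF-style build driver with incremental updates and accurate rebuilds
#'
#' Processes a sequence of density matrices. Iteration 1 and every
#' `restart_cycle`-th iteration perform a full build from the current
#' density (at the accurate multipole settings when `accurate_rebuild` is
#' on); all other iterations add the Coulomb matrix of the difference
#' density at the reduced settings. The accumulated matrix tracks a one-shot
#' build on the current density to within the accumulated multipole noise.
#'
#' @param eng `bupo_engine`.
#' @param D_list list of symmetric density matrices (SCF iterates).
#' @return list of `bupo_jresult`, one per iteration (each holding the
#'   accumulated J and the energy for that iteration's density); attribute
#'   `full_builds` records which iterations were full rebuilds.
#' @export
build_driver <- function(eng, D_list) {
  cfg <- eng$cfg
  Jacc <- matrix(0, eng$nbf, eng$nbf)
  out <- vector("list", length(D_list))
  full_iters <- integer(0)
  for (n in seq_along(D_list)) {
    full <- (n == 1L) || ((n - 1L) %% cfg$restart_cycle == 0L)
    if (full) {
      res <- rbupo_J(eng, D_list[[n]], reduced = !cfg$accurate_rebuild)
      Jacc <- res$J
      full_iters <- c(full_iters, n)
    } else {
      dD <- D_list[[n]] - D_list[[n - 1L]]
      res <- rbupo_J(eng, dD, reduced = TRUE)
      Jacc <- Jacc + res$J
    }
    out[[n]] <- bupo_result(Jacc, D_list[[n]], res$stats, "RI-BUPO-J (driver)")
  }
  attr(out, "full_builds") <- full_iters
  out
}
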