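# Balanced k-means "bubble" hierarchies.
#
# Objects (shell pairs, auxiliary shells, point charges) are clustered into
# spheres that enclose every member including its extent -- no leakage is
# possible, which is the property that distinguishes bubbles from boxes.
# Bubbles recursively combine into superbubbles until one top-level bubble
# encloses the whole system.  All clustering is deterministic given the seed:
# farthest-point seeding starting from the object nearest the centroid, a
# fixed iteration cap, and lowest-index tie-breaking.

# deterministic k-means on rows of `centers`; returns integer assignment
kmeans_assign <- function(centers, k, iter_max = 100L) {
  n <- nrow(centers)
  if (k >= n) return(seq_len(n))
  centroid <- colMeans(centers)
  d0 <- rowSums((centers - rep(centroid, each = n))^2)
  seeds <- integer(k)
  seeds[1L] <- which.min(d0)  # ties: which.min takes the lowest index
  dmin <- rowSums((centers - rep(centers[seeds[1L], ], each = n))^2)
  if (k > 1L) for (j in 2:k) {
    seeds[j] <- which.max(dmin)
    dmin <- pmin(dmin, rowSums((centers - rep(centers[seeds[j], ], each = n))^2))
  }
  means <- centers[seeds, , drop = FALSE]
  assign_prev <- integer(n)
  for (it in seq_len(iter_max)) {
    d2 <- outer(rowSums(centers^2), rep(1, k)) - 2 * centers %*% t(means) +
      outer(rep(1, n), rowSums(means^2))
    a <- max.col(-d2, ties.method = "first")
    if (identical(a, assign_prev)) break
    assign_prev <- a
    for (j in seq_len(k)) {
      mem <- which(a == j)
      if (length(mem)) means[j, ] <- colMeans(centers[mem, , drop = FALSE])
    }
  }
  # drop empty clusters, renumber compactly
  keep <- sort(unique(assign_prev))
  match(assign_prev, keep)
}

make_bubble <- function(level, members, centers, extents) {
  C <- colMeans(centers[members, , drop = FALSE])
  r <- max(sqrt(rowSums((centers[members, , drop = FALSE] -
                           rep(C, each = length(members)))^2)) + extents[members])
  list(level = level, center = C, radius = r, members = members,
       M = NULL, L = NA_integer_, pkmax = 0)
}

#' Bottom-level bubbles by balanced k-means
#'
#' Clusters object centers into `ceiling(N / TargetDim)` bubbles. The bubble
#' center is the member centroid and the radius encloses every member center
#' plus its extent (strict no-leakage invariant). After convergence, any
#' cluster larger than `2 * TargetDim` is split once by the same seeding,
#' keeping the population roughly balanced.
#'
#' @param centers numeric matrix `N x 3` of object centers (Bohr).
#' @param extents numeric vector of object extents (Bohr).
#' @param TargetDim target number of objects per bubble (>= 1).
#' @param seed integer seed (clustering here is fully deterministic; the seed
#'   is recorded for provenance).
#' @return list of level-1 bubbles.
#' @export
kmeans_bubbles <- function(centers, extents, TargetDim = 150L, seed = 1L) {
  stopifnot(TargetDim >= 1L)
  n <- nrow(centers)
  if (n == 0L) return(list())
  k <- ceiling(n / TargetDim)
  a <- kmeans_assign(centers, k)
  groups <- split(seq_len(n), a)
  # balance: split oversized clusters once
  out_groups <- list()
  for (g in groups) {
    if (length(g) > 2L * TargetDim) {
      sub <- kmeans_assign(centers[g, , drop = FALSE],
                           ceiling(length(g) / TargetDim))
      out_groups <- c(out_groups, split(g, sub))
    } else {
      out_groups <- c(out_groups, list(g))
    }
  }
  lapply(out_groups, function(g) make_bubble(1L, g, centers, extents))
}

#' Recursive bubble hierarchy
#'
#' Combines level-1 bubbles into superbubbles of ~`TargetDim2` children per
#' level (clustering bubble centers with the same deterministic k-means)
#' until a single top-level bubble encloses the whole system. Parent radii
#' enclose every child sphere entirely.
#'
#' @param level1 list of level-1 bubbles (from [kmeans_bubbles()] or
#'   [atomic_aux_bubbles()]).
#' @param TargetDim2 children per superbubble.
#' @param max_levels hard cap on the number of levels.
#' @return `bupo_hierarchy`: list with `levels` (list of bubble lists,
#'   bottom first) and bookkeeping fields.
#' @export
build_hierarchy <- function(level1, TargetDim2 = 3L, max_levels = 20L) {
  levels <- list(level1)
  while (length(levels[[length(levels)]]) > 1L) {
    if (length(levels) >= max_levels) {
      stop("bubble hierarchy exceeded ", max_levels, " levels")
    }
    cur <- levels[[length(levels)]]
    cen <- do.call(rbind, lapply(cur, `[[`, "center"))
    ext <- vapply(cur, `[[`, 0, "radius")
    k <- ceiling(length(cur) / TargetDim2)
    a <- kmeans_assign(cen, k)
    nxt <- lapply(split(seq_along(cur), a), function(g) {
      make_bubble(length(levels) + 1L, g, cen, ext)
    })
    levels <- c(levels, list(nxt))
  }
  structure(list(levels = levels, nlevels = length(levels)),
            class = "bupo_hierarchy")
}

#' @export
print.bupo_hierarchy <- function(x, ...) {
  cat("bubble hierarchy,", x$nlevels, "levels:\n")
  print(hierarchy_table(x))
  invisible(x)
}

#' Per-level hierarchy summary
#'
#' One row per level: bubble count, mean radius and mean dimension (members
#' per bubble), the same columns used to document hierarchy bookkeeping.
#'
#' @param h `bupo_hierarchy`.
#' @return data.frame.
#' @export
hierarchy_table <- function(h) {
  do.call(rbind, lapply(seq_along(h$levels), function(i) {
    lv <- h$levels[[i]]
    data.frame(level = i, n_bubbles = length(lv),
               mean_radius = mean(vapply(lv, `[[`, 0, "radius")),
               mean_dimension = mean(lengths(lapply(lv, `[[`, "members"))))
  }))
}

#' Fill bottom-level bubble multipoles
#'
#' Sets each level-1 bubble's multipole vector to the sum over member objects
#' of the object's (optionally density-contracted) multipoles translated to
#' the bubble center, drops coefficients below `T_screen`, and stores the
#' bubble's Schwarz value `PKMAX = max(K_IJ * D_IJ)` over members.
#'
#' @param h `bupo_hierarchy`.
#' @param moments list over objects: each a function-resolved moment matrix
#'   `(L+1)^2 x nfun` about the object's own center.
#' @param obj_centers matrix of the objects' own expansion centers.
#' @param weights list over objects of contraction vectors (e.g. pair density
#'   values), or NULL for unit contraction of a single-function object.
#' @param pk numeric vector of per-object Schwarz-density values.
#' @param L bottom-level expansion order.
#' @param T_screen multipole screening threshold.
#' @return hierarchy with level-1 multipoles filled.
#' @export
aggregate_bottom_multipoles <- function(h, moments, obj_centers, weights,
                                        pk, L, T_screen = 1e-10) {
  h$levels[[1L]] <- lapply(h$levels[[1L]], function(b) {
    M <- numeric((L + 1L)^2)
    for (i in b$members) {
      mom <- as.matrix(moments[[i]])
      v <- if (is.null(weights)) rowSums(mom) else drop(mom %*% weights[[i]])
      Lobj <- as.integer(sqrt(length(v))) - 1L
      W <- translation_matrix(obj_centers[i, ], b$center, Lobj, L)
      M <- M + drop(W %*% v)
    }
    M[abs(M) < T_screen] <- 0
    b$M <- M
    b$L <- as.integer(L)
    b$pkmax <- if (length(b$members)) max(pk[b$members]) else 0
    b
  })
  h
}

#' Up-translate multipoles through the hierarchy
#'
#' Translates each level's bubble multipoles to the centers of their parent
#' superbubbles, increasing the expansion order by `Lincr[level]` at each
#' step (capped at the absolute maximum order). Parent PKMAX is the maximum
#' over children. Only the first up-translation matters much for accuracy,
#' so schedules typically front-load the first increment.
#'
#' @param h hierarchy with level-1 multipoles filled.
#' @param Lincr integer vector of order increments per translation step
#'   (recycled if shorter than the number of steps).
#' @param T_screen multipole screening threshold.
#' @return hierarchy with every level's multipoles filled.
#' @export
up_translate <- function(h, Lincr = c(6L, 4L, 4L), T_screen = 1e-10) {
  nl <- h$nlevels
  if (nl == 1L) return(h)
  for (lev in 2:nl) {
    inc <- Lincr[min(lev - 1L, length(Lincr))]
    children <- h$levels[[lev - 1L]]
    h$levels[[lev]] <- lapply(h$levels[[lev]], function(b) {
      Lc <- max(unlist(lapply(children[b$members], `[[`, "L")))
      Lnew <- as.integer(min(Lc + inc, L_ABS_MAX))
      M <- numeric((Lnew + 1L)^2)
      for (ci in b$members) {
        ch <- children[[ci]]
        W <- translation_matrix(ch$center, b$center, ch$L, Lnew)
        M <- M + drop(W %*% ch$M)
      }
      M[abs(M) < T_screen] <- 0
      b$M <- M
      b$L <- Lnew
      b$pkmax <- max(vapply(children[b$members], `[[`, 0, "pkmax"))
      b
    })
  }
  h
}

#' Atomic auxiliary bubbles
#'
#' One level-1 bubble per atom holding all of that atom's auxiliary shells.
#' Because every member shell is expanded at the shared atomic center, the
#' bottom-level multipoles terminate exactly at the atom's maximum auxiliary
#' angular momentum; up-translation is needed only at higher levels.
#'
#' @param sys `bupo_system` with auxiliary shells.
#' @return list of level-1 bubbles whose members index `sys$aux_shells`.
#' @export
atomic_aux_bubbles <- function(sys) {
  stopifnot(!is.null(sys$aux_shells))
  byatom <- split(seq_along(sys$aux_shells),
                  vapply(sys$aux_shells, `[[`, 0L, "atom"))
  cen <- do.call(rbind, lapply(sys$aux_shells, `[[`, "center"))
  ext <- vapply(sys$aux_shells, `[[`, 0, "extent")
  lapply(byatom, function(g) make_bubble(1L, g, cen, ext))
}

# exhaustive no-leakage audit: every member sphere inside its bubble, every
# child sphere inside its parent; returns worst signed violation (<= 0 ok)
enclosure_violation <- function(h, obj_centers = NULL, obj_extents = NULL) {
  worst <- -Inf
  if (!is.null(obj_centers)) {
    for (b in h$levels[[1L]]) {
      d <- sqrt(rowSums((obj_centers[b$members, , drop = FALSE] -
                           rep(b$center, each = length(b$members)))^2))
      worst <- max(worst, max(d + obj_extents[b$members] - b$radius))
    }
  }
  if (h$nlevels > 1L) for (lev in 2:h$nlevels) {
    children <- h$levels[[lev - 1L]]
    for (b in h$levels[[lev]]) {
      for (ci in b$members) {
        ch <- children[[ci]]
        worst <- max(worst, vnorm(ch$center - b$center) + ch$radius - b$radius)
      }
    }
  }
  worst
}
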