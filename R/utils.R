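# Internal helpers shared across modules.

# package-local cache for per-l coefficient tables etc.
.bupo_cache <- new.env(parent = emptyenv())

#' @noRd
cache_get <- function(key, builder) {
  if (!exists(key, envir = .bupo_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .bupo_cache)
  }
  get(key, envir = .bupo_cache, inherits = FALSE)
}

# Conversion factor: 1 Angstrom in Bohr (CODATA).
ANGSTROM_TO_BOHR <- 1.8897261254578281

# Supported angular momentum cap for AO/aux shells.
L_SHELL_MAX <- 5L

# Cartesian monomials of total degree n, as a matrix with columns t,u,v.
# Ordering is fixed (t descending, then u descending) and shared everywhere.
monomials <- function(n) {
  key <- paste0("mono", n)
  cache_get(key, function() {
    out <- matrix(0L, nrow = (n + 1L) * (n + 2L) / 2L, ncol = 3L)
    r <- 1L
    for (t in n:0) for (u in (n - t):0) {
      out[r, ] <- c(t, u, n - t - u)
      r <- r + 1L
    }
    colnames(out) <- c("t", "u", "v")
    out
  })
}

# Hermite index triples (t,u,v) with t+u+v <= n, in a fixed ordering.
hermite_indices <- function(n) {
  key <- paste0("herm", n)
  cache_get(key, function() {
    do.call(rbind, lapply(0:n, monomials))
  })
}

# double factorial with (-1)!! = 1
dfact <- function(n) {
  if (n <= 0) return(1)
  prod(seq(n, 1, by = -2))
}

# angular integral over the unit sphere of x^(2i) y^(2j) z^(2k);
# odd powers integrate to zero.
sphere_moment <- function(t, u, v) {
  if (t %% 2L || u %% 2L || v %% 2L) return(0)
  4 * pi * dfact(t - 1) * dfact(u - 1) * dfact(v - 1) / dfact(t + u + v + 1)
}

# squared-norm helper
vnorm <- function(x) sqrt(sum(x * x))

`%||%` <- function(a, b) if (is.null(a)) b else a
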