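# Shared fixtures: everything is generated in code, nothing read from disk.

# a single-shell record (for extent / aux oracles)
mk_shell <- function(l, exps, coefs = rep(1, length(exps)),
                     center = c(0, 0, 0), atom = 1L, offset = 0L) {
  ord <- order(exps, decreasing = TRUE)
  list(atom = atom, l = as.integer(l), exps = exps[ord],
       coefs = bupo:::normalize_contraction(as.integer(l), exps[ord], coefs[ord]),
       center = center, nf = 2L * as.integer(l) + 1L, offset = offset)
}

# one-element s-only basis
s_basis <- function(exps, coefs = rep(1, length(exps)), el = "H") {
  b <- list(list(list(l = 0L, exps = exps, coefs = coefs)))
  names(b) <- el
  bupo:::basis_set(b)
}

# compact 5-atom fragment of the helical chain (all near field)
compact_system <- function() {
  at <- make_chain(2, "peptide")[1:5, ]
  build_system(at, toy_basis("ao"), toy_basis("aux"))
}

# helical study chain
chain_system <- function(units) {
  build_system(make_chain(units, "peptide"), toy_basis("ao"), toy_basis("aux"))
}

# linear heavy-atom chain (scaling witness)
linear_system <- function(units, spacing = 3.0) {
  build_system(make_chain(units, "linear", spacing = spacing),
               toy_basis("ao"), toy_basis("aux"))
}

# potential of a unit s Gaussian charge distribution (alpha) at distance r:
# erf(sqrt(alpha) r)/r -- closed form used as an independent Coulomb oracle
gauss_potential <- function(alpha, r) {
  ifelse(r < 1e-12, 2 * sqrt(alpha / pi), erf_(sqrt(alpha) * r) / r)
}

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Gauss-Hermite nodes/weights (weight e^{-x^2}) via the Golub-Welsch
# eigenvalue construction -- independent quadrature oracle for ERIs
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# random rigid rotation matrix from a seed
rotation_matrix <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

rotate_atoms <- function(atoms, R) {
  pos <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  bupo::atoms(atoms$element, pos)
}
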