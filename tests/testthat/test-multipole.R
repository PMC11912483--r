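test_that("interaction tensor reproduces classical point-charge energies", {
  # monopole-monopole: 1/R
  expect_equal(interaction_tensor(c(0, 0, 0), c(0, 0, 10), 0, 0)[1, 1], 0.1)
  # two unit monopoles at distance 10 -> 0.1 Hartree
  M0 <- regular_solid_real(0, c(0, 0, 0))
  expect_equal(drop(M0 %*% interaction_tensor(c(0, 0, 0), c(0, 0, 10), 0, 0) %*% M0),
               0.1)
  # monopole-dipole along z at distance R: mu_z / R^2, checked against two
  # finite point charges
  R <- 8; d <- 0.4
  Mdip <- regular_solid_real(1, c(0, 0, d / 2)) - regular_solid_real(1, c(0, 0, -d / 2))
  Tm <- interaction_tensor(c(0, 0, R), c(0, 0, 0), 0, 1)
  e_mp <- drop(regular_solid_real(0, c(0, 0, 0)) %*% Tm[1, , drop = FALSE] %*% Mdip)
  e_exact <- 1 / (R - d / 2) - 1 / (R + d / 2)
  # the monopole+dipole truncation reproduces finite charges to O((d/2R)^2)
  expect_equal(e_mp, e_exact, tolerance = 2 * (d / (2 * R))^2)
  # dipole term alone: mu_z/R^2
  expect_equal(drop(Tm[1, 3]) * d, d / R^2, tolerance = 1e-12)
})

test_that("interaction tensor decays and obeys parity", {
  P <- c(0, 0, 0)
  T1 <- interaction_tensor(P, c(0, 0, 5), 3, 3)
  T2 <- interaction_tensor(P, c(0, 0, 10), 3, 3)
  for (l1 in 0:3) for (l2 in 0:3) {
    i <- bupo:::lm_index(l1, 0); j <- bupo:::lm_index(l2, 0)
    expect_equal(T1[i, j] / T2[i, j], 2^(l1 + l2 + 1), tolerance = 1e-10)
  }
  Tm <- interaction_tensor(P, c(1.2, -0.7, 2.0), 3, 3)
  Tp <- interaction_tensor(P, -c(1.2, -0.7, 2.0), 3, 3)
  for (l1 in 0:3) for (l2 in 0:3) {
    i <- bupo:::lm_index(l1, -l1):bupo:::lm_index(l1, l1)
    j <- bupo:::lm_index(l2, -l2):bupo:::lm_index(l2, l2)
    expect_equal(Tp[i, j], (-1)^(l1 + l2) * Tm[i, j], tolerance = 1e-12)
  }
})

test_that("translation is exact, composable, and charge conserving", {
  # zero displacement: identity
  W0 <- translation_matrix(c(1, 2, 3), c(1, 2, 3), 4, 4)
  expect_equal(W0, diag(25))
  set.seed(7)
  q <- rnorm(6); pos <- matrix(rnorm(18, sd = 0.6), 6)
  M <- Reduce(`+`, lapply(1:6, function(i) q[i] * regular_solid_real(10, pos[i, ])))
  # monopole invariant under any shift
  W <- translation_matrix(c(0, 0, 0), c(2.2, -1, 0.5), 10, 12)
  expect_equal(drop(W %*% M)[1], M[1], tolerance = 1e-13)
  # point-dipole rule: new dipole = old dipole + charge * displacement
  shift <- c(2.2, -1, 0.5)
  Mt <- drop(W %*% M)
  dip_direct <- Reduce(`+`, lapply(1:6, function(i) {
    q[i] * regular_solid_real(1, pos[i, ] - shift)
  }))
  expect_equal(Mt[2:4], dip_direct[2:4], tolerance = 1e-12)
  # composition A->B->C equals A->C at sufficient order
  A <- c(0, 0, 0); B <- c(1, 0.5, -0.3); C <- c(-0.8, 1.1, 0.9)
  Wab <- translation_matrix(A, B, 10, 14)
  Wbc <- translation_matrix(B, C, 14, 14)
  Wac <- translation_matrix(A, C, 10, 14)
  expect_equal(drop(Wbc %*% (Wab %*% M)), drop(Wac %*% M), tolerance = 1e-11)
})

test_that("contractions are rotationally invariant", {
  set.seed(3)
  qa <- rnorm(5); pa <- matrix(rnorm(15, sd = 0.7), 5)
  qb <- rnorm(4); pb <- matrix(rnorm(12, sd = 0.7), 4)
  P <- c(0, 0, 0); Q <- c(9, 2, -3)
  ener <- function(R) {
    MP <- Reduce(`+`, lapply(1:5, function(i) qa[i] * regular_solid_real(8, drop(R %*% pa[i, ]))))
    MQ <- Reduce(`+`, lapply(1:4, function(j) qb[j] * regular_solid_real(8, drop(R %*% pb[j, ]))))
    drop(t(MP) %*% interaction_tensor(drop(R %*% P), drop(R %*% Q), 8, 8) %*% MQ)
  }
  e0 <- ener(diag(3))
  for (s in 1:3) expect_equal(ener(rotation_matrix(s)), e0, tolerance = 1e-10)
})

test_that("scaled harmonics stay finite to the absolute order cap", {
  v <- regular_solid_real(44, c(1.3, -2.1, 0.8))
  expect_true(all(is.finite(v)))
  W <- translation_matrix(c(0, 0, 0), c(3, 1, -2), 44, 44)
  expect_true(all(is.finite(W)))
  Tm <- interaction_tensor(c(0, 0, 0), c(40, 5, 1), 20, 20)
  expect_true(all(is.finite(Tm)))
  expect_error(dist_multipoles(aux_dist(mk_shell(0L, 1.0)), c(0, 0, 0), 45L),
               "exceeds")
})

test_that("terminating expansions terminate exactly", {
  # primitive s.s pair at its Gaussian-product point: monopole only,
  # equal to the pair overlap charge
  sys <- build_system(atoms(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.5))),
                      s_basis(0.8), s_basis(1.0))
  pr <- Filter(function(p) p$I != p$J, build_shell_pairs(sys, 1e-15))[[1]]
  M <- dist_multipoles(pr, pr$prims[[1]]$P, 6)
  S <- (pi / pr$prims[[1]]$p)^1.5 * pr$prims[[1]]$E[1, ]
  expect_equal(M[1, ], unname(S), tolerance = 1e-13)
  expect_lt(max(abs(M[-1, ])), 1e-13)
  # expanded 1 Bohr off-center along z: dipole = -charge * offset
  Moff <- dist_multipoles(pr, pr$prims[[1]]$P + c(0, 0, 1), 6)
  expect_equal(Moff[3, ], -unname(S), tolerance = 1e-12)
  # one-center p.s contracted pair: zero above l = 1
  sys2 <- build_system(atoms("X", matrix(0, 1, 3)),
                       bupo:::basis_set(list(X = list(
                         list(l = 1L, exps = c(1.4, 0.5), coefs = c(0.4, 0.7)),
                         list(l = 0L, exps = c(2.0, 0.6), coefs = c(0.5, 0.6))
                       ))), NULL)
  pr2 <- Filter(function(p) p$I != p$J, build_shell_pairs(sys2))[[1]]
  M2 <- dist_multipoles(pr2, c(0, 0, 0), 5)
  expect_lt(max(abs(M2[-(1:4), ])), 1e-13)
  # auxiliary shells at the parent atom: d shell nonzero only at l = 2
  Kd <- aux_dist(mk_shell(2L, 0.9, center = c(1, 1, 1)))
  Md <- dist_multipoles(Kd, c(1, 1, 1), 4)
  expect_lt(max(abs(Md[-(5:9), ])), 1e-14)
  expect_gt(max(abs(Md[5:9, ])), 1e-3)
  # s aux shell: monopole equals its total charge
  Ks <- aux_dist(mk_shell(0L, 1.1))
  Ms <- dist_multipoles(Ks, c(0, 0, 0), 3)
  sh <- mk_shell(0L, 1.1)
  q_ref <- sh$coefs * bupo:::radial_norm(1.1, 0L) / sqrt(4 * pi) * (pi / 1.1)^1.5
  expect_equal(Ms[1, 1], q_ref, tolerance = 1e-13)
  expect_lt(max(abs(Ms[-1, ])), 1e-14)
})

test_that("multipole approximation converges to eri3 and survives translation", {
  sys <- build_system(atoms(c("X", "H"), rbind(c(0, 0, 0), c(1.2, 0.5, 0.8))),
                      toy_basis("ao"), toy_basis("aux"))
  pr <- Filter(function(p) p$I == 2L && p$J == 3L, build_shell_pairs(sys))[[1]]
  Kfar <- aux_dist(mk_shell(1L, 0.9, center = c(0.5, 16, 1)))
  exact <- eri_dist(Kfar, pr)
  MK <- dist_multipoles(Kfar, Kfar$center, 1)
  errs <- vapply(c(2, 4, 6, 8, 10), function(L) {
    MP <- dist_multipoles(pr, pr$P, L)
    Tm <- interaction_tensor(Kfar$center, pr$P, 1, L)
    max(abs(crossprod(MK, Tm %*% MP) - exact))
  }, 0)
  # envelope decrease with expansion order
  expect_true(all(diff(log10(pmax(errs, 1e-17))) < 0.5))
  expect_lt(errs[5] / max(abs(exact)), 1e-10)
  # p aux re-expanded 0.5 Bohr away, up-translated by +6 orders
  newc <- Kfar$center + c(0.3, 0.4, 0)
  W <- translation_matrix(Kfar$center, newc, 1, 7)
  MKt <- W %*% MK
  Tm <- interaction_tensor(newc, pr$P, 7, 10)
  MP <- dist_multipoles(pr, pr$P, 10)
  expect_lt(max(abs(t(MKt) %*% Tm %*% MP - exact)) / max(abs(exact)), 1e-10)
})
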