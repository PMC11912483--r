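test_that("the allowedness gate is boundary inclusive", {
  # touching spheres: allowed at R_allow = 1
  expect_true(mp_allowed(c(0, 0, 0), 2, c(0, 0, 5), 3, 1, "ratio"))
  expect_false(mp_allowed(c(0, 0, 0), 2, c(0, 0, 2.5), 3, 1, "ratio"))
  expect_false(mp_allowed(c(0, 0, 0), 2, c(0, 0, 5 - 1e-9), 3, 1, "ratio"))
  expect_true(mp_allowed(c(0, 0, 0), 2, c(0, 0, 50), 3, 1, "ratio"))
  # additive-margin reading
  expect_true(mp_allowed(c(0, 0, 0), 2, c(0, 0, 6), 3, 1, "offset"))
  expect_false(mp_allowed(c(0, 0, 0), 2, c(0, 0, 5.5), 3, 1, "offset"))
  # Inf disables the far field
  expect_false(mp_allowed(c(0, 0, 0), 2, c(0, 0, 1e6), 3, Inf, "ratio"))
})

test_that("pivoted Cholesky fit solve matches dense solves", {
  expect_equal(solve_fit(diag(4), c(1, 2, 3, 4)), c(1, 2, 3, 4))
  expect_equal(solve_fit(rbind(c(2, 1), c(1, 2)), c(1, 1)), c(1, 1) / 3,
               tolerance = 1e-14)
  set.seed(8)
  A <- matrix(rnorm(144), 12); M <- crossprod(A); g <- rnorm(12)
  expect_equal(solve_fit(M, g), solve(M, g), tolerance = 1e-10)
  expect_error(solve_fit(-diag(3), c(1, 1, 1)), "positive semi-definite")
  # rank-deficient but consistent system still solves
  Mr <- tcrossprod(A[, 1:8] %*% t(A[, 1:8]))
  Mr <- crossprod(A[, 1:8, drop = FALSE] %*% matrix(rnorm(8 * 12), 8))
  xr <- solve_fit(Mr, Mr %*% rnorm(12))
  expect_true(all(is.finite(xr)))
})

test_that("RI-J agrees with the four-index oracle to the fit error", {
  sys <- build_system(atoms(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4))),
                      toy_basis("ao"), toy_basis("aux"))
  eng <- bupo_engine(sys, bupo_config())
  D <- make_density(sys, "sad")
  res <- fit_residual(eng, D)
  expect_gt(res, 0)
  expect_equal(exact_J(eng, D)$energy - rij_J(eng, D)$energy, res / 2,
               tolerance = 1e-10)
})

test_that("Coulomb builds are linear in the density", {
  eng <- bupo_engine(compact_system(), bupo_config())
  D <- make_density(eng$sys, "random_spd", seed = 3)
  r0 <- rij_J(eng, matrix(0, eng$nbf, eng$nbf))
  expect_equal(max(abs(r0$J)), 0)
  expect_equal(r0$energy, 0)
  r1 <- rij_J(eng, D); r2 <- rij_J(eng, 2.5 * D)
  expect_equal(r2$J, 2.5 * r1$J, tolerance = 1e-12)
})

test_that("Split-RI-J reproduces RI-J exactly", {
  for (sys in list(compact_system(), linear_system(4))) {
    eng <- bupo_engine(sys, bupo_config())
    D <- make_density(sys, "sad")
    r1 <- rij_J(eng, D); r2 <- split_rij_J(eng, D)
    expect_lt(max(abs(r1$J - r2$J)), 1e-12)
    expect_lt(abs(r1$energy - r2$energy), 1e-10 * abs(r1$energy))
  }
})

test_that("with an empty far field RI-BUPO-J collapses onto Split-RI-J", {
  sys <- compact_system()
  cfg <- bupo_config(Thresh = 1e-300)   # no Schwarz skips: pure comparison
  eng <- bupo_engine(sys, cfg)
  D <- make_density(sys, "sad")
  r2 <- split_rij_J(eng, D)
  r3 <- rbupo_J(eng, D)
  expect_lt(max(abs(r3$J - r2$J)), 1e-12)
  expect_equal(sum(r3$stats$ff), 0)   # compact: no far field at all
})

test_that("R_allow = Inf makes every builder collapse onto its analytic twin", {
  sys <- linear_system(6)
  cfg <- bupo_config(R_allow = Inf, Thresh = 1e-300)
  eng <- bupo_engine(sys, cfg)
  D <- make_density(sys, "sad")
  r2 <- rij_J(eng, D)
  r3 <- rbupo_J(eng, D)
  expect_lt(max(abs(r3$J - r2$J)), 1e-12)
  r4 <- bupoJ_fullJ(eng, D)
  rx <- exact_J(eng, D)
  expect_lt(max(abs(r4$J - rx$J)), 1e-12)
})

test_that("distant fragments: far-field auxiliary vector is accurate", {
  at1 <- make_chain(1, "peptide")
  at2 <- make_chain(1, "peptide")
  at2$x <- at2$x + 28
  at <- atoms(c(at1$element, at2$element), rbind(as.matrix(at1[, 2:4]),
                                                 as.matrix(at2[, 2:4])))
  sys <- build_system(at, toy_basis("ao"), toy_basis("aux"))
  eng <- bupo_engine(sys, bupo_config(TargetDim1 = 30L))
  D <- make_density(sys, "sad")
  s1 <- bupo_step1(eng, D)
  expect_gt(s1$stats$ff, 0)
  expect_lt(max(abs(s1$g - bupo:::exact_g(eng, D))), 1e-8)
})

test_that("BUPO-J (four-index near field) tracks the exact oracle on a chain", {
  sys <- build_system(make_chain(12, "linear", spacing = 2.5, element = "H"),
                      s_basis(c(1.8, 0.35), c(0.4, 0.75)), toy_basis("aux"))
  eng <- bupo_engine(sys, bupo_config(TargetDim1 = 10L))
  D <- make_density(sys, "sad")
  r <- bupoJ_fullJ(eng, D)
  rx <- exact_J(eng, D)
  expect_lt(max(abs(r$J - rx$J)), 1e-8)
  st <- r$stats
  expect_equal(st$pct_nf + st$pct_ff + st$pct_skipped, 100, tolerance = 1e-10)
  # cap on four-index builds
  eng$cfg$eri4_cap <- 4L
  expect_error(bupoJ_fullJ(eng, D), "exceed")
})

test_that("every auxiliary/pair interaction is handled exactly once", {
  sys <- linear_system(6)
  eng <- bupo_engine(sys, bupo_config(TargetDim1 = 6L, Thresh = 1e-300))
  D <- make_density(sys, "sad")
  s1 <- bupo_step1(eng, D, audit = TRUE)
  ok1 <- vapply(seq_along(eng$auxd), function(k) {
    a <- s1$audit[[k]]
    identical(sort(c(a$ff, a$nf, a$skipped)), seq_along(eng$pairs))
  }, TRUE)
  expect_true(all(ok1))
  cK <- solve_fit(eng$M, s1$g)
  s2 <- bupo_step2(eng, cK, audit = TRUE)
  ok2 <- vapply(seq_along(eng$pairs), function(ip) {
    a <- s2$audit[[ip]]
    identical(sort(c(a$ff, a$nf, a$skipped)), seq_along(eng$auxd))
  }, TRUE)
  expect_true(all(ok2))
})

test_that("incremental driver schedules rebuilds and tracks one-shot builds", {
  sys <- linear_system(5)
  eng <- bupo_engine(sys, bupo_config(TargetDim1 = 10L))
  D0 <- make_density(sys, "sad")
  # constant density: every increment is a zero update
  resc <- build_driver(eng, list(D0, D0, D0))
  expect_equal(attr(resc, "full_builds"), 1L)
  expect_equal(resc[[3]]$J, resc[[1]]$J, tolerance = 1e-14)
  expect_equal(sum(resc[[2]]$stats$nf) + sum(resc[[2]]$stats$ff), 0)
  # 12 synthetic iterations, restart cycle 10: full builds at 1 and 11
  set.seed(6)
  Ds <- lapply(1:12, function(n) D0 * (1 + 2^(-n)) )
  res <- build_driver(eng, Ds)
  expect_equal(attr(res, "full_builds"), c(1L, 11L))
  one_shot <- rbupo_J(eng, Ds[[12]])
  expect_lt(max(abs(res[[12]]$J - one_shot$J)), 1e-8)
})

test_that("RI-BUPO-J energies show no systematic orientation dependence", {
  sys <- chain_system(4)
  D <- make_density(sys, "sad")   # equal occupation per shell: rotation safe
  cfg <- bupo_config(TargetDim1 = 40L)
  e0 <- rbupo_J(bupo_engine(sys, cfg), D)$energy
  for (s in 1:2) {
    R <- rotation_matrix(s)
    sys_r <- build_system(rotate_atoms(sys$atoms, R), toy_basis("ao"),
                          toy_basis("aux"))
    er <- rbupo_J(bupo_engine(sys_r, cfg), D)$energy
    # at production settings the bound is the multipole accuracy itself
    expect_lt(abs(er - e0), 1e-8)
  }
})

test_that("diffuse auxiliary shells ride the always-near-field throwaway bubble", {
  aux <- bupo:::basis_set(list(
    X = list(list(l = 0L, exps = 1.1, coefs = 1),
             list(l = 0L, exps = 0.004, coefs = 1),  # very diffuse
             list(l = 1L, exps = 0.8, coefs = 1),
             list(l = 2L, exps = 0.7, coefs = 1)),
    H = list(list(l = 0L, exps = 0.7, coefs = 1))
  ))
  sys <- build_system(make_chain(6, "linear"), toy_basis("ao"), aux)
  eng <- bupo_engine(sys, bupo_config(TargetDim1 = 10L))
  expect_gt(length(eng$aux_throwaway), 0)
  D <- make_density(sys, "sad")
  r <- rbupo_J(eng, D)
  rr <- rij_J(eng, D)
  expect_lt(abs(r$energy - rr$energy), 1e-6 * abs(rr$energy))
})
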