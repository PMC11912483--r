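test_that("bottom-level clustering is balanced, enclosing, and deterministic", {
  # everything fits in one bubble
  set.seed(5)
  cen <- matrix(rnorm(30), 10)
  ext <- runif(10, 0.5, 2)
  b1 <- kmeans_bubbles(cen, ext, TargetDim = 150L)
  expect_length(b1, 1L)
  expect_setequal(b1[[1]]$members, 1:10)

  # 300 objects on a line, TargetDim 150: two bubbles splitting the line
  cen2 <- cbind(seq(0, 60, length.out = 300), 0, 0)
  ext2 <- rep(1, 300)
  b2 <- kmeans_bubbles(cen2, ext2, TargetDim = 150L)
  expect_length(b2, 2L)
  for (b in b2) {
    d <- sqrt(rowSums((cen2[b$members, , drop = FALSE] -
                         rep(b$center, each = length(b$members)))^2))
    expect_true(all(d + ext2[b$members] <= b$radius + 1e-12))
  }

  # random 3-d cloud: exhaustive enclosure + balance + determinism
  set.seed(9)
  cen3 <- matrix(rnorm(900, sd = 8), 300)
  ext3 <- runif(300, 0.3, 3)
  b3 <- kmeans_bubbles(cen3, ext3, TargetDim = 40L, seed = 1L)
  for (b in b3) {
    d <- sqrt(rowSums((cen3[b$members, , drop = FALSE] -
                         rep(b$center, each = length(b$members)))^2))
    expect_true(all(d + ext3[b$members] <= b$radius + 1e-12))
    expect_lte(length(b$members), 2L * 40L)
  }
  expect_setequal(unlist(lapply(b3, `[[`, "members")), 1:300)
  b3b <- kmeans_bubbles(cen3, ext3, TargetDim = 40L, seed = 1L)
  expect_identical(b3, b3b)

  # clustering objective sanity: within-cluster scatter comparable to the
  # reference k-means implementation on the same data and cluster count
  wss <- function(groups) {
    sum(vapply(groups, function(g) {
      m <- colMeans(cen3[g, , drop = FALSE])
      sum((cen3[g, , drop = FALSE] - rep(m, each = length(g)))^2)
    }, 0))
  }
  ours <- wss(lapply(b3, `[[`, "members"))
  km <- stats::kmeans(cen3, centers = length(b3), nstart = 10, iter.max = 100)
  expect_lt(ours, 1.5 * km$tot.withinss)
})

test_that("hierarchies terminate at one top bubble with enclosing parents", {
  set.seed(5)
  cen <- matrix(rnorm(30), 10); ext <- runif(10, 0.5, 2)
  h1 <- build_hierarchy(kmeans_bubbles(cen, ext, 150L))
  expect_equal(h1$nlevels, 1L)

  # 9 bubbles, TargetDim2 = 3: 9 -> 3 -> 1
  cen9 <- cbind(seq(0, 80, 10), 0, 0)
  b9 <- kmeans_bubbles(cen9, rep(1, 9), TargetDim = 1L)
  h9 <- build_hierarchy(b9, TargetDim2 = 3L)
  expect_equal(lengths(h9$levels), c(9L, 3L, 1L))

  # chain system: per-level counts decrease by about TargetDim2
  eng <- bupo_engine(linear_system(24), bupo_config(TargetDim1 = 10L))
  tab <- hierarchy_table(eng$pair_hier)
  expect_equal(tab$n_bubbles[nrow(tab)], 1L)
  ratios <- tab$n_bubbles[-nrow(tab)] / tab$n_bubbles[-1]
  expect_true(all(ratios[-length(ratios)] >= 2 & ratios[-length(ratios)] <= 4.5))
  expect_lte(bupo:::enclosure_violation(eng$pair_hier, eng$pair_centers,
                                        eng$pair_extents), 1e-12)
})

test_that("bottom aggregation reproduces classical multipoles", {
  # a bubble holding two opposite unit point charges: zero monopole,
  # dipole q*d along the separation axis
  d <- 1.2
  moments <- list(regular_solid_real(6, c(0, 0, 0)),
                  -regular_solid_real(6, c(0, 0, 0)))
  centers <- rbind(c(0, 0, d / 2), c(0, 0, -d / 2))
  b <- list(bupo:::make_bubble(1L, 1:2, centers, c(0, 0)))
  h <- build_hierarchy(b)
  h <- aggregate_bottom_multipoles(h, moments, centers, NULL, c(1, 1), 6L,
                                   T_screen = 0)
  M <- h$levels[[1]][[1]]$M
  expect_equal(M[1], 0, tolerance = 1e-14)
  expect_equal(M[3], d, tolerance = 1e-13)       # z dipole
  # single-member bubble centered on the member: multipole = object moments
  b1 <- list(bupo:::make_bubble(1L, 1L, centers[1, , drop = FALSE], 0))
  h1 <- aggregate_bottom_multipoles(build_hierarchy(b1),
                                    moments[1], centers[1, , drop = FALSE],
                                    NULL, 1, 6L, T_screen = 0)
  expect_equal(h1$levels[[1]][[1]]$M, c(moments[[1]]), tolerance = 1e-14)
})

test_that("bubble potentials match explicit member sums far away", {
  set.seed(12)
  n <- 25
  pos <- matrix(rnorm(3 * n, sd = 2), n)
  q <- rnorm(n)
  moments <- lapply(1:n, function(i) matrix(regular_solid_real(10, c(0, 0, 0)) * q[i]))
  b <- kmeans_bubbles(pos, rep(0, n), TargetDim = 30L)
  h <- aggregate_bottom_multipoles(build_hierarchy(b), moments, pos, NULL,
                                   abs(q), 10L, T_screen = 0)
  bb <- h$levels[[1]][[1]]
  probe <- bb$center + c(5 * bb$radius, 0, 0)
  exact <- sum(q / sqrt(rowSums((pos - rep(probe, each = n))^2)))
  Tm <- interaction_tensor(probe, bb$center, 0, bb$L)
  approxv <- drop(Tm %*% bb$M)
  expect_lt(abs(approxv - exact) / abs(exact), 1e-8)
})

test_that("up-translation conserves charge and converges with the increment", {
  set.seed(21)
  n <- 60
  pos <- matrix(rnorm(3 * n, sd = 6), n)
  q <- rnorm(n)
  moments <- lapply(1:n, function(i) matrix(regular_solid_real(4, c(0, 0, 0)) * q[i]))
  b <- kmeans_bubbles(pos, rep(0.5, n), TargetDim = 8L)
  h0 <- aggregate_bottom_multipoles(build_hierarchy(b, 3L), moments, pos,
                                    NULL, abs(q), 4L, T_screen = 0)
  errs <- vapply(c(0L, 2L, 4L, 6L), function(inc) {
    h <- up_translate(h0, Lincr = c(inc, 2L), T_screen = 0)
    top <- h$levels[[h$nlevels]][[1]]
    # total charge conserved at every level
    for (lev in seq_len(h$nlevels)) {
      expect_equal(sum(vapply(h$levels[[lev]], function(x) x$M[1], 0)),
                   sum(q), tolerance = 1e-12)
    }
    probe <- top$center + c(2.2 * top$radius, 1, 0)
    exact <- sum(q / sqrt(rowSums((pos - rep(probe, each = n))^2)))
    abs(drop(interaction_tensor(probe, top$center, 0, top$L) %*% top$M) - exact)
  }, 0)
  # the error drops sharply with the first increment, then plateaus at the
  # floor set by the (fixed) later increments
  expect_true(all(errs[-1] < errs[1] / 5))
  expect_true(all(diff(log10(errs)) < 0.3))
})

test_that("atomic auxiliary bubbles give exact terminating bottom levels", {
  sys <- build_system(atoms(c("X", "X"), rbind(c(0, 0, 0), c(0, 0, 3))),
                      toy_basis("ao"), toy_basis("aux"))
  b <- atomic_aux_bubbles(sys)
  expect_length(b, 2L)
  h <- build_hierarchy(b, 3L)
  expect_equal(h$nlevels, 2L)
  eng <- bupo_engine(sys, bupo_config())
  D <- make_density(sys, "sad")
  cK <- solve_fit(eng$M, bupo:::exact_g(eng, D))
  h <- bupo:::fill_aux_hierarchy(eng, cK, c(10L, 6L), 1e-30)
  # the aux-density-weighted bubble potential matches the eri3-exact
  # potential of a distant s-probe pair after up-translation
  probe_sys <- build_system(atoms("H", matrix(c(0, 30, 1.5), 1)),
                            s_basis(0.8), s_basis(1.0))
  ppr <- build_shell_pairs(probe_sys, 1e-15)[[1]]
  exact <- 0
  for (k in seq_along(eng$auxd)) {
    kseg <- eng$aux_off[k] + seq_len(eng$auxd[[k]]$nfun)
    exact <- exact + drop(crossprod(eri_dist(eng$auxd[[k]], ppr), cK[kseg]))
  }
  top <- h$levels[[h$nlevels]][[1]]
  Mp <- dist_multipoles(ppr, ppr$P, 10)
  Tm <- interaction_tensor(ppr$P, top$center, 10, top$L)
  expect_lt(abs(drop(crossprod(Mp, Tm %*% top$M)) - exact) / abs(exact), 1e-9)
})
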