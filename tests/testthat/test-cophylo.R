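cophylo_fixture <- function(seed = 17, n = 8, p_switch = 0) {
  cfg <- sim_config(n_samples = n, p_switch = p_switch)
  tr <- simulate_host_tree(cfg, seed)
  ps <- simulate_parasite_system(tr, cfg, seed + 1)
  dh <- patristic_matrix(tr)
  dp <- patristic_matrix(ps$tree)
  A <- assoc_matrix(unclass(ps$assoc)[rownames(dp), rownames(dh)])
  list(dh = dh, dp = dp, A = A)
}

test_that("ParaFit global statistic matches ape::parafit on the same input", {
  fx <- cophylo_fixture()
  ours <- parafit_test(fx$dh, fx$dp, fx$A, n_perm = 49, seed = 1,
                       per_link = FALSE)
  # ape::parafit takes the association with hosts as rows
  ref <- ape::parafit(unclass(fx$dh), unclass(fx$dp), t(unclass(fx$A)),
                      nperm = 9, silent = TRUE)
  expect_equal(ours$global, ref$ParaFitGlobal, tolerance = 1e-6)
})

test_that("ParaFit is invariant to joint host relabeling and to PCoA sign flips", {
  fx <- cophylo_fixture()
  base <- parafit_test(fx$dh, fx$dp, fx$A, n_perm = 9, seed = 1,
                       per_link = FALSE)
  p <- sample(nrow(fx$dh))
  dh2 <- dist_matrix(unclass(fx$dh)[p, p], "patristic")
  A2 <- assoc_matrix(unclass(fx$A)[, p])
  perm <- parafit_test(dh2, fx$dp, A2, n_perm = 9, seed = 1, per_link = FALSE)
  expect_equal(perm$global, base$global, tolerance = 1e-9)
  # sign indeterminacy: the statistic uses squared projections only, so
  # flipping any embedding axis cannot change it; verified via the
  # quadratic form trace(t(B) t(A) C t(C) A B) computed directly
  B <- yartsa:::pcoa_axes(fx$dh)
  C <- yartsa:::pcoa_axes(fx$dp)
  s <- sample(c(-1, 1), ncol(C), replace = TRUE)
  D1 <- crossprod(C, unclass(fx$A) %*% B)
  D2 <- crossprod(sweep(C, 2, s, `*`), unclass(fx$A) %*% B)
  expect_equal(sum(D1^2), sum(D2^2), tolerance = 1e-9)
})

test_that("exact ParaFit row-permutation null matches an independent enumeration", {
  # 3 hosts x 3 parasites keeps the null at 6^3 = 216 states
  fx <- cophylo_fixture(seed = 23, n = 3)
  ours <- parafit_test(fx$dh, fx$dp, fx$A, n_perm = 0, seed = 1, exact = TRUE)
  expect_equal(ours$n_perm, 216L)
  # oracle: explicit nested loops over per-row host permutations
  B <- yartsa:::pcoa_axes(fx$dh)
  C <- yartsa:::pcoa_axes(fx$dp)
  Am <- unclass(fx$A)
  gstat <- function(Ax) sum(crossprod(C, Ax %*% B)^2)
  obs <- gstat(Am)
  perms <- yartsa:::all_permutations(3)
  cnt <- 0L; tot <- 0L
  for (i1 in 1:6) for (i2 in 1:6) for (i3 in 1:6) {
    Ap <- rbind(Am[1, perms[i1, ]], Am[2, perms[i2, ]], Am[3, perms[i3, ]])
    if (gstat(Ap) >= obs - 1e-12) cnt <- cnt + 1L
    tot <- tot + 1L
  }
  expect_identical(ours$p_global, cnt / tot)
})

test_that("degenerate cophylogeny inputs are rejected", {
  fx <- cophylo_fixture()
  one <- matrix(0, 1, 1, dimnames = list("h", "h"))
  expect_error(parafit_test(dist_matrix(one + diag(0, 1)), fx$dp, fx$A),
               "square, n >= 2|association")
  badA <- unclass(fx$A)[, c(2, 1, 3:8)]
  expect_error(parafit_test(fx$dh, fx$dp, assoc_matrix(badA)),
               "association columns")
})

test_that("PACo: identical configurations give m2 ~ 0 and residuals sum to m2", {
  fx <- cophylo_fixture()
  dp_same <- dist_matrix(unclass(fx$dh), "patristic")
  rownames_dp <- rownames(fx$dp)
  m <- unclass(dp_same)
  dimnames(m) <- list(rownames_dp, rownames_dp)
  A <- assoc_matrix(diag(nrow(m)) |>
                      (\(x) { dimnames(x) <- list(rownames_dp, rownames(fx$dh)); x })())
  pc <- paco_test(fx$dh, dist_matrix(m, "patristic"), A, n_perm = 49, seed = 1)
  expect_lt(pc$m2, 1e-9)
  expect_equal(sum(pc$residuals), pc$m2, tolerance = 1e-9)
  expect_equal(length(pc$residuals), sum(unclass(A)))

  # shuffled associations are worse than the identity in >= 95% of shuffles
  real <- cophylo_fixture(seed = 31, n = 10)
  pc0 <- paco_test(real$dh, real$dp, real$A, n_perm = 9, seed = 1)
  set.seed(40)
  worse <- 0
  for (i in 1:100) {
    Am <- unclass(real$A)[sample(nrow(real$A)), ]
    rownames(Am) <- rownames(real$A) # keep label alignment with d_par
    pci <- paco_test(real$dh, real$dp, assoc_matrix(Am), n_perm = 9, seed = 1)
    if (pci$m2 > pc0$m2) worse <- worse + 1
  }
  expect_gte(worse, 95)
})

test_that("Procrustes residual agrees with vegan::procrustes", {
  fx <- cophylo_fixture(seed = 29, n = 9)
  X <- yartsa:::cailliez_pcoa(fx$dh)
  Y <- yartsa:::cailliez_pcoa(fx$dp)
  k <- min(ncol(X), ncol(Y))
  ours <- yartsa:::procrustes_m2(X[, 1:k, drop = FALSE], Y[, 1:k, drop = FALSE])
  ref <- vegan::procrustes(X[, 1:k, drop = FALSE], Y[, 1:k, drop = FALSE],
                           symmetric = FALSE, scale = TRUE)
  expect_equal(ours$m2, ref$ss, tolerance = 1e-8)
})
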