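test_that("exact chain matches the closed-form L1 probabilities", {
  M <- brute_force_macromodel(toy_L1())
  ch <- exact_macro_chain(M)
  q01 <- 0.5 * exp(-2) / (1 + exp(-2))
  q10 <- 0.5 * exp(-1)
  expect_equal(ch$P[1, 2], q01, tolerance = 1e-9)
  expect_equal(ch$P[2, 1], q10, tolerance = 1e-9)
  expect_equal(rowSums(ch$P), c(1, 1), tolerance = 1e-12)
  # macro detailed balance through the symmetric Z{b,c}
  expect_equal(M$Z[1] * ch$P[1, 2], M$Z[2] * ch$P[2, 1], tolerance = 1e-12)
  expect_equal(M$Z[1] * ch$P[1, 2], 0.5 * exp(-2), tolerance = 1e-12)
})

test_that("a single-basin model yields the trivial chain", {
  M <- brute_force_macromodel(rna_landscape("AAAA"))
  ch <- exact_macro_chain(M)
  expect_equal(ch$P, matrix(1, 1, 1))
  expect_equal(first_passage_times(ch, 1), c("...." = 0), ignore_attr = TRUE)
})

test_that("chains are row-stochastic with macro detailed balance everywhere", {
  for (L in list(toy_L2(), random_toy_landscape(120, 4, 0, 6, seed = 8),
                 rna_landscape("GCGCAAAUUCGC"))) {
    fl <- barriers_flood(L)
    M <- fl$model
    ex <- exact_macro_chain(M)
    ar <- arrhenius_chain(fl$tree, L$beta)
    mg <- merged_chain(ex, ar)
    for (ch in list(ex, ar, mg)) {
      expect_true(all(ch$P >= 0))
      expect_equal(rowSums(ch$P), rep(1, nrow(ch$P)), tolerance = 1e-12)
    }
    ZP <- M$Z * ex$P
    expect_equal(ZP, t(ZP), tolerance = 1e-9)
  }
})

test_that("Arrhenius chain connects all pairs through saddle energies", {
  fl <- barriers_flood(toy_L2())
  ar <- arrhenius_chain(fl$tree, beta = 1)
  m <- setNames(seq_along(ar$minima), ar$minima)
  # adjacent pair {s2},{s3,s4}: exponent -(2.0 - 1.0)
  expect_equal(ar$P[m["s2"], m["s4"]], ar$A * exp(-1), tolerance = 1e-12)
  # non-adjacent pair {s0,s1},{s3,s4}: saddle 3.0 from minimum s0
  expect_equal(ar$P[m["s0"], m["s4"]], ar$A * exp(-3), tolerance = 1e-12)
  # detailed balance w.r.t. minima energies
  expect_equal(ar$P[m["s0"], m["s2"]] / ar$P[m["s2"], m["s0"]],
               exp(-(1 - 0)), tolerance = 1e-12)
  expect_error(arrhenius_chain(fl$tree, 1, A = -1), "positive")
})

test_that("merged chain keeps exact topology with Arrhenius values", {
  # L1: both basins adjacent, so merged equals Arrhenius off the diagonal
  fl1 <- barriers_flood(toy_L1())
  ex1 <- exact_macro_chain(fl1$model)
  ar1 <- arrhenius_chain(fl1$tree, 1)
  mg1 <- merged_chain(ex1, ar1)
  off <- row(mg1$P) != col(mg1$P)
  expect_equal(mg1$P[off], ar1$P[off])
  # L2: {s0,s1} and {s3,s4} are not adjacent in the exact topology
  fl2 <- barriers_flood(toy_L2())
  ex2 <- exact_macro_chain(fl2$model)
  ar2 <- arrhenius_chain(fl2$tree, 1)
  mg2 <- merged_chain(ex2, ar2)
  m <- setNames(seq_along(mg2$minima), mg2$minima)
  expect_equal(mg2$P[m["s0"], m["s4"]], 0)
  expect_gt(ar2$P[m["s0"], m["s4"]], 0)
  # no exact transitions -> merged chain is the identity
  Mmono <- brute_force_macromodel(chain_landscape(c(0, 1)))
  ch <- exact_macro_chain(Mmono)
  expect_equal(merged_chain(ch, ch)$P, ch$P)
})

test_that("first-passage times solve the defining recursion", {
  # geometric mean: q(b -> t) = 0.5 gives tau = 2
  two <- structure(list(
    P = matrix(c(0.5, 0, 0.5, 1), 2), minima = c("b", "t"),
    energy = c(1, 0), model_tag = "exact", A = NA_real_, beta = 1,
    pi = c(0.5, 0.5)), class = "macro_chain")
  expect_equal(unname(first_passage_times(two, "t")["b"]), 2)
  # L1 exact chain: two-state closed form 1/q
  ch <- exact_macro_chain(brute_force_macromodel(toy_L1()))
  tau <- first_passage_times(ch, "s2")
  expect_equal(unname(tau["s0"]), (1 + exp(-2)) / (0.5 * exp(-2)),
               tolerance = 1e-9)
  expect_equal(unname(tau["s2"]), 0)
  # residual of the recursion at non-target rows
  fl <- barriers_flood(toy_L2())
  ex <- exact_macro_chain(fl$model)
  for (t in seq_along(ex$minima)) {
    tau <- unname(first_passage_times(ex, t))
    resid <- tau - (1 + ex$P %*% tau)
    expect_lt(max(abs(resid[-t])), 1e-8)
  }
})

test_that("unreachable targets get infinite first-passage times", {
  # two disconnected components in one (artificial) chain
  P <- diag(2)
  ch <- structure(list(P = P, minima = c("a", "b"), energy = c(0, 0),
                       model_tag = "exact", A = NA_real_, beta = 1,
                       pi = c(0.5, 0.5)), class = "macro_chain")
  tau <- first_passage_times(ch, "b")
  expect_equal(unname(tau), c(Inf, 0), ignore_attr = TRUE)
})

test_that("fundamental-matrix route equals the per-target solves", {
  for (L in list(toy_L2(), random_toy_landscape(60, 4, 0, 6, seed = 14))) {
    fl <- barriers_flood(L)
    for (ch in list(exact_macro_chain(fl$model),
                    arrhenius_chain(fl$tree, L$beta))) {
      start <- 1L
      tau_all <- basinflood:::.fpt_from_start(ch, start)
      for (t in seq_along(ch$minima)[-start]) {
        tau_t <- first_passage_times(ch, t)
        expect_equal(unname(tau_all[t]), unname(tau_t[start]),
                     tolerance = 1e-7)
      }
    }
  }
})

test_that("FPT ranks are invariant to the Arrhenius prefactor", {
  fl <- barriers_flood(rna_landscape("GCGCAAAUUCGC"))
  A0 <- arrhenius_chain(fl$tree, 1)$A
  for (mk in list(function(a) arrhenius_chain(fl$tree, 1, a),
                  function(a) merged_chain(exact_macro_chain(fl$model),
                                           arrhenius_chain(fl$tree, 1, a)))) {
    t1 <- basinflood:::.fpt_from_start(mk(A0), 1L)
    t2 <- basinflood:::.fpt_from_start(mk(A0 / 10), 1L)
    # halving A makes the chain lazy: tau scales by exactly A0/A
    expect_equal(t2 * 0.1, t1, tolerance = 1e-8)
    # ranks identical once solver noise below 10 significant digits is dropped
    expect_identical(rank(signif(t1[-1], 10)), rank(signif(t2[-1] * 0.1, 10)))
  }
})

test_that("Spearman correlation handles ties, reversals and degeneracy", {
  expect_equal(as.numeric(spearman_rho(1:5, 1:5)), 1)
  expect_equal(as.numeric(spearman_rho(1:5, 5:1)), -1)
  expect_equal(as.numeric(spearman_rho(c(1, 2, 3), c(3, 1, 2))), -0.5)
  expect_error(spearman_rho(c(1, 2), c(1, NA)), "fewer than 2")
  expect_error(spearman_rho(c(1, 2, 3), c(7, 7, 7)), "zero rank variance")
  # non-finite pairs are excluded, with the count reported
  r <- spearman_rho(c(1, 2, 3, Inf), c(4, 5, 6, 7))
  expect_equal(attr(r, "n_used"), 3L)
})

test_that("model comparison cross-checks against hand-solved systems", {
  cmp <- compare_models(toy_L2(), start = "s0")
  expect_equal(cmp$start_basin, "s0")
  # hand solve the exact 3x3 system for tau(s0 -> each target)
  fl <- barriers_flood(toy_L2())
  ex <- exact_macro_chain(fl$model)
  for (t in 2:3) {
    keep <- setdiff(1:3, t)
    tau <- solve(diag(2) - ex$P[keep, keep], c(1, 1))
    expect_equal(cmp$fpt$exact[t], tau[which(keep == 1)], tolerance = 1e-8)
  }
  # a model compared against itself correlates perfectly
  expect_equal(as.numeric(spearman_rho(cmp$fpt$exact[-1], cmp$fpt$exact[-1])), 1)
  expect_equal(cmp$excluded, c(barrier = 0L, merged = 0L))
})
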