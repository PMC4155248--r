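test_that("Boltzmann weights follow the closed form", {
  expect_equal(boltzmann_weight(0, 2.5), 1)
  expect_equal(boltzmann_weight(2, 1), exp(-2))
  expect_equal(boltzmann_weight(17, 0), 1)
  expect_error(boltzmann_weight(1, -1))
})

test_that("Metropolis probabilities clamp downhill moves at 1/delta", {
  L1 <- toy_L1()
  expect_equal(metropolis_probability(L1, "s1", "s0"), 0.5)       # downhill
  expect_equal(metropolis_probability(L1, "s0", "s1"), 0.5 * exp(-2))
  expect_error(metropolis_probability(L1, "s0", "s2"),
               "only defined for neighboring states")
})

test_that("micro detailed balance holds on every edge", {
  for (L in list(toy_L1(), toy_L2(), random_toy_landscape(150, 4, 0, 5, seed = 3),
                 rna_landscape("GCGCAAAUUCGC"))) {
    keys <- enumerate_states(L)
    e <- setNames(basinflood:::.ls_energy(L, keys), keys)
    for (x in keys) {
      for (y in basinflood:::.ls_neighbors(L, x)) {
        lhs <- boltzmann_weight(e[[x]], L$beta) * metropolis_probability(L, x, y)
        rhs <- boltzmann_weight(e[[y]], L$beta) * metropolis_probability(L, y, x)
        expect_equal(lhs, rhs, tolerance = 1e-12)
      }
    }
  }
})

test_that("steepest descent follows the total order and stops at minima", {
  L1 <- toy_L1()
  expect_equal(steepest_descent_neighbor(L1, "s1"), "s0")
  expect_null(steepest_descent_neighbor(L1, "s2"))
  expect_equal(gradient_walk(L1, "s1"), list(minimum = "s0", path_length = 1L))
  expect_equal(gradient_walk(L1, "s2"), list(minimum = "s2", path_length = 0L))
  # plateau tie: equal-energy lower neighbors resolved by id order
  Lt <- toy_landscape(data.frame(id = c("a", "b", "m"), energy = c(1, 1, 2)),
                      edges = rbind(c("m", "a"), c("m", "b")))
  expect_equal(steepest_descent_neighbor(Lt, "m"), "a")
  # hairpin is a fixed point under the simple model
  L <- rna_landscape("GGGAAACCC")
  expect_equal(gradient_walk(L, "(((...)))")$minimum, "(((...)))")
  # idempotence: F(F(x)) = F(x) for every state
  for (x in enumerate_states(L)) {
    m <- gradient_walk(L, x)$minimum
    expect_equal(gradient_walk(L, m)$path_length, 0L)
  }
})

test_that("state enumeration matches an independent combinatorial count", {
  expect_length(enumerate_states(toy_L1()), 3)
  expect_identical(enumerate_states(rna_landscape("AAAA")), "....")
  for (seq in c("GGGAAACCC", "GCGCAAAUUC", "ACGUACGUACGUAC")) {
    keys <- enumerate_states(rna_landscape(seq))
    expect_length(keys, count_structures_oracle(seq))
    expect_false(anyDuplicated(keys) > 0)
    expect_true(strrep(".", nchar(seq)) %in% keys)
  }
  expect_true("(((...)))" %in% enumerate_states(rna_landscape("GGGAAACCC")))
  # overflow cap reports the count
  expect_error(enumerate_states(rna_landscape("GGGAAACCC"), cap = 10),
               "overflow.*20", )
})

test_that("energy-bounded enumeration keeps the open-chain component", {
  # toy: plain energy filter (L2 below its lowest saddle keeps 3 states)
  expect_length(enumerate_states(toy_L2(), energy_bound = 1.6), 3)
  # rna: bounded states must connect to the open chain
  L <- rna_landscape("GGGAAACCC")
  keys <- enumerate_states(L, energy_bound = -3)
  en <- basinflood:::.ls_energy(L, keys)
  expect_true(all(en <= -3))
  expect_false(strrep(".", 9) %in% keys)   # open chain at 0 excluded
  expect_length(keys, 0)                   # hence nothing connects
  keys0 <- enumerate_states(L, energy_bound = 0)
  expect_length(keys0, 20)                 # full space lies at E <= 0
})

test_that("every enumerated state maps to exactly one basin", {
  L <- rna_landscape("GCGCAAAUUCGC")
  keys <- enumerate_states(L)
  F <- vapply(keys, function(x) gradient_walk(L, x)$minimum, character(1))
  M <- brute_force_macromodel(L)
  expect_setequal(unique(unname(F)), M$minima)
  expect_equal(sum(M$size), length(keys))
})

test_that("toy TSV round-trips through writer and reader", {
  L2 <- toy_L2()
  path <- tempfile(fileext = ".tsv")
  write_toy_tsv(L2, path)
  L2b <- read_toy_tsv(path)
  expect_setequal(L2b$ids, L2$ids)
  expect_equal(L2b$energy[L2$ids], L2$energy[L2$ids])
  expect_equal(L2b$adj[order(names(L2b$adj))], L2$adj[order(names(L2$adj))])
  expect_equal(L2b$delta, L2$delta)
  # comments and state sorting in the written file
  lines <- readLines(path)
  expect_match(lines[1], "^#")
  srec <- lines[startsWith(lines, "S")]
  expect_equal(srec[1], "S\ts0\t0")
})
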