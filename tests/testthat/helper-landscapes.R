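# Shared fixtures: the two canonical toy chains and small RNA landscapes.
# L1: s0(0.0) - s1(2.0) - s2(1.0); basins {s0, s1} and {s2}.
# L2: s0(0.0) - s1(3.0) - s2(1.0) - s3(2.0) - s4(0.5); three basins.

toy_L1 <- function(beta = 1) chain_landscape(c(0, 2, 1), beta = beta)
toy_L2 <- function(beta = 1) chain_landscape(c(0, 3, 1, 2, 0.5), beta = beta)

# fixture sequences <= 20 nt: the hand-checkable hairpin plus one random
# uniform-composition sequence per length 9..20
fixture_sequences <- function() {
  c("GGGAAACCC", random_rna_set(per_length = 1, len_min = 9, len_max = 20,
                                seed = 7))
}

# independent combinatorial oracle: number of nested structures of a
# sequence, by interval recursion over admissible pairs (no shared code
# with the enumeration path)
count_structures_oracle <- function(seq, min_loop = 3) {
  chars <- strsplit(toupper(seq), "")[[1]]
  ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  n <- length(chars)
  memo <- new.env(parent = emptyenv())
  cnt <- function(i, j) {
    if (i >= j) return(1)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    total <- cnt(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (k > j) break
      if (ok(chars[i], chars[k])) {
        total <- total + cnt(i + 1, k - 1) * cnt(k + 1, j)
      }
    }
    memo[[key]] <- total
    total
  }
  if (n < min_loop + 2) return(1)
  cnt(1, n)
}

# compare two macro models field by field (rel tolerance on Z values)
expect_equivalent_models <- function(a, b, tol = 1e-9) {
  expect_identical(a$minima, b$minima)
  expect_identical(a$size, b$size)
  expect_equal(a$Z, b$Z, tolerance = tol)
  expect_identical(a$transitions$i, b$transitions$i)
  expect_identical(a$transitions$j, b$transitions$j)
  expect_equal(a$transitions$Z, b$transitions$Z, tolerance = tol)
  expect_identical(a$total_states, b$total_states)
}

# local flooding of every basin assembled through discover_landscape
local_model <- function(L, seed_state) {
  discover_landscape(L, seed_state)
}

first_toy_state <- function(L) {
  L$ids[order(unname(L$energy), L$ids, method = "radix")][1]
}
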