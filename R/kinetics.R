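## Discrete-time macro-state Markov chains (exact / Arrhenius barrier /
## merged), first-passage times and Spearman model comparison.

.new_chain <- function(P, minima, energy, tag, A, beta, pi) {
  if (any(P < 0)) stop("internal-consistency error: negative chain entry")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("internal-consistency error: chain rows do not sum to 1 (max dev ",
         format(max(abs(rs - 1))), ")")
  }
  structure(list(P = P, minima = minima, energy = energy, model_tag = tag,
                 A = A, beta = beta, pi = pi),
            class = "macro_chain")
}

#' @export
print.macro_chain <- function(x, ...) {
  cat("macro-state chain (", x$model_tag, "): ", nrow(x$P), " basins",
      if (!is.na(x$A)) paste0(", prefactor A = ", format(x$A)), "\n", sep = "")
  invisible(x)
}

#' Exact macro-state transition chain
#'
#' The row-stochastic one-step chain with off-diagonal probabilities
#' `q(b -> c) = Z{b,c} / Z_b` (the `delta^-1` Metropolis factor is already
#' inside `Z{b,c}`) and diagonals completing each row.  Satisfies macro
#' detailed balance `Z_b q(b -> c) = Z_c q(c -> b)` by construction.
#'
#' @param M a `macro_model` covering one connected component.
#' @return A `macro_chain` with `model_tag = "exact"`.
#' @export
exact_macro_chain <- function(M) {
  stopifnot(inherits(M, "macro_model"))
  nb <- length(M$minima)
  P <- matrix(0, nb, nb)
  tr <- M$transitions
  if (nrow(tr) > 0) {
    P[cbind(tr$i, tr$j)] <- tr$Z / M$Z[tr$i]
    P[cbind(tr$j, tr$i)] <- tr$Z / M$Z[tr$j]
  }
  off <- rowSums(P)
  if (any(off > 1 + 1e-12)) {
    stop("internal-consistency error: negative diagonal in exact chain")
  }
  diag(P) <- pmax(0, 1 - off)
  .new_chain(P, M$minima, M$energy, "exact", NA_real_, M$beta, M$Z / sum(M$Z))
}

#' Arrhenius barrier-tree transition chain
#'
#' Transition probabilities between *all* basin pairs from the barrier
#' tree: `a(b -> c) = A exp(-beta (E(b,c) - E(min_b)))` where `E(b,c)` is
#' the saddle energy between the minima.  This model deliberately ignores
#' landscape topology: every pair gets positive probability.  With
#' `A = "auto"` the prefactor is set to `0.99 / max_b sum_c exp(...)` so
#' that every diagonal stays positive; first-passage-time *ranks* are
#' invariant to the choice of `A`.
#'
#' @param tree a `barrier_tree` covering one connected component.
#' @param beta inverse temperature.
#' @param A positive prefactor, or `"auto"`.
#' @return A `macro_chain` with `model_tag = "barrier"`.
#' @export
arrhenius_chain <- function(tree, beta, A = "auto") {
  stopifnot(inherits(tree, "barrier_tree"))
  S <- .saddle_matrix(tree)
  if (anyNA(S)) {
    stop("barrier tree is a forest: all minima must be in one component")
  }
  nb <- tree$n_basins
  P <- exp(-beta * (S - tree$energy))     # vector recycles down columns: row b loses E_b
  diag(P) <- 0
  if (identical(A, "auto")) {
    A <- 0.99 / max(rowSums(P))
  }
  if (!is.numeric(A) || A <= 0) stop("prefactor A must be positive")
  P <- A * P
  off <- rowSums(P)
  if (any(off >= 1)) {
    stop("prefactor A too large: diagonal would be non-positive")
  }
  diag(P) <- 1 - off
  w <- exp(-beta * (tree$energy - min(tree$energy)))
  .new_chain(P, tree$minima, tree$energy, "barrier", A, beta, w / sum(w))
}

#' Merged transition chain
#'
#' Arrhenius probabilities restricted to the exact transition topology:
#' `q'(b -> c)` equals the barrier-model probability wherever the exact
#' chain has `q(b -> c) > 0`, and zero otherwise.  Separates the barrier
#' model's loss of precision from its loss of topology.
#'
#' @param exact an exact `macro_chain`.
#' @param arrhenius a barrier `macro_chain` over the same basins.
#' @return A `macro_chain` with `model_tag = "merged"`.
#' @export
merged_chain <- function(exact, arrhenius) {
  stopifnot(inherits(exact, "macro_chain"), inherits(arrhenius, "macro_chain"))
  if (!identical(exact$minima, arrhenius$minima)) {
    stop("basin index mismatch between exact and Arrhenius chains")
  }
  nb <- nrow(exact$P)
  mask <- exact$P > 0
  diag(mask) <- FALSE
  P <- ifelse(mask, arrhenius$P, 0)
  diag(P) <- 0
  off <- rowSums(P)
  diag(P) <- 1 - off
  .new_chain(P, exact$minima, exact$energy, "merged", arrhenius$A,
             arrhenius$beta, arrhenius$pi)
}

#' First-passage times to a target basin
#'
#' Expected number of chain steps to first reach `target`, from every
#' basin: `tau(t, t) = 0` and `tau(b, t) = 1 + sum_c q(b -> c) tau(c, t)`
#' otherwise, solved as the linear system `(I - Q) tau = 1` over
#' non-target states with the target row and column removed.  Basins that
#' cannot reach the target (or can escape into a region that cannot) get
#' `Inf`.
#'
#' @param chain a `macro_chain`.
#' @param target basin index or minimum key.
#' @return Named numeric vector of expected step counts (one per basin,
#'   named by minimum), with attribute `target`.
#' @export
first_passage_times <- function(chain, target) {
  stopifnot(inherits(chain, "macro_chain"))
  t <- .resolve_basin(chain, target)
  nb <- nrow(chain$P)
  tau <- rep(Inf, nb)
  tau[t] <- 0
  if (nb > 1) {
    ## states with a positive-probability path to the target
    pos <- chain$P > 0
    reach <- logical(nb)
    reach[t] <- TRUE
    frontier <- t
    while (length(frontier) > 0) {
      nxt <- which(apply(pos[, frontier, drop = FALSE], 1, any) & !reach)
      reach[nxt] <- TRUE
      frontier <- nxt
    }
    ## drop states whose walk can leak into a no-return region: their
    ## expected passage time is infinite as well
    repeat {
      ok <- which(reach)
      bad <- ok[vapply(ok, function(b) {
        any(pos[b, ] & !reach & seq_len(nb) != t)
      }, logical(1))]
      bad <- setdiff(bad, t)
      if (length(bad) == 0) break
      reach[bad] <- FALSE
    }
    R <- setdiff(which(reach), t)
    if (length(R) > 0) {
      Q <- chain$P[R, R, drop = FALSE]
      sol <- tryCatch(
        solve(diag(length(R)) - Q, rep(1, length(R))),
        error = function(e) stop("singular first-passage system: ",
                                 conditionMessage(e))
      )
      tau[R] <- sol
    }
  }
  names(tau) <- chain$minima
  attr(tau, "target") <- chain$minima[t]
  tau
}

## FPT from one start basin to every target at once, via the fundamental
## matrix Z = (I - P + 1 pi')^-1 of an irreducible chain:
## tau(b, t) = (Z[t,t] - Z[b,t]) / pi[t].  One dense solve instead of one
## per target.
.fpt_from_start <- function(chain, start) {
  nb <- nrow(chain$P)
  if (nb == 1) return(setNames(0, chain$minima))
  pi <- chain$pi
  Zf <- solve(diag(nb) - chain$P + matrix(pi, nb, nb, byrow = TRUE))
  tau <- (diag(Zf) - Zf[start, ]) / pi
  tau[start] <- 0
  setNames(tau, chain$minima)
}

.chain_connected <- function(chain) {
  nb <- nrow(chain$P)
  if (nb == 1) return(TRUE)
  pos <- chain$P > 0 | t(chain$P) > 0
  diag(pos) <- FALSE
  seen <- logical(nb)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- which(apply(pos[, frontier, drop = FALSE], 1, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged).  Pairs where
#' either entry is non-finite are dropped; fewer than two usable pairs or
#' zero rank variance is an error, not `NA`.
#'
#' @param u,v numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`, with attribute `n_used`.
#' @examples
#' spearman_rho(c(1, 2, 3), c(3, 1, 2))   # -0.5
#' @export
spearman_rho <- function(u, v) {
  stopifnot(length(u) == length(v))
  keep <- is.finite(u) & is.finite(v)
  u <- u[keep]; v <- v[keep]
  if (length(u) < 2) stop("Spearman correlation undefined: fewer than 2 usable pairs")
  ru <- rank(u); rv <- rank(v)
  if (stats::sd(ru) == 0 || stats::sd(rv) == 0) {
    stop("Spearman correlation undefined: zero rank variance")
  }
  rho <- stats::cor(ru, rv)
  attr(rho, "n_used") <- length(u)
  rho
}

#' Compare exact, barrier and merged kinetic models
#'
#' Decomposes the landscape, builds the three macro-state chains, and
#' computes the first-passage time from the unfolded-state basin (the
#' basin containing the open chain, found by a gradient walk; for toy
#' landscapes pass `start` explicitly) to every other basin under each
#' model.  Model quality is summarized as the Spearman rank correlation
#' of the approximate models' FPTs against the exact ones; ranks are
#' invariant to the Arrhenius prefactor.  Targets with a non-finite FPT
#' under either model of a pair are excluded (counts reported).
#'
#' @inheritParams enumerate_states
#' @param start state key seeding the start basin; default the open chain
#'   for RNA landscapes.
#' @param A Arrhenius prefactor (`"auto"` or positive number).
#' @return Object of class `model_comparison`: the per-target FPT table
#'   (`fpt`), `rho_exact_barrier`, `rho_exact_merged`, exclusion counts,
#'   the prefactor used, and basin/state counts.
#' @export
compare_models <- function(L, start = NULL, A = "auto", energy_bound = NULL,
                           cap = getOption("basinflood.cap", 1e6)) {
  stopifnot(inherits(L, "landscape"))
  if (is.null(start)) {
    if (L$kind != "rna") stop("start state required for toy landscapes")
    start <- .open_chain(L)
  }
  fl <- barriers_flood(L, energy_bound, cap)
  M <- fl$model
  start_min <- gradient_walk(L, start)$minimum
  s <- match(start_min, M$minima)
  if (is.na(s)) stop("start basin not part of the decomposition")
  exact <- exact_macro_chain(M)
  if (!.chain_connected(exact)) {
    stop("landscape decomposition is not connected; model comparison undefined")
  }
  tau_exact <- .fpt_from_start(exact, s)
  arrh <- arrhenius_chain(fl$tree, L$beta, A)
  tau_barrier <- .fpt_from_start(arrh, s)
  merged <- merged_chain(exact, arrh)
  A_used <- arrh$A
  rm(arrh)
  tau_merged <- .fpt_from_start(merged, s)
  rm(merged, exact)
  targets <- setdiff(seq_along(M$minima), s)
  rho_b <- spearman_rho(tau_exact[targets], tau_barrier[targets])
  rho_m <- spearman_rho(tau_exact[targets], tau_merged[targets])
  excl <- c(
    barrier = sum(!(is.finite(tau_exact[targets]) & is.finite(tau_barrier[targets]))),
    merged = sum(!(is.finite(tau_exact[targets]) & is.finite(tau_merged[targets])))
  )
  structure(list(
    start_state = start,
    start_basin = M$minima[s],
    n_basins = length(M$minima),
    n_states = M$total_states,
    A = A_used,
    fpt = data.frame(
      basin = M$minima,
      energy = M$energy,
      exact = unname(tau_exact),
      barrier = unname(tau_barrier),
      merged = unname(tau_merged)
    ),
    rho_exact_barrier = as.numeric(rho_b),
    rho_exact_merged = as.numeric(rho_m),
    excluded = excl
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("kinetic model comparison (", x$n_basins, " basins, ",
      x$n_states, " micro-states)\n",
      "  start basin: ", x$start_basin, "\n",
      "  Spearman exact vs barrier: ", sprintf("%.3f", x$rho_exact_barrier), "\n",
      "  Spearman exact vs merged:  ", sprintf("%.3f", x$rho_exact_merged), "\n",
      "  excluded targets: barrier ", x$excluded[["barrier"]],
      ", merged ", x$excluded[["merged"]],
      "; Arrhenius prefactor A = ", format(x$A), "\n", sep = "")
  invisible(x)
}
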