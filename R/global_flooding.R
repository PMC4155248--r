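## Exhaustive landscape decomposition: brute-force oracle and the
## energy-sorted ("bottom-up") flood with saddle detection.

## Build a macro-state model from an indexed landscape plus a basin
## assignment F (state index of each state's local minimum).
.macromodel_from_assignment <- function(idx, F, method, backend = "toy") {
  roots <- sort(unique(F))               # ascending index = landscape total order
  nb <- length(roots)
  basin_of_root <- integer(idx$n)
  basin_of_root[roots] <- seq_len(nb)
  B <- basin_of_root[F]
  Z <- as.vector(rowsum(idx$w, B))
  size <- tabulate(B, nb)
  ## states are rank-sorted, so the last member of a basin (stable order)
  ## carries its maximal energy
  o <- order(B)
  e_max <- idx$energy[o[cumsum(tabulate(B, nb))]]
  trans <- data.frame(i = integer(0), j = integer(0), Z = numeric(0))
  lens <- lengths(idx$adj)
  if (sum(lens) > 0) {
    from <- rep.int(seq_len(idx$n), lens)
    to <- unlist(idx$adj, use.names = FALSE)
    up <- to > from                      # each unordered edge once, `to` higher
    from <- from[up]; to <- to[up]
    cross <- B[from] != B[to]
    if (any(cross)) {
      a <- pmin(B[from[cross]], B[to[cross]])
      b <- pmax(B[from[cross]], B[to[cross]])
      contrib <- idx$w[to[cross]] / idx$delta   # higher endpoint contributes
      pair_id <- (a - 1) * nb + b
      agg <- rowsum(contrib, pair_id)
      ids <- as.numeric(rownames(agg))
      trans <- data.frame(i = as.integer((ids - 1) %/% nb + 1),
                          j = as.integer((ids - 1) %% nb + 1),
                          Z = as.vector(agg))
      trans <- trans[order(trans$i, trans$j), , drop = FALSE]
      rownames(trans) <- NULL
    }
  }
  structure(list(
    minima = idx$keys[roots],
    energy = idx$energy[roots],
    size = size,
    Z = Z,
    e_min = idx$energy[roots],
    e_max = e_max,
    transitions = trans,
    delta = idx$delta,
    beta = idx$beta,
    total_states = idx$n,
    method = method,
    backend = backend
  ), class = "macro_model")
}

.backend_name <- function(L) {
  if (L$kind == "toy") "toy" else L$backend$name
}

#' Brute-force gradient-basin decomposition
#'
#' The reference route: enumerate every micro-state, assign it to its
#' basin by an explicit gradient walk, accumulate the basin partition
#' functions `Z_b` from Boltzmann weights, and add
#' `delta^-1 * w(higher state)` once per basin-crossing micro-edge to the
#' transition-state partition function `Z{b,c}`.  Serves as the oracle
#' the flooding algorithms are validated against.
#'
#' @inheritParams enumerate_states
#' @return A `macro_model`: basins ordered by the landscape total order of
#'   their minima, with sizes, energies, `Z_b`, and the symmetric
#'   transition table `Z{b,c}`.
#' @export
brute_force_macromodel <- function(L, energy_bound = NULL,
                                   cap = getOption("basinflood.cap", 1e6)) {
  stopifnot(inherits(L, "landscape"))
  idx <- .index_landscape(L, energy_bound, cap)
  sdn <- .sdn_all(idx)
  F <- .assign_basins(sdn)
  .macromodel_from_assignment(idx, F, "brute_force", .backend_name(L))
}

#' Energy-sorted global flooding with barrier tree
#'
#' Processes all micro-states in ascending total order.  A state whose
#' neighbors all lie above it founds a new basin; every other state
#' inherits the basin of its steepest-descent neighbor by a single lookup
#' (the neighbor has already been processed).  A state adjacent to
#' several distinct basin components merges them; the state's energy is
#' recorded as the saddle between the previously unconnected components,
#' yielding the barrier tree.  The macro-state model is identical to
#' [brute_force_macromodel()] on the same state set.
#'
#' @inheritParams enumerate_states
#' @return List of class `barriers_flood` with elements `model`
#'   (a `macro_model`) and `tree` (a `barrier_tree` whose `merge_events`
#'   hold `(saddle_energy, basin_a, basin_b)` in ascending flood order).
#'   With an `energy_bound`, components connected only above the bound
#'   remain unmerged and the tree is a forest.
#' @export
barriers_flood <- function(L, energy_bound = NULL,
                           cap = getOption("basinflood.cap", 1e6)) {
  stopifnot(inherits(L, "landscape"))
  idx <- .index_landscape(L, energy_bound, cap)
  n <- idx$n
  B <- integer(n)                        # basin index per state
  nb <- 0L
  roots <- integer(0)                    # state index of each basin minimum
  parent <- integer(0)                   # union-find over basins
  rep_comp <- integer(0)                 # lowest basin index per component root
  ev_e <- numeric(0); ev_a <- integer(0); ev_b <- integer(0)
  ufind <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    a <- idx$adj[[i]]
    lower <- a[a < i]
    if (length(lower) == 0) {            # local minimum founds a basin
      nb <- nb + 1L
      B[i] <- nb
      roots[nb] <- i
      parent[nb] <- nb
      rep_comp[nb] <- nb
    } else {
      B[i] <- B[lower[1]]                # steepest-descent lookup (min index)
      comps <- unique(vapply(unique(B[lower]), ufind, integer(1)))
      if (length(comps) > 1) {
        keep <- comps[1]
        for (other in comps[-1]) {
          ra <- ufind(keep); rb <- ufind(other)
          ev_e <- c(ev_e, idx$energy[i])
          ev_a <- c(ev_a, min(rep_comp[ra], rep_comp[rb]))
          ev_b <- c(ev_b, max(rep_comp[ra], rep_comp[rb]))
          parent[rb] <- ra
          rep_comp[ra] <- min(rep_comp[ra], rep_comp[rb])
          keep <- ra
        }
      }
    }
  }
  F <- roots[B]
  model <- .macromodel_from_assignment(idx, F, "barriers_flood", .backend_name(L))
  tree <- structure(list(
    minima = model$minima,
    energy = model$energy,
    merge_events = data.frame(energy = ev_e, a = ev_a, b = ev_b),
    n_basins = nb
  ), class = "barrier_tree")
  structure(list(model = model, tree = tree), class = "barriers_flood")
}

#' @export
print.barriers_flood <- function(x, ...) {
  print(x$model)
  cat("barrier tree: ", nrow(x$tree$merge_events), " merge events\n", sep = "")
  invisible(x)
}

.resolve_basin <- function(obj, b) {
  if (is.character(b)) {
    i <- match(b, obj$minima)
    if (is.na(i)) stop("unknown basin minimum: ", b)
    return(i)
  }
  b <- as.integer(b)
  if (b < 1 || b > length(obj$minima)) stop("basin index out of range")
  b
}

#' Saddle energy between two basins
#'
#' The minimal flood level at which the two basins become connected: the
#' lowest path maximum between their minima, read off the merge hierarchy
#' of the barrier tree.  Symmetric in its arguments;
#' `saddle_energy(tree, b, b)` is the energy of the basin minimum.
#'
#' @param tree a `barrier_tree` from [barriers_flood()].
#' @param b,c basins, as indices into the minima list or as minimum keys.
#' @return Numeric saddle energy.
#' @export
saddle_energy <- function(tree, b, c) {
  stopifnot(inherits(tree, "barrier_tree"))
  b <- .resolve_basin(tree, b)
  c <- .resolve_basin(tree, c)
  if (b == c) return(tree$energy[b])
  nb <- tree$n_basins
  parent <- seq_len(nb)
  ufind <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ev <- tree$merge_events
  for (r in seq_len(nrow(ev))) {
    ra <- ufind(ev$a[r]); rb <- ufind(ev$b[r])
    parent[rb] <- ra
    if (ufind(b) == ufind(c)) return(ev$energy[r])
  }
  stop("basins ", b, " and ", c, " are in different components: unreachable")
}

## Full saddle matrix by replaying the merge hierarchy (block assignment
## per union); NA off-diagonals mark disconnected pairs (forest).
.saddle_matrix <- function(tree) {
  nb <- tree$n_basins
  S <- matrix(NA_real_, nb, nb)
  diag(S) <- tree$energy
  comp_id <- seq_len(nb)
  members <- as.list(seq_len(nb))
  ev <- tree$merge_events
  if (nrow(ev) > 0) {
    for (r in seq_len(nrow(ev))) {
      ra <- comp_id[ev$a[r]]; rb <- comp_id[ev$b[r]]
      A <- members[[ra]]; Bm <- members[[rb]]
      S[A, Bm] <- ev$energy[r]
      S[Bm, A] <- ev$energy[r]
      members[[ra]] <- c(A, Bm)
      comp_id[Bm] <- ra
      members[[rb]] <- integer(0)
    }
  }
  S
}

#' @export
print.macro_model <- function(x, ...) {
  cat("macro-state model (", x$method, ", ", x$backend, " backend)\n",
      "  ", length(x$minima), " gradient basins over ",
      x$total_states, " micro-states; ",
      nrow(x$transitions), " basin adjacencies\n",
      "  beta = ", format(x$beta), ", delta = ", x$delta, "\n", sep = "")
  invisible(x)
}

#' @export
summary.macro_model <- function(object, ...) {
  df <- data.frame(
    index = seq_along(object$minima),
    minimum = object$minima,
    energy = object$energy,
    size = object$size,
    Z = object$Z,
    degree = tabulate(c(object$transitions$i, object$transitions$j),
                      length(object$minima))
  )
  df[order(df$index), ]
}

#' @export
print.barrier_tree <- function(x, ...) {
  cat("barrier tree over ", x$n_basins, " minima, ",
      nrow(x$merge_events), " merge events\n", sep = "")
  if (nrow(x$merge_events) > 0) {
    print(utils::head(x$merge_events, 10))
  }
  invisible(x)
}
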