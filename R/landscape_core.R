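#' RNA energy landscape
#'
#' Bundle a sequence, an energy backend and the single base-pair move set
#' into a discrete landscape: the state space is every nested structure of
#' the sequence, the move set connects structures differing by exactly one
#' pair, and transitions follow Metropolis probabilities at inverse
#' temperature `beta`, normalized by the maximal neighborhood size `delta`.
#'
#' @param seq an [rna_sequence()] or string.
#' @param backend an `energy_backend`; default the built-in pair model.
#' @param beta inverse temperature in 1/energy-unit.  Defaults to the
#'   backend's natural choice: 1 for the built-in model (arbitrary units),
#'   `1/kT` at the backend temperature for the nearest-neighbor backend.
#' @param min_loop minimum hairpin loop length (default 3).
#' @return An object of class `c("rna_landscape", "landscape")`.
#' @examples
#' L <- rna_landscape("GGGAAACCC")
#' gradient_walk(L, ".........")
#' @export
rna_landscape <- function(seq, backend = simple_energy_backend(), beta = NULL,
                          min_loop = 3L) {
  seq <- rna_sequence(seq)
  stopifnot(inherits(backend, "energy_backend"))
  if (is.null(beta)) beta <- backend$default_beta
  stopifnot(is.numeric(beta), beta >= 0)
  structure(list(
    kind = "rna",
    seq = seq,
    backend = backend,
    beta = beta,
    min_loop = as.integer(min_loop),
    delta = delta_max_neighbors(seq, min_loop),
    cache = new.env(parent = emptyenv())
  ), class = c("rna_landscape", "landscape"))
}

#' Explicit toy landscape
#'
#' A landscape given directly as a labelled graph with per-state energies.
#' Toy landscapes make every downstream quantity hand-checkable and serve
#' as oracle substrates for the flooding algorithms.  The normalization
#' constant `delta` is the maximal vertex degree, exactly the maximal
#' neighborhood size of the graph.
#'
#' @param states data.frame with columns `id` (unique strings) and
#'   `energy` (numeric).
#' @param edges two-column data.frame or matrix of state ids (undirected,
#'   no self-edges).
#' @param beta inverse temperature (default 1).
#' @return An object of class `c("toy_landscape", "landscape")`.
#' @examples
#' L1 <- chain_landscape(c(0, 2, 1))   # two basins
#' @export
toy_landscape <- function(states, edges = NULL, beta = 1) {
  stopifnot(is.data.frame(states), all(c("id", "energy") %in% names(states)))
  ids <- as.character(states$id)
  if (anyDuplicated(ids)) stop("duplicate state ids")
  energy <- as.numeric(states$energy)
  names(energy) <- ids
  adj <- setNames(vector("list", length(ids)), ids)
  for (id in ids) adj[[id]] <- character(0)
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    if (ncol(edges) != 2) stop("edges must have two columns")
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      if (!a %in% ids || !b %in% ids) stop("edge references unknown id: ", a, "-", b)
      if (a == b) stop("self-edge at ", a)
      if (!b %in% adj[[a]]) {
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
      }
    }
    adj <- lapply(adj, sort)
  }
  structure(list(
    kind = "toy",
    ids = ids,
    energy = energy,
    adj = adj,
    beta = beta,
    delta = max(1L, max(lengths(adj))),
    cache = new.env(parent = emptyenv())
  ), class = c("toy_landscape", "landscape"))
}

#' @export
print.landscape <- function(x, ...) {
  if (x$kind == "rna") {
    cat("RNA landscape: ", x$seq$bases, "\n",
        "  backend ", x$backend$name, " (", x$backend$unit, "), beta = ",
        format(x$beta), ", delta = ", x$delta,
        ", min_loop = ", x$min_loop, "\n", sep = "")
  } else {
    cat("toy landscape: ", length(x$ids), " states, ",
        sum(lengths(x$adj)) / 2, " edges, beta = ", format(x$beta),
        ", delta = ", x$delta, "\n", sep = "")
  }
  invisible(x)
}

## ---- internal state interface -------------------------------------------

.open_chain <- function(L) strrep(".", L$seq$n)

.ls_energy <- function(L, keys) {
  if (L$kind == "toy") {
    e <- L$energy[keys]
    if (anyNA(e)) stop("unknown toy state id")
    return(unname(e))
  }
  cache <- L$cache
  if (is.null(cache$E)) cache$E <- new.env(parent = emptyenv())
  miss <- keys[!vapply(keys, exists, logical(1), envir = cache$E, inherits = FALSE)]
  if (length(miss) > 0) {
    vals <- L$backend$eval(L$seq, miss)
    for (k in seq_along(miss)) assign(miss[k], vals[k], envir = cache$E)
  }
  unname(vapply(keys, get, numeric(1), envir = cache$E, inherits = FALSE))
}

.ls_neighbors <- function(L, key) {
  if (L$kind == "toy") {
    nb <- L$adj[[key]]
    if (is.null(nb)) stop("unknown toy state id: ", key)
    return(nb)
  }
  cpp_neighbors(key, L$seq$codes, L$min_loop)
}

## strict total order: (energy, byte-wise encoding)
.state_lt <- function(ea, ka, eb, kb) {
  if (ea != eb) return(ea < eb)
  cpp_str_lt(ka, kb)[1]
}

#' Boltzmann weight
#'
#' `w(x) = exp(-beta * E)`; the unnormalized equilibrium weight of a
#' state.
#'
#' @param energy state energy (vectorized).
#' @param beta inverse temperature, `>= 0`.
#' @return Numeric vector of positive weights.
#' @export
boltzmann_weight <- function(energy, beta) {
  stopifnot(beta >= 0)
  exp(-beta * energy)
}

#' Metropolis transition probability between neighboring states
#'
#' `p(x -> y) = delta^-1 * min{ exp(-beta [E(y) - E(x)]), 1 }`, defined
#' only for `y` in the move set of `x`.
#'
#' @param L a landscape.
#' @param x,y state keys (dot-bracket strings or toy ids).
#' @return Probability in `(0, 1/delta]`.
#' @export
metropolis_probability <- function(L, x, y) {
  stopifnot(inherits(L, "landscape"))
  if (!y %in% .ls_neighbors(L, x)) {
    stop("transition probability only defined for neighboring states")
  }
  e <- .ls_energy(L, c(x, y))
  min(exp(-L$beta * (e[2] - e[1])), 1) / L$delta
}

#' Steepest-descent neighbor
#'
#' The neighbor of `x` minimal under the landscape total order (energy,
#' then string encoding), provided it precedes `x`; `NULL` when `x` is a
#' local minimum.  The encoding tie-break makes the descent single-valued
#' on energy plateaus.
#'
#' @inheritParams metropolis_probability
#' @param x a state key.
#' @return A state key or `NULL`.
#' @export
steepest_descent_neighbor <- function(L, x) {
  nb <- .ls_neighbors(L, x)
  if (length(nb) == 0) return(NULL)
  en <- .ls_energy(L, nb)
  o <- order(en, nb, method = "radix")
  best <- nb[o[1]]
  if (.state_lt(en[o[1]], best, .ls_energy(L, x), x)) best else NULL
}

#' Gradient walk
#'
#' Iterate [steepest_descent_neighbor()] from `x` until a local minimum is
#' reached.  This is the gradient-basin assignment map: every micro-state
#' belongs to the basin of the minimum its walk ends in.  The walk
#' terminates because each step strictly decreases the total-order key.
#'
#' @inheritParams steepest_descent_neighbor
#' @return List with `minimum` (state key) and `path_length` (integer
#'   number of steps; 0 when `x` is itself a local minimum).
#' @export
gradient_walk <- function(L, x) {
  steps <- 0L
  repeat {
    nxt <- steepest_descent_neighbor(L, x)
    if (is.null(nxt)) return(list(minimum = x, path_length = steps))
    x <- nxt
    steps <- steps + 1L
  }
}

#' Is a state a local minimum?
#'
#' @inheritParams steepest_descent_neighbor
#' @return Logical.
#' @export
is_local_minimum <- function(L, x) {
  is.null(steepest_descent_neighbor(L, x))
}

#' Enumerate the state space
#'
#' For RNA landscapes, every nested structure of the sequence (the full
#' state space is connected to the open chain under the add/remove move
#' set); for toy landscapes, the explicit state list.  With
#' `energy_bound`, RNA landscapes keep exactly the states with
#' `E <= energy_bound` connected to the open chain through bounded states,
#' while toy landscapes keep all bounded states.
#'
#' @inheritParams metropolis_probability
#' @param energy_bound optional upper energy bound (flood level).
#' @param cap maximal number of states before an overflow error; defaults
#'   to `getOption("basinflood.cap", 1e6)`.
#' @return Character vector of state keys, sorted by the landscape total
#'   order.
#' @export
enumerate_states <- function(L, energy_bound = NULL,
                             cap = getOption("basinflood.cap", 1e6)) {
  stopifnot(inherits(L, "landscape"))
  if (L$kind == "toy") {
    keys <- L$ids
    en <- unname(L$energy[keys])
    if (!is.null(energy_bound)) {
      keep <- en <= energy_bound
      keys <- keys[keep]; en <- en[keep]
    }
    return(keys[order(en, keys, method = "radix")])
  }
  count <- cpp_count_structures(L$seq$codes, L$min_loop)
  if (count > cap) {
    stop("state-space overflow: ", format(count, big.mark = ","),
         " structures exceed the cap of ", format(cap, big.mark = ","))
  }
  keys <- cpp_enumerate_structures(L$seq$codes, L$min_loop)
  en <- L$backend$eval(L$seq, keys)
  if (!is.null(energy_bound)) {
    keep <- en <= energy_bound
    keys <- keys[keep]; en <- en[keep]
    if (length(keys) == 0) return(character(0))
    open <- .open_chain(L)
    start <- match(open, keys)
    if (is.na(start)) return(character(0))
    adj <- cpp_adjacency(keys, L$seq$codes, L$min_loop)
    seen <- logical(length(keys))
    seen[start] <- TRUE
    frontier <- start
    while (length(frontier) > 0) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    keys <- keys[seen]; en <- en[seen]
  }
  keys[order(en, keys, method = "radix")]
}

## ---- indexed landscape (internal) ---------------------------------------

## A fully materialized view: states sorted by the total order (so index
## equals rank), energies, Boltzmann weights and integer adjacency lists.
.index_landscape <- function(L, energy_bound = NULL,
                             cap = getOption("basinflood.cap", 1e6)) {
  tag <- if (is.null(energy_bound)) "idx:full" else sprintf("idx:%.15g", energy_bound)
  cached <- L$cache[[tag]]
  if (!is.null(cached)) return(cached)
  keys <- enumerate_states(L, energy_bound, cap)
  if (length(keys) == 0) stop("empty state set under the given energy bound")
  en <- .ls_energy(L, keys)
  if (L$kind == "toy") {
    pos <- setNames(seq_along(keys), keys)
    adj <- lapply(keys, function(k) sort(unname(pos[L$adj[[k]][L$adj[[k]] %in% keys]])))
  } else {
    adj <- cpp_adjacency(keys, L$seq$codes, L$min_loop)
  }
  idx <- list(keys = keys, energy = en, w = boltzmann_weight(en, L$beta),
              adj = adj, delta = L$delta, beta = L$beta, n = length(keys))
  L$cache[[tag]] <- idx
  idx
}

## steepest-descent neighbor index for every state of an indexed landscape;
## NA marks local minima.  States are rank-sorted, so the steepest-descent
## neighbor is simply the neighbor with the smallest index, when smaller
## than the state's own index.
.sdn_all <- function(idx) {
  vapply(seq_len(idx$n), function(i) {
    a <- idx$adj[[i]]
    if (length(a) == 0 || a[1] > i) NA_integer_ else a[1]
  }, integer(1))
}

## basin assignment by explicit walks along the steepest-descent pointers
## (path compression keeps repeated walks cheap)
.assign_basins <- function(sdn) {
  n <- length(sdn)
  F <- integer(n)
  for (i in seq_len(n)) {
    if (F[i] != 0L) next
    path <- i
    j <- i
    while (!is.na(sdn[j]) && F[j] == 0L) {
      j <- sdn[j]
      path <- c(path, j)
    }
    root <- if (F[j] != 0L) F[j] else j
    F[path] <- root
  }
  F
}

## ---- toy landscape TSV --------------------------------------------------

#' Read / write explicit toy landscapes as TSV
#'
#' Format: comment lines start with `#`; state lines are
#' `S<TAB>id<TAB>energy`; edge lines are `E<TAB>id1<TAB>id2`.  The writer
#' emits states sorted by (energy, id).
#'
#' @param path file path.
#' @param L a toy landscape.
#' @param beta inverse temperature attached to the landscape read back.
#' @return `read_toy_tsv` returns a [toy_landscape()]; `write_toy_tsv`
#'   returns `path` invisibly.
#' @export
read_toy_tsv <- function(path, beta = 1) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tags <- vapply(parts, `[`, character(1), 1)
  if (!all(tags %in% c("S", "E"))) stop("unknown record tag in toy TSV")
  st <- parts[tags == "S"]
  ed <- parts[tags == "E"]
  states <- data.frame(
    id = vapply(st, `[`, character(1), 2),
    energy = as.numeric(vapply(st, `[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  edges <- if (length(ed) > 0) {
    cbind(vapply(ed, `[`, character(1), 2), vapply(ed, `[`, character(1), 3))
  } else NULL
  toy_landscape(states, edges, beta = beta)
}

#' @rdname read_toy_tsv
#' @export
write_toy_tsv <- function(L, path) {
  stopifnot(inherits(L, "toy_landscape"))
  o <- order(unname(L$energy), L$ids, method = "radix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# toy landscape: S<TAB>id<TAB>energy, E<TAB>id1<TAB>id2", con)
  writeLines(sprintf("S\t%s\t%.12g", L$ids[o], unname(L$energy)[o]), con)
  seen <- character(0)
  for (id in L$ids[o]) {
    for (nb in L$adj[[id]]) {
      key <- paste(sort(c(id, nb)), collapse = "\r")
      if (!key %in% seen) {
        seen <- c(seen, key)
        writeLines(sprintf("E\t%s\t%s", sort(c(id, nb))[1], sort(c(id, nb))[2]), con)
      }
    }
  }
  invisible(path)
}
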