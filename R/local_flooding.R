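## Per-basin local flooding: computes Z_b and all transition-state
## partition functions Z{b,.} of one gradient basin without any global
## enumeration or hashing of the full state space.  Memory is bounded by
## the basin members (set D) plus the candidate/contact states (set T).

## min-heap over (energy, key) under the landscape total order
.heap_new <- function() {
  h <- new.env(parent = emptyenv())
  h$e <- numeric(64)
  h$k <- character(64)
  h$n <- 0L
  h
}

.heap_less <- function(h, i, j) {
  if (h$e[i] != h$e[j]) return(h$e[i] < h$e[j])
  cpp_str_lt(h$k[i], h$k[j])[1]
}

.heap_push <- function(h, e, k) {
  n <- h$n + 1L
  if (n > length(h$e)) {
    h$e <- c(h$e, numeric(length(h$e)))
    h$k <- c(h$k, character(length(h$k)))
  }
  h$e[n] <- e
  h$k[n] <- k
  h$n <- n
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    if (.heap_less(h, i, p)) {
      tmp_e <- h$e[i]; tmp_k <- h$k[i]
      h$e[i] <- h$e[p]; h$k[i] <- h$k[p]
      h$e[p] <- tmp_e; h$k[p] <- tmp_k
      i <- p
    } else break
  }
  invisible(h)
}

.heap_pop <- function(h) {
  stopifnot(h$n > 0L)
  top <- list(e = h$e[1], k = h$k[1])
  h$e[1] <- h$e[h$n]
  h$k[1] <- h$k[h$n]
  h$n <- h$n - 1L
  i <- 1L
  repeat {
    l <- 2L * i
    r <- l + 1L
    m <- i
    if (l <= h$n && .heap_less(h, l, m)) m <- l
    if (r <= h$n && .heap_less(h, r, m)) m <- r
    if (m == i) break
    tmp_e <- h$e[i]; tmp_k <- h$k[i]
    h$e[i] <- h$e[m]; h$k[i] <- h$k[m]
    h$e[m] <- tmp_e; h$k[m] <- tmp_k
    i <- m
  }
  top
}

## gradient walk to the basin minimum, memoized in `cache` (bounded:
## beyond `cache_max` entries results are still correct, just not stored)
.walk_min <- function(L, key, cache, cache_max = 1e6) {
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  path <- character(0)
  k <- key
  repeat {
    hit <- cache[[k]]
    if (!is.null(hit)) {
      m <- hit
      break
    }
    nxt <- steepest_descent_neighbor(L, k)
    if (is.null(nxt)) {
      m <- k
      break
    }
    path <- c(path, k)
    k <- nxt
  }
  if (length(path) > 0 && length(ls(cache, all.names = TRUE)) < cache_max) {
    for (p in path) cache[[p]] <- m
  }
  m
}

#' Local flooding of one gradient basin
#'
#' Enumerates the basin of local minimum `m` in ascending total order.
#' Starting from `Z_b = w(m)`, `D = {m}` and `T = M(m)`, the minimal
#' candidate `x` is repeatedly popped from `T`.  If the steepest-descent
#' neighbor of `x` is in `D`, then `x` is a basin member: its weight is
#' added to `Z_b`, its higher neighbors join `T`, and every edge to a
#' lower state outside `D` contributes `delta^-1 w(x)` to the transition
#' partition function toward that state's basin.  Otherwise `x` is a
#' contact state of a foreign basin and each of its edges down into `D`
#' contributes `delta^-1 w(x)` to the transition partition function
#' between its own basin and `b`.  Basin assignments of foreign states
#' are computed by explicit gradient walks (optionally memoized; the
#' cache affects speed only, never results).
#'
#' The result reproduces the global oracle's `Z_b` and `Z{b,.}` exactly,
#' while only ever holding `|F^-1(b)| + |T(b)|` states in memory.
#'
#' @inheritParams metropolis_probability
#' @param m a local minimum (checked; error otherwise).
#' @param cap maximal number of processed states before an overflow error.
#' @param walk_cache_max bound on the memoization cache for foreign
#'   gradient walks.
#' @return An object of class `flood_result`: `minimum`, `Z`,
#'   `members_count` (= basin size), `contacts_count` (distinct foreign
#'   states held during the flood: candidates that entered `T` plus lower
#'   endpoints of transitions leaving the basin), `mem_local` (their sum,
#'   the local memory footprint), `e_min`, `e_max`, and `boundary`, a
#'   named vector of `Z{b,c}` contributions keyed by adjacent minima.
#' @examples
#' L1 <- chain_landscape(c(0, 2, 1))
#' local_flood(L1, "s0")
#' @export
local_flood <- function(L, m, cap = getOption("basinflood.cap", 1e6),
                        walk_cache_max = 1e6) {
  stopifnot(inherits(L, "landscape"))
  if (!is_local_minimum(L, m)) {
    stop("local_flood must start from a local minimum; '", m, "' is not one")
  }
  beta <- L$beta
  delta <- L$delta
  e_m <- .ls_energy(L, m)
  D <- new.env(parent = emptyenv())
  seen <- new.env(parent = emptyenv())      # everything ever pushed to T
  walks <- new.env(parent = emptyenv())
  boundary <- new.env(parent = emptyenv())
  contact <- new.env(parent = emptyenv())  # distinct foreign states held
  assign(m, TRUE, envir = D)
  walks[[m]] <- m
  Z <- boltzmann_weight(e_m, beta)
  members <- 1L
  e_max <- e_m
  h <- .heap_new()
  for (nb in .ls_neighbors(L, m)) {
    .heap_push(h, .ls_energy(L, nb), nb)
    assign(nb, TRUE, envir = seen)
  }
  add_boundary <- function(min_key, val) {
    cur <- boundary[[min_key]]
    boundary[[min_key]] <- if (is.null(cur)) val else cur + val
  }
  while (h$n > 0L) {
    top <- .heap_pop(h)
    x <- top$k
    ex <- top$e
    if (members + length(ls(contact, all.names = TRUE)) >= cap) {
      stop("local flooding overflow: more than ", cap, " states processed")
    }
    nbx <- .ls_neighbors(L, x)
    enx <- .ls_energy(L, nbx)
    o <- order(enx, nbx, method = "radix")
    nbx <- nbx[o]
    enx <- enx[o]
    ## neighbors strictly below x in the total order
    is_lower <- enx < ex | (enx == ex & cpp_str_lt(nbx, x))
    sdn <- nbx[1]                           # minimal neighbor; x came from T,
    wx <- boltzmann_weight(ex, beta)        # so it always has a lower neighbor
    if (!is.null(D[[sdn]])) {
      ## member of b
      assign(x, TRUE, envir = D)
      members <- members + 1L
      Z <- Z + wx
      if (ex > e_max) e_max <- ex
      for (idx in which(!is_lower)) {
        k <- nbx[idx]
        if (is.null(seen[[k]])) {
          assign(k, TRUE, envir = seen)
          .heap_push(h, enx[idx], k)
        }
      }
      for (idx in which(is_lower)) {
        k <- nbx[idx]
        if (is.null(D[[k]])) {
          assign(k, TRUE, envir = contact)
          add_boundary(.walk_min(L, k, walks, walk_cache_max), wx / delta)
        }
      }
    } else {
      ## contact state of a foreign basin
      assign(x, TRUE, envir = contact)
      n_down <- sum(vapply(nbx[is_lower], function(k) !is.null(D[[k]]), logical(1)))
      if (n_down > 0) {
        add_boundary(.walk_min(L, x, walks, walk_cache_max), n_down * wx / delta)
      }
    }
  }
  contacts <- length(ls(contact, all.names = TRUE))
  bkeys <- ls(boundary, all.names = TRUE)
  bvals <- vapply(bkeys, function(k) boundary[[k]], numeric(1))
  if (length(bkeys) > 0) {
    be <- .ls_energy(L, bkeys)
    o <- order(be, bkeys, method = "radix")
    bkeys <- bkeys[o]; bvals <- unname(bvals[o])
  }
  structure(list(
    minimum = m,
    Z = Z,
    members_count = members,
    contacts_count = contacts,
    mem_local = members + contacts,
    e_min = e_m,
    e_max = e_max,
    boundary = setNames(bvals, bkeys)
  ), class = "flood_result")
}

#' @export
print.flood_result <- function(x, ...) {
  cat("local flood of basin ", x$minimum, "\n",
      "  Z = ", format(x$Z), ", members = ", x$members_count,
      ", contacts = ", x$contacts_count,
      ", adjacent basins = ", length(x$boundary), "\n", sep = "")
  invisible(x)
}

#' Per-basin memory footprint relative to global flooding
#'
#' Global flooding must hash the entire state space (`mem(G) = |X|`);
#' local flooding of basin `b` holds only its members and contact states
#' (`mem(L) = |F^-1(b)| + |T(b)|`).  This returns `mem(L) / mem(G)`.
#'
#' @param r a `flood_result`.
#' @param total_states `|X|` of the landscape.
#' @return Ratio in `(0, 1]`.
#' @export
memory_ratio <- function(r, total_states) {
  stopifnot(inherits(r, "flood_result"))
  if (total_states == 0) stop("total_states must be positive")
  if (total_states < r$members_count) stop("total_states below basin size")
  (r$members_count + r$contacts_count) / total_states
}

#' Whole-landscape discovery by repeated local flooding
#'
#' Worklist exploration: flood the basin of `seed_min` (any state; it is
#' gradient-walked first), enqueue every newly seen adjacent minimum, and
#' repeat until no unexplored basin remains.  Each transition-state
#' partition function is obtained twice, once from either side; the two
#' values must agree within `1e-6` relative (a built-in consistency
#' check) and the value computed from the basin earlier in the total
#' order is stored.  The assembled model is independent of the
#' exploration order and of `workers`.
#'
#' @inheritParams local_flood
#' @param seed_min a state whose basin seeds the exploration.
#' @param workers number of parallel flooding processes (fork-based via
#'   \pkg{parallel}; 1 = sequential).  Affects wall time only.
#' @return A `macro_model` (method `"local_flooding"`); the individual
#'   [local_flood()] results are attached as the `floods` element, keyed
#'   by minimum, for memory accounting.
#' @export
discover_landscape <- function(L, seed_min, workers = 1L,
                               cap = getOption("basinflood.cap", 1e6),
                               walk_cache_max = 1e6) {
  stopifnot(inherits(L, "landscape"))
  m0 <- gradient_walk(L, seed_min)$minimum
  results <- list()
  queue <- m0
  while (length(queue) > 0) {
    new_res <- if (workers > 1L) {
      parallel::mclapply(queue, function(m) {
        local_flood(L, m, cap, walk_cache_max)
      }, mc.cores = workers)
    } else {
      lapply(queue, function(m) local_flood(L, m, cap, walk_cache_max))
    }
    for (r in new_res) {
      if (inherits(r, "try-error")) stop(r)
      results[[r$minimum]] <- r
    }
    found <- unique(unlist(lapply(new_res, function(r) names(r$boundary)),
                           use.names = FALSE))
    queue <- setdiff(found, names(results))
  }
  minima <- names(results)
  e_min <- vapply(results, function(r) r$e_min, numeric(1))
  o <- order(unname(e_min), minima, method = "radix")
  minima <- minima[o]
  nb <- length(minima)
  pos <- setNames(seq_len(nb), minima)
  ti <- integer(0); tj <- integer(0); tz <- numeric(0)
  for (b in seq_len(nb)) {
    r <- results[[minima[b]]]
    for (ck in names(r$boundary)) {
      cpos <- pos[[ck]]
      if (is.na(cpos)) stop("boundary names an undiscovered basin: ", ck)
      if (cpos <= b) next                 # handled from the earlier side
      other <- results[[ck]]$boundary[[minima[b]]]
      if (is.null(other)) {
        stop("one-sided transition between basins ", minima[b], " and ", ck)
      }
      v1 <- r$boundary[[ck]]
      if (abs(v1 - other) > 1e-6 * max(abs(v1), abs(other))) {
        stop("inconsistent transition partition function between basins ",
             minima[b], " and ", ck, ": ", v1, " vs ", other)
      }
      ti <- c(ti, b); tj <- c(tj, cpos); tz <- c(tz, v1)
    }
  }
  trans <- data.frame(i = ti, j = tj, Z = tz)
  trans <- trans[order(trans$i, trans$j), , drop = FALSE]
  rownames(trans) <- NULL
  ord_res <- results[minima]
  model <- structure(list(
    minima = minima,
    energy = unname(e_min[o]),
    size = vapply(ord_res, function(r) r$members_count, integer(1), USE.NAMES = FALSE),
    Z = vapply(ord_res, function(r) r$Z, numeric(1), USE.NAMES = FALSE),
    e_min = unname(e_min[o]),
    e_max = vapply(ord_res, function(r) r$e_max, numeric(1), USE.NAMES = FALSE),
    transitions = trans,
    delta = L$delta,
    beta = L$beta,
    total_states = sum(vapply(ord_res, function(r) r$members_count, integer(1))),
    method = "local_flooding",
    backend = .backend_name(L),
    floods = ord_res
  ), class = "macro_model")
  model
}
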