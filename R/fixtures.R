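## Deterministic synthetic inputs: toy chain/graph landscapes and random
## RNA sequence sets mirroring the evaluation data (uniform base
## composition, fixed counts per length).

## run `expr` under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Path-graph toy landscape
#'
#' States `s0, s1, ...` with the given energies, connected in a chain.
#' The two canonical worked examples used throughout the documentation
#' are `chain_landscape(c(0, 2, 1))` (two basins: \{s0, s1\} and \{s2\})
#' and `chain_landscape(c(0, 3, 1, 2, 0.5))` (three basins with saddles
#' at 2 and 3).
#'
#' @param energies numeric vector, one energy per state (>= 1 state).
#' @param beta inverse temperature.
#' @return A [toy_landscape()].
#' @export
chain_landscape <- function(energies, beta = 1) {
  if (length(energies) < 1) stop("at least one energy required")
  ids <- paste0("s", seq_along(energies) - 1)
  edges <- if (length(ids) > 1) cbind(ids[-length(ids)], ids[-1]) else NULL
  toy_landscape(data.frame(id = ids, energy = energies), edges, beta = beta)
}

#' Random connected toy landscape
#'
#' A random spanning tree plus extra uniform random edges up to the
#' target mean degree; energies uniform on `[e_low, e_high]`, with exact
#' ties broken by tiny (1e-9-scale) deterministic nudges so that the
#' default fixtures exercise the algorithms rather than the tie-break
#' logic.  Fully reproducible from `seed`.
#'
#' @param n number of states (>= 1).
#' @param mean_degree target average vertex degree (< n).
#' @param e_low,e_high energy bounds.
#' @param seed mandatory RNG seed.
#' @param beta inverse temperature.
#' @return A [toy_landscape()].
#' @export
random_toy_landscape <- function(n, mean_degree = 3, e_low = 0, e_high = 10,
                                 seed, beta = 1) {
  stopifnot(n >= 1, e_low <= e_high)
  if (mean_degree >= n) stop("infeasible mean degree: must be < n")
  m_target <- min(round(mean_degree * n / 2), n * (n - 1) / 2)
  .with_seed(seed, {
    ids <- paste0("s", seq_len(n) - 1)
    energy <- runif(n, e_low, e_high)
    while (anyDuplicated(energy)) {
      d <- which(duplicated(energy))
      energy[d] <- energy[d] + 1e-9 * d
    }
    edges <- NULL
    if (n > 1) {
      to <- vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))
      emat <- cbind(pmin(2:n, to), pmax(2:n, to))
      extra_needed <- m_target - nrow(emat)
      if (extra_needed > 0) {
        all_i <- rep(seq_len(n - 1), times = (n - 1):1)
        all_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
        have <- (emat[, 1] - 1) * n + emat[, 2]
        pool <- which(!((all_i - 1) * n + all_j) %in% have)
        take <- pool[sample.int(length(pool), min(extra_needed, length(pool)))]
        emat <- rbind(emat, cbind(all_i[take], all_j[take]))
      }
      edges <- cbind(ids[emat[, 1]], ids[emat[, 2]])
    }
    toy_landscape(data.frame(id = ids, energy = energy), edges, beta = beta)
  })
}

#' Random RNA sequence set
#'
#' `per_length` sequences for every length in `len_min:len_max`, bases
#' i.i.d. uniform over \{A,C,G,U\}; reproducible from `seed`.  The
#' defaults (10 per length, 25-35 nt) regenerate a 110-sequence
#' evaluation set with uniform base composition.
#'
#' @param per_length sequences per length (>= 1).
#' @param len_min,len_max inclusive length range.
#' @param seed mandatory RNG seed.
#' @return Character vector of RNA sequences.
#' @export
random_rna_set <- function(per_length = 10, len_min = 25, len_max = 35, seed) {
  stopifnot(per_length >= 1, len_min <= len_max)
  .with_seed(seed, {
    unlist(lapply(len_min:len_max, function(L) {
      vapply(seq_len(per_length), function(i) {
        paste(sample(BASES, L, replace = TRUE), collapse = "")
      }, character(1))
    }))
  })
}

#' Write sequences as FASTA
#'
#' @param seqs character vector of sequences (names used as record ids;
#'   unnamed records get `seq1, seq2, ...`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  writeLines(as.vector(rbind(paste0(">", ids), unname(seqs))), path)
  invisible(path)
}
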