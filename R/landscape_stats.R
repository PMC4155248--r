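## Gradient-basin property analyses: sizes, energy ranges, connectivity,
## memory footprints and their correlations.

#' Per-basin property report
#'
#' Collects, for every gradient basin of a full decomposition: the
#' minimum and its energy, the basin's energy range (absolute and
#' relative to the landscape's energy span,
#' `E_rel(x) = (E(x) - E_min) / (E_max - E_min)`), size, partition
#' function, number of adjacent basins, and, when the model came from
#' local flooding, the memory ratio.  Identifies the basin of the open
#' (unstructured) chain and its share of the state space.
#'
#' @param M a `macro_model` from a full decomposition.
#' @param L the landscape the model was computed from (needed to locate
#'   the open-chain basin of RNA landscapes; optional for toys).
#' @return Object of class `basin_report`: a per-basin data.frame
#'   (`basins`) plus the global fields `E_min`, `E_max`, `n_states`,
#'   `n_basins`, `open_basin` (index or `NA`), `open_share`, and
#'   `e_rel_defined` (`FALSE` for single-energy landscapes, where
#'   relative energies are undefined).
#' @export
basin_report <- function(M, L = NULL) {
  stopifnot(inherits(M, "macro_model"))
  nb <- length(M$minima)
  degree <- tabulate(c(M$transitions$i, M$transitions$j), nb)
  E_min <- min(M$e_min)
  E_max <- max(M$e_max)
  span <- E_max - E_min
  e_rel_defined <- span > 0
  mem_ratio <- rep(NA_real_, nb)
  if (!is.null(M$floods)) {
    mem_ratio <- vapply(M$floods, function(r) memory_ratio(r, M$total_states),
                        numeric(1), USE.NAMES = FALSE)
  }
  open_basin <- NA_integer_
  open_share <- NA_real_
  if (!is.null(L) && L$kind == "rna") {
    open_min <- gradient_walk(L, .open_chain(L))$minimum
    open_basin <- match(open_min, M$minima)
    if (!is.na(open_basin)) open_share <- M$size[open_basin] / M$total_states
  }
  basins <- data.frame(
    index = seq_len(nb),
    minimum = M$minima,
    e_min = M$e_min,
    e_max = M$e_max,
    e_rel_min = if (e_rel_defined) (M$e_min - E_min) / span else NA_real_,
    e_rel_max = if (e_rel_defined) (M$e_max - E_min) / span else NA_real_,
    size = M$size,
    Z = M$Z,
    degree = degree,
    mem_ratio = mem_ratio
  )
  structure(list(
    basins = basins,
    E_min = E_min,
    E_max = E_max,
    n_states = M$total_states,
    n_basins = nb,
    open_basin = open_basin,
    open_share = open_share,
    e_rel_defined = e_rel_defined
  ), class = "basin_report")
}

#' @export
print.basin_report <- function(x, ...) {
  cat("basin report: ", x$n_basins, " basins over ", x$n_states,
      " states; energy span [", format(x$E_min), ", ", format(x$E_max), "]\n",
      sep = "")
  if (!is.na(x$open_basin)) {
    cat("  open-chain basin #", x$open_basin, " covers ",
        sprintf("%.1f%%", 100 * x$open_share), " of the state space\n", sep = "")
  }
  print(utils::head(x$basins, 10))
  invisible(x)
}

.safe_spearman <- function(u, v) {
  tryCatch(as.numeric(spearman_rho(u, v)), error = function(e) NA_real_)
}

#' Summary statistics of a basin decomposition
#'
#' The headline numbers of a gradient-basin analysis: the fraction of
#' realized basin adjacencies among all `choose(|B|, 2)` pairs, Spearman
#' correlations of basin size, minimum energy and connectivity, the
#' fraction of basins with stable (negative-energy) minima, low
#' connectivity fractions, the open-chain basin's connectivity share, and
#' memory-ratio summaries when local flooding ran.  Correlations on
#' degenerate inputs are reported as `NA`.
#'
#' @param r a `basin_report`.
#' @param M the `macro_model` the report came from.
#' @return Named list of statistics.
#' @export
summary_statistics <- function(r, M) {
  stopifnot(inherits(r, "basin_report"), inherits(M, "macro_model"))
  b <- r$basins
  nb <- r$n_basins
  realized <- if (nb >= 2) nrow(M$transitions) / choose(nb, 2) else 0
  out <- list(
    n_basins = nb,
    n_states = r$n_states,
    realized_transition_fraction = realized,
    spearman_size_vs_emin = if (nb >= 2) .safe_spearman(b$size, b$e_min) else NA_real_,
    spearman_degree_vs_size = if (nb >= 2) .safe_spearman(b$degree, b$size) else NA_real_,
    spearman_degree_vs_emin = if (nb >= 2) .safe_spearman(b$degree, b$e_min) else NA_real_,
    frac_negative_minima = mean(b$e_min < 0),
    frac_degree_below_10 = mean(b$degree < 10),
    frac_degree_below_2pct = mean(b$degree < 0.02 * nb),
    open_basin_degree_share = if (!is.na(r$open_basin) && nb >= 2) {
      b$degree[r$open_basin] / (nb - 1)
    } else NA_real_,
    open_basin_size_share = r$open_share,
    mean_mem_ratio = if (all(is.na(b$mem_ratio))) NA_real_ else mean(b$mem_ratio),
    median_mem_ratio = if (all(is.na(b$mem_ratio))) NA_real_ else
      stats::median(b$mem_ratio)
  )
  out
}
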