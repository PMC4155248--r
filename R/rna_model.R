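#' @useDynLib basinflood, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor setNames rnorm runif
#' @importFrom utils head write.csv read.csv
NULL

BASES <- c("A", "C", "G", "U")

## admissible pair types (both orientations) used throughout
.PAIR_OK <- matrix(FALSE, 4, 4, dimnames = list(BASES, BASES))
.PAIR_OK["A", "U"] <- .PAIR_OK["U", "A"] <- TRUE
.PAIR_OK["G", "C"] <- .PAIR_OK["C", "G"] <- TRUE
.PAIR_OK["G", "U"] <- .PAIR_OK["U", "G"] <- TRUE

.encode_bases <- function(bases) {
  match(bases, BASES) - 1L
}

#' RNA sequence
#'
#' Construct a validated RNA sequence.  Input is case-normalized and DNA
#' thymine is silently converted to uracil, so FASTA records in either
#' alphabet are accepted; any other character is an error.
#'
#' @param x a single string over \{A,C,G,U\} (or T, lowercase tolerated), or
#'   an object already of class `rna_sequence`.
#' @return An object of class `rna_sequence`: the normalized base string,
#'   its length `n`, and an integer encoding used by the compiled routines.
#' @examples
#' rna_sequence("gggaaaccc")
#' rna_sequence("GGGAAUUAUUGUUCCCUGAGAGCGGUAGUUCUC")  # bistable d33
#' @export
rna_sequence <- function(x) {
  if (inherits(x, "rna_sequence")) return(x)
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  bases <- chartr("T", "U", toupper(x))
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), BASES)
  if (length(bad) > 0) {
    stop("invalid characters in RNA sequence: ", paste(bad, collapse = ", "))
  }
  if (length(chars) == 0L) stop("empty sequence")
  structure(
    list(bases = bases, n = length(chars), codes = .encode_bases(chars)),
    class = "rna_sequence"
  )
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat("RNA sequence (", x$n, " nt)\n", x$bases, "\n", sep = "")
  invisible(x)
}

#' Parse a dot-bracket string
#'
#' Stack-matching of `(`/`)` yields the base-pair set; unbalanced input is
#' an error naming the offending position.
#'
#' @param text a string over `(`, `)`, `.`.
#' @return An object of class `secondary_structure` with elements
#'   `dot_bracket` (the input) and `pairs`, an integer matrix with columns
#'   `i`, `j` (1-based, `i < j`), one row per base pair.
#' @examples
#' parse_dotbracket("((...))")$pairs
#' @export
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad) > 0) stop("invalid dot-bracket characters: ", paste(bad, collapse = ", "))
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  out <- vector("list", sum(chars == ")"))
  k <- 0L
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") {
      open <- c(open, pos)
    } else if (chars[pos] == ")") {
      if (length(open) == 0L) {
        stop("unbalanced dot-bracket: unmatched ')' at position ", pos)
      }
      k <- k + 1L
      out[[k]] <- c(open[length(open)], pos)
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0L) {
    stop("unbalanced dot-bracket: unmatched '(' at position ", open[length(open)])
  }
  if (k > 0L) {
    pairs <- do.call(rbind, out)
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    dimnames(pairs) <- list(NULL, c("i", "j"))
  }
  structure(list(dot_bracket = text, pairs = pairs), class = "secondary_structure")
}

#' Encode a base-pair set as dot-bracket
#'
#' Inverse of [parse_dotbracket()] for nested pair sets.
#'
#' @param pairs integer matrix with columns `i`, `j` (1-based, `i < j`).
#' @param n sequence length.
#' @return A dot-bracket string of length `n`.
#' @export
format_dotbracket <- function(pairs, n) {
  chars <- rep(".", n)
  if (NROW(pairs) > 0) {
    chars[pairs[, 1]] <- "("
    chars[pairs[, 2]] <- ")"
  }
  paste(chars, collapse = "")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("secondary structure: ", x$dot_bracket, " (", NROW(x$pairs), " pairs)\n",
      sep = "")
  invisible(x)
}

.as_structure <- function(s) {
  if (inherits(s, "secondary_structure")) s else parse_dotbracket(s)
}

#' Validate a secondary structure against a sequence
#'
#' Checks the structure rules: pair admissibility (A-U, G-C, G-U only),
#' minimum hairpin-loop length, base-pair disjointness and nestedness.
#' Disjointness and nestedness are enforced by the dot-bracket encoding
#' itself; they are re-checked here for pair sets built by hand.
#'
#' @param seq an [rna_sequence()] (or string coerced to one).
#' @param s a `secondary_structure` or dot-bracket string of the same length.
#' @param min_loop minimum number of unpaired bases enclosed by a hairpin
#'   (default 3): a pair `(i, j)` requires `j - i >= min_loop + 1`.
#' @return A list with `ok` (logical) and `violations` (character vector).
#' @examples
#' validate_structure("GGGAAACCC", "(((...)))")$ok
#' @export
validate_structure <- function(seq, s, min_loop = 3L) {
  seq <- rna_sequence(seq)
  s <- .as_structure(s)
  if (nchar(s$dot_bracket) != seq$n) {
    stop("structure length ", nchar(s$dot_bracket),
         " does not match sequence length ", seq$n)
  }
  v <- character(0)
  p <- s$pairs
  chars <- strsplit(seq$bases, "", fixed = TRUE)[[1]]
  if (NROW(p) > 0) {
    for (r in seq_len(NROW(p))) {
      i <- p[r, 1]; j <- p[r, 2]
      if (!.PAIR_OK[chars[i], chars[j]]) {
        v <- c(v, sprintf("inadmissible pair (%d,%d): %s-%s", i, j, chars[i], chars[j]))
      }
      if (j - i < min_loop + 1L) {
        v <- c(v, sprintf("hairpin loop < %d at pair (%d,%d)", min_loop, i, j))
      }
    }
    idx <- c(p[, 1], p[, 2])
    if (anyDuplicated(idx)) v <- c(v, "base in more than one pair")
    if (NROW(p) > 1) {
      for (r in seq_len(NROW(p) - 1)) {
        for (q in (r + 1):NROW(p)) {
          i <- p[r, 1]; j <- p[r, 2]; k <- p[q, 1]; l <- p[q, 2]
          if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) {
            v <- c(v, sprintf("crossing pairs (%d,%d) and (%d,%d)", i, j, k, l))
          }
        }
      }
    }
  }
  list(ok = length(v) == 0L, violations = v)
}

#' Single base-pair move set
#'
#' All structures reachable from `s` by removing one base pair or adding
#' one admissible pair that keeps the structure nested and loop-valid.
#' The relation is symmetric: `y` is a neighbor of `x` iff `x` is one of
#' `y`.
#'
#' @inheritParams validate_structure
#' @return Character vector of neighbor dot-bracket strings (sorted,
#'   duplicate-free).
#' @examples
#' structure_neighbors("GGGAAACCC", ".........")
#' @export
structure_neighbors <- function(seq, s, min_loop = 3L) {
  seq <- rna_sequence(seq)
  s <- .as_structure(s)
  val <- validate_structure(seq, s, min_loop)
  if (!val$ok) stop("invalid structure: ", paste(val$violations, collapse = "; "))
  cpp_neighbors(s$dot_bracket, seq$codes, as.integer(min_loop))
}

#' Maximal neighborhood size of a landscape
#'
#' The Metropolis normalization constant: the number of admissible base
#' pairs `(i, j)` with `j - i >= min_loop + 1`.  The open chain attains
#' this neighborhood size, and no structure can exceed it, so it equals
#' the maximal move count over the whole structure space.
#'
#' @inheritParams validate_structure
#' @return Integer.
#' @examples
#' delta_max_neighbors("GGGAAACCC")  # 9
#' @export
delta_max_neighbors <- function(seq, min_loop = 3L) {
  seq <- rna_sequence(seq)
  chars <- strsplit(seq$bases, "", fixed = TRUE)[[1]]
  n <- seq$n
  count <- 0L
  if (n >= min_loop + 2L) {
    for (i in seq_len(n - min_loop - 1L)) {
      js <- (i + min_loop + 1L):n
      count <- count + sum(.PAIR_OK[chars[i], chars[js]])
    }
  }
  count
}

#' Total-order key of a state
#'
#' Degenerate (equal-energy) states are ordered by byte-wise comparison of
#' their string encoding, making every landscape operation deterministic.
#' The key compares by energy first, then by encoding, where
#' `'(' < ')' < '.'` (plain byte order).
#'
#' @param encoding dot-bracket string (or toy state id).
#' @param energy the state's energy.
#' @return A classed key object; keys support `<` style comparison via
#'   [state_precedes()].
#' @export
structure_order_key <- function(encoding, energy) {
  structure(list(energy = as.numeric(energy), encoding = as.character(encoding)),
            class = "state_order_key")
}

#' Compare two states in the landscape total order
#'
#' @param a,b keys from [structure_order_key()].
#' @return `TRUE` iff `a` strictly precedes `b`.
#' @export
state_precedes <- function(a, b) {
  stopifnot(inherits(a, "state_order_key"), inherits(b, "state_order_key"))
  if (a$energy != b$energy) return(a$energy < b$energy)
  cpp_str_lt(a$encoding, b$encoding)[1]
}

#' Built-in additive base-pair energy model
#'
#' A deterministic, dependency-free energy function in arbitrary units:
#' each G-C pair contributes -3, each A-U pair -2, each G-U pair -1; the
#' open chain has energy 0.  This is deliberately *not* the Turner
#' nearest-neighbor model; use [external_energy()] (ViennaRNA backend) for
#' physical free energies.
#'
#' @inheritParams validate_structure
#' @return Energy in model units (numeric scalar).
#' @examples
#' simple_pair_energy("GGGAAACCC", "(((...)))")  # -9
#' @export
simple_pair_energy <- function(seq, s, min_loop = 3L) {
  seq <- rna_sequence(seq)
  s <- .as_structure(s)
  val <- validate_structure(seq, s, min_loop)
  if (!val$ok) stop("invalid structure: ", paste(val$violations, collapse = "; "))
  cpp_simple_energy(s$dot_bracket, seq$codes, c(-3, -2, -1))[1]
}

#' Energy backends
#'
#' An energy backend couples a name, unit, and a vectorized evaluator
#' mapping (sequence, dot-bracket strings) to energies.
#' `simple_energy_backend()` is the built-in additive pair model (see
#' [simple_pair_energy()]); `vienna_energy_backend()` evaluates the full
#' nearest-neighbor model by calling the `RNAeval` program of the
#' ViennaRNA package, in kcal/mol at the given temperature, and records
#' the program version for provenance.
#'
#' @param gc,au,gu pair energies of the built-in model (arbitrary units).
#' @param temperature evaluation temperature in Celsius (ViennaRNA backend).
#' @return A list of class `energy_backend` with fields `name`, `unit`,
#'   `default_beta`, `version` and the evaluator `eval(seq, keys)`.
#' @export
simple_energy_backend <- function(gc = -3, au = -2, gu = -1) {
  pe <- c(gc, au, gu)
  structure(list(
    name = "simple",
    unit = "model units",
    version = "builtin pair table",
    default_beta = 1,
    eval = function(seq, keys) cpp_simple_energy(keys, seq$codes, pe)
  ), class = "energy_backend")
}

.vienna_binary <- function() {
  bin <- Sys.which("RNAeval")
  if (!nzchar(bin)) {
    stop("nearest-neighbor backend unavailable: RNAeval (ViennaRNA) not on PATH")
  }
  unname(bin)
}

#' @rdname simple_energy_backend
#' @export
vienna_energy_backend <- function(temperature = 37) {
  bin <- .vienna_binary()
  ver <- tryCatch(
    system2(bin, "--version", stdout = TRUE, stderr = TRUE)[1],
    error = function(e) "RNAeval (version unknown)"
  )
  # kT in kcal/mol at `temperature`; 1.98717e-3 kcal/(mol K)
  kt <- 0.0019872 * (273.15 + temperature)
  evalfun <- function(seq, keys) {
    lines <- as.vector(rbind(rep(seq$bases, length(keys)), keys))
    out <- system2(bin, c("--noconv", "-T", format(temperature)),
                   stdout = TRUE, input = lines)
    res <- regmatches(out, regexpr("\\(\\s*-?[0-9]+\\.[0-9]+\\)$", out))
    if (length(res) != length(keys)) {
      stop("RNAeval returned ", length(res), " energies for ", length(keys),
           " structures")
    }
    as.numeric(gsub("[() ]", "", res))
  }
  structure(list(
    name = "vienna",
    unit = "kcal/mol",
    version = ver,
    temperature = temperature,
    default_beta = 1 / kt,
    eval = evalfun
  ), class = "energy_backend")
}

#' Nearest-neighbor free energy of a structure
#'
#' Full Turner-model free energy through the ViennaRNA `RNAeval` program
#' (kcal/mol, 37 C by default).  Errors if the program is not available;
#' there is no silent fallback to the built-in model.
#'
#' @inheritParams validate_structure
#' @param temperature temperature in Celsius.
#' @return Free energy in kcal/mol, with attribute `backend_version`.
#' @export
external_energy <- function(seq, s, temperature = 37, min_loop = 3L) {
  seq <- rna_sequence(seq)
  s <- .as_structure(s)
  val <- validate_structure(seq, s, min_loop)
  if (!val$ok) stop("invalid structure: ", paste(val$violations, collapse = "; "))
  be <- vienna_energy_backend(temperature)
  e <- be$eval(seq, s$dot_bracket)
  attr(e, "backend_version") <- be$version
  e
}
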