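#' Default composition bounds for P1 chains
#'
#' Each P1 chain carries 5-6 hydrophobic M1 monomers, exactly 4 hydrophilic
#' M2 monomers and 1-2 ligand-bearing M3 monomers (10-12 monomers in total,
#' matching the experimentally reported 11 +/- 4 monomers and the
#' 0.48:0.37:0.15 molar ratio).
#'
#' @return A list of integer ranges: `m1 = c(5, 6)`, `m2 = c(4, 4)`,
#'   `m3 = c(1, 2)`.
#' @export
default_chain_constraints <- function() {
  list(m1 = c(5L, 6L), m2 = c(4L, 4L), m3 = c(1L, 2L))
}

check_constraints <- function(constraints) {
  for (nm in c("m1", "m2", "m3")) {
    b <- constraints[[nm]]
    if (is.null(b) || length(b) != 2L || any(!is.finite(b)) ||
        b[1] > b[2] || b[1] < 0) {
      stop("infeasible constraint for ", toupper(nm),
           ": bounds must be a non-negative, non-decreasing pair, got [",
           paste(b, collapse = ", "), "]", call. = FALSE)
    }
  }
  invisible(constraints)
}

new_chain_spec <- function(counts) {
  structure(list(counts = counts), class = "chain_spec")
}

#' Generate a set of random-copolymer chain specifications
#'
#' Draws `n_chains` P1 sequences. Monomer counts are drawn within the
#' composition bounds and the monomer order is uniformly shuffled under the
#' seed: P1 polymers are random copolymers, so no block structure is imposed.
#' With `balanced = TRUE` (the default used for the standard 4-chain set) the
#' compositions cycle through \{(5,4,1), (6,4,2), (5,4,2), (6,4,1)\} so that a
#' set of four chains averages exactly 11 monomers per chain.
#'
#' @param n_chains Number of chains (>= 0).
#' @param constraints Composition bounds, see [default_chain_constraints()].
#' @param seed Integer seed; the same seed yields the identical chain set.
#' @param balanced Cycle through the balanced composition set instead of
#'   sampling counts uniformly.
#' @return A list of `chain_spec` objects, each with a `sequence` (character
#'   vector of monomer labels) and `counts` (named integer vector).
#' @examples
#' chains <- generate_chain_set(4, seed = 42)
#' sapply(chains, function(ch) ch$counts)
#' @export
generate_chain_set <- function(n_chains,
                               constraints = default_chain_constraints(),
                               seed = 1L,
                               balanced = TRUE) {
  stopifnot(n_chains >= 0)
  check_constraints(constraints)
  if (n_chains == 0L) return(list())
  rng <- local_rng(seed)
  balanced_set <- list(c(5L, 4L, 1L), c(6L, 4L, 2L), c(5L, 4L, 2L), c(6L, 4L, 1L))
  balanced_ok <- all(vapply(balanced_set, function(cc) {
    cc[1] >= constraints$m1[1] && cc[1] <= constraints$m1[2] &&
    cc[2] >= constraints$m2[1] && cc[2] <= constraints$m2[2] &&
    cc[3] >= constraints$m3[1] && cc[3] <= constraints$m3[2]
  }, logical(1)))
  lapply(seq_len(n_chains), function(ic) {
    cc <- if (balanced && balanced_ok) {
      balanced_set[[(ic - 1L) %% 4L + 1L]]
    } else {
      c(sample_range(rng, constraints$m1),
        sample_range(rng, constraints$m2),
        sample_range(rng, constraints$m3))
    }
    seqn <- c(rep("M1", cc[1]), rep("M2", cc[2]), rep("M3", cc[3]))
    seqn <- seqn[rng$sample(length(seqn))]
    out <- new_chain_spec(c(M1 = cc[1], M2 = cc[2], M3 = cc[3]))
    out$sequence <- seqn
    out
  })
}

#' @export
print.chain_spec <- function(x, ...) {
  cat("<chain_spec> ", paste(x$sequence, collapse = "-"), "\n", sep = "")
  invisible(x)
}

# Self-contained RNG wrapper: keeps package randomness off the global stream
# except through the explicit seed.
local_rng <- function(seed) {
  seed <- as.integer(seed)
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    res <- f()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    res
  }
  env$unif <- function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max))
  env$norm <- function(n) with_state(function() stats::rnorm(n))
  env$sample <- function(n, size = n, replace = FALSE)
    with_state(function() sample.int(n, size, replace = replace))
  env
}

sample_range <- function(rng, bounds) {
  if (bounds[1] == bounds[2]) return(as.integer(bounds[1]))
  as.integer(bounds[1] + rng$sample(bounds[2] - bounds[1] + 1L, 1L) - 1L)
}
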