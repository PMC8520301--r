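#' Exact median permutation under summed edit distance (toy scale)
#'
#' Enumerates every permutation of the symbol set and returns one
#' minimizing the summed unit-cost Levenshtein distance to the given
#' permutations (ties: lexicographically smallest). Finding the median
#' string under edit distance is NP-complete, so this is feasible only
#' at toy scale; it exists as an independent reference for the greedy
#' consensus.
#'
#' @param perms list of integer vectors (unsigned permutations of the
#'   same symbol set), or a \code{CorePermutationList}.
#' @param max_m guard on the number of symbols (default 8).
#' @return list with \code{ordering} and \code{cost}.
#' @examples
#' exactMedianOrdering(list(c(1, 2, 3), c(1, 2, 3), c(2, 1, 3)))
#' @export
exactMedianOrdering <- function(perms, max_m = 8L) {
  if (inherits(perms, "CorePermutationList")) {
    gs <- vapply(perms, `[[`, "", "genome")
    perms <- lapply(unique(gs), function(g)
      abs(unlist(lapply(perms[gs == g], `[[`, "ids"))))
  }
  perms <- lapply(perms, function(p) as.integer(abs(p)))
  symbols <- sort(unique(unlist(perms)))
  if (length(symbols) > max_m)
    stop(sprintf("usage error: %d symbols exceed the enumeration limit (%d)",
                 length(symbols), max_m))
  r <- .exact_median_cpp(perms, symbols)
  list(ordering = r$ordering, cost = as.integer(r$cost))
}

#' Exhaustive local alignment score (test oracle)
#'
#' Enumerates all substring pairs of the two symbol sequences and scores
#' each with a global +1/-1/-1 alignment; returns the maximum (0 for the
#' empty alignment). Independent reference for
#' \code{\link{localAlignBlocks}}.
#'
#' @param a,b integer vectors (compared unsigned).
#' @param max_len guard on input length (default 8).
#' @return best local alignment score (non-negative integer).
#' @examples
#' exhaustiveLocalAlign(c(1, 2, 3), c(3, 2, 1))  # 1
#' @export
exhaustiveLocalAlign <- function(a, b, max_len = 8L) {
  a <- abs(as.integer(a)); b <- abs(as.integer(b))
  if (length(a) > max_len || length(b) > max_len)
    stop("usage error: inputs exceed the enumeration limit")
  if (length(a) == 0L || length(b) == 0L) return(0L)
  .exhaustive_local_cpp(a, b)
}
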