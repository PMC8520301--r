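#' Tally core-block adjacencies across genomes
#'
#' Adjacency is counted on the core-only projection (dispensable and
#' unique blocks are transparent), within each (genome, sequence)
#' permutation. Each observed signed adjacency \eqn{x \to y} is stored
#' together with its reverse-reading form \eqn{-y \to -x}, so a genome
#' traversed right-to-left contributes flipped adjacencies; permutation
#' ends contribute single-sided adjacencies only.
#'
#' @param perms a \code{CorePermutationList}.
#' @return a \code{NeighborTable}: \code{data.frame} of directed signed
#'   pairs (\code{from}, \code{to}, \code{count}).
#' @examples
#' nt <- neighborTable(corePermutationList(list(1:3, 1:3, 1:3)))
#' neighborFrequencies(nt, 2)
#' @export
neighborTable <- function(perms) {
  stopifnot(inherits(perms, "CorePermutationList"))
  from <- integer(0); to <- integer(0)
  for (e in perms) {
    s <- e$ids
    if (length(s) < 2L) next
    a <- s[-length(s)]; b <- s[-1L]
    from <- c(from, a, -b)
    to <- c(to, b, -a)
  }
  if (length(from)) {
    key <- paste(from, to)
    agg <- table(key)
    parts <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
    tab <- data.frame(from = as.integer(parts[, 1]),
                      to = as.integer(parts[, 2]),
                      count = as.integer(agg), stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(from = integer(), to = integer(), count = integer())
  }
  attr(tab, "n_genomes") <- length(unique(vapply(perms, `[[`, "", "genome")))
  class(tab) <- c("NeighborTable", "data.frame")
  tab
}

#' Pooled neighbor frequencies of one core block
#'
#' Left- and right-side adjacencies are pooled: the returned counts are,
#' per neighboring block, the number of genomes in which it is adjacent
#' to \code{block} on either side.
#'
#' @param table a \code{NeighborTable}.
#' @param block unsigned core block id.
#' @return named integer vector (names = neighbor ids), decreasing.
#' @export
neighborFrequencies <- function(table, block) {
  sel <- table[abs(table$from) == abs(block), , drop = FALSE]
  if (nrow(sel) == 0L) return(stats::setNames(integer(0), character(0)))
  f <- tapply(sel$count, abs(sel$to), sum)
  f <- stats::setNames(as.integer(f), names(f))
  f[order(-f, as.integer(names(f)))]
}

# Candidates supported on one side of a signed terminus.
# side "right": blocks y with observed (t -> y); side "left": (y -> t).
.sideSupport <- function(nt, t, side) {
  if (side == "right") sel <- nt[nt$from == t, , drop = FALSE]
  else sel <- nt[nt$to == t, , drop = FALSE]
  other <- if (side == "right") sel$to else sel$from
  data.frame(id = abs(other), sign = sign(other), count = sel$count)
}

# Extend one side of a path to exhaustion. Returns list(ids, suspended).
.extendSide <- function(nt, ids, side, assigned) {
  suspended <- FALSE
  repeat {
    t <- if (side == "right") ids[length(ids)] else ids[1L]
    sup <- .sideSupport(nt, t, side)
    sup <- sup[!(sup$id %in% assigned$ids), , drop = FALSE]
    if (nrow(sup) == 0L) break
    cands <- unique(sup$id)
    pooled <- vapply(cands, function(c0) {
      sel <- nt[abs(nt$from) == abs(t) & abs(nt$to) == c0, , drop = FALSE]
      sum(sel$count)
    }, numeric(1))
    ord <- order(-pooled, cands)
    cands <- cands[ord]; pooled <- pooled[ord]
    f <- c(pooled, 0, 0)[1:3]
    if (length(cands) >= 3L && f[1] == f[2] && f[2] == f[3]) {
      suspended <- TRUE
      break
    }
    c1 <- cands[1L]
    votes <- sup[sup$id == c1, , drop = FALSE]
    spos <- sum(votes$count[votes$sign > 0])
    sneg <- sum(votes$count[votes$sign < 0])
    signed <- if (sneg > spos) -c1 else c1
    ids <- if (side == "right") c(ids, signed) else c(signed, ids)
    assigned$ids <- c(assigned$ids, c1)
  }
  list(ids = ids, suspended = suspended)
}

#' Grow one consensus path greedily from a seed block
#'
#' Starting from the seed, the path is extended first to the left as far
#' as possible, then to the right. At each terminus the unassigned
#' neighbors supported on that side are ranked by pooled adjacency
#' frequency; the three top frequencies \eqn{f_1 \ge f_2 \ge f_3} decide
#' the step: a three-way tie suspends the side, otherwise the most
#' frequent neighbor (ties to the lower block id) is appended with the
#' majority orientation. Neighbors already assigned to a path are
#' excluded before ranking.
#'
#' @param seed unsigned core block id, not yet assigned.
#' @param table a \code{NeighborTable}.
#' @param assigned integer vector of block ids already assigned to paths.
#' @return list with \code{ids} (signed path), \code{status}
#'   (\code{"open"} or \code{"suspended"}), \code{seed} and
#'   \code{assigned} (updated assignment vector).
#' @export
greedyExtend <- function(seed, table, assigned = integer(0)) {
  seed <- abs(as.integer(seed))
  if (seed %in% assigned) stop("usage error: seed already assigned")
  env <- new.env()
  env$ids <- c(assigned, seed)
  left <- .extendSide(table, seed, "left", env)
  right <- .extendSide(table, left$ids, "right", env)
  list(ids = right$ids,
       status = if (left$suspended || right$suspended) "suspended" else "open",
       seed = seed, assigned = env$ids)
}

#' Build the full set of greedy consensus paths
#'
#' Seeds \code{\link{greedyExtend}} repeatedly from the lowest-numbered
#' unassigned core block until every core block is assigned, yielding a
#' partition of the core blocks into paths. Deterministic given the
#' input.
#'
#' @param perms a \code{CorePermutationList}.
#' @param table optional precomputed \code{NeighborTable}.
#' @return a \code{PathSet}: list with \code{paths} (each as returned by
#'   \code{greedyExtend}, minus the assignment vector) and
#'   \code{block_ids} (all core ids).
#' @export
buildPathSet <- function(perms, table = neighborTable(perms)) {
  all_ids <- sort(unique(abs(unlist(lapply(perms, `[[`, "ids")))))
  assigned <- integer(0)
  paths <- list()
  remaining <- all_ids
  while (length(remaining)) {
    seed <- remaining[1L]
    p <- greedyExtend(seed, table, assigned)
    assigned <- p$assigned
    paths[[length(paths) + 1L]] <- list(ids = p$ids, status = p$status,
                                        seed = p$seed)
    remaining <- setdiff(all_ids, assigned)
  }
  out <- list(paths = paths, block_ids = all_ids)
  class(out) <- "PathSet"
  out
}

#' @export
print.PathSet <- function(x, ...) {
  cat(sprintf("PathSet: %d paths over %d core blocks\n",
              length(x$paths), length(x$block_ids)))
  for (i in seq_along(x$paths)) {
    p <- x$paths[[i]]
    cat(sprintf("  path %d (%s, seed %d): %d blocks\n", i, p$status, p$seed,
                length(p$ids)))
  }
  invisible(x)
}

#' Summed edit distance of an ordering to the genome permutations
#'
#' The consensus objective: the sum over genomes of the unit-cost
#' Levenshtein distance between the proposed ordering and the genome's
#' core permutation (chromosome permutations of one genome are
#' concatenated in order). By default block ids are compared unsigned;
#' with \code{signed = TRUE} orientation enters the comparison.
#'
#' @param ordering signed integer vector (a proposed consensus).
#' @param perms a \code{CorePermutationList}.
#' @param signed compare signed symbols instead of unsigned.
#' @return non-negative integer.
#' @examples
#' sumEditDistance(c(1, 2, 3), corePermutationList(list(c(1, 3, 2))))
#' @export
sumEditDistance <- function(ordering, perms, signed = FALSE) {
  stopifnot(inherits(perms, "CorePermutationList"))
  o <- as.integer(ordering)
  if (!signed) o <- abs(o)
  genomes <- unique(vapply(perms, `[[`, "", "genome"))
  tot <- 0L
  for (g in genomes) {
    gp <- unlist(lapply(perms[vapply(perms, `[[`, "", "genome") == g],
                        `[[`, "ids"))
    gp <- as.integer(gp)
    if (!signed) gp <- abs(gp)
    tot <- tot + .edit_distance_cpp(o, gp)
  }
  tot
}

#' Dump a neighbor table or path set as TSV (debug aid)
#' @param x a \code{NeighborTable} or \code{PathSet}
#' @param path output file
#' @export
dumpTSV <- function(x, path) {
  if (inherits(x, "NeighborTable")) {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (inherits(x, "PathSet")) {
    df <- do.call(rbind, lapply(seq_along(x$paths), function(i)
      data.frame(path = i, status = x$paths[[i]]$status,
                 position = seq_along(x$paths[[i]]$ids),
                 signed_id = x$paths[[i]]$ids)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
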