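#' Markov-chain transition matrix for rank aggregation
#'
#' Builds the row-stochastic transition matrix of the classical Markov-chain
#' rank-aggregation schemes over the union of items in the input ranked
#' lists. From the current item u a candidate v is proposed uniformly over
#' all items; among the lists that rank both u and v, let f be the fraction
#' that rank v above u. The chain moves with probability
#' \itemize{
#'   \item MC1: 1 if f > 0 (at least one list prefers v),
#'   \item MC2: 1 if f > 1/2 (a strict majority prefers v),
#'   \item MC3: f itself.
#' }
#' Lists enter with uniform weight. A teleportation term
#' `(1 - teleport) * P + teleport / n` guarantees irreducibility.
#'
#' @param lists list of ranked lists: character vectors, best item first, no
#'   duplicates within a list.
#' @param variant `"MC1"`, `"MC2"` or `"MC3"`.
#' @param teleport teleportation weight in `[0, 1)`; 0 gives the raw chain.
#' @param items optional item universe; every item must appear in at least
#'   one list.
#' @return row-stochastic matrix with dimnames = items.
#' @export
mc_transition_matrix <- function(lists, variant = c("MC3", "MC2", "MC1"),
                                 teleport = 0.05, items = NULL) {
  variant <- match.arg(variant)
  if (length(lists) < 2L) stop("need at least two ranked lists")
  if (!is.numeric(teleport) || teleport < 0 || teleport >= 1) {
    stop("teleport must lie in [0, 1)")
  }
  for (l in lists) {
    if (anyDuplicated(l) > 0L) stop("ranked lists must not contain duplicates")
  }
  universe <- sort(unique(unlist(lists)))
  if (is.null(items)) {
    items <- universe
  } else {
    missing <- setdiff(items, universe)
    if (length(missing) > 0L) {
      stop(sprintf("item(s) appearing in zero lists: %s",
                   paste(missing, collapse = ", ")))
    }
    items <- sort(unique(as.character(items)))
  }
  n <- length(items)
  # pos[l, i]: rank of item i in list l (NA when absent)
  pos <- t(vapply(lists, function(l) match(items, l), integer(n)))
  P <- matrix(0, n, n, dimnames = list(items, items))
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      if (u == v) next
      both <- !is.na(pos[, u]) & !is.na(pos[, v])
      nb <- sum(both)
      if (nb == 0L) next
      f <- sum(pos[both, v] < pos[both, u]) / nb
      move <- switch(variant,
                     MC1 = as.numeric(f > 0),
                     MC2 = as.numeric(f > 0.5),
                     MC3 = f)
      P[u, v] <- move / n
    }
  }
  diag(P) <- 1 - rowSums(P)
  if (teleport > 0) P <- (1 - teleport) * P + teleport / n
  P
}

#' Stationary distribution of a stochastic matrix by power iteration
#'
#' Iterates `pi <- pi %*% P` from the uniform start until the L-infinity
#' change drops below `tol`.
#'
#' @param P row-stochastic matrix (rows must sum to 1 within 1e-8).
#' @param tol convergence tolerance on the L-infinity change per iteration.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return probability vector summing to 1, named like `P`'s rows.
#' @export
stationary_distribution <- function(P, tol = 1e-10, max_iter = 100000L) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop("P must be a square matrix")
  if (any(abs(rowSums(P) - 1) > 1e-8) || any(P < -1e-12)) {
    stop("P must be row-stochastic")
  }
  n <- nrow(P)
  pi_ <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    nxt <- as.numeric(pi_ %*% P)
    nxt <- nxt / sum(nxt)
    if (max(abs(nxt - pi_)) < tol) {
      return(setNames(nxt, rownames(P)))
    }
    pi_ <- nxt
  }
  stop(sprintf("power iteration did not converge in %d iterations (residual %.3g)",
               max_iter, max(abs(as.numeric(pi_ %*% P) - pi_))))
}

#' Modified Kendall distance between two top-k lists
#'
#' Pairwise-disagreement distance over the union of the two top-k lists.
#' For each unordered item pair: a pair ordered by both lists contributes 1
#' if the orders disagree, 0 otherwise (an item absent from a list's top-k is
#' implicitly ranked below every present item); a pair whose relative order
#' one list leaves completely undetermined (both items present in one top-k,
#' neither in the other) contributes `penalty_p`. The sum is normalised by
#' the number of evaluated pairs, giving a value in `[0, 1]`.
#'
#' @param list_a,list_b ranked lists (character vectors, best first).
#' @param penalty_p penalty in `[0, 1]` for undetermined pairs; 0.5 is the
#'   neutral default.
#' @param top_k depth of comparison; defaults to the shorter list's length.
#' @return distance in `[0, 1]`.
#' @export
modified_kendall <- function(list_a, list_b, penalty_p = 0.5, top_k = NULL) {
  if (is.null(top_k)) top_k <- min(length(list_a), length(list_b))
  if (top_k < 2L) stop("top_k must be at least 2")
  if (top_k > min(length(list_a), length(list_b))) {
    stop("top_k exceeds the shorter list's length")
  }
  if (penalty_p < 0 || penalty_p > 1) stop("penalty_p must lie in [0, 1]")
  ta <- head(list_a, top_k)
  tb <- head(list_b, top_k)
  u <- union(ta, tb)
  if (length(u) < 2L) return(0)
  pa <- match(u, ta)
  pb <- match(u, tb)
  idx <- utils::combn(length(u), 2L)
  x <- idx[1L, ]; y <- idx[2L, ]
  in_ax <- !is.na(pa[x]); in_ay <- !is.na(pa[y])
  in_bx <- !is.na(pb[x]); in_by <- !is.na(pb[y])
  contrib <- numeric(ncol(idx))

  both_a <- in_ax & in_ay
  both_b <- in_bx & in_by
  # case 1: ordered by both lists
  c1 <- both_a & both_b
  contrib[c1] <- as.numeric((pa[x][c1] < pa[y][c1]) != (pb[x][c1] < pb[y][c1]))
  # case 2: both in one list, exactly one in the other (absence = ranked below)
  c2a <- both_a & xor(in_bx, in_by)           # B says: present item first
  contrib[c2a] <- as.numeric(ifelse(in_bx[c2a],
                                    pa[y][c2a] < pa[x][c2a],
                                    pa[x][c2a] < pa[y][c2a]))
  c2b <- both_b & xor(in_ax, in_ay) & !both_a
  contrib[c2b] <- as.numeric(ifelse(in_ax[c2b],
                                    pb[y][c2b] < pb[x][c2b],
                                    pb[x][c2b] < pb[y][c2b]))
  # case 3: x only in one list, y only in the other — always discordant
  c3 <- (in_ax & !in_ay & !in_bx & in_by) | (!in_ax & in_ay & in_bx & !in_by)
  contrib[c3] <- 1
  # case 4: both in one top-k, neither in the other — undetermined
  c4 <- (both_a & !in_bx & !in_by) | (both_b & !in_ax & !in_ay)
  contrib[c4] <- penalty_p

  sum(contrib) / ncol(idx)
}

#' Aggregate ranked lists with one algorithm
#'
#' MC variants rank items by descending stationary probability of the chain
#' from [mc_transition_matrix()]; Borda ranks by ascending mean rank (items
#' absent from a list are assigned rank `length(list) + 1`). Ties are broken
#' lexicographically by item so the consensus is a strict order.
#'
#' @param lists list of ranked lists.
#' @param algorithm `"MC3"`, `"MC2"`, `"MC1"` or `"Borda"`.
#' @param teleport teleportation weight for the MC variants.
#' @return list with `algorithm`, `consensus` (character vector, best first)
#'   and `stationary` (named probabilities; `NULL` for Borda).
#' @export
aggregate_ranks <- function(lists, algorithm = c("MC3", "MC2", "MC1", "Borda"),
                            teleport = 0.05) {
  algorithm <- match.arg(algorithm)
  items <- sort(unique(unlist(lists)))
  if (algorithm == "Borda") {
    ranks <- vapply(lists, function(l) {
      r <- match(items, l)
      r[is.na(r)] <- length(l) + 1L
      r
    }, numeric(length(items)))
    mean_rank <- rowMeans(ranks)
    consensus <- items[order(mean_rank, items)]
    return(list(algorithm = "Borda", consensus = consensus, stationary = NULL))
  }
  P <- mc_transition_matrix(lists, variant = algorithm, teleport = teleport)
  st <- stationary_distribution(P)
  consensus <- items[order(-st, items)]
  list(algorithm = algorithm, consensus = consensus, stationary = st)
}

#' Run candidate aggregation algorithms and select the best by modified
#' Kendall distance
#'
#' Each candidate algorithm is run with uniform list weights; its consensus
#' is scored by the mean modified Kendall distance to the input lists, and
#' the minimiser is returned. Ties follow the fixed precedence
#' MC3 > MC2 > MC1 > Borda.
#'
#' @param lists list of at least two ranked lists.
#' @param candidates subset of `c("MC3", "MC2", "MC1", "Borda")`.
#' @param penalty_p,top_k passed to [modified_kendall()].
#' @param teleport teleportation weight for MC variants.
#' @return list of class `aggregation_result`: `algorithm`, `consensus`,
#'   `stationary`, `mean_kendall`, and `scores` (the per-algorithm mean
#'   distances).
#' @export
select_and_aggregate <- function(lists,
                                 candidates = c("MC3", "MC2", "MC1", "Borda"),
                                 penalty_p = 0.5, top_k = NULL,
                                 teleport = 0.05) {
  if (length(lists) < 2L) stop("need at least two ranked lists")
  precedence <- c("MC3", "MC2", "MC1", "Borda")
  candidates <- precedence[precedence %in% candidates]
  if (length(candidates) == 0L) stop("no valid candidate algorithm")
  fits <- lapply(candidates, function(a) aggregate_ranks(lists, a, teleport))
  scores <- vapply(fits, function(f) {
    mean(vapply(lists, function(l) {
      modified_kendall(f$consensus, l, penalty_p = penalty_p, top_k = top_k)
    }, numeric(1L)))
  }, numeric(1L))
  names(scores) <- candidates
  best <- which.min(scores)  # first minimum follows the precedence order
  out <- fits[[best]]
  out$mean_kendall <- scores[[best]]
  out$scores <- scores
  class(out) <- "aggregation_result"
  out
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat(sprintf("aggregation_result: %s consensus over %d items (mean modified Kendall %.4f)\n",
              x$algorithm, length(x$consensus), x$mean_kendall))
  invisible(x)
}

#' Write a consensus ranking and the algorithm-selection report
#'
#' @param result an `aggregation_result`.
#' @param dir output directory.
#' @return file paths, invisibly.
#' @export
write_consensus <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pc <- file.path(dir, "consensus.tsv")
  pj <- file.path(dir, "aggregation_report.json")
  stat <- if (is.null(result$stationary)) NA_real_ else
    as.numeric(result$stationary[result$consensus])
  write.table(data.frame(rank = seq_along(result$consensus),
                         drug_id = result$consensus,
                         stationary = stat),
              pc, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(algorithm = result$algorithm,
                            mean_kendall = result$mean_kendall,
                            scores = as.list(result$scores)),
                       pj, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(pc, pj))
}
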