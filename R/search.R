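#' Exhaustive joint ranking of assignments
#'
#' Enumerates all sex-consistent assignments (optionally excluding
#' forbidden pairings), computes the joint log-likelihood of each, and
#' returns them ranked by likelihood, with likelihood ratios against the
#' empty (null) assignment and flat-prior posterior probabilities.
#'
#' @param problem A [dvi_problem()].
#' @param forbidden Optional excluded pairings, as in
#'   [enumerate_assignments()].
#' @param cap Maximum number of assignments to evaluate; exceeded means
#'   an error (use [joint_search()] to shrink the space first).
#' @return A `dvi_ranking`: a data frame with one column per victim,
#'   then `loglik` (natural log), `LR` (vs null) and `posterior`
#'   (flat prior over the enumerated assignments), ordered by
#'   non-increasing log-likelihood. Ties keep enumeration order.
#' @examples
#' head(rank_assignments(dvi_example(1)), 3)
#' @export
rank_assignments <- function(problem, forbidden = NULL, cap = 1e6) {
  A <- enumerate_assignments(problem, forbidden = forbidden)
  if (nrow(A) > cap)
    stop(nrow(A), " assignments exceed the cap (", format(cap),
         "); reduce the threshold T so that more undisputed pairings",
         " shrink the joint step, or raise `cap`")
  ll <- vapply(seq_len(nrow(A)), function(r)
    assignment_loglik(problem, A[r, ]), numeric(1))
  ranking(A, ll, ll0 = assignment_loglik(problem, rep("*", nrow(problem$victims))))
}

# Assemble a ranked data.frame from an assignment matrix and logliks.
ranking <- function(A, ll, ll0) {
  lr <- exp(ll - ll0)
  post <- if (all(lr == 0)) rep(NaN, length(lr)) else lr / sum(lr)
  ord <- order(-ll)
  out <- data.frame(A[ord, , drop = FALSE], loglik = ll[ord], LR = lr[ord],
                    posterior = post[ord], check.names = FALSE,
                    row.names = NULL)
  class(out) <- c("dvi_ranking", "data.frame")
  out
}

# relative tolerance under which two LR values (or logliks) tie
TIE_TOL <- 1e-9

#' Sequential (pairwise) victim identification
#'
#' The PM-driven sequential strategy: repeatedly take the largest entry
#' of the pairwise LR matrix; if it reaches the threshold `T`, accept
#' the pairing and delete its row and column. With `update = TRUE` the
#' remaining LRs are recomputed conditional on all accepted pairings
#' after every step (the victim's genotypes become reference data);
#' with `update = FALSE` the matrix is static. Tied maxima are branched
#' exhaustively and all distinct terminal assignments are returned.
#'
#' @param problem A [dvi_problem()].
#' @param threshold LR threshold `T > 1` for accepting a pairing.
#' @param update Recompute LRs conditional on accepted pairings?
#' @return A `dvi_search` list: `solutions` (character matrix, one row
#'   per terminal assignment), and `trail` (a list, per solution, of
#'   data frames logging each accepted pairing and its LR at the time
#'   of choice).
#' @examples
#' sequential_search(dvi_example(1), threshold = 5, update = TRUE)$solutions
#' @export
sequential_search <- function(problem, threshold, update = FALSE) {
  if (threshold <= 1)
    stop("`threshold` must be > 1")
  vict_ids <- problem$victims$id
  sols <- list()
  trails <- list()
  recurse <- function(cur, fixed, trail) {
    B <- pairwise_lr_matrix(cur)
    mx <- if (length(B)) max(B) else 0
    if (mx < threshold * (1 - TIE_TOL) || mx == 0) {
      a <- stats::setNames(rep("*", length(vict_ids)), vict_ids)
      a[names(fixed)] <- fixed
      sols[[length(sols) + 1]] <<- a
      trails[[length(trails) + 1]] <<- trail
      return(invisible())
    }
    ties <- which(B >= mx * (1 - TIE_TOL) & B > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(ties))) {
      v <- rownames(B)[ties[r, 1]]
      m <- colnames(B)[ties[r, 2]]
      pair <- stats::setNames(m, v)
      step <- data.frame(victim = v, mp = m, LR = B[v, m])
      nxt <- if (update) condition_problem(cur, pair) else drop_pair(cur, v, m)
      recurse(nxt, c(fixed, pair), rbind(trail, step))
    }
  }
  recurse(problem, character(0), data.frame())
  keep <- !duplicated(vapply(sols, paste, character(1), collapse = "\r"))
  structure(list(solutions = do.call(rbind, sols)[keep, , drop = FALSE],
                 trail = trails[keep]),
            class = "dvi_search")
}

# Remove a victim and a missing person without conditioning (static
# matrix semantics: remaining LRs are unchanged).
drop_pair <- function(problem, victim, mp) {
  out <- problem
  keep <- out$victims$id != victim
  out$victims <- out$victims[keep, , drop = FALSE]
  out$victim_gt <- lapply(out$victim_gt, function(g)
    g[names(g) != victim])
  for (k in seq_along(out$families))
    out$families[[k]]$missing <- setdiff(out$families[[k]]$missing, mp)
  out
}

#' @export
print.dvi_search <- function(x, ...) {
  cat("Sequential search:", nrow(x$solutions), "terminal assignment(s)\n")
  print(x$solutions)
  invisible(x)
}

#' Undisputed pairings
#'
#' A pairing \eqn{V_i = M_j} is *undisputed* when its pairwise LR
#' reaches the threshold `T` while every other entry in row `i` and
#' column `j` is at most 1 (strict criterion). The relaxed criterion
#' raises that limit to \eqn{LR_{i,j}/T}, admitting pairings whose
#' competitors are small relative to the winner rather than absolutely
#' small.
#'
#' @param B A pairwise LR matrix (victims x missing persons).
#' @param threshold LR threshold `T > 1`.
#' @param relaxed Use the relaxed competitor limit `LR/T` instead of 1?
#' @return A data frame with columns `victim`, `mp`, `LR` (possibly
#'   zero rows).
#' @export
find_undisputed <- function(B, threshold, relaxed = FALSE) {
  if (threshold <= 1)
    stop("`threshold` must be > 1")
  out <- data.frame(victim = character(0), mp = character(0), LR = numeric(0))
  for (i in seq_len(nrow(B))) {
    for (j in seq_len(ncol(B))) {
      lr <- B[i, j]
      if (lr < threshold * (1 - TIE_TOL)) next
      limit <- if (relaxed) lr / threshold else 1
      others <- c(B[i, -j], B[-i, j])
      if (all(others <= limit * (1 + TIE_TOL)))
        out <- rbind(out, data.frame(victim = rownames(B)[i],
                                     mp = colnames(B)[j], LR = lr))
    }
  }
  out
}

#' Combined undisputed-plus-joint search
#'
#' The recommended two-step strategy for DVI problems too large for
#' exhaustive ranking. Step 1 iterates [find_undisputed()] on the
#' pairwise LR matrix, fixing each undisputed pairing and recomputing
#' the remaining LRs conditional on it, until no further undisputed
#' pairing appears. Step 2 enumerates the assignments of the remaining
#' (conditioned) problem, drops every assignment containing a zero-LR
#' pairing of the updated matrix, ranks the rest by joint likelihood
#' conditional on the undisputed findings, and merges the fixed
#' pairings back in.
#'
#' @param problem A [dvi_problem()].
#' @param threshold LR threshold `T > 1`.
#' @param relaxed Use the relaxed undisputed criterion (see
#'   [find_undisputed()])?
#' @param cap Maximum size of the joint enumeration in Step 2; if
#'   exceeded, the search stops with an error suggesting a lower `T`.
#' @return A `dvi_ranking` data frame as in [rank_assignments()]:
#'   assignments (including the undisputed pairings) ranked by
#'   log-likelihood, with `LR` against the overall null and flat-prior
#'   `posterior` over the enumerated (conditional) space. The
#'   undisputed pairings of Step 1 are attached as
#'   `attr(, "undisputed")`.
#' @examples
#' joint_search(dvi_example(2), threshold = 10)[1:3, ]
#' @export
joint_search <- function(problem, threshold, relaxed = FALSE, cap = 1e6) {
  if (threshold <= 1)
    stop("`threshold` must be > 1")
  cur <- problem
  fixed <- character(0)
  repeat {
    B <- pairwise_lr_matrix(cur)
    und <- find_undisputed(B, threshold, relaxed = relaxed)
    if (!nrow(und)) break
    pairs <- stats::setNames(und$mp, und$victim)
    fixed <- c(fixed, pairs)
    cur <- condition_problem(cur, pairs)
  }
  forbidden <- which(B == 0, arr.ind = TRUE)
  forbidden <- data.frame(victim = rownames(B)[forbidden[, 1]],
                          mp = colnames(B)[forbidden[, 2]])
  rk <- rank_assignments(cur, forbidden = forbidden, cap = cap)
  # merge fixed pairings back; conditional logliks already equal the full
  # joint logliks because fixed victims' data moved into the families
  vict_ids <- problem$victims$id
  A <- matrix("*", nrow(rk), length(vict_ids),
              dimnames = list(NULL, vict_ids))
  for (v in names(fixed))
    A[, v] <- fixed[[v]]
  open <- setdiff(vict_ids, names(fixed))
  for (v in open)
    A[, v] <- rk[[v]]
  ll0 <- assignment_loglik(problem, rep("*", length(vict_ids)))
  out <- ranking(A, rk$loglik, ll0)
  attr(out, "undisputed") <- fixed
  out
}
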