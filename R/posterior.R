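#' Posterior pairing probabilities
#'
#' Converts a ranked enumeration of assignments into per-victim
#' posterior identification probabilities. For victim \eqn{V_i} and
#' missing person \eqn{M_j},
#' \deqn{q_{i,j} = \frac{\sum_{a:\,V_i = M_j} L(a)\,\pi(a)}
#'                      {\sum_{a} L(a)\,\pi(a)},}
#' summing over the assignments in the table, and the non-pairing
#' probability \eqn{q_{i,*}} sums over assignments leaving \eqn{V_i}
#' unmatched. With a flat prior the weights cancel and the sums may be
#' taken over likelihood ratios; internally everything is accumulated
#' in log space. Each row of the resulting table sums to 1, and for any
#' column \eqn{j} and two victims, \eqn{q_{i,j} + q_{i',j} \le 1}: two
#' victims can never both be probable matches of the same missing
#' person.
#'
#' When the table comes from [joint_search()] after undisputed pairings
#' were fixed, those pairings appear in every enumerated assignment and
#' therefore receive posterior 1: the table is then conditional on the
#' undisputed identifications.
#'
#' @param problem The [dvi_problem()] the ranking belongs to.
#' @param ranked A `dvi_ranking` data frame ([rank_assignments()] or
#'   [joint_search()]), or any data frame with one column per victim
#'   and a `loglik` column, covering the complete assignment space to
#'   condition on.
#' @param prior Optional prior weights, one per row of `ranked`
#'   (unnormalized; renormalized internally). Default: flat.
#' @return A `posterior_table`: numeric matrix with victims as rows and
#'   missing persons plus `"*"` as columns.
#' @examples
#' prob <- dvi_example(1)
#' posterior_table(prob, rank_assignments(prob))
#' @export
posterior_table <- function(problem, ranked, prior = NULL) {
  vict_ids <- problem$victims$id
  mp_ids <- missing_persons(problem)$id
  if (!all(vict_ids %in% names(ranked)))
    stop("`ranked` must contain one column per victim")
  if (!"loglik" %in% names(ranked))
    stop("`ranked` must contain a loglik column")
  n <- nrow(ranked)
  if (is.null(prior)) {
    logw <- rep(0, n)
  } else {
    if (length(prior) != n)
      stop("`prior` must have one weight per ranked assignment")
    if (any(prior < 0) || all(prior == 0))
      stop("`prior` weights must be non-negative with positive total")
    logw <- log(prior)
  }
  logpost <- ranked$loglik + logw
  denom <- logsumexp(logpost)
  if (denom == -Inf)
    stop("all assignments have zero posterior weight")
  tab <- matrix(0, length(vict_ids), length(mp_ids) + 1,
                dimnames = list(vict_ids, c(mp_ids, "*")))
  for (v in vict_ids) {
    col <- as.character(ranked[[v]])
    for (m in unique(col))
      tab[v, m] <- exp(logsumexp(logpost[col == m]) - denom)
  }
  structure(tab, class = c("posterior_table", class(tab)))
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  mx <- max(x)
  if (mx == -Inf) return(-Inf)
  mx + log(sum(exp(x - mx)))
}

#' @export
print.posterior_table <- function(x, digits = 3, ...) {
  cat("Posterior pairing probabilities (rows: victims; '*': no match)\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Conclude identifications from posterior probabilities
#'
#' Returns the pairings whose posterior probability exceeds `alpha`.
#' For any `alpha > 0.5` the conclusions are guaranteed conflict-free:
#' since \eqn{q_{i,j} + q_{i',j} \le 1}, two victims cannot both pass
#' the bar for the same missing person. Values `alpha <= 0.5` are
#' rejected because that guarantee would be lost.
#'
#' @param table A [posterior_table()].
#' @param alpha Posterior threshold in `(0.5, 1]`; a value close to 1
#'   (say 0.99) for reportable conclusions, 0.5 +) to read off most
#'   likely matches.
#' @return A data frame with columns `victim`, `mp`, `posterior`.
#' @export
classify_pairings <- function(table, alpha = 0.99) {
  if (!is.numeric(alpha) || alpha <= 0.5 || alpha > 1)
    stop("`alpha` must lie in (0.5, 1]; below 0.5 the consistency",
         " guarantee is lost")
  mp_cols <- setdiff(colnames(table), "*")
  hits <- which(table[, mp_cols, drop = FALSE] > alpha, arr.ind = TRUE)
  data.frame(victim = rownames(table)[hits[, 1]],
             mp = mp_cols[hits[, 2]],
             posterior = table[, mp_cols, drop = FALSE][hits])
}
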