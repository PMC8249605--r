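#' Likelihoods of assignments
#'
#' The likelihood \eqn{L(a)} of an assignment is the probability of all
#' PM and AM data given the pairings in `a`: each matched victim's
#' genotypes are substituted into the pedigree slot of its missing
#' person, families are evaluated by exact peeling, and every unmatched
#' victim contributes its Hardy-Weinberg genotype probabilities as an
#' unrelated singleton. The empty assignment gives the null likelihood
#' \eqn{L_0} (all victims unrelated to all missing persons).
#'
#' @param problem A [dvi_problem()].
#' @param a An assignment: character vector with one entry per victim
#'   (missing-person ID or `"*"`), e.g. a row of
#'   [enumerate_assignments()].
#' @return [assignment_loglik()] returns the natural-log likelihood
#'   (possibly `-Inf`); [lr_vs_null()] the likelihood ratio
#'   \eqn{L(a)/L_0}, with `-Inf` log-likelihoods mapping to LR 0.
#' @examples
#' prob <- dvi_example(1)
#' assignment_loglik(prob, c("*", "*", "*"))       # log L_0 = -21.64
#' lr_vs_null(prob, c("M1", "M2", "M3"))           # 250
#' @export
assignment_loglik <- function(problem, a) {
  a <- check_assignment(problem, a)
  ll <- singleton_loglik(problem, names(a)[a == "*"])
  for (fam in problem$families)
    ll <- ll + family_loglik(problem, fam, a)
  ll
}

# Joint singleton (HWE) loglik of a set of victims across all markers.
singleton_loglik <- function(problem, victim_ids) {
  ll <- 0
  for (m in names(problem$victim_gt)) {
    g <- problem$victim_gt[[m]]
    g <- g[names(g) %in% victim_ids]
    g <- g[!is.na(g) & g != "-"]
    for (gt in g)
      ll <- ll + log(hwe_genotype_probability(gt, m, problem$db))
  }
  ll
}

# Loglik of one family with the victims assigned to its missing persons
# inserted as typed members.
family_loglik <- function(problem, fam, a) {
  data <- insert_victims(problem, fam, a)
  pedigree_loglik(fam$ped, data, problem$db, problem$model)
}

# Merge a family's reference genotypes with the genotypes of victims
# paired (by assignment `a`) to this family's missing persons.
insert_victims <- function(problem, fam, a) {
  pairs <- a[a %in% fam$missing]
  data <- fam$gt
  for (m in names(problem$victim_gt)) {
    vg <- problem$victim_gt[[m]]
    add <- vg[names(vg) %in% names(pairs)]
    add <- add[!is.na(add) & add != "-"]
    if (!length(add)) next
    slot <- stats::setNames(unname(add), pairs[names(add)])
    data[[m]] <- c(data[[m]], slot)
  }
  data
}

#' @rdname assignment_loglik
#' @export
lr_vs_null <- function(problem, a) {
  null <- rep("*", nrow(problem$victims))
  exp(assignment_loglik(problem, a) - assignment_loglik(problem, null))
}

#' Pairwise likelihood-ratio matrix
#'
#' Computes the victims-by-missing-persons matrix \eqn{B} whose entry
#' \eqn{(i,j)} is the likelihood ratio comparing the single pairing
#' \eqn{V_i = M_j} against unrelatedness. Each entry is computed on the
#' *reduced* problem consisting of \eqn{V_i}'s profile and the data of
#' \eqn{M_j}'s family only; this equals the LR computed from the full
#' data set (see [full_vs_reduced_lr_check()]) but is much cheaper.
#' Sex-inconsistent pairings and Mendelian exclusions yield 0.
#'
#' @param problem A [dvi_problem()].
#' @return A numeric matrix with victims as rows and missing persons as
#'   columns.
#' @examples
#' pairwise_lr_matrix(dvi_example(2))["V1", "M2"]  # 20
#' @export
pairwise_lr_matrix <- function(problem) {
  vict <- problem$victims
  mp <- missing_persons(problem)
  B <- matrix(0, nrow(vict), nrow(mp), dimnames = list(vict$id, mp$id))
  if (!nrow(mp) || !nrow(vict)) return(B)
  # per-family loglik of reference data alone, and per-victim singleton loglik
  fam_ll <- vapply(problem$families, function(fam)
    pedigree_loglik(fam$ped, fam$gt, problem$db, problem$model), numeric(1))
  v_ll <- vapply(vict$id, function(v) singleton_loglik(problem, v), numeric(1))
  for (j in seq_len(nrow(mp))) {
    k <- mp$family[j]
    fam <- problem$families[[k]]
    for (i in seq_len(nrow(vict))) {
      if (vict$sex[i] != mp$sex[j]) next
      a <- stats::setNames(mp$id[j], vict$id[i])
      num <- pedigree_loglik(fam$ped, insert_victims(problem, fam, a),
                             problem$db, problem$model)
      B[i, j] <- exp(num - fam_ll[k] - v_ll[i])
    }
  }
  B
}

#' Condition a DVI problem on confirmed pairings
#'
#' Fixes a set of identifications \eqn{V_i = M_j}: each fixed victim's
#' genotypes become reference data of its missing person's family, and
#' both are removed from the open problem. The remaining pairwise LRs
#' are then those *conditional* on the fixed identifications.
#'
#' @param problem A [dvi_problem()].
#' @param fixed Confirmed pairings: a data frame (or 2-column matrix)
#'   with columns `victim` and `mp`, or a named character vector
#'   `c(victim = mp, ...)`. Must be mutually consistent (no victim or
#'   missing person repeated, sexes matching).
#' @return [condition_problem()] returns the reduced [dvi_problem()];
#'   [conditioned_lr_matrix()] its pairwise LR matrix (rows and columns
#'   of fixed pairings removed). With `fixed` empty both reduce to the
#'   unconditional versions.
#' @export
conditioned_lr_matrix <- function(problem, fixed) {
  pairwise_lr_matrix(condition_problem(problem, fixed))
}

#' @rdname conditioned_lr_matrix
#' @export
condition_problem <- function(problem, fixed) {
  fixed <- as_pairing_vector(fixed)
  if (!length(fixed)) return(problem)
  vict <- problem$victims
  mp <- missing_persons(problem)
  if (anyDuplicated(names(fixed)) || anyDuplicated(fixed))
    stop("inconsistent fixed pairings: victim or missing person repeated")
  full <- stats::setNames(rep("*", nrow(vict)), vict$id)
  if (length(setdiff(names(fixed), vict$id)))
    stop("unknown victim in fixed pairings")
  full[names(fixed)] <- fixed
  check_assignment(problem, full)  # validates sexes, MP ids
  families <- problem$families
  for (k in seq_along(families)) {
    fam <- families[[k]]
    families[[k]]$gt <- insert_victims(problem, fam, fixed)
    families[[k]]$missing <- setdiff(fam$missing, fixed)
  }
  keep <- !vict$id %in% names(fixed)
  victim_gt <- lapply(problem$victim_gt, function(g)
    g[names(g) %in% vict$id[keep]])
  out <- problem
  out$victims <- vict[keep, , drop = FALSE]
  out$victim_gt <- victim_gt
  out$families <- families
  out
}

as_pairing_vector <- function(fixed) {
  if (is.null(fixed)) return(character(0))
  if (is.character(fixed) && !is.null(names(fixed))) return(fixed)
  fixed <- as.data.frame(fixed)
  if (!nrow(fixed)) return(character(0))
  if (!all(c("victim", "mp") %in% names(fixed)))
    names(fixed)[1:2] <- c("victim", "mp")
  stats::setNames(as.character(fixed$mp), as.character(fixed$victim))
}

#' Verify the full-data versus reduced-problem LR identity
#'
#' The pairwise LR of a single pairing can be computed either from the
#' complete data set (via [lr_vs_null()] on the one-pair assignment) or
#' on the reduced problem restricted to the victim and the missing
#' person's family (as [pairwise_lr_matrix()] does). The two agree
#' exactly; this function checks the identity numerically over all
#' pairs.
#'
#' @param problem A [dvi_problem()].
#' @param tol Relative tolerance.
#' @return `TRUE` if every entry agrees within `tol`, else `FALSE`.
#' @export
full_vs_reduced_lr_check <- function(problem, tol = 1e-9) {
  B <- pairwise_lr_matrix(problem)
  vict <- problem$victims
  for (i in seq_len(nrow(B))) {
    for (j in seq_len(ncol(B))) {
      if (vict$sex[i] != missing_persons(problem)$sex[j]) next
      a <- stats::setNames(rep("*", nrow(vict)), vict$id)
      a[i] <- colnames(B)[j]
      full <- lr_vs_null(problem, a)
      if (abs(full - B[i, j]) > tol * max(1, abs(full)))
        return(FALSE)
    }
  }
  TRUE
}
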