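#' DVI problems
#'
#' A DVI problem bundles the post-mortem (PM) side -- victim samples
#' `V1..Vs`, each with known sex and genotype data -- and the ante-mortem
#' (AM) side: reference families, each a pedigree containing one or more
#' untyped *missing persons* and at least one genotyped reference, plus
#' the allele frequency database and mutation model shared by all
#' likelihood computations.
#'
#' @param victims Data frame with columns `id` and `sex` (1 = male,
#'   2 = female), one row per victim, in PM input order.
#' @param victim_gt Genotype map for the victims: named list per marker
#'   of named `"a/b"` genotype vectors.
#' @param families List of reference families. Each family is a list with
#'   elements `ped` (a [pedigree()]), `gt` (genotype map for its typed
#'   reference members) and `missing` (character vector of missing-person
#'   IDs, a subset of the untyped members).
#' @param db A [freq_db()].
#' @param model A [mutation_model()]; defaults to no mutation.
#' @return An object of class `dvi_problem`.
#' @seealso [dvi_example()] for ready-made toy problems.
#' @export
dvi_problem <- function(victims, victim_gt, families, db,
                        model = mutation_model(db)) {
  if (!is.data.frame(victims) || !all(c("id", "sex") %in% names(victims)))
    stop("`victims` must be a data frame with columns id and sex")
  victims$id <- as.character(victims$id)
  victims$sex <- as.integer(victims$sex)
  if (!all(victims$sex %in% 1:2))
    stop("victim sex must be coded 1 (male) or 2 (female)")
  if (anyDuplicated(victims$id))
    stop("duplicated victim IDs")
  all_mp <- unlist(lapply(families, function(fam) as.character(fam$missing)))
  if (anyDuplicated(all_mp))
    stop("missing person '", all_mp[duplicated(all_mp)][1],
         "' is declared in two families")
  seen_mp <- character(0)
  for (k in seq_along(families)) {
    fam <- families[[k]]
    if (!all(c("ped", "missing") %in% names(fam)))
      stop("family ", k, " must have elements ped, gt and missing")
    if (is.null(fam$gt)) families[[k]]$gt <- list()
    fam$missing <- as.character(fam$missing)
    typed <- unique(unlist(lapply(fam$gt, names)))
    bad <- setdiff(fam$missing, fam$ped$id)
    if (length(bad))
      stop("missing person '", bad[1], "' is not a member of family ", k)
    bad <- intersect(fam$missing, typed)
    if (length(bad))
      stop("missing person '", bad[1], "' in family ", k, " is genotyped")
    dup <- intersect(fam$missing, seen_mp)
    if (length(dup))
      stop("missing person '", dup[1], "' is declared in two families")
    seen_mp <- c(seen_mp, fam$missing)
    if (!length(typed))
      stop("family ", k, " has no genotyped reference member")
    check_genotype_map(fam$ped, fam$gt, db)
    families[[k]]$missing <- fam$missing
  }
  bad <- intersect(victims$id, seen_mp)
  if (length(bad))
    stop("ID '", bad[1], "' is both a victim and a missing person")
  for (m in names(victim_gt)) {
    check_marker(db, m)
    bad <- setdiff(names(victim_gt[[m]]), victims$id)
    if (length(bad))
      stop("genotyped victim '", bad[1], "' at marker ", m, " is not declared")
  }
  structure(list(victims = victims, victim_gt = victim_gt,
                 families = families, db = db, model = model),
            class = "dvi_problem")
}

#' @export
print.dvi_problem <- function(x, ...) {
  mp <- missing_persons(x)
  cat("DVI problem:", nrow(x$victims), "victims,", nrow(mp),
      "missing persons in", length(x$families), "reference families;",
      length(x$db), "markers\n")
  invisible(x)
}

# Missing persons with family index and sex, in declaration order.
missing_persons <- function(problem) {
  rows <- lapply(seq_along(problem$families), function(k) {
    fam <- problem$families[[k]]
    if (!length(fam$missing)) return(NULL)
    sex <- fam$ped$sex[match(fam$missing, fam$ped$id)]
    data.frame(id = fam$missing, sex = sex, family = k)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(0), sex = integer(0), family = integer(0))
  out
}

#' Count sex-consistent assignments
#'
#' Closed-form count of the a priori possible assignments of `s` victims
#' to `m` missing persons. With unknown sex the count is
#' \deqn{\sum_{k=0}^{\min(s,m)} \binom{s}{k}\binom{m}{k}\, k!,}
#' summing over the number `k` of matched victims. With known sexes the
#' formula applies to the female and male subproblems independently and
#' the total is the product. The count is a useful size measure of a DVI
#' problem: it tells whether exhaustive joint ranking is feasible.
#'
#' @param s,m Numbers of victims and missing persons.
#' @return The exact number of assignments (as a double; exact for all
#'   realistic sizes).
#' @examples
#' count_assignments_nosex(5, 8)   # 19081
#' count_assignments(1, 2, 1, 2)   # 14
#' count_assignments(3, 2, 6, 6)   # 9847
#' @export
count_assignments_nosex <- function(s, m) {
  if (s < 0 || m < 0)
    stop("s and m must be non-negative")
  k <- 0:min(s, m)
  sum(choose(s, k) * choose(m, k) * factorial(k))
}

#' @rdname count_assignments_nosex
#' @param s_F,s_M Numbers of female and male victims.
#' @param m_F,m_M Numbers of female and male missing persons.
#' @export
count_assignments <- function(s_F, s_M, m_F, m_M) {
  if (any(c(s_F, s_M, m_F, m_M) < 0))
    stop("counts must be non-negative")
  count_assignments_nosex(s_F, m_F) * count_assignments_nosex(s_M, m_M)
}

#' Enumerate sex-consistent assignments
#'
#' Generates every sex-consistent assignment of the problem's victims to
#' its missing persons. An assignment is a tuple whose i-th entry is the
#' missing person matched to victim i, or `"*"` for no match; no missing
#' person may appear twice. Enumeration is deterministic: recursion by
#' victim index with candidates ordered `"*"` first, then missing
#' persons in declaration order. The first row is always the empty
#' assignment.
#'
#' @param problem A [dvi_problem()].
#' @param forbidden Optional set of excluded victim/missing-person pairs:
#'   a data frame (or 2-column matrix) with columns `victim` and `mp`.
#' @param ignore_sex If `TRUE`, all pairings are allowed regardless of
#'   sex, reproducing the unknown-sex count.
#' @return A character matrix, one row per assignment, one column per
#'   victim (named by victim ID); entries are missing-person IDs or `"*"`.
#' @examples
#' nrow(enumerate_assignments(dvi_example(1)))  # 14
#' @export
enumerate_assignments <- function(problem, forbidden = NULL, ignore_sex = FALSE) {
  vict <- problem$victims
  mp <- missing_persons(problem)
  s <- nrow(vict)
  forb <- matrix(FALSE, s, nrow(mp), dimnames = list(vict$id, mp$id))
  if (!is.null(forbidden) && NROW(forbidden)) {
    forbidden <- as.data.frame(forbidden)
    if (ncol(forbidden) < 2)
      stop("`forbidden` needs columns victim and mp")
    if (!all(c("victim", "mp") %in% names(forbidden)))
      names(forbidden)[1:2] <- c("victim", "mp")
    for (r in seq_len(nrow(forbidden))) {
      v <- as.character(forbidden$victim[r]); m <- as.character(forbidden$mp[r])
      if (!v %in% vict$id) stop("unknown victim in forbidden pairs: ", v)
      if (!m %in% mp$id) stop("unknown missing person in forbidden pairs: ", m)
      forb[v, m] <- TRUE
    }
  }
  rows <- list()
  cur <- character(s)
  recurse <- function(i) {
    if (i > s) {
      rows[[length(rows) + 1]] <<- cur
      return(invisible())
    }
    cand <- mp$id[(ignore_sex | mp$sex == vict$sex[i]) &
                    !mp$id %in% cur[seq_len(i - 1)] & !forb[i, mp$id]]
    for (ch in c("*", cand)) {
      cur[i] <<- ch
      recurse(i + 1)
    }
  }
  if (s == 0) {
    out <- matrix(character(0), nrow = 1, ncol = 0)
  } else {
    recurse(1)
    out <- do.call(rbind, rows)
    colnames(out) <- vict$id
  }
  out
}

# Validate an assignment (named or positional character vector) against a
# problem; returns it named by victim id.
check_assignment <- function(problem, a) {
  vict <- problem$victims
  mp <- missing_persons(problem)
  a <- as.character(unlist(a))
  if (length(a) != nrow(vict))
    stop("assignment must have one entry per victim")
  names(a) <- vict$id
  matched <- a[a != "*"]
  bad <- setdiff(matched, mp$id)
  if (length(bad))
    stop("unknown missing person in assignment: ", bad[1])
  if (anyDuplicated(matched))
    stop("assignment pairs one missing person with two victims: ",
         matched[duplicated(matched)][1])
  sexes <- mp$sex[match(matched, mp$id)]
  clash <- vict$sex[match(names(matched), vict$id)] != sexes
  if (any(clash))
    stop("sex-inconsistent pairing: ", names(matched)[clash][1], " = ",
         matched[clash][1])
  a
}
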