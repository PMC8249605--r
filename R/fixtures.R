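#' Built-in toy DVI problems
#'
#' Two small single-marker problems, useful for illustration and as
#' worked examples whose every number can be checked by hand.
#'
#' **Example 1** (two reference families): three victims (V1, V2 male;
#' V3 female) against three missing persons. Family 1 consists of the
#' couple M1 (male, missing) and the typed reference R1 (genotype 2/2),
#' with missing son M2; M1 is genetically unrelated to R1, so he can
#' only be identified through M2. Family 2 has the typed mother R2
#' (3/3) and missing daughter M3. The marker has 10 equifrequent
#' alleles (frequency 0.1). Victim genotypes: V1 = 1/1, V2 = 1/2,
#' V3 = 3/4.
#'
#' **Example 2** (one family, three generations): the typed grandmother
#' R1 (1/1) married to the missing grandfather M1; their missing son
#' M2; M2's missing son M3 (M3's mother is an untyped non-missing
#' spouse). Victims V1 = 1/1, V2 = 2/2, V3 = 1/2, all male, are matched
#' against M1, M2, M3. The marker has alleles 1, 2, 3 with frequencies
#' 0.05, 0.05, 0.90. This is the classic situation where sequential
#' (one-victim-at-a-time) identification fails: the best pairwise match
#' V1 = M2 blocks the jointly optimal solution (M3, M1, M2), which is
#' ten times more likely.
#'
#' @param which `1` or `2`.
#' @return A [dvi_problem()].
#' @examples
#' prob <- dvi_example(1)
#' pairwise_lr_matrix(prob)
#' @export
dvi_example <- function(which = 1) {
  if (which == 1) {
    db <- freq_db(list(L1 = stats::setNames(rep(0.1, 10), as.character(1:10))))
    fam1 <- list(
      ped = pedigree(id  = c("M1", "R1", "M2"),
                     fid = c(NA, NA, "M1"),
                     mid = c(NA, NA, "R1"),
                     sex = c(1, 2, 1)),
      gt = list(L1 = c(R1 = "2/2")),
      missing = c("M1", "M2"))
    fam2 <- list(
      ped = pedigree(id  = c("FA2", "R2", "M3"),
                     fid = c(NA, NA, "FA2"),
                     mid = c(NA, NA, "R2"),
                     sex = c(1, 2, 2)),
      gt = list(L1 = c(R2 = "3/3")),
      missing = "M3")
    victims <- data.frame(id = c("V1", "V2", "V3"), sex = c(1, 1, 2))
    victim_gt <- list(L1 = c(V1 = "1/1", V2 = "1/2", V3 = "3/4"))
    return(dvi_problem(victims, victim_gt, list(fam1, fam2), db))
  }
  if (which == 2) {
    db <- freq_db(list(L1 = c("1" = 0.05, "2" = 0.05, "3" = 0.90)))
    fam <- list(
      ped = pedigree(id  = c("M1", "R1", "M2", "S", "M3"),
                     fid = c(NA, NA, "M1", NA, "M2"),
                     mid = c(NA, NA, "R1", NA, "S"),
                     sex = c(1, 2, 1, 2, 1)),
      gt = list(L1 = c(R1 = "1/1")),
      missing = c("M1", "M2", "M3"))
    victims <- data.frame(id = c("V1", "V2", "V3"), sex = c(1, 1, 1))
    victim_gt <- list(L1 = c(V1 = "1/1", V2 = "2/2", V3 = "1/2"))
    return(dvi_problem(victims, victim_gt, list(fam), db))
  }
  stop("unknown example: ", which)
}

#' Synthetic larger-scale DVI problems
#'
#' Structure-realistic problems with simulated genotype data, for
#' exercising the search machinery at the scale of published case work.
#' Both are entirely synthetic: pedigree shapes are chosen to be
#' typical, and all genotypes are gene-dropped under a known ground
#' truth (recorded in `attr(, "truth")`).
#'
#' * [synthetic_crash_problem()]: 8 victims against 5 reference
#'   families, each with one missing person and one typed parent
#'   reference; 15 markers with 10 equifrequent alleles. Truth: five
#'   victims are the five missing persons, three are unrelated.
#' * [synthetic_family_problem()]: 5 victims (3 female, 2 male) against
#'   a single three-generation family with 12 missing persons (6
#'   female, 6 male) and 6 typed references; 13 markers. The a priori
#'   assignment count for this sex configuration is 9847.
#'
#' @param seed Integer seed for the gene-drop.
#' @return A [dvi_problem()] with attribute `truth` (the simulated
#'   assignment).
#' @export
synthetic_crash_problem <- function(seed = 1) {
  db <- equifreq_db(n_markers = 15, n_alleles = 10)
  families <- lapply(1:5, function(k) {
    mp <- paste0("M", k)
    ref <- paste0("R", k)
    list(ped = pedigree(id  = c("FA", ref, mp),
                        fid = c(NA, NA, "FA"),
                        mid = c(NA, NA, ref),
                        sex = c(1, 2, 1)),
         gt = stats::setNames(lapply(names(db), function(.) {
           stats::setNames("1/1", ref)  # placeholder, overwritten below
         }), names(db)),
         missing = mp)
  })
  victims <- data.frame(id = paste0("V", 1:8), sex = 1)
  victim_gt <- stats::setNames(lapply(names(db), function(.)
    stats::setNames(rep("1/1", 8), victims$id)), names(db))
  prob <- dvi_problem(victims, victim_gt, families, db)
  truth <- c(V1 = "M1", V2 = "M3", V3 = "*", V4 = "M5",
             V5 = "*", V6 = "M2", V7 = "*", V8 = "*")
  out <- simulate_problem(prob, truth, seed = seed)
  attr(out, "truth") <- truth
  out
}

#' @rdname synthetic_crash_problem
#' @export
synthetic_family_problem <- function(seed = 1) {
  db <- equifreq_db(n_markers = 13, n_alleles = 10)
  #   generation 1: founder couple M1 x M2 (both missing)
  #   generation 2: their children R1, R2, M3..M6; spouses M7, R4, R6
  #   generation 3: grandchildren M8, M9, R3, M10, M11, R5, M12
  ped <- pedigree(
    id  = c("M1", "M2", "R1", "R2", "M3", "M4", "M5", "M6",
            "M7", "M8", "M9", "R3",
            "R4", "M10", "M11", "R5",
            "R6", "M12"),
    fid = c(NA, NA, "M1", "M1", "M1", "M1", "M1", "M1",
            NA, "M3", "M3", "M3",
            NA, "R4", "R4", "R4",
            NA, "M5"),
    mid = c(NA, NA, "M2", "M2", "M2", "M2", "M2", "M2",
            NA, "M7", "M7", "M7",
            NA, "M4", "M4", "M4",
            NA, "R6"),
    sex = c(1, 2, 1, 2, 1, 2, 1, 2,
            2, 1, 2, 1,
            1, 2, 1, 2,
            2, 1))
  refs <- paste0("R", 1:6)
  fam <- list(ped = ped,
              gt = stats::setNames(lapply(names(db), function(.)
                stats::setNames(rep("1/1", length(refs)), refs)), names(db)),
              missing = paste0("M", 1:12))
  victims <- data.frame(id = paste0("V", 1:5), sex = c(2, 2, 2, 1, 1))
  victim_gt <- stats::setNames(lapply(names(db), function(.)
    stats::setNames(rep("1/1", 5), victims$id)), names(db))
  prob <- dvi_problem(victims, victim_gt, list(fam), db)
  truth <- c(V1 = "M4", V2 = "M9", V3 = "M10", V4 = "M8", V5 = "M12")
  out <- simulate_problem(prob, truth, seed = seed)
  attr(out, "truth") <- truth
  out
}
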