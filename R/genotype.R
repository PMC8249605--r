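#' Genotype probabilities under Hardy-Weinberg equilibrium
#'
#' Genotypes are unordered allele pairs written `"a/b"`; `"a/b"` and
#' `"b/a"` denote the same genotype. A missing genotype is written `"-"`
#' (or `NA`). Under Hardy-Weinberg equilibrium (HWE) a homozygote `a/a`
#' has probability \eqn{p_a^2} and a heterozygote `a/b` probability
#' \eqn{2 p_a p_b}.
#'
#' @param g A genotype string, e.g. `"7/9.3"`.
#' @param marker Marker name, present in `db`.
#' @param db A [freq_db()] object.
#' @return The HWE genotype probability.
#' @examples
#' db <- equifreq_db(1, 10)
#' hwe_genotype_probability("1/1", "M1", db)  # 0.01
#' hwe_genotype_probability("1/2", "M1", db)  # 0.02
#' @export
hwe_genotype_probability <- function(g, marker, db) {
  al <- gt_alleles(g)
  if (anyNA(al))
    stop("missing genotype has no HWE probability")
  check_allele(db, marker, al)
  p <- db[[marker]]
  if (al[1] == al[2]) p[[al[1]]]^2 else 2 * p[[al[1]]] * p[[al[2]]]
}

# Split "a/b" into c(a, b); "-", "" and NA mean missing -> c(NA, NA).
gt_alleles <- function(g) {
  if (is.na(g) || g == "-" || g == "")
    return(c(NA_character_, NA_character_))
  parts <- strsplit(g, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2 || any(parts == ""))
    stop("malformed genotype '", g, "': expected \"a/b\"")
  parts
}

gt_format <- function(a, b) {
  if (is.na(a)) "-" else paste0(a, "/", b)
}

# TRUE if two "a/b" strings denote the same unordered genotype.
gt_equal <- function(g1, g2) {
  a1 <- sort(gt_alleles(g1))
  a2 <- sort(gt_alleles(g2))
  identical(a1, a2) || (all(is.na(a1)) && all(is.na(a2)))
}
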