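#' Mutation models for allele transmission
#'
#' A mutation model specifies, per marker, the probability
#' \eqn{m_{ab} = P(\textrm{transmitted allele } b \mid \textrm{parental
#' allele } a)} for every ordered pair of alleles. Two kinds are
#' supported:
#'
#' * `"none"`: the identity matrix; alleles are transmitted unchanged.
#' * `"proportional"`: off-diagonal entries proportional to the frequency
#'   of the target allele, \eqn{m_{ab} = \gamma p_b} for \eqn{b \ne a} and
#'   \eqn{m_{aa} = 1 - \gamma(1 - p_a)}, with
#'   \eqn{\gamma = r / \sum_a p_a (1 - p_a)} calibrated so that the
#'   expected per-transmission mutation rate equals `rate` when the
#'   parental allele is drawn from the frequency distribution.
#'
#' The proportional model is *stationary*: the allele frequency vector is
#' a left fixed point of the transition matrix, so HWE founder frequencies
#' are preserved down the pedigree. It is also lumpable, i.e. exact when
#' unobserved alleles are pooled, which the likelihood engine exploits.
#'
#' @param db A [freq_db()] object.
#' @param kind `"none"` or `"proportional"`.
#' @param rate Mutation probability per transmission, in `[0, 1)`. With
#'   `rate = 0` the proportional model degenerates to the identity.
#' @return An object of class `mutation_model` with elements `kind`,
#'   `rate`, and per-marker transition matrices (`$matrices`).
#' @examples
#' db <- equifreq_db(1, 10)
#' mod <- mutation_model(db, "proportional", rate = 0.001)
#' mod$matrices$M1["1", "1"]  # 0.999
#' @export
mutation_model <- function(db, kind = c("none", "proportional"), rate = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate >= 1)
    stop("`rate` must be a single number in [0, 1)")
  if (kind == "none" && rate != 0)
    stop("kind = \"none\" requires rate = 0")
  mats <- lapply(names(db), function(m) {
    p <- db[[m]]
    n <- length(p)
    if (kind == "none" || rate == 0) {
      mat <- diag(n)
      dimnames(mat) <- list(names(p), names(p))
      return(mat)
    }
    het <- sum(p * (1 - p))
    gamma <- rate / het
    mat <- gamma * matrix(p, n, n, byrow = TRUE)
    diag(mat) <- 1 - gamma * (1 - p)
    if (any(diag(mat) < 0))
      stop("mutation rate ", rate, " too large for marker ", m,
           ": transition matrix would have a negative diagonal entry")
    dimnames(mat) <- list(names(p), names(p))
    mat
  })
  names(mats) <- names(db)
  structure(list(kind = kind, rate = rate, matrices = mats),
            class = "mutation_model")
}

#' @rdname mutation_model
#' @param model A `mutation_model`.
#' @param parent_allele,child_allele Allele labels.
#' @param marker Marker name.
#' @return [transmission_probability()] returns
#'   \eqn{P(\textrm{transmitted} = b \mid \textrm{parental} = a)}.
#' @export
transmission_probability <- function(model, marker, parent_allele, child_allele) {
  mat <- model$matrices[[marker]]
  if (is.null(mat))
    stop("unknown marker: ", marker)
  if (!parent_allele %in% rownames(mat))
    stop("unknown allele '", parent_allele, "' at marker ", marker)
  if (!child_allele %in% colnames(mat))
    stop("unknown allele '", child_allele, "' at marker ", marker)
  mat[parent_allele, child_allele]
}

#' @export
print.mutation_model <- function(x, ...) {
  cat("Mutation model:", x$kind,
      if (x$kind != "none") paste0("(rate ", x$rate, ")"), "\n")
  invisible(x)
}

# Transition matrix for a marker restricted to `keep` alleles plus one
# pooled "lump" allele absorbing all others. Exact for the identity and
# proportional models (both strongly lumpable). Returns list(freq, mat)
# with the lump labelled "." (only used internally, never printed).
lump_marker <- function(db, model, marker, keep) {
  p <- db[[marker]]
  keep <- intersect(names(p), keep)
  rest <- setdiff(names(p), keep)
  if (length(rest) < 2) {
    keep <- names(p)
    rest <- character(0)
  }
  if (!length(rest))
    return(list(freq = p, mat = model$matrices[[marker]]))
  pl <- sum(p[rest])
  freq <- c(p[keep], "." = pl)
  if (model$kind == "none" || model$rate == 0) {
    mat <- diag(length(freq))
    dimnames(mat) <- list(names(freq), names(freq))
    return(list(freq = freq, mat = mat))
  }
  het <- sum(p * (1 - p))  # gamma from the full spectrum, not the lumped one
  gamma <- model$rate / het
  n <- length(freq)
  mat <- gamma * matrix(freq, n, n, byrow = TRUE)
  diag(mat) <- 1 - gamma * (1 - freq)
  dimnames(mat) <- list(names(freq), names(freq))
  list(freq = freq, mat = mat)
}
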