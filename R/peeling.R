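#' Exact pedigree likelihoods
#'
#' Computes the log-likelihood of genotype data observed on a pedigree,
#' assuming founders drawn from Hardy-Weinberg equilibrium and Mendelian
#' transmission through the supplied mutation model. Markers are treated
#' as independent: the total is the sum of per-marker log-likelihoods.
#'
#' The computation is exact peeling in the Elston-Stewart style:
#' genotypes of untyped members are summed out one individual at a time,
#' eliminating outwards-in over nuclear families, so cost is linear in
#' pedigree size for loop-free pedigrees. Alleles not observed in the
#' marker's data are pooled into a single lumped allele, which is exact
#' for the identity and proportional mutation models. Pedigrees with
#' loops are rejected.
#'
#' @param ped A [pedigree()] object.
#' @param data A genotype map: a named list with one element per marker,
#'   each a named character vector of `"a/b"` genotypes indexed by
#'   individual ID. Individuals absent from a marker's vector (or with
#'   genotype `"-"`) are untyped at that marker and are marginalized.
#' @param db A [freq_db()] object covering all markers in `data`.
#' @param model A [mutation_model()]; defaults to no mutation.
#' @return The natural-log likelihood; `-Inf` when the data are
#'   impossible under the pedigree (e.g. a Mendelian exclusion without
#'   mutation modelling).
#' @examples
#' db <- equifreq_db(1, 10)
#' trio <- pedigree(c("FA", "MO", "CH"), c(NA, NA, "FA"),
#'                  c(NA, NA, "MO"), c(1, 2, 1))
#' pedigree_loglik(trio, list(M1 = c(FA = "1/1", CH = "1/2")), db)
#' @export
pedigree_loglik <- function(ped, data, db, model = mutation_model(db)) {
  check_genotype_map(ped, data, db)
  if (has_loops(ped))
    stop("pedigree loops unsupported by the peeling engine")
  sum(vapply(names(data), function(m) {
    log(marker_likelihood(ped, data[[m]], db, model, m))
  }, numeric(1)))
}

check_genotype_map <- function(ped, data, db) {
  if (!is.list(data))
    stop("`data` must be a named list of per-marker genotype vectors")
  for (m in names(data)) {
    check_marker(db, m)
    g <- data[[m]]
    if (!length(g)) next
    bad <- setdiff(names(g), ped$id)
    if (length(bad))
      stop("genotyped individual '", bad[1], "' at marker ", m,
           " is not a pedigree member")
    for (i in seq_along(g)) {
      al <- gt_alleles(g[[i]])
      if (!anyNA(al))
        check_allele(db, m, al)
    }
  }
  invisible(TRUE)
}

# Iteratively remove untyped members without children among the
# remaining members: their marginal sums contribute a factor of 1, so
# trimming them is exact and shrinks the elimination problem.
prune_untyped <- function(ped, typed_ids) {
  repeat {
    parents <- c(ped$fid, ped$mid)
    drop <- !(ped$id %in% typed_ids) & !(ped$id %in% parents)
    if (!any(drop)) return(ped)
    ped <- ped[!drop, , drop = FALSE]
  }
}

# ---- single-marker likelihood via variable elimination ------------------

# Factors are lists(vars = character ids, a = array whose d-th dimension
# ranges over the restricted genotype domain of vars[d]). States are
# ordered allele pairs (paternal, maternal): s = a + (b-1)*n; a typed
# individual's domain holds only the 1-2 states matching its genotype,
# an untyped individual's all n^2 states.

marker_likelihood <- function(ped, gts, db, model, marker) {
  gts <- gts[!is.na(gts) & gts != "-"]
  ped <- prune_untyped(ped, names(gts))
  gts <- gts[names(gts) %in% ped$id]
  if (!nrow(ped)) return(1)
  obs <- unique(unlist(lapply(gts, gt_alleles)))
  lk <- lump_marker(db, model, marker, keep = obs)
  p <- lk$freq
  tm <- lk$mat
  n <- length(p)
  n2 <- n * n

  # restricted state domain per individual
  domain <- function(id) {
    if (!id %in% names(gts)) return(seq_len(n2))
    al <- gt_alleles(gts[[id]])
    i <- match(al[1], names(p))
    j <- match(al[2], names(p))
    unique(c(i + (j - 1) * n, j + (i - 1) * n))
  }
  dom <- lapply(ped$id, domain)
  names(dom) <- ped$id
  dims <- vapply(dom, length, numeric(1))

  prior <- as.vector(outer(p, p))  # s = a + (b-1)*n: paternal varies fastest

  factors <- list()
  for (id in ped_founders(ped))
    factors[[length(factors) + 1]] <- list(vars = id, a = prior[dom[[id]]])
  nf <- ped[!is.na(ped$fid), , drop = FALSE]
  if (nrow(nf)) {
    base <- transmission_tensor(marker, p, tm, model)
    for (r in seq_len(nrow(nf))) {
      who <- c(nf$id[r], nf$fid[r], nf$mid[r])
      a <- base[dom[[who[1]]], dom[[who[2]]], dom[[who[3]]], drop = FALSE]
      factors[[length(factors) + 1]] <- list(vars = who, a = a)
    }
  }
  eliminate_all(factors, ped$id, dims)
}

# Genotype-to-genotype transmission tensor for one marker:
# triple[c, f, m] = P(child state c | father state f, mother state m),
# with c = a + (b-1)*n, a from the father and b from the mother. The
# tensors are memoized (keyed by marker, allele set and mutation
# settings): within one analysis the same marker and allele lumping
# recur thousands of times.
.peel_cache <- new.env(parent = emptyenv())

transmission_tensor <- function(marker, p, tm, model) {
  key <- paste(marker, model$kind, model$rate,
               paste(names(p), collapse = "|"),
               paste(signif(p, 15), collapse = "|"), sep = "\r")
  hit <- .peel_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(p)
  n2 <- n * n
  # allele transmission from an ordered-genotype state: TP[state, allele]
  TP <- 0.5 * (tm[rep(seq_len(n), n), , drop = FALSE] +
               tm[rep(seq_len(n), each = n), , drop = FALSE])
  base <- outer(t(TP), t(TP))          # [a, f, b, m]
  base <- aperm(base, c(1, 3, 2, 4))   # [a, b, f, m]
  dim(base) <- c(n2, n2, n2)
  if (length(ls(.peel_cache)) >= 48)   # bound memory use
    rm(list = ls(.peel_cache), envir = .peel_cache)
  .peel_cache[[key]] <- base
  base
}

# Sum-product elimination of all variables; `dims` gives the domain
# size per variable. Returns the scalar result.
eliminate_all <- function(factors, vars, dims) {
  result <- 1
  remaining <- vars
  while (length(remaining)) {
    # cheapest variable first: smallest combined factor
    cost <- vapply(remaining, function(v) {
      inv <- unique(unlist(lapply(factors, function(f)
        if (v %in% f$vars) f$vars)))
      prod(dims[inv])
    }, numeric(1))
    v <- remaining[which.min(cost)]
    hit <- vapply(factors, function(f) v %in% f$vars, logical(1))
    merged <- factor_product(factors[hit], dims)
    merged <- factor_sum_out(merged, v, dims)
    factors <- factors[!hit]
    if (!length(merged$vars)) {
      result <- result * merged$a
    } else {
      factors[[length(factors) + 1]] <- merged
    }
    remaining <- setdiff(remaining, v)
  }
  for (f in factors)  # only scalars can remain
    result <- result * f$a
  result
}

factor_product <- function(fs, dims) {
  vars <- unique(unlist(lapply(fs, `[[`, "vars")))
  a <- Reduce(`*`, lapply(fs, function(f) expand_factor(f, vars, dims)))
  list(vars = vars, a = a)
}

expand_factor <- function(f, vars, dims) {
  a <- f$a
  cur <- f$vars
  miss <- setdiff(vars, cur)
  if (length(miss)) {
    a <- array(a, dim = c(dims[cur], dims[miss]))
    cur <- c(cur, miss)
  }
  perm <- match(vars, cur)
  if (!identical(perm, seq_along(perm)))
    a <- aperm(array(a, dims[cur]), perm)
  array(a, dims[vars])
}

factor_sum_out <- function(f, v, dims) {
  iv <- match(v, f$vars)
  k <- length(f$vars)
  a <- array(f$a, dims[f$vars])
  if (k == 1)
    return(list(vars = character(0), a = sum(a)))
  perm <- c(setdiff(seq_len(k), iv), iv)
  a <- aperm(a, perm)
  dim(a) <- c(prod(dims[f$vars[-iv]]), dims[[v]])
  list(vars = f$vars[-iv], a = array(rowSums(a), dims[f$vars[-iv]]))
}

# ---- brute-force oracle -------------------------------------------------

#' @rdname pedigree_loglik
#' @param max_states Guard for [pedigree_loglik_bruteforce()]: maximum
#'   number of genotype combinations enumerated per marker.
#' @details [pedigree_loglik_bruteforce()] has the identical contract but
#'   sums explicitly over every genotype combination of the untyped
#'   members. It is exponentially slow and intended as an independent
#'   cross-check of the peeling engine on small instances.
#' @export
pedigree_loglik_bruteforce <- function(ped, data, db, model = mutation_model(db),
                                       max_states = 5e6) {
  check_genotype_map(ped, data, db)
  sum(vapply(names(data), function(m) {
    log(marker_likelihood_bruteforce(ped, data[[m]], db, model, m, max_states))
  }, numeric(1)))
}

marker_likelihood_bruteforce <- function(ped, gts, db, model, marker, max_states) {
  gts <- gts[!is.na(gts) & gts != "-"]
  p <- db[[marker]]
  tm <- model$matrices[[marker]]
  n <- length(p)
  ids <- ped$id
  # ordered states per individual: typed -> their 1-2 orderings, untyped -> all
  states <- lapply(ids, function(id) {
    if (id %in% names(gts)) {
      al <- match(gt_alleles(gts[[id]]), names(p))
      unique(c(al[1] + (al[2] - 1) * n, al[2] + (al[1] - 1) * n))
    } else seq_len(n * n)
  })
  names(states) <- ids
  total <- prod(vapply(states, length, numeric(1)))
  if (total > max_states)
    stop("brute-force instance too large: ", format(total), " combinations")
  grid <- as.matrix(expand.grid(states, KEEP.OUT.ATTRS = FALSE))
  pat <- (grid - 1) %% n + 1          # paternal allele per individual
  mat <- (grid - 1) %/% n + 1         # maternal allele per individual
  pr <- rep(1, nrow(grid))
  for (id in ped_founders(ped))
    pr <- pr * p[pat[, id]] * p[mat[, id]]
  trans <- function(parent_col_p, parent_col_m, allele)
    0.5 * (tm[cbind(parent_col_p, allele)] + tm[cbind(parent_col_m, allele)])
  for (id in ped_nonfounders(ped)) {
    r <- ped[ped$id == id, ]
    pr <- pr * trans(pat[, r$fid], mat[, r$fid], pat[, id]) *
               trans(pat[, r$mid], mat[, r$mid], mat[, id])
  }
  sum(pr)
}
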