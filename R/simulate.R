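#' Gene-drop genotype simulation
#'
#' Simulates genotypes for every pedigree member at every marker of the
#' database: founders draw two alleles from the population frequencies
#' (HWE), and each non-founder receives one allele from each parent,
#' sampled uniformly from the parent's two alleles and passed through
#' the mutation model. Members are processed founders-first and markers
#' in database order, so results are reproducible for a fixed seed.
#'
#' @param ped A [pedigree()] (loop-free).
#' @param db A [freq_db()].
#' @param model A [mutation_model()].
#' @param seed Optional integer seed (`set.seed` is called when given);
#'   omit to use the current RNG state.
#' @return A genotype map: named list per marker of named `"a/b"`
#'   genotype vectors covering all members.
#' @export
gene_drop <- function(ped, db, model = mutation_model(db), seed = NULL) {
  if (has_loops(ped))
    stop("pedigree loops unsupported")
  if (!is.null(seed))
    set.seed(seed)
  ord <- peeling_order(ped)
  out <- vector("list", length(db))
  names(out) <- names(db)
  for (m in names(db)) {
    p <- db[[m]]
    tm <- model$matrices[[m]]
    als <- names(p)
    gt <- matrix(NA_character_, length(ord), 2, dimnames = list(ord, NULL))
    for (id in ord) {
      r <- ped[ped$id == id, ]
      if (is.na(r$fid)) {
        gt[id, ] <- sample(als, 2, replace = TRUE, prob = p)
      } else {
        gt[id, 1] <- transmit_allele(gt[r$fid, ], tm, als)
        gt[id, 2] <- transmit_allele(gt[r$mid, ], tm, als)
      }
    }
    out[[m]] <- stats::setNames(paste(gt[, 1], gt[, 2], sep = "/"), ord)
  }
  out
}

transmit_allele <- function(parent_gt, tm, als) {
  a <- parent_gt[sample.int(2, 1)]
  if (all(tm[a, ] == (als == a)))  # identity row: no mutation possible
    return(a)
  sample(als, 1, prob = tm[a, ])
}

#' Simulate a DVI problem conditional on a true assignment
#'
#' Generates fresh genotype data for a DVI problem under a known ground
#' truth: victims paired in `true_assignment` are gene-dropped inside
#' their missing person's family (taking that person's pedigree slot),
#' unmatched victims are drawn as unrelated HWE singletons, and the
#' typed reference members receive their gene-dropped genotypes. The
#' problem structure (IDs, sexes, families, markers) is unchanged.
#'
#' @param problem A [dvi_problem()].
#' @param true_assignment The assignment to condition on.
#' @param seed Optional integer seed.
#' @return A [dvi_problem()] with new `victim_gt` and family reference
#'   genotypes.
#' @export
simulate_problem <- function(problem, true_assignment, seed = NULL) {
  a <- check_assignment(problem, true_assignment)
  if (!is.null(seed))
    set.seed(seed)
  db <- problem$db
  model <- problem$model
  victim_gt <- lapply(db, function(.) character(0))
  families <- problem$families
  for (k in seq_along(families)) {
    fam <- families[[k]]
    sim <- gene_drop(fam$ped, db, model)
    refs <- unique(unlist(lapply(fam$gt, names)))
    pairs <- a[a %in% fam$missing]  # victim -> MP within this family
    for (m in names(db)) {
      families[[k]]$gt[[m]] <- sim[[m]][refs]
      if (length(pairs)) {
        got <- stats::setNames(sim[[m]][unname(pairs)], names(pairs))
        victim_gt[[m]] <- c(victim_gt[[m]], got)
      }
    }
  }
  # unmatched victims: independent HWE singletons
  loose <- names(a)[a == "*"]
  for (m in names(db)) {
    p <- db[[m]]
    for (v in loose) {
      al <- sample(names(p), 2, replace = TRUE, prob = p)
      victim_gt[[m]] <- c(victim_gt[[m]], stats::setNames(paste(al, collapse = "/"), v))
    }
    victim_gt[[m]] <- victim_gt[[m]][intersect(problem$victims$id,
                                               names(victim_gt[[m]]))]
  }
  out <- problem
  out$victim_gt <- victim_gt
  out$families <- families
  out
}

# Restrict a problem to the first k markers of its database.
restrict_markers <- function(problem, markers) {
  if (is.numeric(markers))
    markers <- names(problem$db)[seq_len(markers)]
  out <- problem
  out$db <- structure(problem$db[markers], class = "freqdb")
  out$model <- structure(list(kind = problem$model$kind,
                              rate = problem$model$rate,
                              matrices = problem$model$matrices[markers]),
                         class = "mutation_model")
  out$victim_gt <- problem$victim_gt[intersect(markers, names(problem$victim_gt))]
  for (k in seq_along(out$families))
    out$families[[k]]$gt <-
      problem$families[[k]]$gt[intersect(markers, names(problem$families[[k]]$gt))]
  out
}

#' True-positive-rate experiment
#'
#' Repeatedly simulates profiles conditional on a known true assignment
#' and measures how often each search strategy recovers it, as a
#' function of the number of markers used. The true positive rate (TPR)
#' is reported under two countings: `tpr_unique`, the fraction of
#' replicates whose reported solution is *exactly* the true assignment
#' (a unique terminal solution; the default reading), and `tpr_among`,
#' the fraction where the truth is among tied solutions. For the joint
#' strategy the threshold applies to the top assignment's LR against
#' the null; `joint_best` ignores the threshold and scores the most
#' likely assignment regardless.
#'
#' @param problem A [dvi_problem()] defining structure, frequency
#'   database and mutation model.
#' @param true_assignment The ground-truth assignment.
#' @param n_reps Number of simulation replicates.
#' @param marker_counts Numbers of markers (prefixes of the database
#'   order) at which to evaluate.
#' @param threshold LR threshold `T`.
#' @param seed Integer seed for the whole experiment (one generator,
#'   replicates drawn sequentially).
#' @param algorithms Subset of `c("sequential", "sequential_updated",
#'   "joint", "joint_best")`.
#' @return A data frame with columns `algorithm`, `n_markers`,
#'   `tpr_unique`, `tpr_among`, `n_reps`.
#' @export
tpr_experiment <- function(problem, true_assignment, n_reps = 100,
                           marker_counts = c(1, 5, length(problem$db)),
                           threshold = 1e4, seed = NULL,
                           algorithms = c("sequential", "sequential_updated",
                                          "joint", "joint_best")) {
  stopifnot(n_reps >= 1, length(marker_counts) >= 1,
            max(marker_counts) <= length(problem$db))
  truth <- check_assignment(problem, true_assignment)
  if (!is.null(seed))
    set.seed(seed)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  hit_u <- hit_a <- array(0, c(length(algorithms), length(marker_counts)),
                          dimnames = list(algorithms, marker_counts))
  for (rep in seq_len(n_reps)) {
    simmed <- simulate_problem(problem, truth)
    for (ik in seq_along(marker_counts)) {
      sub <- restrict_markers(simmed, marker_counts[ik])
      res <- score_algorithms(sub, truth, threshold, algorithms)
      hit_u[, ik] <- hit_u[, ik] + res$unique
      hit_a[, ik] <- hit_a[, ik] + res$among
    }
  }
  data.frame(algorithm = rep(algorithms, times = length(marker_counts)),
             n_markers = rep(marker_counts, each = length(algorithms)),
             tpr_unique = as.vector(hit_u) / n_reps,
             tpr_among = as.vector(hit_a) / n_reps,
             n_reps = n_reps)
}

score_algorithms <- function(problem, truth, threshold, algorithms) {
  uniq <- among <- stats::setNames(numeric(length(algorithms)), algorithms)
  key <- paste(truth, collapse = "\r")
  for (alg in intersect(algorithms, c("sequential", "sequential_updated"))) {
    sols <- sequential_search(problem, threshold,
                              update = alg == "sequential_updated")$solutions
    keys <- apply(sols, 1, paste, collapse = "\r")
    uniq[alg] <- as.numeric(length(keys) == 1 && keys == key)
    among[alg] <- as.numeric(key %in% keys)
  }
  if (length(intersect(algorithms, c("joint", "joint_best")))) {
    rk <- joint_search(problem, threshold)
    vict <- problem$victims$id
    top_ll <- rk$loglik[1]
    tied <- which(rk$loglik >= top_ll - TIE_TOL)
    keys <- apply(rk[tied, vict, drop = FALSE], 1, paste, collapse = "\r")
    best_u <- length(keys) == 1 && keys == key
    best_a <- key %in% keys
    if ("joint" %in% algorithms) {
      if (rk$LR[1] >= threshold) {
        uniq["joint"] <- as.numeric(best_u)
        among["joint"] <- as.numeric(best_a)
      } else {
        # below the threshold no identification is reported: the
        # outcome is the empty assignment
        empty <- paste(rep("*", length(vict)), collapse = "\r")
        uniq["joint"] <- among["joint"] <- as.numeric(key == empty)
      }
    }
    if ("joint_best" %in% algorithms) {
      uniq["joint_best"] <- as.numeric(best_u)
      among["joint_best"] <- as.numeric(best_a)
    }
  }
  list(unique = uniq[algorithms], among = among[algorithms])
}
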