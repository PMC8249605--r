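#' Read and write genotype tables
#'
#' Tab-separated tables with a column `individual_id` followed by one
#' column per marker; entries are `"a/b"` genotypes, `"-"` meaning
#' missing.
#'
#' @param path File path.
#' @param db A [freq_db()] used to validate marker names and alleles.
#' @return [read_genotypes()] returns a genotype map (named list per
#'   marker of named genotype vectors).
#' @export
read_genotypes <- function(path, db) {
  if (!file.exists(path))
    stop("genotype file not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (!"individual_id" %in% names(tab))
    stop("genotype file ", path, " must have an individual_id column")
  markers <- setdiff(names(tab), "individual_id")
  bad <- setdiff(markers, names(db))
  if (length(bad))
    stop("genotype file ", path, " references marker '", bad[1],
         "' absent from the frequency database")
  out <- lapply(markers, function(m) {
    g <- stats::setNames(tab[[m]], tab$individual_id)
    g <- g[!is.na(g) & g != "-" & g != ""]
    for (i in seq_along(g)) {
      al <- gt_alleles(g[[i]])
      check_allele(db, m, al)
    }
    g
  })
  stats::setNames(out, markers)
}

#' @rdname read_genotypes
#' @param gt A genotype map to write.
#' @param ids Individuals (row order); defaults to all appearing.
#' @export
write_genotypes <- function(gt, path, ids = NULL) {
  if (is.null(ids))
    ids <- unique(unlist(lapply(gt, names)))
  tab <- data.frame(individual_id = ids, check.names = FALSE)
  for (m in names(gt)) {
    v <- gt[[m]][ids]
    v[is.na(v)] <- "-"
    tab[[m]] <- unname(v)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write DVI problem bundles
#'
#' A bundle is a YAML configuration naming the component files of a DVI
#' problem, with paths relative to the config file:
#'
#' ```yaml
#' pedigrees: families.ped        # PED-style, one family per family_id
#' references: references.tsv     # genotype TSV for typed AM members
#' victims: victims.tsv           # genotype TSV for PM samples
#' frequencies: freqs.tsv         # marker/allele/freq TSV
#' victim_sex: {V1: 1, V2: 1, V3: 2}
#' missing:                       # missing persons per family_id
#'   FAM1: [M1, M2]
#'   FAM2: [M3]
#' mutation: {kind: proportional, rate: 0.001}   # optional
#' ```
#'
#' @param path Path of the YAML config file.
#' @return [read_bundle()] returns a validated [dvi_problem()].
#' @export
read_bundle <- function(path) {
  if (!file.exists(path))
    stop("bundle config not found: ", path)
  cfg <- yaml::read_yaml(path)
  need <- c("pedigrees", "references", "victims", "frequencies",
            "victim_sex", "missing")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("bundle config ", path, " lacks entries: ",
         paste(miss, collapse = ", "))
  dir <- dirname(path)
  rel <- function(f) if (file.exists(f)) f else file.path(dir, f)
  db <- read_freq_db(rel(cfg$frequencies),
                     renormalize = isTRUE(cfg$renormalize))
  peds <- read_ped(rel(cfg$pedigrees))
  ref_gt <- read_genotypes(rel(cfg$references), db)
  victim_gt <- read_genotypes(rel(cfg$victims), db)
  model <- if (is.null(cfg$mutation)) mutation_model(db)
           else mutation_model(db, cfg$mutation$kind,
                               rate = cfg$mutation$rate %||% 0)
  bad <- setdiff(names(cfg$missing), names(peds))
  if (length(bad))
    stop("missing persons declared for unknown family '", bad[1], "'")
  families <- lapply(names(peds), function(f) {
    ped <- peds[[f]]
    gt <- lapply(ref_gt, function(g) g[names(g) %in% ped$id])
    gt <- gt[vapply(gt, length, integer(1)) > 0]
    list(ped = ped, gt = gt,
         missing = as.character(unlist(cfg$missing[[f]])))
  })
  names(families) <- names(peds)
  vict_ids <- names(cfg$victim_sex)
  victims <- data.frame(id = vict_ids,
                        sex = as.integer(unlist(cfg$victim_sex)))
  dvi_problem(victims, victim_gt, families, db, model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_bundle
#' @param problem A [dvi_problem()] to write.
#' @param dir Output directory (created if needed).
#' @return [write_bundle()] invisibly returns the config file path.
#' @export
write_bundle <- function(problem, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_freq_db(problem$db, file.path(dir, "freqs.tsv"))
  fam_names <- names(problem$families)
  if (is.null(fam_names) || any(fam_names == ""))
    fam_names <- paste0("FAM", seq_along(problem$families))
  peds <- stats::setNames(lapply(problem$families, `[[`, "ped"), fam_names)
  write_ped(peds, file.path(dir, "families.ped"))
  ref_gt <- stats::setNames(lapply(names(problem$db), function(m) {
    do.call(c, lapply(problem$families, function(fam) fam$gt[[m]]))
  }), names(problem$db))
  ref_ids <- unique(unlist(lapply(problem$families, function(fam)
    unlist(lapply(fam$gt, names)))))
  write_genotypes(ref_gt, file.path(dir, "references.tsv"), ids = ref_ids)
  write_genotypes(problem$victim_gt, file.path(dir, "victims.tsv"),
                  ids = problem$victims$id)
  cfg <- list(
    pedigrees = "families.ped",
    references = "references.tsv",
    victims = "victims.tsv",
    frequencies = "freqs.tsv",
    victim_sex = stats::setNames(as.list(problem$victims$sex),
                                 problem$victims$id),
    missing = stats::setNames(lapply(problem$families, function(fam)
      as.list(fam$missing)), fam_names))
  if (problem$model$kind != "none")
    cfg$mutation <- list(kind = problem$model$kind, rate = problem$model$rate)
  path <- file.path(dir, "problem.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write analysis results
#'
#' Writes the ranked assignment table, the posterior pairing table and
#' the pairwise LR matrix as deterministic TSV files, plus a JSON
#' companion holding the full-precision numbers. Display rounding in
#' the TSVs: log-likelihoods to 2 decimals, LRs to 3 significant
#' figures (scientific for values over 1000), posteriors to 3
#' decimals.
#'
#' @param ranked A `dvi_ranking` (from [rank_assignments()] or
#'   [joint_search()]), or `NULL` to skip.
#' @param posterior A [posterior_table()], or `NULL`.
#' @param pairwise A [pairwise_lr_matrix()], or `NULL`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(ranked = NULL, posterior = NULL, pairwise = NULL,
                          dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  fmt_lr <- fmt_lr_string
  if (!is.null(ranked)) {
    disp <- as.data.frame(ranked)
    disp$loglik <- sprintf("%.2f", ranked$loglik)
    disp$LR <- fmt_lr(ranked$LR)
    disp$posterior <- sprintf("%.3f", ranked$posterior)
    p <- file.path(dir, "ranked.tsv")
    utils::write.table(disp, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(posterior)) {
    disp <- data.frame(victim = rownames(posterior),
                       round(unclass(posterior), 3), check.names = FALSE)
    p <- file.path(dir, "posterior.tsv")
    utils::write.table(disp, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(pairwise)) {
    disp <- data.frame(victim = rownames(pairwise),
                       apply(pairwise, 2, fmt_lr), check.names = FALSE)
    p <- file.path(dir, "pairwise.tsv")
    utils::write.table(disp, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  full <- list()
  if (!is.null(ranked)) full$ranked <- as.data.frame(ranked)
  if (!is.null(posterior)) {
    full$posterior <- as.data.frame(unclass(posterior))
    full$posterior_victims <- rownames(posterior)
  }
  if (!is.null(pairwise)) {
    full$pairwise <- as.data.frame(unclass(pairwise))
    full$pairwise_victims <- rownames(pairwise)
  }
  p <- file.path(dir, "results.json")
  jsonlite::write_json(full, p, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  paths <- c(paths, p)
  invisible(paths)
}

# LR display: 2 decimals, scientific with 3 significant digits from 1000 up.
fmt_lr_string <- function(x)
  ifelse(x >= 1000, sprintf("%.2e", x), sprintf("%.2f", x))
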