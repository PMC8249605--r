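#' Pedigrees
#'
#' A pedigree is a set of individuals with optional father/mother links
#' and a sex code (1 = male, 2 = female). Every non-founder must have
#' both parents present, the father male and the mother female, and the
#' parent relation must be acyclic. Disconnected components and
#' unconnected singletons are allowed, which is convenient for modelling
#' unrelated individuals jointly.
#'
#' @param id Character vector of unique individual IDs.
#' @param fid,mid Father/mother IDs; `"0"`, `""` or `NA` mean no parent.
#'   A parent must itself be a member.
#' @param sex Integer vector, 1 = male, 2 = female.
#' @return An object of class `ped`: a data frame with columns `id`,
#'   `fid`, `mid`, `sex` (`NA` parent entries for founders).
#' @examples
#' # Parent-child trio
#' trio <- pedigree(id  = c("FA", "MO", "CH"),
#'                  fid = c(NA, NA, "FA"),
#'                  mid = c(NA, NA, "MO"),
#'                  sex = c(1, 2, 1))
#' ped_founders(trio)
#' @export
pedigree <- function(id, fid, mid, sex) {
  id <- as.character(id)
  fid <- as.character(fid)
  mid <- as.character(mid)
  fid[fid %in% c("0", "")] <- NA
  mid[mid %in% c("0", "")] <- NA
  sex <- as.integer(sex)
  if (length(fid) != length(id) || length(mid) != length(id) || length(sex) != length(id))
    stop("id, fid, mid and sex must have equal length")
  if (anyDuplicated(id))
    stop("duplicated individual IDs: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (!all(sex %in% 1:2))
    stop("sex must be coded 1 (male) or 2 (female)")
  if (any(is.na(fid) != is.na(mid)))
    stop("individuals must have either two parents or none: ",
         paste(id[is.na(fid) != is.na(mid)], collapse = ", "))
  for (p in stats::na.omit(unique(c(fid, mid))))
    if (!p %in% id)
      stop("parent '", p, "' is not a pedigree member")
  sex_of <- stats::setNames(sex, id)
  bad <- !is.na(fid) & sex_of[fid] != 1
  if (any(bad))
    stop("father of ", id[bad][1], " is not male")
  bad <- !is.na(mid) & sex_of[mid] != 2
  if (any(bad))
    stop("mother of ", id[bad][1], " is not female")
  p <- structure(data.frame(id = id, fid = fid, mid = mid, sex = sex,
                            stringsAsFactors = FALSE),
                 class = c("ped", "data.frame"))
  if (is.null(peeling_order(p)))
    stop("pedigree parent links are cyclic")
  p
}

#' @rdname pedigree
#' @param ped A `ped` object.
#' @return [ped_founders()] / [ped_nonfounders()] return the IDs of
#'   members without / with parents.
#' @export
ped_founders <- function(ped) ped$id[is.na(ped$fid)]

#' @rdname pedigree
#' @export
ped_nonfounders <- function(ped) ped$id[!is.na(ped$fid)]

#' @export
print.ped <- function(x, ...) {
  cat("Pedigree with", nrow(x), "members (",
      length(ped_founders(x)), "founders )\n")
  print.data.frame(x, ...)
  invisible(x)
}

# Topological order (founders first); NULL if the parent relation is cyclic.
peeling_order <- function(ped) {
  remaining <- ped$id
  placed <- character(0)
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      r <- ped[ped$id == i, ]
      (is.na(r$fid) || r$fid %in% placed) && (is.na(r$mid) || r$mid %in% placed)
    }, logical(1))]
    if (!length(ready)) break
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining)) NULL else placed
}

#' Detect pedigree loops
#'
#' A pedigree has a loop when some individual can be reached from a
#' couple by two disjoint descent paths (e.g. inbreeding or two related
#' founders marrying in twice). Loops are detected on the marriage graph:
#' the bipartite graph of individuals and nuclear-family nodes is a
#' forest exactly when the pedigree is loop-free. The exact peeling
#' engine in [pedigree_loglik()] only supports loop-free pedigrees.
#'
#' @param ped A [pedigree()] object.
#' @return `TRUE` if the pedigree contains a loop.
#' @export
has_loops <- function(ped) {
  fams <- nuclear_families(ped)
  if (!length(fams)) return(FALSE)
  # nodes: individuals + one node per nuclear family; edges: member-family
  edges <- do.call(rbind, lapply(seq_along(fams), function(k) {
    f <- fams[[k]]
    cbind(c(f$father, f$mother, f$children), paste0("..fam", k))
  }))
  nodes <- unique(c(edges[, 1], edges[, 2]))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(match(edges[r, 1], nodes))
    b <- find(match(edges[r, 2], nodes))
    if (a == b) return(TRUE)  # edge closes a cycle
    parent[[a]] <- b
  }
  FALSE
}

# Nuclear families: unique parent couples with their children.
nuclear_families <- function(ped) {
  nf <- ped[!is.na(ped$fid), , drop = FALSE]
  if (!nrow(nf)) return(list())
  key <- paste(nf$fid, nf$mid)
  lapply(split(seq_len(nrow(nf)), factor(key, levels = unique(key))),
         function(i) list(father = nf$fid[i[1]], mother = nf$mid[i[1]],
                          children = nf$id[i]))
}

#' Read and write PED-style pedigree files
#'
#' Whitespace-separated columns `family_id individual_id father_id
#' mother_id sex`, with `0` meaning "no parent" and sex coded 1 = male,
#' 2 = female. [read_ped()] returns one [pedigree()] per family ID.
#'
#' @param path File path.
#' @return A named list of `ped` objects, one per family ID.
#' @export
read_ped <- function(path) {
  if (!file.exists(path))
    stop("pedigree file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("family_id", "id", "fid", "mid", "sex"))
  out <- lapply(split(tab, factor(tab$family_id, levels = unique(tab$family_id))),
                function(d) pedigree(d$id, d$fid, d$mid, d$sex))
  out
}

#' @rdname read_ped
#' @param peds A named list of `ped` objects (names become family IDs).
#' @export
write_ped <- function(peds, path) {
  tab <- do.call(rbind, lapply(names(peds), function(f) {
    p <- peds[[f]]
    data.frame(family_id = f, id = p$id,
               fid = ifelse(is.na(p$fid), "0", p$fid),
               mid = ifelse(is.na(p$mid), "0", p$mid),
               sex = p$sex)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
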