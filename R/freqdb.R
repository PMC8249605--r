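#' Allele frequency databases
#'
#' A frequency database holds, for each marker, the allele labels and their
#' population frequencies. Allele labels are opaque strings, so STR
#' nomenclature such as `"9.3"` is allowed; no numeric interpretation is
#' ever attempted. Frequencies must be strictly positive and sum to 1 per
#' marker.
#'
#' @param markers A named list; each element is a named numeric vector of
#'   allele frequencies for one marker. Names of the vector are the allele
#'   labels. Marker order is preserved.
#' @param renormalize If `TRUE`, per-marker frequency vectors whose sum
#'   deviates from 1 by at most `1e-3` are rescaled to sum to exactly 1.
#'   Larger deviations are always an error.
#'
#' @return An object of class `freqdb`: a named list of named numeric
#'   vectors, one per marker.
#'
#' @examples
#' db <- freq_db(list(L1 = c("1" = 0.4, "2" = 0.6)))
#' db
#'
#' # A panel of equifrequent markers
#' equifreq_db(n_markers = 2, n_alleles = 10)
#' @export
freq_db <- function(markers, renormalize = FALSE) {
  if (!is.list(markers) || is.null(names(markers)) || any(names(markers) == ""))
    stop("`markers` must be a named list of named numeric frequency vectors")
  if (anyDuplicated(names(markers)))
    stop("duplicated marker names: ",
         paste(unique(names(markers)[duplicated(names(markers))]), collapse = ", "))
  out <- lapply(names(markers), function(m) {
    p <- markers[[m]]
    if (!is.numeric(p) || is.null(names(p)) || any(names(p) == ""))
      stop("marker ", m, ": frequencies must be a named numeric vector")
    if (anyDuplicated(names(p)))
      stop("marker ", m, ": duplicated allele labels")
    if (any(p <= 0))
      stop("marker ", m, ": all allele frequencies must be > 0")
    s <- sum(p)
    if (abs(s - 1) > 1e-6) {
      if (renormalize && abs(s - 1) <= 1e-3)
        p <- p / s
      else
        stop("marker ", m, ": allele frequencies sum to ", format(s),
             ", not 1", if (abs(s - 1) <= 1e-3)
               " (set renormalize = TRUE to rescale small deviations)")
    }
    p
  })
  names(out) <- names(markers)
  structure(out, class = "freqdb")
}

#' @param n_markers,n_alleles Panel dimensions for [equifreq_db()]. Markers
#'   are named `<prefix>1, <prefix>2, ...`; alleles are labelled
#'   `"1", "2", ...` and all have frequency `1/n_alleles`.
#' @param prefix Marker name prefix for [equifreq_db()].
#' @rdname freq_db
#' @export
equifreq_db <- function(n_markers = 1, n_alleles = 10, prefix = "L") {
  p <- stats::setNames(rep(1 / n_alleles, n_alleles), as.character(seq_len(n_alleles)))
  freq_db(stats::setNames(rep(list(p), n_markers), paste0(prefix, seq_len(n_markers))))
}

#' @export
print.freqdb <- function(x, ...) {
  cat("Allele frequency database:", length(x), "marker(s)\n")
  for (m in names(x))
    cat("  ", m, ": ", length(x[[m]]), " alleles\n", sep = "")
  invisible(x)
}

db_markers <- function(db) names(db)

db_alleles <- function(db, marker) names(check_marker(db, marker))

check_marker <- function(db, marker) {
  if (!marker %in% names(db))
    stop("unknown marker: ", marker)
  db[[marker]]
}

check_allele <- function(db, marker, allele) {
  p <- check_marker(db, marker)
  bad <- setdiff(allele, names(p))
  if (length(bad))
    stop("unknown allele '", bad[1], "' at marker ", marker)
  invisible(allele)
}

#' Read and write allele frequency tables
#'
#' The on-disk format is a tab-separated table with columns `marker`,
#' `allele` and `freq`. Markers are ordered by first appearance in the
#' file; alleles by row order within marker.
#'
#' @param path Path of the TSV file.
#' @param renormalize Passed on to [freq_db()].
#' @return [read_freq_db()] returns a [freq_db()] object;
#'   [write_freq_db()] invisibly returns `path`.
#' @export
read_freq_db <- function(path, renormalize = FALSE) {
  if (!file.exists(path))
    stop("frequency file not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character")
  need <- c("marker", "allele", "freq")
  if (!all(need %in% names(tab)))
    stop("frequency file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  freqs <- suppressWarnings(as.numeric(tab$freq))
  if (anyNA(freqs))
    stop("frequency file ", path, ": non-numeric freq at line ",
         which(is.na(freqs))[1] + 1L)
  marker_order <- unique(tab$marker)
  lst <- lapply(marker_order, function(m) {
    i <- tab$marker == m
    stats::setNames(freqs[i], tab$allele[i])
  })
  freq_db(stats::setNames(lst, marker_order), renormalize = renormalize)
}

#' @param db A `freqdb` object to write.
#' @rdname read_freq_db
#' @export
write_freq_db <- function(db, path) {
  tab <- do.call(rbind, lapply(names(db), function(m)
    data.frame(marker = m, allele = names(db[[m]]), freq = unname(db[[m]]))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
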