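#' Construct and validate a binary incidence matrix
#'
#' An incidence matrix records which taxa were observed in which samples:
#' rows are samples, columns are taxa, and every cell is 0 (absent) or
#' 1 (present). It is the single input to the pairwise co-occurrence test
#' and to network construction. Multiple specimens of a taxon within one
#' sample are not representable: the matrix is strictly presence/absence.
#'
#' @param x a numeric matrix (or object coercible to one) with unique,
#'   non-empty row names (sample labels) and column names (taxon labels),
#'   all entries 0 or 1.
#' @return an object of class \code{incidence_matrix} (an integer matrix).
#' @examples
#' m <- incidence_matrix(matrix(c(1, 0, 0, 1, 1, 1), nrow = 3, byrow = TRUE,
#'   dimnames = list(paste0("s", 1:3), c("A", "B"))))
#' incidence_counts(m)
#' @export
incidence_matrix <- function(x) {
  x <- as.matrix(x)
  if (length(x) == 0L || nrow(x) < 1L || ncol(x) < 1L) {
    stop("incidence matrix must have at least one sample and one taxon")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("incidence matrix requires sample row names and taxon column names")
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate sample labels: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate taxon labels: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  suppressWarnings(storage <- as.integer(x))
  bad <- which(is.na(storage) | !(storage %in% c(0L, 1L)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(x)) + 1L
    stop(sprintf(
      "non-binary cell at sample '%s', taxon '%s': %s",
      rownames(x)[i], colnames(x)[j], as.character(x[i, j])))
  }
  out <- matrix(storage, nrow = nrow(x), dimnames = dimnames(x))
  class(out) <- c("incidence_matrix", class(out))
  out
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("Incidence matrix: %d samples x %d taxa, %d presences\n",
              nrow(x), ncol(x), sum(x)))
  y <- x
  class(y) <- "matrix"
  if (nrow(y) > 10L || ncol(y) > 10L) {
    cat("(first rows/columns)\n")
    print(y[seq_len(min(10L, nrow(y))), seq_len(min(10L, ncol(y))), drop = FALSE])
  } else {
    print(y)
  }
  invisible(x)
}

#' Read an incidence matrix from CSV or TSV
#'
#' The first row must be a header of taxon labels and the first column must
#' hold sample labels; the remaining cells must parse as 0/1.
#'
#' @param path file path.
#' @param sep field delimiter, \code{","} (default) or \code{"\t"}.
#' @return an \code{\link{incidence_matrix}} preserving file order of rows
#'   and columns.
#' @export
read_incidence_matrix <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty incidence table: ", path)
  m <- as.matrix(df)
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = dimnames(m)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at sample '%s', taxon '%s': %s",
                 rownames(m)[bad[1]], colnames(m)[bad[2]],
                 m[bad[1], bad[2]]))
  }
  incidence_matrix(num)
}

#' Write an incidence matrix to CSV or TSV
#'
#' Output has a header row of taxon labels and a leading \code{sample}
#' column, so that \code{\link{read_incidence_matrix}} round-trips exactly.
#'
#' @param x an \code{\link{incidence_matrix}}.
#' @param path output file path.
#' @param sep field delimiter, \code{","} (default) or \code{"\t"}.
#' @return \code{path}, invisibly.
#' @export
write_incidence_matrix <- function(x, path, sep = ",") {
  x <- incidence_matrix(x)
  df <- data.frame(sample = rownames(x), as.data.frame(unclass(x),
                   check.names = FALSE), check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-taxon incidence counts
#'
#' The incidence of a taxon is the number of samples in which it was
#' recorded, i.e. its column sum.
#'
#' @param x an \code{\link{incidence_matrix}}.
#' @return a named integer vector, one count per taxon, in matrix column order.
#' @export
incidence_counts <- function(x) {
  x <- incidence_matrix(x)
  counts <- colSums(unclass(x))
  storage.mode(counts) <- "integer"
  counts
}

#' Read a taxon metadata table
#'
#' Expects a CSV with columns \code{taxon_id}, \code{phylum}, \code{family}.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return a data frame with one row per taxon.
#' @export
read_taxon_metadata <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("taxon_id", "phylum", "family")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon_id in metadata")
  df
}

#' Incidence totals by phylum or family
#'
#' Sums per-taxon incidences within taxonomic groups, reproducing the
#' per-phylum "Total" rows of a frequency table.
#'
#' @param x an \code{\link{incidence_matrix}}.
#' @param metadata data frame with columns \code{taxon_id}, \code{phylum},
#'   \code{family}; every taxon in \code{x} must appear.
#' @param level \code{"phylum"} or \code{"family"}.
#' @return a data frame with columns \code{group} and \code{total},
#'   ordered by first appearance in the metadata.
#' @export
summarize_by_group <- function(x, metadata, level = c("phylum", "family")) {
  level <- match.arg(level)
  counts <- incidence_counts(x)
  missing <- setdiff(names(counts), metadata$taxon_id)
  if (length(missing)) {
    stop("taxa without metadata: ", paste(missing, collapse = ", "))
  }
  grp <- metadata[[level]][match(names(counts), metadata$taxon_id)]
  totals <- tapply(counts, grp, sum)
  ord <- unique(metadata[[level]][metadata$taxon_id %in% names(counts)])
  data.frame(group = ord, total = as.integer(totals[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}
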