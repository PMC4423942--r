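# Mutation-matrix input/output: binary matrix TSV and MAF-lite call lists.

#' Read a mutation matrix
#'
#' Two dialects are accepted.  \code{"matrix_tsv"}: a tab-separated file
#' whose header row names the patients (first column header is the gene-id
#' column), one gene per row, entries strictly 0/1.  \code{"maf_lite"}: a
#' tab-separated call list with columns \code{gene} and \code{sample};
#' repeated (gene, sample) calls collapse to a single 1 (presence
#' semantics).  Lines starting with \code{#} are skipped.  Malformed input
#' (ragged rows, non-binary entries, duplicate identifiers) raises an error
#' naming the offending line.
#'
#' @param path file path.
#' @param dialect \code{"matrix_tsv"} or \code{"maf_lite"}.
#' @return a \linkS4class{MutationMatrix}.
#' @export
readMutationMatrix <- function(path, dialect = c("matrix_tsv", "maf_lite")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) usageStop(paste("cannot read mutation file:", path))
  if (dialect == "maf_lite") {
    d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("gene", "sample") %in% names(d)))
      dataStop("MAF-lite input needs columns 'gene' and 'sample'")
    genes <- sort(unique(d$gene))
    patients <- sort(unique(d$sample))
    inc <- matrix(0L, length(genes), length(patients),
                  dimnames = list(genes, patients))
    inc[cbind(match(d$gene, genes), match(d$sample, patients))] <- 1L
    return(MutationMatrix(inc))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) < 1L) dataStop("empty mutation matrix file")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  nCol <- length(header)
  patients <- header[-1L]
  if (anyDuplicated(patients)) dataStop("duplicate patient identifiers in header")
  body <- cells[-1L]
  genes <- character(length(body))
  inc <- matrix(0L, length(body), length(patients),
                dimnames = list(NULL, patients))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != nCol)
      dataStop(sprintf("line %d: expected %d fields, found %d",
                       i + 1L, nCol, length(row)))
    vals <- suppressWarnings(as.integer(row[-1L]))
    if (any(is.na(vals)) || !all(vals %in% c(0L, 1L)))
      dataStop(sprintf("line %d: non-binary entry", i + 1L))
    genes[i] <- row[1L]
    inc[i, ] <- vals
  }
  if (anyDuplicated(genes)) dataStop("duplicate gene identifiers")
  rownames(inc) <- genes
  MutationMatrix(inc)
}

#' Write a mutation matrix as TSV
#'
#' Inverse of the \code{"matrix_tsv"} dialect of
#' \code{\link{readMutationMatrix}}.
#'
#' @param m a \linkS4class{MutationMatrix}.
#' @param path output file path.
#' @param idColumn header of the gene-id column.
#' @export
writeMutationMatrix <- function(m, path, idColumn = "gene") {
  stopifnot(is(m, "MutationMatrix"))
  d <- data.frame(rownames(m@incidence), m@incidence,
                  check.names = FALSE, stringsAsFactors = FALSE)
  names(d)[1L] <- idColumn
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a clinical table as TSV
#'
#' @param clinical data.frame with \code{sample_id}, \code{time},
#'   \code{event} (and optionally \code{group}).
#' @param path output file path.
#' @export
writeClinicalTable <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
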