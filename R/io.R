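#' Read a binary genotype matrix from delimited text
#'
#' Expects one row per taxon: the first column is the taxon label, the
#' remaining columns are 0/1 minor-allele indicators.  The field separator is
#' sniffed (tab, comma, or whitespace) and a header line is detected
#' automatically: if every non-label field of the first line is 0 or 1, the
#' file is taken to be headerless.
#'
#' @param path Path to the file.
#' @return An N x M numeric 0/1 matrix with taxon labels as row names.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  fields <- strsplit(trimws(first), if (sep == "") "[[:space:]]+" else sep)[[1L]]
  has_header <- !all(fields[-1L] %in% c("0", "1"))
  d <- utils::read.table(path, header = has_header, sep = sep,
                         stringsAsFactors = FALSE)
  G <- as.matrix(d[, -1L, drop = FALSE])
  rownames(G) <- as.character(d[[1L]])
  storage.mode(G) <- "double"
  G
}

#' Read a phenotype vector from two-column delimited text
#'
#' @param path Path to a file with taxon label in the first column and a
#'   numeric phenotype value in the second.
#' @return A named numeric vector.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  fields <- strsplit(trimws(first), if (sep == "") "[[:space:]]+" else sep)[[1L]]
  has_header <- is.na(suppressWarnings(as.numeric(fields[2L])))
  d <- utils::read.table(path, header = has_header, sep = sep,
                         stringsAsFactors = FALSE)
  y <- as.numeric(d[[2L]])
  names(y) <- as.character(d[[1L]])
  if (anyNA(y)) stop("non-numeric phenotype value in ", path)
  y
}

#' Write a similarity matrix as TSV
#'
#' Writes the full square matrix with taxon labels as both the header row and
#' the first column.  Optional comment lines (prefixed `#`) are written first;
#' the command-line drivers use them to record the seed and parameters.
#'
#' @param K A matrix (typically a `"gsm"`) with dimnames.
#' @param path Output path.
#' @param comments Optional character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_gsm <- function(K, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(c("taxon", colnames(K)), collapse = "\t"), con)
  M <- unclass(K)
  for (i in seq_len(nrow(M)))
    writeLines(paste(c(rownames(M)[i], format(M[i, ], digits = 15L,
                                              scientific = FALSE,
                                              trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a similarity matrix written by [write_gsm()]
#'
#' @param path Path to the TSV file; `#` comment lines are skipped.
#' @return A numeric matrix with taxon labels as dimnames.
#' @export
read_gsm <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(d[, -1L, drop = FALSE])
  rownames(K) <- as.character(d[[1L]])
  storage.mode(K) <- "double"
  K
}

#' Write genotypes in ms-style output format
#'
#' Emits one `//` block with a `segsites:` count, uniform pseudo-positions,
#' and one 0/1 haplotype string per taxon, for cross-checking against
#' coalescent simulators that speak this format.
#'
#' @param G An N x M 0/1 genotype matrix with taxon row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ms <- function(G, path) {
  m <- ncol(G)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("//", paste("segsites:", m),
               paste(c("positions:", format((seq_len(m) - 0.5) / m, digits = 5L)),
                     collapse = " "),
               apply(G, 1L, paste, collapse = "")), con)
  invisible(path)
}
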