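#' Read the bundled synthetic germline segment library
#'
#' The package ships a small, fully synthetic V/J segment library
#' (`inst/extdata/synthetic_germline_segments.fasta`) used by
#' [simulate_repertoire()]. V segments are IMGT-style gapped strings covering
#' FR1-CDR1-FR2-CDR2-FR3, with `.` gap characters inside the CDR spans; the
#' FASTA header encodes `name|locus|type|fr1,cdr1,fr2,cdr2,fr3` where the
#' comma list gives the gapped span length of each region.
#'
#' @param path Path to a segment FASTA in the format above. Defaults to the
#'   bundled library.
#' @return A data.frame with columns `name`, `locus`, `type`, `sequence`
#'   (gapped) and a list-column `spans` (integer vector of the five gapped
#'   region spans; `NULL` for J segments).
#' @export
read_germline_segments <- function(path = system.file("extdata",
    "synthetic_germline_segments.fasta", package = "bcrtrace")) {
  seqs <- Biostrings::readBStringSet(path)
  fields <- strsplit(names(seqs), "|", fixed = TRUE)
  spans <- lapply(fields, function(f) {
    if (length(f) < 4L || !nzchar(f[4])) return(NULL)
    as.integer(strsplit(f[4], ",", fixed = TRUE)[[1]])
  })
  out <- data.frame(
    name = vapply(fields, `[`, "", 1L),
    locus = vapply(fields, `[`, "", 2L),
    type = vapply(fields, `[`, "", 3L),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE
  )
  out$spans <- spans
  out
}

#' Read and write AIRR-style rearrangement tables
#'
#' Tab-separated rearrangement tables following the AIRR Rearrangement
#' conventions (one contig per row). Unknown extra columns are preserved on a
#' round-trip; logical columns `productive` and `complete_vdj` are written as
#' `T`/`F` per AIRR practice.
#'
#' @param x A rearrangement data.frame.
#' @param path File path of the TSV.
#' @return `read_airr()` returns a data.frame; `write_airr()` returns `path`
#'   invisibly.
#' @export
write_airr <- function(x, path) {
  x <- as.data.frame(x)
  for (cn in names(x)) {
    if (is.logical(x[[cn]])) x[[cn]] <- ifelse(x[[cn]], "T", "F")
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_airr
#' @export
read_airr <- function(path) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  for (cn in intersect(c("productive", "complete_vdj", "full_length"), names(x))) {
    x[[cn]] <- x[[cn]] %in% c("T", "TRUE", "true")
  }
  for (cn in intersect(c("duplicate_count", "consensus_count",
                         "fwr1_mutations", "cdr1_mutations", "fwr2_mutations",
                         "cdr2_mutations", "fwr3_mutations"), names(x))) {
    x[[cn]] <- as.integer(x[[cn]])
  }
  x
}

#' Read and write UMI count matrices in Matrix Market triplet format
#'
#' Counts are stored as `matrix.mtx` plus `features.tsv` and `barcodes.tsv`
#' in a directory, the layout emitted by common single-cell quantifiers.
#' Matrices are genes x cells sparse integer counts.
#'
#' @param counts A genes x cells matrix (coerced to `dgCMatrix`) with
#'   dimnames.
#' @param dir Directory to write to / read from (created if missing).
#' @return `read_mtx()` returns a `dgCMatrix` with gene and cell dimnames.
#' @export
write_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- Matrix::Matrix(counts, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  dimnames(m) <- list(readLines(file.path(dir, "features.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  m
}

#' Read and write gene sets in GMT format
#'
#' GMT is tab-separated: set name, description, then member genes. Empty
#' member fields are dropped on read.
#'
#' @param path GMT file path.
#' @param sets Named list of character vectors of gene identifiers.
#' @param descriptions Optional character vector of set descriptions.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) {
    genes <- p[-(1:2)]
    genes[nzchar(genes)]
  })
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a JSON run report
#'
#' Records provenance for a pipeline run: package version, R version, the
#' seeds and parameters of every random stage, and cell counts in/out at each
#' filtering step (e.g. cells dropped as unpaired by [select_contigs()]).
#'
#' @param path Output JSON path.
#' @param ... Named report sections (lists or scalars), typically one per
#'   pipeline stage.
#' @return The report list, invisibly.
#' @export
run_report <- function(path, ...) {
  report <- list(
    package = "bcrtrace",
    package_version = as.character(utils::packageVersion("bcrtrace")),
    r_version = as.character(getRversion()),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(...)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(report)
}
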