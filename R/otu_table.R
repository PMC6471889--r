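#' OTU count table
#'
#' The universal exchange object of the pipeline: a non-negative integer
#' matrix of read counts with features (OTUs/ASVs) in rows and samples in
#' columns. Identifiers must be unique on both margins.
#'
#' @param counts integer matrix, features x samples, all values >= 0.
#' @param feature_ids,sample_ids character vectors; default taken from
#'   `dimnames(counts)`.
#' @return An `otu_table` object (an integer matrix with class attribute).
#' @export
otu_table <- function(counts, feature_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature and sample identifiers are required", call. = FALSE)
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(counts) || length(sample_ids) != ncol(counts))
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id: ",
         feature_ids[duplicated(feature_ids)][1L], call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ",
         sample_ids[duplicated(sample_ids)][1L], call. = FALSE)
  if (length(counts) && (anyNA(counts) || any(counts < 0)))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  if (length(counts) && any(counts != round(counts)))
    stop("counts must be integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(feature_ids, sample_ids)
  structure(counts, class = c("otu_table", "matrix", "array"))
}

#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  otu_table(unclass(x)[i, j, ..., drop = FALSE])
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d features x %d samples, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Read an OTU table from a QIIME-style TSV (or BIOM) file
#'
#' The TSV dialect is UTF-8, tab-separated, first column = feature id,
#' header row = sample ids. A leading `#OTU ID` header cell (QIIME
#' convention) and a `# Constructed from biom file` comment line are
#' accepted. With `format = "biom"` the file is read via the biomformat
#' package (BIOM 2.1), if installed.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("BIOM support requires the 'biomformat' package", call. = FALSE)
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(otu_table(m))
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) && grepl("^# ", lines[1L]) && !grepl("^#OTU", lines[1L]))
    lines <- lines[-1L]  # "# Constructed from biom file"
  if (!length(lines)) stop("empty OTU table file: ", path, call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 1L) stop("malformed header in ", path, call. = FALSE)
  sample_ids <- header[-1L]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  n <- length(body)
  feature_ids <- character(n)
  counts <- matrix(0L, n, length(sample_ids))
  for (i in seq_len(n)) {
    cells <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(cells) != length(header))
      stop(sprintf("row %d has %d cells, expected %d",
                   i, length(cells), length(header)), call. = FALSE)
    feature_ids[i] <- cells[1L]
    vals <- suppressWarnings(as.numeric(cells[-1L]))
    if (anyNA(vals) || any(vals < 0) || any(vals != round(vals)))
      stop(sprintf("non-integer or negative count in row '%s'", cells[1L]),
           call. = FALSE)
    counts[i, ] <- as.integer(vals)
  }
  otu_table(counts, feature_ids, sample_ids)
}

#' Write an OTU table as TSV
#'
#' Deterministic writer: input row/column order preserved, `#OTU ID` first
#' header cell. `read_otu_table(write_otu_table(x, f))` round-trips exactly.
#'
#' @param table an [otu_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("#OTU ID", colnames(table)), collapse = "\t"), con)
  if (nrow(table))
    writeLines(paste(rownames(table),
                     apply(table, 1L, paste, collapse = "\t"),
                     sep = "\t"),
               con)
  invisible(path)
}

#' Per-sample relative abundances
#'
#' @param table an [otu_table()] or a numeric count matrix.
#' @return numeric matrix of proportions; every column sums to 1.
#' @export
to_relative_abundance <- function(table) {
  m <- unclass(as.matrix(table))
  storage.mode(m) <- "double"
  tot <- colSums(m)
  zero <- tot == 0
  if (any(zero))
    stop("sample(s) with zero total count: ",
         paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  sweep(m, 2L, tot, "/")
}

#' Rarefy an OTU table to a fixed depth
#'
#' Subsamples every sample column without replacement (multivariate
#' hypergeometric, drawn as a chain of univariate hypergeometrics), matching
#' the behaviour of QIIME-style rarefaction. Samples whose total count is
#' below `depth` are dropped with a warning.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample (> 0).
#' @param seed RNG seed; same seed, same output.
#' @return An [otu_table()] whose retained columns each sum to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "otu_table"))
  assert_scalar_number(depth, "depth", lower = 1)
  depth <- as.integer(depth)
  tot <- colSums(table)
  keep <- tot >= depth
  if (!any(keep)) stop("no sample reaches depth ", depth, call. = FALSE)
  if (any(!keep))
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(colnames(table)[!keep], collapse = ", "), call. = FALSE)
  m <- unclass(table)[, keep, drop = FALSE]
  out <- with_seed(seed, {
    res <- m
    for (j in seq_len(ncol(m))) res[, j] <- rmvhyper(m[, j], depth)
    res
  })
  otu_table(out, rownames(m), colnames(m))
}

## One multivariate-hypergeometric draw: subsample `depth` reads without
## replacement from a count vector.
rmvhyper <- function(counts, depth) {
  remaining <- sum(counts)
  need <- depth
  out <- integer(length(counts))
  for (i in seq_along(counts)) {
    if (need == 0L) break
    k <- counts[i]
    if (k > 0L) {
      x <- rhyper(1L, k, remaining - k, need)
      out[i] <- x
      need <- need - x
    }
    remaining <- remaining - k
  }
  out
}
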