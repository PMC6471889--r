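## Sample metadata: QIIME2-style sample-metadata TSV, first column
## 'sample-id'. Internal representation is a data.frame with column
## `sample_id` plus the design and environmental columns below. Missing
## measurements are explicit NA (empty cell in the TSV), never silent zeros.

.locations <- c("UASB_bed", "UASB_effluent", "aeration_tank",
                "clarifier_underflow")
.env_params <- c("temperature", "DO", "TOC", "NH4", "PO4", "TA")

#' Read sample metadata (QIIME2-style TSV)
#'
#' First column must be `sample-id` (or `sample_id`); a second-line
#' `#q2:types` row is skipped. Expected columns: `event` (sampling-event
#' index), `location` (one of UASB_bed, UASB_effluent, aeration_tank,
#' clarifier_underflow), `tank` (A/B/C or `none`), and the environmental
#' parameters temperature, DO, TOC, NH4, PO4, TA (units: degrees C for
#' temperature, mg/L otherwise). Empty cells become `NA`.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#q2:types", lines)]
  df <- read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  names(df)[1L] <- "sample_id"
  names(df) <- sub("^sample-id$", "sample_id", names(df))
  validate_metadata(df)
}

validate_metadata <- function(df) {
  req <- c("sample_id", "event", "location", "tank")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id in metadata", call. = FALSE)
  bad <- !df$location %in% .locations
  if (any(bad))
    stop("unknown location value(s): ",
         paste(unique(df$location[bad]), collapse = ", "), call. = FALSE)
  for (p in intersect(.env_params, names(df))) {
    v <- df[[p]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      if (any(!is.na(df[[p]]) & is.na(v)))
        stop("non-numeric value in metadata column ", p, call. = FALSE)
      df[[p]] <- v
    }
    if (any(is.infinite(df[[p]]), na.rm = TRUE))
      stop("non-finite value in metadata column ", p, call. = FALSE)
  }
  df
}

#' Write sample metadata as a QIIME2-style TSV
#'
#' @param metadata data.frame as returned by [read_sample_metadata()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  df <- metadata
  names(df)[names(df) == "sample_id"] <- "sample-id"
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

## Sample ids of the activated-sludge community (aeration tanks plus
## clarifier underflows), the subset all downstream community analyses use.
as_sample_ids <- function(metadata) {
  metadata$sample_id[metadata$location %in%
                       c("aeration_tank", "clarifier_underflow")]
}
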