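# Readers and writers for the plain-text formats used across modules:
# FASTA (via Biostrings), taxonomy sidecar TSV, count tables and sample
# metadata. TSV (tab-separated, UTF-8, '.' decimal) is the canonical
# tabular dialect; CSV is accepted on read.

SUBSTRATE_LEVELS <- c("Wastewater sludge", "Industrial", "Food waste",
                      "Manure", "Other")
TEMPERATURE_LEVELS <- c("Mesophilic", "Thermophilic", "unknown")
TECHNOLOGY_LEVELS <- c("CSTR", "TSAD", "UASB", "Other")
PRIMER_SET_LEVELS <- c("V1-V3", "V4", "V3-V5")

#' Read a FASTA file into a reference data.frame
#'
#' Wrapped and unwrapped line dialects are both accepted; sequences are
#' uppercased on read. Duplicate ids are an error; an empty file returns
#' an empty set with a warning.
#'
#' @param path FASTA file path.
#' @return data.frame: `accession`, `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) {
    warning("empty FASTA: ", path, call. = FALSE)
    return(data.frame(accession = character(0), sequence = character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    abort_input("duplicate FASTA id(s): ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(accession = ids, sequence = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a reference data.frame to FASTA
#'
#' @param records data.frame with `accession` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::DNAStringSet(setNames(toupper(records$sequence),
                                           records$accession))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a taxonomy sidecar table
#'
#' Two tab-separated columns: accession and a semicolon-delimited taxonomy
#' string (with or without `k__` prefixes), no header. Returns the seven
#' rank columns ready to join onto a reference set.
#'
#' @param path File path.
#' @return data.frame: `accession` plus kingdom..species.
#' @export
read_taxonomy <- function(path) {
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character")
  if (ncol(raw) != 2)
    abort_input("taxonomy file must have 2 tab-separated columns")
  paths <- lapply(raw[[2]], parse_taxonomy)
  tax <- as.data.frame(do.call(rbind, lapply(paths, `[[`, "ranks")),
                       stringsAsFactors = FALSE)
  cbind(data.frame(accession = raw[[1]], stringsAsFactors = FALSE), tax)
}

#' Read a sample x feature count table
#'
#' Rectangular TSV/CSV with a header of feature names and the first column
#' holding sample ids. Negative or non-numeric counts are an error.
#'
#' @param path File path.
#' @param sep Field separator (default tab; `","` for CSV).
#' @return Integer matrix, samples x features.
#' @export
read_counts <- function(path, sep = "\t") {
  raw <- read.delim(path, sep = sep, check.names = FALSE,
                    row.names = 1, stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  if (!is.numeric(m))
    abort_input("non-numeric counts in ", path)
  if (any(m < 0)) abort_input("negative counts in ", path)
  if (any(m != round(m))) abort_input("non-integer counts in ", path)
  storage.mode(m) <- "integer"
  m
}

#' Read sample metadata
#'
#' Requires a `sample` column; validates the closed category vocabularies
#' for `substrate`, `temperature`, `technology` and `primer_set` when
#' those columns are present, mapping unrecognised substrate/technology
#' values to `"Other"` and unrecognised temperatures to `"unknown"`.
#'
#' @param path File path.
#' @param sep Field separator (default tab; `","` for CSV).
#' @param counts Optional count matrix; every sample in it must have
#'   exactly one metadata row.
#' @return data.frame of metadata.
#' @export
read_sample_metadata <- function(path, sep = "\t", counts = NULL) {
  meta <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!"sample" %in% names(meta))
    abort_input("metadata must have a 'sample' column")
  if (anyDuplicated(meta$sample))
    abort_input("duplicate metadata rows for sample(s): ",
                paste(unique(meta$sample[duplicated(meta$sample)]),
                      collapse = ", "))
  coerce <- function(x, levels, fallback) {
    ifelse(x %in% levels, x, fallback)
  }
  if ("substrate" %in% names(meta))
    meta$substrate <- coerce(meta$substrate, SUBSTRATE_LEVELS, "Other")
  if ("temperature" %in% names(meta))
    meta$temperature <- coerce(meta$temperature, TEMPERATURE_LEVELS, "unknown")
  if ("technology" %in% names(meta))
    meta$technology <- coerce(meta$technology, TECHNOLOGY_LEVELS, "Other")
  if ("primer_set" %in% names(meta) &&
      !all(meta$primer_set %in% PRIMER_SET_LEVELS))
    abort_input("unknown primer_set value(s) in ", path)
  if (!is.null(counts)) {
    missing <- setdiff(rownames(counts), meta$sample)
    if (length(missing) > 0)
      abort_input("sample(s) missing from metadata: ",
                  paste(missing, collapse = ", "))
  }
  meta
}

#' Write a data.frame as canonical TSV
#'
#' Tab-separated, UTF-8, no quoting, no row names; byte-identical across
#' reruns for identical input.
#'
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_out <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
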