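#' Read a taxa-by-samples count table
#'
#' TSV layout: first column taxon id, remaining header fields sample ids,
#' cells nonnegative integer counts.  Tables exported samples-by-taxa are
#' detected (header overlapping the metadata's sample ids, when supplied)
#' and transposed with a warning.  BIOM 2.x files are read densely through
#' the biomformat package.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param metadata optional metadata tibble (from [read_metadata()]) used
#'   only to detect a transposed TSV.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom"),
                             metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("BIOM input requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(count_table(m))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (nrow(df) == 0L) abort("no taxa: count table has a header row only")
  if (ncol(df) < 2L) abort("no samples: count table has a taxon column only")
  ids <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(num) | num < 0 | num != round(num))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(cells)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(cells)) + 1L
    abort(sprintf(
      "count table cell (%s, %s) = \"%s\" is not a nonnegative integer",
      ids[i], colnames(cells)[j], cells[i, j]))
  }
  m <- matrix(as.integer(num), nrow = nrow(cells),
              dimnames = list(ids, colnames(cells)))
  if (!is.null(metadata)) {
    hdr_hits <- sum(colnames(m) %in% metadata$sample_id)
    row_hits <- sum(rownames(m) %in% metadata$sample_id)
    if (row_hits > hdr_hits) {
      warn("count table looks samples-by-taxa; transposing to taxa-by-samples")
      m <- t(m)
    }
  }
  if (anyDuplicated(rownames(m))) abort("duplicate taxon ids in count table")
  if (anyDuplicated(colnames(m))) abort("duplicate sample ids in count table")
  count_table(m)
}

#' Read sample metadata
#'
#' Required columns: `sample_id`, `subject_id`, `time_point` (integer days),
#' `condition`.  Optional: `pen`, `litter`.  Unknown extra columns are kept
#' but flagged with a warning.
#'
#' @param path TSV file path.
#' @return a tibble, one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  validate_metadata(as_tibble(df))
}

validate_metadata <- function(df) {
  required <- c("sample_id", "subject_id", "time_point", "condition")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("metadata is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), c(required, "pen", "litter"))
  if (length(extra)) {
    warn(sprintf("ignoring unknown metadata column(s): %s",
                 paste(extra, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) abort("duplicated sample_id in metadata")
  tp <- suppressWarnings(as.numeric(df$time_point))
  if (any(is.na(tp) | tp != round(tp))) {
    bad <- df$time_point[is.na(tp) | tp != round(tp)][1L]
    abort(sprintf("time_point \"%s\" is not an integer number of days", bad))
  }
  df$time_point <- as.integer(tp)
  as_tibble(df)
}

#' Read a taxonomy table of 7-rank GreenGenes-style lineages
#'
#' TSV with columns `taxon_id` and a semicolon-delimited lineage string
#' (`k__...;p__...;c__...;o__...;f__...;g__...;s__...`).  Missing trailing
#' ranks are treated as unclassified.
#'
#' @param path TSV file path.
#' @return a tibble with columns `taxon_id`, `kingdom` ... `species`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (!all(c("taxon_id", "lineage") %in% names(df))) {
    abort("taxonomy file must have columns taxon_id and lineage")
  }
  parse_lineages(df$taxon_id, df$lineage)
}

#' @rdname read_taxonomy
#' @param taxon_id character vector of taxon ids.
#' @param lineage character vector of semicolon-delimited lineage strings.
#' @export
parse_lineages <- function(taxon_id, lineage) {
  if (anyDuplicated(taxon_id)) abort("duplicated taxon_id in taxonomy")
  ranks <- taxonomic_ranks()
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  parts <- strsplit(lineage, ";", fixed = TRUE)
  mat <- vapply(parts, function(p) {
    p <- trimws(p)
    if (length(p) > 7L) abort("lineage has more than 7 ranks")
    p <- c(p, rep("", 7L - length(p)))
    out <- sub("^[kpcofgs]__", "", p)
    out[out %in% c("NA", "unclassified")] <- ""
    out
  }, character(7L))
  out <- as_tibble(stats::setNames(as.data.frame(t(mat),
                                                 stringsAsFactors = FALSE),
                                   ranks))
  dplyr::bind_cols(tibble(taxon_id = taxon_id), out)
}

#' The seven taxonomic ranks used throughout
#' @return character vector kingdom ... species.
#' @export
taxonomic_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}
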