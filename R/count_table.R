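#' Construct a taxa-by-samples count table
#'
#' The basic container for amplicon counts: a nonnegative integer matrix
#' with taxa as rows and samples as columns.  Per-sample sequencing depth
#' is the column sum.
#'
#' @param counts numeric matrix of nonnegative integers, taxa in rows.
#' @param taxa_ids,sample_ids optional character vectors; default to the
#'   matrix dimnames.
#' @return a `count_table` object.
#' @examples
#' m <- matrix(c(1L, 2L, 3L, 4L), 2, dimnames = list(c("A", "B"), c("s1", "s2")))
#' ct <- count_table(m)
#' sample_depths(ct)
#' @export
count_table <- function(counts, taxa_ids = rownames(counts),
                        sample_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(taxa_ids) || is.null(sample_ids)) {
    abort("count_table requires taxon and sample ids (dimnames or arguments)")
  }
  taxa_ids <- as.character(taxa_ids)
  sample_ids <- as.character(sample_ids)
  if (length(taxa_ids) != nrow(counts) || length(sample_ids) != ncol(counts)) {
    abort("id lengths do not match matrix dimensions")
  }
  if (anyDuplicated(taxa_ids)) abort("duplicate taxon ids")
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids")
  if (any(!is.finite(counts))) abort("counts must be finite")
  if (any(counts < 0)) abort("counts must be nonnegative")
  if (any(counts != round(counts))) abort("counts must be integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(taxa_ids, sample_ids)
  structure(list(counts = counts), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d taxa x %d samples, total reads %s\n",
              n_taxa(x), n_samples(x),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
taxa_ids <- function(x) rownames(x$counts)

#' @rdname count_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @rdname count_table
#' @export
n_taxa <- function(x) nrow(x$counts)

#' @rdname count_table
#' @export
n_samples <- function(x) ncol(x$counts)

#' Per-sample sequencing depth (column sums)
#' @param x a `count_table`.
#' @return named numeric vector of read depths.
#' @export
sample_depths <- function(x) colSums(x$counts)

# subset keeping the class invariants
subset_count_table <- function(x, taxa = NULL, samples = NULL) {
  m <- x$counts
  if (!is.null(taxa)) m <- m[taxa, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  structure(list(counts = m), class = "count_table")
}

#' @method as_tibble count_table
#' @export
as_tibble.count_table <- function(x, ...) {
  as_tibble(as.data.frame(x$counts), rownames = "taxon_id")
}
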