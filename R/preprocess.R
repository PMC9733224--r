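#' Taxon filter settings for network construction
#'
#' Captures the detection-and-prevalence rule applied before inferring a
#' stratum network: a taxon is kept when it reaches `min_count` reads in at
#' least `global_prevalence` of ALL samples and in at least
#' `stratum_prevalence` of the stratum's own samples.  Both prevalence
#' comparisons are inclusive (>=).
#'
#' @param min_count detection threshold in reads (default 3).
#' @param global_prevalence fraction of all samples (default 0.20).
#' @param stratum_prevalence fraction of the stratum's samples (default 0.50).
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(min_count = 3L, global_prevalence = 0.20,
                        stratum_prevalence = 0.50) {
  if (min_count < 1) abort("min_count must be >= 1")
  for (f in c(global_prevalence, stratum_prevalence)) {
    if (!(f > 0 && f <= 1)) abort("prevalence fractions must be in (0, 1]")
  }
  structure(list(min_count = as.integer(min_count),
                 global_prevalence = global_prevalence,
                 stratum_prevalence = stratum_prevalence),
            class = "filter_spec")
}

#' Define a (time point, condition) stratum
#'
#' @param time_point integer day.
#' @param condition condition label.
#' @param sample_ids the member samples.
#' @return a `stratum` list.
#' @export
stratum <- function(time_point, condition, sample_ids) {
  if (!length(sample_ids)) abort("stratum has no samples")
  structure(list(time_point = as.integer(time_point),
                 condition = as.character(condition),
                 sample_ids = as.character(sample_ids)),
            class = "stratum")
}

#' Enumerate the strata present in a metadata table
#'
#' @param metadata tibble with `sample_id`, `time_point`, `condition`.
#' @return list of [stratum()] objects ordered by condition then time.
#' @export
make_strata <- function(metadata) {
  groups <- dplyr::group_split(
    dplyr::arrange(metadata, .data$condition, .data$time_point),
    .data$condition, .data$time_point)
  purrr::map(groups, ~ stratum(.x$time_point[1L], .x$condition[1L],
                               .x$sample_id))
}

#' Collapse a count table to a taxonomic rank
#'
#' Taxa sharing an identical lineage prefix down to `rank` are summed into
#' one row.  Taxa unclassified at `rank` are grouped by their deepest
#' classified prefix with an explicit `unclassified` suffix, so unnamed
#' genera from different families stay distinct.  Total counts are
#' conserved exactly.
#'
#' @param table a [count_table()].
#' @param lineages taxonomy tibble as from [read_taxonomy()].
#' @param rank one of [taxonomic_ranks()] (default `"genus"`).
#' @return a [count_table()] whose taxa are lineage-prefix labels.
#' @export
agglomerate_to_rank <- function(table, lineages, rank = "genus") {
  ranks <- taxonomic_ranks()
  if (!rank %in% ranks) abort(sprintf("unknown rank: %s", rank))
  miss <- setdiff(taxa_ids(table), lineages$taxon_id)
  if (length(miss)) {
    abort(sprintf("taxa missing from the lineage set: %s",
                  paste(utils::head(miss, 5L), collapse = ", ")))
  }
  depth <- match(rank, ranks)
  lin <- lineages[match(taxa_ids(table), lineages$taxon_id), ]
  keys <- vapply(seq_len(nrow(lin)), function(i) {
    slots <- as.character(lin[i, ranks[seq_len(depth)]])
    slots[is.na(slots)] <- ""
    if (slots[depth] != "") {
      paste(slots, collapse = ";")
    } else {
      classified <- which(slots != "")
      top <- if (length(classified)) max(classified) else 0L
      paste(c(slots[seq_len(top)], "unclassified"), collapse = ";")
    }
  }, character(1L))
  m <- rowsum(table$counts, group = keys, reorder = TRUE)
  count_table(m, taxa_ids = rownames(m), sample_ids = sample_ids(table))
}

#' Apply the detection-and-prevalence taxon filter for one stratum
#'
#' Implements the pre-network filter: keep a taxon when it has at least
#' `min_count` reads in at least `global_prevalence` of all samples of the
#' full table AND in at least `stratum_prevalence` of the stratum's own
#' samples.  Returns the stratum sub-table restricted to surviving taxa.
#'
#' @param table the full [count_table()] (all strata).
#' @param spec a [filter_spec()].
#' @param stratum a [stratum()] whose samples must be present in `table`.
#' @return the filtered stratum [count_table()]; zero surviving taxa is a
#'   valid (warned) outcome.
#' @export
filter_taxa <- function(table, spec = filter_spec(), stratum) {
  if (!length(stratum$sample_ids)) abort("empty stratum")
  missing <- setdiff(stratum$sample_ids, sample_ids(table))
  if (length(missing)) {
    abort(sprintf("stratum samples absent from table: %s",
                  paste(utils::head(missing, 5L), collapse = ", ")))
  }
  detected <- table$counts >= spec$min_count
  n_all <- n_samples(table)
  n_str <- length(stratum$sample_ids)
  hits_all <- rowSums(detected)
  hits_str <- rowSums(detected[, stratum$sample_ids, drop = FALSE])
  # inclusive thresholds; epsilon guards against decimal fractions that are
  # not binary-exact (3/10 vs 0.3) without ever flipping a true boundary
  eps <- 1e-9
  keep <- hits_all >= spec$global_prevalence * n_all - eps &
    hits_str >= spec$stratum_prevalence * n_str - eps
  if (!any(keep)) warn("no taxa survive the filter for this stratum")
  subset_count_table(table, taxa = which(keep),
                     samples = stratum$sample_ids)
}

#' Drop samples below a sequencing-depth threshold
#'
#' Samples whose total read count is strictly less than `min_reads` are
#' removed (a sample at exactly the threshold is kept).  Taxon rows are
#' retained even if all-zero afterwards.
#'
#' @param table a [count_table()].
#' @param min_reads nonnegative integer depth threshold.
#' @return the filtered [count_table()].
#' @export
filter_samples_by_depth <- function(table, min_reads) {
  if (min_reads < 0) abort("min_reads must be >= 0")
  keep <- sample_depths(table) >= min_reads
  if (!any(keep)) warn("all samples fall below the depth threshold")
  subset_count_table(table, samples = which(keep))
}

#' Mean relative abundance per (time point, condition) group
#'
#' Converts each sample to proportions (counts over depth), optionally
#' after collapsing to a taxonomic rank, then averages the member samples
#' of each group without depth weighting.
#'
#' @param table a [count_table()].
#' @param metadata metadata tibble covering the table's samples.
#' @param lineages optional taxonomy tibble; required when `level` is given.
#' @param level optional rank to collapse to before averaging.
#' @return a tibble with `condition`, `time_point`, `taxon_id`,
#'   `mean_proportion`; each group's proportions sum to 1.
#' @export
relative_abundance_group_means <- function(table, metadata, lineages = NULL,
                                           level = NULL) {
  if (!is.null(level)) {
    if (is.null(lineages)) abort("collapsing to a rank requires lineages")
    table <- agglomerate_to_rank(table, lineages, level)
  }
  meta <- dplyr::filter(metadata, .data$sample_id %in% sample_ids(table))
  if (!nrow(meta)) abort("no metadata rows match the table's samples")
  depths <- sample_depths(table)
  zero <- names(depths)[depths == 0]
  if (length(zero)) {
    warn(sprintf("excluding %d zero-depth sample(s)", length(zero)))
    meta <- dplyr::filter(meta, !.data$sample_id %in% zero)
  }
  if (!nrow(meta)) abort("group is empty after removing zero-depth samples")
  props <- sweep(table$counts[, meta$sample_id, drop = FALSE], 2L,
                 depths[meta$sample_id], "/")
  long <- as_tibble(as.data.frame(props), rownames = "taxon_id")
  long <- tidyr::pivot_longer(long, -"taxon_id", names_to = "sample_id",
                              values_to = "proportion")
  long <- dplyr::left_join(long, meta[c("sample_id", "condition",
                                        "time_point")], by = "sample_id")
  dplyr::summarise(
    dplyr::group_by(long, .data$condition, .data$time_point, .data$taxon_id),
    mean_proportion = mean(.data$proportion), .groups = "drop")
}

#' Plug-in Shannon diversity index
#'
#' The maximum-likelihood (plug-in) Shannon entropy
#' \eqn{H = -\sum_i p_i \ln p_i} in nats, with \eqn{0 \ln 0 := 0}.
#'
#' @param proportions nonnegative vector summing to 1 (tolerance 1e-9).
#' @return nonnegative entropy in nats.
#' @examples
#' shannon_plugin(rep(1 / 100, 100)) # log(100)
#' @export
shannon_plugin <- function(proportions) {
  if (any(proportions < 0)) abort("proportions must be nonnegative")
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("proportions must sum to 1 (tolerance 1e-9)")
  }
  p <- proportions[proportions > 0]
  -sum(p * log(p))
}
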