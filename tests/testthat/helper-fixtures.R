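# Small fixtures built in code at test time.

write_tsv_text <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

tiny_count_tsv <- function(...) {
  write_tsv_text(c("taxon\ts1\ts2", "A\t1\t3", "B\t2\t4"), ...)
}

tiny_metadata <- function() {
  tibble::tibble(sample_id = c("s1", "s2"), subject_id = c("P1", "P2"),
                 time_point = c(8L, 8L), condition = c("YL", "YL"))
}

# simple deterministic network fixture from a compact edge description:
# edges given as list(c("A", "B", 1), ...)
net_fix <- function(nodes, edges, time_point, condition = "X") {
  e <- if (length(edges)) {
    tibble::tibble(
      node_u = vapply(edges, `[[`, "", 1),
      node_v = vapply(edges, `[[`, "", 2),
      sign = vapply(edges, function(x) as.numeric(x[[3]]), 0),
      weight = vapply(edges, function(x) as.numeric(x[[3]]) * 0.5, 0),
      stability = 1)
  } else {
    empty_edges()
  }
  signed_network(nodes, e, time_point = time_point, condition = condition)
}

# 12-sample count fixture for exact filter checks: stratum = s1..s6 (d8),
# the other six samples belong to d22.  Expected survivors enumerated by
# hand against min_count = 3, 20% global / 50% stratum prevalence.
filter_fixture <- function() {
  samples <- paste0("s", 1:12)
  mk <- function(...) as.integer(c(...))
  counts <- rbind(
    # detected (>=3) in exactly 3/6 stratum samples (50%) and 3/12
    # globally (25%): kept on the inclusive stratum boundary
    keep_boundary_stratum = mk(3, 4, 5, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    # detected everywhere: kept
    keep_everywhere = mk(rep(5L, 12)),
    # 4/12 globally but only 2/6 (33%) in the stratum: dropped
    drop_stratum = mk(3, 3, 0, 0, 0, 0, 0, 0, 4, 5, 0, 0),
    # counts of 2 everywhere: below min_count, dropped
    drop_mincount = mk(rep(2L, 12)),
    # 2/12 globally (16.7% < 20%): dropped
    drop_global = mk(4, 4, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  colnames(counts) <- samples
  ct <- count_table(counts)
  strat <- stratum(8L, "X", paste0("s", 1:6))
  meta <- tibble::tibble(
    sample_id = samples,
    subject_id = paste0("P", 1:12),
    time_point = c(rep(8L, 6), rep(22L, 6)),
    condition = "X")
  list(table = ct, stratum = strat, meta = meta,
       expected_keep = c("keep_boundary_stratum", "keep_everywhere"))
}
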