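#' A time-ordered series of networks for one condition
#'
#' @param networks list of [signed_network()]s sharing one condition label,
#'   with strictly increasing, unique time points (sorted here).
#' @param condition optional label; defaults to the networks' common label.
#' @return a `network_series`.
#' @export
network_series <- function(networks, condition = NULL) {
  if (length(networks) < 2L) abort("a series needs at least 2 networks")
  conds <- unique(purrr::map_chr(networks, "condition"))
  if (is.null(condition)) condition <- conds[1L]
  if (length(conds) > 1L || !identical(conds, condition)) {
    abort("all networks in a series must share the condition label")
  }
  tps <- unname(purrr::map_int(networks, "time_point"))
  if (anyDuplicated(tps)) abort("duplicate time points in series")
  networks <- networks[order(tps)]
  structure(list(condition = condition, networks = networks,
                 time_points = sort(tps)),
            class = "network_series")
}

#' @export
print.network_series <- function(x, ...) {
  cat(sprintf("<network_series> %s: %d time points (d%s)\n", x$condition,
              length(x$networks), paste(x$time_points, collapse = ", d")))
  invisible(x)
}

# presence matrix: nodes x time points, under the configured rule
presence_matrix <- function(series,
                            presence_rule = c("degree_ge_1", "in_node_set")) {
  presence_rule <- match.arg(presence_rule)
  present_sets <- purrr::map(series$networks, function(net) {
    if (presence_rule == "degree_ge_1") connected_nodes(net) else net$nodes
  })
  nodes <- sort(unique(unlist(present_sets)))
  m <- vapply(present_sets, function(s) nodes %in% s,
              logical(length(nodes)))
  if (length(nodes) == 1L) m <- matrix(m, nrow = 1L)
  dimnames(m) <- list(nodes, paste0("d", series$time_points))
  m
}

#' Classify node persistence across consecutive networks
#'
#' A node is *present* at a time point when it has degree >= 1 in that
#' network (default rule).  A node is *stable* when present at two or more
#' consecutive time points (n_transitions >= 1) and *transient* when
#' present somewhere but never at consecutive time points.  A node
#' *transits the whole experiment* when present at every time point, with
#' the baseline (first) network excluded when `exclude_baseline` is TRUE.
#'
#' @param series a [network_series()].
#' @param exclude_baseline drop the first time point from the
#'   whole-experiment transit requirement (default TRUE, the d0-excluded
#'   convention).
#' @param presence_rule `"degree_ge_1"` (default) or `"in_node_set"`.
#' @return tibble with `node`, `presence_pattern` (e.g. `"011110"`),
#'   `n_transitions`, `classification` (stable/transient),
#'   `transits_whole_experiment`.
#' @export
classify_nodes <- function(series, exclude_baseline = TRUE,
                           presence_rule = c("degree_ge_1", "in_node_set")) {
  m <- presence_matrix(series, presence_rule)
  if (nrow(m) == 0L) {
    return(tibble(node = character(), presence_pattern = character(),
                  n_transitions = integer(), classification = character(),
                  transits_whole_experiment = logical()))
  }
  t_cols <- seq_len(ncol(m))
  transit_cols <- if (exclude_baseline) t_cols[-1L] else t_cols
  n_trans <- if (ncol(m) >= 2L) {
    rowSums(m[, -ncol(m), drop = FALSE] & m[, -1L, drop = FALSE])
  } else {
    rep(0L, nrow(m))
  }
  tibble(node = rownames(m) %||% character(),
         presence_pattern = unname(apply(m, 1L, function(r) {
           paste(as.integer(r), collapse = "")
         })),
         n_transitions = unname(as.integer(n_trans)),
         classification = unname(ifelse(n_trans >= 1L, "stable",
                                        "transient")),
         transits_whole_experiment =
           unname(rowSums(m[, transit_cols, drop = FALSE]) ==
                    length(transit_cols)))
}

#' Classify signed-edge persistence across consecutive networks
#'
#' Each edge occurrence (pair, time point, sign) is classified once:
#' `stable_positive` / `stable_negative` when the same pair is present in
#' the immediately following network with the same sign, otherwise
#' `transient_positive` / `transient_negative`.  A sign flip breaks
#' stability.  Occurrences at the final time point have no following
#' network, are classified transient, and are flagged `terminal` so
#' summaries can exclude them.
#'
#' @param series a [network_series()].
#' @param sign_strict require the same sign at t+1 for stability (default
#'   TRUE); when FALSE, presence of the pair with either sign suffices.
#' @return tibble with `node_u`, `node_v`, `time_point`, `sign`,
#'   `classification`, `terminal`.
#' @export
classify_edges <- function(series, sign_strict = TRUE) {
  T_ <- length(series$networks)
  keyed <- purrr::map(series$networks, function(net) {
    stats::setNames(net$edges$sign, pair_key(net$edges$node_u,
                                             net$edges$node_v))
  })
  rows <- purrr::map_dfr(seq_len(T_), function(t) {
    e <- series$networks[[t]]$edges
    if (!nrow(e)) return(NULL)
    terminal <- t == T_
    stable <- if (terminal) rep(FALSE, nrow(e)) else {
      nxt <- keyed[[t + 1L]]
      k <- pair_key(e$node_u, e$node_v)
      found <- k %in% names(nxt)
      if (sign_strict) found & !is.na(nxt[k]) & nxt[k] == e$sign else found
    }
    tibble(node_u = e$node_u, node_v = e$node_v,
           time_point = series$time_points[t], sign = e$sign,
           classification = paste0(ifelse(stable, "stable_", "transient_"),
                                   ifelse(e$sign > 0, "positive", "negative")),
           terminal = terminal)
  })
  if (!nrow(rows)) {
    rows <- tibble(node_u = character(), node_v = character(),
                   time_point = integer(), sign = double(),
                   classification = character(), terminal = logical())
  }
  rows
}

#' Pairs maintaining the same signed relationship across consecutive networks
#'
#' Returns every pair with at least one stable occurrence, one row per
#' maximal run of consecutive same-sign presence of length >= 2, with the
#' spanned time points.
#'
#' @param series a [network_series()].
#' @param sign_strict as in [classify_edges()].
#' @return tibble with `node_u`, `node_v`, `sign`, `t_start`, `t_end`,
#'   `run_length`.
#' @export
stable_edge_pairs <- function(series, sign_strict = TRUE) {
  tps <- series$time_points
  occ <- purrr::map_dfr(seq_along(series$networks), function(t) {
    e <- series$networks[[t]]$edges
    if (!nrow(e)) return(NULL)
    tibble(node_u = e$node_u, node_v = e$node_v, t_index = t, sign = e$sign)
  })
  empty <- tibble(node_u = character(), node_v = character(),
                  sign = double(), t_start = integer(), t_end = integer(),
                  run_length = integer())
  if (!nrow(occ)) return(empty)
  runs <- dplyr::group_modify(
    dplyr::group_by(occ, .data$node_u, .data$node_v), function(d, key) {
      d <- dplyr::arrange(d, .data$t_index)
      brk <- c(TRUE, diff(d$t_index) != 1L |
                 (sign_strict & d$sign[-1L] != d$sign[-nrow(d)]))
      d$run <- cumsum(brk)
      dplyr::summarise(dplyr::group_by(d, .data$run),
                       sign = .data$sign[dplyr::n()],
                       t_start = tps[min(.data$t_index)],
                       t_end = tps[max(.data$t_index)],
                       run_length = dplyr::n(), .groups = "drop")
    })
  runs <- dplyr::ungroup(runs)
  runs <- dplyr::filter(runs, .data$run_length >= 2L)
  out <- dplyr::select(runs, "node_u", "node_v", "sign", "t_start",
                       "t_end", "run_length")
  out <- dplyr::mutate(out, t_start = as.integer(.data$t_start),
                       t_end = as.integer(.data$t_end),
                       run_length = as.integer(.data$run_length))
  dplyr::arrange(out, .data$node_u, .data$node_v, .data$t_start)
}

#' Build the per-condition persistence report
#'
#' Runs [classify_nodes()], [classify_edges()] and [stable_edge_pairs()]
#' on a series and gathers summary counts.
#'
#' @inheritParams classify_nodes
#' @inheritParams classify_edges
#' @return a `persistence_report` with elements `condition`,
#'   `time_points`, `nodes`, `edges`, `stable_pairs`, `summary`.
#' @export
persistence_report <- function(series, exclude_baseline = TRUE,
                               presence_rule = c("degree_ge_1",
                                                 "in_node_set"),
                               sign_strict = TRUE) {
  nodes <- classify_nodes(series, exclude_baseline, presence_rule)
  edges <- classify_edges(series, sign_strict)
  pairs <- stable_edge_pairs(series, sign_strict)
  non_terminal <- dplyr::filter(edges, !.data$terminal)
  summary <- tibble(
    condition = series$condition,
    n_nodes_observed = nrow(nodes),
    n_stable_nodes = sum(nodes$classification == "stable"),
    n_transient_nodes = sum(nodes$classification == "transient"),
    n_whole_experiment_transit = sum(nodes$transits_whole_experiment),
    n_stable_pairs = nrow(pairs),
    n_stable_positive = sum(non_terminal$classification == "stable_positive"),
    n_stable_negative = sum(non_terminal$classification == "stable_negative"),
    n_transient_positive =
      sum(non_terminal$classification == "transient_positive"),
    n_transient_negative =
      sum(non_terminal$classification == "transient_negative"))
  structure(list(condition = series$condition,
                 time_points = series$time_points,
                 nodes = nodes, edges = edges, stable_pairs = pairs,
                 summary = summary),
            class = "persistence_report")
}

#' @export
print.persistence_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<persistence_report> %s: %d nodes (%d stable, %d transient, %d transit whole experiment); %d stable pair(s)\n",
    x$condition, s$n_nodes_observed, s$n_stable_nodes, s$n_transient_nodes,
    s$n_whole_experiment_transit, s$n_stable_pairs))
  invisible(x)
}

#' @method tidy persistence_report
#' @export
tidy.persistence_report <- function(x, ...) {
  dplyr::mutate(x$nodes, condition = x$condition, .before = 1L)
}

#' @method glance persistence_report
#' @export
glance.persistence_report <- function(x, ...) x$summary

#' Compare persistence between two conditions
#'
#' @param report_a,report_b [persistence_report()]s built over the same
#'   time grid.
#' @return a `condition_comparison` list: `summary` tibble of per-metric
#'   differences (a minus b) and the transit-set differences
#'   (`transit_only_a`, `transit_only_b`, `transit_shared`).
#' @export
compare_conditions <- function(report_a, report_b) {
  if (!identical(report_a$time_points, report_b$time_points)) {
    abort("reports were built over different time grids")
  }
  ta <- report_a$nodes$node[report_a$nodes$transits_whole_experiment]
  tb <- report_b$nodes$node[report_b$nodes$transits_whole_experiment]
  metrics <- c("n_stable_nodes", "n_transient_nodes",
               "n_whole_experiment_transit", "n_stable_pairs",
               "n_stable_positive", "n_stable_negative")
  lab_a <- report_a$condition
  lab_b <- report_b$condition
  if (identical(lab_a, lab_b)) {
    lab_a <- paste0(lab_a, "_a")
    lab_b <- paste0(lab_b, "_b")
  }
  summary <- tibble(
    metric = metrics,
    !!lab_a := as.integer(report_a$summary[1L, metrics]),
    !!lab_b := as.integer(report_b$summary[1L, metrics]),
    difference = as.integer(report_a$summary[1L, metrics]) -
      as.integer(report_b$summary[1L, metrics]))
  structure(list(condition_a = report_a$condition,
                 condition_b = report_b$condition,
                 summary = summary,
                 transit_only_a = sort(setdiff(ta, tb)),
                 transit_only_b = sort(setdiff(tb, ta)),
                 transit_shared = sort(intersect(ta, tb))),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %s vs %s\n", x$condition_a,
              x$condition_b))
  print(x$summary)
  cat(sprintf("transit only in %s: %d; only in %s: %d; shared: %d\n",
              x$condition_a, length(x$transit_only_a), x$condition_b,
              length(x$transit_only_b), length(x$transit_shared)))
  invisible(x)
}
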