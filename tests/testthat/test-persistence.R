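test_that("nodes bridging consecutive networks are stable, others transient", {
  series <- network_series(list(
    net_fix(LETTERS[1:4], list(list("A", "B", 1)), 0),
    net_fix(LETTERS[1:4], list(list("B", "C", 1)), 8),
    net_fix(LETTERS[1:4], list(list("C", "D", 1)), 22)),
    "X")
  nodes <- classify_nodes(series, exclude_baseline = FALSE)
  stable <- nodes$node[nodes$classification == "stable"]
  transient <- nodes$node[nodes$classification == "transient"]
  expect_identical(sort(stable), c("B", "C"))
  expect_identical(sort(transient), c("A", "D"))
  expect_identical(nodes$n_transitions[nodes$node == "B"], 1L)
})

test_that("a node present at all five post-baseline points has 4 transitions", {
  tps <- c(0, 8, 22, 36, 57, 87)
  nets <- lapply(seq_along(tps), function(t) {
    edges <- if (t >= 2) list(list("blautia", "partner", 1)) else list()
    net_fix(c("blautia", "partner", "other"), edges, tps[t])
  })
  series <- network_series(nets, "X")
  nodes <- classify_nodes(series, exclude_baseline = TRUE)
  blautia <- nodes[nodes$node == "blautia", ]
  expect_identical(blautia$n_transitions, 4L)
  expect_identical(blautia$presence_pattern, "011111")
  expect_true(blautia$transits_whole_experiment)
  # with the baseline required instead, it no longer transits throughout
  strict <- classify_nodes(series, exclude_baseline = FALSE)
  expect_false(strict$transits_whole_experiment[strict$node == "blautia"])
})

test_that("an identical network repeated T times makes every node stable", {
  net <- function(tp) net_fix(c("A", "B", "C"),
                              list(list("A", "B", 1), list("B", "C", -1)), tp)
  series <- network_series(lapply(c(0, 8, 22, 36), net), "X")
  nodes <- classify_nodes(series)
  expect_true(all(nodes$classification == "stable"))
  expect_true(all(nodes$n_transitions == 3L))
  expect_identical(sum(nodes$classification == "transient"), 0L)
})

test_that("edge occurrences classify by same-sign presence in the next net", {
  series <- network_series(list(
    net_fix(c("A", "B"), list(list("A", "B", 1)), 0),
    net_fix(c("A", "B"), list(list("A", "B", 1)), 8)), "X")
  e <- classify_edges(series)
  expect_identical(e$classification[e$time_point == 0], "stable_positive")
  expect_identical(e$classification[e$time_point == 8], "transient_positive")
  expect_true(e$terminal[e$time_point == 8])

  flip <- network_series(list(
    net_fix(c("B", "C"), list(list("B", "C", -1)), 0),
    net_fix(c("B", "C"), list(list("B", "C", 1)), 8)), "X")
  ef <- classify_edges(flip)
  expect_identical(ef$classification[ef$time_point == 0],
                   "transient_negative")
  # relaxed sign rule restores stability
  ef2 <- classify_edges(flip, sign_strict = FALSE)
  expect_identical(ef2$classification[ef2$time_point == 0],
                   "stable_negative")

  empty <- network_series(list(net_fix("A", list(), 0),
                               net_fix("A", list(), 8)), "X")
  expect_identical(nrow(classify_edges(empty)), 0L)
})

test_that("stable pairs report maximal consecutive same-sign runs", {
  tps <- c(0, 8, 22, 36, 57)
  nets <- lapply(seq_along(tps), function(t) {
    edges <- list()
    if (t %in% c(4, 5)) edges <- c(edges, list(list("D", "S", 1)))
    if (t %in% c(1, 3)) edges <- c(edges, list(list("P", "F", 1)))
    if (t %in% 1:3) edges <- c(edges, list(list("C", "R", -1)))
    net_fix(c("D", "S", "P", "F", "C", "R"), edges, tps[t])
  })
  series <- network_series(nets, "X")
  pairs <- stable_edge_pairs(series)
  expect_identical(nrow(pairs), 2L)
  ds <- pairs[pairs$node_u == "D", ]
  expect_identical(c(ds$t_start, ds$t_end), c(36L, 57L))
  cr <- pairs[pairs$node_u == "C", ]
  expect_identical(c(cr$t_start, cr$t_end, cr$run_length), c(0L, 22L, 3L))
  expect_false(any(pairs$node_u == "F" | pairs$node_v == "F"))
})

test_that("condition comparison reports count and set differences", {
  mk_series <- function(cond, transit_nodes) {
    nets <- lapply(c(0, 8, 22), function(tp) {
      edges <- lapply(transit_nodes, function(v) list(v, "hub", 1))
      net_fix(c(transit_nodes, "hub"), edges, tp, cond)
    })
    network_series(nets, cond)
  }
  ra <- persistence_report(mk_series("A", c("x", "y", "z")))
  rb <- persistence_report(mk_series("B", "x"))
  cmp <- compare_conditions(ra, rb)
  transit_row <- cmp$summary[cmp$summary$metric == "n_whole_experiment_transit", ]
  expect_identical(transit_row$difference, 2L)
  expect_identical(cmp$transit_only_a, c("y", "z"))
  expect_identical(cmp$transit_only_b, character(0))
  same <- compare_conditions(ra, ra)
  expect_true(all(same$summary$difference == 0L))
  expect_identical(length(same$transit_only_a), 0L)
  rb_shift <- persistence_report(mk_series("B", "x"))
  rb_shift$time_points <- c(0L, 9L, 22L)
  expect_error(compare_conditions(ra, rb_shift), "time grids")
})

test_that("every observed node is exactly one of stable or transient", {
  withr::with_seed(101, {
    for (rep in 1:25) {
      series <- random_series(sample(3:10, 1), sample(2:4, 1),
                              p_edge = runif(1, 0.05, 0.4))
      nodes <- classify_nodes(series)
      observed <- sort(unique(unlist(lapply(series$networks, function(n) {
        c(n$edges$node_u, n$edges$node_v)
      }))))
      expect_identical(sort(nodes$node), observed)
      expect_identical(sum(nodes$classification == "stable") +
                         sum(nodes$classification == "transient"),
                       nrow(nodes))
    }
  })
})

test_that("adding an edge never decreases any node's transition count", {
  withr::with_seed(103, {
    for (rep in 1:10) {
      series <- random_series(6, 3, p_edge = 0.25)
      base <- classify_nodes(series)
      # add one absent edge to a random network
      t_pick <- sample(3, 1)
      net <- series$networks[[t_pick]]
      pool <- t(utils::combn(net$nodes, 2))
      keys <- paste(pool[, 1], pool[, 2])
      used <- paste(net$edges$node_u, net$edges$node_v)
      free <- which(!keys %in% used)
      if (!length(free)) next
      pick <- pool[sample(free, 1), ]
      net$edges <- dplyr::bind_rows(net$edges,
                                    tibble::tibble(node_u = pick[1],
                                                   node_v = pick[2],
                                                   sign = 1, weight = 0.5,
                                                   stability = 1))
      series$networks[[t_pick]] <- signed_network(net$nodes, net$edges,
                                                  net$time_point,
                                                  net$condition)
      after <- classify_nodes(series)
      joined <- merge(base, after, by = "node", all = TRUE)
      joined$n_transitions.x[is.na(joined$n_transitions.x)] <- 0L
      expect_true(all(joined$n_transitions.y >= joined$n_transitions.x))
    }
  })
})

test_that("classifications match the brute-force enumerator on random series", {
  withr::with_seed(107, {
    for (rep in 1:50) {
      series <- random_series(sample(3:10, 1), sample(2:4, 1),
                              p_edge = runif(1, 0.05, 0.5))
      for (rule in c("degree_ge_1", "in_node_set")) {
        got <- classify_nodes(series, presence_rule = rule)
        want <- brute_classify_nodes(series, rule = rule)
        got <- got[order(got$node), ]
        expect_identical(got$node, want$node)
        expect_identical(got$n_transitions, want$n_transitions)
        expect_identical(got$classification, want$classification)
        expect_identical(got$transits_whole_experiment,
                         want$transits_whole_experiment)
      }
      got_e <- classify_edges(series)
      want_e <- brute_classify_edges(series)
      ord <- function(d) d[order(d$node_u, d$node_v, d$time_point), ]
      got_e <- ord(as.data.frame(got_e))
      want_e <- ord(want_e)
      expect_identical(got_e$classification, want_e$classification)
      expect_identical(got_e$terminal, want_e$terminal)
    }
  })
})
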