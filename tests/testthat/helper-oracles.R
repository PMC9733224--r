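# Independent oracles used to validate the package implementations.
# These are deliberately naive (plain loops, exhaustive enumeration) and
# share no code with the functions they check.

# --- brute-force node persistence ------------------------------------------

brute_present <- function(net, rule) {
  if (rule == "degree_ge_1") {
    unique(c(net$edges$node_u, net$edges$node_v))
  } else {
    net$nodes
  }
}

brute_classify_nodes <- function(series, exclude_baseline = TRUE,
                                 rule = "degree_ge_1") {
  sets <- lapply(series$networks, brute_present, rule = rule)
  nodes <- sort(unique(unlist(sets)))
  if (!length(nodes)) {
    return(data.frame(node = character(), presence_pattern = character(),
                      n_transitions = integer(),
                      classification = character(),
                      transits_whole_experiment = logical()))
  }
  T_ <- length(sets)
  out <- lapply(nodes, function(v) {
    pres <- vapply(sets, function(s) v %in% s, logical(1))
    n_trans <- 0L
    for (t in seq_len(T_ - 1L)) {
      if (pres[t] && pres[t + 1L]) n_trans <- n_trans + 1L
    }
    span <- if (exclude_baseline) pres[-1L] else pres
    data.frame(node = v,
               presence_pattern = paste(as.integer(pres), collapse = ""),
               n_transitions = n_trans,
               classification = if (n_trans >= 1L) "stable" else "transient",
               transits_whole_experiment = all(span),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

brute_classify_edges <- function(series, sign_strict = TRUE) {
  T_ <- length(series$networks)
  rows <- list()
  for (t in seq_len(T_)) {
    e <- series$networks[[t]]$edges
    if (!nrow(e)) next
    for (r in seq_len(nrow(e))) {
      u <- min(e$node_u[r], e$node_v[r])
      v <- max(e$node_u[r], e$node_v[r])
      s <- e$sign[r]
      stable <- FALSE
      if (t < T_) {
        nx <- series$networks[[t + 1L]]$edges
        for (q in seq_len(nrow(nx))) {
          nu <- min(nx$node_u[q], nx$node_v[q])
          nv <- max(nx$node_u[q], nx$node_v[q])
          if (nu == u && nv == v && (!sign_strict || nx$sign[q] == s)) {
            stable <- TRUE
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        node_u = u, node_v = v, time_point = series$time_points[t],
        sign = s,
        classification = paste0(if (stable) "stable_" else "transient_",
                                if (s > 0) "positive" else "negative"),
        terminal = t == T_, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(node_u = character(), node_v = character(),
                      time_point = integer(), sign = double(),
                      classification = character(), terminal = logical()))
  }
  do.call(rbind, rows)
}

# random signed network series for property tests
random_series <- function(n_nodes = 10, n_time = 4, p_edge = 0.2,
                          condition = "X") {
  nodes <- paste0("n", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  tps <- sort(sample(0:100, n_time))
  nets <- lapply(seq_len(n_time), function(t) {
    keep <- stats::runif(nrow(pairs)) < p_edge
    k <- sum(keep)
    edges <- tibble::tibble(node_u = pairs[keep, 1], node_v = pairs[keep, 2],
                            sign = sample(c(-1, 1), k, replace = TRUE),
                            weight = stats::runif(k, -1, 1),
                            stability = stats::runif(k))
    edges$weight <- abs(edges$weight) * edges$sign
    signed_network(nodes, edges, time_point = tps[t], condition = condition)
  })
  network_series(nets, condition)
}

# --- exhaustive active-set lasso (p <= 4 variables) ------------------------

# solves min_b 1/2 b' G b - g' b + lambda ||b||_1 by enumerating every
# active set and sign pattern and checking the KKT conditions
lasso_enumerate <- function(G, g, lambda) {
  m <- length(g)
  best <- rep(0, m)
  found <- all(abs(g) <= lambda + 1e-12)
  if (found) return(best)
  for (size in seq_len(m)) {
    for (A in utils::combn(m, size, simplify = FALSE)) {
      signs_grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), size)))
      for (row in seq_len(nrow(signs_grid))) {
        s <- signs_grid[row, ]
        GA <- G[A, A, drop = FALSE]
        sol <- try(solve(GA, g[A] - lambda * s), silent = TRUE)
        if (inherits(sol, "try-error")) next
        if (any(sign(sol) != s)) next
        inactive <- setdiff(seq_len(m), A)
        grad_ok <- TRUE
        if (length(inactive)) {
          resid <- g[inactive] - G[inactive, A, drop = FALSE] %*% sol
          grad_ok <- all(abs(resid) <= lambda + 1e-9)
        }
        if (grad_ok) {
          b <- rep(0, m)
          b[A] <- sol
          return(b)
        }
      }
    }
  }
  best
}

# neighborhood regressions of every column on the others via enumeration,
# on population-standardized columns (the same preprocessing mb_fit states)
oracle_mb <- function(x, lambda) {
  n <- nrow(x); p <- ncol(x)
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(x^2) - mu^2)
  z <- sweep(sweep(x, 2, mu), 2, sd_pop, "/")
  C <- crossprod(z) / n
  B <- matrix(0, p, p)
  for (i in seq_len(p)) {
    oth <- setdiff(seq_len(p), i)
    B[oth, i] <- lasso_enumerate(C[oth, oth, drop = FALSE], C[oth, i], lambda)
  }
  B
}

# --- recovery scoring -------------------------------------------------------

edge_recovery <- function(net, omega) {
  tr <- attr(omega, "truth")
  taxa <- net$nodes
  truth_keys <- paste(taxa[tr$node_u], taxa[tr$node_v])
  est_keys <- paste(net$edges$node_u, net$edges$node_v)
  tp <- sum(est_keys %in% truth_keys)
  precision <- if (length(est_keys)) tp / length(est_keys) else 0
  recall <- tp / length(truth_keys)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  idx <- match(est_keys, truth_keys)
  ok <- !is.na(idx)
  sign_agreement <- if (any(ok)) {
    mean(net$edges$sign[ok] == tr$sign[idx[ok]])
  } else NA_real_
  list(f1 = f1, precision = precision, recall = recall,
       sign_agreement = sign_agreement)
}
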