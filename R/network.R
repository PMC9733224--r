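#' Construct a signed co-occurrence network for one stratum
#'
#' An undirected graph over the taxa of one (time point, condition)
#' stratum.  The node set is fixed by the filtered count table, so nodes
#' of degree zero (isolated taxa) are legitimate members.  Edges carry a
#' sign (+1 proportional, -1 inverse-proportional association), a weight
#' (the signed neighborhood-regression coefficient of larger magnitude)
#' and a stability (StARS selection frequency at the chosen penalty).
#'
#' @param nodes character vector of taxon ids.
#' @param edges tibble with columns `node_u`, `node_v`, `sign`, `weight`,
#'   `stability`; pairs are stored with the lexicographically smaller id
#'   first, and are canonicalized here if not.
#' @param time_point integer day of the stratum.
#' @param condition condition label of the stratum.
#' @return a `signed_network`.
#' @export
signed_network <- function(nodes, edges = empty_edges(),
                           time_point = NA_integer_,
                           condition = NA_character_) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("duplicate node ids")
  edges <- as_tibble(edges)
  needed <- c("node_u", "node_v", "sign", "weight", "stability")
  missing <- setdiff(needed, names(edges))
  if (length(missing)) {
    abort(sprintf("edges lack column(s): %s", paste(missing, collapse = ", ")))
  }
  edges <- edges[needed]
  if (nrow(edges)) {
    if (any(edges$node_u == edges$node_v)) abort("self-loops are not allowed")
    if (!all(c(edges$node_u, edges$node_v) %in% nodes)) {
      abort("edge endpoints must belong to the node set")
    }
    if (!all(edges$sign %in% c(-1, 1))) abort("edge sign must be +1 or -1")
    canon <- canonical_pair(edges$node_u, edges$node_v)
    edges$node_u <- canon$node_u
    edges$node_v <- canon$node_v
    if (anyDuplicated(paste(edges$node_u, edges$node_v))) {
      abort("duplicate edges")
    }
    edges <- dplyr::arrange(edges, .data$node_u, .data$node_v)
  }
  structure(list(nodes = nodes, edges = edges,
                 time_point = as.integer(time_point),
                 condition = as.character(condition)),
            class = "signed_network")
}

#' @rdname signed_network
#' @export
empty_edges <- function() {
  tibble(node_u = character(), node_v = character(),
         sign = double(), weight = double(), stability = double())
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf(
    "<signed_network> %s d%s: %d nodes, %d edges (%d +, %d -), %d connected\n",
    x$condition, x$time_point, length(x$nodes), nrow(x$edges),
    sum(x$edges$sign > 0), sum(x$edges$sign < 0),
    length(connected_nodes(x))))
  invisible(x)
}

# nodes with degree >= 1
connected_nodes <- function(net) {
  sort(unique(c(net$edges$node_u, net$edges$node_v)))
}

#' Tidy a signed network into its edge list
#'
#' @param x a `signed_network`.
#' @param ... unused.
#' @return a tibble of edges annotated with the stratum labels.
#' @method tidy signed_network
#' @export
tidy.signed_network <- function(x, ...) {
  dplyr::bind_cols(
    tibble(condition = rep(x$condition, nrow(x$edges)),
           time_point = rep(x$time_point, nrow(x$edges))),
    x$edges)
}

#' One-row summary of a signed network
#'
#' @param x a `signed_network`.
#' @param ... unused.
#' @return tibble with node, edge, sign and connectivity counts.
#' @method glance signed_network
#' @export
glance.signed_network <- function(x, ...) {
  p <- length(x$nodes)
  tibble(condition = x$condition, time_point = x$time_point,
         n_nodes = p, n_edges = nrow(x$edges),
         n_positive = sum(x$edges$sign > 0),
         n_negative = sum(x$edges$sign < 0),
         n_connected = length(connected_nodes(x)),
         density = if (p > 1) nrow(x$edges) / (p * (p - 1) / 2) else 0)
}

#' Assemble a signed network from neighborhood-selection coefficients
#'
#' Symmetrizes the directed neighborhoods fitted at the StARS-selected
#' penalty into an undirected signed graph.  Under the `"or"` rule an edge
#' exists when either direction has a nonzero coefficient, under `"and"`
#' only when both do.  The edge weight is the coefficient of larger
#' magnitude and the sign is its sign.
#'
#' @param coef p-by-p coefficient matrix, `coef[j, i]` the coefficient of
#'   predictor j in the regression of response i (as from [mb_fit()]).
#' @param rule symmetrization rule, `"or"` (default) or `"and"`.
#' @param stability optional symmetric matrix of StARS selection
#'   frequencies at the selected penalty; defaults to NA.
#' @param nodes node ids; default the matrix dimnames.
#' @param time_point,condition stratum labels.
#' @return a [signed_network()].
#' @export
assemble_network <- function(coef, rule = c("or", "and"), stability = NULL,
                             nodes = rownames(coef),
                             time_point = NA_integer_,
                             condition = NA_character_) {
  rule <- match.arg(rule)
  p <- nrow(coef)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  ij <- which(upper.tri(coef), arr.ind = TRUE)
  a <- coef[cbind(ij[, 2L], ij[, 1L])]  # coef of j in the regression of i
  b <- coef[cbind(ij[, 1L], ij[, 2L])]  # coef of i in the regression of j
  keep <- if (rule == "or") (a != 0 | b != 0) else (a != 0 & b != 0)
  ij <- ij[keep, , drop = FALSE]
  a <- a[keep]; b <- b[keep]
  w <- ifelse(abs(a) >= abs(b), a, b)
  stab <- if (is.null(stability)) rep(NA_real_, length(w)) else {
    stability[ij]
  }
  edges <- tibble(node_u = nodes[ij[, 1L]], node_v = nodes[ij[, 2L]],
                  sign = sign(w), weight = w, stability = stab)
  signed_network(nodes, edges, time_point = time_point, condition = condition)
}
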