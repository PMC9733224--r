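#' Centered log-ratio transform of a count table
#'
#' Adds a pseudocount, logs, and centers each sample by its mean log
#' abundance: \eqn{z_{si} = \ln(x_{si} + c) - \frac{1}{p}\sum_j \ln(x_{sj} + c)}.
#' Rows (samples) of the result sum to zero, which removes the
#' compositional (unit-sum) constraint before covariance-based inference.
#'
#' @param table a [count_table()] with at least 2 taxa and 2 samples.
#' @param pseudocount positive offset `c` added to every count (default 1).
#' @return a samples-by-taxa numeric matrix of class `clr_matrix` with
#'   attributes `pseudocount`, `time_point`, `condition`.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  if (n_taxa(table) < 2L || n_samples(table) < 2L) {
    abort("clr_transform needs at least 2 taxa and 2 samples")
  }
  if (pseudocount <= 0 && any(table$counts == 0L)) {
    abort("pseudocount must be > 0 when zero counts are present")
  }
  lg <- log(t(table$counts) + pseudocount)   # samples x taxa
  z <- lg - rowMeans(lg)
  structure(z, class = c("clr_matrix", "matrix"),
            pseudocount = pseudocount)
}

#' Log-spaced penalty path for neighborhood selection
#'
#' The largest penalty is the maximum absolute off-diagonal entry of the
#' empirical correlation matrix of the CLR columns -- the smallest value at
#' which every lasso neighborhood is empty.  The path descends
#' log-linearly to `lambda_max * min_ratio`.
#'
#' @param clr a [clr_transform()] matrix.
#' @param n_lambda number of penalties (default 20).
#' @param min_ratio ratio of smallest to largest penalty (default 1e-2).
#' @return decreasing positive vector of length `n_lambda`.
#' @export
make_lambda_path <- function(clr, n_lambda = 20L, min_ratio = 1e-2) {
  if (n_lambda < 2L) abort("n_lambda must be >= 2")
  if (!(min_ratio > 0 && min_ratio < 1)) abort("min_ratio must be in (0, 1)")
  C <- safe_correlation(clr)
  lambda_max <- max(abs(C[upper.tri(C)]))
  if (!is.finite(lambda_max) || lambda_max <= 0) {
    abort("degenerate data: no nonzero pairwise correlation")
  }
  exp(seq(log(lambda_max), log(lambda_max * min_ratio),
          length.out = n_lambda))
}

# correlation matrix with constant columns mapped to zero correlation
safe_correlation <- function(x) {
  x <- scale_columns(x)
  crossprod(x) / nrow(x)
}

# population standardization (mean 0, variance 1/n); constant columns
# become all-zero with a warning, which drops them from every regression
scale_columns <- function(x) {
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2
  const <- v <= 1e-12
  if (any(const)) {
    warn(sprintf("%d constant column(s) dropped from regressions",
                 sum(const)))
    v[const] <- 1
  }
  z <- sweep(sweep(x, 2L, mu), 2L, sqrt(v), "/")
  z[, const] <- 0
  z
}

#' Neighborhood-selection lasso fit at one penalty
#'
#' For each taxon i, fits the L1-penalized regression of its CLR column on
#' all other columns (columns standardized internally to zero mean and
#' unit population variance), by cyclic coordinate descent on the Gram
#' matrix with fixed coordinate ordering, convergence tolerance 1e-6 and
#' at most 10^4 sweeps -- so the fit is deterministic given its inputs.
#'
#' @param clr CLR matrix (samples x taxa) or any numeric matrix.
#' @param lambda positive penalty, or a decreasing vector of penalties
#'   (warm-started path).
#' @return for scalar `lambda`, a p-by-p matrix `B` with `B[j, i]` the
#'   coefficient of predictor j in the regression of response i (zero
#'   diagonal); for a vector, a p-by-p-by-K array.
#' @export
mb_fit <- function(clr, lambda) {
  if (any(!is.finite(clr))) abort("non-finite values in CLR matrix")
  if (any(lambda <= 0)) abort("lambda must be positive")
  if (is.unsorted(rev(lambda), strictly = FALSE)) {
    abort("lambda path must be decreasing")
  }
  z <- scale_columns(unclass(clr))
  C <- crossprod(z) / nrow(z)
  coefs <- cd_lasso_path(C, as.numeric(lambda), tol = 1e-6,
                         max_sweeps = 10000L)
  dn <- list(colnames(clr), colnames(clr), NULL)
  if (length(lambda) == 1L) {
    out <- coefs[, , 1L]
    dimnames(out) <- dn[1:2]
    out
  } else {
    dimnames(coefs) <- dn
    coefs
  }
}

#' StARS stability selection over a penalty path
#'
#' Draws `n_subsamples` subsamples without replacement of size
#' `b = min(floor(10 sqrt(n)), floor(0.8 n))`, fits the neighborhood
#' lasso on each over the whole path, and records for every possible edge
#' its selection frequency \eqn{\xi_e(\lambda)}.  The total instability
#' \eqn{D(\lambda)} is the mean of \eqn{2\xi_e(1 - \xi_e)} over all node
#' pairs.  After monotonizing D from the sparse end (running maximum along
#' decreasing lambda), the selected penalty is the smallest lambda -- the
#' densest graph -- whose monotonized instability stays at or below `beta`.
#'
#' @param clr CLR matrix (samples x taxa).
#' @param path decreasing penalty vector from [make_lambda_path()].
#' @param n_subsamples number of subsamples N (default 50).
#' @param beta instability threshold (default 0.05), in (0, 0.5).
#' @param seed integer seed making the subsample draw reproducible.
#' @param rule symmetrization rule used when counting edges (default "or").
#' @return a `stars_result` list: `freq` (p x p x K selection frequencies),
#'   `instability`, `monotone_instability`, `lambda_path`, `lambda_star`,
#'   `index_star`, `b`, `n_subsamples`, `beta`, `seed`.
#' @export
stars_select <- function(clr, path, n_subsamples = 50L, beta = 0.05,
                         seed = 1L, rule = c("or", "and")) {
  rule <- match.arg(rule)
  if (n_subsamples < 2L) abort("n_subsamples must be >= 2")
  if (!(beta > 0 && beta < 0.5)) abort("beta must be in (0, 0.5)")
  n <- nrow(clr)
  p <- ncol(clr)
  b <- min(floor(10 * sqrt(n)), floor(0.8 * n))
  if (b < 3) abort("too few samples for subsampling")
  if (b < 10) {
    inform(sprintf(
      "StARS subsample size b = %d (n = %d): stability estimates are coarse",
      b, n))
  }
  counts <- array(0, dim = c(p, p, length(path)))
  draws <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_subsamples), function(i) sort(sample.int(n, b)))
  })
  for (idx in draws) {
    z <- suppressWarnings(scale_columns(unclass(clr)[idx, , drop = FALSE]))
    C <- crossprod(z) / length(idx)
    coefs <- cd_lasso_path(C, as.numeric(path), tol = 1e-6,
                           max_sweeps = 10000L)
    counts <- counts + symmetrized_support(coefs, and_rule = rule == "and")
  }
  freq <- counts / n_subsamples
  n_pairs <- p * (p - 1) / 2
  instability <- vapply(seq_along(path), function(k) {
    xi <- freq[, , k][upper.tri(freq[, , k])]
    sum(2 * xi * (1 - xi)) / n_pairs
  }, numeric(1L))
  monotone <- cummax(instability)       # path is ordered lambda_max -> min
  ok <- which(monotone <= beta)
  if (length(ok)) {
    index_star <- max(ok)               # densest graph still stable
  } else {
    warn("no penalty meets the instability threshold; selecting lambda_max")
    index_star <- 1L
  }
  structure(list(freq = freq, instability = instability,
                 monotone_instability = monotone,
                 lambda_path = as.numeric(path),
                 lambda_star = path[index_star], index_star = index_star,
                 b = b, n_subsamples = n_subsamples, beta = beta,
                 seed = as.integer(seed)),
            class = "stars_result")
}

#' @export
print.stars_result <- function(x, ...) {
  cat(sprintf(
    "<stars_result> K = %d penalties, N = %d subsamples of b = %d; lambda* = %.4g (D-bar = %.3f <= beta = %.2f)\n",
    length(x$lambda_path), x$n_subsamples, x$b, x$lambda_star,
    x$monotone_instability[x$index_star], x$beta))
  invisible(x)
}

#' Infer the signed co-occurrence network of one stratum
#'
#' The full per-stratum chain: prevalence filter, CLR transform, penalty
#' path, StARS selection, a final neighborhood fit on the complete stratum
#' data at the selected penalty, and symmetrization into a signed network.
#' The node set is every taxon surviving the filter, including taxa that
#' end up with no edges.
#'
#' @param table the full [count_table()] (all strata; the global prevalence
#'   clause is evaluated on it).
#' @param stratum a [stratum()] with at least 4 samples.
#' @param spec a [filter_spec()].
#' @param config an [inference_config()].
#' @return a [signed_network()] with a `stars` attribute holding the
#'   [stars_select()] result (NULL for degenerate strata).
#' @export
infer_stratum_network <- function(table, stratum, spec = filter_spec(),
                                  config = inference_config()) {
  if (length(stratum$sample_ids) < 4L) {
    abort("stratum must have at least 4 samples")
  }
  sub <- filter_taxa(table, spec, stratum)
  if (n_taxa(sub) < 2L) {
    warn("fewer than 2 taxa survive the filter; returning an empty network")
    net <- signed_network(taxa_ids(sub), time_point = stratum$time_point,
                          condition = stratum$condition)
    attr(net, "stars") <- NULL
    return(net)
  }
  seed <- config$seed %||% 1L
  clr <- clr_transform(sub, pseudocount = config$pseudocount)
  path <- make_lambda_path(clr, n_lambda = config$n_lambda,
                           min_ratio = config$lambda_min_ratio)
  st <- stars_select(clr, path, n_subsamples = config$n_subsamples,
                     beta = config$beta, seed = seed, rule = config$sym_rule)
  coef <- mb_fit(clr, st$lambda_star)
  net <- assemble_network(coef, rule = config$sym_rule,
                          stability = st$freq[, , st$index_star],
                          nodes = taxa_ids(sub),
                          time_point = stratum$time_point,
                          condition = stratum$condition)
  attr(net, "stars") <- st
  net
}

#' Inference settings
#'
#' @param pseudocount CLR pseudocount (default 1).
#' @param n_lambda penalty path length (default 20).
#' @param lambda_min_ratio smallest/largest penalty ratio (default 1e-2).
#' @param n_subsamples StARS subsample count N (default 50).
#' @param beta StARS instability threshold (default 0.05).
#' @param sym_rule symmetrization rule, `"or"` (default) or `"and"`.
#' @param seed integer seed for the StARS subsample draw.
#' @return an `inference_config` list.
#' @export
inference_config <- function(pseudocount = 1, n_lambda = 20L,
                             lambda_min_ratio = 1e-2, n_subsamples = 50L,
                             beta = 0.05, sym_rule = c("or", "and"),
                             seed = 1L) {
  structure(list(pseudocount = pseudocount, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 n_subsamples = as.integer(n_subsamples), beta = beta,
                 sym_rule = match.arg(sym_rule), seed = as.integer(seed)),
            class = "inference_config")
}
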