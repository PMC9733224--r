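#' Build a planted sparse precision matrix
#'
#' Support patterns: `chain` links consecutive taxa; `band` links taxa
#' within `band_width` positions; `random` draws edges at the requested
#' density.  Off-diagonal magnitudes are `strength` with random signs,
#' positive definiteness is enforced by diagonal loading until the minimum
#' eigenvalue is at least 0.05, and the matrix is rescaled to unit
#' diagonal (which shrinks off-diagonals but preserves support and sign).
#'
#' @param p number of taxa (>= 3).
#' @param structure `"chain"`, `"band"` or `"random"`.
#' @param density edge density for `random` (fraction of all pairs).
#' @param strength off-diagonal magnitude before rescaling (default 0.3).
#' @param band_width half-width for `band` (default 2).
#' @param seed integer seed for signs and random support.
#' @return a p-by-p `precision` matrix with attribute `truth` (the signed
#'   truth edge tibble: `node_u`, `node_v` as integer indices, `sign`).
#' @export
make_precision <- function(p, structure = c("band", "chain", "random"),
                           density = 0.1, strength = 0.3, band_width = 2L,
                           seed = 1L) {
  structure_ <- match.arg(structure)
  if (p < 3L) abort("p must be >= 3")
  if (strength <= 0) abort("strength must be > 0")
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  support <- switch(structure_,
    chain = pairs[, 2L] - pairs[, 1L] == 1L,
    band = pairs[, 2L] - pairs[, 1L] <= band_width,
    random = {
      n_edges <- round(density * nrow(pairs))
      if (n_edges < 1L) abort("density too low: no edges can be planted")
      sel <- withr::with_seed(as.integer(seed), {
        sample.int(nrow(pairs), n_edges)
      })
      seq_len(nrow(pairs)) %in% sel
    })
  idx <- pairs[support, , drop = FALSE]
  signs <- withr::with_seed(as.integer(seed) + 1L, {
    sample(c(-1, 1), nrow(idx), replace = TRUE)
  })
  omega_from_edges(p, idx, signs, strength)
}

# assemble + regularize a precision matrix from an integer edge list
omega_from_edges <- function(p, idx, signs, strength) {
  omega <- diag(p)
  if (nrow(idx)) {
    omega[idx] <- signs * strength
    omega[idx[, c(2L, 1L), drop = FALSE]] <- signs * strength
  }
  for (i in 1:100) {
    ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev >= 0.05) break
    diag(omega) <- diag(omega) + (0.05 - ev) + 1e-8
    d <- sqrt(diag(omega))
    omega <- omega / tcrossprod(d)
  }
  o <- order(idx[, 1L], idx[, 2L])
  attr(omega, "truth") <- tibble(node_u = as.integer(idx[o, 1L]),
                                 node_v = as.integer(idx[o, 2L]),
                                 sign = -signs[o])
  attr(omega, "strength") <- strength
  class(omega) <- c("precision", "matrix")
  omega
}

#' The signed truth graph encoded by a precision matrix
#'
#' An edge links i and j when the precision entry is nonzero; its sign is
#' the partial-correlation sign, `-sign(omega_ij)` -- the association sign
#' network inference is expected to recover.
#'
#' @param omega a [make_precision()] matrix.
#' @param nodes node labels (default `taxon_1` ...).
#' @param time_point,condition stratum labels for the returned network.
#' @return a [signed_network()] with unit weights and stability 1.
#' @export
truth_network <- function(omega, nodes = default_taxa(nrow(omega)),
                          time_point = NA_integer_,
                          condition = NA_character_) {
  tr <- attr(omega, "truth")
  edges <- tibble(node_u = nodes[tr$node_u], node_v = nodes[tr$node_v],
                  sign = tr$sign, weight = tr$sign,
                  stability = rep(1, nrow(tr)))
  signed_network(nodes, edges, time_point = time_point,
                 condition = condition)
}

default_taxa <- function(p) sprintf("taxon_%03d", seq_len(p))

#' Evolve a planted precision matrix with controlled turnover
#'
#' Removes `round(edge_turnover * E)` of the current edges and plants the
#' same number of new edges on previously empty pairs (random signs); then
#' isolates `round(node_turnover * p)` nodes by deleting all their
#' incident edges.  Positive definiteness is re-enforced.  The returned
#' record lists exactly which edges and nodes changed, so persistence
#' classifications downstream can be checked against known turnover.
#'
#' @param base a [make_precision()] matrix.
#' @param node_turnover,edge_turnover fractions in \[0, 1).
#' @param seed integer seed.
#' @return the evolved `precision` matrix with attributes `truth` and
#'   `turnover` (list: `edges_removed`, `edges_added`, `nodes_isolated`).
#' @export
evolve_truth <- function(base, node_turnover = 0, edge_turnover = 0,
                         seed = 1L) {
  for (f in c(node_turnover, edge_turnover)) {
    if (!(f >= 0 && f < 1)) abort("turnover fractions must be in [0, 1)")
  }
  p <- nrow(base)
  tr <- attr(base, "truth")
  strength <- attr(base, "strength") %||% 0.3
  all_pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  key <- function(i, j) (i - 1L) * p + j
  have <- key(tr$node_u, tr$node_v)
  withr::with_seed(as.integer(seed), {
    n_remove <- round(edge_turnover * nrow(tr))
    remove_idx <- if (n_remove > 0) sample.int(nrow(tr), n_remove) else
      integer()
    free <- which(!key(all_pairs[, 1L], all_pairs[, 2L]) %in% have)
    n_add <- min(n_remove, length(free))
    add_sel <- if (n_add > 0) sample(free, n_add) else integer()
    add_signs <- if (n_add > 0) sample(c(-1, 1), n_add, replace = TRUE) else
      double()
    n_iso <- round(node_turnover * p)
    iso <- if (n_iso > 0) sort(sample.int(p, n_iso)) else integer()
  })
  kept <- tr[setdiff(seq_len(nrow(tr)), remove_idx), ]
  added <- tibble(node_u = as.integer(all_pairs[add_sel, 1L]),
                  node_v = as.integer(all_pairs[add_sel, 2L]),
                  sign = add_signs)
  new_tr <- dplyr::bind_rows(kept, added)
  touch_iso <- new_tr$node_u %in% iso | new_tr$node_v %in% iso
  final_tr <- new_tr[!touch_iso, ]
  # record from the actual support difference, so it is consistent by
  # construction with the before/after truth graphs
  before_keys <- have
  after_keys <- key(final_tr$node_u, final_tr$node_v)
  removed <- tr[!before_keys %in% after_keys, ]
  added_rec <- final_tr[!after_keys %in% before_keys, ]
  omega <- omega_from_edges(p, cbind(final_tr$node_u, final_tr$node_v),
                            -final_tr$sign, strength)
  attr(omega, "turnover") <- list(
    edges_removed = removed, edges_added = added_rec,
    nodes_isolated = as.integer(iso))
  omega
}

#' Sample a logistic-normal-multinomial count table
#'
#' Latent abundances are multivariate normal with covariance the inverse
#' of the planted precision matrix; each sample's composition is the
#' softmax of its latent vector; sequencing depth is log-normal; counts
#' are multinomial at that depth.  This is the model class under which
#' CLR-based sparse precision estimation is consistent.
#'
#' @param omega a [make_precision()] matrix (SPD).
#' @param n_samples number of samples to draw.
#' @param depth_median median sequencing depth (default 60000).
#' @param depth_sdlog log-normal sigma of the depth (default 0.3).
#' @param seed integer seed.
#' @param taxa,sample_ids optional id vectors.
#' @param keep_latent attach the latent Gaussian draw as attribute
#'   `latent` (samples x taxa), e.g. to check the planted partial
#'   correlations directly (default FALSE).
#' @return a [count_table()]; each column sums to its drawn depth.
#' @export
sample_counts <- function(omega, n_samples, depth_median = 60000,
                          depth_sdlog = 0.3, seed = 1L,
                          taxa = default_taxa(nrow(omega)),
                          sample_ids = sprintf("S%03d", seq_len(n_samples)),
                          keep_latent = FALSE) {
  p <- nrow(omega)
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) abort("precision matrix is not positive definite")
  sigma <- chol2inv(chol(omega))
  R <- chol(sigma)
  z <- NULL
  counts <- withr::with_seed(as.integer(seed), {
    z <- matrix(stats::rnorm(n_samples * p), n_samples, p) %*% R
    depth <- pmax(1, round(stats::rlnorm(n_samples, log(depth_median),
                                         depth_sdlog)))
    vapply(seq_len(n_samples), function(s) {
      w <- exp(z[s, ] - max(z[s, ]))
      stats::rmultinom(1L, depth[s], w / sum(w))[, 1L]
    }, integer(p))
  })
  ct <- count_table(counts, taxa_ids = taxa, sample_ids = sample_ids)
  if (keep_latent) attr(ct, "latent") <- z
  ct
}

#' Study design for the synthetic generator
#'
#' Defaults emulate the longitudinal two-arm weaner-pig study shape: two
#' conditions (CL, YL), six sampling days (0, 8, 22, 36, 57, 87 post-
#' weaning), eight subjects per arm, and log-normal sequencing depth with
#' median 60,000 reads.
#'
#' @param conditions condition labels.
#' @param time_points increasing integer days.
#' @param subjects_per_condition subjects per arm (>= 2).
#' @param n_taxa number of taxa p (>= 3).
#' @param structure,density,strength,band_width passed to
#'   [make_precision()] for the initial truth graph of each condition.
#' @param node_turnover,edge_turnover per-step turnover fractions between
#'   consecutive time points.
#' @param depth_median,depth_sdlog sequencing-depth distribution.
#' @param seed master seed.
#' @return a `design_spec` list.
#' @export
design_spec <- function(conditions = c("CL", "YL"),
                        time_points = c(0L, 8L, 22L, 36L, 57L, 87L),
                        subjects_per_condition = 8L, n_taxa = 60L,
                        structure = "band", density = 0.08,
                        strength = 0.3, band_width = 2L,
                        node_turnover = 0.1, edge_turnover = 0.2,
                        depth_median = 60000, depth_sdlog = 0.3,
                        seed = 1L) {
  if (length(time_points) < 2L) abort("need at least 2 time points")
  if (subjects_per_condition < 2L) abort("need at least 2 subjects per arm")
  if (n_taxa < 3L) abort("need at least 3 taxa")
  if (is.unsorted(time_points, strictly = TRUE)) {
    abort("time points must be strictly increasing")
  }
  structure(list(conditions = conditions,
                 time_points = as.integer(time_points),
                 subjects_per_condition = as.integer(subjects_per_condition),
                 n_taxa = as.integer(n_taxa), structure = structure,
                 density = density, strength = strength,
                 band_width = as.integer(band_width),
                 node_turnover = node_turnover,
                 edge_turnover = edge_turnover,
                 depth_median = depth_median, depth_sdlog = depth_sdlog,
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Generate a full synthetic longitudinal study
#'
#' For each condition, plants an initial truth graph and evolves it across
#' the time grid with the design's turnover fractions; samples a
#' logistic-normal-multinomial count table per stratum; and assigns
#' synthetic 7-rank lineages with one unique genus per taxon.  The
#' returned truth series carries, per stratum, the precision matrix, the
#' signed truth network and the turnover record, giving planted ground
#' truth for every downstream stage.
#'
#' @param design a [design_spec()].
#' @return list with `counts` (one [count_table()] spanning all strata),
#'   `metadata`, `taxonomy` (tibbles), and `truth` (per condition: list of
#'   `precisions`, `networks`, `turnover`).
#' @export
generate_study <- function(design = design_spec()) {
  p <- design$n_taxa
  taxa <- default_taxa(p)
  tabs <- list(); metas <- list(); truth <- list()
  for (cond in design$conditions) {
    omegas <- vector("list", length(design$time_points))
    omegas[[1L]] <- make_precision(
      p, structure = design$structure, density = design$density,
      strength = design$strength, band_width = design$band_width,
      seed = derive_seed(design$seed, paste0(cond, "_base")))
    for (t in seq_along(design$time_points)[-1L]) {
      omegas[[t]] <- evolve_truth(
        omegas[[t - 1L]], node_turnover = design$node_turnover,
        edge_turnover = design$edge_turnover,
        seed = derive_seed(design$seed, sprintf("%s_evolve_%d", cond, t)))
    }
    nets <- purrr::map2(omegas, design$time_points, function(om, tp) {
      truth_network(om, nodes = taxa, time_point = tp, condition = cond)
    })
    for (t in seq_along(design$time_points)) {
      tp <- design$time_points[t]
      ids <- sprintf("%s_P%02d_d%02d", cond,
                     seq_len(design$subjects_per_condition), tp)
      tabs[[paste(cond, tp)]] <- sample_counts(
        omegas[[t]], design$subjects_per_condition,
        depth_median = design$depth_median,
        depth_sdlog = design$depth_sdlog,
        seed = derive_seed(design$seed, sprintf("%s_counts_%d", cond, t)),
        taxa = taxa, sample_ids = ids)
      metas[[paste(cond, tp)]] <- tibble(
        sample_id = ids,
        subject_id = sprintf("%s_P%02d", cond,
                             seq_len(design$subjects_per_condition)),
        time_point = rep(tp, length(ids)),
        condition = rep(cond, length(ids)))
    }
    truth[[cond]] <- list(
      precisions = omegas, networks = nets,
      turnover = purrr::map(omegas[-1L], ~ attr(.x, "turnover")))
  }
  counts <- count_table(do.call(cbind, purrr::map(tabs, "counts")))
  list(counts = counts,
       metadata = dplyr::bind_rows(metas),
       taxonomy = synthetic_lineages(taxa),
       truth = truth,
       design = design)
}

# unique synthetic 7-rank lineages, one genus per taxon
synthetic_lineages <- function(taxa) {
  n <- length(taxa)
  phyla <- sprintf("SimPhylum%02d", ((seq_len(n) - 1L) %% 6L) + 1L)
  parse_lineages(taxa, sprintf(
    "k__Bacteria;p__%s;c__SimClass;o__SimOrder;f__SimFamily%02d;g__SimGenus%03d;s__",
    phyla, ((seq_len(n) - 1L) %% 12L) + 1L, seq_len(n)))
}

#' Build the truth network series for one condition
#'
#' Convenience accessor turning the planted truth graphs of
#' [generate_study()] into a [network_series()], e.g. to validate the
#' persistence classifier against known turnover without inference noise.
#'
#' @param study the [generate_study()] result.
#' @param condition condition label.
#' @return a [network_series()] of truth networks.
#' @export
truth_series <- function(study, condition) {
  network_series(study$truth[[condition]]$networks, condition)
}
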