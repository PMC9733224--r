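#' Pipeline configuration
#'
#' Exactly one of `input` (paths to counts/metadata/taxonomy TSVs) or
#' `simulate` (a [design_spec()]) must be active.  The master seed drives
#' every source of randomness; per-stratum seeds are derived from it with
#' [derive_seed()] and recorded in the per-stratum JSON sidecars.
#'
#' @param input NULL, or list with `counts`, `metadata` and optionally
#'   `taxonomy` file paths.
#' @param simulate NULL, or a [design_spec()].
#' @param filter a [filter_spec()].
#' @param inference an [inference_config()] (its `seed` is overridden by
#'   the master seed).
#' @param agglomerate_rank rank to collapse counts to before filtering,
#'   or NULL to skip (default `"genus"` when a taxonomy is available).
#' @param min_depth optional sample-depth discard threshold applied before
#'   anything else (NULL = keep all samples).
#' @param exclude_baseline,presence_rule,sign_strict persistence settings,
#'   see [classify_nodes()] and [classify_edges()].
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            filter = filter_spec(),
                            inference = inference_config(),
                            agglomerate_rank = "genus",
                            min_depth = NULL,
                            exclude_baseline = TRUE,
                            presence_rule = "degree_ge_1",
                            sign_strict = TRUE,
                            seed = 1L) {
  if (is.null(input) == is.null(simulate)) {
    abort("exactly one of `input` and `simulate` must be given")
  }
  structure(list(input = input, simulate = simulate, filter = filter,
                 inference = inference, agglomerate_rank = agglomerate_rank,
                 min_depth = min_depth, exclude_baseline = exclude_baseline,
                 presence_rule = presence_rule, sign_strict = sign_strict,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments; `filter`,
#' `inference` and `simulate` blocks hold the respective constructor
#' arguments.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    input = y$input,
    simulate = if (!is.null(y$simulate)) do.call(design_spec, y$simulate),
    filter = do.call(filter_spec, y$filter %||% list()),
    inference = do.call(inference_config, y$inference %||% list()),
    agglomerate_rank = y$agglomerate_rank %||% "genus",
    min_depth = y$min_depth,
    exclude_baseline = y$exclude_baseline %||% TRUE,
    presence_rule = y$presence_rule %||% "degree_ge_1",
    sign_strict = y$sign_strict %||% TRUE,
    seed = y$seed %||% 1L)
}

#' Run the full network-persistence pipeline
#'
#' Loads (or simulates) the study, optionally collapses to a rank and
#' applies the depth discard, infers one signed network per (time point,
#' condition) stratum, classifies persistence per condition, compares the
#' first two conditions, and writes every artifact plus a manifest with
#' MD5 checksums.  Identical config and seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `networks`, `reports`, `comparison` and
#'   the `manifest` tibble.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$simulate)) {
    design <- config$simulate
    design$seed <- config$seed
    study <- generate_study(design)
    counts <- study$counts; metadata <- study$metadata
    taxonomy <- study$taxonomy
  } else {
    metadata <- read_metadata(config$input$metadata)
    counts <- read_count_table(config$input$counts, metadata = metadata)
    taxonomy <- if (!is.null(config$input$taxonomy)) {
      read_taxonomy(config$input$taxonomy)
    }
  }
  if (!is.null(config$min_depth)) {
    counts <- filter_samples_by_depth(counts, config$min_depth)
    metadata <- dplyr::filter(metadata,
                              .data$sample_id %in% sample_ids(counts))
  }
  if (!is.null(config$agglomerate_rank) && !is.null(taxonomy) &&
      is.null(config$simulate)) {
    counts <- agglomerate_to_rank(counts, taxonomy,
                                  config$agglomerate_rank)
  }
  strata <- make_strata(metadata)
  files <- character()
  networks <- list()
  for (s in strata) {
    label <- sprintf("%s_d%02d", s$condition, s$time_point)
    cfg <- config$inference
    cfg$seed <- derive_seed(config$seed, label)
    net <- infer_stratum_network(counts, s, spec = config$filter,
                                 config = cfg)
    networks[[label]] <- net
    g_path <- file.path(out_dir, paste0("network_", label, ".graphml"))
    e_path <- file.path(out_dir, paste0("network_", label, ".edges.tsv"))
    write_network(net, g_path, "graphml")
    write_network(net, e_path, "edgelist_tsv")
    st <- attr(net, "stars")
    sidecar <- file.path(out_dir, paste0("network_", label, ".json"))
    jsonlite::write_json(list(
      stratum = list(condition = s$condition, time_point = s$time_point,
                     n_samples = length(s$sample_ids)),
      seed = cfg$seed,
      lambda_path = st$lambda_path, instability = st$instability,
      lambda_star = st$lambda_star, b = st$b,
      n_subsamples = st$n_subsamples,
      n_nodes = length(net$nodes), n_edges = nrow(net$edges)),
      sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, g_path, e_path, nodes_companion_path(e_path), sidecar)
  }
  conditions <- unique(metadata$condition)
  reports <- purrr::map(conditions, function(cond) {
    series <- network_series(
      networks[purrr::map_chr(networks, "condition") == cond], cond)
    persistence_report(series, exclude_baseline = config$exclude_baseline,
                       presence_rule = config$presence_rule,
                       sign_strict = config$sign_strict)
  })
  names(reports) <- conditions
  rep_path <- file.path(out_dir, "persistence_report.json")
  write_persistence_report(reports, rep_path)
  files <- c(files, rep_path, sub("\\.json$", ".nodes.tsv", rep_path),
             sub("\\.json$", ".edges.tsv", rep_path))
  comparison <- NULL
  if (length(conditions) >= 2L) {
    comparison <- compare_conditions(reports[[1L]], reports[[2L]])
    cmp_path <- file.path(out_dir, "condition_comparison.json")
    jsonlite::write_json(list(
      condition_a = comparison$condition_a,
      condition_b = comparison$condition_b,
      summary = comparison$summary,
      transit_only_a = comparison$transit_only_a,
      transit_only_b = comparison$transit_only_b,
      transit_shared = comparison$transit_shared),
      cmp_path, dataframe = "columns", auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    files <- c(files, cmp_path)
  }
  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)),
                     bytes = unname(file.size(files)))
  manifest <- dplyr::arrange(manifest, .data$file)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(networks = networks, reports = reports,
                 comparison = comparison, manifest = manifest))
}
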