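#' Read a per-sample label file
#'
#' Two-column delimited file with a header: sample id, category.
#'
#' @param path Path to a TSV/CSV file.
#' @return Named character vector, sample -> category.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(x) == 0) stop("label file is empty: ", path, call. = FALSE)
  if (ncol(x) < 2) stop("label file needs (sample, category) columns",
                        call. = FALSE)
  as_label_vector(x, basename(path))
}

#' Assemble a pipeline configuration
#'
#' @param expression_path Path to the expression TSV/CSV.
#' @param panel_path Path to a panel file; `NULL` uses [default_panel()].
#' @param units Units of the expression file (`"TPM"`, `"log2TPM"`,
#'   `"zscore"`).
#' @param log_transform Log2(v+1)-transform TPM before z-scoring.
#' @param k Fixed cluster count; `NULL` selects k by the elbow rule.
#' @param k_max Maximum k considered (default 10).
#' @param restarts k-means restarts (default 25).
#' @param n_sim Chi-square Monte-Carlo replicates (default 2000).
#' @param seed Seed for every random step (default 0).
#' @param labels_path Optional per-sample category file (e.g. subtypes);
#'   triggers the cluster-association stage.
#' @param out_dir Output directory.
#' @return A `run_config` list (paths validated).
#' @export
run_config <- function(expression_path, panel_path = NULL, units = "TPM",
                       log_transform = TRUE, k = NULL, k_max = 10,
                       restarts = 25, n_sim = 2000, seed = 0,
                       labels_path = NULL, out_dir = "wescore_run") {
  if (!file.exists(expression_path)) {
    stop("expression file not found: ", expression_path, call. = FALSE)
  }
  if (!is.null(panel_path) && !file.exists(panel_path)) {
    stop("panel file not found: ", panel_path, call. = FALSE)
  }
  if (!is.null(labels_path) && !file.exists(labels_path)) {
    stop("label file not found: ", labels_path, call. = FALSE)
  }
  if (k_max < 3) stop("k_max must be at least 3", call. = FALSE)
  if (n_sim < 1) stop("n_sim must be at least 1", call. = FALSE)
  structure(list(
    expression_path = expression_path, panel_path = panel_path,
    units = match.arg(units, c("TPM", "log2TPM", "zscore")),
    log_transform = log_transform, k = k, k_max = k_max,
    restarts = restarts, n_sim = n_sim, seed = seed,
    labels_path = labels_path, out_dir = out_dir
  ), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  do.call(run_config, yaml::read_yaml(path))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the scoring, clustering and association pipeline end to end
#'
#' Stages: read panel and expression, per-gene z-scores, raw and scaled WE
#' scores, WSS curve, elbow-based k selection (unless `k` is fixed),
#' k-means clustering with ordered labels, and — when a label file is
#' configured — the cluster-by-label contingency table with Monte-Carlo
#' chi-square. Writes `we_scores_raw.tsv`, `we_scores_scaled.tsv`,
#' `zscore_provenance.json`, `wss_curve.tsv`, `clusters.tsv`,
#' `cluster_summary.tsv`, optional `chisq_result.json`, and a
#' `manifest.json` recording the package version, seeds, input checksums
#' and the chosen k. Reruns with the same config and inputs are
#' byte-identical.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @return The manifest, invisibly, with the fitted objects attached as
#'   attribute `results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- if (is.null(config$panel_path)) default_panel(quiet = TRUE) else
    read_panel(config$panel_path)
  expr <- read_expression(config$expression_path, units = config$units)
  z <- zscore_genes(expr, log = config$log_transform)
  scores <- scale_we(we_scores(z, panel))
  out <- function(f) file.path(config$out_dir, f)
  readr::write_tsv(
    tibble::as_tibble(scores$raw, rownames = "pathway"),
    out("we_scores_raw.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble::as_tibble(scores$scaled, rownames = "pathway"),
    out("we_scores_scaled.tsv"), progress = FALSE)
  write_json_out(list(
    provenance = attr(z, "provenance"),
    degenerate_genes = as.list(attr(z, "degenerate")),
    unmatched_panel_genes = as.list(scores$unmatched)
  ), out("zscore_provenance.json"))
  sol <- we_cluster(scores, k = config$k, k_max = config$k_max,
                    restarts = config$restarts, seed = config$seed)
  curve <- if (is.null(sol$curve)) {
    wss_curve(scores, k_max = config$k_max, restarts = config$restarts,
              seed = config$seed)
  } else sol$curve
  readr::write_tsv(tibble::tibble(k = curve$k, wss = curve$wss),
                   out("wss_curve.tsv"), progress = FALSE)
  readr::write_tsv(
    dplyr::mutate(sol$assignments, label = as.character(.data$label)),
    out("clusters.tsv"), progress = FALSE)
  readr::write_tsv(cluster_summary(sol, scores), out("cluster_summary.tsv"),
                   progress = FALSE)
  chisq <- NULL
  if (!is.null(config$labels_path)) {
    labels <- read_labels(config$labels_path)
    cluster_labels <- stats::setNames(as.character(sol$assignments$label),
                                      sol$assignments$sample)
    tab <- contingency(cluster_labels, labels)
    chisq <- chisq_mc(tab, n_sim = config$n_sim, seed = config$seed)
    write_json_out(list(
      statistic = chisq$statistic, df = chisq$df,
      p_asymptotic = chisq$p_asymptotic, p_simulated = chisq$p_simulated,
      n_sim = chisq$n_sim, seed = chisq$seed,
      observed = as.data.frame(tidy.chisq_mc(chisq))
    ), out("chisq_result.json"))
  }
  manifest <- list(
    package = "wescore",
    version = as.character(utils::packageVersion("wescore")),
    seed = config$seed,
    units = config$units,
    log_transform = config$log_transform,
    input_checksums = list(
      expression = unname(tools::md5sum(config$expression_path)),
      panel = if (is.null(config$panel_path)) "packaged-default" else
        unname(tools::md5sum(config$panel_path)),
      labels = if (is.null(config$labels_path)) NULL else
        unname(tools::md5sum(config$labels_path))
    ),
    n_samples = ncol(expr),
    n_genes = nrow(expr),
    k = sol$k,
    k_fixed = !is.null(config$k),
    cluster_sizes = as.list(table(sol$assignments$label)),
    outputs = list.files(config$out_dir)
  )
  manifest$outputs <- sort(unique(c(manifest$outputs, "manifest.json")))
  write_json_out(manifest, out("manifest.json"))
  attr(manifest, "results") <- list(panel = panel, zscores = z,
                                    scores = scores, solution = sol,
                                    curve = curve, chisq = chisq)
  invisible(manifest)
}
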