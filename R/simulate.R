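#' SCLC subtype vocabulary
#'
#' @return Character vector of the four transcriptional subtypes.
#' @export
sclc_subtypes <- function() c("SCLC-A", "SCLC-N", "SCLC-P", "SCLC-I")

default_pathway_effects <- function(pathways, delta) {
  k <- 3
  eff <- matrix(0, nrow = k, ncol = length(pathways),
                dimnames = list(c("Low", "Intermediate", "High"), pathways))
  eff["Low", ] <- -delta
  # hybrid intermediate signature: upregulation of a deterministic half of
  # the pathways (the first ceiling(p/2) in panel order)
  half <- seq_len(ceiling(length(pathways) / 2))
  eff["Intermediate", half] <- delta
  eff["High", ] <- delta
  eff
}

default_subtype_probs <- function() {
  probs <- rbind(
    Low          = c(0.30, 0.10, 0.30, 0.30),
    Intermediate = c(0.55, 0.15, 0.15, 0.15),
    High         = c(0.25, 0.55, 0.10, 0.10)
  )
  colnames(probs) <- sclc_subtypes()
  probs
}

#' Specify a synthetic cohort
#'
#' Parameters of the generator: planted cluster count and proportions,
#' per-pathway mean shifts in z-units, background gene count, Gaussian noise
#' level, cluster-conditional subtype frequencies and a monotone covariate.
#' Defaults encode the cohort structure the scoring-and-clustering pipeline
#' assumes: three clusters in equal proportions; the Low cluster shifted
#' down by `delta` on every pathway, High up by `delta` on every pathway,
#' and Intermediate up by `delta` on a deterministic half of the pathways
#' (a hybrid signature); neuroendocrine-high subtypes enriched in High,
#' SCLC-A in Intermediate and SCLC-P/SCLC-I in Low.
#'
#' @param n_samples Cohort size (default 120).
#' @param n_clusters Planted cluster count (default 3; other values require
#'   explicit `pathway_effects` and `subtype_probs`).
#' @param proportions Cluster membership probabilities (default uniform).
#' @param delta Mean-shift magnitude in z-units (default 1.5).
#' @param pathway_effects Optional clusters x pathways matrix of mean shifts
#'   overriding the default geometry.
#' @param n_background_genes Genes with no cluster effect (default 500).
#' @param noise_sd Gaussian noise SD in log2 space (default 1).
#' @param subtype_probs Optional clusters x subtypes probability matrix
#'   (rows sum to 1).
#' @param covariate_slope Slope of the monotone per-cluster covariate
#'   (default 1).
#' @param panel A `ddr_panel` whose genes and pathways are simulated
#'   (default: the packaged panel).
#' @param seed Integer seed (default 0).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 120, n_clusters = 3, proportions = NULL,
                        delta = 1.5, pathway_effects = NULL,
                        n_background_genes = 500, noise_sd = 1,
                        subtype_probs = NULL, covariate_slope = 1,
                        panel = default_panel(quiet = TRUE), seed = 0) {
  stopifnot(inherits(panel, "ddr_panel"))
  pathways <- panel_pathways(panel)
  if (is.null(proportions)) proportions <- rep(1 / n_clusters, n_clusters)
  if (length(proportions) != n_clusters ||
      abs(sum(proportions) - 1) > 1e-12 || any(proportions < 0)) {
    stop("`proportions` must be a length-", n_clusters,
         " simplex vector", call. = FALSE)
  }
  if (is.null(pathway_effects)) {
    if (n_clusters != 3) {
      stop("default pathway_effects are defined for 3 clusters; supply a ",
           n_clusters, " x ", length(pathways), " effect matrix",
           call. = FALSE)
    }
    pathway_effects <- default_pathway_effects(pathways, delta)
  }
  if (!identical(dim(pathway_effects),
                 c(as.integer(n_clusters), length(pathways)))) {
    stop("`pathway_effects` must be ", n_clusters, " x ", length(pathways),
         call. = FALSE)
  }
  if (is.null(subtype_probs)) {
    if (n_clusters != 3) {
      stop("default subtype_probs are defined for 3 clusters; supply a ",
           n_clusters, "-row probability matrix", call. = FALSE)
    }
    subtype_probs <- default_subtype_probs()
  }
  if (nrow(subtype_probs) != n_clusters ||
      any(abs(rowSums(subtype_probs) - 1) > 1e-9) || any(subtype_probs < 0)) {
    stop("each `subtype_probs` row must be a probability vector",
         call. = FALSE)
  }
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  if (n_samples < 3 * n_clusters) {
    stop("need n_samples >= 3 * n_clusters", call. = FALSE)
  }
  structure(list(
    n_samples = as.integer(n_samples), n_clusters = as.integer(n_clusters),
    proportions = proportions, delta = delta,
    pathway_effects = pathway_effects,
    n_background_genes = as.integer(n_background_genes),
    noise_sd = noise_sd, subtype_probs = subtype_probs,
    covariate_slope = covariate_slope, panel = panel,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic expression cohort with planted structure
#'
#' Deterministic under the spec's seed. Per sample: a cluster membership is
#' drawn from the spec proportions; each panel gene takes a latent log2
#' value baseline + effect(cluster, pathway) + N(0, noise_sd); background
#' genes take baseline + noise with no cluster effect; latent values map to
#' TPM via `2^x - 1` floored at 0. Per-gene baselines are drawn once per
#' cohort from N(5, 2) in log2 space (a typical bulk RNA-seq dynamic
#' range). Subtypes are drawn from the cluster-conditional rows of
#' `subtype_probs`, and a monotone covariate is
#' `covariate_slope * cluster_rank + N(0, 1)`.
#'
#' @param spec A `cohort_spec` (default: `cohort_spec()` defaults).
#' @return A `synthetic_cohort`: list with `expression` (an `expr_matrix`
#'   in TPM units), `truth` (tibble: `sample`, `cluster`, `cluster_label`,
#'   `subtype`, `covariate`), `latent` (the pre-transform log2-space matrix,
#'   kept for diagnostics) and `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  panel <- spec$panel
  pathways <- panel_pathways(panel)
  n <- spec$n_samples
  k <- spec$n_clusters
  withr::with_seed(spec$seed, {
    cluster <- sample.int(k, n, replace = TRUE, prob = spec$proportions)
    if (length(unique(cluster)) < k) {
      stop("a planted cluster received no samples; increase n_samples or ",
           "its proportion", call. = FALSE)
    }
    genes <- c(panel$gene,
               sprintf("BG%04d", seq_len(spec$n_background_genes)))
    baseline <- stats::rnorm(length(genes), mean = 5, sd = 2)
    latent <- matrix(baseline, nrow = length(genes), ncol = n) +
      matrix(stats::rnorm(length(genes) * n, sd = spec$noise_sd),
             nrow = length(genes))
    path_idx <- match(panel$pathway, pathways)
    for (s in seq_len(n)) {
      latent[seq_len(nrow(panel)), s] <- latent[seq_len(nrow(panel)), s] +
        spec$pathway_effects[cluster[s], path_idx]
    }
    tpm <- pmax(2^latent - 1, 0)
    dimnames(latent) <- dimnames(tpm) <- list(genes,
                                              sprintf("S%03d", seq_len(n)))
    subtypes <- vapply(cluster, function(cl) {
      sample(colnames(spec$subtype_probs), 1, prob = spec$subtype_probs[cl, ])
    }, character(1))
    covariate <- spec$covariate_slope * cluster + stats::rnorm(n)
  })
  labels <- if (k == 3) c("Low", "Intermediate", "High") else
    paste0("C", seq_len(k))
  truth <- tibble::tibble(
    sample = colnames(tpm),
    cluster = cluster,
    cluster_label = factor(labels[cluster], levels = labels),
    subtype = subtypes,
    covariate = covariate
  )
  structure(list(expression = as_expr_matrix(tpm, units = "TPM"),
                 truth = truth, latent = latent, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d genes x %d samples, %d planted clusters\n",
              nrow(x$expression), ncol(x$expression), x$spec$n_clusters))
  print(table(x$truth$cluster_label))
  invisible(x)
}

#' Ground-truth association tables of a synthetic cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @return A list: `cluster_by_subtype` (a `contingency` table of planted
#'   cluster label by planted subtype) and `covariate_summary` (tibble of
#'   per-cluster covariate medians and IQRs).
#' @export
truth_tables <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tr <- cohort$truth
  tab <- contingency(
    stats::setNames(as.character(tr$cluster_label), tr$sample),
    stats::setNames(tr$subtype, tr$sample)
  )
  cov_sum <- tr |>
    dplyr::group_by(.data$cluster_label) |>
    dplyr::summarise(n = dplyr::n(),
                     median = stats::median(.data$covariate),
                     q1 = unname(stats::quantile(.data$covariate, 0.25)),
                     q3 = unname(stats::quantile(.data$covariate, 0.75)),
                     .groups = "drop")
  list(cluster_by_subtype = tab, covariate_summary = cov_sum)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `expression.tsv` (gene column plus one column per sample),
#' `truth_clusters.tsv`, `truth_subtypes.tsv` and `spec.yaml` into a
#' directory.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr_df <- tibble::as_tibble(unclass(cohort$expression), rownames = "gene")
  readr::write_tsv(expr_df, file.path(dir, "expression.tsv"), progress = FALSE)
  readr::write_tsv(cohort$truth[c("sample", "cluster", "cluster_label")],
                   file.path(dir, "truth_clusters.tsv"), progress = FALSE)
  readr::write_tsv(cohort$truth[c("sample", "subtype")],
                   file.path(dir, "truth_subtypes.tsv"), progress = FALSE)
  sp <- cohort$spec
  yaml::write_yaml(list(
    n_samples = sp$n_samples, n_clusters = sp$n_clusters,
    proportions = sp$proportions, delta = sp$delta,
    n_background_genes = sp$n_background_genes, noise_sd = sp$noise_sd,
    covariate_slope = sp$covariate_slope, seed = sp$seed
  ), file.path(dir, "spec.yaml"))
  invisible(dir)
}
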