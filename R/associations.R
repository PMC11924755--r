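as_label_vector <- function(x, arg = "labels") {
  if (is.data.frame(x)) {
    if (ncol(x) < 2) stop(arg, " data frame needs (sample, category) columns",
                          call. = FALSE)
    out <- stats::setNames(as.character(x[[2]]), as.character(x[[1]]))
  } else {
    if (is.null(names(x))) stop(arg, " must be named by sample", call. = FALSE)
    out <- stats::setNames(as.character(x), names(x))
  }
  if (anyDuplicated(names(out))) {
    stop("duplicate sample id(s) in ", arg, ": ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Cross-tabulate two per-sample label sets
#'
#' Builds the contingency table of two categorical labelings over their
#' shared samples (e.g. DDR cluster by molecular subtype). Samples missing
#' from either labeling are dropped and counted.
#'
#' @param labels_a,labels_b Named character vectors (names are sample ids)
#'   or two-column data frames (sample, category).
#' @return A `contingency` object (a base `table`, rows from `labels_a`)
#'   with attribute `n_dropped`.
#' @export
contingency <- function(labels_a, labels_b) {
  a <- as_label_vector(labels_a, "labels_a")
  b <- as_label_vector(labels_b, "labels_b")
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0) stop("no shared samples between the two labelings",
                                call. = FALSE)
  n_dropped <- length(union(names(a), names(b))) - length(shared)
  if (n_dropped > 0) {
    message(n_dropped, " sample(s) missing one of the labels were dropped")
  }
  tab <- table(a[shared], b[shared])
  structure(tab, n_dropped = n_dropped,
            class = c("contingency", class(tab)))
}

#' Chi-square test with Monte-Carlo p-value and Pearson residuals
#'
#' Pearson chi-square without continuity correction. Alongside the
#' asymptotic p-value, a simulated p-value is computed from `n_sim` tables
#' drawn uniformly conditional on both margins fixed (Patefield sampling via
#' [stats::r2dtable()]), mirroring the R convention
#' `chisq.test(simulate.p.value = TRUE)`:
#' \deqn{p_{sim} = (1 + \#\{\chi^2_{sim} \ge \chi^2_{obs}\}) / (n_{sim}+1).}
#' Pearson residuals \eqn{(O - E)/\sqrt{E}} are returned for dot-plot
#' rendering; their squares sum to the statistic.
#'
#' @param tab A `contingency` object, base table, or integer matrix of
#'   counts (at least 2 x 2 with positive margins).
#' @param n_sim Number of Monte-Carlo replicates (default 2000).
#' @param seed Integer seed for the simulation (default 0).
#' @return A `chisq_mc` object: list with `statistic`, `df`,
#'   `p_asymptotic`, `p_simulated`, `n_sim`, `observed`, `expected`,
#'   `residuals`, `seed`.
#' @export
chisq_mc <- function(tab, n_sim = 2000, seed = 0) {
  obs <- unclass(as.matrix(tab))
  storage.mode(obs) <- "double"
  if (any(obs < 0) || any(obs != round(obs))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (nrow(obs) < 2 || ncol(obs) < 2) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  if (n_sim < 1) stop("n_sim must be at least 1", call. = FALSE)
  rs <- rowSums(obs)
  cs <- colSums(obs)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero row or column margin; drop empty categories first",
         call. = FALSE)
  }
  n <- sum(obs)
  expected <- outer(rs, cs) / n
  stat <- sum((obs - expected)^2 / expected)
  df <- (nrow(obs) - 1L) * (ncol(obs) - 1L)
  resid <- (obs - expected) / sqrt(expected)
  sims <- withr::with_seed(seed, stats::r2dtable(n_sim, rs, cs))
  sim_stats <- vapply(sims, function(m) sum((m - expected)^2 / expected),
                      numeric(1))
  structure(list(
    statistic = stat,
    df = df,
    p_asymptotic = stats::pchisq(stat, df, lower.tail = FALSE),
    p_simulated = (1 + sum(sim_stats >= stat)) / (n_sim + 1),
    n_sim = as.integer(n_sim),
    observed = obs,
    expected = expected,
    residuals = resid,
    seed = seed
  ), class = "chisq_mc")
}

#' @export
print.chisq_mc <- function(x, ...) {
  cat(sprintf(
    "<chisq_mc> X-squared = %.4f, df = %d, p (asymptotic) = %.4g, p (%d sims) = %.4g\n",
    x$statistic, x$df, x$p_asymptotic, x$n_sim, x$p_simulated))
  invisible(x)
}

#' Tidy chi-square cells
#'
#' @param x A `chisq_mc` object.
#' @param ... Unused.
#' @return A tibble with one row per cell: `row`, `col`, `observed`,
#'   `expected`, `residual`.
#' @export
tidy.chisq_mc <- function(x, ...) {
  dn <- dimnames(x$observed)
  rows <- if (is.null(dn[[1]])) as.character(seq_len(nrow(x$observed))) else dn[[1]]
  cols <- if (is.null(dn[[2]])) as.character(seq_len(ncol(x$observed))) else dn[[2]]
  tidyr::expand_grid(col = cols, row = rows) |>
    dplyr::mutate(
      observed = as.vector(x$observed[cbind(.data$row, .data$col)]),
      expected = as.vector(x$expected[cbind(.data$row, .data$col)]),
      residual = as.vector(x$residuals[cbind(.data$row, .data$col)])
    ) |>
    dplyr::select("row", "col", "observed", "expected", "residual")
}

#' One-row chi-square summary
#'
#' @param x A `chisq_mc` object.
#' @param ... Unused.
#' @return A tibble with `statistic`, `df`, `p_asymptotic`, `p_simulated`,
#'   `n_sim`, `seed`.
#' @export
glance.chisq_mc <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df,
                 p_asymptotic = x$p_asymptotic,
                 p_simulated = x$p_simulated,
                 n_sim = x$n_sim, seed = x$seed)
}

#' Pearson residual dot plot
#'
#' Residual magnitude scales dot size; sign sets color (enrichment red,
#' depletion blue).
#'
#' @param object A `chisq_mc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chisq_mc <- function(object, ...) {
  cells <- tidy.chisq_mc(object)
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$col, y = .data$row,
                                      size = abs(.data$residual),
                                      color = .data$residual)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_gradient2(low = "#2166AC", mid = "grey80",
                                   high = "#B2182B", name = "Pearson residual") +
    ggplot2::scale_size_continuous(name = "|residual|", range = c(1, 10)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

wilcox_pair <- function(x, y, paired) {
  if (paired) {
    if (length(x) != length(y)) {
      stop("paired comparison requires equal-length matched vectors",
           call. = FALSE)
    }
    if (all(x - y == 0)) {
      warning("all paired differences are zero; returning p = 1",
              call. = FALSE)
      return(list(statistic = 0, p_value = 1))
    }
  }
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, alternative = "two.sided")
  )
  p <- ht$p.value
  # fully tied samples give a 0/0 normal approximation; no evidence -> p = 1
  if (is.nan(p)) p <- 1
  list(statistic = unname(ht$statistic), p_value = p)
}

#' Pairwise Wilcoxon tests across groups
#'
#' Two-sided rank-sum tests for every pair of groups (or a signed-rank test
#' for two matched vectors with `paired = TRUE`). The exact null
#' distribution is used for small tie-free samples and the normal
#' approximation with tie correction otherwise (the [stats::wilcox.test()]
#' convention).
#'
#' @param data A data frame with a value column and a group column.
#' @param value,group Column names (tidy-eval) holding the measurements and
#'   group labels.
#' @param paired Paired signed-rank test; requires exactly two groups of
#'   equal length whose rows are matched in order.
#' @param adjust Add a Benjamini-Hochberg adjusted p column (default FALSE;
#'   raw p-values are always reported).
#' @param alpha Significance threshold reported in the `significant` column
#'   (default 0.05).
#' @return A tibble with one row per pair: `group1`, `group2`, `n1`, `n2`,
#'   `statistic`, `p_value`, `paired`, `significant` (and `p_adjusted` when
#'   `adjust = TRUE`).
#' @export
pairwise_wilcoxon <- function(data, value, group, paired = FALSE,
                              adjust = FALSE, alpha = 0.05) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  vals <- rlang::eval_tidy(value, data)
  grp <- as.character(rlang::eval_tidy(group, data))
  split_vals <- split(vals, grp)
  if (is.factor(rlang::eval_tidy(group, data))) {
    lv <- levels(rlang::eval_tidy(group, data))
    split_vals <- split_vals[intersect(lv, names(split_vals))]
  }
  ns <- vapply(split_vals, length, integer(1))
  small <- names(ns)[ns < 2]
  if (length(small) > 0) {
    warning("excluding group(s) with n < 2: ", paste(small, collapse = ", "),
            call. = FALSE)
    split_vals <- split_vals[ns >= 2]
  }
  if (length(split_vals) < 2) stop("need at least 2 groups with n >= 2",
                                   call. = FALSE)
  if (paired && length(split_vals) != 2) {
    stop("paired comparison requires exactly 2 groups", call. = FALSE)
  }
  pairs <- utils::combn(names(split_vals), 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(p) {
    res <- wilcox_pair(split_vals[[p[1]]], split_vals[[p[2]]], paired)
    tibble::tibble(group1 = p[1], group2 = p[2],
                   n1 = length(split_vals[[p[1]]]),
                   n2 = length(split_vals[[p[2]]]),
                   statistic = res$statistic, p_value = res$p_value,
                   paired = paired)
  })
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out
}

#' Compare a per-sample score across DDR clusters
#'
#' Pairwise Wilcoxon tests of a continuous score (e.g. a weighted signature
#' score) across cluster labels, plus per-cluster median and interquartile
#' summaries. Clusters with fewer than 2 scored samples are excluded with a
#' warning.
#'
#' @param scores Named numeric vector (names are sample ids).
#' @param sol A `we_clusters` object.
#' @return A list of class `score_by_cluster`: `summary` (tibble: `label`,
#'   `n`, `median`, `q1`, `q3`) and `comparisons` (pairwise Wilcoxon tibble).
#' @export
score_by_cluster <- function(scores, sol) {
  stopifnot(inherits(sol, "we_clusters"))
  if (is.null(names(scores))) stop("`scores` must be named by sample",
                                   call. = FALSE)
  asn <- sol$assignments
  shared <- intersect(names(scores), asn$sample)
  if (length(shared) == 0) stop("scores cover no clustered samples",
                                call. = FALSE)
  df <- tibble::tibble(
    sample = shared,
    score = unname(scores[shared]),
    label = asn$label[match(shared, asn$sample)]
  )
  covered <- levels(df$label)[table(df$label) >= 2]
  if (length(covered) < 2) stop("scores cover fewer than 2 clusters",
                                call. = FALSE)
  summary <- df |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(),
                     median = stats::median(.data$score),
                     q1 = unname(stats::quantile(.data$score, 0.25)),
                     q3 = unname(stats::quantile(.data$score, 0.75)),
                     .groups = "drop")
  comparisons <- pairwise_wilcoxon(df[df$label %in% covered, ],
                                   value = score, group = label)
  structure(list(summary = summary, comparisons = comparisons),
            class = "score_by_cluster")
}

#' @export
print.score_by_cluster <- function(x, ...) {
  cat("<score_by_cluster>\n")
  print(x$summary)
  print(x$comparisons)
  invisible(x)
}
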