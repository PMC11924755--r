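# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      # all remaining points coincide with a center; fall back to uniform
      centers[j] <- sample.int(n, 1)
    } else {
      centers[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums((x - matrix(x[centers[j], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  x[centers, , drop = FALSE]
}

run_lloyd <- function(x, centers) {
  # centers must be distinct for stats::kmeans
  if (anyDuplicated(round(centers, 12))) return(NULL)
  tryCatch(
    suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd")
    ),
    error = function(e) NULL
  )
}

best_kmeans <- function(x, k, restarts, warm_centers = NULL) {
  best <- NULL
  attempts <- 0
  while (is.null(best) && attempts < 10) {
    for (r in seq_len(restarts)) {
      fit <- run_lloyd(x, kmeanspp_centers(x, k))
      if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
        best <- fit
      }
    }
    attempts <- attempts + 1
  }
  if (!is.null(warm_centers)) {
    fit <- run_lloyd(x, warm_centers)
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("k-means failed to produce ", k,
         " non-empty clusters after repeated restarts", call. = FALSE)
  }
  best
}

# warm-start candidate for k: centers of the best (k-1) solution plus the
# point farthest from its assigned center; starting Lloyd there bounds
# wss(k) by wss(k-1), making the reported curve non-increasing.
split_candidate <- function(x, prev_fit) {
  d2 <- rowSums((x - prev_fit$centers[prev_fit$cluster, , drop = FALSE])^2)
  if (max(d2) <= 0) return(NULL)
  rbind(prev_fit$centers, x[which.max(d2), ])
}

samples_points <- function(scores) {
  if (is.null(scores$scaled)) {
    stop("scores have no scaled matrix; call scale_we() first", call. = FALSE)
  }
  t(scores$scaled)
}

#' Within-cluster sum-of-squares curve
#'
#' Runs k-means (Lloyd iterations, k-means++ seeding, best of `restarts`
#' runs) on samples in scaled WE-score space for each k from 1 to `k_max`
#' and records the total within-cluster sum of squares. The best solution
#' for k-1 also seeds a split-refinement candidate at k, so the curve is
#' non-increasing.
#'
#' @param scores A `we_scores` object with a scaled matrix (samples are
#'   points, pathways are dimensions).
#' @param k_max Maximum number of clusters considered (default 10).
#' @param restarts Random restarts per k (default 25).
#' @param seed Integer seed; the whole curve is deterministic given it.
#' @return A `wss_curve` tibble with columns `k`, `wss` and attributes
#'   `restarts`, `seed`.
#' @export
wss_curve <- function(scores, k_max = 10, restarts = 25, seed = 0) {
  x <- samples_points(scores)
  n <- nrow(x)
  if (n <= k_max) {
    stop(sprintf("n_samples (%d) must exceed k_max (%d); use a smaller k_max",
                 n, k_max), call. = FALSE)
  }
  wss <- numeric(k_max)
  wss[1] <- sum(scale(x, center = TRUE, scale = FALSE)^2)
  fits <- vector("list", k_max)
  withr::with_seed(seed, {
    prev <- NULL
    for (k in 2:k_max) {
      warm <- if (!is.null(prev)) split_candidate(x, prev) else NULL
      fit <- best_kmeans(x, k, restarts, warm_centers = warm)
      wss[k] <- fit$tot.withinss
      fits[[k]] <- fit
      prev <- fit
    }
  })
  out <- tibble::tibble(k = seq_len(k_max), wss = wss)
  structure(out, restarts = restarts, seed = seed, fits = fits,
            class = c("wss_curve", class(out)))
}

#' Choose k by the maximum chord-distance (elbow) rule
#'
#' Min-max normalizes both axes of the WSS curve, draws the chord from
#' (k = 1) to (k = k_max), and returns the k in 2..(k_max - 1) whose curve
#' point lies farthest below the chord. Ties break toward smaller k; a flat
#' (or chord-hugging) curve returns 2 with a warning.
#'
#' @param curve A `wss_curve`.
#' @return The selected integer k.
#' @export
select_k <- function(curve) {
  stopifnot(inherits(curve, "wss_curve"))
  k <- curve$k
  wss <- curve$wss
  k_max <- max(k)
  if (k_max < 3) stop("k_max must be at least 3 to select k", call. = FALSE)
  rng <- max(wss) - min(wss)
  if (rng == 0) {
    warning("flat WSS curve; returning k = 2", call. = FALSE)
    return(2L)
  }
  xs <- (k - 1) / (k_max - 1)
  ys <- (wss - min(wss)) / rng
  chord <- ys[1] + (ys[k_max] - ys[1]) * xs
  dist <- chord - ys
  inner <- 2:(k_max - 1)
  best <- max(dist[inner])
  if (best <= 1e-12) {
    warning("no elbow: WSS curve does not dip below its chord", call. = FALSE)
  }
  # ties (to numerical precision) break toward the smaller k
  as.integer(min(inner[dist[inner] >= best - 1e-12]))
}

ordinal_labels <- function(k) {
  if (k == 3) c("DDR Low", "DDR Intermediate", "DDR High")
  else paste0("DDR-", seq_len(k))
}

#' Cluster samples into ordered DDR phenotype groups
#'
#' Partitions samples in scaled WE-score space with k-means (k-means++
#' seeding, best of `restarts` Lloyd runs) and relabels clusters by
#' ascending grand-mean scaled WE score of their members, so that labels are
#' ordinal: for k = 3 they are exactly "DDR Low", "DDR Intermediate",
#' "DDR High"; otherwise "DDR-1" (lowest) through "DDR-k".
#'
#' @param scores A `we_scores` object with a scaled matrix.
#' @param k Number of clusters; if `NULL`, chosen by [select_k()] on a
#'   [wss_curve()] computed with `k_max`.
#' @param k_max Maximum k considered when `k` is `NULL`.
#' @param restarts Random restarts (default 25).
#' @param seed Integer seed (default 0).
#' @return A `we_clusters` object: list with `k`, `assignments` (tibble:
#'   `sample`, `cluster`, `label`), `centroids` (k x pathways, in label
#'   order), `cluster_means` (grand-mean scaled WE per label), `wss`,
#'   `curve` (NULL when `k` was given), `seed`.
#' @export
we_cluster <- function(scores, k = NULL, k_max = 10, restarts = 25, seed = 0) {
  x <- samples_points(scores)
  n <- nrow(x)
  curve <- NULL
  if (is.null(k)) {
    curve <- wss_curve(scores, k_max = k_max, restarts = restarts, seed = seed)
    k <- select_k(curve)
    fit <- attr(curve, "fits")[[k]]
  } else {
    if (k < 2 || k >= n) {
      stop("k must satisfy 2 <= k < n_samples", call. = FALSE)
    }
    fit <- withr::with_seed(seed, best_kmeans(x, k, restarts))
  }
  grand_means <- vapply(seq_len(k), function(j) {
    mean(x[fit$cluster == j, , drop = FALSE])
  }, numeric(1))
  ord <- order(grand_means) # ascending: Low first
  rank_of <- match(seq_len(k), ord)
  labels <- ordinal_labels(k)
  assignments <- tibble::tibble(
    sample = rownames(x),
    cluster = rank_of[fit$cluster],
    label = factor(labels[rank_of[fit$cluster]], levels = labels)
  )
  structure(list(
    k = as.integer(k),
    assignments = assignments,
    centroids = {
      cen <- fit$centers[ord, , drop = FALSE]
      rownames(cen) <- labels
      cen
    },
    cluster_means = stats::setNames(grand_means[ord], labels),
    wss = fit$tot.withinss,
    curve = curve,
    seed = seed
  ), class = "we_clusters")
}

#' @export
print.we_clusters <- function(x, ...) {
  cat(sprintf("<we_clusters> k = %d, n = %d, total WSS = %.4f\n",
              x$k, nrow(x$assignments), x$wss))
  print(table(x$assignments$label))
  invisible(x)
}

#' Tidy cluster assignments
#'
#' @param x A `we_clusters` object.
#' @param ... Unused.
#' @return The per-sample assignment tibble (`sample`, `cluster`, `label`).
#' @export
tidy.we_clusters <- function(x, ...) x$assignments

#' One-row summary of a clustering
#'
#' @param x A `we_clusters` object.
#' @param ... Unused.
#' @return A tibble with `k`, `n_samples`, `tot_withinss`, `seed`.
#' @export
glance.we_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n_samples = nrow(x$assignments),
                 tot_withinss = x$wss, seed = x$seed)
}

#' Per-cluster summary table
#'
#' @param sol A `we_clusters` object.
#' @param scores The `we_scores` object the solution was fitted on.
#' @return A tibble with one row per label: `label`, `n_samples`,
#'   `prevalence`, and one column per pathway holding the mean scaled WE
#'   score of member samples.
#' @export
cluster_summary <- function(sol, scores) {
  stopifnot(inherits(sol, "we_clusters"))
  scaled <- scores$scaled
  asn <- sol$assignments
  if (!setequal(asn$sample, colnames(scaled))) {
    stop("assignments and scores cover different samples", call. = FALSE)
  }
  rows <- lapply(levels(asn$label), function(lab) {
    members <- asn$sample[asn$label == lab]
    means <- rowMeans(scaled[, members, drop = FALSE])
    tibble::tibble(label = lab, n_samples = length(members),
                   prevalence = length(members) / ncol(scaled),
                   !!!as.list(means))
  })
  dplyr::bind_rows(rows)
}

#' Elbow plot of a WSS curve
#'
#' @param object A `wss_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wss_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$wss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "Number of clusters k",
                  y = "Total within-cluster sum of squares") +
    ggplot2::theme_minimal()
}

#' Heatmap of scaled WE scores ordered by cluster
#'
#' @param object A `we_clusters` object.
#' @param scores The `we_scores` object the solution was fitted on.
#' @param ... Unused.
#' @return A ggplot tile heatmap (samples ordered by label).
#' @export
autoplot.we_clusters <- function(object, scores, ...) {
  asn <- dplyr::arrange(object$assignments, .data$label)
  long <- tidy.we_scores(scores) |>
    dplyr::mutate(sample = factor(.data$sample, levels = asn$sample),
                  pathway = factor(.data$pathway,
                                   levels = rev(rownames(scores$raw))))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$pathway,
                                     fill = .data$scaled)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", name = "Scaled WE") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
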