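# Shared fixtures and independent oracles, all built in code.

toy_panel <- function() {
  as_ddr_panel(tibble::tibble(
    gene = c("BRCA1", "XRCC1", "POLH"),
    pathway = c("HR", "BER", "TLS"),
    esf = c(2, 1, 1)
  ))
}

# wrap an arbitrary matrix as a z-score matrix (rows genes, cols samples)
as_zmat <- function(m) {
  structure(m, degenerate = character(0), provenance = "fixture",
            class = c("zscore_matrix", "matrix", "array"))
}

# wrap a pathways x samples matrix as scaled WE scores for clustering tests
fake_scores <- function(scaled, raw = scaled) {
  structure(list(raw = raw, scaled = scaled,
                 n_genes_used = stats::setNames(rep(1L, nrow(scaled)),
                                                rownames(scaled)),
                 n_genes_panel = stats::setNames(rep(1L, nrow(scaled)),
                                                 rownames(scaled)),
                 unmatched = character(0), strict = FALSE),
            class = "we_scores")
}

random_expr <- function(n_genes, n_samples, seed, units = "TPM") {
  withr::with_seed(seed, {
    m <- matrix(2^stats::rnorm(n_genes * n_samples, mean = 5, sd = 2) - 1,
                nrow = n_genes,
                dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                sprintf("S%02d", seq_len(n_samples))))
    m[m < 0] <- 0
    as_expr_matrix(m, units = units)
  })
}

random_panel <- function(genes, n_pathways, seed) {
  withr::with_seed(seed, {
    pw <- sample(ddr_pathways()[seq_len(n_pathways)], length(genes),
                 replace = TRUE)
    as_ddr_panel(tibble::tibble(gene = genes, pathway = pw,
                                esf = stats::runif(length(genes), 0.5, 3)))
  })
}

# independent naive triple-loop WE score oracle
naive_we <- function(z, panel, strict = FALSE) {
  pathways <- unique(panel$pathway)
  out <- matrix(NA_real_, nrow = length(pathways), ncol = ncol(z),
                dimnames = list(pathways, colnames(z)))
  for (p in pathways) {
    genes_p <- panel$gene[panel$pathway == p]
    for (s in seq_len(ncol(z))) {
      total <- 0
      n_used <- 0
      for (g in genes_p) {
        if (g %in% rownames(z)) {
          total <- total + panel$esf[panel$gene == g] * z[g, s]
          n_used <- n_used + 1
        }
      }
      denom <- if (strict) length(genes_p) else n_used
      if (n_used > 0) out[p, s] <- total / denom
    }
  }
  out[rowSums(!is.na(out)) > 0, , drop = FALSE]
}

# independent chord-distance elbow oracle (plain loop)
chord_elbow <- function(wss) {
  k_max <- length(wss)
  xs <- (seq_len(k_max) - 1) / (k_max - 1)
  ys <- (wss - min(wss)) / (max(wss) - min(wss))
  best_k <- NA_integer_
  best_d <- -Inf
  for (k in 2:(k_max - 1)) {
    chord_y <- ys[1] + (ys[k_max] - ys[1]) * xs[k]
    d <- chord_y - ys[k]
    if (d > best_d + 1e-15) {
      best_d <- d
      best_k <- k
    }
  }
  best_k
}

make_curve <- function(wss) {
  out <- tibble::tibble(k = seq_along(wss), wss = wss)
  structure(out, restarts = 1L, seed = 0L,
            class = c("wss_curve", class(out)))
}

# exact two-sided tail mass of the Pearson chi-square statistic over all
# 2x2 tables with both margins fixed (hypergeometric enumeration)
exact_chisq_p_2x2 <- function(obs) {
  rs <- rowSums(obs)
  cs <- colSums(obs)
  n <- sum(obs)
  expected <- outer(rs, cs) / n
  stat_of <- function(a) {
    tab <- matrix(c(a, cs[1] - a, rs[1] - a, n - rs[1] - cs[1] + a), 2, 2)
    sum((tab - expected)^2 / expected)
  }
  a_min <- max(0, rs[1] + cs[1] - n)
  a_max <- min(rs[1], cs[1])
  a_vals <- a_min:a_max
  probs <- stats::dhyper(a_vals, cs[1], n - cs[1], rs[1])
  stats_all <- vapply(a_vals, stat_of, numeric(1))
  obs_stat <- sum((obs - expected)^2 / expected)
  sum(probs[stats_all >= obs_stat - 1e-9])
}
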