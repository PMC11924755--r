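#' Construct an expression matrix
#'
#' Wraps a genes-by-samples numeric matrix (or a data frame whose first
#' column holds gene symbols and remaining columns hold samples) together
#' with a units declaration. TPM values must be non-negative; at least two
#' samples are required because downstream z-scoring standardizes each gene
#' across samples.
#'
#' @param x Numeric matrix (genes x samples, dimnames required) or data
#'   frame with gene symbols in the first column.
#' @param units One of `"TPM"`, `"log2TPM"`, `"zscore"`.
#' @return An `expr_matrix`: a numeric matrix with a `units` attribute.
#' @export
as_expr_matrix <- function(x, units = c("TPM", "log2TPM", "zscore")) {
  units <- match.arg(units)
  if (is.data.frame(x)) {
    genes <- toupper(trimws(as.character(x[[1]])))
    m <- as.matrix(x[-1])
    storage.mode(m) <- "double"
    rownames(m) <- genes
  } else if (is.matrix(x)) {
    m <- x
    storage.mode(m) <- "double"
    if (!is.null(rownames(m))) rownames(m) <- toupper(rownames(m))
  } else {
    stop("`x` must be a matrix or a data frame", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs gene row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene labels", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate sample labels", call. = FALSE)
  if (ncol(m) < 2) stop("at least 2 samples are required", call. = FALSE)
  if (units == "TPM" && any(m < 0, na.rm = TRUE)) {
    stop("TPM values must be non-negative", call. = FALSE)
  }
  structure(m, units = units, class = c("expr_matrix", "matrix", "array"))
}

#' Read an expression matrix from a delimited file
#'
#' First column gene symbol, remaining columns samples.
#'
#' @param path Path to a TSV/CSV file.
#' @inheritParams as_expr_matrix
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, units = c("TPM", "log2TPM", "zscore")) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  as_expr_matrix(x, units = match.arg(units))
}

expr_units <- function(x) attr(x, "units")

#' Log-transform a TPM matrix
#'
#' Applies `log2(v + 1)` elementwise. A no-op (with a warning) on input
#' already declared `log2TPM`.
#'
#' @param expr An `expr_matrix` in TPM or log2TPM units.
#' @return An `expr_matrix` in log2TPM units.
#' @export
log_transform <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  units <- expr_units(expr)
  if (units == "log2TPM") {
    warning("input already log2TPM; returning unchanged", call. = FALSE)
    return(expr)
  }
  if (units != "TPM") stop("log_transform() expects TPM input", call. = FALSE)
  if (any(expr < 0, na.rm = TRUE)) stop("negative TPM values", call. = FALSE)
  out <- log2(unclass(expr) + 1)
  structure(out, units = "log2TPM", class = class(expr))
}

#' Per-gene z-scores across samples
#'
#' Standardizes each gene row to mean 0 and unit sample standard deviation
#' (denominator n - 1) across samples. TPM input is log2(v+1)-transformed
#' first (disable with `log = FALSE`); input declared `zscore` passes
#' through unchanged. Constant (zero-variance) rows are set to all zeros and
#' recorded as degenerate rather than producing NaN.
#'
#' @param expr An `expr_matrix`.
#' @param log Apply [log_transform()] to TPM input first (default TRUE).
#' @return A `zscore_matrix`: genes x samples matrix with attributes
#'   `degenerate` (character vector of constant genes) and `provenance`.
#' @export
zscore_genes <- function(expr, log = TRUE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (ncol(expr) < 2) stop("z-scoring needs at least 2 samples", call. = FALSE)
  if (anyNA(expr)) {
    idx <- which(is.na(unclass(expr)), arr.ind = TRUE)[1, ]
    stop(sprintf("NaN/NA in expression at gene %s, sample %s",
                 rownames(expr)[idx[1]], colnames(expr)[idx[2]]),
         call. = FALSE)
  }
  units <- expr_units(expr)
  if (units == "zscore") {
    z <- unclass(expr)
    return(structure(z, degenerate = character(0),
                     provenance = "pass-through (input already z-scores)",
                     class = c("zscore_matrix", "matrix", "array")))
  }
  prov <- "row z-score of log2TPM"
  if (units == "TPM") {
    if (log) {
      expr <- log_transform(expr)
    } else {
      prov <- "row z-score of TPM (log disabled)"
    }
  }
  m <- unclass(expr)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  degenerate <- rownames(m)[sdv == 0]
  sdv[sdv == 0] <- Inf # constant rows -> 0 after centering
  z <- (m - mu) / sdv
  structure(z, degenerate = degenerate, provenance = prov,
            class = c("zscore_matrix", "matrix", "array"))
}

#' Raw per-pathway WE scores
#'
#' For pathway P and sample s the raw weighted-expression (WE) score is
#' \deqn{raw(P, s) = \sum_{g \in P} esf_g \, z_{gs} / n_P}
#' where the sum runs over panel genes present in the data and `n_P` is the
#' number of matched genes (or, in strict mode, the full panel size of P, so
#' that absent genes deflate the score). Pathways with no matched genes are
#' dropped with a warning.
#'
#' @param z A `zscore_matrix` from [zscore_genes()].
#' @param panel A `ddr_panel`.
#' @param strict Divide by the full panel pathway size instead of the number
#'   of matched genes.
#' @return A `we_scores` object: list with `raw` (pathways x samples matrix),
#'   `scaled` (NULL until [scale_we()]), `n_genes_used`, `n_genes_panel`,
#'   `unmatched` (panel genes absent from the data).
#' @export
we_scores <- function(z, panel, strict = FALSE) {
  stopifnot(inherits(z, "zscore_matrix"), inherits(panel, "ddr_panel"))
  pathways <- panel_pathways(panel)
  matched <- panel$gene %in% rownames(z)
  if (!any(matched)) {
    stop("no panel genes found in the expression data", call. = FALSE)
  }
  unmatched <- panel$gene[!matched]
  raw <- matrix(NA_real_, nrow = length(pathways), ncol = ncol(z),
                dimnames = list(pathways, colnames(z)))
  n_used <- stats::setNames(integer(length(pathways)), pathways)
  n_panel <- stats::setNames(integer(length(pathways)), pathways)
  for (p in pathways) {
    genes_p <- panel$gene[panel$pathway == p]
    n_panel[[p]] <- length(genes_p)
    genes_in <- genes_p[genes_p %in% rownames(z)]
    n_used[[p]] <- length(genes_in)
    if (length(genes_in) == 0) next
    esf <- panel$esf[match(genes_in, panel$gene)]
    denom <- if (strict) length(genes_p) else length(genes_in)
    raw[p, ] <- colSums(z[genes_in, , drop = FALSE] * esf) / denom
  }
  empty <- pathways[n_used == 0]
  if (length(empty) > 0) {
    warning("dropping pathway(s) with no genes in the data: ",
            paste(empty, collapse = ", "), call. = FALSE)
    keep <- setdiff(pathways, empty)
    raw <- raw[keep, , drop = FALSE]
    n_used <- n_used[keep]
    n_panel <- n_panel[keep]
  }
  structure(list(raw = raw, scaled = NULL, n_genes_used = n_used,
                 n_genes_panel = n_panel, unmatched = unmatched,
                 strict = strict),
            class = "we_scores")
}

#' Scale WE scores across samples
#'
#' Standardizes each pathway row of the raw WE matrix to mean 0 and unit
#' sample standard deviation across samples, putting pathways on a common
#' scale for clustering and heatmaps. Constant rows become zeros with a
#' warning.
#'
#' @param we A `we_scores` object.
#' @return The same object with the `scaled` matrix filled in.
#' @export
scale_we <- function(we) {
  stopifnot(inherits(we, "we_scores"))
  raw <- we$raw
  if (ncol(raw) < 2) stop("scaling needs at least 2 samples", call. = FALSE)
  mu <- rowMeans(raw)
  sdv <- apply(raw, 1, stats::sd)
  if (any(sdv == 0)) {
    warning("constant WE score row(s) set to zero: ",
            paste(rownames(raw)[sdv == 0], collapse = ", "), call. = FALSE)
    sdv[sdv == 0] <- Inf
  }
  we$scaled <- (raw - mu) / sdv
  we
}

#' One-call WE scoring pipeline
#'
#' [zscore_genes()] then [we_scores()] then [scale_we()].
#'
#' @inheritParams zscore_genes
#' @inheritParams we_scores
#' @return A `we_scores` object with raw and scaled matrices.
#' @export
we_score_pipeline <- function(expr, panel, log = TRUE, strict = FALSE) {
  scale_we(we_scores(zscore_genes(expr, log = log), panel, strict = strict))
}

#' @export
print.we_scores <- function(x, ...) {
  cat(sprintf("<we_scores> %d pathways x %d samples (%s)\n",
              nrow(x$raw), ncol(x$raw),
              if (is.null(x$scaled)) "raw only" else "raw + scaled"))
  invisible(x)
}

#' Tidy WE scores into long form
#'
#' @param x A `we_scores` object.
#' @param ... Unused.
#' @return A tibble with columns `pathway`, `sample`, `raw` and (when
#'   available) `scaled`.
#' @export
tidy.we_scores <- function(x, ...) {
  out <- tibble::as_tibble(as.table(x$raw), .name_repair = "minimal")
  names(out) <- c("pathway", "sample", "raw")
  if (!is.null(x$scaled)) {
    out$scaled <- as.vector(x$scaled[cbind(out$pathway, out$sample)])
  }
  out
}

#' Weighted signature score
#'
#' Generic weighted-mean signature over gene z-scores:
#' \deqn{score(s) = \sum_g w_g z_{gs} / \sum_g |w_g|}
#' over signature genes matched in the data (weight signs encode direction).
#' This is a generic stand-in for published signature formulas such as
#' replication-stress or neuroendocrine scores; it is not a reimplementation
#' of any specific published signature.
#'
#' @param z A `zscore_matrix`.
#' @param weights Named numeric vector, gene symbol -> weight.
#' @param name Optional signature name attached to the result.
#' @return Named numeric vector of per-sample scores with attributes
#'   `matched` and `missing` (gene symbols).
#' @export
signature_score <- function(z, weights, name = NULL) {
  stopifnot(inherits(z, "zscore_matrix"))
  if (is.null(names(weights)) || length(weights) == 0) {
    stop("`weights` must be a named numeric vector", call. = FALSE)
  }
  if (any(!is.finite(weights)) || all(weights == 0)) {
    stop("weights must be finite and not all zero", call. = FALSE)
  }
  genes <- toupper(names(weights))
  matched <- genes[genes %in% rownames(z)]
  if (length(matched) == 0) {
    stop("no signature genes found in the data", call. = FALSE)
  }
  w <- weights[match(matched, genes)]
  scores <- colSums(z[matched, , drop = FALSE] * as.numeric(w)) / sum(abs(w))
  structure(scores, matched = matched, missing = setdiff(genes, matched),
            name = name)
}
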