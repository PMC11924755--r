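#' DDR pathway vocabulary
#'
#' The ten DNA damage response pathways scored by the default panel:
#' non-homologous end-joining (NHEJ), translesion synthesis (TLS), nucleotide
#' excision repair (NER), microhomology-mediated end-joining (MMEJ),
#' homologous recombination (HR), Fanconi anemia (FA), damage sensing and
#' signaling (Checkpoint), mismatch repair (MMR), base excision repair (BER)
#' and direct reversal repair (DR).
#'
#' @return Character vector of the ten pathway names.
#' @export
ddr_pathways <- function() {
  c("NHEJ", "TLS", "NER", "MMEJ", "HR", "FA",
    "Checkpoint", "MMR", "BER", "DR")
}

new_ddr_panel <- function(x) {
  structure(x, class = c("ddr_panel", class(tibble::tibble())))
}

validate_panel <- function(x, warn_unknown = TRUE) {
  required <- c("gene", "pathway", "esf")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("panel table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x[required])
  x$gene <- toupper(trimws(as.character(x$gene)))
  x$pathway <- as.character(x$pathway)
  if (any(!nzchar(x$gene))) stop("panel contains empty gene symbols", call. = FALSE)
  dup <- unique(x$gene[duplicated(x$gene)])
  if (length(dup) > 0) {
    stop("duplicate gene(s) in panel: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  esf <- suppressWarnings(as.numeric(x$esf))
  bad <- x$gene[is.na(esf) | esf <= 0]
  if (length(bad) > 0) {
    stop("non-positive or non-numeric esf for gene(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x$esf <- esf
  unknown <- setdiff(unique(x$pathway), ddr_pathways())
  if (warn_unknown && length(unknown) > 0) {
    warning("panel extends the default pathway vocabulary with: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  new_ddr_panel(x)
}

#' Build a DDR gene panel from a data frame
#'
#' A panel maps each gene symbol to exactly one DDR pathway and a positive
#' essentiality scaling factor (ESF). Gene symbols are uppercased; pathway
#' order is the order of first appearance in the table.
#'
#' @param x A data frame with columns `gene`, `pathway`, `esf`.
#' @param warn_unknown Warn when a pathway is outside [ddr_pathways()].
#' @return A `ddr_panel` tibble.
#' @export
as_ddr_panel <- function(x, warn_unknown = TRUE) {
  validate_panel(x, warn_unknown = warn_unknown)
}

#' Read a DDR panel from a delimited or YAML file
#'
#' Accepts TSV/CSV (header `gene`, `pathway`, `esf`; delimiter sniffed from
#' the extension and content) or a YAML list of records with the same fields.
#'
#' @param path Path to the panel file.
#' @param warn_unknown Warn when a pathway is outside [ddr_pathways()].
#' @return A `ddr_panel` tibble.
#' @export
read_panel <- function(path, warn_unknown = TRUE) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    x <- dplyr::bind_rows(lapply(recs, tibble::as_tibble))
  } else {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  }
  validate_panel(x, warn_unknown = warn_unknown)
}

#' Write a DDR panel to TSV
#'
#' @param panel A `ddr_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "ddr_panel"))
  readr::write_tsv(tibble::as_tibble(unclass(panel)), path, progress = FALSE)
  invisible(path)
}

#' The packaged default DDR panel
#'
#' Returns the packaged 130-gene, 10-pathway DDR panel. The gene list is a
#' synthetic stand-in curated from the DNA-repair literature, and all ESF
#' weights are uniform (1.0): per-gene essentiality tiers are study-specific
#' curation that users should supply through their own panel file
#' (see [read_panel()]). With uniform weights the WE score reduces to the
#' per-pathway mean z-score.
#'
#' @param quiet Suppress the uniform-ESF message.
#' @return A `ddr_panel` tibble with 130 genes across 10 pathways.
#' @export
default_panel <- function(quiet = FALSE) {
  path <- system.file("extdata", "ddr_panel_synthetic.tsv", package = "wescore")
  panel <- read_panel(path)
  if (!quiet) {
    message("default_panel(): packaged panel uses uniform ESF weights (1.0); ",
            "supply a curated panel via read_panel() for weighted scoring.")
  }
  panel
}

#' Pathway order of a panel
#'
#' @param panel A `ddr_panel`.
#' @return Character vector of pathways in order of first appearance.
#' @export
panel_pathways <- function(panel) {
  stopifnot(inherits(panel, "ddr_panel"))
  unique(panel$pathway)
}

#' Summarize a panel by pathway
#'
#' @param panel A `ddr_panel`.
#' @return A tibble with one row per pathway: `pathway`, `n_genes`,
#'   `mean_esf`. `n_genes` sums to the panel size.
#' @export
panel_summary <- function(panel) {
  stopifnot(inherits(panel, "ddr_panel"))
  tibble::as_tibble(unclass(panel)) |>
    dplyr::mutate(pathway = factor(.data$pathway, levels = panel_pathways(panel))) |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(n_genes = dplyr::n(), mean_esf = mean(.data$esf),
                     .groups = "drop") |>
    dplyr::mutate(pathway = as.character(.data$pathway))
}

#' @export
print.ddr_panel <- function(x, ...) {
  cat(sprintf("<ddr_panel> %d genes across %d pathways\n",
              nrow(x), length(panel_pathways(x))))
  NextMethod()
}
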