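#' The packaged voltage-gated ion channel gene list
#'
#' The 145-member voltage-gated ion channel gene superfamily with official
#' IUPHAR classification (mouse symbols), grouped by channel subfamily. This
#' is the universe against which expression tables are screened. Shipped as
#' a pinned data file (`extdata/vgic_channel_list.csv`), not a live database
#' lookup, because the classification evolves.
#'
#' @return A tibble with columns `gene`, `subfamily` (145 rows).
#' @examples
#' nrow(channel_gene_list()) # 145
#' @export
channel_gene_list <- function() {
  path <- system.file("extdata", "vgic_channel_list.csv", package = "dendricap",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a differential-expression gene table
#'
#' Reads CSV/TSV (or XLSX when the readxl package is installed) tables with
#' at least columns `gene`, `fold_change`, `p_value`, `q_value`. Fold change
#' is oriented mutant relative to wild-type.
#'
#' @param path File path.
#' @param timepoint Label attached to the table (e.g. "5wk", "12wk").
#' @return A tibble of class `gene_table`.
#' @export
read_gene_table <- function(path, timepoint = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  tab <- switch(ext,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    tsv = , txt = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading .xlsx requires the readxl package", call. = FALSE)
      }
      tibble::as_tibble(readxl::read_excel(path))
    },
    stop(sprintf("unsupported table format: .%s", ext), call. = FALSE))
  need <- c("gene", "fold_change", "p_value", "q_value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("gene table missing columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  structure(tab, class = c("gene_table", class(tab)), timepoint = timepoint)
}

as_gene_table <- function(tab, timepoint = attr(tab, "timepoint")) {
  if (!inherits(tab, "gene_table")) {
    class(tab) <- c("gene_table", class(tab))
  }
  attr(tab, "timepoint") <- timepoint
  tab
}

#' Restrict an expression table to the channel gene list
#'
#' Keeps only the listed channel genes, in list order. Genes in the list but
#' absent from the table are reported in the `missing_genes` attribute (and
#' a message), never an error.
#'
#' @param table A `gene_table` (gene symbols must be unique).
#' @param channel_list Tibble with columns `gene`, `subfamily`, or a
#'   character vector of symbols. Default: the packaged 145-gene list.
#' @return The subset `gene_table` with a `subfamily` column joined on;
#'   attribute `missing_genes` lists symbols not found.
#' @export
subset_channels <- function(table, channel_list = channel_gene_list()) {
  if (is.character(channel_list)) {
    channel_list <- tibble::tibble(gene = channel_list, subfamily = NA_character_)
  }
  if (nrow(channel_list) == 0L) stop("`channel_list` must be non-empty", call. = FALSE)
  if (anyDuplicated(table$gene)) {
    stop("gene symbols in `table` are not unique", call. = FALSE)
  }
  tp <- attr(table, "timepoint")
  found <- channel_list$gene %in% table$gene
  missing <- channel_list$gene[!found]
  if (length(missing)) {
    message(sprintf("%d channel gene(s) absent from the table: %s",
                    length(missing), paste(missing, collapse = ", ")))
  }
  out <- channel_list |>
    dplyr::filter(found) |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(table),
                    -dplyr::any_of(c("subfamily", "is_channel"))),
      by = "gene") |>
    dplyr::mutate(is_channel = TRUE)
  out <- as_gene_table(out, tp)
  attr(out, "missing_genes") <- missing
  out
}

#' Flag statistically significant expression changes
#'
#' A gene is significantly altered when its q-value is at most `q_cut`
#' (inclusive, default 0.05). Rows without a q-value are flagged
#' unevaluable (`significant = NA`).
#'
#' @param table A `gene_table`.
#' @param q_cut Significance cutoff on the q-value.
#' @return The table with a logical `significant` column added.
#' @export
flag_significant <- function(table, q_cut = 0.05) {
  if (!is.numeric(q_cut) || q_cut < 0 || q_cut > 1) {
    stop("`q_cut` must be a probability in [0, 1]", call. = FALSE)
  }
  tp <- attr(table, "timepoint")
  out <- dplyr::mutate(
    tibble::as_tibble(table),
    significant = dplyr::if_else(is.na(.data$q_value), NA,
                                 .data$q_value <= q_cut))
  as_gene_table(out, tp)
}

#' Log2 fold-change matrix for heat-map display
#'
#' Builds the genes-by-timepoints matrix of log2(fold change) underlying the
#' expression heat maps. With `significant_only = TRUE`, a gene is kept when
#' it is significant in at least one timepoint, and its entries at
#' timepoints where it is not significant are set to NA -- each column shows
#' only that timepoint's significant changes.
#'
#' @param tables List of flagged `gene_table`s sharing a gene universe
#'   (typically after [subset_channels()] and [flag_significant()]).
#' @param significant_only Restrict rows/entries to significant changes.
#' @return A numeric matrix, rownames = genes, colnames = timepoints.
#' @export
log2_heatmap_matrix <- function(tables, significant_only = FALSE) {
  stopifnot(length(tables) >= 1L)
  tps <- purrr::imap_chr(tables, function(tb, i) {
    attr(tb, "timepoint") %||% as.character(i)
  })
  genes <- tables[[1]]$gene
  for (tb in tables) {
    if (!setequal(tb$gene, genes)) {
      stop("tables do not share a gene universe", call. = FALSE)
    }
    if (any(tb$fold_change <= 0, na.rm = TRUE)) {
      stop("fold_change must be positive to take log2", call. = FALSE)
    }
  }
  m <- vapply(tables, function(tb) {
    log2(tb$fold_change[match(genes, tb$gene)])
  }, numeric(length(genes)))
  m <- matrix(m, ncol = length(tables),
              dimnames = list(genes, unname(tps)))
  if (significant_only) {
    sig <- vapply(tables, function(tb) {
      if (!"significant" %in% names(tb)) {
        stop("`significant_only` requires flagged tables (see flag_significant)",
             call. = FALSE)
      }
      isTRUE_v(tb$significant[match(genes, tb$gene)])
    }, logical(length(genes)))
    sig <- matrix(sig, ncol = length(tables))
    m[!sig] <- NA_real_
    m <- m[rowSums(sig) > 0, , drop = FALSE]
  }
  m
}

isTRUE_v <- function(x) !is.na(x) & x

#' Genes dysregulated at both timepoints
#'
#' The persistently dysregulated set: genes significant in both the
#' five-week and twelve-week tables, with the direction of change at each
#' timepoint.
#'
#' @param table_5wk,table_12wk Flagged `gene_table`s.
#' @return A tibble with `gene`, `direction_5wk`, `direction_12wk`
#'   (`"up"`/`"down"`); zero rows when the significant sets are disjoint.
#' @export
persistent_dysregulated <- function(table_5wk, table_12wk) {
  for (tb in list(table_5wk, table_12wk)) {
    if (!"significant" %in% names(tb)) {
      stop("tables must be flagged first (see flag_significant)", call. = FALSE)
    }
  }
  sig5 <- dplyr::filter(tibble::as_tibble(table_5wk), isTRUE_v(.data$significant))
  sig12 <- dplyr::filter(tibble::as_tibble(table_12wk), isTRUE_v(.data$significant))
  dplyr::inner_join(
    dplyr::transmute(sig5, gene = .data$gene,
                     direction_5wk = ifelse(.data$fold_change >= 1, "up", "down")),
    dplyr::transmute(sig12, gene = .data$gene,
                     direction_12wk = ifelse(.data$fold_change >= 1, "up", "down")),
    by = "gene")
}

#' Write a gene table as CSV
#'
#' @param table A `gene_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}
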