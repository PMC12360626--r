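#' Filter a MERFISH-style cell table
#'
#' Subsets a cell-by-gene table (one row per cell; metadata columns
#' `cell_id`, `slice_id`, `region_label`, `nt_class`, `x`, `y`, then one
#' column per gene in log2(CPM+1)) by region parcellation label,
#' neurotransmitter class, and brain-slice identifiers. The three
#' predicates are conjoined; filters left `NULL` are skipped, so the
#' operation is idempotent and order-independent. Requesting a label absent
#' from the table's vocabulary warns and returns the (possibly empty)
#' subset rather than erroring.
#'
#' @param table Data frame of cells.
#' @param region Region label (e.g. `"CLA"`), or `NULL`.
#' @param nt_class Neurotransmitter class label (e.g. `"Glut"`), or `NULL`.
#' @param slice_ids Character vector of slice identifiers, or `NULL`.
#' @return The filtered tibble.
#' @export
filter_cells <- function(table, region = NULL, nt_class = NULL,
                         slice_ids = NULL) {
  out <- as_tibble(table)
  check_vocab <- function(requested, col) {
    missing <- setdiff(requested, unique(out[[col]]))
    if (length(missing) > 0) {
      warn(sprintf("No cells with %s: %s", col,
                   paste(missing, collapse = ", ")))
    }
  }
  if (!is.null(region)) {
    check_vocab(region, "region_label")
    out <- out %>% filter(.data$region_label %in% .env$region)
  }
  if (!is.null(nt_class)) {
    check_vocab(nt_class, "nt_class")
    out <- out %>% filter(.data$nt_class %in% .env$nt_class)
  }
  if (!is.null(slice_ids)) {
    check_vocab(slice_ids, "slice_id")
    out <- out %>% filter(.data$slice_id %in% .env$slice_ids)
  }
  out
}

#' Per-gene expression summary
#'
#' Quartiles (linear interpolation between order statistics, the type-7
#' convention), mean, and cell count for each requested gene over a cell
#' table, typically after [filter_cells()].
#'
#' @param table Data frame of cells with one column per gene.
#' @param genes Character vector of gene column names.
#' @return Tibble: `gene`, `q25`, `median`, `q75`, `mean`, `n`.
#' @examples
#' tab <- tibble::tibble(cell_id = 1:5, oprk1 = c(0, 1, 2, 3, 4))
#' expression_summary(tab, "oprk1")
#' @export
expression_summary <- function(table, genes) {
  if (nrow(table) == 0) abort("Empty cell table; nothing to summarise.")
  missing <- setdiff(genes, names(table))
  if (length(missing) > 0) {
    abort(sprintf("Genes absent from the table: %s",
                  paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(genes, function(g) {
    v <- table[[g]]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble(gene = g, q25 = q[1], median = q[2], q75 = q[3],
           mean = mean(v), n = length(v))
  })
}
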