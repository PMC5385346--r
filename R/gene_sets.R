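# Expression-category labelling of curated gene sets (e.g. testes-specific
# X-linked genes) and cross-cell fold comparisons.

EXPRESSION_CATEGORIES <- c("none_to_weak", "weak_to_moderate", "moderate_to_high")

#' Categorise gene-set expression per cell
#'
#' Threshold labelling of mean FPKM: below the first threshold is
#' none-to-weak, between the thresholds (boundaries included) is
#' weak-to-moderate, and strictly above the second threshold is
#' moderate-to-high. Boundary values fall in the lower category.
#'
#' @param means `xdg_group_means`
#' @param gene_list gene symbols or ids (intersection with the dataset must
#'   be non-empty)
#' @param thresholds two increasing FPKM thresholds
#' @return list with `records` (long data.frame `gene_id, symbol, cell,
#'   mean_fpkm, category`) and `counts` (category counts per cell)
#' @export
categorize_expression <- function(means, gene_list, thresholds = c(0.1, 0.5)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  ann <- means$genes
  keep <- ann$symbol %in% gene_list | ann$gene_id %in% gene_list
  if (!any(keep)) stop("none of the requested genes are in the dataset")
  ids <- ann$gene_id[keep]
  m <- means$means[keep, , drop = FALSE]
  recs <- do.call(rbind, lapply(colnames(m), function(cl) {
    v <- m[, cl]
    cat <- ifelse(v < thresholds[1], EXPRESSION_CATEGORIES[1],
                  ifelse(v <= thresholds[2], EXPRESSION_CATEGORIES[2],
                         EXPRESSION_CATEGORIES[3]))
    data.frame(gene_id = ids, symbol = ann$symbol[keep], cell = cl,
               mean_fpkm = unname(v), category = cat,
               stringsAsFactors = FALSE)
  }))
  counts <- table(cell = recs$cell,
                  category = factor(recs$category, levels = EXPRESSION_CATEGORIES))
  list(records = recs, counts = counts)
}

#' Aggregate and per-gene expression fold of a gene set between two cells
#'
#' The aggregate fold is the ratio of the set's mean expression in `cell_a`
#' to that in `cell_b`; per-gene folds are reported alongside, missing when
#' the gene's denominator is zero.
#'
#' @param means `xdg_group_means`
#' @param gene_list gene symbols or ids
#' @param cell_a,cell_b named vectors `c(sex=, group=)`
#' @return list with `aggregate_fold` and `per_gene` data.frame
#' @export
set_fold_comparison <- function(means, gene_list, cell_a, cell_b) {
  ann <- means$genes
  keep <- ann$symbol %in% gene_list | ann$gene_id %in% gene_list
  if (!any(keep)) stop("none of the requested genes are in the dataset")
  a <- get_cell(means, cell_a[["sex"]], cell_a[["group"]])[keep]
  b <- get_cell(means, cell_b[["sex"]], cell_b[["group"]])[keep]
  agg <- if (mean(b) > 0) mean(a) / mean(b) else NA_real_
  if (is.na(agg)) warning("zero aggregate denominator; fold is missing")
  list(aggregate_fold = agg,
       per_gene = data.frame(gene_id = ann$gene_id[keep],
                             symbol = ann$symbol[keep],
                             mean_a = unname(a), mean_b = unname(b),
                             fold = unname(ifelse(b > 0, a / b, NA_real_)),
                             stringsAsFactors = FALSE))
}
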