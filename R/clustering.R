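# Relative-expression heatmap matrix with deterministic hierarchical gene
# ordering, and k-means clustering of donor -> SCNT -> IVF trajectories.

reference_means <- function(dataset, reference_cell) {
  s <- dataset$samples
  ids <- s$sample_id[s$sex == reference_cell[["sex"]] &
                       s$group == reference_cell[["group"]]]
  if (!length(ids)) stop("reference cell has no samples: ",
                         paste(reference_cell, collapse = "."))
  rowMeans(dataset$matrix[, ids, drop = FALSE])
}

#' Per-sample log2 relative expression matrix with hierarchical gene order
#'
#' Rows are genes of `gene_class` (X-linked by default), columns samples;
#' entries are `log2((FPKM + pc) / (reference mean + pc))` against the mean
#' of the reference cell (male IVF by convention). All-zero gene rows are
#' dropped with a message. Gene ordering comes from average-linkage
#' hierarchical clustering on Euclidean row distance, with each dendrogram
#' branch oriented by its mean value so the order is invariant to input row
#' shuffling.
#'
#' @param dataset `xdg_dataset`
#' @param reference_cell named vector `c(sex=, group=)`
#' @param pseudocount added to numerator and denominator
#' @param gene_class chromosome class of the rows
#' @return list with `matrix` (rows in dendrogram order), `order` (gene ids)
#'   and the `hclust` object
#' @export
heatmap_matrix <- function(dataset, reference_cell = c(sex = "male", group = "IVF"),
                           pseudocount = 0.01, gene_class = "x_linked") {
  ann <- dataset$annotation
  keep <- ann$chrom_class %in% gene_class
  ref <- reference_means(dataset, reference_cell)[keep]
  m <- dataset$matrix[keep, , drop = FALSE]
  nonzero <- rowSums(m) > 0 | ref > 0
  if (any(!nonzero)) message(sum(!nonzero), " all-zero gene row(s) dropped")
  m <- m[nonzero, , drop = FALSE]; ref <- ref[nonzero]
  rel <- log2((m + pseudocount) / (ref + pseudocount))
  hc <- stats::hclust(stats::dist(rel), method = "average")
  dend <- stats::reorder(stats::as.dendrogram(hc), rowMeans(rel), agglo.FUN = mean)
  ord <- labels(dend)
  list(matrix = rel[ord, , drop = FALSE], order = ord, hclust = hc)
}

#' Gene-wise reprogramming trajectories relative to a reference cell
#'
#' For one sex, the ordered log2 relative expression of each gene across the
#' reprogramming series (donor cells, SCNT, IVF by default), against the
#' male-IVF group mean. Genes with a zero reference mean are excluded (count
#' messaged) when no pseudocount is used.
#'
#' @param dataset `xdg_dataset` containing all requested groups
#' @param sex sex of the trajectory columns
#' @param groups ordered groups forming the trajectory
#' @param reference_cell reference for the relative scale
#' @param pseudocount added to numerator and denominator
#' @param gene_class chromosome class of the rows
#' @return numeric matrix, genes x groups, of log2 relative expression
#' @export
trajectory_matrix <- function(dataset, sex = "female",
                              groups = c("DONOR", "SCNT", "IVF"),
                              reference_cell = c(sex = "male", group = "IVF"),
                              pseudocount = 0.01, gene_class = "x_linked") {
  ann <- dataset$annotation
  keep <- ann$chrom_class %in% gene_class
  ref <- reference_means(dataset, reference_cell)[keep]
  gm <- group_means(dataset)
  cols <- vapply(groups, function(g) get_cell(gm, sex, g)[keep],
                 numeric(sum(keep)))
  ok <- ref + pseudocount > 0
  if (any(!ok)) message(sum(!ok), " gene(s) with zero reference mean excluded")
  rel <- log2((cols[ok, , drop = FALSE] + pseudocount) / (ref[ok] + pseudocount))
  rownames(rel) <- ann$gene_id[keep][ok]
  colnames(rel) <- groups
  rel
}

#' K-means clustering of expression trajectories
#'
#' Standard k-means (Lloyd-type iterations via [stats::kmeans()]) with
#' `n_restarts` random starts, deterministic given `seed`; the best restart
#' by within-cluster sum of squares is kept. When fewer distinct points than
#' `k` exist, `k` is reduced with a warning.
#'
#' @param traj matrix from [trajectory_matrix()] (>= k rows)
#' @param k number of clusters
#' @param seed RNG seed for the restarts
#' @param n_restarts number of random starts
#' @return list with `assignment` (named cluster id per gene), `centers`,
#'   `sizes` (per-cluster frequencies) and `tot_withinss`
#' @export
kmeans_trajectories <- function(traj, k = 9, seed = 1, n_restarts = 10) {
  stopifnot(nrow(traj) >= k)
  n_distinct <- nrow(unique(traj))
  if (n_distinct < k) {
    warning("only ", n_distinct, " distinct points; reducing k")
    k <- n_distinct
  }
  set.seed(seed)
  km <- stats::kmeans(traj, centers = k, nstart = n_restarts, iter.max = 100)
  assignment <- km$cluster
  names(assignment) <- rownames(traj)
  list(assignment = assignment, centers = km$centers,
       sizes = as.integer(km$size), tot_withinss = km$tot.withinss)
}
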