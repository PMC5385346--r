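# Core dosage statistics: per-cell group means, female:male ratio tables and
# aggregates, per-sample X:A ratios, ratio histograms, expressed-gene counts,
# threshold proportions, and the nonparametric distribution comparisons.

cell_label <- function(sex, group, lineage = NULL) {
  if (is.null(lineage)) paste(sex, group, sep = ".")
  else paste(sex, group, lineage, sep = ".")
}

#' Per-gene mean FPKM for each (sex, group, lineage) cell
#'
#' @param dataset `xdg_dataset`
#' @param by grouping columns of the sample sheet; either
#'   `c("sex","group")` (default) or `c("sex","group","lineage")`
#' @return object of class `xdg_group_means`: list with `means` (genes x
#'   cells matrix of arithmetic mean FPKM), `cells` (cell descriptors) and
#'   `genes` (the dataset's annotation)
#' @export
group_means <- function(dataset, by = c("sex", "group")) {
  stopifnot(inherits(dataset, "xdg_dataset"),
            all(by %in% c("sex", "group", "lineage")))
  s <- dataset$samples
  key <- interaction(s[by], drop = TRUE, sep = ".", lex.order = FALSE)
  cells <- unique(data.frame(s[by], cell = as.character(key),
                             stringsAsFactors = FALSE))
  m <- vapply(cells$cell, function(cl) {
    rowMeans(dataset$matrix[, key == cl, drop = FALSE])
  }, numeric(nrow(dataset$matrix)))
  colnames(m) <- cells$cell
  structure(list(means = m, cells = cells, genes = dataset$annotation),
            class = "xdg_group_means")
}

get_cell <- function(means, sex, group, lineage = NULL) {
  lbl <- cell_label(sex, group, lineage)
  if (!lbl %in% colnames(means$means)) {
    # lineage-resolved means may still carry WHOLE labels
    lbl2 <- cell_label(sex, group, "WHOLE")
    if (is.null(lineage) && lbl2 %in% colnames(means$means)) lbl <- lbl2
    else stop("cell not present in group means: ", lbl)
  }
  means$means[, lbl]
}

#' Per-gene female:male ratio table for one group
#'
#' Computes `log2((female_mean + pc) / (male_mean + pc))` per gene, with the
#' ratio left missing when either sex mean is zero and no pseudocount is
#' used. `passes_min_fpkm` flags genes whose larger sex mean exceeds
#' `min_fpkm` (the expression filter applied before distribution statistics).
#'
#' @param means `xdg_group_means`
#' @param group group present in both sexes (hard error otherwise)
#' @param min_fpkm expression filter on `max(female_mean, male_mean)`
#' @param pseudocount added to both means before the ratio (0 = off)
#' @param gene_class optional chromosome-class restriction
#'   (e.g. `"x_linked"`, `"autosomal"`)
#' @param exclude_xist drop XIST from the table?
#' @param exclude_par drop pseudoautosomal genes?
#' @return data.frame `gene_id, female_mean, male_mean, log2_fm,
#'   passes_min_fpkm`
#' @export
fm_ratios <- function(means, group, min_fpkm = 1, pseudocount = 0,
                      gene_class = NULL, exclude_xist = FALSE,
                      exclude_par = FALSE) {
  f <- get_cell(means, "female", group)
  m <- get_cell(means, "male", group)
  ann <- means$genes
  keep <- rep(TRUE, nrow(ann))
  if (!is.null(gene_class)) keep <- keep & ann$chrom_class %in% gene_class
  if (exclude_xist) keep <- keep & !ann$is_xist
  if (exclude_par) keep <- keep & !ann$is_par
  f <- f[keep]; m <- m[keep]
  l2 <- ifelse(pseudocount > 0 | (f > 0 & m > 0),
               log2((f + pseudocount) / (m + pseudocount)), NA_real_)
  data.frame(gene_id = ann$gene_id[keep],
             female_mean = unname(f), male_mean = unname(m),
             log2_fm = unname(l2),
             passes_min_fpkm = unname(pmax(f, m) > min_fpkm),
             stringsAsFactors = FALSE)
}

#' Aggregate female:male X-linked expression ratio
#'
#' Default mode is the ratio of aggregate means: the mean female FPKM over
#' qualifying genes divided by the mean male FPKM over the same genes. This
#' is stable under small denominators, unlike averaging per-gene ratios
#' (available as `mode = "per_gene"`). Qualifying genes are of the requested
#' class, pass the expression filter, and have both sex means positive.
#'
#' @param means `xdg_group_means`
#' @param group group present in both sexes
#' @param gene_class chromosome class of the aggregate (default X-linked)
#' @param min_fpkm expression filter on `max(female_mean, male_mean)`
#' @param exclude_xist drop XIST before aggregating?
#' @param mode `"aggregate"` (ratio of means) or `"per_gene"` (mean of
#'   per-gene ratios)
#' @return single numeric fold
#' @export
fm_mean_ratio <- function(means, group, gene_class = "x_linked", min_fpkm = 1,
                          exclude_xist = FALSE,
                          mode = c("aggregate", "per_gene")) {
  mode <- match.arg(mode)
  fm <- fm_ratios(means, group, min_fpkm = min_fpkm, gene_class = gene_class,
                  exclude_xist = exclude_xist)
  fm <- fm[fm$passes_min_fpkm & fm$female_mean > 0 & fm$male_mean > 0, ]
  if (!nrow(fm)) stop("no qualifying genes for fm_mean_ratio")
  if (mode == "aggregate") {
    den <- mean(fm$male_mean)
    if (den == 0) stop("male aggregate mean is zero")
    mean(fm$female_mean) / den
  } else {
    mean(fm$female_mean / fm$male_mean)
  }
}

#' Per-sample X:A expression ratio
#'
#' For each sample, the mean FPKM over X-linked genes passing the expression
#' filter divided by the mean FPKM over passing autosomal genes (the filter
#' is applied per sample). Expected near 0.5 with one active X against
#' biallelic autosomes and near 1 with two active X chromosomes.
#'
#' @param dataset `xdg_dataset`
#' @param expressed_min_fpkm per-sample expression filter
#' @param exclude_xist drop XIST from the X aggregate?
#' @param exclude_par drop pseudoautosomal genes from the X aggregate?
#' @return data.frame `sample_id, sex, group, lineage, mean_x, mean_a,
#'   xa_ratio`
#' @export
xa_ratios <- function(dataset, expressed_min_fpkm = 0.1,
                      exclude_xist = FALSE, exclude_par = FALSE) {
  ann <- dataset$annotation
  xg <- ann$chrom_class == "x_linked"
  if (exclude_xist) xg <- xg & !ann$is_xist
  if (exclude_par) xg <- xg & !ann$is_par
  ag <- ann$chrom_class == "autosomal"
  res <- lapply(colnames(dataset$matrix), function(id) {
    v <- dataset$matrix[, id]
    xs <- v[xg][v[xg] > expressed_min_fpkm]
    as <- v[ag][v[ag] > expressed_min_fpkm]
    mx <- if (length(xs)) mean(xs) else NA_real_
    ma <- if (length(as)) mean(as) else NA_real_
    if (is.na(mx)) warning("no X-linked genes pass the filter in sample ", id)
    data.frame(sample_id = id, mean_x = mx, mean_a = ma,
               xa_ratio = if (!is.na(mx) && !is.na(ma) && ma > 0) mx / ma
                          else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  i <- match(out$sample_id, dataset$samples$sample_id)
  cbind(out[, "sample_id", drop = FALSE],
        dataset$samples[i, c("sex", "group", "lineage")],
        out[, c("mean_x", "mean_a", "xa_ratio")],
        row.names = NULL)
}

#' Histogram of log2 female:male ratios
#'
#' Left-closed right-open bins of width `bin_width` aligned at zero; counts
#' sum to the number of defined, filter-passing ratios.
#'
#' @param fm table from [fm_ratios()]
#' @param bin_width bin size in log2 units
#' @return data.frame `bin_start, bin_end, count`
#' @export
fm_histogram <- function(fm, bin_width = 0.2) {
  v <- fm$log2_fm[!is.na(fm$log2_fm) & fm$passes_min_fpkm]
  if (!length(v)) stop("no defined ratios to bin")
  idx <- floor(v / bin_width + 1e-9)
  tab <- table(idx)
  i <- as.integer(names(tab))
  data.frame(bin_start = i * bin_width, bin_end = (i + 1) * bin_width,
             count = as.integer(tab))
}

#' Two-sample Mann-Whitney and Kolmogorov-Smirnov comparison
#'
#' Two-sided tests on two lists of (ratio) values; exact small-sample
#' p-values where the underlying tests support them (no ties, small n).
#' Fully tied degenerate input yields p = 1 with a warning.
#'
#' @param a,b numeric vectors (>= 3 defined values each)
#' @return one-row data.frame `mw_statistic, mw_p, ks_statistic, ks_p`
#' @export
compare_distributions <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) stop("need >= 3 defined values per list")
  degenerate <- length(unique(c(a, b))) == 1L
  if (degenerate) warning("fully tied input; p-values set to 1")
  mw <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  ks <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  data.frame(mw_statistic = unname(mw$statistic),
             mw_p = if (degenerate || is.na(mw$p.value)) 1 else mw$p.value,
             ks_statistic = unname(ks$statistic),
             ks_p = if (degenerate || is.na(ks$p.value)) 1 else ks$p.value)
}

#' Rank-based test for a male-female X:A difference within one group
#'
#' The X:A values of the two sexes are unpaired samples, so the default is
#' the two-sided Mann-Whitney rank-sum test; a signed-rank mode is retained
#' for genuinely paired designs.
#'
#' @param xa table from [xa_ratios()]
#' @param group group to test (both sexes required, >= 2 samples each)
#' @param paired use the paired signed-rank test?
#' @return p-value
#' @export
sexed_xa_test <- function(xa, group, paired = FALSE) {
  f <- xa$xa_ratio[xa$group == group & xa$sex == "female"]
  m <- xa$xa_ratio[xa$group == group & xa$sex == "male"]
  f <- f[!is.na(f)]; m <- m[!is.na(m)]
  if (length(f) < 2 || length(m) < 2) stop("need >= 2 samples per sex in group ", group)
  p <- suppressWarnings(
    stats::wilcox.test(f, m, paired = paired, alternative = "two.sided")$p.value)
  if (is.na(p)) 1 else p
}

#' Count genes of a class expressed above a threshold, per group
#'
#' A gene counts as expressed in a group when the larger of its two sex means
#' exceeds `threshold` (sexes pooled by max, so a gene expressed in either
#' sex counts).
#'
#' @param means `xdg_group_means`
#' @param gene_class chromosome class to count
#' @param threshold mean-FPKM expression threshold
#' @return named integer vector per group
#' @export
expressed_counts <- function(means, gene_class = "x_linked", threshold = 0.1) {
  ann <- means$genes
  keep <- ann$chrom_class %in% gene_class
  groups <- unique(means$cells$group)
  out <- vapply(groups, function(g) {
    cl <- means$cells$cell[means$cells$group == g]
    pooled <- apply(means$means[keep, cl, drop = FALSE], 1, max)
    sum(pooled > threshold)
  }, integer(1))
  names(out) <- groups
  out
}

#' Proportion of genes whose female:male ratio strictly exceeds given folds
#'
#' Computed over defined, filter-passing genes of the ratio table; strict
#' inequality, so ratios exactly at the fold do not count.
#'
#' @param fm table from [fm_ratios()]
#' @param folds thresholds on the (linear) female:male ratio
#' @return named numeric vector of proportions in `[0, 1]`
#' @export
fm_exceed_proportions <- function(fm, folds = c(1, 2)) {
  keep <- !is.na(fm$log2_fm) & fm$passes_min_fpkm & fm$male_mean > 0
  if (!any(keep)) stop("no defined ratios")
  ratio <- fm$female_mean[keep] / fm$male_mean[keep]
  out <- vapply(folds, function(k) mean(ratio > k), numeric(1))
  names(out) <- paste0("gt", folds)
  out
}
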