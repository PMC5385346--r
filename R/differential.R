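# Sex-differential expression within a group, partition into X-linked vs
# autosomal DEGs with direction accounting, volcano coordinates, and DEG-set
# overlap between groups.

row_welch_t <- function(xf, xm) {
  nf <- ncol(xf); nm <- ncol(xm)
  mf <- rowMeans(xf); mm <- rowMeans(xm)
  vf <- rowSums((xf - mf)^2) / (nf - 1)
  vm <- rowSums((xm - mm)^2) / (nm - 1)
  se2 <- vf / nf + vm / nm
  t <- (mf - mm) / sqrt(se2)
  df <- se2^2 / ((vf / nf)^2 / (nf - 1) + (vm / nm)^2 / (nm - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # both variances zero: p = 1 for equal means, ~0 otherwise
  degen <- se2 == 0
  p[degen] <- ifelse(mf[degen] == mm[degen], 1, 0)
  list(t = t, df = df, p = p)
}

#' Per-gene sex-differential expression within one group
#'
#' Genes passing `min_mean_fpkm` in at least one sex are tested with a
#' two-sided Welch two-sample t-test on `log2(FPKM + 1)` (vectorised across
#' genes); a rank-sum alternative is available via `method`. P-values are
#' unadjusted by default, matching the nominal `p < 0.05` DEG convention of
#' single-embryo designs; set `adjust = "BH"` for FDR control. Fold changes
#' are computed from group FPKM means with a 0.01 pseudocount so they remain
#' finite for display.
#'
#' @param dataset `xdg_dataset`
#' @param group group to test (>= 2 samples per sex)
#' @param alpha significance level
#' @param min_mean_fpkm expression filter (mean FPKM in >= 1 sex)
#' @param method `"welch"` or `"wilcoxon"`
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method applied
#'   before the significance call
#' @param pseudocount_fc pseudocount used for the displayed fold change
#' @return data.frame of DEG records: `gene_id, group, p_value, log2_fc,
#'   direction, chrom_class, is_significant` (plus `p_adjusted` when
#'   adjusting)
#' @export
sex_de_test <- function(dataset, group, alpha = 0.05, min_mean_fpkm = 0.1,
                        method = c("welch", "wilcoxon"), adjust = "none",
                        pseudocount_fc = 0.01) {
  method <- match.arg(method)
  s <- dataset$samples
  fid <- s$sample_id[s$group == group & s$sex == "female"]
  mid <- s$sample_id[s$group == group & s$sex == "male"]
  if (length(fid) < 2 || length(mid) < 2) {
    stop("need >= 2 samples per sex in group ", group)
  }
  mf <- rowMeans(dataset$matrix[, fid, drop = FALSE])
  mm <- rowMeans(dataset$matrix[, mid, drop = FALSE])
  keep <- mf > min_mean_fpkm | mm > min_mean_fpkm
  lf <- log2(dataset$matrix[keep, fid, drop = FALSE] + 1)
  lm_ <- log2(dataset$matrix[keep, mid, drop = FALSE] + 1)
  p <- if (method == "welch") {
    row_welch_t(lf, lm_)$p
  } else {
    vapply(seq_len(nrow(lf)), function(i) {
      suppressWarnings(stats::wilcox.test(lf[i, ], lm_[i, ])$p.value)
    }, numeric(1))
  }
  p[is.na(p)] <- 1
  l2fc <- log2((mf[keep] + pseudocount_fc) / (mm[keep] + pseudocount_fc))
  ann <- dataset$annotation
  out <- data.frame(
    gene_id = ann$gene_id[keep],
    group = group,
    p_value = unname(p),
    log2_fc = unname(l2fc),
    direction = ifelse(l2fc >= 0, "female_high", "male_high"),
    chrom_class = ann$chrom_class[keep],
    stringsAsFactors = FALSE
  )
  if (!identical(adjust, "none")) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
    out$is_significant <- out$p_adjusted < alpha
  } else {
    out$is_significant <- out$p_value < alpha
  }
  attr(out, "alpha") <- alpha
  out
}

#' Partition significant DEGs into X-linked and autosomal sets
#'
#' @param degs table from [sex_de_test()]
#' @param annotation unused when `degs` already carries `chrom_class`;
#'   otherwise joined by `gene_id`
#' @return list with `xdegs` and `adegs` (significant records), a `counts`
#'   data.frame over (chrom_class, direction), and `proportions`
#' @export
classify_degs <- function(degs, annotation = NULL) {
  if (is.null(degs$chrom_class)) {
    degs$chrom_class <- annotation$chrom_class[match(degs$gene_id,
                                                     annotation$gene_id)]
  }
  sig <- degs[degs$is_significant, ]
  xdegs <- sig[sig$chrom_class == "x_linked", ]
  adegs <- sig[sig$chrom_class == "autosomal", ]
  xa <- sig[sig$chrom_class %in% c("x_linked", "autosomal"), ]
  counts <- as.data.frame(table(
    chrom_class = factor(xa$chrom_class, levels = c("x_linked", "autosomal")),
    direction = factor(xa$direction,
                       levels = c("female_high", "male_high"))),
    stringsAsFactors = FALSE)
  names(counts)[3] <- "count"
  prop <- function(d) if (nrow(d)) mean(d$direction == "female_high") else NA_real_
  list(xdegs = xdegs, adegs = adegs, counts = counts,
       proportions = c(xdeg_female_high = prop(xdegs),
                       adeg_female_high = prop(adegs)))
}

#' Overlap of two DEG sets
#'
#' @param degs_a,degs_b DEG tables (their significant gene ids) or plain
#'   character vectors of gene ids
#' @return list with `counts` (only_a, only_b, both) and the member id lists
#' @export
overlap_sets <- function(degs_a, degs_b) {
  ids <- function(x) {
    if (is.character(x)) unique(x)
    else unique(x$gene_id[if (is.null(x$is_significant)) TRUE else x$is_significant])
  }
  a <- ids(degs_a); b <- ids(degs_b)
  both <- intersect(a, b)
  list(counts = c(only_a = length(setdiff(a, b)),
                  only_b = length(setdiff(b, a)),
                  both = length(both)),
       only_a = setdiff(a, b), only_b = setdiff(b, a), both = both)
}

#' Volcano-plot coordinates for a DEG table
#'
#' One row per tested gene: `log2_fc` against `-log10(p)`, with a fold-change
#' stratum label. Zero p-values are clipped to the smallest representable
#' double.
#'
#' @param degs table from [sex_de_test()]
#' @param fold_breaks stratum boundaries on the linear fold change
#' @return data.frame `gene_id, log2_fc, neg_log10_p, stratum`
#' @export
volcano_table <- function(degs, fold_breaks = c(1, 2, 4)) {
  p <- pmax(degs$p_value, .Machine$double.xmin)
  fold <- 2^abs(degs$log2_fc)
  stratum <- cut(fold, breaks = c(0, fold_breaks, Inf), right = TRUE,
                 labels = c(paste0("<=", fold_breaks), paste0(">", max(fold_breaks))))
  data.frame(gene_id = degs$gene_id, log2_fc = degs$log2_fc,
             neg_log10_p = -log10(p), stratum = as.character(stratum),
             stringsAsFactors = FALSE)
}
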