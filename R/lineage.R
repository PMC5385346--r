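# Paired IT (ICM + TE) versus TE-only comparison: X-linked dosage, X:A
# ratios, and XIST levels per dissected blastocyst. The design is genuinely
# paired, so paired tests are used throughout.

#' Per-embryo IT/TE expression summary
#'
#' For each embryo with both parts present: the mean X-linked FPKM of each
#' part (reported normalised so the IT group mean is exactly 1), the
#' per-embryo IT:TE ratio (computed before normalisation), each part's X:A
#' ratio, and each part's XIST expression. Unpaired parts are excluded with
#' a warning.
#'
#' @param dataset `xdg_dataset` with paired IT/TE samples
#' @param expressed_min_fpkm filter for the X:A ratios
#' @return data.frame of class `xdg_lineage_pairs`: `embryo_id, it_mean_x,
#'   te_mean_x, it_te_ratio, it_xa, te_xa, xist_it, xist_te`
#' @export
lineage_pairs <- function(dataset, expressed_min_fpkm = 0.1) {
  s <- dataset$samples
  it <- s[s$lineage == "IT", ]
  te <- s[s$lineage == "TE", ]
  embryos <- intersect(it$embryo_id, te$embryo_id)
  if (!length(embryos)) stop("no paired IT/TE embryos in dataset")
  orphan <- setdiff(union(it$embryo_id, te$embryo_id), embryos)
  if (length(orphan)) warning(length(orphan), " unpaired part(s) excluded")

  ann <- dataset$annotation
  xg <- ann$chrom_class == "x_linked"
  xist <- ann$gene_id[ann$is_xist]
  xa <- xa_ratios(dataset, expressed_min_fpkm = expressed_min_fpkm)

  one <- function(sample_id) {
    v <- dataset$matrix[, sample_id]
    c(mean_x = mean(v[xg]),
      xa = xa$xa_ratio[xa$sample_id == sample_id],
      xist = if (length(xist)) unname(v[xist[1]]) else NA_real_)
  }
  it_ids <- it$sample_id[match(embryos, it$embryo_id)]
  te_ids <- te$sample_id[match(embryos, te$embryo_id)]
  itv <- vapply(it_ids, one, numeric(3))
  tev <- vapply(te_ids, one, numeric(3))

  raw_it <- itv["mean_x", ]; raw_te <- tev["mean_x", ]
  out <- data.frame(
    embryo_id = embryos,
    it_mean_x = unname(raw_it / mean(raw_it)),
    te_mean_x = unname(raw_te / mean(raw_it)),
    it_te_ratio = unname(ifelse(raw_te > 0, raw_it / raw_te, NA_real_)),
    it_xa = unname(itv["xa", ]),
    te_xa = unname(tev["xa", ]),
    xist_it = unname(itv["xist", ]),
    xist_te = unname(tev["xist", ]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("xdg_lineage_pairs", "data.frame")
  out
}

#' Paired test for an IT versus TE X:A difference
#'
#' Two-sided paired Wilcoxon signed-rank test on the per-embryo
#' (it_xa, te_xa) pairs. All-zero differences yield p = 1.
#'
#' @param pairs table from [lineage_pairs()] (>= 3 pairs)
#' @return p-value
#' @export
lineage_xa_test <- function(pairs) {
  ok <- !is.na(pairs$it_xa) & !is.na(pairs$te_xa)
  if (sum(ok) < 3) stop("need >= 3 complete pairs")
  d <- pairs$it_xa[ok] - pairs$te_xa[ok]
  if (all(d == 0)) return(1)
  p <- suppressWarnings(
    stats::wilcox.test(pairs$it_xa[ok], pairs$te_xa[ok], paired = TRUE,
                       alternative = "two.sided")$p.value)
  if (is.na(p)) 1 else p
}

#' IT versus TE XIST comparison
#'
#' Per-part mean and standard deviation of XIST expression plus a two-sided
#' paired signed-rank test at the stated significance level.
#'
#' @param pairs table from [lineage_pairs()]
#' @param alpha significance level reported alongside the test
#' @return list `it_mean, it_sd, te_mean, te_sd, p_value, alpha, significant`
#' @export
xist_compare <- function(pairs, alpha = 0.01) {
  if (all(is.na(pairs$xist_it))) {
    warning("XIST absent from dataset; comparison skipped")
    return(NULL)
  }
  d <- pairs$xist_it - pairs$xist_te
  p <- if (all(d == 0)) 1 else {
    pv <- suppressWarnings(
      stats::wilcox.test(pairs$xist_it, pairs$xist_te, paired = TRUE,
                         alternative = "two.sided")$p.value)
    if (is.na(pv)) 1 else pv
  }
  list(it_mean = mean(pairs$xist_it), it_sd = stats::sd(pairs$xist_it),
       te_mean = mean(pairs$xist_te), te_sd = stats::sd(pairs$xist_te),
       p_value = p, alpha = alpha, significant = p < alpha)
}
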