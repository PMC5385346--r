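# Shared fixtures: hand-built datasets and reduced-size simulation profiles.

# Reduced-size calibrated profile: keeps every distributional feature of the
# default profile but shrinks the gene complement for fast property loops.
fast_profile <- function(seed, n_autosomal_genes = 800, n_x_genes = 150,
                         n_y_genes = 6, testes_gene_count = 12, ...) {
  paper_profile(seed = seed, n_autosomal_genes = n_autosomal_genes,
                n_x_genes = n_x_genes, n_y_genes = n_y_genes,
                testes_gene_count = testes_gene_count, ...)
}

fast_null <- function(seed, n_autosomal_genes = 300, n_x_genes = 80, ...) {
  null_profile(seed = seed, n_autosomal_genes = n_autosomal_genes,
               n_x_genes = n_x_genes, testes_gene_count = 0, ...)
}

# Minimal annotation row constructor.
make_ann <- function(gene_id, symbol = gene_id, chrom = "1",
                     start = seq(1e6, by = 1e6, length.out = length(gene_id)),
                     end = start + 999, strand = "+") {
  df <- data.frame(gene_id = gene_id, symbol = symbol, chrom = as.character(chrom),
                   start_bp = as.integer(start), end_bp = as.integer(end),
                   strand = strand, stringsAsFactors = FALSE)
  xdosage:::finish_annotation(df, c("ZBED1", "CD99"), NULL,
                              c("GAPDH", "ACTB"))
}

# Hand dataset: `mat` is genes x samples with dimnames; samples described by
# parallel vectors.
make_ds <- function(ann, mat, sex, group, lineage = "WHOLE", embryo_id = "") {
  samples <- data.frame(sample_id = colnames(mat), sex = sex, group = group,
                        lineage = lineage, embryo_id = embryo_id,
                        stringsAsFactors = FALSE)
  validate_dataset(ann, mat, samples)
}

# Dataset with genes at chosen start coordinates for window assignment tests.
window_test_ds <- function(starts, fpkm, chrom = "1", chrom_len = 5e6) {
  n <- length(starts)
  ann <- make_ann(c(sprintf("w%d", seq_len(n)), "x1", "a_pad"),
                  chrom = c(rep(chrom, n), "X", "2"),
                  start = c(starts, 1e6, 1e6))
  mat <- cbind(s1 = c(fpkm, 1, 1), s2 = c(fpkm, 1, 1))
  rownames(mat) <- ann$gene_id
  make_ds(ann, mat, sex = c("female", "female"), group = "IVF")
}

# A tiny two-sex dataset: 1 autosomal + n_x X-linked genes, explicit values.
two_sex_ds <- function(x_female, x_male, a_female = 1, a_male = 1,
                       group = "IVF") {
  n_x <- length(x_female)
  ann <- make_ann(c("a1", paste0("x", seq_len(n_x))),
                  chrom = c("1", rep("X", n_x)))
  mat <- rbind(c(a_female, a_male), cbind(x_female, x_male))
  dimnames(mat) <- list(ann$gene_id, c("F1", "M1"))
  # duplicate columns so every cell has two samples (test prerequisites)
  mat <- cbind(mat, mat)
  colnames(mat) <- c("F1", "M1", "F2", "M2")
  make_ds(ann, mat, sex = c("female", "male", "female", "male"), group = group)
}
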