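test_that("annotation loading derives chromosome classes and gene flags", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsymbol\tchrom\tstart\tend\tstrand",
               "g1\tXIST\tX\t100\t900\t+",
               "g2\tGAPDH\t5\t10\t20\t-",
               "g3\tZBED1\tchrX\t500\t600\t*",
               "g4\tFOO\tScaffold_12\t1\t10\t+"), f)
  ann <- load_annotation(f)
  expect_equal(ann$chrom_class, c("x_linked", "autosomal", "x_linked", "unmapped"))
  expect_equal(ann$is_xist, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(ann$is_housekeeping[2])
  expect_true(ann$is_par[3])
  expect_equal(ann$strand[3], "unknown")
  expect_true(ann$is_unmapped[4])

  writeLines(c("gene_id\tsymbol\tchrom\tstart\tend\tstrand",
               "g1\tA\t1\t10\t20\t+", "g1\tB\t2\t10\t20\t+"), f)
  expect_error(load_annotation(f), "duplicate gene_id")
  writeLines(c("gene_id\tsymbol\tchrom\tstart\tend\tstrand",
               "gbad\tA\t1\t50\t20\t+"), f)
  expect_error(load_annotation(f), "gbad")
})

test_that("GTF annotation reduces multi-exon genes to one spanning record", {
  skip_if_not_installed("rtracklayer")
  f <- withr::local_tempfile(fileext = ".gtf")
  attrs <- 'gene_id "gA"; gene_name "MYGENE";'
  writeLines(c(
    paste("X", "test", "exon", "1000", "1200", ".", "+", ".", attrs, sep = "\t"),
    paste("X", "test", "exon", "2000", "2500", ".", "+", ".", attrs, sep = "\t"),
    paste("X", "test", "exon", "1500", "1700", ".", "+", ".", attrs, sep = "\t")), f)
  ann <- load_annotation(f)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$start_bp, 1000L)   # min over the three printed lines
  expect_equal(ann$end_bp, 2500L)     # max over the three printed lines
  expect_equal(ann$symbol, "MYGENE")
  expect_equal(ann$chrom_class, "x_linked")
})

test_that("expression loading parses values exactly and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1.5\t0", "g2\t3\t2.25"), f)
  m <- load_expression(f)
  expect_identical(dim(m), c(2L, 2L))
  expect_equal(unname(m), rbind(c(1.5, 0), c(3, 2.25)))

  writeLines(c("gene_id\ts1\ts1", "g1\t1\t2"), f)
  expect_error(load_expression(f), "duplicated sample")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t-2"), f)
  expect_error(load_expression(f), "negative")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\tabc"), f)
  expect_error(load_expression(f), "gene 'g1', sample 's2'")
})

test_that("expression tables round-trip through write and load", {
  set.seed(7)
  m <- matrix(round(stats::rexp(20, 0.2), 6), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, f, params = list(note = "roundtrip"))
  m2 <- load_expression(f)
  expect_identical(dimnames(m2), dimnames(m))
  expect_equal(m2, m, tolerance = 1e-9)
})

test_that("sample sheets validate counts, lineage defaults and enum errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "sample_id\tsex\tgroup\tlineage\tembryo_id"
  rows <- c(sprintf("m%d\tMale\tivf\tWHOLE\t", 1:6),
            sprintf("f%d\tfemale\tIVF\tWHOLE\t", 1:6))
  writeLines(c(hdr, rows), f)
  s <- load_samples(f)
  cnt <- sample_counts(s)
  expect_equal(cnt["male", "IVF"], 6L, ignore_attr = TRUE)
  expect_equal(cnt["female", "IVF"], 6L, ignore_attr = TRUE)

  writeLines(c("sample_id\tsex\tgroup", "a\tfemale\tIVF"), f)
  expect_equal(load_samples(f)$lineage, "WHOLE")

  writeLines(c(hdr, "a\tfemale\tIVF\tIT\t"), f)
  expect_error(load_samples(f), "embryo_id")
  writeLines(c(hdr, "a\tfemale\tNOPE\tWHOLE\t"), f)
  expect_error(load_samples(f), "IVF, SCNT, SHAM, DONOR")
})

test_that("dataset validation intersects inputs and is idempotent", {
  ann <- make_ann(paste0("g", 1:5), chrom = c("1", "2", "X", "X", "3"))
  mat <- matrix(1:9, 3, 3, dimnames = list(c("g1", "g3", "g4"),
                                           c("s1", "s2", "s3")))
  samples <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                        sex = "female", group = "IVF", lineage = "WHOLE",
                        embryo_id = "", stringsAsFactors = FALSE)
  ds <- suppressWarnings(validate_dataset(ann, mat, samples))
  expect_equal(rownames(ds$matrix), c("g1", "g3", "g4"))  # set intersection
  expect_equal(ds$samples$sample_id, c("s1", "s2", "s3"))
  w <- capture_warnings(validate_dataset(ann, mat, samples))
  expect_true(any(grepl("gene id", w)))   # dropped gene count reported
  expect_true(any(grepl("sample id", w))) # dropped sample count reported

  ds2 <- validate_dataset(ds$annotation, ds$matrix, ds$samples)
  expect_identical(ds2$matrix, ds$matrix)
  expect_identical(ds2$annotation, ds$annotation)
  expect_identical(ds2$samples, ds$samples)

  bad <- mat; rownames(bad) <- paste0("z", 1:3)
  expect_error(validate_dataset(ann, bad, samples), "no genes shared")
})

test_that("sample correlation is symmetric, unit-diagonal and log-invariant", {
  ds <- generate_dataset(fast_profile(3), groups = "IVF")
  r <- sample_correlation(ds)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, ncol(ds$matrix)))

  # doubling a sample is removed by the log transform (affine invariance)
  m <- cbind(s1 = c(1, 4, 9, 2), s2 = 2 * c(1, 4, 9, 2))
  expect_equal(sample_correlation(m, pseudocount = 0)[1, 2], 1)

  # brute-force Pearson on log2(FPKM+1) for a hand-sized table
  m3 <- cbind(s1 = c(1, 4, 9, 2), s2 = c(2, 3, 10, 1), s3 = c(5, 5, 1, 7))
  lg <- log2(m3 + 1)
  manual <- function(x, y) {
    mean((x - mean(x)) * (y - mean(y))) / (sqrt(mean((x - mean(x))^2)) *
                                             sqrt(mean((y - mean(y))^2)))
  }
  r3 <- sample_correlation(m3)
  expect_equal(r3[1, 2], manual(lg[, 1], lg[, 2]))
  expect_equal(r3[2, 3], manual(lg[, 2], lg[, 3]))

  # zero-variance sample: undefined correlations reported as missing
  m4 <- cbind(s1 = c(1, 2, 3), s2 = c(0, 0, 0))
  r4 <- sample_correlation(m4)
  expect_true(is.na(r4[1, 2]))
  expect_equal(unname(diag(r4)), c(1, 1))
})

test_that("housekeeping CV is exact on hand values and low for replicates", {
  ann <- make_ann(c("g1", "g2", "x1"), symbol = c("GAPDH", "ACTB", "x1"),
                  chrom = c("1", "1", "X"))
  mat <- rbind(c(2, 2, 2), c(1, 2, 3), c(1, 1, 1))
  dimnames(mat) <- list(ann$gene_id, c("s1", "s2", "s3"))
  ds <- make_ds(ann, mat, sex = "female", group = "IVF")
  cv <- housekeeping_variability(ds)
  expect_equal(cv$cv[cv$gene_id == "g1"], 0)
  expect_equal(cv$cv[cv$gene_id == "g2"], stats::sd(c(1, 2, 3)) / 2)

  # technical replicates vary less than independent embryos
  reps <- generate_replicates(fast_profile(11), n_replicates = 4)
  emb <- generate_dataset(fast_profile(11), groups = "IVF", sexes = "female")
  cv_rep <- housekeeping_variability(reps)
  cv_emb <- housekeeping_variability(emb)
  expect_lt(mean(cv_rep$cv, na.rm = TRUE), mean(cv_emb$cv, na.rm = TRUE))
})

test_that("sex-marker verification follows the marker logic and matches truth", {
  ann <- make_ann(c("a1", "x1", "y1"), symbol = c("A1", "XIST", "DDX3Y"),
                  chrom = c("1", "X", "Y"))
  mat <- rbind(a1 = c(5, 5, 5), x1 = c(50, 0, 50), y1 = c(0, 5, 5))
  colnames(mat) <- c("s1", "s2", "s3")
  ds <- make_ds(ann, mat, sex = c("female", "male", "female"), group = "IVF")
  v <- verify_sex_markers(ds)
  expect_equal(v$predicted_sex, c("female", "male", "ambiguous"))
  expect_equal(v$concordant, c(TRUE, TRUE, FALSE))

  # simulated data: predictions fully concordant with simulated sex labels
  sim <- generate_dataset(fast_profile(5))
  expect_true(all(verify_sex_markers(sim)$concordant))
})
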