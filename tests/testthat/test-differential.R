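test_that("the vectorised Welch test matches stats::t.test per gene", {
  # hand vectors on the log2(FPKM+1) scale; FPKM constructed to invert the log
  vf <- c(5, 6, 7); vm <- c(1, 1.5, 2)
  ann <- make_ann(c("x1", "a1"), chrom = c("X", "1"))
  mat <- rbind(x1 = 2^c(vf, vm) - 1, a1 = rep(4, 6))
  colnames(mat) <- paste0("s", 1:6)
  ds <- make_ds(ann, mat, sex = rep(c("female", "male"), each = 3),
                group = "IVF")
  degs <- sex_de_test(ds, "IVF")
  expect_equal(degs$p_value[degs$gene_id == "x1"],
               stats::t.test(vf, vm)$p.value)
  expect_equal(degs$direction[degs$gene_id == "x1"], "female_high")
  expect_equal(degs$p_value[degs$gene_id == "a1"], 1)  # zero variance, equal

  # random matrix: every gene agrees with the reference implementation
  set.seed(3)
  lf <- matrix(stats::rnorm(30, 3), 10, 3)
  lm_ <- matrix(stats::rnorm(40, 3.5), 10, 4)
  w <- xdosage:::row_welch_t(lf, lm_)
  ref <- sapply(seq_len(10), function(i) stats::t.test(lf[i, ], lm_[i, ])$p.value)
  expect_equal(w$p, ref)
})

test_that("null data yield ~alpha significant genes and no direction bias", {
  ds <- generate_dataset(fast_null(12, n_autosomal_genes = 600,
                                   n_x_genes = 120), groups = "IVF")
  degs <- sex_de_test(ds, "IVF")
  frac <- mean(degs$is_significant)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)

  # permuting sex labels on real-effect data also gives ~alpha
  ds2 <- generate_dataset(fast_profile(13), groups = "IVF")
  set.seed(99)
  ds2$samples$sex <- sample(ds2$samples$sex)
  frac2 <- mean(sex_de_test(ds2, "IVF")$is_significant)
  expect_lt(frac2, 0.09)
})

test_that("DEG classification counts X and autosomal directions exactly", {
  degs <- data.frame(
    gene_id = paste0("g", 1:5),
    p_value = c(0.01, 0.02, 0.03, 0.2, 0.01),
    log2_fc = c(2, 1, -1, 3, -0.5),
    direction = c("female_high", "female_high", "male_high", "female_high",
                  "male_high"),
    chrom_class = c("x_linked", "x_linked", "x_linked", "x_linked",
                    "autosomal"),
    is_significant = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  cls <- classify_degs(degs)
  expect_equal(nrow(cls$xdegs), 3L)
  expect_equal(sum(cls$xdegs$direction == "female_high"), 2L)
  expect_equal(sum(cls$xdegs$direction == "male_high"), 1L)
  expect_equal(sum(cls$counts$count), 4L)  # counts conserve significant DEGs

  all_a <- degs; all_a$chrom_class <- "autosomal"
  expect_equal(nrow(classify_degs(all_a)$xdegs), 0L)
})

test_that("most simulated X-linked DEGs are female-high at default settings", {
  frac <- sapply(1:3, function(s) {
    ds <- generate_dataset(paper_profile(seed = s), groups = "IVF")
    cls <- classify_degs(sex_de_test(ds, "IVF"))
    unname(cls$proportions["xdeg_female_high"])
  })
  expect_gte(mean(frac), 0.90)
})

test_that("expressed up-responder genes are detected with high power", {
  det <- sapply(1:5, function(s) {
    ds <- generate_dataset(paper_profile(seed = s), groups = "IVF")
    tr <- attr(ds, "truth")
    tr <- tr[tr$group == "IVF" & tr$responder & tr$true_fold > 1, ]
    gm <- group_means(ds)
    f <- gm$means[, "female.IVF"]; m <- gm$means[, "male.IVF"]
    expressed <- rownames(gm$means)[pmax(f, m) > 1]
    degs <- sex_de_test(ds, "IVF")
    target <- intersect(tr$gene_id, expressed)
    hit <- degs$gene_id[degs$is_significant & degs$direction == "female_high"]
    mean(target %in% hit)
  })
  expect_gte(mean(det), 0.80)
})

test_that("set overlaps follow hand set algebra", {
  expect_equal(overlap_sets(c("a", "b"), c("c"))$counts,
               c(only_a = 2L, only_b = 1L, both = 0L))
  expect_equal(overlap_sets(c("a", "b"), c("a", "b"))$counts,
               c(only_a = 0L, only_b = 0L, both = 2L))
  ov <- overlap_sets(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov$counts, c(only_a = 1L, only_b = 1L, both = 2L))
  expect_equal(sort(ov$both), c("b", "c"))
})

test_that("volcano coordinates transform p and fold change correctly", {
  degs <- data.frame(gene_id = c("g1", "g2", "g3"),
                     p_value = c(0.01, 0.001, 0),
                     log2_fc = c(1, -2, 0.5),
                     stringsAsFactors = FALSE)
  v <- volcano_table(degs)
  expect_equal(nrow(v), 3L)               # one row per tested gene
  expect_equal(v$neg_log10_p[1], 2)
  expect_equal(v$log2_fc[1], 1)
  expect_true(is.finite(v$neg_log10_p[3]))  # p = 0 clipped, not infinite
  expect_true(v$neg_log10_p[2] > v$neg_log10_p[1])  # smaller p, larger y
})
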