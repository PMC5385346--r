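test_that("group means are exact per-cell arithmetic means", {
  ann <- make_ann(c("g1", "g2", "x1"), chrom = c("1", "2", "X"))
  mat <- rbind(g1 = c(2, 4, 1, 3), g2 = c(0, 0, 5, 5), x1 = c(1, 1, 2, 2))
  colnames(mat) <- paste0("s", 1:4)
  ds <- make_ds(ann, mat, sex = c("female", "female", "male", "male"),
                group = "IVF")
  gm <- group_means(ds)
  expect_equal(unname(gm$means[, "female.IVF"]), c(3, 0, 1))
  expect_equal(unname(gm$means[, "male.IVF"]), c(2, 5, 2))

  one <- make_ds(ann, mat[, 1, drop = FALSE], sex = "female", group = "SCNT")
  expect_equal(unname(group_means(one)$means[, 1]), unname(mat[, 1]))
})

test_that("F:M ratio tables implement the log ratio and filter contract", {
  ds <- two_sex_ds(x_female = c(5, 4, 3), x_male = c(5, 1, 0))
  fm <- fm_ratios(group_means(ds), "IVF", gene_class = "x_linked")
  expect_equal(fm$log2_fm[1], 0)        # equal means
  expect_equal(fm$log2_fm[2], 2)        # 4 vs 1
  expect_true(is.na(fm$log2_fm[3]))     # zero male mean, no pseudocount
  expect_true(all(fm$passes_min_fpkm))
  fm_pc <- fm_ratios(group_means(ds), "IVF", gene_class = "x_linked",
                     pseudocount = 1)
  expect_equal(fm_pc$log2_fm[3], 2)     # (3+1)/(0+1)
  expect_error(fm_ratios(group_means(ds), "SCNT"), "cell not present")
})

test_that("the aggregate F:M mean ratio is the ratio of aggregate means", {
  ds <- two_sex_ds(x_female = c(2, 4), x_male = c(1, 2))
  gm <- group_means(ds)
  expect_equal(fm_mean_ratio(gm, "IVF"), 2)  # (2+4)/2 over (1+2)/2
  expect_equal(fm_mean_ratio(gm, "IVF", mode = "per_gene"), 2)
  eq <- two_sex_ds(x_female = c(3, 7), x_male = c(3, 7))
  expect_equal(fm_mean_ratio(group_means(eq), "IVF"), 1)
})

test_that("F:M statistics are invariant to gene order and flip with sex labels", {
  ds <- generate_dataset(fast_profile(4), groups = "IVF")
  gm <- group_means(ds)
  r1 <- fm_mean_ratio(gm, "IVF")
  perm <- sample(nrow(ds$matrix))
  ds2 <- validate_dataset(ds$annotation[perm, ], ds$matrix[perm, ], ds$samples)
  expect_equal(fm_mean_ratio(group_means(ds2), "IVF"), r1)

  swapped <- ds
  swapped$samples$sex <- ifelse(ds$samples$sex == "female", "male", "female")
  fm_a <- fm_ratios(gm, "IVF", gene_class = "x_linked")
  fm_b <- fm_ratios(group_means(swapped), "IVF", gene_class = "x_linked")
  expect_equal(fm_b$log2_fm, -fm_a$log2_fm)
})

test_that("X:A ratios match hand arithmetic and are scale invariant", {
  ann <- make_ann(c("x1", "x2", "a1", "a2", "a3", "a4"),
                  chrom = c("X", "X", "1", "1", "2", "3"))
  mat <- cbind(s1 = c(4, 6, 1, 2, 3, 4), s2 = rep(2, 6))
  rownames(mat) <- ann$gene_id
  ds <- make_ds(ann, mat, sex = c("female", "male"), group = "IVF")
  xa <- xa_ratios(ds)
  expect_equal(xa$xa_ratio[1], 5 / 2.5)   # X {4,6} over A {1,2,3,4}
  expect_equal(xa$xa_ratio[2], 1)         # constant FPKM

  ds2 <- ds
  ds2$matrix[, "s1"] <- ds2$matrix[, "s1"] * 7.3
  expect_equal(xa_ratios(ds2)$xa_ratio[1], xa$xa_ratio[1])
})

test_that("F:M histograms bin at zero with left-closed bins and conserve counts", {
  fm <- data.frame(log2_fm = c(-0.1, 0.1, 0.3), passes_min_fpkm = TRUE)
  h <- fm_histogram(fm)
  expect_equal(h$bin_start, c(-0.2, 0, 0.2))
  expect_equal(h$count, c(1L, 1L, 1L))

  h0 <- fm_histogram(data.frame(log2_fm = rep(0, 5), passes_min_fpkm = TRUE))
  expect_equal(h0$bin_start, 0)
  expect_equal(h0$count, 5L)

  set.seed(1)
  fmr <- data.frame(log2_fm = stats::rnorm(500),
                    passes_min_fpkm = stats::runif(500) > 0.3)
  expect_equal(sum(fm_histogram(fmr)$count), sum(fmr$passes_min_fpkm))
})

test_that("distribution comparisons reproduce exact enumeration p-values", {
  r <- compare_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$mw_statistic, 0)
  expect_equal(r$mw_p, 0.1)          # 2 / choose(6, 3) by full enumeration
  expect_equal(r$mw_p, mw_exact_p_enum(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$ks_statistic, 1)

  same <- compare_distributions(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$ks_statistic, 0)

  set.seed(5)
  a <- stats::rnorm(6); b <- stats::rnorm(5, 0.5)
  expect_equal(compare_distributions(a, b)$mw_p, mw_exact_p_enum(a, b))

  expect_warning(compare_distributions(rep(1, 4), rep(1, 4)), "tied")
  expect_error(compare_distributions(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("the sexed X:A test separates sexes and matches rank enumeration", {
  xa <- data.frame(
    sample_id = paste0("s", 1:12),
    sex = rep(c("female", "male"), each = 6),
    group = "IVF", lineage = "WHOLE",
    xa_ratio = c(rep(c(0.9, 1.1), 3), rep(c(0.4, 0.5), 3)))
  p <- sexed_xa_test(xa, "IVF")
  expect_lt(p, 0.01)
  # enumeration oracle agrees that complete separation is extreme
  expect_lt(mw_exact_p_enum(xa$xa_ratio[xa$sex == "female"],
                            xa$xa_ratio[xa$sex == "male"]), 0.01)
  # tie-free case: test p equals full enumeration exactly
  xa2 <- xa; xa2$xa_ratio <- c(0.91, 1.13, 0.97, 1.22, 1.05, 0.88,
                               0.41, 0.55, 0.47, 0.52, 0.44, 0.58)
  expect_equal(sexed_xa_test(xa2, "IVF"),
               mw_exact_p_enum(xa2$xa_ratio[1:6], xa2$xa_ratio[7:12]))

  same <- xa; same$xa_ratio <- rep(1:6 / 10, 2)
  expect_gt(sexed_xa_test(same, "IVF"), 0.9)
  expect_error(sexed_xa_test(xa[1:7, ], "IVF"), ">= 2 samples")
})

test_that("expressed-gene counts pool sexes by max and are threshold-monotone", {
  ds <- two_sex_ds(x_female = c(0, 0.05, 0.2, 3), x_male = c(0, 0, 0.05, 0.01))
  gm <- group_means(ds)
  expect_equal(unname(expressed_counts(gm, "x_linked", 0.1)), 2L)
  expect_equal(unname(expressed_counts(gm, "x_linked", 1e9)), 0L)
  thr <- c(0.01, 0.1, 0.5, 1, 5)
  cnt <- sapply(thr, function(t) unname(expressed_counts(gm, "x_linked", t)))
  expect_true(all(diff(cnt) <= 0))
})

test_that("exceedance proportions use strict inequality over defined ratios", {
  ds <- two_sex_ds(x_female = c(5, 15, 25, 30), x_male = rep(10, 4))
  pr <- fm_exceed_proportions(fm_ratios(group_means(ds), "IVF",
                                        gene_class = "x_linked"))
  expect_equal(unname(pr["gt1"]), 0.75)
  expect_equal(unname(pr["gt2"]), 0.50)

  ones <- two_sex_ds(x_female = c(2, 3, 4), x_male = c(2, 3, 4))
  pr1 <- fm_exceed_proportions(fm_ratios(group_means(ones), "IVF",
                                         gene_class = "x_linked"))
  expect_equal(unname(pr1["gt1"]), 0)  # ratios exactly 1 do not count
})
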