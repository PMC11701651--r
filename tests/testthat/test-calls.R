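# Intergenic reference selection, empirical p-values, pseudo-bulking and
# p-value integration.

test_that("reference selection keeps quiet regions and drops loud ones", {
  set.seed(31)
  # all-zero regions: everything retained
  zero <- matrix(0, 20, 3, dimnames = list(sprintf("IG%02d", 1:20), NULL))
  expect_identical(select_reference_intergenic(zero), rownames(zero))

  # one region above every gene is discarded
  m <- matrix(2^rnorm(19 * 4), 19, 4)
  m <- rbind(m, loud = rep(5000, 4))
  rownames(m) <- c(sprintf("IG%02d", 1:19), "loud")
  kept <- select_reference_intergenic(m)
  expect_false("loud" %in% kept)
  expect_identical(setdiff(rownames(m), kept), "loud")

  expect_error(select_reference_intergenic(zero[1:5, ]),
               class = "oe_too_few_regions")
})

test_that("planted gene-like regions are screened out of the reference", {
  set.seed(32)
  sim <- simulate_bundle(synth_config(seed = 5))
  kept <- select_reference_intergenic(sim$bundle$bulk$intergenic)
  dubious <- names(sim$truth$dubious)[sim$truth$dubious]
  expect_gte(sum(!dubious %in% kept), 90L)        # >= 90 of 100 discarded
  clean <- names(sim$truth$dubious)[!sim$truth$dubious]
  expect_gte(mean(clean %in% kept), 0.99)          # null kept essentially whole
})

test_that("the genic-percentile rule is available and behaves as stated", {
  set.seed(33)
  regions <- matrix(2^rnorm(50 * 3), 50, 3,
                    dimnames = list(sprintf("IG%02d", 1:50), NULL))
  genic <- matrix(8 * 2^rnorm(200 * 3), 200, 3,
                  dimnames = list(sprintf("G%03d", 1:200), NULL))
  kept <- select_reference_intergenic(regions, genic, rule = "genic_quantile")
  thr <- quantile(rowMeans(log2(genic + 1)), 0.05, names = FALSE)
  expect_identical(kept,
                   rownames(regions)[rowMeans(log2(regions + 1)) <= thr])
  hot <- regions * 1e6
  expect_error(
    select_reference_intergenic(hot, genic, rule = "genic_quantile"),
    class = "oe_all_regions_dubious"
  )
})

test_that("present_pvalue is the add-one empirical tail with tie handling", {
  refs <- sprintf("IG%02d", 1:99)
  s <- fixed_sample(c(setNames(seq(0.001, 0.099, by = 0.001), refs), g1 = 5),
                    detectable_genes = "g1")
  expect_equal(present_pvalue(s, "g1", refs)$p, 1 / 100)

  s0 <- fixed_sample(c(setNames(rep(0, 99), refs), g1 = 0),
                     detectable_genes = "g1")
  expect_equal(present_pvalue(s0, "g1", refs)$p, 1)

  # gene at the median of 199 distinct reference values: counting oracle
  refs199 <- sprintf("IG%03d", 1:199)
  vals <- seq_len(199)
  sm <- fixed_sample(c(setNames(vals, refs199), g1 = 100),
                     detectable_genes = "g1")
  k_oracle <- sum(vals >= 100)
  expect_equal(present_pvalue(sm, "g1", refs199)$p, (k_oracle + 1) / 200)
  expect_equal(present_pvalue(sm, "g1", refs199)$p, 0.505, tolerance = 0.02)

  expect_error(present_pvalue(s, "IG01", refs),
               class = "oe_gene_not_detectable")
  expect_error(present_pvalue(
    fixed_sample(c(IG01 = 1, g1 = 2), detectable_genes = "g1"),
    "g1", "IG01"), class = "oe_empty_reference")
})

test_that("p-values are monotone in abundance and super-uniform under the null", {
  set.seed(34)
  refs <- sprintf("IG%03d", 1:200)
  rv <- 2^rnorm(200)
  gv <- sort(2^rnorm(50))
  s <- fixed_sample(c(setNames(rv, refs), setNames(gv, sprintf("g%02d", 1:50))),
                    detectable_genes = sprintf("g%02d", 1:50))
  p <- ontoexpress:::.sample_pvalues(s, sprintf("g%02d", 1:50), refs)
  expect_true(all(diff(unname(p)) <= 0))  # higher abundance -> smaller p

  # null: genes drawn from the reference distribution
  n <- 200
  draws <- replicate(200, {
    x <- 2^rnorm(n + 1)
    s2 <- fixed_sample(c(setNames(x[1:n], refs), g = x[n + 1]),
                       detectable_genes = "g")
    ontoexpress:::.sample_pvalues(s2, "g", refs)
  })
  for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(draws <= alpha),
               alpha + 2 / (n + 1) + 3 * sqrt(alpha * (1 - alpha) / 200))
  }
})

test_that("pseudobulk sums counts per cluster and conserves totals exactly", {
  # additivity on two cells
  counts <- cbind(c1 = c(g1 = 3, g2 = 0), c2 = c(g1 = 2, g2 = 5))
  ps <- pseudobulk(counts, c(c1 = "A", c2 = "A"), library_id = "L")
  expect_identical(ps[["L#A"]]$raw_counts, c(g1 = 5, g2 = 5))
  expect_equal(sum(ps[["L#A"]]$abundance), 1e6)

  # identity partition: one cluster per cell
  ps2 <- pseudobulk(counts, c(c1 = "x", c2 = "y"), library_id = "L")
  expect_identical(ps2[["L#x"]]$raw_counts, c(g1 = 3, g2 = 0))
  expect_identical(ps2[["L#y"]]$raw_counts, c(g1 = 2, g2 = 5))

  # random 50-cell fixture, sparse input: exact integer conservation
  set.seed(35)
  m <- Matrix::rsparsematrix(30, 50, density = 0.3,
                             rand.x = function(n) rpois(n, 4) + 1)
  dimnames(m) <- list(sprintf("g%02d", 1:30), sprintf("bc%02d", 1:50))
  cl <- setNames(sample(c("A", "B", "C"), 50, replace = TRUE),
                 colnames(m))
  ps3 <- pseudobulk(m, cl, library_id = "L")
  total <- Reduce(`+`, lapply(ps3, `[[`, "raw_counts"))
  expect_identical(unname(total), unname(Matrix::rowSums(m)))
  dense <- as.matrix(m)
  for (k in unique(cl)) {
    expect_identical(unname(ps3[[paste0("L#", k)]]$raw_counts),
                     unname(rowSums(dense[, names(cl)[cl == k], drop = FALSE])))
  }

  # unknown clustered barcode is an error in strict mode
  expect_error(pseudobulk(counts, c(c1 = "A", zz = "A")),
               class = "oe_unknown_barcode")
  expect_warning(pseudobulk(counts, c(c1 = "A", c2 = "A", zz = "A"),
                            strict = FALSE),
                 "dropping")
})

test_that("combine_pvalues matches closed forms", {
  # identity on singletons, every method
  for (m in c("fisher", "stouffer", "bh_best")) {
    expect_equal(combine_pvalues(0.03, m), 0.03, tolerance = 1e-12)
  }
  # fisher (0.5, 0.5): chi-square(4 df) tail of -4 ln 0.5, frozen from the
  # closed form exp(-x/2) (1 + x/2)
  x <- -2 * sum(log(c(0.5, 0.5)))
  expect_equal(combine_pvalues(c(0.5, 0.5), "fisher"),
               exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(combine_pvalues(c(0.5, 0.5), "fisher"), 0.5966, tolerance = 1e-4)
  # bh_best hand computation
  expect_equal(combine_pvalues(c(0.01, 0.04), "bh_best"),
               min(0.01 * 2 / 1, 0.04 * 2 / 2))
  expect_equal(combine_pvalues(c(0.9, 0.95), "bh_best"),
               min(0.9 * 2 / 1, 0.95 * 2 / 2))
  expect_equal(combine_pvalues(1, "bh_best"), 1)  # capped at 1

  expect_error(combine_pvalues(numeric(0)), class = "oe_empty_list")
  expect_error(combine_pvalues(c(0.5, 0)), class = "oe_out_of_range")
  expect_error(combine_pvalues(1.2), class = "oe_out_of_range")
})

test_that("call_expression classifies, propagates and reports provenance", {
  axes <- retina_axes()
  child <- compose_condition(axes, anat = "UBERON:0000966",
                             cell_type = "CL:0000561",
                             stage = "ST:0000002", species = "9606")
  parent <- compose_condition(axes, anat = "UBERON:0000966",
                              cell_type = "CL:0000099",
                              stage = "ST:0000002", species = "9606")
  g <- single_condition_graph(axes, child)
  refs <- sprintf("IG%02d", 1:99)
  abund <- c(setNames(seq(0.01, 0.99, by = 0.01), refs),
             hi = 50, lo = 0.0001)
  s <- new_sample("S1", abund, detectable_genes = c("hi", "lo"),
                  condition = child, data_type = "bulk")
  samples <- list(S1 = s)

  call_hi <- call_expression("hi", child, g, samples, refs)
  expect_identical(call_hi$state, "present")
  expect_identical(call_hi$quality, "silver")   # one sample: never gold
  expect_identical(call_hi$n_samples_self, 1L)
  expect_identical(call_hi$data_types, "bulk")

  call_lo <- call_expression("lo", child, g, samples, refs)
  expect_identical(call_lo$state, "absent")

  # data only in the child still produces a parent call
  call_parent <- call_expression("hi", parent, g, samples, refs)
  expect_identical(call_parent$state, "present")
  expect_identical(call_parent$n_samples_self, 0L)
  expect_identical(call_parent$n_samples_descendant, 1L)
  expect_equal(call_parent$p_integrated, call_hi$p_integrated)

  expect_error(call_expression("hi", compose_condition(axes, species = "9606",
                                                       sex = "male"),
                               g, samples, refs),
               class = "oe_no_data")
})

test_that("two significant samples reach gold; propagation pools samples", {
  axes <- retina_axes()
  cond <- compose_condition(axes, anat = "UBERON:0000955",
                            stage = "ST:0000002", species = "9606")
  g <- single_condition_graph(axes, cond)
  refs <- sprintf("IG%02d", 1:99)
  mk <- function(id) new_sample(
    id, c(setNames(seq(0.01, 0.99, by = 0.01), refs), hi = 50),
    detectable_genes = "hi", condition = cond)
  samples <- list(S1 = mk("S1"), S2 = mk("S2"))
  call2 <- call_expression("hi", cond, g, samples, refs)
  expect_identical(call2$quality, "gold")
  expect_identical(call2$n_samples_self, 2L)
  # fisher of (0.01, 0.01) equals the closed form
  expect_equal(call2$p_integrated,
               combine_pvalues(c(0.01, 0.01), "fisher"))
})
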