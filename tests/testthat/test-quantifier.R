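test_that("the count matrix reproduces planted counts exactly", {
  run <- ef_run()
  cm <- build_count_matrix(run$evidence, run$calls)
  tc <- run$sim$true_counts
  for (v in rownames(tc)) {
    name <- run$calls$calls$name[match(run$sim$keys[v], run$calls$calls$key)]
    expect_equal(unname(cm[name, colnames(tc)]), unname(tc[v, ]))
  }
  expect_equal(unname(cm["unassigned", ]), rep(0L, ncol(cm)))
  # determinism under row shuffling
  set.seed(4)
  cm2 <- build_count_matrix(run$evidence[sample(nrow(run$evidence)), ],
                            run$calls)
  expect_identical(cm2, cm)
})

test_that("zero-read samples are flagged and unknown tags are errors", {
  run <- ef_run()
  cm <- build_count_matrix(run$evidence, run$calls,
                           samples = c(run$calls$samples, "empty_pool"))
  expect_equal(unname(cm[, "empty_pool"]), rep(0L, nrow(cm)))
  expect_equal(attr(cm, "zero_samples"), "empty_pool")
  bad <- run$evidence
  bad$sample[1] <- "mystery"
  expect_error(build_count_matrix(bad, run$calls), "unknown sample tag")
})

test_that("size factors match the hand-computed median-of-ratios oracle", {
  # 5 x 3 fixture; row geometric means and ratio medians worked out by
  # explicit arithmetic: rows 1, 2, 5 give ratios (2,1,0.5), (1,2,0.5),
  # (1,1,1); row 3 gives (0.5928, 1.1856, 1.4227); row 4 gives
  # (1.5874, 0.7937, 0.7937); column medians are 1, 1 and 100/(2e6)^(1/3).
  cm <- rbind(c(120, 60, 30), c(20, 40, 10), c(25, 50, 60),
              c(200, 100, 100), c(9, 9, 9))
  dimnames(cm) <- list(paste0("v", 1:5), paste0("s", 1:3))
  sf <- mrn_size_factors(cm)
  expect_equal(as.numeric(sf), c(1, 1, 2^(-1/3)), tolerance = 1e-12)
  expect_equal(attr(sf, "n_reference_rows"), 5L)
})

test_that("size factors agree with the established MRN implementation", {
  set.seed(21)
  # odd number of all-positive rows: the arithmetic median of ratios and
  # the log-scale median used by the reference implementation coincide
  cm <- matrix(rpois(65, lambda = 40) + 1L, nrow = 13,
               dimnames = list(paste0("v", 1:13), paste0("s", 1:5)))
  sf <- mrn_size_factors(cm)
  ref <- DESeq2::estimateSizeFactorsForMatrix(cm)
  expect_equal(as.numeric(sf), unname(ref), tolerance = 1e-10)
})

test_that("size factors obey symmetry, scale and permutation invariances", {
  cm <- rbind(a = c(30, 30), b = c(11, 11), c = c(70, 70))
  colnames(cm) <- c("s1", "s2")
  expect_equal(as.numeric(mrn_size_factors(cm)), c(1, 1))
  # doubling one sample doubles its factor relative to the other, and
  # normalized counts change only by a global scalar, so relative
  # abundances (hence every log2FC) are untouched
  cm2 <- cm
  cm2[, 2] <- cm2[, 2] * 2L
  sf2 <- mrn_size_factors(cm2)
  expect_equal(as.numeric(sf2[2] / sf2[1]), 2)
  n1 <- normalize_counts(cm, mrn_size_factors(cm))
  n2 <- normalize_counts(cm2, sf2)
  ratio <- n2 / n1
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-12)
  expect_equal(sweep(n2, 2, colSums(n2), "/"),
               sweep(n1, 2, colSums(n1), "/"), tolerance = 1e-12)
  # row permutation and all-zero rows do not move the factors
  cm3 <- rbind(c(120, 60, 30), c(20, 40, 10), c(25, 50, 60),
               c(200, 100, 100), c(9, 9, 9))
  dimnames(cm3) <- list(paste0("v", 1:5), paste0("s", 1:3))
  set.seed(2)
  perm <- cm3[sample(nrow(cm3)), ]
  expect_equal(mrn_size_factors(perm), mrn_size_factors(cm3),
               ignore_attr = TRUE)
  with_zero <- rbind(cm3, zz = c(0, 0, 0))
  expect_equal(as.numeric(mrn_size_factors(with_zero)),
               as.numeric(mrn_size_factors(cm3)))
  # no all-positive row: actionable error
  sparse <- rbind(c(0, 5, 5), c(5, 0, 5))
  expect_error(mrn_size_factors(sparse), "poscounts")
  expect_length(mrn_size_factors(sparse, method = "poscounts"), 3L)
})

test_that("log2 fold changes follow the pseudocounted ratio formula", {
  run <- ef_run()
  q <- quantify_variants(run$evidence, run$calls)
  ann <- run$calls$calls$name[run$calls$calls$status == "annotated"]
  nov <- run$calls$calls$name[run$calls$calls$status == "novel"]
  denom <- colSums(q$normalized[ann, ])
  for (v in nov) {
    expect_equal(q$log2fc[v, ],
                 log2((q$normalized[v, ] + 0.5) / (denom + 0.5)))
  }
  # every novel is rarer than the annotated set in this regime
  expect_true(all(q$log2fc < 0))
  # forced arithmetic: zero novel vs denominator 127.5 gives exactly -8
  expect_equal(log2((0 + 0.5) / (127.5 + 0.5)), -8)
  # equal numerator and denominator cancel to zero
  expect_equal(log2((40 + 0.5) / (40 + 0.5)), 0)
})

test_that("log2FC is antisymmetric under role swap", {
  set.seed(14)
  a <- runif(20, 0, 200)
  b <- runif(20, 0, 200)
  expect_equal(log2((a + 0.5) / (b + 0.5)), -log2((b + 0.5) / (a + 0.5)))
})

test_that("the heatmap export round-trips and degrades gracefully", {
  set.seed(6)
  fc <- matrix(rnorm(12), nrow = 4,
               dimnames = list(paste0("G v.", 5:8), paste0("s", 1:3)))
  dir <- tempfile("hm")
  out <- export_heatmap(fc, dir)
  back <- utils::read.table(out$tsv, sep = "\t", header = TRUE,
                            row.names = 1, check.names = FALSE)
  expect_equal(as.matrix(back), fc, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(file.exists(out$image))
  expect_gt(file.size(out$image), 0)
  expect_warning(out0 <- export_heatmap(fc[0, , drop = FALSE],
                                        tempfile("hm0")),
                 "no novel variants")
  expect_null(out0$image)
})
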