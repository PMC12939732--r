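test_that("slice generation is deterministic and respects mask structure", {
  spec <- tiny_phantom_spec()
  a <- generate_slice(spec, 2, seed = 5)
  b <- generate_slice(spec, 2, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$tumor_mask <= a$brain_mask))
  expect_gt(sum(a$tumor_mask), 0)
  expect_error(generate_slice(spec, 99, seed = 1), "invalid class")

  spec4 <- phantom_spec()  # includes the tumour-free class
  s0 <- generate_slice(spec4, "non-tumor", seed = 5)
  expect_identical(sum(s0$tumor_mask), 0L)
})

test_that("noise-free, bias-free slices are piecewise constant over regions", {
  spec <- phantom_spec(bias_strength = 0, noise_sigma = 0)
  sl <- generate_slice(spec, 2, seed = 3)
  for (k in 1:2) {
    ch <- sl$channels[k, , ]
    bg <- ch[sl$brain_mask == 0]
    brain <- ch[sl$brain_mask == 1 & sl$tumor_mask == 0]
    tum <- ch[sl$tumor_mask == 1]
    expect_equal(diff(range(bg)), 0)
    expect_equal(diff(range(brain)), 0)
    expect_equal(diff(range(tum)), 0)
    expect_gt(tum[1], brain[1])  # positive tumour contrast
  }
})

test_that("dataset split follows the floor rounding rule and partitions subjects", {
  spec <- tiny_phantom_spec()
  ds <- generate_dataset(spec, 20, seed = 1)
  expect_equal(as.vector(table(ds$manifest$split)[c("train", "val", "test")]),
               c(14L, 3L, 3L))
  expect_setequal(ds$manifest$subject_id,
                  vapply(ds$slices, `[[`, "", "subject_id"))
  expect_equal(anyDuplicated(ds$manifest$subject_id), 0L)
  expect_error(generate_dataset(spec, 20, class_proportions = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("realised class counts stay within one subject of the request", {
  spec <- tiny_phantom_spec()
  ds <- generate_dataset(spec, 100, seed = 7)
  counts <- table(factor(ds$manifest$class_label, levels = 1:3))
  expect_true(all(abs(counts - 100 / 3) <= 1))
})

test_that("class-conditional tumour contrast separates classes by at least one SD", {
  spec <- tiny_phantom_spec()
  # per-class, per-modality mean tumour intensity over 20 slices each;
  # the class signature is the per-modality pattern, so two classes are
  # separated when some modality differs by at least one within-class SD
  per_class <- lapply(1:3, function(cl) {
    t(vapply(1:20, function(s) {
      sl <- generate_slice(spec, cl, seed = 400 + s)
      vapply(1:4, function(k) mean(sl$channels[k, , ][sl$tumor_mask == 1]),
             numeric(1))
    }, numeric(4)))
  })
  mus <- vapply(per_class, colMeans, numeric(4))         # 4 x 3
  sds <- vapply(per_class, function(m) apply(m, 2, sd), numeric(4))
  for (a in 1:2) for (b in (a + 1):3) {
    sep <- abs(mus[, a] - mus[, b]) / ((sds[, a] + sds[, b]) / 2)
    expect_gte(max(sep), 1)
  }
})

test_that("feature tables are reproducible and carry the planted structure", {
  fs <- feature_table_spec(120, 10, 3, 2, effect_size = 4, seed = 9)
  a <- generate_feature_table(fs)
  b <- generate_feature_table(fs)
  expect_identical(a, b)
  expect_equal(a$informative, 1:3)
  expect_equal(a$redundant, 4:5)
  expect_error(feature_table_spec(50, 10, 0, 2), "informative")
})

test_that("zero effect size gives chance-level 5-NN accuracy", {
  accs <- vapply(1:10, function(s) {
    ft <- generate_feature_table(
      feature_table_spec(200, 8, 4, 0, effect_size = 0, n_classes = 2,
                         seed = 100 + s))
    tr <- 1:150; va <- 151:200
    pred <- class::knn(ft$features[tr, ], ft$features[va, ],
                       factor(ft$labels[tr]), k = 5)
    mean(pred == factor(ft$labels[va], levels = levels(pred)))
  }, numeric(1))
  # chance = 0.5; SE of the mean of 10 runs of 50 predictions ~ 0.022
  expect_lt(abs(mean(accs) - 0.5), 3 * 0.022)
})

test_that("strong planted signal yields near-perfect held-out 5-NN accuracy", {
  ft <- generate_feature_table(
    feature_table_spec(300, 5, 5, 0, effect_size = 4, n_classes = 3,
                       seed = 21))
  tr <- 1:225; va <- 226:300
  pred <- class::knn(ft$features[tr, ], ft$features[va, ],
                     factor(ft$labels[tr]), k = 5)
  expect_gte(mean(pred == factor(ft$labels[va], levels = levels(pred))),
             0.95)
})
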