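test_that("weighted distance follows the closed form", {
  expect_equal(weighted_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(weighted_distance(c(1, 2), c(3, 2), c(4, 1)), 4)
  # identity weights reduce to the plain Euclidean distance
  x <- c(0.3, -1, 2); y <- c(1, 0.5, 2.5)
  expect_equal(weighted_distance(x, y), sqrt(sum((x - y)^2)))
  expect_equal(weighted_distance(x, y, c(2, 3, 1)),
               weighted_distance(y, x, c(2, 3, 1)))
  expect_error(weighted_distance(c(1, 2), c(1, 2, 3)), "length")
  expect_error(weighted_distance(c(1, 2), c(3, 4), c(-1, 1)), "non-negative")
})

test_that("k-NN reproduces exhaustive hand computations", {
  train <- matrix(c(0, 1, 4, 5), ncol = 1)
  labels <- c(0L, 0L, 1L, 1L)
  # k=1 on an exact duplicate of a training point
  expect_equal(knn_predict(train, labels, matrix(4), k = 1), 1L)
  # k=3 at x=3: neighbors 4 (d=1), 1 (d=2), 5 (d=2) -> labels 1,0,1 -> 1
  expect_equal(knn_predict(train, labels, matrix(3), k = 3), 1L)
  # k=3 at x=1.4: neighbors 1 (0.4), 0 (1.4), 4 (2.6) -> labels 0,0,1 -> 0
  expect_equal(knn_predict(train, labels, matrix(1.4), k = 3), 0L)
  # k = n gives the global majority; the 2/2 tie breaks to 0
  expect_equal(knn_predict(train, labels, matrix(c(-10, 10), ncol = 1), k = 4),
               c(0L, 0L))
  expect_error(knn_predict(train[0, , drop = FALSE], integer(0), matrix(1),
                           k = 1), "empty")
})

test_that("distance ties at the k-th neighbor break by training index", {
  train <- matrix(c(0, 2, 2), ncol = 1)  # rows 2 and 3 tie at distance 1
  expect_equal(knn_predict(train, c(0L, 1L, 0L), matrix(1), k = 2), 0L)
  expect_equal(knn_predict(train, c(0L, 0L, 1L), matrix(1), k = 2), 0L)
})

test_that("the cascade filters, reduces, and matches a hand trace", {
  # 4 training instances, clearly separated in both feature spaces
  tr_u <- rbind(c(5, 0), c(6, 0), c(0, 0), c(0, 1))
  tr_m <- rbind(c(3, 3), c(4, 4), c(0, 0), c(1, 0))
  lab <- c(1L, 1L, 0L, 0L)
  te_u <- rbind(c(5.5, 0), c(0, 0.5))
  te_m <- rbind(c(3.5, 3.5), c(0.5, 0))

  out <- two_layer_classify(tr_u, tr_m, lab, te_u, te_m, k = 1)
  # instance 1 passes the UFP filter and is called intron on MFP features;
  # instance 2 fails the filter and is finalized 0 without reaching layer 2
  expect_equal(out$layer1_pass, c(TRUE, FALSE))
  expect_equal(out$final_label, c(1L, 0L))
  expect_true(all(out$final_label[!out$layer1_pass] == 0L))

  # all-reject layer 1: flip UFP labels so every test neighbor votes 0
  out0 <- two_layer_classify(tr_u, tr_m, c(0L, 0L, 0L, 0L), te_u, te_m, k = 1)
  expect_true(all(out0$final_label == 0L))

  # pass-all layer 1 reduces to MFP-only k-NN
  pass_u <- matrix(0, 4, 2); pass_te <- matrix(0, 2, 2)
  out1 <- two_layer_classify(pass_u, tr_m, lab, pass_te, te_m, k = 3)
  expect_equal(out1$final_label,
               unname(knn_predict(tr_m, lab, te_m, k = 3)))
})

test_that("a six-instance cascade matches the step-by-step trace", {
  tr_u <- rbind(c(2, 0), c(3, 1), c(2, 1), c(0, 0), c(0, 1), c(1, 0))
  tr_m <- rbind(c(4, 0), c(5, 0), c(4, 1), c(0, 2), c(0, 3), c(1, 2))
  lab <- c(1L, 1L, 1L, 0L, 0L, 0L)
  te_u <- rbind(c(2, 1), c(1, 1))
  te_m <- rbind(c(0, 2), c(4, 0))
  w_u <- c(2, 1); w_m <- c(1, 3)
  # hand trace, layer 1 (weighted UFP distances, k = 3):
  #  test1 (2,1): d^2 to train = 2*0+1, 2*1+0, 0, 2*4+1, 2*4+0, 2*1+1
  #             = 1,2,0,9,8,3 -> neighbors 3,1,2 -> labels 1,1,1 -> pass
  #  test2 (1,1): d^2 = 2*1+1, 2*4+0, 2*1+0, 2*1+1, 2*1+0, 0+1
  #             = 3,8,2,3,2,1 -> neighbors 6,3,5 -> labels 0,1,0 -> reject
  # layer 2 for test1 (weighted MFP distances to all training):
  #  (0,2): d^2 = 16+12, 25+12, 16+3, 0, 0+3, 1 -> neighbors 4,6,5 -> 0
  out <- two_layer_classify(tr_u, tr_m, lab, te_u, te_m, w_u, w_m, k = 3)
  expect_equal(out$layer1_pass, c(TRUE, FALSE))
  expect_equal(out$final_label, c(0L, 0L))
})

test_that("rescaling all weights by a positive constant changes nothing", {
  set.seed(23)
  tr <- matrix(runif(60), 20, 3)
  lab <- as.integer(tr[, 1] > 0.5)
  te <- matrix(runif(15), 5, 3)
  w <- c(3, 0.5, 1.2)
  expect_identical(knn_predict(tr, lab, te, w, k = 3),
                   knn_predict(tr, lab, te, 17.3 * w, k = 3))
})

test_that("oracle weights beat identity weights when noise attributes dominate", {
  ufp <- packaged_patterns("UFP")
  mfp <- packaged_patterns("MFP")
  pats <- rbind(ufp, mfp)
  enrich <- planted_enrichment(ufp, mfp)
  w_u <- ifelse(enrich[seq_len(nrow(ufp))] > 0, 25, 1)
  w_m <- ifelse(enrich[nrow(ufp) + seq_len(nrow(mfp))] > 0, 25, 1)
  err <- sapply(1:10, function(s) {
    cfg <- generator_config(80, 80, background_freqs = study_background(),
                            enrichment = enrich, seed = s)
    d <- generate_dataset(cfg, pats)
    Xu <- encode_dataset(d, ufp); Xm <- encode_dataset(d, mfp)
    folds <- stratified_kfold(d$label, 5, seed = s)
    fe <- sapply(1:5, function(f) {
      te <- folds == f; tr <- !te
      po <- two_layer_classify(Xu[tr, ], Xm[tr, ], d$label[tr],
                               Xu[te, ], Xm[te, ], w_u, w_m, k = 3)
      pi <- two_layer_classify(Xu[tr, ], Xm[tr, ], d$label[tr],
                               Xu[te, ], Xm[te, ], k = 3)
      c(compute_metrics(d$label[te], po$final_label)$error,
        compute_metrics(d$label[te], pi$final_label)$error)
    })
    rowMeans(fe)
  })
  expect_lt(mean(err[1, ]), mean(err[2, ]))
})
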