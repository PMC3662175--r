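test_that("stratified folds are balanced overall and per class", {
  lab <- rep(c(1L, 0L), each = 50)
  f <- stratified_kfold(lab, 10, seed = 1)
  expect_equal(as.vector(table(f)), rep(10L, 10))
  expect_true(all(table(f[lab == 1L]) == 5L))
  expect_true(all(table(f[lab == 0L]) == 5L))

  lab2 <- c(rep(1L, 52), rep(0L, 51))
  f2 <- stratified_kfold(lab2, 10, seed = 2)
  expect_true(all(table(f2) %in% c(10L, 11L)))
  expect_lte(diff(range(table(f2[lab2 == 1L]))), 1L)
  expect_lte(diff(range(table(f2[lab2 == 0L]))), 1L)

  expect_identical(stratified_kfold(lab, 10, seed = 9),
                   stratified_kfold(lab, 10, seed = 9))
  expect_error(stratified_kfold(c(rep(1L, 5), rep(0L, 50)), 10), "at least")
})

test_that("fold assignment is a partition for random datasets", {
  set.seed(3)
  for (i in 1:50) {
    n1 <- sample(10:40, 1); n0 <- sample(10:40, 1)
    lab <- sample(rep(c(1L, 0L), c(n1, n0)))
    nf <- sample(2:10, 1)
    f <- stratified_kfold(lab, nf, seed = i)
    expect_equal(length(f), n1 + n0)        # every record assigned once
    expect_true(all(f %in% seq_len(nf)))
    expect_lte(diff(range(table(factor(f, levels = seq_len(nf))))), 1L)
  }
})

test_that("performance measures follow the confusion-table arithmetic", {
  perfect <- compute_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(perfect[c("error", "precision", "recall", "f_measure")],
               list(error = 0, precision = 1, recall = 1, f_measure = 1))

  all0 <- compute_metrics(rep(c(1L, 0L), 5), rep(0L, 10))
  expect_equal(all0$error, 0.5)
  expect_equal(all0$recall, 0)
  expect_false(all0$defined[["precision"]])

  # TP=3 FP=1 FN=2 TN=4
  y <- c(rep(1, 5), rep(0, 5))
  p <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  m <- compute_metrics(y, p)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f_measure, 2 / 3)
  expect_equal(m$error, 0.3)

  expect_error(compute_metrics(numeric(0), numeric(0)), "empty")
})

test_that("paired t-test handles degenerate and symmetric differences", {
  a <- c(0.1, 0.2, 0.3, 0.15, 0.25)
  expect_error(paired_ttest(a, a), "zero variance")
  b <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  d <- rep(c(1, -1), 5)
  tt <- paired_ttest(b + d, b)
  expect_equal(tt$t_statistic, 0)
  expect_equal(tt$p_value, 1)
  expect_equal(tt$df, 9)
})

test_that("t-test p-values match quadrature and track sign-flip permutation", {
  # The exact sign-flip permutation distribution at n = 10 is discrete
  # (granularity 2/1024) and conditions on the observed magnitudes, so its
  # two-sided p can deviate from the t approximation by several hundredths
  # for unlucky samples; the agreement is tight in the typical case.
  set.seed(41)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  gaps <- numeric(20)
  for (i in 1:20) {
    d <- stats::rnorm(10, mean = stats::runif(1, -0.5, 0.5))
    b <- stats::runif(10)
    tt <- paired_ttest(b + d, b)
    # quadrature: two-sided tail mass of the t density with 9 df
    quad <- 2 * stats::integrate(function(x) stats::dt(x, df = 9),
                                 abs(tt$t_statistic), Inf,
                                 rel.tol = 1e-12)$value
    expect_equal(tt$p_value, quad, tolerance = 1e-8)
    # exact sign-flip permutation distribution of |t|
    tstats <- apply(signs, 1, function(s) {
      ds <- d * s
      mean(ds) / (sd(ds) / sqrt(10))
    })
    gaps[i] <- abs(tt$p_value -
                     mean(abs(tstats) >= abs(tt$t_statistic) - 1e-12))
  }
  expect_lt(stats::median(gaps), 0.02)
  expect_lt(max(gaps), 0.1)
})

small_study <- function(seed, enrichment, n = 30L, k_values = 3L) {
  pats_u <- packaged_patterns("UFP")
  pats_m <- packaged_patterns("MFP")
  gen <- generator_config(n, n, background_freqs = study_background(),
                          enrichment = enrichment, seed = seed)
  experiment_config(generator = gen, ufp = pats_u, mfp = pats_m,
                    k_values = k_values, n_folds = 10L,
                    n_hidden_ufp = 3L, n_hidden_mfp = 3L,
                    sahs = sahs_config(hms = 6L, max_evals = 30L),
                    learning_rate = 0.5, epochs = 60L, seed = seed)
}

test_that("the experiment report is deterministic and well shaped", {
  enrich <- planted_enrichment()
  cfg <- small_study(5, enrich, k_values = c(1L, 3L, 5L, 10L))
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1, r2)
  # 4 k values x 2 arms x 4 measures in the summary
  expect_equal(nrow(r1$summary), 32L)
  expect_equal(nrow(r1$ttests), 16L)
  # fold-level rows: 10 folds x 2 arms x 4 k x 4 measures
  expect_equal(nrow(r1$folds), 320L)
  # reported averages equal the mean of the fold values exactly
  for (i in seq_len(nrow(r1$summary))) {
    s <- r1$summary[i, ]
    v <- r1$folds$value[r1$folds$arm == s$arm & r1$folds$k == s$k &
                          r1$folds$measure == s$measure]
    expect_equal(s$mean, mean(v), tolerance = 1e-12)
  }
})

test_that("perfectly separating plants drive the weighted arm to near-zero error", {
  ufp <- packaged_patterns("UFP")
  mfp <- packaged_patterns("MFP")
  pats <- rbind(ufp, mfp)
  key <- paste(pats$category, pats$expression, pats$location, pats$signal)
  enrich <- rep(0, nrow(pats))
  enrich[key %in% c("UFP AAG 1 5SS", "UFP CAG 1 3SS",
                    "MFP GGG 25 5SS", "MFP AAA 22 3SS")] <- 0.6
  gen <- generator_config(200, 200, background_freqs = study_background(),
                          enrichment = enrich, seed = 13)
  cfg <- experiment_config(generator = gen, ufp = ufp, mfp = mfp,
                           k_values = 3L, n_folds = 10L,
                           n_hidden_ufp = 3L, n_hidden_mfp = 4L,
                           sahs = sahs_config(hms = 8L, max_evals = 60L),
                           learning_rate = 0.5, epochs = 150L, seed = 13)
  res <- run_experiment(cfg)
  werr <- res$summary$mean[res$summary$arm == "weighted" &
                             res$summary$measure == "error"]
  expect_lt(werr, 0.02)
})
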