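#' Stratified k-fold assignment
#'
#' Randomly partitions the records into `n_folds` folds whose sizes differ
#' by at most one, with each class represented in nearly the same proportion
#' in every fold (per-class counts across folds also differ by at most one).
#'
#' @param labels 0/1 label vector.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return integer vector of fold indices in `1..n_folds`, one per record.
#' @export
stratified_kfold <- function(labels, n_folds = 10L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  stopifnot(n_folds >= 2L)
  counts <- table(labels)
  if (any(counts < n_folds)) {
    stop("every class needs at least ", n_folds, " members; got ",
         paste(names(counts), counts, sep = ":", collapse = ", "))
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    offset <- 0L
    for (cl in sample(names(counts))) {
      idx <- which(labels == as.integer(cl))
      idx <- sample(idx)
      # continue the global round-robin so overall fold sizes stay balanced
      folds[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      offset <- offset + length(idx)
    }
  })
  folds
}

#' Classification performance measures for one fold
#'
#' The positive class is intron (label 1). `error = (FP + FN) / n`,
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and the
#' F-measure is the harmonic mean of precision and recall. Ratios with a
#' zero denominator are reported as 0 and flagged in the `defined` field.
#'
#' @param y_true,y_pred 0/1 vectors of equal, nonzero length.
#' @return list with `error`, `precision`, `recall`, `f_measure`, the
#'   confusion counts, and `defined` flags for the three ratio measures.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  stopifnot(length(y_true) == length(y_pred),
            all(y_true %in% c(0L, 1L)), all(y_pred %in% c(0L, 1L)))
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  precision_def <- (tp + fp) > 0L
  recall_def <- (tp + fn) > 0L
  precision <- if (precision_def) tp / (tp + fp) else 0
  recall <- if (recall_def) tp / (tp + fn) else 0
  f_def <- precision + recall > 0
  f_measure <- if (f_def) 2 * precision * recall / (precision + recall) else 0
  list(error = (fp + fn) / length(y_true),
       precision = precision, recall = recall, f_measure = f_measure,
       tp = tp, fp = fp, fn = fn, tn = tn,
       defined = c(precision = precision_def, recall = recall_def,
                   f_measure = f_def))
}

#' Paired t-test between two sets of fold measures
#'
#' Two-sided paired t-test on the per-fold differences `a - b`, with
#' `t = mean(d) / (sd(d) / sqrt(n))` and `n - 1` degrees of freedom.
#'
#' @param a,b numeric vectors of equal length (>= 2), typically one measure
#'   across the 10 cross-validation folds under two classifier
#'   configurations.
#' @return list with `t_statistic`, `p_value`, `df`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (sd(d) == 0) {
    stop("degenerate paired t-test: differences have zero variance")
  }
  fit <- t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(t_statistic = unname(fit$statistic), p_value = fit$p.value,
       df = unname(fit$parameter))
}

#' Configuration for a cross-validated weighting experiment
#'
#' Bundles every tunable of the end-to-end pipeline: the synthetic data
#' set (or pre-made records), the pattern tables, the network/optimizer
#' settings used to derive weights per fold, and the `k` values at which the
#' two-layered classifier is evaluated.
#'
#' @param generator a [generator_config()], or `NULL` when `records` is
#'   supplied.
#' @param records optional pre-made record data frame (overrides
#'   `generator`).
#' @param ufp,mfp pattern tables; default the packaged tables.
#' @param k_values neighbor counts to evaluate.
#' @param n_folds cross-validation folds.
#' @param n_hidden_ufp,n_hidden_mfp hidden-layer sizes for the two
#'   sensitivity networks (`NULL` = the [network_params()] default).
#' @param sahs a [sahs_config()] for the initializer.
#' @param learning_rate,epochs back-propagation settings per fold.
#' @param d disturbance ratio for sensitivity analysis.
#' @param seed master seed for fold assignment and per-fold training.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(generator = NULL, records = NULL,
                              ufp = packaged_patterns("UFP"),
                              mfp = packaged_patterns("MFP"),
                              k_values = c(1L, 3L, 5L, 10L),
                              n_folds = 10L,
                              n_hidden_ufp = NULL, n_hidden_mfp = NULL,
                              sahs = sahs_config(),
                              learning_rate = 0.1, epochs = 5000L,
                              d = 0.1, seed = 1L) {
  if (is.null(generator) && is.null(records)) {
    stop("either a generator config or a records data frame is required")
  }
  structure(list(generator = generator, records = records,
                 ufp = ufp, mfp = mfp,
                 k_values = as.integer(k_values), n_folds = as.integer(n_folds),
                 n_hidden_ufp = n_hidden_ufp, n_hidden_mfp = n_hidden_mfp,
                 sahs = sahs, learning_rate = learning_rate,
                 epochs = as.integer(epochs), d = d, seed = as.integer(seed)),
            class = "experiment_config")
}

train_category_net <- function(X, y, n_hidden, config, fold_seed) {
  sahs <- config$sahs
  sahs$seed <- fold_seed
  if (is.null(n_hidden)) n_hidden <- max(4L, ceiling((ncol(X) + 1) / 2))
  train_hybrid(X, y, n_hidden = n_hidden, sahs = sahs,
               learning_rate = config$learning_rate, epochs = config$epochs)
}

#' Run the full weighted-vs-conventional classifier experiment
#'
#' For every cross-validation fold: encode the training nine-tenths into
#' UFP and MFP count features, min-max scale them with training-fold
#' statistics, train one hybrid SAHS+BP network per category on the scaled
#' features, convert each network into per-pattern weights by relative
#' sensitivity, then classify the held-out fold with the two-layered
#' classifier twice -- once with the derived weights ("weighted" arm) and
#' once with identity weights ("identity" arm, the conventional k-NN on
#' normalized attributes). Both arms classify in the same scaled feature
#' space the sensitivity network was trained in, so the derived weights act
#' on exactly the geometry they were measured in. Weights and scalers are
#' re-derived inside each fold from that fold's training data only, so no
#' information leaks from the test fold.
#'
#' @param config an [experiment_config()].
#' @return list with `folds` (a long data frame: arm, k, fold, measure,
#'   value), `summary` (fold-averaged measures per arm and k), and `ttests`
#'   (paired t-test of weighted vs identity per k and measure).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  records <- if (!is.null(config$records)) config$records else
    generate_dataset(config$generator, rbind(config$ufp, config$mfp))
  validate_records(records)
  X_ufp <- encode_dataset(records, config$ufp)
  X_mfp <- encode_dataset(records, config$mfp)
  labels <- records$label
  folds <- stratified_kfold(labels, config$n_folds, seed = config$seed)
  measures <- c("error", "precision", "recall", "f_measure")
  rows <- list()
  for (f in seq_len(config$n_folds)) {
    te <- folds == f
    tr <- !te
    scaler_u <- fit_scaler(X_ufp[tr, , drop = FALSE])
    scaler_m <- fit_scaler(X_mfp[tr, , drop = FALSE])
    Xu <- apply_scaler(scaler_u, X_ufp[tr, , drop = FALSE])
    Xm <- apply_scaler(scaler_m, X_mfp[tr, , drop = FALSE])
    fold_seed <- as.integer((as.numeric(config$seed) * 1009 + f) %% 2147483647)
    net_u <- train_category_net(Xu, labels[tr], config$n_hidden_ufp,
                                config, fold_seed)
    net_m <- train_category_net(Xm, labels[tr], config$n_hidden_mfp,
                                config, fold_seed + 1L)
    w_ufp <- relative_sensitivity(net_u, Xu, d = config$d)$rs
    w_mfp <- relative_sensitivity(net_m, Xm, d = config$d)$rs
    Xu_te <- apply_scaler(scaler_u, X_ufp[te, , drop = FALSE])
    Xm_te <- apply_scaler(scaler_m, X_mfp[te, , drop = FALSE])
    arms <- list(weighted = list(u = w_ufp, m = w_mfp),
                 identity = list(u = rep(1, ncol(X_ufp)),
                                 m = rep(1, ncol(X_mfp))))
    for (arm in names(arms)) {
      for (k in config$k_values) {
        pred <- two_layer_classify(
          Xu, Xm, labels[tr], Xu_te, Xm_te,
          w_ufp = arms[[arm]]$u, w_mfp = arms[[arm]]$m, k = k,
          record_ids = records$record_id[te])
        met <- compute_metrics(labels[te], pred$final_label)
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm, k = k, fold = f, measure = measures,
          value = unlist(met[measures], use.names = FALSE),
          stringsAsFactors = FALSE)
      }
    }
  }
  fold_df <- do.call(rbind, rows)
  summary_df <- stats::aggregate(value ~ arm + k + measure, data = fold_df,
                                 FUN = mean)
  names(summary_df)[names(summary_df) == "value"] <- "mean"
  ttests <- list()
  for (k in config$k_values) {
    for (m in measures) {
      a <- fold_df$value[fold_df$arm == "weighted" & fold_df$k == k &
                           fold_df$measure == m]
      b <- fold_df$value[fold_df$arm == "identity" & fold_df$k == k &
                           fold_df$measure == m]
      tt <- tryCatch(paired_ttest(a, b), error = function(e) NULL)
      ttests[[length(ttests) + 1L]] <- data.frame(
        k = k, measure = m,
        t_statistic = if (is.null(tt)) NA_real_ else tt$t_statistic,
        p_value = if (is.null(tt)) NA_real_ else tt$p_value,
        df = if (is.null(tt)) NA_real_ else tt$df,
        stringsAsFactors = FALSE)
    }
  }
  list(folds = fold_df, summary = summary_df,
       ttests = do.call(rbind, ttests))
}
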