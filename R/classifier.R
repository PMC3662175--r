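#' Weighted Euclidean distance
#'
#' `d(x, x') = sqrt(sum_i w_i (x_i - x'_i)^2)`. With all weights 1 this is
#' the plain Euclidean distance of the conventional nearest-neighbor
#' classifier; pattern-derived weights stretch the informative axes.
#'
#' @param x,xp numeric vectors of equal length.
#' @param w non-negative weights, not all zero; defaults to the identity
#'   vector.
#' @return non-negative scalar distance.
#' @export
weighted_distance <- function(x, xp, w = rep(1, length(x))) {
  if (length(x) != length(xp) || length(w) != length(x)) {
    stop("x, xp and w must have the same length")
  }
  if (any(w < 0) || sum(w) == 0) stop("weights must be non-negative, not all zero")
  sqrt(sum(w * (x - xp)^2))
}

# All pairwise weighted distances between rows of A (tests) and B (train).
weighted_distance_matrix <- function(A, B, w) {
  Aw <- sweep(A, 2L, sqrt(w), `*`)
  Bw <- sweep(B, 2L, sqrt(w), `*`)
  d2 <- outer(rowSums(Aw^2), rowSums(Bw^2), `+`) - 2 * tcrossprod(Aw, Bw)
  sqrt(pmax(d2, 0))
}

#' Weighted k-nearest-neighbor prediction
#'
#' Lazy majority-vote classification under the weighted Euclidean distance.
#' Distance ties at the k-th neighbor are broken by training-set index
#' order; vote ties (possible for even `k`) are broken toward label 0, the
#' non-intron / reject class.
#'
#' @param train_features,train_labels training matrix and 0/1 labels.
#' @param test_features matrix of instances to classify.
#' @param w attribute weights (see [weighted_distance()]).
#' @param k number of neighbors, `1 <= k <= nrow(train_features)`.
#' @return integer vector of predicted 0/1 labels.
#' @export
knn_predict <- function(train_features, train_labels, test_features,
                        w = rep(1, ncol(train_features)), k = 3L) {
  if (is.null(dim(train_features))) train_features <- as.matrix(train_features)
  if (is.null(dim(test_features))) {
    test_features <- matrix(test_features, ncol = ncol(train_features))
  }
  n_train <- nrow(train_features)
  if (n_train == 0L) stop("empty training set")
  stopifnot(k >= 1L, k <= n_train, length(train_labels) == n_train)
  if (nrow(test_features) == 0L) return(integer(0))
  D <- weighted_distance_matrix(test_features, train_features, w)
  apply(D, 1L, function(di) {
    nn <- order(di)[seq_len(k)]     # order() breaks ties by index
    votes <- sum(train_labels[nn] == 1L)
    if (votes > k / 2) 1L else 0L
  })
}

#' Two-layered weighted nearest-neighbor classification
#'
#' Cascade classifier for intron windows: the first layer runs weighted
#' k-NN on the uniframe-pattern (UFP) features and filters out instances it
#' predicts as non-intron; survivors are classified by a second weighted
#' k-NN on the multiframe-pattern (MFP) features against the full training
#' set, which gives the final label. The cascade can only remove positives:
#' every final intron call passed the UFP filter.
#'
#' @param train_ufp,train_mfp training feature matrices for the two
#'   categories (same row order).
#' @param train_labels 0/1 labels for the training rows.
#' @param test_ufp,test_mfp test feature matrices (same row order).
#' @param w_ufp,w_mfp weight vectors aligned to the UFP / MFP pattern
#'   tables; identity vectors reproduce the conventional k-NN cascade.
#' @param k neighbors used in both layers.
#' @param record_ids optional ids for the test rows.
#' @return data frame with `record_id`, `layer1_pass`, `final_label`;
#'   `final_label` is 0 whenever `layer1_pass` is `FALSE`.
#' @export
two_layer_classify <- function(train_ufp, train_mfp, train_labels,
                               test_ufp, test_mfp,
                               w_ufp = rep(1, ncol(train_ufp)),
                               w_mfp = rep(1, ncol(train_mfp)),
                               k = 3L, record_ids = NULL) {
  stopifnot(nrow(train_ufp) == nrow(train_mfp),
            nrow(test_ufp) == nrow(test_mfp))
  n_test <- nrow(test_ufp)
  if (is.null(record_ids)) record_ids <- as.character(seq_len(n_test))
  layer1 <- knn_predict(train_ufp, train_labels, test_ufp, w = w_ufp, k = k)
  pass <- layer1 == 1L
  final <- integer(n_test)
  if (any(pass)) {
    final[pass] <- knn_predict(train_mfp, train_labels,
                               test_mfp[pass, , drop = FALSE],
                               w = w_mfp, k = k)
  }
  data.frame(record_id = record_ids, layer1_pass = pass,
             final_label = final, stringsAsFactors = FALSE)
}
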