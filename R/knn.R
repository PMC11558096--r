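# k-nearest-neighbour classification in RGB space.

#' K-nearest-neighbour classifier on RGB features
#'
#' Stores the training features and labels; prediction computes Euclidean
#' distances in RGB space, takes the `k` nearest training points, and returns
#' the majority class. Ties are broken deterministically: first by the
#' smaller summed distance of the tied classes within the neighbour set,
#' then by the class of the single nearest neighbour (if it belongs to a tied
#' class), finally by label order. Equal distances at the k-th rank are
#' resolved by training-set order.
#'
#' @param train_rgb Numeric matrix (n x 3) of training features.
#' @param train_labels Vector/factor of class labels, length n.
#' @param k Number of neighbours (1 <= k <= n); the default 5 is odd and
#'   robust at ~15 replicates per class.
#' @return An object of class `uelfa_knn`.
#' @export
knn_model <- function(train_rgb, train_labels, k = 5) {
  train_rgb <- as.matrix(train_rgb)
  assert_that(nrow(train_rgb) >= 1, "training set must be non-empty")
  assert_that(length(train_labels) == nrow(train_rgb),
              "labels must match the number of training rows")
  assert_that(is_scalar_number(k) && k >= 1 && k <= nrow(train_rgb),
              "`k` must satisfy 1 <= k <= n")
  structure(
    list(train_rgb = train_rgb, train_labels = as.character(train_labels),
         k = as.integer(k)),
    class = "uelfa_knn"
  )
}

#' @rdname knn_model
#' @param model A `uelfa_knn` model.
#' @param query_rgb Numeric vector (one query) or matrix (one query per row).
#' @return `knn_predict()`: character vector of predicted labels, one per
#'   query row.
#' @export
knn_predict <- function(model, query_rgb) {
  assert_that(inherits(model, "uelfa_knn") && nrow(model$train_rgb) >= 1,
              "`model` must be a non-empty uelfa_knn model")
  if (is.null(dim(query_rgb))) query_rgb <- matrix(query_rgb, nrow = 1)
  query_rgb <- as.matrix(query_rgb)
  vapply(seq_len(nrow(query_rgb)), function(i) {
    knn_vote(model, query_rgb[i, ])
  }, character(1))
}

knn_vote <- function(model, q) {
  d <- sqrt(colSums((t(model$train_rgb) - q)^2))
  nn <- order(d)[seq_len(model$k)]        # stable: index order breaks d-ties
  lab <- model$train_labels[nn]
  counts <- table(lab)
  tied <- names(counts)[counts == max(counts)]
  if (length(tied) > 1) {
    sums <- vapply(tied, function(cl) sum(d[nn][lab == cl]), numeric(1))
    tied <- tied[sums == min(sums)]
    if (length(tied) > 1) {
      nearest <- lab[1]
      tied <- if (nearest %in% tied) nearest else sort(tied)[1]
    }
  }
  tied[1]
}

#' @export
print.uelfa_knn <- function(x, ...) {
  cat("KNN classifier: n =", nrow(x$train_rgb), ", k =", x$k, ",",
      length(unique(x$train_labels)), "classes\n")
  invisible(x)
}
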