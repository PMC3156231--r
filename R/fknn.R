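# Fuzzy K-nearest-neighbor classifier.
#
# For a query q with K nearest reference neighbors at distances d_j and crisp
# reference memberships u_ij in {0,1} (1 iff neighbor j carries class i), the
# fuzzy membership of q in class i is
#
#   mu_i(q) = sum_j u_ij d_j^(-2/(m-1)) / sum_j d_j^(-2/(m-1))
#
# with m > 1 the fuzzy coefficient; the query is assigned to the class of
# highest membership. Distances are Euclidean in PseAAC feature space.

#' FKNN parameters
#'
#' @param K Number of nearest neighbors counted.
#' @param m Fuzzy coefficient (> 1) weighting how heavily distance counts;
#'   as m tends to 1 the rule approaches the crisp nearest neighbor, as m
#'   grows it approaches the unweighted K-neighbor vote.
#' @return List of class \code{fknn_params}.
#' @export
fknn_params <- function(K = 1L, m = 2) {
  stopifnot(length(K) == 1L, K >= 1L, K == as.integer(K))
  if (!(length(m) == 1L && m > 1)) {
    stop("fuzzy coefficient m must be > 1 (exponent 2/(m-1) must be finite)")
  }
  structure(list(K = as.integer(K), m = as.numeric(m)),
            class = "fknn_params")
}

#' Build a labeled reference set
#'
#' @param x Feature matrix, one row per reference protein.
#' @param labels Character vector of class tags, one per row.
#' @param classes Ordered distinct class list; defaults to order of first
#'   appearance in \code{labels}.
#' @return List of class \code{reference_set} with fields \code{x},
#'   \code{labels}, \code{classes}.
#' @export
reference_set <- function(x, labels, classes = unique(labels)) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels), nrow(x) >= 2L)
  if (anyNA(labels)) stop("reference labels must not be missing")
  if (!all(labels %in% classes)) stop("labels outside the declared class list")
  if (length(unique(labels)) < 2L) {
    stop("reference set needs at least 2 distinct classes")
  }
  structure(list(x = x, labels = as.character(labels),
                 classes = as.character(classes)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("Reference set: %d proteins, %d features, classes: %s\n",
              nrow(x$x), ncol(x$x), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' K nearest neighbors of a query
#'
#' Euclidean distances from the query to every reference vector; returns the
#' K smallest with their labels, ascending, ties on distance broken by
#' reference insertion order.
#'
#' @param query Numeric feature vector.
#' @param ref A \code{\link{reference_set}}.
#' @param K Number of neighbors.
#' @return data.frame with columns \code{index}, \code{distance},
#'   \code{label}.
#' @export
neighbor_search <- function(query, ref, K) {
  n <- nrow(ref$x)
  if (K > n) stop(sprintf("K = %d exceeds reference size %d", K, n))
  d <- sqrt(colSums((t(ref$x) - query)^2))
  ord <- order(d, seq_along(d))[seq_len(K)]
  data.frame(index = ord, distance = unname(d[ord]), label = ref$labels[ord],
             stringsAsFactors = FALSE)
}

# Memberships from precomputed neighbor distances/labels. Distances below
# 1e-12 would blow up the inverse-distance weight, so when any neighbor
# coincides with the query the profile is a uniform vote over the
# zero-distance neighbors only (the crisp limit of the rule).
.fknn_profile <- function(distance, label, classes, m) {
  zero <- distance < 1e-12
  if (any(zero)) {
    w <- as.numeric(zero)
  } else {
    # scale by the minimum distance first: the exponent -2/(m-1) is huge for
    # m near 1 and relative weights are invariant under rescaling
    w <- (distance / min(distance))^(-2 / (m - 1))
    if (!any(is.finite(w) & w > 0)) w <- as.numeric(distance == min(distance))
  }
  mu <- vapply(classes, function(cl) sum(w[label == cl]), numeric(1))
  mu / sum(mu)
}

#' Fuzzy class memberships of a query
#'
#' @param query Numeric feature vector.
#' @param ref A \code{\link{reference_set}}.
#' @param params An \code{\link{fknn_params}} object.
#' @return Named numeric vector over \code{ref$classes}, summing to 1.
#' @export
fknn_memberships <- function(query, ref, params) {
  stopifnot(inherits(params, "fknn_params"))
  nb <- neighbor_search(query, ref, params$K)
  .fknn_profile(nb$distance, nb$label, ref$classes, params$m)
}

# Argmax with ties broken toward the nearest neighbor's class (consistent
# with the crisp K-NN limit), then by class order.
.fknn_decide <- function(mu, nearest_label, classes) {
  best <- which(mu >= max(mu) - 1e-12)
  winner <- if (match(nearest_label, classes) %in% best) {
    match(nearest_label, classes)
  } else {
    best[1L]
  }
  list(label = classes[winner], membership = unname(mu[winner]))
}

#' Crisp FKNN decision for a query
#'
#' @inheritParams fknn_memberships
#' @return List with \code{label} (winning class) and \code{membership}
#'   (its fuzzy membership value).
#' @export
fknn_predict <- function(query, ref, params) {
  nb <- neighbor_search(query, ref, params$K)
  mu <- .fknn_profile(nb$distance, nb$label, ref$classes, params$m)
  .fknn_decide(mu, nb$label[1L], ref$classes)
}
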