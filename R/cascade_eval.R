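# Two-level cascade, jackknife cross-validation, MCC, and the 2-D (K, m)
# grid search.
#
# Level 1 separates nuclear receptors (NR) from background (NONNR); queries
# called NR continue to level 2, which assigns one of the NR subfamilies.
# The jackknife (leave-one-out) test predicts every reference protein with
# itself removed from the reference set; (K, m) are chosen by maximizing the
# overall jackknife success rate over a 2-D grid.

default_grid_K <- function() 1:15
default_grid_m <- function() seq(1.1, 3.0, by = 0.1)

#' Matthews correlation coefficient from confusion quadrants
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). When any
#' marginal factor is zero the coefficient is undefined and 0 is returned by
#' convention, flagged via attribute \code{degenerate}.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return MCC in [-1, 1].
#' @export
#' @examples
#' mcc(10, 0, 10, 0)  # 1
mcc <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) {
    return(structure(0, degenerate = TRUE))
  }
  (tp * tn - fp * fn) / sqrt(denom)
}

# ---- leave-one-out machinery ------------------------------------------------

# Sorted neighbor tables for leave-one-out prediction: for each row of the
# distance matrix D, the maxK nearest other rows (ascending distance, ties by
# insertion order). Returns distance matrix and integer label-code matrix.
.loo_neighbors <- function(D, label_codes, maxK) {
  n <- nrow(D)
  nbd <- matrix(0, n, maxK)
  nbl <- matrix(0L, n, maxK)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d, seq_along(d))[seq_len(maxK)]
    nbd[i, ] <- d[ord]
    nbl[i, ] <- label_codes[ord]
  }
  list(distance = nbd, label = nbl)
}

# Vectorized FKNN decision over precomputed neighbor tables; returns integer
# predicted class codes. Same rule as .fknn_profile/.fknn_decide.
.fknn_decide_batch <- function(nbd, nbl, K, m, n_classes) {
  nbd <- nbd[, seq_len(K), drop = FALSE]
  nbl <- nbl[, seq_len(K), drop = FALSE]
  W <- (nbd / nbd[, 1L])^(-2 / (m - 1))
  W[!is.finite(W)] <- 0
  W[nbd == nbd[, 1L] & nbd[, 1L] < Inf] <- 1  # min-distance columns weigh 1
  zd <- nbd < 1e-12
  any_zd <- rowSums(zd) > 0L
  if (any(any_zd)) W[any_zd, ] <- zd[any_zd, , drop = FALSE] * 1
  mu <- vapply(seq_len(n_classes), function(cl) {
    rowSums(W * (nbl == cl))
  }, numeric(nrow(nbd)))
  mu <- matrix(mu, nrow = nrow(nbd))
  mx <- do.call(pmax, as.data.frame(mu))
  cand <- mu >= mx - 1e-12 * pmax(mx, 1)
  nearest <- nbl[, 1L]
  nearest_is_cand <- cand[cbind(seq_len(nrow(cand)), nearest)]
  pred <- ifelse(nearest_is_cand, nearest, max.col(cand, ties.method = "first"))
  list(pred = pred, membership = mu[cbind(seq_len(nrow(mu)), pred)] /
         rowSums(mu))
}

# ---- reports ----------------------------------------------------------------

.build_report <- function(truth, predicted, classes) {
  n <- length(truth)
  rows <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    tn <- n - tp - fp - fn
    n_cl <- tp + fn
    m <- if (n_cl == 0L) NA_real_ else mcc(tp, fp, tn, fn)
    data.frame(class = cl, n = n_cl,
               accuracy = if (n_cl == 0L) NA_real_ else tp / n_cl,
               TP = tp, FP = fp, TN = tn, FN = fn,
               MCC = as.numeric(m),
               mcc_degenerate = isTRUE(attr(m, "degenerate")),
               stringsAsFactors = FALSE)
  })
  structure(list(
    per_class = do.call(rbind, rows),
    overall_accuracy = mean(truth == predicted),
    n = n,
    predictions = data.frame(truth = truth, predicted = predicted,
                             stringsAsFactors = FALSE)
  ), class = "nr_eval")
}

#' @export
print.nr_eval <- function(x, ...) {
  cat(sprintf("Evaluation over %d proteins: overall accuracy %.4f\n",
              x$n, x$overall_accuracy))
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Export an evaluation report
#'
#' Writes per-class rows (class, n, accuracy, TP, FP, TN, FN, MCC) plus an
#' overall row as TSV, or the full report as JSON.
#'
#' @param report An evaluation report.
#' @param path Output path; format chosen by extension (.json for JSON,
#'   otherwise TSV).
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(per_class = report$per_class,
                              overall_accuracy = report$overall_accuracy,
                              n = report$n),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    per <- report$per_class
    per$mcc_degenerate <- NULL
    overall <- data.frame(class = "Overall", n = report$n,
                          accuracy = report$overall_accuracy,
                          TP = NA, FP = NA, TN = NA, FN = NA, MCC = NA)
    utils::write.table(rbind(per, overall), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# ---- jackknife and grid search ----------------------------------------------

#' Jackknife (leave-one-out) test of an FKNN reference set
#'
#' Each reference protein is predicted with itself removed from the
#' reference; the report aggregates all N predictions. Deterministic.
#'
#' @param ref A \code{\link{reference_set}}.
#' @param params An \code{\link{fknn_params}} object; K must be <= N - 1.
#' @return Evaluation report with per-class accuracy, one-vs-rest confusion
#'   quadrants and MCC, and overall accuracy.
#' @export
jackknife <- function(ref, params) {
  n <- nrow(ref$x)
  if (params$K >= n) {
    stop(sprintf("K = %d must be < reference size %d for the jackknife",
                 params$K, n))
  }
  D <- as.matrix(stats::dist(ref$x))
  codes <- match(ref$labels, ref$classes)
  nb <- .loo_neighbors(D, codes, params$K)
  dec <- .fknn_decide_batch(nb$distance, nb$label, params$K, params$m,
                            length(ref$classes))
  .build_report(ref$labels, ref$classes[dec$pred], ref$classes)
}

#' 2-D grid search of the FKNN parameters
#'
#' Runs the jackknife at every (K, m) grid point and returns the full
#' accuracy surface and the best point; ties resolved to smallest K, then
#' smallest m.
#'
#' @param ref A \code{\link{reference_set}}.
#' @param K_values Integer vector of neighbor counts (all < N).
#' @param m_values Numeric vector of fuzzy coefficients (all > 1).
#' @return List of class \code{grid_search_result} with \code{grid}
#'   (data.frame K, m, accuracy) and \code{best} (list K, m, accuracy).
#' @export
grid_search <- function(ref, K_values = default_grid_K(),
                        m_values = default_grid_m()) {
  if (length(K_values) == 0L || length(m_values) == 0L) {
    stop("empty parameter grid")
  }
  n <- nrow(ref$x)
  if (any(K_values >= n)) stop("all K values must be < reference size")
  if (any(m_values <= 1)) stop("all m values must be > 1")
  K_values <- sort(unique(as.integer(K_values)))
  m_values <- sort(unique(as.numeric(m_values)))
  D <- as.matrix(stats::dist(ref$x))
  codes <- match(ref$labels, ref$classes)
  truth <- codes
  nb <- .loo_neighbors(D, codes, max(K_values))
  grid <- expand.grid(m = m_values, K = K_values)[, c("K", "m")]
  grid$accuracy <- NA_real_
  for (r in seq_len(nrow(grid))) {
    dec <- .fknn_decide_batch(nb$distance, nb$label, grid$K[r], grid$m[r],
                              length(ref$classes))
    grid$accuracy[r] <- mean(dec$pred == truth)
  }
  best_row <- grid[order(-grid$accuracy, grid$K, grid$m), ][1L, ]
  structure(list(grid = grid,
                 best = list(K = best_row$K, m = best_row$m,
                             accuracy = best_row$accuracy)),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("Grid search over %d points: best K = %d, m = %.2f, jackknife accuracy %.4f\n",
              nrow(x$grid), x$best$K, x$best$m, x$best$accuracy))
  invisible(x)
}

#' Export a grid-search surface as TSV
#'
#' @param result A \code{\link{grid_search}} result.
#' @param path Output TSV path with columns K, m, accuracy.
#' @return Invisibly, \code{path}.
#' @export
write_grid <- function(result, path) {
  utils::write.table(result$grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- the two-level cascade --------------------------------------------------

.is_nr_label <- function(label) grepl("^NR[0-9]+$", label)

#' Train the two-level cascade
#'
#' Builds the level-1 reference set (NR vs NONNR over all proteins) and the
#' level-2 reference set (subfamilies over the NR-labeled proteins only).
#' When \code{params1}/\code{params2} are NULL the (K, m) of that level are
#' chosen by jackknife grid search.
#'
#' @param records Validated, labeled data.frame (labels NR0..NRk or NONNR).
#' @param params1,params2 \code{\link{fknn_params}} per level, or NULL to
#'   grid-search.
#' @param weights A \code{\link{fusion_weights}} object.
#' @param scales A \code{\link{property_scales}} object.
#' @param K_values,m_values Grid used when a params argument is NULL.
#' @return List of class \code{cascade_model}.
#' @export
train_cascade <- function(records, params1 = NULL, params2 = NULL,
                          weights = fusion_weights(),
                          scales = property_scales(),
                          K_values = default_grid_K(),
                          m_values = default_grid_m()) {
  if (anyNA(records$label)) stop("all training records must be labeled")
  bad <- !(records$label == "NONNR" | .is_nr_label(records$label))
  if (any(bad)) {
    stop("invalid label(s): ", paste(unique(records$label[bad]), collapse = ", "))
  }
  x <- featurize_records(records, weights = weights, scales = scales)
  lvl1_labels <- ifelse(.is_nr_label(records$label), "NR", "NONNR")
  ref1 <- reference_set(x, lvl1_labels, classes = c("NR", "NONNR"))
  is_nr <- .is_nr_label(records$label)
  ref2 <- reference_set(x[is_nr, , drop = FALSE], records$label[is_nr],
                        classes = sort(unique(records$label[is_nr])))
  if (is.null(params1)) {
    gs1 <- grid_search(ref1, K_values, m_values)
    params1 <- fknn_params(gs1$best$K, gs1$best$m)
  }
  if (is.null(params2)) {
    gs2 <- grid_search(ref2, K_values, m_values)
    params2 <- fknn_params(gs2$best$K, gs2$best$m)
  }
  structure(list(
    version = "1",
    weights = weights,
    scales = scales,
    level1 = list(ref = ref1, params = params1),
    level2 = list(ref = ref2, params = params2),
    train = records[, c("id", "sequence", "label")]
  ), class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf(paste0("Two-level cascade model: %d references ",
                     "(level 1: K=%d m=%.2f; level 2: %d NRs, K=%d m=%.2f)\n"),
              nrow(x$level1$ref$x), x$level1$params$K, x$level1$params$m,
              nrow(x$level2$ref$x), x$level2$params$K, x$level2$params$m))
  invisible(x)
}

#' Predict query proteins through the two-level cascade
#'
#' Each query gets a level-1 decision (NR or NONNR) with its fuzzy
#' membership; queries called NR continue to the subfamily level. Per-record
#' featurization errors are logged and the batch continues.
#'
#' @param model A \code{\link{train_cascade}} model.
#' @param records Validated query data.frame (id, sequence).
#' @return data.frame with columns id, level1_label, level1_membership,
#'   level2_label, level2_membership, final_label (NA level-2 fields for
#'   NONNR calls; NA everywhere for failed records).
#' @export
predict_cascade <- function(model, records) {
  out <- data.frame(id = records$id,
                    level1_label = NA_character_,
                    level1_membership = NA_real_,
                    level2_label = NA_character_,
                    level2_membership = NA_real_,
                    final_label = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(records))) {
    v <- tryCatch(featurize(records$sequence[i], weights = model$weights,
                            scales = model$scales),
                  error = function(e) e)
    if (inherits(v, "error")) {
      warning(sprintf("record '%s' skipped: %s", records$id[i],
                      conditionMessage(v)), call. = FALSE)
      next
    }
    d1 <- fknn_predict(v, model$level1$ref, model$level1$params)
    out$level1_label[i] <- d1$label
    out$level1_membership[i] <- d1$membership
    if (d1$label == "NR") {
      d2 <- fknn_predict(v, model$level2$ref, model$level2$params)
      out$level2_label[i] <- d2$label
      out$level2_membership[i] <- d2$membership
      out$final_label[i] <- d2$label
    } else {
      out$final_label[i] <- "NONNR"
    }
  }
  out
}

#' Two-level jackknife test
#'
#' Leave-one-out over the full labeled set: each protein is removed from both
#' reference sets and routed through the cascade; its final call is NONNR or
#' a subfamily. The report is over the combined label set.
#'
#' @param records Validated, labeled data.frame.
#' @param params1,params2 \code{\link{fknn_params}} per level.
#' @inheritParams train_cascade
#' @param x Optional precomputed feature matrix for \code{records} (one row
#'   each, 881 columns) to avoid re-featurizing.
#' @return Evaluation report over classes NONNR + subfamilies.
#' @export
jackknife_cascade <- function(records, params1, params2,
                              weights = fusion_weights(),
                              scales = property_scales(), x = NULL) {
  if (is.null(x)) x <- featurize_records(records, weights, scales)
  n <- nrow(x)
  is_nr <- .is_nr_label(records$label)
  lvl1 <- ifelse(is_nr, "NR", "NONNR")
  classes1 <- c("NR", "NONNR")
  D <- as.matrix(stats::dist(x))

  # level 1: standard leave-one-out on all proteins
  nb1 <- .loo_neighbors(D, match(lvl1, classes1), params1$K)
  dec1 <- .fknn_decide_batch(nb1$distance, nb1$label, params1$K, params1$m, 2L)
  called_nr <- classes1[dec1$pred] == "NR"

  # level 2: reference = NR-labeled proteins; an NR query is left out of the
  # reference, a NONNR query routed here by a level-1 error is not in it
  sub_classes <- sort(unique(records$label[is_nr]))
  nr_idx <- which(is_nr)
  sub_codes <- match(records$label[nr_idx], sub_classes)
  final <- ifelse(called_nr, NA_character_, "NONNR")
  for (i in which(called_nr)) {
    refs <- setdiff(nr_idx, i)
    d <- D[i, refs]
    K2 <- min(params2$K, length(refs))
    ord <- order(d, seq_along(d))[seq_len(K2)]
    mu <- .fknn_profile(d[ord], sub_classes[sub_codes[match(refs[ord], nr_idx)]],
                        sub_classes, params2$m)
    final[i] <- .fknn_decide(mu, sub_classes[sub_codes[match(refs[ord[1L]],
                                                             nr_idx)]],
                             sub_classes)$label
  }
  .build_report(records$label, final, c(sub_classes, "NONNR"))
}

#' Evaluate a trained cascade on an independent test set
#'
#' Refuses any overlap between test and training material, by identifier or
#' by exact sequence match (leakage check). Level 1 scores NR-vs-NONNR over
#' the whole test set; level 2 scores subfamily assignment over the
#' NR-labeled test proteins using the model's level-2 reference. A class with
#' no test members is reported as NA.
#'
#' @param model A \code{\link{train_cascade}} model.
#' @param test Validated, labeled test data.frame.
#' @param level 1 or 2.
#' @return Evaluation report.
#' @export
independent_test <- function(model, test, level = 1L) {
  stopifnot(level %in% c(1L, 2L))
  overlap_id <- intersect(test$id, model$train$id)
  overlap_seq <- test$id[test$sequence %in% model$train$sequence]
  offenders <- union(overlap_id, overlap_seq)
  if (length(offenders) > 0L) {
    stop("test set overlaps the training material (identifier or exact ",
         "sequence): ", paste(offenders, collapse = ", "))
  }
  if (level == 1L) {
    x <- featurize_records(test, model$weights, model$scales)
    truth <- ifelse(.is_nr_label(test$label), "NR", "NONNR")
    pred <- character(nrow(x))
    for (i in seq_len(nrow(x))) {
      pred[i] <- fknn_predict(x[i, ], model$level1$ref,
                              model$level1$params)$label
    }
    .build_report(truth, pred, model$level1$ref$classes)
  } else {
    nr_test <- test[.is_nr_label(test$label), , drop = FALSE]
    if (nrow(nr_test) == 0L) stop("no NR-labeled test proteins for level 2")
    x <- featurize_records(nr_test, model$weights, model$scales)
    pred <- character(nrow(x))
    for (i in seq_len(nrow(x))) {
      pred[i] <- fknn_predict(x[i, ], model$level2$ref,
                              model$level2$params)$label
    }
    classes <- union(model$level2$ref$classes, unique(nr_test$label))
    .build_report(nr_test$label, pred, classes)
  }
}

#' Feature-ablation study
#'
#' For each feature mode (descriptor-block subset of the 881-D vector) the
#' (K, m) parameters are re-optimized by grid search and the best jackknife
#' success rate reported. Run on the subfamily level (NR-labeled proteins) it
#' reproduces the classical "which descriptor family helps most" table.
#'
#' @param records Validated, labeled data.frame.
#' @param modes Character vector of \code{\link{feature_mode_columns}} modes.
#' @inheritParams train_cascade
#' @param x Optional precomputed 881-column feature matrix.
#' @return data.frame with columns mode, dims, K, m, accuracy.
#' @export
feature_ablation <- function(records,
                             modes = c("AAC", "AAC+DC(0)", "AAC+DC(1)",
                                       "AAC+CF", "AAC+FSC", "ALL"),
                             weights = fusion_weights(),
                             scales = property_scales(),
                             K_values = default_grid_K(),
                             m_values = default_grid_m(), x = NULL) {
  cols <- lapply(modes, feature_mode_columns)  # validates mode names first
  if (is.null(x)) x <- featurize_records(records, weights, scales)
  rows <- vector("list", length(modes))
  for (j in seq_along(modes)) {
    ref <- reference_set(x[, cols[[j]], drop = FALSE], records$label)
    gs <- grid_search(ref, K_values, m_values)
    rows[[j]] <- data.frame(mode = modes[j], dims = length(cols[[j]]),
                            K = gs$best$K, m = gs$best$m,
                            accuracy = gs$best$accuracy,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
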