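test_that("MCC follows the quadrant formula, with a flagged degenerate case", {
  expect_equal(mcc(10, 0, 10, 0), 1, ignore_attr = TRUE)
  expect_equal(mcc(0, 10, 0, 10), -1, ignore_attr = TRUE)
  expect_equal(mcc(5, 5, 5, 5), 0, ignore_attr = TRUE)
  deg <- mcc(5, 0, 0, 5)  # no negative predictions at all
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
  # oracle: MCC is the Pearson correlation of the binary truth/prediction
  set.seed(101)
  for (i in 1:50) {
    q <- sample(1:30, 4, replace = TRUE)  # TP, FP, TN, FN
    truth <- rep(c(1, 0, 0, 1), q)
    pred <- rep(c(1, 1, 0, 0), q)
    expect_equal(as.numeric(mcc(q[1], q[2], q[3], q[4])), cor(truth, pred),
                 tolerance = 1e-12)
  }
})

test_that("jackknife on coincident points is forced by their labels", {
  p <- c(1, 2); far <- c(50, 60)
  # two coincident pairs, each pair labeled consistently -> perfect
  ref_ok <- reference_set(rbind(p, p, far, far), c("A", "A", "B", "B"))
  expect_equal(jackknife(ref_ok, fknn_params(1, 2))$overall_accuracy, 1)
  # two coincident points with conflicting labels -> both always wrong
  ref_bad <- reference_set(rbind(p, p), c("A", "B"))
  expect_equal(jackknife(ref_bad, fknn_params(1, 2))$overall_accuracy, 0)
  expect_error(jackknife(ref_bad, fknn_params(2, 2)), "must be <")
})

test_that("jackknife separates synthetic families perfectly and reports quadrants", {
  fs <- small_family_set()
  nr <- fs$records[fs$is_nr, ]
  ref <- reference_set(fs$x[fs$is_nr, ], nr$label)
  rep <- jackknife(ref, fknn_params(3, 2))
  expect_equal(rep$overall_accuracy, 1.0)
  expect_equal(rep$per_class$accuracy, rep(1, 4))
  expect_equal(rep$per_class$MCC, rep(1, 4))
  expect_equal(rep$per_class$TP + rep$per_class$FP + rep$per_class$TN +
                 rep$per_class$FN, rep(rep$n, 4))
})

test_that("jackknife accuracy is invariant under reference reordering", {
  fs <- small_family_set()
  idx <- which(fs$is_nr)
  ref <- reference_set(fs$x[idx, ], fs$records$label[idx])
  set.seed(7)
  perm <- sample(length(idx))
  ref_p <- reference_set(fs$x[idx[perm], ], fs$records$label[idx[perm]],
                         classes = ref$classes)
  params <- fknn_params(4, 1.7)
  expect_equal(jackknife(ref_p, params)$overall_accuracy,
               jackknife(ref, params)$overall_accuracy)
})

test_that("grid search scans the surface and resolves ties to small (K, m)", {
  fs <- small_family_set()
  idx <- which(fs$is_nr)
  ref <- reference_set(fs$x[idx, ], fs$records$label[idx])
  gs <- grid_search(ref, K_values = c(5, 1, 3), m_values = c(2.5, 1.3))
  expect_equal(nrow(gs$grid), 6L)
  # every surface value equals an independent single-point jackknife
  for (r in seq_len(nrow(gs$grid))) {
    expect_equal(gs$grid$accuracy[r],
                 jackknife(ref, fknn_params(gs$grid$K[r],
                                            gs$grid$m[r]))$overall_accuracy)
  }
  # separable families: many points reach the maximum; smallest K then m wins
  expect_equal(max(gs$grid$accuracy), gs$best$accuracy)
  top <- gs$grid[gs$grid$accuracy == gs$best$accuracy, ]
  expect_equal(gs$best$K, min(top$K))
  expect_equal(gs$best$m, min(top$m[top$K == gs$best$K]))
  # singleton grid is its own best
  gs1 <- grid_search(ref, 2, 1.9)
  expect_equal(gs1$best, list(K = 2L, m = 1.9,
                              accuracy = gs1$grid$accuracy[1]))
  expect_error(grid_search(ref, integer(0), 2), "empty")
})

test_that("the cascade routes zero-distance queries through both levels", {
  fs <- small_family_set()
  model <- train_cascade(fs$records, params1 = fknn_params(1, 2),
                         params2 = fknn_params(1, 2))
  nr1 <- fs$records[fs$records$label == "NR1", ][1, ]
  bg <- fs$records[fs$records$label == "NONNR", ][1, ]
  res <- predict_cascade(model, rbind(nr1, bg))
  expect_equal(res$level1_label, c("NR", "NONNR"))
  expect_equal(res$final_label, c("NR1", "NONNR"))
  expect_equal(res$level2_label, c("NR1", NA))
  expect_true(is.na(res$level2_membership[2]))
  expect_equal(res$level1_membership, c(1, 1))
})

test_that("cascade jackknife routes held-out queries correctly on separable families", {
  fs <- small_family_set()
  rep <- jackknife_cascade(fs$records, fknn_params(3, 2), fknn_params(3, 2),
                           x = fs$x)
  expect_equal(rep$overall_accuracy, 1.0)
  expect_setequal(rep$per_class$class, c(paste0("NR", 1:4), "NONNR"))
})

test_that("the independent test refuses leakage and handles empty classes", {
  fs <- small_family_set()
  model <- train_cascade(fs$records, params1 = fknn_params(1, 2),
                         params2 = fknn_params(1, 2))
  # leakage by identifier
  expect_error(independent_test(model, fs$records[1, ], level = 1),
               "overlaps")
  # leakage by exact sequence under a fresh identifier
  leaky <- fs$records[3, ]; leaky$id <- "fresh_name"
  expect_error(independent_test(model, leaky, level = 1), "overlaps")

  # near-identity test set: one substitution per training sequence, fresh ids
  set.seed(9)
  test_fx <- fs$records
  test_fx$id <- paste0("T_", test_fx$id)
  test_fx$sequence <- vapply(test_fx$sequence, function(s) {
    chars <- strsplit(s, "")[[1]]
    i <- sample(length(chars), 1)
    chars[i] <- sample(setdiff(amino_acid_order(), chars[i]), 1)
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  stopifnot(!any(test_fx$sequence %in% fs$records$sequence))
  rep1 <- independent_test(model, test_fx, level = 1)
  expect_equal(rep1$overall_accuracy, 1.0)
  expect_equal(independent_test(model, test_fx, level = 2)$overall_accuracy,
               1.0)

  # an NR subfamily absent from the test set is reported as NA
  no4 <- test_fx[test_fx$label != "NR4", ]
  rep2 <- independent_test(model, no4, level = 2)
  expect_true(is.na(rep2$per_class$accuracy[rep2$per_class$class == "NR4"]))
  expect_true(is.na(rep2$per_class$MCC[rep2$per_class$class == "NR4"]))
})

test_that("feature ablation re-optimizes each descriptor subset", {
  fs <- small_family_set()
  nr <- fs$records[fs$is_nr, ]
  tab <- feature_ablation(nr, modes = c("AAC", "AAC+DC(0)", "ALL"),
                          K_values = c(1, 3), m_values = c(1.5, 2.5),
                          x = fs$x[fs$is_nr, ])
  expect_equal(tab$dims, c(20L, 420L, 881L))
  expect_equal(tab$accuracy[tab$mode == "ALL"], 1.0)
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_error(feature_ablation(nr, modes = "DC-only", x = fs$x[fs$is_nr, ]),
               "unknown feature mode")
})

test_that("evaluation reports and grid surfaces export to disk", {
  fs <- small_family_set()
  idx <- which(fs$is_nr)
  ref <- reference_set(fs$x[idx, ], fs$records$label[idx])
  rep <- jackknife(ref, fknn_params(2, 2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 5L)  # 4 classes + overall row
  expect_equal(tab$accuracy[tab$class == "Overall"], rep$overall_accuracy)
  json <- withr::local_tempfile(fileext = ".json")
  write_report(rep, json)
  parsed <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(parsed$overall_accuracy, rep$overall_accuracy)
  gs <- grid_search(ref, 1:2, c(1.5, 2))
  gtsv <- withr::local_tempfile(fileext = ".tsv")
  write_grid(gs, gtsv)
  expect_equal(nrow(read.delim(gtsv)), 4L)
})

test_that("cascade models round-trip through their archive file", {
  fs <- small_family_set()
  model <- train_cascade(fs$records, params1 = fknn_params(2, 1.8),
                         params2 = fknn_params(1, 1.5))
  # level-2 reference is exactly the NR-labeled half of level 1
  expect_equal(nrow(model$level2$ref$x), sum(fs$is_nr))
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$level1$params, model$level1$params)
  expect_equal(back$level2$ref$labels, model$level2$ref$labels)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(read_model(bad), "not a cascade model")
})
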