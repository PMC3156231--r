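make_ref <- function(x, labels) reference_set(as.matrix(x), labels)

test_that("neighbor search returns the K nearest by Euclidean distance", {
  set.seed(55)
  x <- matrix(rnorm(50 * 4), 50)
  ref <- make_ref(x, rep(c("A", "B"), 25))
  q <- rnorm(4)
  nb <- neighbor_search(q, ref, K = 5)
  # full-sort oracle
  d <- sqrt(colSums((t(x) - q)^2))
  expect_equal(nb$distance, sort(d)[1:5])
  expect_equal(nb$index, order(d)[1:5])
  # identity and exhaustive cases
  expect_equal(neighbor_search(x[7, ], ref, K = 1)$distance, 0)
  expect_equal(nrow(neighbor_search(q, ref, K = 50)), 50L)
  expect_error(neighbor_search(q, ref, K = 51), "exceeds")
})

test_that("distance ties at the K boundary break by insertion order", {
  x <- rbind(c(1, 0), c(0, 1), c(-1, 0))  # all at distance 1 from origin
  ref <- make_ref(x, c("A", "B", "C"))
  nb <- neighbor_search(c(0, 0), ref, K = 2)
  expect_equal(nb$index, c(1L, 2L))
})

test_that("fuzzy memberships follow the inverse-distance rule", {
  # K=1: point mass on the nearest neighbor's class
  ref <- make_ref(rbind(c(0, 0), c(5, 5)), c("A", "B"))
  mu <- fknn_memberships(c(1, 0), ref, fknn_params(K = 1, m = 2))
  expect_equal(unname(mu), c(1, 0))
  # equidistant neighbors of different classes split evenly
  mu2 <- fknn_memberships(c(0, 0), ref = make_ref(rbind(c(1, 0), c(-1, 0)),
                                                  c("A", "B")),
                          fknn_params(K = 2, m = 2))
  expect_equal(unname(mu2), c(0.5, 0.5))
  # hand evaluation: distances (1, 2, 2), labels (A, B, A), m = 2
  # weights d^-2 = (1, 1/4, 1/4) -> mu_A = 5/6, mu_B = 1/6
  ref3 <- make_ref(rbind(c(1, 0), c(2, 0), c(0, 2)), c("A", "B", "A"))
  mu3 <- fknn_memberships(c(0, 0), ref3, fknn_params(K = 3, m = 2))
  expect_equal(unname(mu3), c(5 / 6, 1 / 6))
  expect_error(fknn_params(K = 3, m = 1), "must be > 1")
})

test_that("memberships sum to 1 and stay within [0, 1] on random data", {
  set.seed(66)
  x <- matrix(rnorm(40 * 6), 40)
  ref <- make_ref(x, sample(c("A", "B", "C"), 40, replace = TRUE))
  for (i in 1:20) {
    mu <- fknn_memberships(rnorm(6), ref,
                           fknn_params(K = sample(1:10, 1),
                                       m = runif(1, 1.05, 4)))
    expect_equal(sum(mu), 1, tolerance = 1e-9)
    expect_true(all(mu >= 0 & mu <= 1))
  }
})

test_that("the fuzzy coefficient interpolates between 1-NN and the K-vote", {
  set.seed(77)
  x <- matrix(rnorm(30 * 3), 30)
  lab <- sample(c("A", "B"), 30, replace = TRUE)
  ref <- make_ref(x, lab)
  q <- rnorm(3)
  K <- 7
  # m -> 1+: point mass on the nearest neighbor's class
  mu_crisp <- fknn_memberships(q, ref, fknn_params(K, m = 1.0001))
  nearest <- neighbor_search(q, ref, 1)$label
  expect_equal(unname(mu_crisp[nearest]), 1, tolerance = 1e-6)
  # m -> infinity: unweighted K-neighbor vote proportions
  mu_vote <- fknn_memberships(q, ref, fknn_params(K, m = 1e7))
  votes <- table(factor(neighbor_search(q, ref, K)$label,
                        levels = ref$classes)) / K
  expect_equal(unname(mu_vote), as.numeric(votes), tolerance = 1e-5)
})

test_that("zero-distance neighbors take a uniform crisp vote", {
  x <- rbind(c(0, 0), c(0, 0), c(3, 3))
  ref <- make_ref(x, c("A", "B", "B"))
  mu <- fknn_memberships(c(0, 0), ref, fknn_params(K = 3, m = 2))
  expect_equal(unname(mu), c(0.5, 0.5))
})

test_that("crisp decisions take the argmax with principled tie-breaking", {
  ref <- make_ref(rbind(c(0, 0), c(4, 0)), c("A", "B"))
  out <- fknn_predict(c(1, 0), ref, fknn_params(K = 1, m = 2))
  expect_equal(out$label, "A")
  expect_equal(out$membership, 1)
  # exact membership tie: won by the nearest neighbor's class even when it
  # is later in class order
  ref2 <- make_ref(rbind(c(1, 0), c(-1, 0)), c("A", "B"))
  out2 <- fknn_predict(c(-0.0, 0), ref2, fknn_params(K = 2, m = 2))
  expect_equal(out2$label, "A")  # equidistant; A first by insertion order
  ref3 <- make_ref(rbind(c(0.5, 0), c(-1, 0), c(1.5, 0)), c("B", "A", "A"))
  out3 <- fknn_predict(c(0.5, 0), ref3, fknn_params(K = 1, m = 2))
  expect_equal(out3$label, "B")
})

test_that("predictions are invariant under class relabeling", {
  set.seed(88)
  x <- matrix(rnorm(30 * 4), 30)
  lab <- sample(c("A", "B", "C"), 30, replace = TRUE)
  relab <- c(A = "Z", B = "Y", C = "X")
  params <- fknn_params(K = 5, m = 1.8)
  ref1 <- reference_set(x, lab, classes = c("A", "B", "C"))
  ref2 <- reference_set(x, unname(relab[lab]), classes = c("Z", "Y", "X"))
  for (i in 1:10) {
    q <- rnorm(4)
    expect_equal(unname(relab[fknn_predict(q, ref1, params)$label]),
                 fknn_predict(q, ref2, params)$label)
  }
})

test_that("linearly separated clusters classify perfectly when held out", {
  set.seed(99)
  centers <- rbind(c(0, 0), c(10, 10))
  x <- rbind(sweep(matrix(rnorm(20), 10), 2, centers[1, ], "+"),
             sweep(matrix(rnorm(20), 10), 2, centers[2, ], "+"))
  lab <- rep(c("A", "B"), each = 10)
  params <- fknn_params(K = 3, m = 2)
  for (i in seq_len(20)) {
    ref <- reference_set(x[-i, ], lab[-i], classes = c("A", "B"))
    expect_equal(fknn_predict(x[i, ], ref, params)$label, lab[i])
  }
})
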