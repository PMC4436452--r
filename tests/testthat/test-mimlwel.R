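test_that("relation matrix thresholds cosine similarity of observed columns", {
  Y <- cbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1), c(1, 1, 0))
  R <- build_relation_matrix(Y, tau = 0.5)
  expect_equal(unclass(R)[1, 2], 1)  # cos = 1/sqrt(2) ~ 0.707 >= 0.5
  expect_equal(unclass(R)[1, 3], 0)  # disjoint support
  expect_equal(unclass(R)[1, 4], 1)  # identical columns
  expect_equal(diag(unclass(R)), rep(0, 4))
  expect_equal(unclass(R), t(unclass(R)))

  Yz <- cbind(c(1, 1, 0), c(0, 0, 0))
  expect_equal(sum(build_relation_matrix(Yz, 0)), 0)  # zero column unrelated
  expect_error(build_relation_matrix(Y, 1.5), "tau")
})

test_that("the bag embedding has dimension K + 1 with unit bias and RBF coordinates", {
  bags <- rand_bags(20, d = 2, seed = 8)
  emb <- fit_bag_embedding(bags, alpha = 0.1, mu = 1.0, seed = 3)
  expect_equal(emb$K, 2L)  # round(0.1 * 20)
  phi <- embed_bags(emb, bags)
  expect_equal(dim(phi), c(20L, 3L))
  expect_equal(phi[, 3], rep(1, 20))
  # a bag identical to a medoid embeds to 1 at that coordinate
  k1 <- emb$medoid_idx[1]
  expect_equal(phi[k1, 1], 1)
  # larger distance means strictly smaller coordinate
  D <- bag_dist_matrix(bags, "avg")
  ord <- order(D[, k1])
  far <- ord[20]; near <- ord[2]
  expect_lt(phi[far, 1], phi[near, 1])
})

test_that("embedding guards K at 1 and is deterministic in the seed", {
  bags <- rand_bags(12, seed = 4)
  emb <- fit_bag_embedding(bags, alpha = 0.01, seed = 5)  # round(0.12) = 0
  expect_equal(emb$K, 1L)
  e1 <- fit_bag_embedding(bags, alpha = 0.3, seed = 9)
  e2 <- fit_bag_embedding(bags, alpha = 0.3, seed = 9)
  expect_identical(e1$medoid_idx, e2$medoid_idx)
  expect_error(fit_bag_embedding(list(), 0.1), "empty")
  expect_error(fit_bag_embedding(bags, alpha = 0), "alpha")
  expect_error(fit_bag_embedding(bags, mu = -1), "mu")
})

test_that("K tracks round(alpha * m) at the published operating point", {
  bags <- rand_bags(25, d = 1, seed = 30, max_n = 1)
  # alpha = 0.1 on m bags: the reference operating point scaled down
  emb <- fit_bag_embedding(bags, alpha = 0.2, mu = 1.0, seed = 2)
  expect_equal(emb$K, 5L)
})

test_that("zero correction budget forces Y_bar == Y_hat", {
  set.seed(10)
  Phi <- cbind(matrix(rnorm(40), 20, 2), 1)
  Yh <- rand_binary(20, 3, seed = 11, p = 0.3)
  fit <- fit_mimlwel(Phi, Yh, epsilon = 0)
  expect_identical(fit$Y_bar, Yh)
  expect_length(fit$trace, 1L)
})

test_that("with no coupling the fit matches the closed-form least-squares oracle", {
  set.seed(7)
  Phi <- matrix(rnorm(100), 20, 5)
  y <- rbinom(20, 1, 0.5)
  fit <- fit_mimlwel(Phi, matrix(y, 20, 1), epsilon = 0)
  w_oracle <- solve(crossprod(Phi), crossprod(Phi, 2 * y - 1))
  expect_lt(max(abs(fit$W - w_oracle)), 1e-4)
})

test_that("jointly fitted W with R == 0 equals independent per-label fits", {
  set.seed(19)
  Phi <- cbind(matrix(rnorm(60), 30, 2), 1)
  Yh <- rand_binary(30, 4, seed = 20, p = 0.4)
  joint <- fit_mimlwel(Phi, Yh, R = matrix(0, 4, 4), epsilon = 0)
  for (l in 1:4) {
    solo <- fit_mimlwel(Phi, Yh[, l, drop = FALSE], epsilon = 0)
    expect_lt(max(abs(joint$W[, l] - solo$W)), 1e-3)
  }
})

test_that("the implemented group penalty equals direct summation over related pairs", {
  set.seed(23)
  W <- matrix(rnorm(5 * 4), 5, 4)
  R <- matrix(0, 4, 4); R[1, 2] <- R[2, 1] <- 1; R[3, 4] <- R[4, 3] <- 1
  pairs <- mimlwel:::related_pairs(R)
  got <- mimlwel:::group_penalty(W, pairs, sigma = 0)$value
  direct <- 0
  for (pr in list(c(1, 2), c(3, 4))) {
    direct <- direct + sum(sqrt(W[, pr[1]]^2 + W[, pr[2]]^2))^2
  }
  expect_equal(got, direct, tolerance = 1e-12)
})

test_that("the objective trace is non-increasing and constraints hold after fitting", {
  gen <- generate_dataset(synthetic_spec(m = 30, L = 8, dim = 10, seed = 14))
  Yh <- mask_labels(gen$dataset$Y, 0.6, seed = 15)
  emb <- fit_bag_embedding(gen$dataset$bags, alpha = 0.2, seed = 16)
  Phi <- embed_bags(emb, gen$dataset$bags)
  R <- build_relation_matrix(Yh, 0.5)
  fit <- fit_mimlwel(Phi, Yh, R, epsilon = 0.3)
  expect_true(all(diff(fit$trace) <= 1e-9))
  expect_true(all(fit$Y_bar >= Yh))
  flips <- colSums(fit$Y_bar) - colSums(Yh)
  expect_true(all(flips <= floor(0.3 * colSums(Yh))))
  # flipped entries must carry positive scores
  scores <- Phi %*% fit$W
  flipped <- which(fit$Y_bar == 1 & Yh == 0)
  if (length(flipped)) expect_true(all(scores[flipped] > 0))
})

test_that("prediction thresholds scores at zero and validates shapes", {
  Phi <- cbind(matrix(rnorm(20), 10, 2), 1)
  Yh <- rand_binary(10, 2, seed = 3, p = 0.5)
  fit <- fit_mimlwel(Phi, Yh, epsilon = 0)
  pred <- predict(fit, Phi)
  expect_equal(dim(pred$scores), c(10L, 2L))
  expect_identical(pred$binary, (pred$scores > 0) * 1)
  fit0 <- fit
  fit0$W[] <- 0
  pred0 <- predict(fit0, Phi)
  expect_true(all(pred0$scores == 0))
  expect_true(all(pred0$binary == 0))
  expect_error(predict(fit, Phi[, 1:2]), "dimension")
})

test_that("a separable training bag with +1 target is predicted positive", {
  bags <- list(new_bag("a", matrix(0, 1, 2)), new_bag("b", matrix(10, 1, 2)))
  Yh <- matrix(c(1, 0), 2, 1)
  model <- mimlwel_train(bags, Yh, alpha = 1, mu = 1, epsilon = 0, seed = 1)
  pred <- predict(model, bags)
  expect_equal(unname(pred$binary[, 1]), c(1, 0))
})

test_that("training scores are invariant to bag order given a fixed embedding", {
  set.seed(31)
  bags <- rand_bags(16, d = 3, seed = 31)
  Yh <- rand_binary(16, 3, seed = 32, p = 0.4)
  emb <- fit_bag_embedding(bags, alpha = 0.25, seed = 33)
  Phi <- embed_bags(emb, bags)
  perm <- sample(16)
  fit1 <- fit_mimlwel(Phi, Yh, epsilon = 0)
  fit2 <- fit_mimlwel(Phi[perm, ], Yh[perm, ], epsilon = 0)
  expect_equal(fit1$W, fit2$W, tolerance = 1e-6)
})

test_that("invalid learner inputs are rejected", {
  Phi <- cbind(1, 1)
  expect_error(fit_mimlwel(matrix(c(1, NA), 1, 2), matrix(1, 1, 1)), "non-finite")
  expect_error(fit_mimlwel(matrix(1, 2, 2), rand_binary(2, 1, 1), eta = 0), "eta")
  expect_error(fit_mimlwel(matrix(1, 2, 2), rand_binary(2, 1, 1), epsilon = -1), "epsilon")
})

test_that("models survive a JSON round trip and keep predicting identically", {
  gen <- generate_dataset(synthetic_spec(m = 15, L = 5, dim = 6, seed = 40))
  Yh <- mask_labels(gen$dataset$Y, 0.8, seed = 41)
  model <- mimlwel_train(gen$dataset$bags, Yh, alpha = 0.2, seed = 42)
  path <- tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  p1 <- predict(model, gen$dataset$bags)
  p2 <- predict(back, gen$dataset$bags)
  expect_equal(p1$scores, p2$scores)
})
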