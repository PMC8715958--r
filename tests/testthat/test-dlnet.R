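test_that("network spec enforces divisibility and filter schedule", {
  spec <- network_spec(input_edge = 96)
  expect_equal(spec$filters, c(16L, 32L, 64L, 128L))
  expect_equal(spec$final_edge, 6L)                 # 96 / 2^4
  expect_equal(network_spec(input_edge = 32)$final_edge, 2L)
  expect_equal(network_spec(input_edge = 32)$feat_len, 8L * 64L)
  expect_error(network_spec(input_edge = 8), class = "petriage_spec_error")
  expect_error(network_spec(input_edge = 30), class = "petriage_spec_error")
})

test_that("closed-form parameter count matches layer-list summation oracle", {
  # first block alone (1 -> 16): conv 16*28 + batchnorm 2*16 = 480
  spec1 <- network_spec(input_edge = 16, n_blocks = 1, head_channels = 0)
  bd <- attr(count_parameters(spec1), "breakdown")
  expect_equal(sum(bd$params[bd$layer %in% c("conv1_1", "bn1_1")]), 480)
  # head conv on 128 channels with 64 head channels: 64 * 129 = 8256
  spec2 <- network_spec(input_edge = 32)
  bd2 <- attr(count_parameters(spec2), "breakdown")
  expect_equal(bd2$params[bd2$layer == "head"], 8256)
  # two convs per block, filters 16..128, head ablated: conv+BN total 879,696
  spec3 <- network_spec(input_edge = 96, convs_per_block = 2, head_channels = 0)
  bd3 <- attr(count_parameters(spec3), "breakdown")
  convbn <- sum(bd3$params[grepl("^(conv|bn)", bd3$layer)])
  # independent oracle: walk the layer list and sum each layer's weights
  oracle <- 0L; cin <- 1L
  for (f in c(16, 32, 64, 128)) for (j in 1:2) {
    oracle <- oracle + f * (27 * cin + 1) + 2 * f
    cin <- f
  }
  expect_equal(convbn, oracle)
  expect_equal(convbn, 879696)
  # the model handle holds exactly count_parameters() trainable values
  for (spec in list(spec1, spec2, tiny_spec())) {
    model <- build_network(spec)
    expect_equal(petriage:::n_parameters(model), as.numeric(count_parameters(spec)))
  }
})

test_that("early stopping fires when the loss stalls for `patience` epochs", {
  losses <- c(1.00, 0.90, rep(0.895, 10))
  expect_equal(early_stop_epoch(losses, 0.01, 10), 12L)
  expect_true(is.na(early_stop_epoch(c(1, 0.9, 0.8, 0.7), 0.01, 10)))
  # an improvement resets the counter
  expect_equal(early_stop_epoch(c(1, rep(0.999, 9), 0.9, rep(0.899, 10)), 0.01, 10), 21L)
})

test_that("untrained network outputs probabilities strictly in (0, 1)", {
  model <- build_network(tiny_spec())
  fx <- fixture_tiny_volumes()
  p <- nn_predict(model, fx$volumes[1:4])
  expect_true(all(p > 0 & p < 1))
  expect_length(p, 4)
})

test_that("training separates phantom classes deterministically", {
  fx <- fixture_tiny_volumes()
  model <- build_network(tiny_spec())
  m1 <- nn_train(model, fx$volumes, fx$labels, tiny_config())
  expect_true(m1$trained)
  expect_lt(dplyr::last(m1$history$train_loss), m1$history$train_loss[1])
  # same data and seed give identical weights and history
  m2 <- nn_train(model, fx$volumes, fx$labels, tiny_config())
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  # trained model separates the classes it saw
  p <- nn_predict(m1, fx$volumes)
  expect_gt(mean(p[fx$labels == 1]), mean(p[fx$labels == 0]))
  # single-class input refuses to train
  expect_error(nn_train(model, fx$volumes[1:4], rep(1, 4), tiny_config()),
               class = "petriage_training_error")
})

test_that("prediction is order-preserving and batch-size independent", {
  fx <- fixture_tiny_volumes()
  model <- nn_train(build_network(tiny_spec()), fx$volumes, fx$labels, tiny_config())
  vols <- fx$volumes[c(1, 1, 5, 20)]
  p <- nn_predict(model, vols)
  expect_equal(p[1], p[2], tolerance = 1e-7)           # pure function
  p1 <- nn_predict(model, vols, batch_size = 1)
  p4 <- nn_predict(model, vols, batch_size = 4)
  expect_equal(p1, p4, tolerance = 1e-6)
  expect_error(nn_predict(model, list(array(0, c(8, 8, 8)))),
               class = "petriage_input_error")
})

test_that("features come from the last flatten layer with the right length", {
  fx <- fixture_tiny_volumes()
  spec <- tiny_spec()  # 16^3, 3 blocks -> final edge 2, head 16 -> 128
  model <- nn_train(build_network(spec), fx$volumes, fx$labels, tiny_config())
  f <- extract_features(model, fx$volumes[c(1, 1, 13)])
  expect_equal(ncol(f), 2^3 * 16)
  expect_equal(f[1, ], f[2, ], tolerance = 1e-7)       # identical inputs
  # between-class distances exceed within-class distances after training
  feats <- extract_features(model, fx$volumes)
  d <- as.matrix(dist(feats))
  same <- outer(fx$labels, fx$labels, "==") & upper.tri(d)
  diff <- outer(fx$labels, fx$labels, "!=") & upper.tri(d)
  expect_gt(mean(d[diff]), mean(d[same]))
})

test_that("diagnosis applies the >= threshold convention", {
  fx <- fixture_tiny_volumes()
  model <- nn_train(build_network(tiny_spec()), fx$volumes, fx$labels, tiny_config())
  expect_error(diagnose_uncertain(build_network(tiny_spec()), fx$volumes[1:2]),
               class = "petriage_state_error")
  dx <- diagnose_uncertain(model, fx$volumes, threshold = 0.5)
  expect_equal(dx$diagnosis, ifelse(dx$diagnosis_prob >= 0.5, "impaired", "healthy"))
  # threshold 1.0 is outside train_config but allowed here: nothing impaired
  dx1 <- diagnose_uncertain(model, fx$volumes, threshold = 1.0)
  expect_true(all(dx1$diagnosis[dx1$diagnosis_prob < 1] == "healthy"))
})

test_that("baseline classifiers fit, predict and are deterministic", {
  set.seed(10)
  n <- 60
  x <- rbind(matrix(rnorm(n / 2 * 5, mean = 2), ncol = 5),
             matrix(rnorm(n / 2 * 5, mean = -2), ncol = 5))
  y <- rep(c(1, 0), each = n / 2)
  for (kind in c("mlp3", "c_svm_linear", "c_svm_rbf", "nu_svm_linear",
                 "nu_svm_rbf", "linear_reg", "logistic_reg")) {
    m <- fit_baseline(kind, x, y, seed = 3)
    pred <- predict(m, x, type = "class")
    expect_equal(mean(pred == y), 1, label = kind)  # separable clouds
    s1 <- predict(m, x, type = "score")
    m2 <- fit_baseline(kind, x, y, seed = 3)
    expect_equal(s1, predict(m2, x, type = "score"), label = kind)
  }
  expect_error(fit_baseline("boost", x, y), class = "petriage_parameter_error")
})

test_that("baselines are at chance on permuted labels", {
  set.seed(11)
  n <- 200
  x <- matrix(rnorm(n * 10), n, 10)
  y <- sample(rep(c(1, 0), each = n / 2))
  fold <- rep(1:5, length.out = n)
  acc <- vapply(1:5, function(i) {
    m <- fit_baseline("c_svm_linear", x[fold != i, ], y[fold != i], seed = 1)
    mean(predict(m, x[fold == i, ], type = "class") == y[fold == i])
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.5), 0.15)
})
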