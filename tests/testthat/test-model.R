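test_that("network parameter counts match layer arithmetic", {
  net <- build_network("tiny", c(16, 10))
  # conv 3x3x1->8, conv 3x3x8->16, dense (2*1*16)->32, dense 32->2
  conv1 <- 3 * 3 * 1 * 8 + 8
  conv2 <- 3 * 3 * 8 * 16 + 16
  dense1 <- (2 * 1 * 16) * 32 + 32
  dense2 <- 32 * 2 + 2
  expect_equal(net$n_params, conv1 + conv2 + dense1 + dense2)

  # inception block output channels = sum of the four branch widths
  inc <- build_network("inception_like", c(32, 32))
  expect_equal(inc$layers[[4]]$out_shape[3], 8L + 16L + 8L + 8L)
  expect_equal(inc$layers[[5]]$out_shape[3], 16L + 24L + 8L + 8L)

  # inputs below the receptive-field minimum are refused with the minimum
  expect_error(build_network("tiny", c(2, 2)), "too small")
})

test_that("softmax output is a probability distribution for all architectures", {
  set.seed(31)
  for (arch in c("tiny", "inception_like")) {
    net <- build_network(arch, c(24, 24), seed = 4)
    X <- matrix(runif(24 * 24 * 5), 24 * 24, 5)
    logits <- cdrscreen:::net_forward(net$layers, X)$out
    p <- cdrscreen:::softmax_cols(logits)
    expect_equal(dim(p), c(2L, 5L))
    expect_equal(colSums(p), rep(1, 5))
    expect_true(all(p >= 0 & p <= 1))
  }
  # alexnet-like needs a larger canvas
  net <- build_network("alexnet_like", c(64, 64), seed = 4)
  p <- cdrscreen:::softmax_cols(
    cdrscreen:::net_forward(net$layers, matrix(runif(64 * 64 * 2),
                                               64 * 64, 2))$out)
  expect_equal(colSums(p), rep(1, 2))
})

test_that("backpropagation matches numerical gradients", {
  nf <- cdrscreen:::net_forward
  nb <- cdrscreen:::net_backward
  sx <- cdrscreen:::softmax_xent
  set.seed(42)
  N <- 3
  y <- c(1L, 0L, 1L); Y <- rbind(1 - y, y)
  eps <- 1e-6

  check_net <- function(net, X, poke) {
    fwd <- nf(net$layers, X, keep_cache = TRUE)
    grads <- nb(net$layers, sx(fwd$out, Y)$dlogits, fwd$caches)
    for (pk in poke) {
      lp <- net$layers; lm <- net$layers
      lp <- pk$set(lp, pk$get(lp) + eps)
      lm <- pk$set(lm, pk$get(lm) - eps)
      num <- (sx(nf(lp, X)$out, Y)$loss - sx(nf(lm, X)$out, Y)$loss) / (2 * eps)
      ana <- pk$grad(grads)
      expect_lt(abs(ana - num) / max(1e-6, abs(ana) + abs(num)), 1e-4)
    }
  }

  net <- build_network("tiny", c(12, 10), seed = 3)
  X <- matrix(runif(12 * 10 * N), 12 * 10, N)
  poke <- lapply(c(1, 4, 7, 9), function(k) {
    i <- k + 1L  # arbitrary but in-range weight index per layer
    list(get = function(l) l[[k]]$W[i],
         set = function(l, v) { l[[k]]$W[i] <- v; l },
         grad = function(g) g[[k]]$W[i])
  })
  check_net(net, X, poke)

  net2 <- build_network("inception_like", c(24, 24), seed = 5)
  X2 <- matrix(runif(24 * 24 * N), 24 * 24, N)
  poke2 <- lapply(1:4, function(br) {
    sub <- if (br == 4) 2L else 1L
    list(get = function(l) l[[4]]$branches[[br]][[sub]]$W[3],
         set = function(l, v) { l[[4]]$branches[[br]][[sub]]$W[3] <- v; l },
         grad = function(g) g[[4]][[br]][[sub]]$W[3])
  })
  check_net(net2, X2, poke2)
})

test_that("training is deterministic, finite and refuses degenerate labels", {
  fx <- tiny_model()
  cfg <- cdr_train_config("tiny", max_epochs = 3, seed = 1)
  m2 <- cdr_cnn(fx$enc$images, fx$enc$labels, cfg)
  expect_identical(fx$model$history, m2$history)
  expect_identical(predict(fx$model, fx$enc$images, type = "prob"),
                   predict(m2, fx$enc$images, type = "prob"))
  expect_true(all(is.finite(fx$model$history$loss)))
  expect_equal(nrow(fx$model$history), 3L)

  expect_error(cdr_cnn(fx$enc$images, rep(1L, ncol(fx$enc$images$x)), cfg),
               "single class")
  expect_error(cdr_cnn(fx$enc$images, fx$enc$labels,
                       cdr_train_config("tiny", input_shape = c(50, 50))),
               "does not match")
})

test_that("a linearly separable planted rule is learned within 20 epochs", {
  w <- simulate_cdr_world(sim_config(n_compounds = 20, n_diseases = 20,
                                     d_compound = 32, d_disease = 16,
                                     seed = 11))
  ci <- match(w$pairs$compound_id, w$compounds$ids)
  di <- match(w$pairs$disease_id, w$diseases$ids)
  score <- w$truth$u[ci, 1] + w$truth$v[di, 1]  # linear in the image pixels
  lab <- as.integer(score > stats::median(score))
  enc <- encode_world(w)
  m <- cdr_cnn(enc$images, lab, cdr_train_config("tiny", seed = 2))
  expect_gt(tail(m$history$accuracy, 1), 0.95)
  prob <- predict(m, enc$images, type = "prob")
  expect_gt(mean((prob > 0.5) == lab), 0.95)
})

test_that("prediction obeys the strict 0.5 rule and batch equivariance", {
  fx <- tiny_model()
  m <- fx$model
  stack <- fx$enc$images

  # predictions are equivariant under permutation of the batch
  p <- predict(m, stack, type = "prob")
  idx <- rev(seq_along(p))
  perm <- stack
  perm$x <- perm$x[, idx]
  expect_equal(predict(m, perm, type = "prob"), p[idx])

  # probability exactly 0.5 is labelled negative: zero the output layer
  m0 <- m
  k <- length(m0$network$layers)
  m0$network$layers[[k]]$W[] <- 0
  m0$network$layers[[k]]$b[] <- 0
  res <- predict(m0, stack)
  expect_true(all(res$probability == 0.5))
  expect_true(all(res$label == "negative"))

  # pair ids are carried through
  res2 <- predict(m, stack, pairs = fx$world$pairs)
  expect_named(res2, c("compound_id", "disease_id", "probability", "label"))

  # shape mismatch is an error
  bad <- array(runif(8 * 8 * 2), c(8, 8, 2))
  expect_error(predict(m, bad), "does not match")
})

test_that("model checkpoints round-trip exactly", {
  fx <- tiny_model()
  path <- withr::local_tempfile(fileext = ".rds")
  write_cdr_model(fx$model, path, norm_hash = "abc123")
  back <- read_cdr_model(path)
  expect_identical(predict(back, fx$enc$images, type = "prob"),
                   predict(fx$model, fx$enc$images, type = "prob"))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$architecture, "tiny")
  expect_equal(side$norm_hash, "abc123")
})
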