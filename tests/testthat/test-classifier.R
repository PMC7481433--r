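# Slice classifier: preprocessing, augmentation, loss, early stopping,
# forward-pass properties.

test_that("preprocessing yields the contracted shape and channel moments", {
  raw <- matrix(runif(256 * 256), 256, 256)
  obs <- preprocess_slice(raw)
  expect_equal(dim(obs$pixels), c(331, 331, 3))
  for (ch in 1:3) {
    expect_equal(mean(obs$pixels[, , ch]), 0.5, tolerance = 1e-9)
    expect_equal(var(as.vector(obs$pixels[, , ch])), 0.5, tolerance = 1e-9)
  }
  # channels are identical replicas of the standardized crop
  expect_identical(obs$pixels[, , 1], obs$pixels[, , 2])
})

test_that("a constant slice maps to the target mean via the degenerate guard", {
  obs <- preprocess_slice(matrix(7, 256, 256))
  expect_true(all(obs$pixels == 0.5))
})

test_that("undersized slices are rejected rather than silently padded", {
  expect_error(preprocess_slice(matrix(0, 128, 128)), "smaller than")
  expect_error(preprocess_slice(matrix(0, 256, 199)), "smaller than")
})

test_that("the centered crop equals independent index arithmetic on a ramp image", {
  H <- 260; W <- 300
  ramp <- outer(seq_len(H), seq_len(W), function(i, j) i * 1000 + j)
  # crop_size == out_size skips the resize, exposing the raw crop
  obs <- preprocess_slice(ramp, crop_size = 200, out_size = 200)
  r0 <- floor((H - 200) / 2) + 1
  c0 <- floor((W - 200) / 2) + 1
  want <- ramp[r0:(r0 + 199), c0:(c0 + 199)]
  want_std <- (want - mean(want)) / sd(want) * sqrt(0.5) + 0.5
  expect_equal(obs$pixels[, , 1], want_std, tolerance = 1e-12)
})

test_that("augmentation is identity when disabled and under null transforms", {
  obs <- preprocess_slice(matrix(runif(256^2), 256, 256))
  expect_identical(augment(obs, enabled = FALSE), obs)
  same <- augment(obs, seed = 1, rotation = 0, mirror = FALSE, affine = 0)
  expect_equal(same$pixels, obs$pixels, tolerance = 1e-12)
})

test_that("mirroring twice with the same axis restores the original pixels", {
  obs <- preprocess_slice(matrix(runif(256^2), 256, 256))
  # find a seed whose draw triggers the mirror branch
  seed <- which(sapply(1:10, function(s)
    gradenav:::with_seed(s, stats::runif(1)) < 0.5))[1]
  once <- augment(obs, seed = seed, rotation = 0, mirror = TRUE, affine = 0)
  twice <- augment(once, seed = seed, rotation = 0, mirror = TRUE, affine = 0)
  expect_false(isTRUE(all.equal(once$pixels, obs$pixels)))
  expect_equal(twice$pixels, obs$pixels, tolerance = 1e-12)
})

test_that("a fixed seed reproduces the augmentation transform exactly", {
  obs <- preprocess_slice(matrix(runif(256^2), 256, 256))
  a1 <- augment(obs, seed = 42)
  a2 <- augment(obs, seed = 42)
  expect_identical(a1$pixels, a2$pixels)
  a3 <- augment(obs, seed = 43)
  expect_false(isTRUE(all.equal(a1$pixels, a3$pixels)))
})

test_that("cross-entropy has its closed-form values and matches a per-sample oracle", {
  onehot <- matrix(c(0, 0, 1, 0, 0), 1, 5)
  expect_equal(suppressWarnings(cross_entropy(onehot, 3L)), 0)
  unif <- matrix(1 / 5, 4, 5)
  expect_equal(cross_entropy(unif, c(1L, 2L, 3L, 5L)), log(5),
               tolerance = 1e-12)
  set.seed(10)
  probs <- matrix(rexp(20 * 5), 20, 5)
  probs <- probs / rowSums(probs)
  labels <- sample(1:5, 20, replace = TRUE)
  manual <- 0
  for (i in 1:20) manual <- manual - log(probs[i, labels[i]])
  expect_equal(cross_entropy(probs, labels), manual / 20, tolerance = 1e-9)
  expect_warning(cross_entropy(matrix(c(1, 0, 0, 0, 0), 1, 5), 2L), "clamped")
  # loss on a batch equals the mean of per-sample losses (linearity)
  per_sample <- sapply(1:20, function(i)
    cross_entropy(probs[i, , drop = FALSE], labels[i]))
  expect_equal(cross_entropy(probs, labels), mean(per_sample),
               tolerance = 1e-12)
})

test_that("early stopping fires exactly patience epochs after the last improvement", {
  # frozen from epoch 2: fires at epoch 7 with patience 5
  acc <- c(0.5, 0.7, rep(0.7, 5))
  expect_equal(gradenav:::.early_stop_epoch(acc, 5L), 7L)
  # still improving: never fires
  expect_true(is.na(gradenav:::.early_stop_epoch(seq(0.1, 0.9, by = 0.1), 5L)))
  # immediate freeze: fires at patience + 1
  expect_equal(gradenav:::.early_stop_epoch(rep(0.4, 10), 3L), 4L)
})

test_that("training refuses an empty validation split", {
  spec <- small_spec(4, seed = 1)
  cohort <- generate_cohort(spec, split_fractions = c(train = 1, val = 0, test = 0))
  expect_error(train_slice_classifier(cohort, small_train_config()),
               "validation split is empty")
})

test_that("readouts are deterministic, normalized, and argmax-consistent", {
  cls <- random_classifier(input_size = 16, feature_dim = 32, seed = 6)
  set.seed(3)
  m <- matrix(runif(16 * 16), 16, 16)
  r1 <- slice_readout(cls, m)
  r2 <- slice_readout(cls, m)
  expect_identical(r1, r2)
  for (k in 1:200) {
    r <- slice_readout(cls, matrix(runif(16 * 16), 16, 16))
    expect_true(all(r$probs >= 0))
    expect_equal(sum(r$probs), 1, tolerance = 1e-6)
    # argmax matches an independent max scan, ties toward the lower class
    want <- which(r$probs == max(r$probs))[1]
    expect_equal(r$predicted, cls$classes[want])
    expect_length(r$features, 32)
  }
})

test_that("readout input shape mismatches raise explicit errors", {
  cls <- random_classifier(input_size = 16)
  expect_error(slice_readout(cls, matrix(0, 20, 20)), "expects")
})

test_that("the convolution primitive matches a direct double-loop convolution", {
  set.seed(4)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  W <- matrix(rnorm(3 * 18), 3, 18)
  b <- c(0.1, -0.2, 0.3)
  out <- gradenav:::conv_forward(x, W, b, relu = FALSE)$out
  # direct computation: same-padding 3x3 convolution; weight rows follow the
  # (shift, channel) layout of the im2col builder
  shifts <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
  for (co in 1:3) for (i in 1:6) for (j in 1:6) {
    acc <- b[co]
    for (s in 1:9) for (ci in 1:2) {
      y <- i + shifts[s, 1]; x_ <- j + shifts[s, 2]
      v <- if (y >= 1 && y <= 6 && x_ >= 1 && x_ <= 6) x[y, x_, ci] else 0
      acc <- acc + W[co, (s - 1) * 2 + ci] * v
    }
    expect_equal(out[i, j, co], acc, tolerance = 1e-12)
  }
})

test_that("conv/pool/dense gradients agree with finite differences", {
  set.seed(9)
  xs <- list(matrix(rnorm(8 * 8), 8, 8))
  net <- gradenav:::cnn_init(8, channels = c(3, 4), feature_dim = 6,
                             n_classes = 3, pool_factor = 1, seed = 2)
  y <- 2L
  loss_of <- function(net) {
    p <- gradenav:::softmax_rows(gradenav:::cnn_forward(net, xs)$logits)
    -log(p[1, y])
  }
  fw <- gradenav:::cnn_forward(net, xs, keep_cache = TRUE)
  p <- gradenav:::softmax_rows(fw$logits)
  dl <- p; dl[1, y] <- dl[1, y] - 1
  g <- gradenav:::cnn_backward(net, fw$caches, dl)
  eps <- 1e-6
  # spot-check a handful of coordinates in each parameter block
  for (blk in list(c("conv", 1), c("conv", 2), c("fc1", NA), c("fc2", NA))) {
    W <- if (blk[1] == "conv") net$conv[[as.integer(blk[2])]]$W else
      net[[blk[1]]]$W
    dW <- if (blk[1] == "conv") g$conv[[as.integer(blk[2])]]$dW else
      g[[blk[1]]]$dW
    idx <- cbind(sample(nrow(W), 3, replace = TRUE),
                 sample(ncol(W), 3, replace = TRUE))
    for (r in 1:3) {
      net2 <- net
      if (blk[1] == "conv") {
        net2$conv[[as.integer(blk[2])]]$W[idx[r, 1], idx[r, 2]] <-
          W[idx[r, 1], idx[r, 2]] + eps
      } else {
        net2[[blk[1]]]$W[idx[r, 1], idx[r, 2]] <- W[idx[r, 1], idx[r, 2]] + eps
      }
      fd <- (loss_of(net2) - loss_of(net)) / eps
      expect_equal(dW[idx[r, 1], idx[r, 2]], fd, tolerance = 1e-3)
    }
  }
})
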