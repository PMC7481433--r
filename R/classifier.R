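# Slice-level grade classifier ("generator net"): preprocessing, augmentation,
# loss, training with early stopping, and per-slice readouts (class
# probabilities + the feature vector consumed by the navigation agent).

#' Preprocess a raw slice into a classifier observation
#'
#' Takes a center-anchored `crop_size` x `crop_size` window (the anchor is the
#' geometric center of the slice; windows at the border are clamped inside the
#' image), rescales it to `out_size` x `out_size` by bilinear interpolation,
#' replicates it to 3 channels, and standardizes each channel to the target
#' moments by the affine map `x' = (x - mean(x)) / sd(x) * sqrt(0.5) + 0.5`.
#' A near-constant channel (sd < 1e-8) is set to the target mean.
#'
#' @param raw_slice 2D numeric matrix, at least `crop_size` in each dimension.
#' @param crop_size side of the centered region of interest (default 200).
#' @param out_size side of the network input (default 331).
#' @param target_mean,target_var target channel moments (defaults 0.5, 0.5).
#' @param source_index 0-based slice index recorded in the observation.
#' @param patient_id identifier recorded in the observation.
#' @return object of class `slice_observation` with `pixels`
#'   (`out_size` x `out_size` x 3 array), `source_index` and `patient_id`.
#' @export
preprocess_slice <- function(raw_slice, crop_size = 200L, out_size = 331L,
                             target_mean = 0.5, target_var = 0.5,
                             source_index = NA_integer_,
                             patient_id = NA_character_) {
  stop_if_not(is.matrix(raw_slice) && is.numeric(raw_slice),
              "raw_slice must be a numeric matrix")
  H <- nrow(raw_slice); W <- ncol(raw_slice)
  stop_if_not(H >= crop_size && W >= crop_size,
              "slice (%dx%d) smaller than the %dx%d crop window; no silent padding",
              H, W, crop_size, crop_size)
  r0 <- min(max(1L, floor((H - crop_size) / 2) + 1L), H - crop_size + 1L)
  c0 <- min(max(1L, floor((W - crop_size) / 2) + 1L), W - crop_size + 1L)
  roi <- raw_slice[r0:(r0 + crop_size - 1L), c0:(c0 + crop_size - 1L)]
  scaled <- if (crop_size == out_size) roi else
    as.matrix(EBImage::resize(roi, w = out_size, h = out_size,
                              filter = "bilinear"))
  s <- stats::sd(scaled)
  chan <- if (s < 1e-8) {
    matrix(target_mean, out_size, out_size)
  } else {
    (scaled - mean(scaled)) / s * sqrt(target_var) + target_mean
  }
  pixels <- array(chan, c(out_size, out_size, 3L))
  structure(list(pixels = pixels, source_index = source_index,
                 patient_id = patient_id),
            class = "slice_observation")
}

#' @export
print.slice_observation <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("slice_observation: %dx%dx%d (patient %s, slice %s)\n",
              d[1], d[2], d[3], x$patient_id, x$source_index))
  invisible(x)
}

# single-channel augmentation used on cached network inputs during training
.augment_matrix <- function(m, rotation = 15, mirror = TRUE, affine = 0.1) {
  size <- nrow(m)
  bg <- stats::median(m)
  if (mirror && stats::runif(1) < 0.5) m <- m[, rev(seq_len(size))]
  ang <- stats::runif(1, -rotation, rotation)
  if (abs(ang) > 1e-12) {
    m <- as.matrix(EBImage::rotate(m, ang, output.dim = c(size, size),
                                   bg.col = bg))
  }
  if (affine > 0) {
    sc <- stats::runif(1, 1 - affine, 1 + affine)
    sh <- stats::runif(1, -affine, affine)
    tx <- stats::runif(2, -affine / 2, affine / 2) * size
    cx <- size / 2
    A <- matrix(c(sc, sh, 0, sc), 2, 2)
    off <- c(cx, cx) - A %*% c(cx, cx) + tx
    mt <- rbind(A, as.numeric(off))          # 3x2 as EBImage expects
    m <- as.matrix(EBImage::affine(m, mt, output.dim = c(size, size),
                                   bg.col = bg))
  }
  m
}

#' Randomly augment a slice observation
#'
#' Applies, in training mode, a random mirror flip, a random rotation and a
#' small random affine (scale/shear/translate) transform, identically to all
#' channels; the spatial dimensions are preserved and the label is untouched.
#' With `enabled = FALSE` the observation is returned unchanged.
#'
#' @param obs a [preprocess_slice()] observation.
#' @param seed RNG seed for the transform draw.
#' @param rotation max rotation in degrees.
#' @param mirror allow horizontal mirroring.
#' @param affine scale of the affine perturbation (0 disables it).
#' @param enabled master switch; FALSE returns the identity.
#' @return a `slice_observation` of identical shape.
#' @export
augment <- function(obs, seed = NULL, rotation = 15, mirror = TRUE,
                    affine = 0.1, enabled = TRUE) {
  stop_if_not(inherits(obs, "slice_observation"),
              "obs must be a slice_observation")
  if (!enabled) return(obs)
  run <- function() {
    m <- .augment_matrix(obs$pixels[, , 1], rotation, mirror, affine)
    obs$pixels <- array(m, dim(obs$pixels))
    obs
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Multiclass cross-entropy loss
#'
#' Mean negative log predicted probability of the true class. Zero
#' probabilities at the true class are clamped at `eps` with a warning.
#'
#' @param probs B x K matrix of class probabilities (rows sum to 1).
#' @param labels integer class indices in 1..K, length B.
#' @param eps clamping constant for log(0).
#' @return scalar loss.
#' @export
cross_entropy <- function(probs, labels, eps = 1e-12) {
  probs <- as.matrix(probs)
  B <- nrow(probs)
  stop_if_not(B >= 1, "batch must be nonempty")
  stop_if_not(length(labels) == B, "labels must match batch size")
  stop_if_not(all(labels >= 1 & labels <= ncol(probs)),
              "labels out of class range 1..%d", ncol(probs))
  p <- probs[cbind(seq_len(B), labels)]
  if (any(p < eps)) {
    warning(sprintf("%d true-class probabilities clamped at eps=%g",
                    sum(p < eps), eps), call. = FALSE)
    p <- pmax(p, eps)
  }
  -mean(log(p))
}

#' Training configuration for the slice classifier
#'
#' Defaults follow routine settings for this kind of model: SGD with momentum
#' 0.9, batch size 64, learning rate 0.01 decayed exponentially by 0.97 per
#' epoch, early stopping after 5 consecutive epochs without validation
#' accuracy improvement, and a 4320-dimensional feature layer.
#'
#' @param batch_size minibatch size.
#' @param lr initial learning rate.
#' @param lr_decay multiplicative decay per epoch.
#' @param momentum SGD momentum.
#' @param early_stop_patience consecutive non-improving epochs tolerated.
#' @param max_epochs hard cap on epochs.
#' @param n_classes 5 (grades only) or 6 (class 0 = non-tumor slice).
#' @param feature_dim length of the feature vector exposed to the agent.
#' @param channels conv channels per block of the default backbone.
#' @param input_size side of the preprocessed input (must match
#'   [preprocess_slice()] `out_size`).
#' @param pool_factor fixed average-pool factor applied before the first
#'   convolution (331 -> 66 with the default 5).
#' @param crop_size region-of-interest side passed to [preprocess_slice()].
#' @param augment_rotation,augment_mirror,augment_affine,augment_enabled
#'   augmentation controls (see [augment()]).
#' @param optimizer "sgd" (momentum SGD with the exponential learning-rate
#'   schedule; the default) or "adam" (adaptive moments, recommended when the
#'   backbone is trained from scratch rather than fine-tuned).
#' @param weight_decay decoupled L2 weight decay per update (0 disables).
#' @param dropout dropout probability on the feature layer during training
#'   (0 disables).
#' @param head how the last convolution map enters the feature layer:
#'   "flatten" keeps positions, "gap" global-average-pools each channel
#'   (position-invariant, far fewer parameters).
#' @param input_stats concatenate global intensity quantiles of the input to
#'   the convolutional features before the feature layer; upper quantiles
#'   carry first-order lesion-contrast information that small conv stacks
#'   extract poorly from little data.
#' @param ema_decay per-epoch Polyak averaging factor for the evaluated
#'   weights (0 disables): validation and the returned model use the
#'   exponential moving average of the epoch-end weights, which damps
#'   epoch-to-epoch oscillation of small-batch adaptive training.
#' @param clip_norm global gradient-norm cap per update (Inf disables);
#'   stabilizes the first from-scratch SGD steps without altering the
#'   learning-rate schedule.
#' @param eps cross-entropy clamping constant.
#' @param seed RNG seed for weight init, shuffling and augmentation.
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, lr = 0.01, lr_decay = 0.97,
                         momentum = 0.9, early_stop_patience = 5L,
                         max_epochs = 30L, n_classes = 5L,
                         feature_dim = 4320L, channels = c(8, 16, 16, 32, 32),
                         input_size = 331L, pool_factor = 5L,
                         crop_size = 200L,
                         augment_rotation = 15, augment_mirror = TRUE,
                         augment_affine = 0.1, augment_enabled = TRUE,
                         clip_norm = 1, optimizer = c("sgd", "adam"),
                         weight_decay = 0, ema_decay = 0, dropout = 0,
                         head = c("flatten", "gap"), input_stats = TRUE,
                         eps = 1e-12, seed = 1L) {
  head <- match.arg(head)
  optimizer <- match.arg(optimizer)
  stop_if_not(n_classes %in% c(5L, 6L), "n_classes must be 5 or 6")
  for (v in list(batch_size, lr, lr_decay, momentum, early_stop_patience,
                 max_epochs, feature_dim)) {
    stop_if_not(all(v > 0), "all hyperparameters must be positive")
  }
  cfg <- list(batch_size = as.integer(batch_size), lr = lr,
              lr_decay = lr_decay, momentum = momentum,
              early_stop_patience = as.integer(early_stop_patience),
              max_epochs = as.integer(max_epochs),
              n_classes = as.integer(n_classes),
              feature_dim = as.integer(feature_dim), channels = channels,
              input_size = as.integer(input_size),
              pool_factor = as.integer(pool_factor),
              crop_size = as.integer(crop_size),
              augment_rotation = augment_rotation,
              augment_mirror = augment_mirror,
              augment_affine = augment_affine,
              augment_enabled = augment_enabled,
              clip_norm = clip_norm, optimizer = optimizer,
              weight_decay = weight_decay, ema_decay = ema_decay,
              dropout = dropout, head = head, input_stats = input_stats,
              eps = eps, seed = as.integer(seed))
  class(cfg) <- "train_config"
  cfg
}

# class labels used by an n-class model: grades 1..5, optionally with the
# non-tumor class 0 in front.
.classifier_classes <- function(n_classes) {
  if (n_classes == 6L) 0:5 else 1:5
}

# index of the epoch at which early stopping fires given per-epoch validation
# accuracies, or NA if it never does: training stops after `patience`
# consecutive epochs without strict improvement over the running best.
.early_stop_epoch <- function(val_acc, patience) {
  best <- -Inf
  stale <- 0L
  for (e in seq_along(val_acc)) {
    if (val_acc[e] > best + 1e-12) {
      best <- val_acc[e]
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) return(e)
    }
  }
  NA_integer_
}

# Extract (network-resolution input, label) pairs from a cohort split.
# 5-class mode: tumor slices only, labeled with the patient grade.
# 6-class mode: all slices; non-tumor slices get class 0.
.cohort_slice_data <- function(cohort, split, cfg) {
  keep <- cohort$manifest$split %in% split
  xs <- list(); labels <- integer(0); pid <- character(0); sidx <- integer(0)
  for (v in cohort$volumes[keep]) {
    take <- if (cfg$n_classes == 5L) which(v$tumor_flags) else
      seq_along(v$slices)
    for (i in take) {
      obs <- preprocess_slice(v$slices[[i]], crop_size = cfg$crop_size,
                              out_size = cfg$input_size,
                              source_index = i - 1L,
                              patient_id = v$patient_id)
      x <- obs$pixels[, , 1]
      dim(x) <- c(dim(x), 1L)
      if (cfg$pool_factor > 1L) x <- avgpool_forward(x, cfg$pool_factor)
      xs[[length(xs) + 1L]] <- x[, , 1]
      labels <- c(labels, if (v$tumor_flags[i]) v$gg_rp else 0L)
      pid <- c(pid, v$patient_id)
      sidx <- c(sidx, i - 1L)
    }
  }
  list(x = xs, label = labels, patient_id = pid, source_index = sidx)
}

#' Train the slice-level grade classifier
#'
#' Fits the convolutional backbone by SGD with momentum (batch 64, learning
#' rate 0.01 decayed by 0.97 per epoch by default) on the tumor slices of the
#' training split, each labeled with its patient-level grade; in 6-class mode
#' all slices are used and non-tumor slices form class 0. Validation accuracy
#' drives early stopping: training stops once it has failed to improve for
#' `early_stop_patience` consecutive epochs and the best-epoch weights are
#' returned.
#'
#' @param cohort a `phantom_cohort` (or list with `volumes` + `manifest`).
#' @param config a [train_config()].
#' @param train_split,val_split manifest split labels used for training and
#'   validation; the validation set must be nonempty.
#' @return object of class `slice_classifier` with the fitted network,
#'   per-epoch `history`, `best_epoch` and the configuration hash.
#' @export
train_slice_classifier <- function(cohort, config = train_config(),
                                   train_split = "train", val_split = "val") {
  stop_if_not(inherits(config, "train_config"), "config must be a train_config")
  tr <- .cohort_slice_data(cohort, train_split, config)
  va <- .cohort_slice_data(cohort, val_split, config)
  stop_if_not(length(tr$x) > 0, "training split contains no usable slices")
  stop_if_not(length(va$x) > 0,
              "validation split is empty: early stopping undefined")
  classes <- .classifier_classes(config$n_classes)
  y_tr <- match(tr$label, classes)
  y_va <- match(va$label, classes)
  stop_if_not(!anyNA(y_tr) && !anyNA(y_va), "labels outside class set")

  n <- length(tr$x)
  net_size <- config$input_size %/% config$pool_factor
  net <- cnn_init(input_size = net_size, channels = config$channels,
                  feature_dim = config$feature_dim,
                  n_classes = config$n_classes, pool_factor = 1L,
                  head = config$head, input_stats = config$input_stats,
                  seed = derive_seed(config$seed, 0))
  # calibrate layer scales on a probe batch before any gradient step
  probe <- tr$x[with_seed(derive_seed(config$seed, 99),
                          sample.int(n, min(16L, n)))]
  net <- cnn_calibrate(net, probe)
  state <- NULL
  history <- NULL
  best <- list(acc = -Inf, net = net, epoch = 0L)
  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$lr * config$lr_decay^(epoch - 1)
    ord <- with_seed(derive_seed(config$seed, epoch), sample.int(n))
    ep_loss <- 0; ep_correct <- 0
    aug_seed <- derive_seed(config$seed, 100000 + epoch)
    with_seed(aug_seed, {
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- lapply(tr$x[idx], function(m) {
          if (config$augment_enabled) {
            m <- .augment_matrix(m, config$augment_rotation,
                                 config$augment_mirror, config$augment_affine)
          }
          m
        })
        fw <- cnn_forward(net, xb, keep_cache = TRUE,
                          dropout = config$dropout)
        probs <- softmax_rows(fw$logits)
        yb <- y_tr[idx]
        ep_loss <- ep_loss + suppressWarnings(
          cross_entropy(probs, yb, config$eps)) * length(idx)
        ep_correct <- ep_correct + sum(max.col(probs, ties.method = "first") == yb)
        dlogits <- probs
        dlogits[cbind(seq_along(idx), yb)] <-
          dlogits[cbind(seq_along(idx), yb)] - 1
        dlogits <- dlogits / length(idx)
        grads <- cnn_clip_grads(cnn_backward(net, fw$caches, dlogits),
                                config$clip_norm)
        upd <- cnn_sgd_step(net, grads, state, lr, config$momentum,
                            config$optimizer, config$weight_decay)
        net <- upd$net; state <- upd$state
      }
    })
    if (config$ema_decay > 0) {
      ema <- if (epoch == 1L) net else
        cnn_blend(ema, net, config$ema_decay)
      eval_net <- ema
    } else eval_net <- net
    vf <- cnn_forward(eval_net, va$x)
    vp <- softmax_rows(vf$logits)
    val_loss <- suppressWarnings(cross_entropy(vp, y_va, config$eps))
    val_acc <- mean(max.col(vp, ties.method = "first") == y_va)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = ep_loss / n,
      train_acc = ep_correct / n, val_loss = val_loss, val_acc = val_acc))
    if (val_acc > best$acc + 1e-12) {
      best <- list(acc = val_acc, net = eval_net, epoch = epoch)
    }
    if (!is.na(.early_stop_epoch(history$val_acc,
                                 config$early_stop_patience))) break
  }
  structure(list(net = best$net, config = config, classes = classes,
                 history = history, best_epoch = best$epoch,
                 val_acc = best$acc, hash = config_hash(config)),
            class = "slice_classifier")
}

#' @export
print.slice_classifier <- function(x, ...) {
  cat(sprintf(
    "slice_classifier (%d-class, feature dim %d, config %s)\n",
    x$config$n_classes, x$config$feature_dim, x$hash))
  cat(sprintf("  trained %d epoch(s); best epoch %d, val accuracy %.3f\n",
              nrow(x$history), x$best_epoch, x$val_acc))
  invisible(x)
}

#' @export
summary.slice_classifier <- function(object, ...) {
  print(object)
  print(utils::tail(object$history, 8), row.names = FALSE)
  invisible(object)
}

#' @export
plot.slice_classifier <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$val_acc, type = "b", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy",
                 main = "slice classifier training", ...)
  graphics::lines(h$epoch, h$train_acc, type = "b", lty = 2)
  graphics::legend("bottomright", c("validation", "training"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

# normalize classifier inputs (observation, matrix at input or network
# resolution) to the single-channel matrix the backbone consumes
.as_net_input <- function(model, obs) {
  cfg <- model$config
  m <- if (inherits(obs, "slice_observation")) obs$pixels[, , 1] else obs
  stop_if_not(is.matrix(m), "observation must be a slice_observation or matrix")
  net_size <- cfg$input_size %/% cfg$pool_factor
  if (nrow(m) == cfg$input_size && cfg$pool_factor > 1L) {
    dim(m) <- c(dim(m), 1L)
    m <- avgpool_forward(m, cfg$pool_factor)[, , 1]
  }
  stop_if_not(nrow(m) == net_size && ncol(m) == net_size,
              "input is %dx%d but the network expects %dx%d (or %dx%d raw)",
              nrow(m), ncol(m), net_size, net_size,
              cfg$input_size, cfg$input_size)
  m
}

#' Slice readout: features + class probabilities for one observation
#'
#' Generic so that the navigation environment and end-to-end loop can work
#' with any slice model (including mock functions in tests). The default
#' classifier method runs a deterministic forward pass and returns the
#' feature vector, softmax probabilities and the argmax grade, ties broken
#' toward the lower grade.
#'
#' @param model a fitted `slice_classifier` (or a function of the
#'   observation returning a readout, for plugging in other backbones).
#' @param obs a `slice_observation` (or an input-resolution matrix).
#' @return object of class `slice_readout` with `features`, `probs` (named by
#'   class), `predicted` (argmax class label; 0 possible in 6-class mode) and
#'   `grade_probs` (probabilities renormalized over grades 1..5).
#' @export
slice_readout <- function(model, obs) UseMethod("slice_readout")

#' @export
slice_readout.slice_classifier <- function(model, obs) {
  m <- .as_net_input(model, obs)
  fw <- cnn_forward(model$net, list(m))
  probs <- softmax_rows(fw$logits)[1, ]
  names(probs) <- model$classes
  gp <- probs[as.character(1:5)]
  gp <- gp / sum(gp)
  structure(list(
    features = fw$features[1, ],
    probs = probs,
    predicted = model$classes[which.max(probs)],
    grade_probs = gp,
    predicted_grade = (1:5)[which.max(gp)]
  ), class = "slice_readout")
}

#' @export
slice_readout.function <- function(model, obs) model(obs)

#' @export
print.slice_readout <- function(x, ...) {
  cat(sprintf("slice_readout: predicted class %s (grade %d), probs %s\n",
              x$predicted, x$predicted_grade,
              paste(sprintf("%.3f", x$probs), collapse = " ")))
  invisible(x)
}

#' Predict slice readouts for a set of observations
#'
#' @param object a fitted `slice_classifier`.
#' @param newdata a `slice_observation`, a list of them, or a `volume_stack`
#'   (all slices are preprocessed and scored).
#' @param ... unused.
#' @return a data.frame with one row per slice: predicted class, predicted
#'   grade and per-class probabilities.
#' @export
predict.slice_classifier <- function(object, newdata, ...) {
  obs_list <- if (inherits(newdata, "slice_observation")) list(newdata)
  else if (inherits(newdata, "volume_stack")) {
    lapply(seq_along(newdata$slices), function(i)
      preprocess_slice(newdata$slices[[i]], crop_size = object$config$crop_size,
                       out_size = object$config$input_size,
                       source_index = i - 1L, patient_id = newdata$patient_id))
  } else newdata
  rows <- lapply(obs_list, function(o) {
    r <- slice_readout(object, o)
    cbind(data.frame(patient_id = if (inherits(o, "slice_observation"))
      o$patient_id else NA_character_,
      source_index = if (inherits(o, "slice_observation"))
        o$source_index else NA_integer_,
      predicted = r$predicted, predicted_grade = r$predicted_grade),
      as.data.frame(t(r$probs)))
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("^X", "p", names(out))
  out
}
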