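# Navigation agent ("action net"): a deep Q-network over slice features with
# 7 discrete slice-displacement actions, trained with experience replay, an
# epsilon-greedy policy and a periodically synchronized target network.

#' The discrete action set of the navigation agent
#'
#' Seven slice displacements, symmetric about 0: -3, -2, -1, 0 (stay-in-place),
#' +1, +2, +3. Action codes index this table; the stay action doubles as the
#' early-stop signal for the end-to-end loop.
#'
#' @return data.frame with columns `code` (1..7) and `displacement`.
#' @export
action_set <- function() {
  data.frame(code = 1:7, displacement = -3:3)
}

#' Configuration of the navigation agent
#'
#' The value network maps the classifier feature vector through two hidden
#' layers of 50 and 30 neurons to the 7 action values. Rewards use a basic
#' reward of 1 plus 0.5 times the predicted probability of the visited slice
#' (positive when the slice is a tumor slice and the predicted grade matches
#' the true patient grade, negative otherwise). Replay updates start only
#' once the experience pool has overflowed and the target network is
#' re-synchronized every 100 accumulated updates.
#'
#' @param input_dim feature dimension (must match the classifier).
#' @param hidden_sizes hidden layer widths.
#' @param pool_capacity replay pool size; no update happens before it fills.
#' @param sync_interval gradient-step count between target-net syncs.
#' @param basic_reward the basic reward y.
#' @param reward_rate the probability weight alpha.
#' @param gamma discount factor in \[0, 1\].
#' @param eps_start,eps_end,eps_anneal_frac linear epsilon-greedy schedule
#'   over the first `eps_anneal_frac` fraction of episodes.
#' @param replay_batch minibatch size sampled from the pool.
#' @param lr,momentum SGD settings for the current net.
#' @param n_episodes training episodes.
#' @param max_steps actions per episode (mirrors the four-circle inference cap).
#' @param update_every environment steps between gradient updates (after the
#'   pool is full).
#' @param stay_terminal whether the stay-in-place action ends a training
#'   episode. With the default FALSE, staying is an ordinary action and
#'   episodes run to `max_steps`, so settling on a rewarding slice
#'   accumulates value; with TRUE, staying forfeits the remaining horizon,
#'   which rewards drifting along the lesion instead of stopping on it.
#' @param seed RNG seed.
#' @return list of class `dqn_config`.
#' @export
dqn_config <- function(input_dim = 4320L, hidden_sizes = c(50L, 30L),
                       pool_capacity = 2000L, sync_interval = 100L,
                       basic_reward = 1, reward_rate = 0.5, gamma = 0.9,
                       eps_start = 1, eps_end = 0.05, eps_anneal_frac = 0.8,
                       replay_batch = 32L, lr = 1e-3, momentum = 0.9,
                       n_episodes = 1000L, max_steps = 4L, update_every = 1L,
                       stay_terminal = FALSE, seed = 1L) {
  stop_if_not(sync_interval >= 1, "sync_interval must be >= 1")
  stop_if_not(reward_rate >= 0, "reward_rate must be >= 0")
  stop_if_not(gamma >= 0 && gamma <= 1, "gamma must lie in [0, 1]")
  stop_if_not(eps_start >= 0 && eps_start <= 1 && eps_end >= 0 && eps_end <= 1,
              "epsilon bounds must lie in [0, 1]")
  structure(list(
    input_dim = as.integer(input_dim), hidden_sizes = as.integer(hidden_sizes),
    n_actions = 7L, pool_capacity = as.integer(pool_capacity),
    sync_interval = as.integer(sync_interval), basic_reward = basic_reward,
    reward_rate = reward_rate, gamma = gamma, eps_start = eps_start,
    eps_end = eps_end, eps_anneal_frac = eps_anneal_frac,
    replay_batch = as.integer(replay_batch), lr = lr, momentum = momentum,
    n_episodes = as.integer(n_episodes), max_steps = as.integer(max_steps),
    update_every = as.integer(update_every),
    stay_terminal = isTRUE(stay_terminal), seed = as.integer(seed)
  ), class = "dqn_config")
}

#' Navigation reward
#'
#' `r = c * (y + alpha * P)` where `P` is the predicted probability at the
#' prediction on the visited slice and the consistency gate `c` is +1 when
#' the visited slice is a tumor slice AND the predicted grade equals the true
#' patient-level grade, and -1 otherwise. With the defaults y = 1 and
#' alpha = 0.5, a correct call on a tumor slice with P = 0.8 earns +1.4 and
#' the same confidence on a non-tumor slice earns -1.4. The composition is
#' isolated here so alternative reward shapes are one-line swaps.
#'
#' @param slice_is_tumor logical flag of the visited slice.
#' @param predicted_grade classifier argmax grade on the visited slice.
#' @param true_grade patient-level reference grade.
#' @param prob probability at the prediction, in \[0, 1\].
#' @param basic_reward the basic reward y (default 1).
#' @param reward_rate the probability weight alpha (default 0.5).
#' @return scalar reward.
#' @export
compute_reward <- function(slice_is_tumor, predicted_grade, true_grade, prob,
                           basic_reward = 1, reward_rate = 0.5) {
  stop_if_not(is.finite(prob) && prob >= 0 && prob <= 1,
              "prob must lie in [0, 1], got %s", format(prob))
  consistent <- isTRUE(slice_is_tumor) && predicted_grade == true_grade
  c_gate <- if (consistent) 1 else -1
  c_gate * (basic_reward + reward_rate * prob)
}

#' Action values for a state
#'
#' Deterministic forward pass of the value network
#' (`input_dim -> 50 -> 30 -> 7` by default).
#'
#' @param net a value network (as stored in a `dqn_agent`'s `current` or
#'   `target` field).
#' @param state numeric feature vector of length `input_dim`.
#' @return numeric 7-vector of action values.
#' @export
q_values <- function(net, state) {
  stop_if_not(length(state) == net$sizes[1],
              "state length %d does not match input_dim %d",
              length(state), net$sizes[1])
  as.numeric(mlp_forward(net, matrix(state, 1))$out)
}

#' Epsilon-greedy action selection
#'
#' With probability `1 - epsilon` the argmax action; ties are broken toward
#' the smallest absolute displacement, then the negative displacement before
#' the positive one (so an all-tied Q picks stay-in-place). With probability
#' `epsilon` a uniformly random action. `epsilon = 0` at inference.
#'
#' @param Q numeric 7-vector of action values.
#' @param epsilon exploration probability in \[0, 1\].
#' @return one row of [action_set()] (`code`, `displacement`).
#' @export
select_action <- function(Q, epsilon = 0) {
  acts <- action_set()
  stop_if_not(length(Q) == nrow(acts), "Q must have length %d", nrow(acts))
  stop_if_not(epsilon >= 0 && epsilon <= 1, "epsilon must lie in [0, 1]")
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    return(acts[sample.int(nrow(acts), 1), ])
  }
  pref <- order(abs(acts$displacement), acts$displacement)  # 0,-1,1,-2,2,-3,3
  best <- pref[which.max(Q[pref])]
  acts[best, ]
}

# matrix-form view of a list of transitions
.batch_arrays <- function(batch) {
  list(states = do.call(rbind, lapply(batch, `[[`, "state")),
       actions = vapply(batch, `[[`, 0L, "action"),
       rewards = vapply(batch, `[[`, 0, "reward"),
       next_states = do.call(rbind, lapply(batch, `[[`, "next_state")),
       terminal = vapply(batch, `[[`, FALSE, "terminal"))
}

#' Temporal-difference loss of a transition batch
#'
#' Mean squared TD error
#' `(r + gamma * max_a' Q_target(s', a') * [not terminal] - Q_current(s, a))^2`;
#' the target-network term is a constant with respect to the current net's
#' parameters (no gradient flows into the target net).
#'
#' @param batch list of transitions, each a list with `state`, `action`
#'   (code 1..7), `reward`, `next_state`, `terminal`.
#' @param current_net,target_net value networks.
#' @param gamma discount factor.
#' @return scalar loss.
#' @export
q_loss <- function(batch, current_net, target_net, gamma) {
  stop_if_not(length(batch) >= 1, "batch must be nonempty")
  b <- .batch_arrays(batch)
  q_cur <- mlp_forward(current_net, b$states)$out
  q_next <- mlp_forward(target_net, b$next_states)$out
  target <- b$rewards + gamma * apply(q_next, 1, max) * (1 - b$terminal)
  taken <- q_cur[cbind(seq_along(batch), b$actions)]
  mean((target - taken)^2)
}

# one gradient step of the current net on a replay minibatch
.q_update <- function(current, target, b, gamma, lr, momentum, state) {
  fw <- mlp_forward(current, b$states, keep_cache = TRUE)
  q_next <- mlp_forward(target, b$next_states)$out
  tgt <- b$rewards + gamma * apply(q_next, 1, max) * (1 - b$terminal)
  B <- nrow(b$states)
  dQ <- matrix(0, B, ncol(fw$out))
  taken <- cbind(seq_len(B), b$actions)
  dQ[taken] <- 2 * (fw$out[taken] - tgt) / B
  grads <- mlp_backward(current, fw$caches, dQ)
  sgd_momentum_step(current, grads, state, lr, momentum)
}

# FIFO replay pool; state vectors are kept in lists so pushes never copy the
# whole buffer
.pool_new <- function(capacity, dim) {
  e <- new.env(parent = emptyenv())
  e$states <- vector("list", capacity)
  e$next_states <- vector("list", capacity)
  e$actions <- integer(capacity)
  e$rewards <- numeric(capacity)
  e$terminal <- logical(capacity)
  e$capacity <- capacity
  e$n <- 0L        # filled count
  e$head <- 0L     # next write position (0-based, FIFO overwrite)
  e
}

.pool_push <- function(pool, s, a, r, s2, term) {
  i <- pool$head + 1L
  pool$states[[i]] <- s
  pool$next_states[[i]] <- s2
  pool$actions[i] <- a
  pool$rewards[i] <- r
  pool$terminal[i] <- term
  pool$head <- (pool$head + 1L) %% pool$capacity
  pool$n <- min(pool$n + 1L, pool$capacity)
  invisible(pool)
}

.pool_sample <- function(pool, batch) {
  idx <- sample.int(pool$n, batch, replace = pool$n < batch)
  list(states = do.call(rbind, pool$states[idx]),
       actions = pool$actions[idx],
       rewards = pool$rewards[idx],
       next_states = do.call(rbind, pool$next_states[idx]),
       terminal = pool$terminal[idx])
}

# Cache classifier readouts for every slice of every volume: the classifier
# is frozen during agent training, so features, predicted grades and
# confidences are computed once.
.env_cache <- function(volumes, classifier) {
  lapply(volumes, function(v) {
    n <- length(v$slices)
    feats <- NULL
    pred <- integer(n); pmax_ <- numeric(n)
    for (i in seq_len(n)) {
      obs <- preprocess_slice(v$slices[[i]],
                              crop_size = classifier$config$crop_size,
                              out_size = classifier$config$input_size,
                              source_index = i - 1L,
                              patient_id = v$patient_id)
      r <- slice_readout(classifier, obs)
      if (is.null(feats)) feats <- matrix(0, n, length(r$features))
      feats[i, ] <- r$features
      pred[i] <- r$predicted_grade
      pmax_[i] <- max(r$probs)
    }
    list(features = feats, predicted = pred, pmax = pmax_,
         tumor = v$tumor_flags, grade = v$gg_rp, n = n)
  })
}

#' Train the navigation agent by deep Q-learning
#'
#' The environment is the cohort of training volumes with the frozen
#' classifier: the state of slice i is its feature vector, an action moves
#' the cursor by the chosen displacement (clipped to the stack), and the
#' reward on the slice arrived at is [compute_reward()]. Episodes start at a
#' uniformly random slice (environment augmentation). Experiences fill a FIFO
#' pool; gradient updates on the current net begin only once the pool has
#' overflowed, and the current net's parameters are copied to the target net
#' every `sync_interval` accumulated updates. Inference uses the target net
#' with epsilon = 0.
#'
#' @param cohort a `phantom_cohort` (or list with `volumes` + `manifest`).
#' @param classifier a fitted [train_slice_classifier()] model (frozen).
#' @param config a [dqn_config()]; `input_dim` must match the classifier's
#'   feature dimension.
#' @param train_split manifest split used as the environment.
#' @return object of class `dqn_agent` with `current` and `target` nets, the
#'   feature scale, an episode `log`, recorded `sync_events` and `clip_count`.
#' @export
train_navigation_agent <- function(cohort, classifier,
                                   config = dqn_config(),
                                   train_split = "train") {
  stop_if_not(inherits(config, "dqn_config"), "config must be a dqn_config")
  stop_if_not(config$input_dim == classifier$config$feature_dim,
              "config input_dim %d does not match classifier feature_dim %d",
              config$input_dim, classifier$config$feature_dim)
  vols <- cohort$volumes[cohort$manifest$split %in% train_split]
  stop_if_not(length(vols) >= 1, "no training volumes in split")
  env <- .env_cache(vols, classifier)

  # scale features to unit root-mean-square so the value net sees inputs of
  # comparable magnitude regardless of the backbone's activation scale
  rms <- sqrt(mean(unlist(lapply(env, function(e) e$features^2))))
  feature_scale <- if (rms > 1e-12) 1 / rms else 1
  for (i in seq_along(env)) env[[i]]$features <- env[[i]]$features * feature_scale

  sizes <- c(config$input_dim, config$hidden_sizes, config$n_actions)
  current <- mlp_init(sizes, seed = derive_seed(config$seed, 0))
  target <- current
  opt_state <- vector("list", length(current$layers))
  pool <- .pool_new(config$pool_capacity, config$input_dim)
  acts <- action_set()

  n_updates <- 0L
  updates_since_sync <- 0L
  sync_events <- integer(0)
  clip_count <- 0L
  first_update_fill <- NA_integer_
  log <- vector("list", config$n_episodes)

  with_seed(derive_seed(config$seed, 1), {
    for (ep in seq_len(config$n_episodes)) {
      frac <- min(1, (ep - 1) / max(1, config$eps_anneal_frac *
                                      (config$n_episodes - 1)))
      epsilon <- config$eps_start + frac * (config$eps_end - config$eps_start)
      e <- env[[sample.int(length(env), 1)]]
      i <- sample.int(e$n, 1)                       # random starting slice
      ep_return <- 0
      steps <- 0L
      for (step in seq_len(config$max_steps)) {
        s <- e$features[i, ]
        Q <- as.numeric(mlp_forward(current, matrix(s, 1))$out)
        act <- select_action(Q, epsilon)
        j_raw <- i + act$displacement
        j <- min(max(j_raw, 1L), e$n)
        if (j != j_raw) clip_count <- clip_count + 1L
        r <- compute_reward(e$tumor[j], e$predicted[j], e$grade,
                            e$pmax[j], config$basic_reward, config$reward_rate)
        terminal <- (config$stay_terminal && act$displacement == 0L) ||
          step == config$max_steps
        .pool_push(pool, s, act$code, r, e$features[j, ], terminal)
        ep_return <- ep_return + r
        steps <- step
        i <- j

        if (pool$n >= pool$capacity && steps %% config$update_every == 0L) {
          if (is.na(first_update_fill)) first_update_fill <- pool$n
          b <- .pool_sample(pool, config$replay_batch)
          upd <- .q_update(current, target, b, config$gamma,
                           config$lr, config$momentum, opt_state)
          current <- upd$net; opt_state <- upd$state
          n_updates <- n_updates + 1L
          updates_since_sync <- updates_since_sync + 1L
          if (updates_since_sync >= config$sync_interval) {
            target <- current
            updates_since_sync <- 0L
            sync_events <- c(sync_events, n_updates)
          }
        }
        if (terminal) break
      }
      log[[ep]] <- data.frame(episode = ep, epsilon = epsilon,
                              steps = steps, return_ = ep_return,
                              pool_fill = pool$n, n_updates = n_updates)
    }
  })
  structure(list(
    current = current, target = target, config = config,
    feature_scale = feature_scale,
    log = do.call(rbind, log), sync_events = sync_events,
    clip_count = clip_count, first_update_fill = first_update_fill,
    n_updates = n_updates, hash = config_hash(config)
  ), class = "dqn_agent")
}

#' @export
print.dqn_agent <- function(x, ...) {
  cat(sprintf("dqn_agent (%s): %d episodes, %d updates, %d target syncs (config %s)\n",
              paste(x$config$input_dim, paste(x$config$hidden_sizes, collapse = "-"),
                    x$config$n_actions, sep = "-"),
              nrow(x$log), x$n_updates, length(x$sync_events), x$hash))
  cat(sprintf("  boundary clips during training: %d\n", x$clip_count))
  invisible(x)
}

#' @export
plot.dqn_agent <- function(x, window = 50, ...) {
  r <- x$log$return_
  sm <- stats::filter(r, rep(1 / window, window), sides = 1)
  graphics::plot(x$log$episode, r, col = "grey70", pch = 16, cex = 0.4,
                 xlab = "episode", ylab = "episode return",
                 main = "navigation agent training", ...)
  graphics::lines(x$log$episode, sm, lwd = 2)
  invisible(x)
}

#' Choose a navigation action from slice features
#'
#' Generic over agent types so mock agents (plain functions returning a
#' displacement) can drive the end-to-end loop in experiments. The
#' `dqn_agent` method applies the stored feature scale and queries the target
#' net, epsilon-greedily (epsilon = 0 at inference).
#'
#' @param agent a `dqn_agent` or a function of the feature vector returning a
#'   displacement.
#' @param features numeric feature vector.
#' @param epsilon exploration probability.
#' @return list with `code` and `displacement`.
#' @export
choose_action <- function(agent, features, epsilon = 0) UseMethod("choose_action")

#' @export
choose_action.dqn_agent <- function(agent, features, epsilon = 0) {
  Q <- q_values(agent$target, features * agent$feature_scale)
  act <- select_action(Q, epsilon)
  list(code = act$code, displacement = act$displacement)
}

#' @export
choose_action.function <- function(agent, features, epsilon = 0) {
  d <- agent(features)
  list(code = NA_integer_, displacement = as.integer(d))
}
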