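# DQN navigation agent: action set, reward, value network, action selection,
# TD loss, replay mechanics.

test_that("the action set has 7 symmetric displacements with one stay action", {
  acts <- action_set()
  expect_equal(nrow(acts), 7)
  expect_equal(sum(acts$displacement == 0), 1)
  expect_setequal(acts$displacement, -3:3)
  expect_equal(sort(acts$displacement), sort(-acts$displacement))
})

test_that("reward follows the sign-gated composition r = c*(y + alpha*P)", {
  expect_equal(compute_reward(TRUE, 3, 3, 0.8), 1.4)
  expect_equal(compute_reward(FALSE, 3, 3, 0.8), -1.4)
  # correct grade but non-tumor slice is still penalized
  expect_equal(compute_reward(TRUE, 2, 3, 0.8), -1.4)
  # degenerate rate: |r| = 1 regardless of P
  for (p in c(0, 0.3, 1)) {
    expect_equal(abs(compute_reward(TRUE, 1, 1, p, reward_rate = 0)), 1)
  }
  expect_error(compute_reward(TRUE, 1, 1, 1.2), "\\[0, 1\\]")
  expect_error(compute_reward(TRUE, 1, 1, -0.1), "\\[0, 1\\]")
})

test_that("q_values is a deterministic forward pass matching hand-computed products", {
  # 2-2-2-7 toy net with hand-set weights
  net <- gradenav:::mlp_init(c(2, 2, 2, 7), seed = 1)
  net$layers[[1]]$W <- matrix(c(1, 0, -1, 2), 2, 2)
  net$layers[[1]]$b <- c(0.5, -0.5)
  net$layers[[2]]$W <- matrix(c(0.3, 1, 0.7, -2), 2, 2)
  net$layers[[2]]$b <- c(0, 0.1)
  net$layers[[3]]$W <- matrix(seq(-0.6, 0.7, by = 0.1), 7, 2)
  net$layers[[3]]$b <- seq(0.1, 0.7, by = 0.1)
  s <- c(0.4, -1.2)
  h1 <- pmax(net$layers[[1]]$W %*% s + net$layers[[1]]$b, 0)
  h2 <- pmax(net$layers[[2]]$W %*% h1 + net$layers[[2]]$b, 0)
  want <- as.numeric(net$layers[[3]]$W %*% h2 + net$layers[[3]]$b)
  expect_equal(q_values(net, s), want, tolerance = 1e-9)
  expect_identical(q_values(net, s), q_values(net, s))
  # zero-weight net returns the bias
  zero <- net
  for (l in 1:3) zero$layers[[l]]$W[] <- 0
  expect_equal(q_values(zero, s),
               as.numeric(zero$layers[[3]]$b), tolerance = 1e-12)
  expect_error(q_values(net, c(1, 2, 3)), "input_dim")
})

test_that("greedy selection picks the argmax and breaks ties toward stay", {
  Q <- c(0, 0, 0, 0, 0, 0, 5)
  for (i in 1:5) expect_equal(select_action(Q, 0)$displacement, 3)
  # all-equal Q: smallest |displacement| wins -> stay-in-place
  expect_equal(select_action(rep(1, 7), 0)$displacement, 0)
  # two-way tie between -2 and +2: negative preferred
  Q <- c(-1, 5, 0, 0, 0, 5, -1)
  expect_equal(select_action(Q, 0)$displacement, -2)
  expect_error(select_action(rep(0, 5), 0), "length 7")
})

test_that("epsilon = 1 explores uniformly within multinomial 99% bands", {
  n <- 10000
  draws <- gradenav:::with_seed(44, {
    replicate(n, select_action(c(9, rep(0, 6)), 1)$code)
  })
  counts <- tabulate(draws, 7)
  band <- qbinom(c(0.005, 0.995), n, 1 / 7)
  # Bonferroni-style: every action's count inside its 99% band
  expect_true(all(counts >= band[1] & counts <= band[2]))
})

test_that("q_loss matches manual TD arithmetic on a hand-set 3-transition batch", {
  net_c <- gradenav:::mlp_init(c(2, 2, 2, 7), seed = 3)
  net_t <- gradenav:::mlp_init(c(2, 2, 2, 7), seed = 4)
  batch <- list(
    list(state = c(1, 0), action = 2L, reward = 1.4,
         next_state = c(0, 1), terminal = FALSE),
    list(state = c(0.5, -0.5), action = 7L, reward = -1.0,
         next_state = c(1, 1), terminal = TRUE),
    list(state = c(-1, 2), action = 4L, reward = 0.2,
         next_state = c(2, -1), terminal = FALSE))
  gamma <- 0.9
  manual <- mean(sapply(batch, function(tr) {
    qc <- q_values(net_c, tr$state)[tr$action]
    tgt <- tr$reward +
      gamma * max(q_values(net_t, tr$next_state)) * (1 - tr$terminal)
    (tgt - qc)^2
  }))
  expect_equal(q_loss(batch, net_c, net_t, gamma), manual, tolerance = 1e-9)
})

test_that("q_loss has its degenerate fixed points", {
  net_c <- gradenav:::mlp_init(c(2, 2, 2, 7), seed = 3)
  # terminal transition whose current Q equals r -> zero loss
  s <- c(0.3, 0.7)
  a <- 5L
  r <- q_values(net_c, s)[a]
  batch <- list(list(state = s, action = a, reward = r,
                     next_state = s, terminal = TRUE))
  expect_equal(q_loss(batch, net_c, net_c, 0.9), 0, tolerance = 1e-12)
  # gamma = 0 reduces to mean (r - Q(s,a))^2
  batch <- list(
    list(state = c(1, 1), action = 1L, reward = 0.5,
         next_state = c(0, 0), terminal = FALSE),
    list(state = c(-1, 0.5), action = 3L, reward = -0.7,
         next_state = c(1, 0), terminal = FALSE))
  manual <- mean(sapply(batch, function(tr)
    (tr$reward - q_values(net_c, tr$state)[tr$action])^2))
  expect_equal(q_loss(batch, net_c, net_c, 0), manual, tolerance = 1e-9)
})

test_that("the replay pool is FIFO at capacity", {
  pool <- gradenav:::.pool_new(3, 2)
  for (k in 1:5) {
    gradenav:::.pool_push(pool, c(k, k), 1L, k, c(k, k), FALSE)
  }
  expect_equal(pool$n, 3)
  # entries 4, 5 overwrote 1, 2; 3 survives
  expect_setequal(pool$rewards, c(4, 5, 3))
})

test_that("agent training syncs the target net and never updates before overflow", {
  spec <- small_spec(8, seed = 5)
  cohort <- generate_cohort(spec, split_fractions = c(train = 1, val = 0, test = 0))
  cls <- random_classifier(input_size = 48, feature_dim = 64, seed = 2)
  cfg <- dqn_config(input_dim = 64L, pool_capacity = 60L, sync_interval = 10L,
                    n_episodes = 60L, seed = 3)
  agent <- train_navigation_agent(cohort, cls, cfg)
  # replay never updates before the pool overflows
  log <- agent$log
  expect_true(all(log$n_updates[log$pool_fill < cfg$pool_capacity] == 0))
  expect_equal(agent$first_update_fill, cfg$pool_capacity)
  expect_gt(agent$n_updates, 0)
  # post-sync invariant: target and current nets identical on a probe state
  expect_gt(length(agent$sync_events), 0)
  expect_equal(diff(agent$sync_events)[1], cfg$sync_interval)
  probe <- rnorm(64)
  last_gap <- agent$n_updates - max(agent$sync_events)
  if (last_gap == 0) {
    expect_identical(q_values(agent$current, probe),
                     q_values(agent$target, probe))
  } else {
    expect_false(identical(q_values(agent$current, probe),
                           q_values(agent$target, probe)))
  }
})

test_that("reward rate changes do not alter trajectories before the first update", {
  spec <- small_spec(6, seed = 11)
  cohort <- generate_cohort(spec, split_fractions = c(train = 1, val = 0, test = 0))
  cls <- random_classifier(input_size = 48, feature_dim = 64, seed = 2)
  base <- dqn_config(input_dim = 64L, pool_capacity = 2000L,  # never fills
                     n_episodes = 40L, seed = 9)
  a_half <- train_navigation_agent(cohort, cls, base)
  base$reward_rate <- 0
  a_zero <- train_navigation_agent(cohort, cls, base)
  # same seeds, no updates -> identical visited-path lengths throughout
  expect_equal(a_half$log$steps, a_zero$log$steps)
  # rewards differ only through the alpha term
  expect_false(isTRUE(all.equal(a_half$log$return_, a_zero$log$return_)))
  expect_equal(sign(a_half$log$return_[a_half$log$steps == 1]),
               sign(a_zero$log$return_[a_zero$log$steps == 1]))
})

test_that("feature-dimension mismatch is rejected before training", {
  spec <- small_spec(4, seed = 2)
  cohort <- generate_cohort(spec, split_fractions = c(train = 1, val = 0, test = 0))
  cls <- random_classifier(input_size = 48, feature_dim = 64)
  expect_error(
    train_navigation_agent(cohort, cls, dqn_config(input_dim = 128L)),
    "does not match")
})
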