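test_that("reward is the guess-target similarity computed on clean coordinates", {
  ch <- chip_chart(rbind(c(0, 0, 0), c(100, 0, 0), c(0, 30, 40)),
                   name = "rw")
  expect_equal(reward(0, 0, ch), 1)
  expect_equal(reward(0, 1, ch), exp(-10))        # dist 100, c = 0.001
  expect_equal(reward(1, 0, ch), reward(0, 1, ch))  # symmetric
  expect_equal(reward(0, 2, ch), exp(-0.001 * 50^2))
  expect_error(reward(0, 3, ch), "chip ids")
})

test_that("continuous batch loss matches an independent forward-pass computation", {
  ch <- chip_chart(rbind(c(10, 0, 0), c(60, 40, -20), c(90, -30, 30)),
                   name = "hand")
  set.seed(12)
  p <- init_agent_parameters(3, k = 2, d = 4)
  cfg <- game_config("continuous", sigma_e_sq = 0, sigma_c_sq = 0,
                     batch_size = 1L, n_episodes = 1L)
  set.seed(77)
  got <- play_batch_continuous(p, ch, cfg)
  # replay the same RNG stream and recompute everything with plain loops
  set.seed(77)
  tgt <- sample.int(3, 1)
  x <- chip_coords(ch)[tgt, ]
  hs <- pmax(as.vector(p$Ws %*% x) + p$bs, 0)
  zs <- as.vector(p$Vs %*% hs) + p$cs
  w <- exp(zs) / sum(exp(zs))
  hr <- pmax(as.vector(p$Wr %*% w) + p$br, 0)
  zr <- as.vector(p$Vr %*% hr) + p$cr
  pu <- exp(zr) / sum(exp(zr))
  gumbel <- -log(-log(runif(3)))
  guess <- which.max(log(pu) + gumbel)
  r <- similarity(chip_coords(ch)[guess, ], x)
  expect_equal(got$targets, tgt - 1L)
  expect_equal(got$guesses, guess - 1L)
  expect_equal(got$rewards, r)
  expect_equal(got$loss, -log(pu[guess]) * r)
})

test_that("discrete batch losses match the hand computation and use the baseline", {
  ch <- chip_chart(rbind(c(10, 0, 0), c(60, 40, -20), c(90, -30, 30)),
                   name = "hand")
  set.seed(13)
  p <- init_agent_parameters(3, k = 2, d = 4)
  cfg <- game_config("discrete", sigma_e_sq = 0, sigma_c_sq = 0,
                     batch_size = 1L, n_episodes = 1L)
  B <- 0.3
  set.seed(88)
  got <- play_batch_discrete(p, ch, cfg, baseline = B)
  set.seed(88)
  tgt <- sample.int(3, 1)
  x <- chip_coords(ch)[tgt, ]
  hs <- pmax(as.vector(p$Ws %*% x) + p$bs, 0)
  zs <- as.vector(p$Vs %*% hs) + p$cs
  pw <- exp(zs) / sum(exp(zs))
  msg <- which.max(log(pw) - log(-log(runif(4))))
  m <- numeric(4); m[msg] <- 1
  hr <- pmax(as.vector(p$Wr %*% m) + p$br, 0)
  zr <- as.vector(p$Vr %*% hr) + p$cr
  pu <- exp(zr) / sum(exp(zr))
  guess <- which.max(log(pu) - log(-log(runif(3))))
  r <- similarity(chip_coords(ch)[guess, ], x)
  expect_equal(got$messages, msg)
  expect_equal(got$loss_sender, -log(pw[msg]) * (r - B))
  expect_equal(got$loss_receiver, -log(pu[guess]) * (r - B))
})

test_that("zero advantage makes both discrete losses vanish", {
  # all chips identical: every reward is exactly 1
  ch <- chip_chart(matrix(5, 4, 3), name = "same")
  set.seed(14)
  p <- init_agent_parameters(4, k = 3, d = 5)
  cfg <- game_config("discrete", sigma_e_sq = 0, sigma_c_sq = 0,
                     batch_size = 16L, n_episodes = 1L)
  got <- play_batch_discrete(p, ch, cfg, baseline = 1)
  expect_equal(got$rewards, rep(1, 16))
  expect_equal(got$loss_sender, 0)
  expect_equal(got$loss_receiver, 0)
  expect_true(all(vapply(got$grads, function(g) max(abs(g)), numeric(1)) == 0))
})

test_that("REINFORCE gradients agree with finite differences", {
  set.seed(15)
  ch <- ring_chart(6)
  modes <- list(
    list(cfg = game_config("continuous", sigma_e_sq = 1, sigma_c_sq = 0.1,
                           batch_size = 5L, n_episodes = 1L),
         fn = function(p, cfg) {
           set.seed(99); play_batch_continuous(p, ch, cfg)
         },
         loss = function(b) b$loss),
    list(cfg = game_config("discrete", sigma_e_sq = 1, sigma_c_sq = 0,
                           batch_size = 5L, n_episodes = 1L),
         fn = function(p, cfg) {
           set.seed(99); play_batch_discrete(p, ch, cfg, baseline = 0.2)
         },
         loss = function(b) b$loss_sender + b$loss_receiver))
  for (m in modes) {
    p <- init_agent_parameters(6, k = 3, d = 4)
    base <- m$fn(p, m$cfg)
    eps <- 1e-6
    for (field in c("Ws", "Vs", "Wr", "Vr", "bs", "cr")) {
      p2 <- p
      if (is.matrix(p2[[field]])) p2[[field]][1, 1] <- p2[[field]][1, 1] + eps
      else p2[[field]][1] <- p2[[field]][1] + eps
      fd <- (m$loss(m$fn(p2, m$cfg)) - m$loss(base)) / eps
      an <- if (is.matrix(base$grads[[field]])) base$grads[[field]][1, 1]
            else base$grads[[field]][1]
      expect_equal(fd, an, tolerance = 1e-4)
    }
  }
})

test_that("continuous and discrete variants share the forward code paths", {
  set.seed(16)
  p <- init_agent_parameters(5, k = 3, d = 4)
  X <- matrix(rnorm(6, 50, 30), 3, 2)
  snd <- colorgame:::sender_forward_batch(p, X)
  for (j in 1:2)
    expect_equal(snd$W[, j], sender_forward(p, X[, j])$values)
  M <- matrix(rnorm(8), 4, 2)
  rcv <- colorgame:::receiver_forward_batch(p, M)
  for (j in 1:2)
    expect_equal(rcv$P[, j], receiver_forward(p, M[, j]))
})

test_that("the training baseline is the running mean of all rewards", {
  ch <- ring_chart(4)
  cfg <- small_cfg(n_episodes = 5L, batch_size = 10L, seed = 3L)
  fit <- train_agents(ch, cfg)
  expect_equal(fit$trace$baseline,
               cumsum(fit$trace$mean_reward) / seq_len(5))
})

test_that("training is deterministic under its seed", {
  ch <- ring_chart(5)
  for (mode in c("continuous", "discrete")) {
    cfg <- small_cfg(mode, n_episodes = 12L, batch_size = 8L, seed = 42L,
                     sigma_e_sq = 2, sigma_c_sq = 0.1)
    f1 <- train_agents(ch, cfg)
    f2 <- train_agents(ch, cfg)
    expect_equal(f1$trace, f2$trace)
    expect_equal(f1$params, f2$params)
    expect_equal(f1$final_partition$labels, f2$final_partition$labels)
  }
})

test_that("continuous training improves the mean reward on a tiny noiseless chart", {
  ch <- ring_chart(4)
  gains <- vapply(1:3, function(s) {
    cfg <- game_config("continuous", sigma_e_sq = 0, sigma_c_sq = 0,
                       batch_size = 30L, n_episodes = 400L, seed = s)
    fit <- train_agents(ch, cfg)
    mean(tail(fit$trace$mean_reward, 50)) -
      mean(head(fit$trace$mean_reward, 10))
  }, numeric(1))
  expect_gt(mean(gains), 0)
  expect_gt(sum(gains > 0), 1L)
})

test_that("probes and snapshots track the developing language", {
  ch <- ring_chart(6)
  cfg <- small_cfg(n_episodes = 40L, batch_size = 10L, seed = 5L,
                   probe_every = 10L)
  fit <- train_agents(ch, cfg)
  expect_equal(fit$probes$episode, c(1L, 10L, 20L, 30L, 40L))
  expect_true(all(fit$probes$term_count >= 1))
  expect_true(all(is.finite(fit$probes$kl_loss)))
  # first probe always snapshots; later ones only on term-count changes
  expect_gte(length(fit$snapshots), 1L)
  expect_s3_class(fit$snapshots[[1]], "color_partition")
  # probe KL agrees with the public metric on the final partition
  expect_equal(tail(fit$probes$kl_loss, 1),
               kl_loss_from_partition(fit$final_partition, ch))
})
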