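#' Configuration of a color-game training run
#'
#' Bundles the noise levels, batch/episode counts, architecture and seed of
#' one training run. Defaults follow the study conditions: continuous
#' messages train with batches of 100 games for 20000 episodes; discrete
#' messages, which learn more slowly because no gradient crosses the
#' channel, use batches of 256 for 25000 episodes. Communication noise
#' defaults to variance 0.1. An "episode" is one batch update.
#'
#' @param message_mode `"continuous"` (differentiable channel, single
#'   REINFORCE cost) or `"discrete"` (sampled one-hot messages, separate
#'   sender/receiver costs with a running-mean reward baseline).
#' @param sigma_e_sq environmental-noise variance on chip coordinates.
#' @param sigma_c_sq communication-noise variance on the message.
#' @param batch_size games per episode (`NULL` = mode default).
#' @param n_episodes training episodes (`NULL` = mode default).
#' @param learning_rate ADAM step size.
#' @param k,d,init_scale architecture knobs, see
#'   [init_agent_parameters()].
#' @param probe_every interval (in episodes) at which the noise-free mode
#'   map is probed for term count and KL loss (`NULL` = ~100 probes per
#'   run).
#' @param adam_beta1,adam_beta2,adam_eps ADAM moment decay rates and
#'   stabilizer.
#' @param seed integer seed; every random draw in the run derives from it.
#' @return An object of class `game_config` (a list).
#' @export
game_config <- function(message_mode = c("continuous", "discrete"),
                        sigma_e_sq = 1, sigma_c_sq = 0.1,
                        batch_size = NULL, n_episodes = NULL,
                        learning_rate = 0.001,
                        k = 20L, d = 50L, init_scale = 0.1,
                        probe_every = NULL,
                        adam_beta1 = 0.9, adam_beta2 = 0.999,
                        adam_eps = 1e-8,
                        seed = NULL) {
  message_mode <- match.arg(message_mode)
  if (is.null(batch_size))
    batch_size <- if (message_mode == "continuous") 100L else 256L
  if (is.null(n_episodes))
    n_episodes <- if (message_mode == "continuous") 20000L else 25000L
  if (is.null(probe_every))
    probe_every <- max(1L, as.integer(round(n_episodes / 100)))
  stopifnot(sigma_e_sq >= 0, sigma_c_sq >= 0, batch_size >= 1,
            n_episodes >= 1, learning_rate > 0)
  structure(list(
    message_mode = message_mode,
    sigma_e_sq = sigma_e_sq, sigma_c_sq = sigma_c_sq,
    batch_size = as.integer(batch_size),
    n_episodes = as.integer(n_episodes),
    learning_rate = learning_rate,
    k = as.integer(k), d = as.integer(d), init_scale = init_scale,
    probe_every = as.integer(probe_every),
    adam_beta1 = adam_beta1, adam_beta2 = adam_beta2, adam_eps = adam_eps,
    seed = seed
  ), class = "game_config")
}

#' Reward of a guess
#'
#' The payoff of one game: the CIELAB similarity between the receiver's
#' guessed chip and the true target chip. Guessing the target exactly
#' earns 1; the reward decays smoothly with perceptual distance, so
#' near-misses are worth almost as much as hits. The reward is computed
#' against the clean target coordinates, not the noise-perturbed stimulus.
#'
#' @param guess,target 0-based chip ids in `chart`.
#' @param chart a [chip_chart()].
#' @param params a [similarity_params()].
#' @return reward in (0, 1].
#' @export
reward <- function(guess, target, chart, params = similarity_params()) {
  n <- n_chips(chart)
  guess <- as.integer(guess); target <- as.integer(target)
  if (anyNA(c(guess, target)) || any(c(guess, target) < 0L) ||
      any(c(guess, target) >= n))
    stop("guess and target must be chip ids in the chart")
  xy <- chip_coords(chart)
  similarity(xy[guess + 1L, ], xy[target + 1L, ], params)
}

# vectorized categorical sampling via the Gumbel-max trick: one column of
# logits per draw; zero-probability entries (log 0 = -Inf) are never picked
sample_categorical_cols <- function(P) {
  logp <- log(P)
  g <- matrix(-log(-log(stats::runif(length(P)))), nrow(P), ncol(P))
  max.col(t(logp + g), ties.method = "first")
}

LOG_CLIP <- log(1e-12)  # floor on log-probabilities entering the loss

#' One REINFORCE batch with continuous messages
#'
#' Plays `batch_size` games: a target chip is drawn uniformly, its
#' coordinates are perturbed with environmental noise, the sender emits a
#' word softmax, Gaussian channel noise is added, the receiver forms a
#' guess distribution and a guess is sampled. The single end-to-end cost is
#' `J = -(1/Nb) sum_n log Pi(c_n | t_n) * r_n`; because the channel is
#' additive the gradient flows from the receiver through the message back
#' into the sender. Gradients are computed in closed form (softmax/ReLU
#' backprop).
#'
#' @param params an [init_agent_parameters()] object.
#' @param chart a [chip_chart()].
#' @param cfg a [game_config()] with `message_mode = "continuous"`.
#' @param sim optional precomputed [similarity_matrix()] of the chart.
#' @return list with `loss`, `grads` (named like the weight fields),
#'   `rewards`, `targets`, `guesses` (0-based ids).
#' @export
play_batch_continuous <- function(params, chart, cfg,
                                  sim = NULL) {
  check_params(params)
  stopifnot(cfg$message_mode == "continuous")
  if (is.null(sim)) sim <- similarity_matrix(chart)
  n <- n_chips(chart); Nb <- cfg$batch_size
  X0 <- t(unname(chip_coords(chart)))                       # 3 x n
  tgt <- sample.int(n, Nb, replace = TRUE)
  X <- X0[, tgt, drop = FALSE]
  if (cfg$sigma_e_sq > 0)
    X <- X + matrix(stats::rnorm(3L * Nb, 0, sqrt(cfg$sigma_e_sq)), 3L, Nb)
  snd <- sender_forward_batch(params, X)
  M <- snd$W
  if (cfg$sigma_c_sq > 0)
    M <- M + matrix(stats::rnorm(length(M), 0, sqrt(cfg$sigma_c_sq)),
                    nrow(M), ncol(M))
  rcv <- receiver_forward_batch(params, M)
  P <- rcv$P                                        # n x Nb
  guess <- sample_categorical_cols(P)
  r <- sim[cbind(guess, tgt)]
  logp <- pmax(log(P[cbind(guess, seq_len(Nb))]), LOG_CLIP)
  loss <- -sum(logp * r) / Nb

  # d(-log softmax_c)/d z = softmax - e_c, weighted by r_n / Nb
  Ec <- matrix(0, n, Nb); Ec[cbind(guess, seq_len(Nb))] <- 1
  G_Zr <- (P - Ec) * rep(r / Nb, each = n)
  gVr <- G_Zr %*% t(rcv$Hr); gcr <- rowSums(G_Zr)
  G_Ar <- (t(params$Vr) %*% G_Zr) * (rcv$Ar > 0)
  gWr <- G_Ar %*% t(M); gbr <- rowSums(G_Ar)
  G_W <- t(params$Wr) %*% G_Ar                      # through additive noise
  # softmax Jacobian: dz = w * (g - <g, w>)
  s <- colSums(G_W * snd$W)
  G_Zs <- snd$W * (G_W - rep(s, each = params$d))
  gVs <- G_Zs %*% t(snd$Hs); gcs <- rowSums(G_Zs)
  G_As <- (t(params$Vs) %*% G_Zs) * (snd$As > 0)
  gWs <- G_As %*% t(X); gbs <- rowSums(G_As)

  list(loss = loss,
       grads = list(Ws = gWs, bs = gbs, Vs = gVs, cs = gcs,
                    Wr = gWr, br = gbr, Vr = gVr, cr = gcr),
       rewards = r, targets = tgt - 1L, guesses = guess - 1L)
}

#' One REINFORCE batch with discrete messages
#'
#' As [play_batch_continuous()], but the message is a one-hot word sampled
#' from the sender softmax, so no gradient can cross the channel. Sender
#' and receiver are therefore updated by two separate costs,
#' `J_s = -(1/Nb) sum log Pi_s(m_n|t_n) (r_n - B)` and
#' `J_r = -(1/Nb) sum log Pi_r(c_n|m_n) (r_n - B)`, where `B` is the
#' running mean of all rewards observed in previous batches (initialized to
#' 0) — the standard variance-reduction baseline for REINFORCE.
#'
#' @inheritParams play_batch_continuous
#' @param baseline current running-mean baseline `B`.
#' @return list with `loss_sender`, `loss_receiver`, `grads`, `rewards`,
#'   `targets`, `guesses`, `messages` (sampled word indices, 1-based).
#' @export
play_batch_discrete <- function(params, chart, cfg, baseline = 0,
                                sim = NULL) {
  check_params(params)
  stopifnot(cfg$message_mode == "discrete")
  if (is.null(sim)) sim <- similarity_matrix(chart)
  n <- n_chips(chart); Nb <- cfg$batch_size; d <- params$d
  X0 <- t(unname(chip_coords(chart)))
  tgt <- sample.int(n, Nb, replace = TRUE)
  X <- X0[, tgt, drop = FALSE]
  if (cfg$sigma_e_sq > 0)
    X <- X + matrix(stats::rnorm(3L * Nb, 0, sqrt(cfg$sigma_e_sq)), 3L, Nb)
  snd <- sender_forward_batch(params, X)
  msg <- sample_categorical_cols(snd$W)
  M <- matrix(0, d, Nb); M[cbind(msg, seq_len(Nb))] <- 1
  rcv <- receiver_forward_batch(params, M)
  guess <- sample_categorical_cols(rcv$P)
  r <- sim[cbind(guess, tgt)]
  adv <- r - baseline

  logps <- pmax(log(snd$W[cbind(msg, seq_len(Nb))]), LOG_CLIP)
  logpr <- pmax(log(rcv$P[cbind(guess, seq_len(Nb))]), LOG_CLIP)
  loss_s <- -sum(logps * adv) / Nb
  loss_r <- -sum(logpr * adv) / Nb

  Em <- M
  G_Zs <- (snd$W - Em) * rep(adv / Nb, each = d)
  gVs <- G_Zs %*% t(snd$Hs); gcs <- rowSums(G_Zs)
  G_As <- (t(params$Vs) %*% G_Zs) * (snd$As > 0)
  gWs <- G_As %*% t(X); gbs <- rowSums(G_As)

  Ec <- matrix(0, n, Nb); Ec[cbind(guess, seq_len(Nb))] <- 1
  G_Zr <- (rcv$P - Ec) * rep(adv / Nb, each = n)
  gVr <- G_Zr %*% t(rcv$Hr); gcr <- rowSums(G_Zr)
  G_Ar <- (t(params$Vr) %*% G_Zr) * (rcv$Ar > 0)
  gWr <- G_Ar %*% t(M); gbr <- rowSums(G_Ar)

  list(loss_sender = loss_s, loss_receiver = loss_r,
       grads = list(Ws = gWs, bs = gbs, Vs = gVs, cs = gcs,
                    Wr = gWr, br = gbr, Vr = gVr, cr = gcr),
       rewards = r, targets = tgt - 1L, guesses = guess - 1L,
       messages = msg)
}

WEIGHT_FIELDS <- c("Ws", "bs", "Vs", "cs", "Wr", "br", "Vr", "cr")

adam_init <- function(params) {
  zero <- lapply(params[WEIGHT_FIELDS], function(x) x * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (f in WEIGHT_FIELDS) {
    g <- grads[[f]]
    state$m[[f]] <- b1 * state$m[[f]] + (1 - b1) * g
    state$v[[f]] <- b2 * state$v[[f]] + (1 - b2) * g^2
    params[[f]] <- params[[f]] - cfg$learning_rate *
      (state$m[[f]] / c1) / (sqrt(state$v[[f]] / c2) + cfg$adam_eps)
  }
  list(params = params, state = state)
}

# KL loss of a label vector given a precomputed similarity matrix
# (internal fast path of kl_loss_from_partition used by training probes)
kl_from_labels <- function(labels, sim) {
  same <- outer(labels, labels, "==")
  s_c <- rowSums(sim * same)
  mean(-log2(s_c / sum(s_c)))
}

#' Train a sender/receiver pair on the color game
#'
#' Runs `cfg$n_episodes` REINFORCE batch updates with the ADAM optimizer.
#' At fixed intervals (`cfg$probe_every`) the run is probed without noise:
#' the sender's mode map is extracted, its term count and exemplar KL loss
#' recorded, and a partition snapshot stored whenever the term count
#' changes — together these give the developmental timeline of the
#' emerging language. Fully deterministic under `cfg$seed`.
#'
#' @param chart a [chip_chart()].
#' @param cfg a [game_config()].
#' @return An object of class `color_game_fit`: list with `params` (final
#'   [init_agent_parameters()]), `trace` (per-episode data.frame with mean
#'   reward, baseline and loss(es)), `probes` (data.frame with episode,
#'   term_count, kl_loss), `snapshots` (named list of partitions at
#'   term-count changes), `config`, `final_partition`.
#' @export
train_agents <- function(chart, cfg) {
  stopifnot(inherits(chart, "chip_chart"), inherits(cfg, "game_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- n_chips(chart)
  params <- init_agent_parameters(n, cfg$k, cfg$d, cfg$init_scale)
  sim <- similarity_matrix(chart)
  state <- adam_init(params)
  discrete <- cfg$message_mode == "discrete"

  N <- cfg$n_episodes
  mean_reward <- numeric(N); baseline_tr <- numeric(N)
  loss1 <- numeric(N); loss2 <- if (discrete) numeric(N) else NULL
  B <- 0; n_rewards <- 0
  probe_eps <- sort(unique(c(1L, seq(cfg$probe_every, N, cfg$probe_every), N)))
  probes <- data.frame(episode = probe_eps, term_count = NA_integer_,
                       kl_loss = NA_real_)
  snapshots <- list()
  last_tc <- NA_integer_

  for (ep in seq_len(N)) {
    if (discrete) {
      batch <- play_batch_discrete(params, chart, cfg, baseline = B,
                                   sim = sim)
      loss1[ep] <- batch$loss_sender; loss2[ep] <- batch$loss_receiver
      if (!is.finite(loss1[ep]) || !is.finite(loss2[ep]))
        stop(sprintf("training diverged (non-finite loss) at episode %d", ep))
    } else {
      batch <- play_batch_continuous(params, chart, cfg, sim = sim)
      loss1[ep] <- batch$loss
      if (!is.finite(loss1[ep]))
        stop(sprintf("training diverged (non-finite loss) at episode %d", ep))
    }
    upd <- adam_step(params, batch$grads, state, cfg)
    params <- upd$params; state <- upd$state
    mean_reward[ep] <- mean(batch$rewards)
    # running mean over all rewards seen so far (baseline for discrete)
    B <- (B * n_rewards + sum(batch$rewards)) /
      (n_rewards + length(batch$rewards))
    n_rewards <- n_rewards + length(batch$rewards)
    baseline_tr[ep] <- B

    if (ep %in% probe_eps) {
      part <- agent_partition(params, chart)
      i <- match(ep, probe_eps)
      probes$term_count[i] <- term_count(part)
      probes$kl_loss[i] <- kl_from_labels(part$labels, sim)
      if (is.na(last_tc) || term_count(part) != last_tc) {
        snapshots[[as.character(ep)]] <- part
        last_tc <- term_count(part)
      }
    }
  }

  trace <- data.frame(episode = seq_len(N), mean_reward = mean_reward,
                      baseline = baseline_tr)
  if (discrete) {
    trace$loss_sender <- loss1; trace$loss_receiver <- loss2
  } else trace$loss <- loss1

  structure(list(params = params, trace = trace, probes = probes,
                 snapshots = snapshots, config = cfg,
                 final_partition = agent_partition(params, chart)),
            class = "color_game_fit")
}

#' @export
print.color_game_fit <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf(
    "<color_game_fit: %s messages, %d episodes, final terms = %d, final mean reward = %.3f>\n",
    x$config$message_mode, n, term_count(x$final_partition),
    mean(utils::tail(x$trace$mean_reward, max(1L, n %/% 20)))))
  invisible(x)
}
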