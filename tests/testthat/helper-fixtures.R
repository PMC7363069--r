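# shared fixtures built in code; nothing is read from disk

# small chart with well-separated chips arranged on a ring with rising L*
ring_chart <- function(n, radius = 70, name = sprintf("ring%d", n)) {
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  chip_chart(cbind(L = seq(20, 90, length.out = n),
                   a = radius * cos(ang), b = radius * sin(ang)),
             name = name)
}

# two tight, far-apart clumps of chips: the obvious 2-category chart
two_clump_chart <- function(per_clump = 3, name = "clumps") {
  base <- rbind(c(30, -60, -60), c(80, 60, 60))
  coords <- do.call(rbind, lapply(1:2, function(i)
    base[rep(i, per_clump), ] + outer(seq_len(per_clump) - 1, c(1, 1, -1))))
  chip_chart(coords, name = name)
}

# random symmetric weight matrix with zero diagonal, entries in [-1/2, 1/2]
random_weight_graph <- function(n) {
  w <- matrix(stats::runif(n * n, -0.5, 0.5), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# naming data object from a matrix of speaker responses (chips x speakers)
naming_from_matrix <- function(resp, language_id = 1L) {
  speakers <- lapply(seq_len(ncol(resp)), function(s) {
    r <- as.character(resp[, s])
    names(r) <- seq_len(nrow(resp)) - 1L
    list(speaker_id = s, responses = r)
  })
  colorgame:::new_language_naming_data(language_id, speakers,
                                       as.character(resp))
}

small_cfg <- function(mode = "continuous", ...) {
  defaults <- list(message_mode = mode, sigma_e_sq = 0, sigma_c_sq = 0,
                   batch_size = 20L, n_episodes = 30L, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(game_config, args)
}
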