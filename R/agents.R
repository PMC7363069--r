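#' Initialize sender and receiver parameters
#'
#' Both agents are two-layer perceptrons with ReLU hidden units and softmax
#' outputs. The sender maps a (noisy) 3-D CIELAB coordinate to a
#' distribution over `d` possible words; the receiver maps a d-dimensional
#' message back to a distribution over the chart's chips. `d` caps the
#' number of color terms the pair can ever use; with the default `d = 50`
#' the cap is far above what emerges in practice. Weights are drawn
#' independently from `uniform(-init_scale, init_scale)`; biases exist and
#' start at zero.
#'
#' @param n_colors number of chips in the chart (receiver output size).
#' @param k hidden width of both agents (default 20).
#' @param d message dimension / maximum vocabulary (default 50).
#' @param init_scale half-width of the uniform weight initialization.
#' @return An object of class `agent_parameters`: a list of the four
#'   weight matrices and four bias vectors, plus the dimensions.
#' @export
init_agent_parameters <- function(n_colors, k = 20L, d = 50L,
                                  init_scale = 0.1) {
  n_colors <- as.integer(n_colors); k <- as.integer(k); d <- as.integer(d)
  if (any(is.na(c(n_colors, k, d))) || n_colors < 1L || k < 1L || d < 1L)
    stop("n_colors, k and d must be positive integers")
  ru <- function(nr, nc)
    matrix(stats::runif(nr * nc, -init_scale, init_scale), nr, nc)
  structure(list(
    Ws = ru(k, 3L), bs = numeric(k),       # sender hidden
    Vs = ru(d, k),  cs = numeric(d),       # sender output (word logits)
    Wr = ru(k, d),  br = numeric(k),       # receiver hidden
    Vr = ru(n_colors, k), cr = numeric(n_colors),  # receiver output
    k = k, d = d, n_colors = n_colors
  ), class = "agent_parameters")
}

#' @export
print.agent_parameters <- function(x, ...) {
  cat(sprintf(
    "<agent_parameters: k = %d hidden units, d = %d words, |U| = %d chips>\n",
    x$k, x$d, x$n_colors))
  invisible(x)
}

check_params <- function(params) {
  if (!inherits(params, "agent_parameters"))
    stop("params must be an agent_parameters object")
  with(params, {
    ok <- all(dim(Ws) == c(k, 3L)) && length(bs) == k &&
      all(dim(Vs) == c(d, k)) && length(cs) == d &&
      all(dim(Wr) == c(k, d)) && length(br) == k &&
      all(dim(Vr) == c(n_colors, k)) && length(cr) == n_colors
    if (!ok) stop("agent parameter shapes are inconsistent")
  })
  invisible(params)
}

# column-wise softmax with max subtraction for stability
softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2L, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

# batched sender forward: X is 3 x N of (noisy) CIELAB coords.
# Returns pre-activations and the word softmax W (d x N).
sender_forward_batch <- function(params, X) {
  As <- params$Ws %*% X + params$bs
  Hs <- pmax(As, 0)
  Zs <- params$Vs %*% Hs + params$cs
  list(As = As, Hs = Hs, W = softmax_cols(Zs))
}

# batched receiver forward: M is d x N messages.
receiver_forward_batch <- function(params, M) {
  Ar <- params$Wr %*% M + params$br
  Hr <- pmax(Ar, 0)
  Zr <- params$Vr %*% Hr + params$cr
  list(Ar = Ar, Hr = Hr, P = softmax_cols(Zr))
}

#' Sender policy: word distribution for a (noisy) chip
#'
#' Computes `softmax(Vs %*% relu(Ws %*% x + bs) + cs)`, the sender's
#' distribution over the `d` possible words for the presented coordinate.
#' In continuous mode the full probability vector is the message; in
#' discrete mode a one-hot message is sampled from it.
#'
#' @param params an [init_agent_parameters()] object.
#' @param noisy_coords numeric 3-vector, typically [perturb_chip()] output.
#' @param mode `"continuous"` (probability-vector message) or
#'   `"discrete_sample"` (sampled one-hot message).
#' @return a `color_message`: list with `values` (d-vector), `discrete`
#'   flag and, for discrete messages, the sampled `index`.
#' @export
sender_forward <- function(params, noisy_coords,
                           mode = c("continuous", "discrete_sample")) {
  check_params(params)
  mode <- match.arg(mode)
  w <- drop(sender_forward_batch(params, matrix(as_coords3(noisy_coords)))$W)
  if (mode == "continuous")
    return(structure(list(values = w, discrete = FALSE, index = NA_integer_),
                     class = "color_message"))
  i <- sample.int(params$d, 1L, prob = w)
  v <- numeric(params$d); v[i] <- 1
  structure(list(values = v, discrete = TRUE, index = i),
            class = "color_message")
}

#' Additive Gaussian channel noise on a message
#'
#' Adds independent zero-mean Gaussian noise of variance `sigma_c_sq` per
#' component to a continuous message. Discrete (one-hot) messages are used
#' only at evaluation time, where the channel is noiseless by construction,
#' so they pass through unchanged.
#'
#' @param msg a `color_message` from [sender_forward()], or a plain
#'   d-vector.
#' @param sigma_c_sq nonnegative noise variance per component.
#' @return the transmitted d-vector.
#' @export
channel_noise <- function(msg, sigma_c_sq) {
  if (!is.numeric(sigma_c_sq) || length(sigma_c_sq) != 1L ||
      !is.finite(sigma_c_sq) || sigma_c_sq < 0)
    stop("sigma_c_sq must be a single nonnegative finite number")
  if (inherits(msg, "color_message")) {
    if (msg$discrete) return(msg$values)   # evaluation-time no-op
    v <- msg$values
  } else v <- as.numeric(msg)
  if (sigma_c_sq > 0)
    v <- v + stats::rnorm(length(v), 0, sqrt(sigma_c_sq))
  v
}

#' Receiver policy: chip distribution for a received message
#'
#' Computes `softmax(Vr %*% relu(Wr %*% m + br) + cr)`, the receiver's
#' posterior guess distribution over all chips of the chart.
#'
#' @param params an [init_agent_parameters()] object.
#' @param m received message (numeric d-vector).
#' @return probability vector of length `n_colors`.
#' @export
receiver_forward <- function(params, m) {
  check_params(params)
  m <- as.numeric(m)
  if (length(m) != params$d) stop("message length must equal d")
  drop(receiver_forward_batch(params, matrix(m))$P)
}

#' Categorize a chip with the trained sender
#'
#' The word the sender assigns to a chip when queried without environmental
#' noise: the argmax of the noise-free word distribution, ties broken
#' toward the smallest word index. Applying this to every chart chip
#' yields the agent pair's mode map.
#'
#' @param params an [init_agent_parameters()] object.
#' @param chip a chart row or numeric 3-vector of CIELAB coordinates.
#' @return 1-based word index.
#' @export
categorize <- function(params, chip) {
  check_params(params)
  w <- sender_forward_batch(params, matrix(as_coords3(chip)))$W
  which.max(w)      # first maximum = smallest index on ties
}

#' Mode map of a trained agent pair
#'
#' [categorize()] applied to every chip of the chart (noise-free,
#' deterministic). Labels are the sender's word indices.
#'
#' @param params an [init_agent_parameters()] object.
#' @param chart a [chip_chart()].
#' @return a [color_partition()].
#' @export
agent_partition <- function(params, chart) {
  check_params(params)
  W <- sender_forward_batch(params, t(chip_coords(chart)))$W
  color_partition(apply(W, 2L, which.max), chart)
}

#' Naming model of a trained agent pair
#'
#' Queries the sender, chip by chip and without environmental noise, for
#' its full word distribution — the in-silico analog of asking a panel of
#' respondents to name every chip. Words that receive no mass anywhere are
#' retained as zero columns only if present; columns are the `d` word
#' slots.
#'
#' @param params an [init_agent_parameters()] object.
#' @param chart a [chip_chart()].
#' @return a [naming_model()] with `d` term columns `w1..wd`.
#' @export
agent_naming_model <- function(params, chart) {
  check_params(params)
  W <- sender_forward_batch(params, t(chip_coords(chart)))$W
  naming_model(t(W), terms = paste0("w", seq_len(params$d)))
}

#' Write / read agent parameter checkpoints
#'
#' Plain-text checkpoint of the four weight matrices, biases and
#' dimensions, portable across platforms.
#'
#' @param params an [init_agent_parameters()] object.
#' @param path file path.
#' @return `path` (write) or the restored `agent_parameters` (read).
#' @export
write_agent_parameters <- function(params, path) {
  check_params(params)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# colorgame agent checkpoint k=%d d=%d n=%d",
                     params$k, params$d, params$n_colors), con)
  for (nm in c("Ws", "bs", "Vs", "cs", "Wr", "br", "Vr", "cr")) {
    x <- params[[nm]]
    dims <- if (is.matrix(x)) dim(x) else c(length(x), 1L)
    writeLines(sprintf("@%s %d %d", nm, dims[1L], dims[2L]), con)
    writeLines(paste(sprintf("%.17g", as.vector(x)), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_agent_parameters
#' @export
read_agent_parameters <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(regmatches(lines[1L],
                               gregexpr("[0-9]+", lines[1L]))[[1L]])
  out <- list(k = hdr[1L], d = hdr[2L], n_colors = hdr[3L])
  i <- 2L
  while (i < length(lines)) {
    meta <- strsplit(sub("^@", "", lines[i]), " ")[[1L]]
    vals <- as.numeric(strsplit(lines[i + 1L], " +")[[1L]])
    x <- if (meta[3L] == "1") vals
         else matrix(vals, as.integer(meta[2L]), as.integer(meta[3L]))
    out[[meta[1L]]] <- x
    i <- i + 2L
  }
  check_params(structure(out, class = "agent_parameters"))
}
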