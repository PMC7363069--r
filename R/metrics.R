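#' Construct a naming model p(w | c)
#'
#' A naming model holds, for every chip, a probability distribution over
#' terms: the probability that a speaker of the language (human respondent
#' or trained agent) uses term w for chip c.
#'
#' @param p_w_given_c numeric matrix, chips in rows (chip_id order) and
#'   terms in columns; every row must sum to 1.
#' @param terms optional term labels (defaults to the matrix column names,
#'   or `t1..tT`).
#' @return An object of class `naming_model`: the row-stochastic matrix.
#' @export
naming_model <- function(p_w_given_c, terms = NULL) {
  m <- as.matrix(p_w_given_c)
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("naming model must have at least one chip and one term")
  if (any(m < -1e-12)) stop("term probabilities must be nonnegative")
  m[m < 0] <- 0
  if (max(abs(rowSums(m) - 1)) > 1e-6)
    stop("every row of p(w|c) must sum to 1")
  m <- m / rowSums(m)
  colnames(m) <- if (!is.null(terms)) as.character(terms)
                 else colnames(m) %||% paste0("t", seq_len(ncol(m)))
  rownames(m) <- seq_len(nrow(m)) - 1L
  structure(m, class = c("naming_model", "matrix"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic naming model induced by a partition
#'
#' The indicator model: chip c uses its partition label with probability 1.
#'
#' @param p a [color_partition()].
#' @return a [naming_model()] with one column per term used.
#' @export
partition_naming_model <- function(p) {
  stopifnot(inherits(p, "color_partition"))
  terms <- sort(unique(as.character(p$labels)))
  m <- matrix(0, p$n, length(terms), dimnames = list(NULL, terms))
  m[cbind(seq_len(p$n), match(as.character(p$labels), terms))] <- 1
  naming_model(m)
}

#' Bayesian decoder p(c | w)
#'
#' Inverts a naming model with Bayes' theorem:
#' `p(c|w) = p(w|c) p(c) / sum_c' p(w|c') p(c')`. The prior `p(c)` is the
#' listener's need probability over chips, uniform by default. Terms with
#' zero total mass are dropped.
#'
#' @param model a [naming_model()].
#' @param prior optional chip prior (length = number of chips, sums to 1).
#' @return matrix with one row per retained term and one column per chip;
#'   every row sums to 1.
#' @export
bayes_decoder <- function(model, prior = NULL) {
  stopifnot(inherits(model, "naming_model"))
  n <- nrow(model)
  if (is.null(prior)) prior <- rep(1 / n, n)
  if (length(prior) != n || any(prior < 0) || abs(sum(prior) - 1) > 1e-6)
    stop("prior must be a probability distribution over the chips")
  joint <- t(unclass(model) * prior)        # terms x chips: p(w|c) p(c)
  mass <- rowSums(joint)
  joint <- joint[mass > 0, , drop = FALSE]
  dec <- joint / rowSums(joint)
  colnames(dec) <- rownames(model)
  dec
}

#' Listener's expected surprise
#'
#' The communication cost of chip c under a naming model and a decoder:
#' `-sum_w p(w|c) log2 p(c|w)` — the expected surprisal incurred by the
#' listener when the true chip is revealed. With `chip = NULL` the uniform
#' (need-probability) average over all chips is returned. If the decoder
#' assigns zero mass to a chip for a term the speaker actually uses, the
#' cost is infinite; `Inf` is returned with a warning rather than being
#' silently dropped (sparse empirical models can produce such cells).
#'
#' @param model a [naming_model()].
#' @param decoder a term-by-chip decoder matrix, e.g. from
#'   [bayes_decoder()] or [partition_decoder()]; rows must be named with
#'   terms matching the model's columns.
#' @param chip 0-based chip id, or `NULL` for the aggregate over chips.
#' @param prior need probability over chips used for the aggregate
#'   (uniform by default).
#' @return expected surprise in bits.
#' @export
expected_surprise <- function(model, decoder, chip = NULL, prior = NULL) {
  stopifnot(inherits(model, "naming_model"))
  n <- nrow(model)
  per_chip_es <- function(ci) {                 # ci is 1-based row index
    pw <- unclass(model)[ci, ]
    used <- which(pw > 0)
    es <- 0
    for (w in used) {
      term <- colnames(model)[w]
      pcw <- if (term %in% rownames(decoder)) decoder[term, ci] else 0
      if (pcw <= 0) {
        warning(sprintf(
          "decoder assigns zero mass to chip %d under term '%s'; surprise is infinite",
          ci - 1L, term))
        return(Inf)
      }
      es <- es - pw[[w]] * log2(pcw)
    }
    unname(es)
  }
  if (!is.null(chip)) {
    chip <- as.integer(chip)
    if (is.na(chip) || chip < 0L || chip >= n) stop("chip id out of range")
    return(per_chip_es(chip + 1L))
  }
  if (is.null(prior)) prior <- rep(1 / n, n)
  sum(prior * vapply(seq_len(n), per_chip_es, numeric(1L)))
}

#' Exemplar-based decoder of a partition
#'
#' The listener distribution computed directly from a mode map: for a chip
#' c in category w,
#' `p(c|w) = sum_{j in Cat(c)} sim(c,j) / sum_i sum_{j in Cat(i)} sim(i,j)`,
#' an exemplar-selection reading in which more representative members of a
#' category are more likely to be selected. As printed, the denominator
#' runs over the whole universe, so the values sum to 1 across all chips
#' (not within each term); set `renormalize = TRUE` for the per-category
#' renormalized variant (off by default).
#'
#' @param p a [color_partition()].
#' @param chart the [chip_chart()] the partition lives on.
#' @param params a [similarity_params()].
#' @param renormalize renormalize within each category (non-default
#'   variant).
#' @return matrix with one row per term and one column per chip; entry
#'   `[w, c]` is `p(c|w)` for chips of category w and 0 elsewhere.
#' @export
partition_decoder <- function(p, chart, params = similarity_params(),
                              renormalize = FALSE) {
  stopifnot(inherits(p, "color_partition"), inherits(chart, "chip_chart"))
  if (p$n != n_chips(chart)) stop("partition and chart sizes differ")
  sim <- similarity_matrix(chart, params)
  labs <- as.character(p$labels)
  terms <- sort(unique(labs))
  same <- outer(labs, labs, "==")
  s_c <- rowSums(sim * same)                 # includes sim(c, c) = 1
  z <- sum(s_c)
  dec <- matrix(0, length(terms), p$n,
                dimnames = list(terms, seq_len(p$n) - 1L))
  dec[cbind(match(labs, terms), seq_len(p$n))] <-
    if (renormalize) NA else s_c / z
  if (renormalize) {
    for (tm in terms) {
      in_cat <- labs == tm
      dec[tm, in_cat] <- s_c[in_cat] / sum(s_c[in_cat])
    }
  }
  dec
}

#' KL communication cost of a partition
#'
#' The aggregate information loss of using a mode map to communicate about
#' the chart: with the speaker distribution a point mass on the target
#' chip, the per-chip KL divergence between speaker and listener reduces to
#' `-log2 p(c|w)` with `p(c|w)` the exemplar-based decoder of
#' [partition_decoder()]. The aggregate is the uniform need-probability
#' average over chips (equivalently, a conditional entropy H(C | W) under
#' the exemplar decoder).
#'
#' @inheritParams partition_decoder
#' @param per_chip return the per-chip vector instead of the aggregate.
#' @return KL loss in bits (scalar, or length-n vector if `per_chip`).
#' @export
kl_loss_from_partition <- function(p, chart, params = similarity_params(),
                                   renormalize = FALSE, per_chip = FALSE) {
  dec <- partition_decoder(p, chart, params, renormalize = renormalize)
  labs <- as.character(p$labels)
  pcw <- dec[cbind(match(labs, rownames(dec)), seq_len(p$n))]
  e <- -log2(pcw)
  if (per_chip) e else mean(e)
}

#' Well-formedness of a partition
#'
#' The maximizing-agreements correlation-clustering objective evaluated on
#' the chart's signed similarity graph: the sum of `sim(x, y) - 1/2` over
#' all unordered pairs of chips placed in the same category. Higher values
#' mean similar chips are grouped and dissimilar chips separated; the
#' attainable maximum for a chart is the [cc_local_search()] /
#' [cc_brute_force()] optimum on the same graph.
#'
#' @inheritParams partition_decoder
#' @return the well-formedness score.
#' @export
wellformedness <- function(p, chart, params = similarity_params()) {
  stopifnot(inherits(p, "color_partition"))
  if (p$n != n_chips(chart)) stop("partition and chart sizes differ")
  cc_objective(build_similarity_graph(chart, params), p$labels)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions
#' (up to relabeling), near 0 for independent ones.
#'
#' @param p1,p2 [color_partition()]s on the same chart.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(p1, p2) {
  stopifnot(inherits(p1, "color_partition"), inherits(p2, "color_partition"))
  if (p1$n != p2$n || p1$chart_name != p2$chart_name)
    stop("partitions must be on the same chart")
  mclust::adjustedRandIndex(p1$labels, p2$labels)
}

#' Mean pairwise adjusted Rand index between (or within) partition groups
#'
#' With two groups, averages the ARI over all cross pairs; with one group,
#' over all unordered within-group pairs (self-pairs excluded). The
#' confidence halfwidth is the normal-approximation `1.96 * sd / sqrt(n)`
#' over the pair values; with a single pair the spread is undefined and the
#' halfwidth is reported as 0 with `ci_defined = FALSE`.
#'
#' @param group1 list of [color_partition()]s.
#' @param group2 optional second list; `NULL` for within-group mode.
#' @return list with `mean`, `ci_halfwidth`, `n_pairs`, `ci_defined`.
#' @export
mean_pairwise_ari <- function(group1, group2 = NULL) {
  check_group <- function(g, nm) {
    if (!is.list(g) || length(g) == 0L ||
        !all(vapply(g, inherits, logical(1L), "color_partition")))
      stop(nm, " must be a non-empty list of color_partition objects")
  }
  check_group(group1, "group1")
  vals <- if (is.null(group2)) {
    if (length(group1) < 2L)
      stop("within-group mode needs at least two partitions")
    pairs <- utils::combn(length(group1), 2L)
    apply(pairs, 2L, function(ij)
      adjusted_rand_index(group1[[ij[1L]]], group1[[ij[2L]]]))
  } else {
    check_group(group2, "group2")
    as.vector(outer(seq_along(group1), seq_along(group2),
                    Vectorize(function(i, j)
                      adjusted_rand_index(group1[[i]], group2[[j]]))))
  }
  n <- length(vals)
  list(mean = mean(vals),
       ci_halfwidth = if (n > 1L) 1.96 * stats::sd(vals) / sqrt(n) else 0,
       n_pairs = n,
       ci_defined = n > 1L)
}

#' Efficiency report of a partition
#'
#' Convenience bundle of the per-partition efficiency measures: exemplar
#' KL loss, expected surprise of the induced deterministic naming model
#' (identical to the KL loss by construction), well-formedness and term
#' count.
#'
#' @inheritParams partition_decoder
#' @return data.frame with one row.
#' @export
metric_report <- function(p, chart, params = similarity_params()) {
  kl <- kl_loss_from_partition(p, chart, params)
  data.frame(
    term_count = term_count(p),
    kl_loss = kl,
    expected_surprise = expected_surprise(partition_naming_model(p),
                                          partition_decoder(p, chart, params)),
    wellformedness = wellformedness(p, chart, params)
  )
}
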