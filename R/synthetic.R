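#' Generate a WCS-like synthetic chip chart
#'
#' Builds a chart with the topology of the World Color Survey array: a ring
#' of `n_hues` hues crossed with `n_values` lightness rows, plus an
#' achromatic column of `n_achromatic` gray chips. Chromatic chips sit on a
#' cylinder in CIELAB — `a* = R cos(2 pi h / n_hues)`,
#' `b* = R sin(2 pi h / n_hues)` with radius `R` from the `a`/`b` ranges —
#' so the hue dimension wraps smoothly (adjacent hues are close) and
#' CIELAB distances behave like the real chart's. L* is spaced evenly over
#' its range across value rows; achromatic chips span the same L* range at
#' `a* = b* = 0`. The default ranges put the per-dimension standard
#' deviations close to the real chart's (lightness the smallest of the
#' three). The construction is deterministic; `jitter_sd > 0` adds seeded
#' Gaussian jitter when distinct-but-irregular coordinates are wanted.
#'
#' @param n_hues hue columns (default 40).
#' @param n_values lightness rows (default 8).
#' @param n_achromatic achromatic chips (default 10); total chart size is
#'   `n_hues * n_values + n_achromatic` (330 by default).
#' @param lab_ranges list with elements `L`, `a`, `b`, each a `(min, max)`
#'   pair.
#' @param jitter_sd standard deviation of optional coordinate jitter.
#' @param seed seed for the jitter (ignored when `jitter_sd = 0`).
#' @param name chart name.
#' @return a [chip_chart()].
#' @examples
#' ch <- make_synthetic_chart()
#' n_chips(ch)  # 330
#' @export
make_synthetic_chart <- function(n_hues = 40L, n_values = 8L,
                                 n_achromatic = 10L,
                                 lab_ranges = list(L = c(20, 91),
                                                   a = c(-45, 45),
                                                   b = c(-45, 45)),
                                 jitter_sd = 0, seed = NULL,
                                 name = "synthetic-chart") {
  n_hues <- as.integer(n_hues); n_values <- as.integer(n_values)
  n_achromatic <- as.integer(n_achromatic)
  if (anyNA(c(n_hues, n_values, n_achromatic)) ||
      n_hues < 1L || n_values < 1L || n_achromatic < 0L)
    stop("invalid synthetic chart spec: sizes must be positive")
  if (!all(c("L", "a", "b") %in% names(lab_ranges)))
    stop("lab_ranges must provide L, a and b ranges")
  Lr <- sort(lab_ranges$L)
  radius <- min(diff(sort(lab_ranges$a)), diff(sort(lab_ranges$b))) / 2

  hue <- rep(seq_len(n_hues) - 1L, each = n_values)
  val <- rep(seq_len(n_values), times = n_hues)
  Lchrom <- if (n_values > 1L)
    Lr[1L] + (val - 1L) * diff(Lr) / (n_values - 1L) else mean(Lr)
  ang <- 2 * pi * hue / n_hues
  coords <- cbind(L = Lchrom, a = radius * cos(ang), b = radius * sin(ang))
  mh <- sprintf("H%02d", hue)
  mv <- as.character(val)
  if (n_achromatic > 0L) {
    Lach <- if (n_achromatic > 1L)
      seq(Lr[1L], Lr[2L], length.out = n_achromatic) else mean(Lr)
    coords <- rbind(coords, cbind(L = Lach, a = 0, b = 0))
    mh <- c(mh, rep("A", n_achromatic))
    mv <- c(mv, as.character(seq_len(n_achromatic)))
  }
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    coords <- coords + matrix(stats::rnorm(length(coords), 0, jitter_sd),
                              nrow(coords), ncol(coords))
  }
  chip_chart(coords, name = name, wcs_chip = seq_len(nrow(coords)),
             munsell_hue = mh, munsell_value = mv)
}

# exactly-k spatially coherent ground-truth partition: k-means on the
# CIELAB coordinates, refined by the correlation-clustering local search
# restricted to the k existing clusters (falls back to raw k-means labels
# if refinement merges clusters)
planted_partition <- function(chart, k, params = similarity_params()) {
  xy <- chip_coords(chart)
  km <- stats::kmeans(xy, centers = k, nstart = 5L, iter.max = 200L,
                      algorithm = "Lloyd")
  w <- build_similarity_graph(chart, params)
  ref <- cc_local_search_once(w, km$cluster, max_clusters = k)
  labels <- if (length(unique(ref$labels)) == k) ref$labels else km$cluster
  color_partition(sprintf("t%02d", labels), chart)
}

#' Generate a planted language over a chart
#'
#' Creates a ground-truth k-way partition of the chart (spatially coherent
#' in CIELAB; see Details) and simulates `n_speakers` respondents naming
#' every chip: each response equals the planted label with probability
#' `1 - confusion_rate`, and otherwise is drawn uniformly from the labels
#' of similarity-adjacent categories — the neighboring categories among
#' the chip's nearest chips — so confusions look like real boundary
#' disagreements rather than arbitrary label swaps.
#'
#' @details The planted partition is an exactly-k correlation clustering of
#' the chart by similarity: k-means on the CIELAB coordinates seeds the
#' clustering, which the maximizing-agreements local search then refines
#' without changing the cluster count.
#'
#' @param chart a [chip_chart()].
#' @param k_terms number of planted categories (2..chart size).
#' @param confusion_rate probability in `[0, 1)` that a single response is
#'   confused into an adjacent category.
#' @param n_speakers respondents (default 25, the WCS average).
#' @param n_neighbors neighborhood size defining category adjacency.
#' @param seed integer seed; generation is deterministic under it.
#' @param language_id id recorded on the naming data.
#' @return list with `partition` (the planted [color_partition()]) and
#'   `naming` (a `language_naming_data` as produced by
#'   [read_naming_data()]).
#' @export
make_planted_language <- function(chart, k_terms, confusion_rate = 0,
                                  n_speakers = 25L, n_neighbors = 10L,
                                  seed = NULL, language_id = 1L) {
  stopifnot(inherits(chart, "chip_chart"))
  n <- n_chips(chart)
  k_terms <- as.integer(k_terms)
  if (is.na(k_terms) || k_terms < 2L || k_terms > n)
    stop("k_terms must be between 2 and the chart size")
  if (confusion_rate < 0 || confusion_rate >= 1)
    stop("confusion_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  planted <- planted_partition(chart, k_terms)
  labs <- as.character(planted$labels)

  # similarity-adjacent categories per chip: categories of the chip's
  # nearest neighbors, own category excluded; fall back to all others
  d <- as.matrix(stats::dist(chip_coords(chart)))
  all_terms <- sort(unique(labs))
  adjacent <- lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[2:(min(n_neighbors, n - 1L) + 1L)]
    adj <- setdiff(unique(labs[nb]), labs[i])
    if (length(adj) == 0L) setdiff(all_terms, labs[i]) else adj
  })

  speakers <- lapply(seq_len(n_speakers), function(sp) {
    resp <- labs
    if (confusion_rate > 0) {
      confused <- which(stats::runif(n) < confusion_rate)
      for (i in confused) {
        adj <- adjacent[[i]]
        resp[i] <- adj[sample.int(length(adj), 1L)]
      }
    }
    names(resp) <- seq_len(n) - 1L
    list(speaker_id = sp, responses = resp)
  })

  naming <- new_language_naming_data(language_id, speakers, labs)
  # inventory should cover everything speakers actually said
  naming$term_inventory <- sort(unique(c(
    naming$term_inventory,
    unlist(lapply(speakers, function(s) unname(s$responses))))))
  list(partition = planted, naming = naming)
}
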