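#' Construct a color-space partition (mode map)
#'
#' A partition assigns every chip of a chart to exactly one category label.
#' Labels are opaque: all downstream comparisons are label-invariant
#' (adjusted Rand index) or use only the grouping structure.
#'
#' @param labels atomic vector of category labels, one per chip, in
#'   `chip_id` order.
#' @param chart the [chip_chart()] the partition lives on, or its name.
#' @return An object of class `color_partition` with fields `labels`,
#'   `chart_name` and `n`.
#' @export
color_partition <- function(labels, chart) {
  if (!is.atomic(labels) || length(labels) == 0L)
    stop("labels must be a non-empty atomic vector")
  if (anyNA(labels))
    stop("every chip must be labeled (NA labels found)")
  chart_name <- if (inherits(chart, "chip_chart")) {
    if (length(labels) != nrow(chart))
      stop(sprintf("partition has %d labels but chart '%s' has %d chips",
                   length(labels), attr(chart, "name"), nrow(chart)))
    attr(chart, "name")
  } else as.character(chart)[1L]
  structure(list(labels = labels, chart_name = chart_name,
                 n = length(labels)),
            class = "color_partition")
}

#' @export
print.color_partition <- function(x, ...) {
  cat(sprintf("<color_partition on '%s': %d chips, %d terms>\n",
              x$chart_name, x$n, term_count(x)))
  invisible(x)
}

#' Number of distinct terms used by a partition
#'
#' The operational "number of color terms" of a naming system: the count of
#' distinct labels that actually appear in its mode map.
#'
#' @param p a [color_partition()].
#' @return integer >= 1.
#' @export
term_count <- function(p) {
  stopifnot(inherits(p, "color_partition"))
  length(unique(p$labels))
}

#' Random baseline partition
#'
#' Chance baseline used to bound efficiency comparisons from below: chips
#' are shuffled and split into `k` groups whose sizes differ by at most one
#' ("uniform distribution of tiles per color word").
#'
#' @param chart a [chip_chart()].
#' @param k number of categories, between 1 and the number of chips.
#' @return a [color_partition()] with exactly `k` terms.
#' @export
random_partition <- function(chart, k) {
  n <- n_chips(chart)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n)
    stop(sprintf("k must be between 1 and %d", n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- integer(n)
  labels[sample.int(n)] <- rep.int(seq_len(k), sizes)
  color_partition(labels, chart)
}

#' Write a partition to a TSV file
#' @param p a [color_partition()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "color_partition"))
  utils::write.table(
    data.frame(chip_id = seq_len(p$n) - 1L, label = p$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a partition from a TSV file written by [write_partition()]
#' @param path input file path.
#' @param chart the chart (or chart name) the partition belongs to.
#' @return a [color_partition()].
#' @export
read_partition <- function(path, chart) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chip_id", "label") %in% names(df)))
    stop("partition file must have columns chip_id and label")
  df <- df[order(df$chip_id), ]
  if (!identical(as.integer(df$chip_id), seq_len(nrow(df)) - 1L))
    stop("partition file must cover chip_ids 0..n-1 exactly once")
  color_partition(df$label, chart)
}
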