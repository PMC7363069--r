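#' Specification of an environmental-noise sweep
#'
#' The central experimental design: train many agent pairs while varying
#' the environmental-noise variance over a ladder of levels, which drives
#' the emerging languages toward different vocabulary sizes, then analyze
#' the resulting partitions in buckets of term count. The default ladder
#' and replication (10 levels doubling from 1 to 512, 25 runs per level,
#' communication noise fixed at 0.1) reproduce the study conditions; for
#' desk-scale smoke runs lower `runs_per_level` and shorten the base
#' config's `n_episodes` — the structure of the results is
#' minutes-scale even though the full sweep is hours-scale.
#'
#' @param sigma_e_sq_levels environmental-noise variances to sweep. To
#'   sweep the communication channel instead, set `vary = "sigma_c_sq"`.
#' @param runs_per_level replicate runs per level.
#' @param base_config a [game_config()] supplying everything except the
#'   swept variance and seed.
#' @param vary which noise variance the levels apply to.
#' @param seed master seed; each run's seed is derived from it.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(sigma_e_sq_levels = c(1, 2, 4, 8, 16, 32, 64, 128,
                                             256, 512),
                       runs_per_level = 25L,
                       base_config = game_config(),
                       vary = c("sigma_e_sq", "sigma_c_sq"),
                       seed = 1L) {
  vary <- match.arg(vary)
  runs_per_level <- as.integer(runs_per_level)
  if (is.na(runs_per_level) || runs_per_level < 1L)
    stop("runs_per_level must be >= 1")
  if (length(sigma_e_sq_levels) < 1L || any(sigma_e_sq_levels < 0))
    stop("noise levels must be nonnegative")
  stopifnot(inherits(base_config, "game_config"))
  structure(list(levels = as.numeric(sigma_e_sq_levels),
                 runs_per_level = runs_per_level,
                 base_config = base_config, vary = vary,
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

#' Run a noise sweep
#'
#' Trains one agent pair per (level, replicate) cell, each with a seed
#' derived deterministically from the spec's master seed, and collects the
#' final mode map and its efficiency measures. Runs that diverge
#' (non-finite loss) are excluded and counted.
#'
#' @param spec a [sweep_spec()].
#' @param chart a [chip_chart()].
#' @param keep_probes keep each run's probe table (term-count / KL
#'   timeline).
#' @return An object of class `color_game_sweep`: list with `table` (one
#'   row per completed run: level, run, seed, term_count, kl_loss,
#'   expected_surprise, wellformedness, final mean reward), `partitions`
#'   (parallel list of [color_partition()]s), `probes` (if kept), `spec`,
#'   `n_diverged`.
#' @export
run_sweep <- function(spec, chart, keep_probes = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"), inherits(chart, "chip_chart"))
  rows <- list(); partitions <- list(); probes <- list()
  n_diverged <- 0L
  idx <- 0L
  for (li in seq_along(spec$levels)) {
    for (ri in seq_len(spec$runs_per_level)) {
      idx <- idx + 1L
      run_seed <- (spec$seed + 7919L * li + 104729L * ri) %% 2147483647L
      cfg <- spec$base_config
      cfg[[spec$vary]] <- spec$levels[li]
      cfg$seed <- run_seed
      fit <- tryCatch(train_agents(chart, cfg), error = function(e) e)
      if (inherits(fit, "error")) {
        n_diverged <- n_diverged + 1L
        warning(sprintf("run excluded (level %g, replicate %d): %s",
                        spec$levels[li], ri, conditionMessage(fit)))
        next
      }
      p <- fit$final_partition
      rep_row <- metric_report(p, chart)
      tail_n <- max(1L, cfg$n_episodes %/% 20L)
      rows[[length(rows) + 1L]] <- data.frame(
        level = spec$levels[li], run = ri, seed = run_seed,
        term_count = rep_row$term_count, kl_loss = rep_row$kl_loss,
        expected_surprise = rep_row$expected_surprise,
        wellformedness = rep_row$wellformedness,
        mean_reward_final = mean(utils::tail(fit$trace$mean_reward, tail_n)))
      partitions[[length(partitions) + 1L]] <- p
      if (keep_probes) probes[[length(probes) + 1L]] <- fit$probes
    }
  }
  if (length(rows) == 0L) stop("all sweep runs diverged")
  structure(list(table = do.call(rbind, rows), partitions = partitions,
                 probes = if (keep_probes) probes, spec = spec,
                 chart_name = attr(chart, "name"),
                 n_diverged = n_diverged),
            class = "color_game_sweep")
}

#' @export
print.color_game_sweep <- function(x, ...) {
  cat(sprintf(
    "<color_game_sweep: %d runs over %d %s levels (%d diverged)>\n",
    nrow(x$table), length(x$spec$levels), x$spec$vary, x$n_diverged))
  print(stats::aggregate(term_count ~ level, x$table, mean))
  invisible(x)
}

#' Group sweep runs by vocabulary size
#'
#' @param sweep a [run_sweep()] result.
#' @return named list, one element per observed term count, each holding
#'   `table` rows and the matching `partitions`. Empty buckets are absent.
#' @export
bucket_by_terms <- function(sweep) {
  stopifnot(inherits(sweep, "color_game_sweep"))
  ks <- sort(unique(sweep$table$term_count))
  out <- lapply(ks, function(k) {
    sel <- which(sweep$table$term_count == k)
    list(term_count = k, table = sweep$table[sel, , drop = FALSE],
         partitions = sweep$partitions[sel])
  })
  names(out) <- ks
  out
}

ci95 <- function(x) if (length(x) > 1L) 1.96 * stats::sd(x) / sqrt(length(x)) else 0

#' Per-term-count efficiency table with baselines
#'
#' For every vocabulary size observed in the sweep, tabulates the mean KL
#' loss, expected surprise and well-formedness of the trained (RL)
#' partitions with 95% confidence halfwidths, next to a chance baseline
#' (equal-sized random partitions with the same term count) and the
#' near-optimal baseline (correlation clustering of the chart capped at
#' that term count). Random and optimal bracket the achievable range;
#' efficient systems sit between them, close to the optimum. Optionally a
#' set of human mode maps is bucketed and tabulated the same way.
#'
#' @param sweep a [run_sweep()] result.
#' @param chart the chart the sweep ran on.
#' @param human optional list of human [color_partition()]s.
#' @param n_random random partitions per term count.
#' @param cc_restarts local-search restarts for the optimal baseline.
#' @param params a [similarity_params()].
#' @return data.frame, one row per term count.
#' @export
efficiency_tables <- function(sweep, chart, human = NULL, n_random = 20L,
                              cc_restarts = 10L,
                              params = similarity_params()) {
  stopifnot(inherits(sweep, "color_game_sweep"))
  buckets <- bucket_by_terms(sweep)
  graph <- build_similarity_graph(chart, params)
  human_tc <- if (!is.null(human))
    vapply(human, term_count, integer(1L))
  rows <- lapply(buckets, function(b) {
    k <- b$term_count
    rnd <- replicate(n_random, {
      p <- random_partition(chart, k)
      c(kl = kl_loss_from_partition(p, chart, params),
        wf = wellformedness(p, chart, params))
    })
    ccp <- cc_local_search(graph, restarts = cc_restarts, max_clusters = k,
                           chart_name = attr(chart, "name"))
    row <- data.frame(
      term_count = k, n_runs = nrow(b$table),
      rl_kl_mean = mean(b$table$kl_loss), rl_kl_ci = ci95(b$table$kl_loss),
      rl_es_mean = mean(b$table$expected_surprise),
      rl_es_ci = ci95(b$table$expected_surprise),
      rl_wf_mean = mean(b$table$wellformedness),
      rl_wf_ci = ci95(b$table$wellformedness),
      random_kl_mean = mean(rnd["kl", ]), random_kl_ci = ci95(rnd["kl", ]),
      random_wf_mean = mean(rnd["wf", ]), random_wf_ci = ci95(rnd["wf", ]),
      cc_kl = kl_loss_from_partition(ccp, chart, params),
      cc_wf = attr(ccp, "objective"),
      cc_terms = term_count(ccp))
    if (!is.null(human)) {
      hsel <- which(human_tc == k)
      if (length(hsel)) {
        hkl <- vapply(human[hsel], kl_loss_from_partition, numeric(1L),
                      chart = chart, params = params)
        hwf <- vapply(human[hsel], wellformedness, numeric(1L),
                      chart = chart, params = params)
        row$human_n <- length(hsel)
        row$human_kl_mean <- mean(hkl); row$human_kl_ci <- ci95(hkl)
        row$human_wf_mean <- mean(hwf); row$human_wf_ci <- ci95(hwf)
      } else {
        row$human_n <- 0L
        row$human_kl_mean <- row$human_kl_ci <- NA_real_
        row$human_wf_mean <- row$human_wf_ci <- NA_real_
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Internal consistency across vs within noise levels
#'
#' For each vocabulary size: the mean pairwise adjusted Rand index among
#' all partitions that ended up with that term count regardless of noise
#' level ("All"), next to the average of the within-level internal
#' consistencies ("Within noise group"). Similar values in both columns
#' mean the noise level leaves no fingerprint on the partition beyond the
#' vocabulary size it induces.
#'
#' @param sweep a [run_sweep()] result.
#' @return data.frame with columns `term_count`, `n_runs`, `all_mean`,
#'   `all_ci`, `within_mean`, `within_ci` (NA where fewer than two
#'   partitions are available).
#' @export
noise_effect_table <- function(sweep) {
  stopifnot(inherits(sweep, "color_game_sweep"))
  buckets <- bucket_by_terms(sweep)
  rows <- lapply(buckets, function(b) {
    k <- b$term_count; nb <- nrow(b$table)
    all_mean <- all_ci <- within_mean <- within_ci <- NA_real_
    if (nb >= 2L) {
      a <- mean_pairwise_ari(b$partitions)
      all_mean <- a$mean; all_ci <- a$ci_halfwidth
      per_level <- lapply(split(seq_len(nb), b$table$level), function(sel) {
        if (length(sel) < 2L) return(NULL)
        mean_pairwise_ari(b$partitions[sel])$mean
      })
      vals <- unlist(per_level)
      if (length(vals)) {
        within_mean <- mean(vals); within_ci <- ci95(vals)
      }
    }
    data.frame(term_count = k, n_runs = nb, all_mean = all_mean,
               all_ci = all_ci, within_mean = within_mean,
               within_ci = within_ci)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Vocabulary size as a function of noise
#'
#' Mean term count per noise level plus the Spearman rank correlation
#' between level and per-run term count. Rising noise — on either channel
#' — is expected to shrink the vocabulary, i.e. a negative correlation.
#' A constant term count across runs yields correlation 0.
#'
#' @param sweep a [run_sweep()] result (any `vary` channel).
#' @return list with `by_level` (data.frame: level, mean_terms, ci,
#'   n_runs) and `rank_correlation`.
#' @export
vocabulary_vs_noise <- function(sweep) {
  stopifnot(inherits(sweep, "color_game_sweep"))
  tab <- sweep$table
  by_level <- do.call(rbind, lapply(split(tab, tab$level), function(g)
    data.frame(level = g$level[1L], mean_terms = mean(g$term_count),
               ci = ci95(g$term_count), n_runs = nrow(g))))
  by_level <- by_level[order(by_level$level), ]
  rownames(by_level) <- NULL
  rho <- if (stats::sd(tab$term_count) == 0 || stats::sd(tab$level) == 0) 0
         else stats::cor(tab$level, tab$term_count, method = "spearman")
  list(by_level = by_level, rank_correlation = rho)
}

#' Noise-by-vocabulary histogram of a sweep
#'
#' Counts how many runs at each noise level ended with each vocabulary
#' size — the 2-D histogram view of how noise modulates lexicon size.
#'
#' @param sweep a [run_sweep()] result.
#' @return integer matrix, rows = noise levels, columns = term counts.
#' @export
term_histogram <- function(sweep) {
  stopifnot(inherits(sweep, "color_game_sweep"))
  t(table(factor(sweep$table$term_count),
          factor(sweep$table$level, levels = sort(unique(sweep$table$level)))))
}
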