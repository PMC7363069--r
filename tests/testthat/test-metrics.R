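# tiny deterministic system: 4 chips, 2 terms, each term used by 2 chips
four_chip_model <- function() {
  m <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  colnames(m) <- c("dark", "light")
  naming_model(m)
}

test_that("bayes_decoder inverts a naming model under a uniform prior", {
  dec <- bayes_decoder(four_chip_model())
  expect_equal(sort(rownames(dec)), c("dark", "light"))
  expect_equal(unname(dec["dark", ]), c(0.5, 0.5, 0, 0))
  expect_equal(unname(dec["light", ]), c(0, 0, 0.5, 0.5))
  # single term covering all chips: p(c|w) = prior
  one <- naming_model(matrix(1, 5, 1, dimnames = list(NULL, "w")))
  prior <- c(0.4, 0.3, 0.1, 0.1, 0.1)
  expect_equal(unname(bayes_decoder(one, prior)["w", ]), prior)
  # normalization on random fixtures
  set.seed(5)
  for (i in 1:10) {
    raw <- matrix(rexp(6 * 3), 6, 3)
    nm <- naming_model(raw / rowSums(raw))
    expect_equal(unname(rowSums(bayes_decoder(nm))), rep(1, 3))
  }
})

test_that("expected_surprise matches closed forms", {
  m <- four_chip_model()
  dec <- bayes_decoder(m)
  # every chip: -log2(1/2) = 1 bit
  for (c in 0:3) expect_equal(expected_surprise(m, dec, chip = c), 1)
  expect_equal(expected_surprise(m, dec), 1)
  # single term over n chips, uniform prior: log2(n)
  n <- 7
  one <- naming_model(matrix(1, n, 1, dimnames = list(NULL, "w")))
  expect_equal(expected_surprise(one, bayes_decoder(one)), log2(n))
  # one term per chip: 0 bits
  perfect <- naming_model(diag(5))
  expect_equal(expected_surprise(perfect, bayes_decoder(perfect)), 0)
})

test_that("zero decoder mass on a used term yields Inf with a warning", {
  m <- four_chip_model()
  dec <- bayes_decoder(m)
  dec["dark", 1] <- 0
  expect_warning(es <- expected_surprise(m, dec, chip = 0), "zero mass")
  expect_identical(es, Inf)
})

test_that("exemplar decoder normalizes across the universe (global denominator)", {
  set.seed(9)
  ch <- ring_chart(12)
  for (k in c(1, 3, 5)) {
    p <- random_partition(ch, k)
    dec <- partition_decoder(p, ch)
    own <- dec[cbind(match(as.character(p$labels), rownames(dec)),
                     seq_len(p$n))]
    expect_equal(sum(own), 1)           # sum_c p(c | Cat(c)) = 1
    expect_equal(sum(dec), 1)           # all mass lives on own-category cells
  }
  # per-category renormalized variant sums to 1 within each term instead
  p <- random_partition(ch, 3)
  decn <- partition_decoder(p, ch, renormalize = TRUE)
  expect_equal(unname(rowSums(decn)), rep(1, nrow(decn)))
})

test_that("KL loss from a partition matches hand cases", {
  # two identical-coordinate chips in one category: p = 1/2 each, 1 bit
  ch <- chip_chart(rbind(c(10, 10, 10), c(10, 10, 10)), name = "twins")
  p <- color_partition(c("x", "x"), ch)
  expect_equal(kl_loss_from_partition(p, ch), 1)
  expect_equal(kl_loss_from_partition(p, ch, per_chip = TRUE), c(1, 1))
})

test_that("expected surprise equals KL loss for the deterministic indicator model", {
  set.seed(31)
  ch <- ring_chart(9)
  for (k in 2:4) {
    p <- random_partition(ch, k)
    dec <- partition_decoder(p, ch)
    es <- expected_surprise(partition_naming_model(p), dec)
    expect_equal(es, kl_loss_from_partition(p, ch))
  }
})

test_that("wellformedness sums intra-category similarity excesses", {
  # all singletons: no intra edges
  ch <- ring_chart(5)
  singl <- color_partition(1:5, ch)
  expect_equal(wellformedness(singl, ch), 0)
  # two chips with similarity 0.9 grouped: 0.9 - 0.5 = 0.4
  d <- sqrt(-log(0.9) / 0.001)
  ch2 <- chip_chart(rbind(c(0, 0, 0), c(d, 0, 0)), name = "pair")
  expect_equal(wellformedness(color_partition(c(1, 1), ch2), ch2), 0.4)
  # never exceeds the solver optimum
  set.seed(2)
  ch3 <- ring_chart(8)
  opt <- cc_brute_force(build_similarity_graph(ch3),
                        chart_name = attr(ch3, "name"))$objective
  for (k in 1:4) {
    p <- random_partition(ch3, k)
    expect_lte(wellformedness(p, ch3), opt + 1e-10)
  }
})

test_that("adjusted Rand index: identity, hand case, label invariance", {
  ch <- ring_chart(4)
  p1 <- color_partition(c(1, 1, 2, 2), ch)
  expect_equal(adjusted_rand_index(p1, p1), 1)
  p2 <- color_partition(c(1, 2, 1, 2), ch)
  expect_equal(adjusted_rand_index(p1, p2), -0.5)
  relab <- color_partition(c("b", "b", "a", "a"), ch)
  expect_equal(adjusted_rand_index(p1, relab), 1)
  other <- color_partition(1:5, ring_chart(5))
  expect_error(adjusted_rand_index(p1, other), "same chart")
})

test_that("mean ARI of independent random partitions is near zero", {
  ch <- make_synthetic_chart()
  set.seed(77)
  draws <- replicate(300, {
    a <- random_partition(ch, 4)
    b <- random_partition(ch, 4)
    adjusted_rand_index(a, b)
  })
  expect_lt(abs(mean(draws)), 0.01)
})

test_that("mean_pairwise_ari aggregates pairs with a normal CI", {
  ch <- ring_chart(6)
  p <- color_partition(c(1, 1, 2, 2, 3, 3), ch)
  g <- list(p, p, p)
  res <- mean_pairwise_ari(g)           # within-group: 3 identical members
  expect_equal(res$mean, 1)
  expect_equal(res$ci_halfwidth, 0)
  expect_equal(res$n_pairs, 3L)
  # two-member group: single pair, CI flagged undefined
  res2 <- mean_pairwise_ari(list(p, color_partition(c(1, 2, 1, 2, 3, 3), ch)))
  expect_equal(res2$n_pairs, 1L)
  expect_false(res2$ci_defined)
  expect_equal(res2$ci_halfwidth, 0)
  # cross mode: formula check on known values
  q <- color_partition(c(1, 2, 1, 2, 3, 3), ch)
  vals <- c(adjusted_rand_index(p, q), adjusted_rand_index(p, p))
  res3 <- mean_pairwise_ari(list(p), list(q, p))
  expect_equal(res3$mean, mean(vals))
  expect_equal(res3$ci_halfwidth, 1.96 * sd(vals) / sqrt(2))
})

test_that("metric_report bundles the per-partition measures consistently", {
  set.seed(4)
  ch <- ring_chart(10)
  p <- random_partition(ch, 3)
  rep <- metric_report(p, ch)
  expect_equal(rep$term_count, 3L)
  expect_equal(rep$kl_loss, kl_loss_from_partition(p, ch))
  expect_equal(rep$expected_surprise, rep$kl_loss)   # deterministic model
  expect_equal(rep$wellformedness, wellformedness(p, ch))
})
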