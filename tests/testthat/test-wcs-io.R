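write_wcs_chart_fixture <- function(path, n = 5) {
  set.seed(14)
  df <- data.frame(cnum = sample(seq_len(n)),       # unsorted on purpose
                   V = rep("5", n), H = as.character(seq_len(n)),
                   C = rep("8", n),
                   MunH = paste0("R", seq_len(n)), MunV = rep("5", n),
                   check.names = FALSE)
  df[["L*"]] <- round(runif(n, 20, 90), 2)
  df[["a*"]] <- round(runif(n, -40, 40), 2)
  df[["b*"]] <- round(runif(n, -40, 40), 2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

test_that("reading a WCS-style chart table recovers coordinates by chip number", {
  f <- withr::local_tempfile(fileext = ".txt")
  df <- write_wcs_chart_fixture(f, n = 5)
  ch <- read_chip_chart(f, "wcs_lab_table")
  expect_equal(n_chips(ch), 5L)
  expect_equal(ch$chip_id, 0:4)
  expect_equal(ch$wcs_chip, 1:5)                     # sorted on read
  o <- order(df$cnum)
  expect_equal(ch$L, df[["L*"]][o])
  expect_equal(ch$b, df[["b*"]][o])
  expect_equal(ch$munsell_hue, df$MunH[o])
})

test_that("chart reader rejects empty, malformed and duplicated input", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("cnum\tL*\ta*\tb*", f)
  expect_error(read_chip_chart(f, "wcs_lab_table"), "no chip rows")
  writeLines(c("cnum\tL*\ta*\tb*", "1\t50\t0\t0", "x\t60\t1\t1"), f)
  expect_error(read_chip_chart(f, "wcs_lab_table"), "malformed chip row")
  writeLines(c("cnum\tL*\ta*\tb*", "1\t50\t0\t0", "1\t60\t1\t1"), f)
  expect_error(read_chip_chart(f, "wcs_lab_table"), "duplicate chip number")
})

test_that("generic TSV charts round-trip through write_chip_chart", {
  ch <- make_synthetic_chart(n_hues = 4, n_values = 3, n_achromatic = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_chip_chart(ch, f)
  back <- read_chip_chart(f, "generic_tsv")
  expect_equal(n_chips(back), n_chips(ch))
  expect_equal(chip_coords(back), chip_coords(ch), tolerance = 1e-8)
})

test_that("naming data reads, groups, validates and round-trips", {
  ch <- ring_chart(4, name = "nm")
  f <- withr::local_tempfile(fileext = ".txt")
  rows <- c("1\t1\t1\tred", "1\t1\t2\tred", "1\t2\t1\tblue",
            "1\t3\t3\tgreen",
            "2\t1\t1\tuni", "2\t2\t2\tuni", "2\t3\t4\tuni")
  writeLines(rows, f)
  langs <- read_naming_data(f, ch)
  expect_length(langs, 2L)
  expect_equal(length(langs[["1"]]$speakers), 3L)
  expect_equal(length(langs[["2"]]$speakers), 3L)
  expect_setequal(langs[["1"]]$term_inventory, c("red", "blue", "green"))
  # round trip
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_naming_data(langs, f2)
  again <- read_naming_data(f2, ch)
  expect_equal(again, langs)
  # chip outside the chart
  writeLines(c(rows, "1\t1\t999\tred"), f)
  expect_error(read_naming_data(f, ch), "chip 999")
})

test_that("human_mode_map takes the majority term and breaks ties lexicographically", {
  ch <- ring_chart(3, name = "mm")
  resp <- cbind(c("red", "red", "green"),
                c("red", "blue", "green"),
                c("blue", "blue", "green"))   # chips x speakers
  mm <- human_mode_map(naming_from_matrix(resp), ch)
  expect_equal(mm$labels, c("red", "blue", "green"))
  # 2-2 tie resolves to the lexicographically smallest term
  tied <- naming_from_matrix(cbind(c("red", "a", "a"), c("blue", "a", "a")))
  expect_equal(human_mode_map(tied, ch)$labels[1], "blue")
  # unanimous speakers reproduce any single speaker's map
  uni <- naming_from_matrix(cbind(c("a", "b", "a"), c("a", "b", "a")))
  expect_equal(human_mode_map(uni, ch)$labels, c("a", "b", "a"))
})

test_that("mode map reports uncovered chips", {
  ch <- ring_chart(3, name = "cov")
  lang <- naming_from_matrix(cbind(c("x", "y", "z")))
  lang$speakers[[1]]$responses <- lang$speakers[[1]]$responses[c("0", "2")]
  expect_error(human_mode_map(lang, ch), "coverage error.*1")
})

test_that("estimate_p_w_given_c gives empirical fractions that sum to one", {
  ch <- ring_chart(2, name = "freq")
  lang <- naming_from_matrix(cbind(c("red", "x"), c("red", "y"),
                                   c("blue", "y")))
  p <- estimate_p_w_given_c(lang, 0)
  expect_equal(unname(p[order(names(p))]), c(1 / 3, 2 / 3))
  expect_equal(sum(p), 1)
  expect_equal(unname(estimate_p_w_given_c(lang, 1)["y"]), 2 / 3)
  set.seed(20)
  resp <- matrix(sample(letters[1:4], 5 * 6, TRUE), 5, 6)
  lang2 <- naming_from_matrix(resp)
  for (c in 0:4) expect_equal(sum(estimate_p_w_given_c(lang2, c)), 1)
  # unanimity gives a point mass
  expect_equal(unname(estimate_p_w_given_c(
    naming_from_matrix(cbind(c("k", "k"), c("k", "k"))), 1)), 1)
})

test_that("empirical_naming_model assembles a row-stochastic model", {
  ch <- ring_chart(3, name = "enm")
  set.seed(21)
  resp <- matrix(sample(c("u", "v"), 3 * 7, TRUE), 3, 7)
  nm <- empirical_naming_model(naming_from_matrix(resp), ch)
  expect_s3_class(nm, "naming_model")
  expect_equal(unname(rowSums(unclass(nm))), rep(1, 3))
  expect_equal(unname(unclass(nm)[1, "u"]), mean(resp[1, ] == "u"))
})
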