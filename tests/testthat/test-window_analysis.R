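test_that("extract_window fills flank slots and marks terminus overhangs", {
  p <- proteome(c(p1 = "MKSTMA", p2 = "SAAAA"))
  w <- extract_window(p, "p1", 3, 2)
  expect_equal(w$offsets, c(-2L, -1L, 1L, 2L))
  expect_equal(w$flank, c("M", "K", "T", "M"))
  # site at position 1: all negative offsets missing, +5/+6 beyond end
  w2 <- extract_window(p, "p2", 1, 6)
  expect_true(all(is.na(w2$flank[w2$offsets < 0])))
  expect_equal(w2$flank[w2$offsets %in% 1:4], c("A", "A", "A", "A"))
  expect_true(all(is.na(w2$flank[w2$offsets %in% 5:6])))
  # degenerate half-width
  expect_length(extract_window(p, "p1", 3, 0)$flank, 0L)
  expect_error(extract_window(p, "p1", 99, 6), "outside")
})

test_that("has_met applies the amino-terminal Met discount", {
  p <- proteome(c(a = "MKSTMA", b = "MKSAAA"))
  expect_true(has_met(extract_window(p, "a", 3, 2), discount_nterm = TRUE))
  # only Met is the initiator: discounted
  expect_false(has_met(extract_window(p, "b", 3, 2), discount_nterm = TRUE))
  expect_true(has_met(extract_window(p, "b", 3, 2), discount_nterm = FALSE))
})

test_that("met_proximity_table counts per residue and evidence group", {
  p <- proteome(c(a = "AMSAA"))
  sites <- data.frame(protein_id = "a", position = 3L, residue = "S",
                      evidence = "experimental")
  tab <- met_proximity_table(p, sites, 6)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_sites, 1L)
  expect_equal(tab$n_with_met, 1L)
  expect_equal(tab$proportion, 100)
  # a proteome without Met: all proportions zero
  p0 <- proteome(c(a = "ASTSYATSYA"))
  tab0 <- met_proximity_table(p0, enumerate_all_sty(p0), 6)
  expect_true(all(tab0$proportion == 0))
})

test_that("positional distribution matches the single-site reads", {
  p <- proteome(c(a = "AMKSTMA"))  # S at 4; -2:M (pos 2, countable), +2:M
  sites <- data.frame(protein_id = "a", position = 4L, residue = "S",
                      evidence = "experimental")
  pd <- positional_distribution(p, sites, "M", half_width = 2)
  expect_equal(pd$percent[pd$offset == -2], 100)
  expect_equal(pd$percent[pd$offset == 2], 100)
  expect_equal(pd$percent[pd$offset == -1], 0)
  # offsets beyond the terminus have denominator 0 and undefined percent
  pd6 <- positional_distribution(p, sites, "M", half_width = 6)
  expect_equal(pd6$denominator[pd6$offset == -5], 0L)
  expect_true(is.nan(pd6$percent[pd6$offset == -5]))
  # pooled VILF class
  pv <- positional_distribution(proteome(c(a = "AAVSA")),
                                data.frame(protein_id = "a", position = 4L,
                                           residue = "S",
                                           evidence = "experimental"),
                                "VILF", half_width = 1)
  expect_equal(pv$percent[pv$offset == -1], 100)
  expect_equal(pv$percent[pv$offset == 1], 0)
})

test_that("composition discounts the initiator Met from both sides", {
  expect_equal(composition(proteome(c(a = "MMMM")))$percent[11], 100)  # M row
  expect_equal(sum(composition(proteome(c(a = "MMMM")))$count), 3L)
  cm <- composition(proteome(c(a = "MA")))
  expect_equal(cm$percent[cm$residue == "A"], 100)
  expect_equal(cm$percent[cm$residue == "M"], 0)
  cu <- composition(proteome(c(a = "ACDEFGHIKLMNPQRSTVWY")),
                    discount_nterm = FALSE)
  expect_true(all(cu$percent == 5))
  expect_equal(sum(cu$percent), 100)
})

test_that("hydropathy is the mean Kyte-Doolittle value of the flank", {
  p <- proteome(c(g = "GGGGGGSGGGGGG", e = "SI", ri = "RSI"))
  expect_equal(hydropathy_score(extract_window(p, "g", 7, 6)), -0.4)
  expect_equal(hydropathy_score(extract_window(p, "e", 1, 6)), 4.5)
  expect_equal(hydropathy_score(extract_window(p, "ri", 2, 1)), 0.0)
  # all-missing flank is an undefined score, not a number
  expect_true(is.na(hydropathy_score(extract_window(proteome(c(s = "S")),
                                                    "s", 1, 6))))
  # ambiguity codes contribute nothing
  px <- proteome(c(x = "XSI"))
  expect_equal(hydropathy_score(extract_window(px, "x", 2, 1)), 4.5)
})

test_that("window size scan grows monotonically and handles edge cases", {
  p <- proteome(c(a = "AAMASAA"))
  sites <- data.frame(protein_id = "a", position = 5L, residue = "S",
                      evidence = "experimental")
  scan <- window_size_scan(p, sites, 1:3)
  expect_equal(scan$proportion[scan$half_width == 1], 0)
  expect_equal(scan$proportion[scan$half_width == 2], 100)
  expect_equal(nrow(window_size_scan(p, sites[0, ], 1:3)), 0L)
})

test_that("window counts match an independent brute-force scan", {
  for (seed in c(3, 17, 23)) {
    p <- random_test_proteome(n = 8, len = 80, seed = seed)
    sites <- enumerate_all_sty(p)
    for (k in c(2, 6)) {
      for (discount in c(TRUE, FALSE)) {
        tab <- met_proximity_table(p, sites, k, discount)
        expect_equal(sum(tab$n_with_met),
                     brute_met_count(p$sequences, sites, k, discount))
      }
      pd <- positional_distribution(p, sites, "M", k)
      for (off in c(-k, -1, 1, k)) {
        oracle <- brute_positional_count(p$sequences, sites, off, "M")
        expect_equal(pd$count[pd$offset == off], unname(oracle["count"]))
        expect_equal(pd$denominator[pd$offset == off],
                     unname(oracle["denominator"]))
      }
    }
    expect_equal(setNames(composition(p)$count, composition(p)$residue),
                 brute_composition_counts(p$sequences))
  }
})

test_that("discounting only ever removes Met counts", {
  p <- random_test_proteome(n = 6, len = 50, seed = 5)
  sites <- enumerate_all_sty(p)
  on <- met_proximity_table(p, sites, 6, TRUE)
  off <- met_proximity_table(p, sites, 6, FALSE)
  expect_true(all(on$proportion <= off$proportion))
})

test_that("positional denominators count sites with the offset inside", {
  p <- random_test_proteome(n = 5, len = 40, seed = 9)
  sites <- enumerate_all_sty(p)
  lens <- nchar(p$sequences)[sites$protein_id]
  pd <- positional_distribution(p, sites, "M", 6)
  for (off in c(-6, -3, 4, 6)) {
    inside <- sites$position + off >= 1 & sites$position + off <= lens
    expect_equal(pd$denominator[pd$offset == off], sum(inside))
  }
})
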