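make_members <- function(query, others) {
  c(setNames(query, "query_taxon"),
    setNames(others, paste0("tax", seq_along(others))))
}

test_that("families are built only for Met-containing query windows", {
  p <- proteome(c(p1 = "AAAAAMSAAAAAA",   # S at 7, M at offset -1
                  p2 = "AAAAAASAAAAAA"),  # S at 7, no Met
                taxon_label = "query_taxon")
  sites <- data.frame(protein_id = c("p1", "p2"), position = 7L,
                      residue = "S", evidence = "experimental")
  mapping <- data.frame(query_protein_id = "p1", query_position = 7L,
                        taxon_label = c("taxA", "taxB"),
                        aligned_window = c("AAAAAMSAAAAAA", "CCCCCMSCCCCCC"))
  fams <- build_families(p, sites, mapping)
  expect_length(fams, 1L)
  fam <- fams[["p1:7"]]
  expect_equal(fam$met_offsets, -1L)
  expect_length(fam$members, 3L)  # query taxon + 2 members
  expect_equal(names(fam$members)[1], "query_taxon")
})

test_that("short mapping windows are rejected but the family survives", {
  p <- proteome(c(p1 = "AAAAAMSAAAAAA"), taxon_label = "query_taxon")
  sites <- data.frame(protein_id = "p1", position = 7L, residue = "S",
                      evidence = "experimental")
  mapping <- data.frame(query_protein_id = "p1", query_position = 7L,
                        taxon_label = c("taxA", "taxB"),
                        aligned_window = c("AAAAAMSAAAAA",  # 12 chars
                                           "CCCCCMSCCCCCC"))
  expect_message(fams <- build_families(p, sites, mapping), "rejected")
  expect_length(fams[["p1:7"]]$members, 2L)
})

test_that("conservation level counts Met and VILF substitutions", {
  # 8 taxa all with M at offset -3 (window position 4)
  all_m <- tiny_family(make_members("AAAMAASAAAAAA",
                                    rep("CCCMCCSCCCCCC", 7)),
                       met_offsets = -3L)
  r <- conservation_level(all_m, -3)
  expect_equal(r$level, 8L)
  expect_true(is.na(r$vilf_fraction))
  # 6 with M, 2 with V
  six <- tiny_family(make_members("AAAMAASAAAAAA",
                                  c(rep("CCCMCCSCCCCCC", 5),
                                    rep("CCCVCCSCCCCCC", 2))),
                     met_offsets = -3L)
  r6 <- conservation_level(six, -3)
  expect_equal(r6$level, 6L)
  expect_equal(r6$vilf_fraction, 1.0)
  # 4 with M, 2 with L, 2 with G
  four <- tiny_family(make_members("AAAMAASAAAAAA",
                                   c(rep("CCCMCCSCCCCCC", 3),
                                     rep("CCCLCCSCCCCCC", 2),
                                     rep("CCCGCCSCCCCCC", 2))),
                      met_offsets = -3L)
  r4 <- conservation_level(four, -3)
  expect_equal(r4$level, 4L)
  expect_equal(r4$vilf_fraction, 0.5)
  # gaps count as neither Met nor VILF
  gap <- tiny_family(make_members("AAAMAASAAAAAA", "CCC-CCSCCCCCC"),
                     met_offsets = -3L)
  expect_equal(conservation_level(gap, -3)$vilf_fraction, 0)
  expect_error(conservation_level(all_m, 2), "not a Met offset")
})

test_that("level is invariant under member permutation and VILF grows", {
  others <- c("CCCMCCSCCCCCC", "CCCVCCSCCCCCC", "CCCGCCSCCCCCC",
              "CCCMCCSCCCCCC", "CCCICCSCCCCCC")
  base <- conservation_level(
    tiny_family(make_members("AAAMAASAAAAAA", others), -3L), -3)
  set.seed(2)
  for (i in 1:5) {
    fam <- tiny_family(make_members("AAAMAASAAAAAA", sample(others)), -3L)
    r <- conservation_level(fam, -3)
    expect_equal(r$level, base$level)
    expect_equal(r$vilf_fraction, base$vilf_fraction)
  }
  # replacing a non-VILF member residue by Leu raises the VILF fraction
  others2 <- others
  others2[3] <- "CCCLCCSCCCCCC"
  r2 <- conservation_level(
    tiny_family(make_members("AAAMAASAAAAAA", others2), -3L), -3)
  expect_gt(r2$vilf_fraction, base$vilf_fraction)
})

test_that("heatmap proportions sum to one and recover toy level sets", {
  recs <- data.frame(family_id = paste0("f", 1:4), offset = -1L,
                     n_taxa = 8L, level = c(8L, 8L, 4L, 4L),
                     vilf_fraction = c(NA, NA, 0.5, 1))
  h <- conservation_heatmap(recs)
  expect_equal(sum(h$proportion), 1)
  expect_equal(h$proportion[h$level == 8], 0.5)
  expect_equal(h$proportion[h$level == 4], 0.5)
  expect_equal(h$mean_vilf_fraction[h$level == 4], 0.75)
  one <- conservation_heatmap(recs[1, ])
  expect_equal(one$proportion[one$level == 8], 1)
  expect_equal(nrow(conservation_heatmap(recs[0, ])), 0L)
})

test_that("crosstalk scenarios follow the conservation rules", {
  centers_ok <- function(win) win  # member windows with S centre
  # fully conserved Met, conserved site
  reg <- tiny_family(make_members("AAAMAASAAAAAA", rep("CCCMCCSCCCCCC", 7)),
                     -3L)
  expect_equal(classify_scenario(reg, -3)$scenario, "regulatory_candidate")
  # level 3, five VILF substitutions, conserved site
  struct <- tiny_family(make_members("AAAMAASAAAAAA",
                                     c(rep("CCCMCCSCCCCCC", 2),
                                       rep("CCCVCCSCCCCCC", 5))), -3L)
  expect_equal(classify_scenario(struct, -3)$scenario,
               "structural_hydrophobic")
  # Met fully conserved but centre S/T/Y in only 2 of 8
  site_lost <- tiny_family(make_members("AAAMAASAAAAAA",
                                        c("CCCMCCSCCCCCC",
                                          rep("CCCMCCGCCCCCC", 6))), -3L)
  expect_equal(classify_scenario(site_lost, -3)$scenario,
               "site_not_conserved")
  # site conserved, Met gone without hydrophobic replacement
  met_lost <- tiny_family(make_members("AAAMAASAAAAAA",
                                       rep("CCCGCCSCCCCCC", 7)), -3L)
  expect_equal(classify_scenario(met_lost, -3)$scenario, "met_not_conserved")
  # both gone
  neither <- tiny_family(make_members("AAAMAASAAAAAA",
                                      rep("CCCGCCGCCCCCC", 7)), -3L)
  expect_equal(classify_scenario(neither, -3)$scenario, "neither_conserved")
})

test_that("toy matcher returns centre-aligned best hits with tie-breaks", {
  q <- proteome(c(q1 = "AAAAAAMSAAAAAA"), taxon_label = "query")
  sites <- data.frame(protein_id = "q1", position = 8L, residue = "S",
                      evidence = "experimental")
  # subject contains the exact query window
  subj <- proteome(c(s1 = paste0("GGGG", "AAAAAMSAAAAAA", "GGGG")),
                   taxon_label = "subject")
  hits <- toy_homolog_matcher(q, sites, subj, min_identity = 1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1)
  expect_equal(hits$aligned_window, "AAAAAMSAAAAAA")
  # no exact window anywhere
  none <- toy_homolog_matcher(q, sites,
                              proteome(c(s1 = "GGGGGGGGGGGGGGGG"),
                                       taxon_label = "subject"),
                              min_identity = 1)
  expect_equal(nrow(none), 0L)
  # two equal-identity hits: first by (protein id, position) wins
  tie <- proteome(c(s2 = paste0("AAAAAMSAAAAAA", "TTTT", "AAAAAMSAAAAAA"),
                    s1 = paste0("CCCC", "AAAAAMSAAAAAA")),
                  taxon_label = "subject")
  th <- toy_homolog_matcher(q, sites, tie, min_identity = 1)
  expect_equal(th$aligned_window, "AAAAAMSAAAAAA")
  # s1 sorts before s2, so the s1 occurrence is the reported one
  expect_equal(nrow(th), 1L)
})
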