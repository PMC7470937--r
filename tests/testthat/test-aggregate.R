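test_that("refcode families strip only CSD-style numeric suffixes", {
  expect_equal(family_key("ABCDEF01"), "ABCDEF")
  expect_equal(family_key("ABCDEF12"), "ABCDEF")
  expect_equal(family_key("URACIL"), "URACIL")
  expect_equal(family_key("fixture_7.cif"), "fixture_7.cif")
  expect_equal(family_key("KTHYMT"), "KTHYMT")
})

test_that("frequencies count one occurrence per family and pair type", {
  rec <- data.frame(
    structure_id = c("ABCDEF01", "ABCDEF02", "ABCDEF03", "XYZQRS", "XYZQRS"),
    base = "A",
    pair_name = c("AA_mWW_(16)(61)", "AA_mWW_(16)(61)", "AA_mWW_(16)(61)",
                  "AA_mWW_(16)(61)", "AA_mHH_(67)(76)"),
    pattern_class = "1 3 7 9R",
    stringsAsFactors = FALSE)
  rec$family <- family_key(rec$structure_id)
  tab <- tabulate_frequencies(rec)
  # 3 depositions of one family collapse to 1; a structure with two pair
  # types counts once in each
  expect_equal(tab$counts$n[tab$counts$pair_name == "AA_mWW_(16)(61)"], 2)
  expect_equal(tab$counts$n[tab$counts$pair_name == "AA_mHH_(67)(76)"], 1)
  expect_equal(unname(tab$totals["A"]), 3)

  empty <- tabulate_frequencies(rec[0, ])
  expect_equal(nrow(empty$counts), 0)
})

test_that("the printed protonation tables reproduce their grand totals", {
  pt <- printed_table_records(printed_tables())
  tab <- tabulate_frequencies(pt$records)
  # guanine: the printed cells sum to 104 (the published Sum row's "No R?"
  # column undercounts its own cells by one)
  expect_equal(unname(tab$totals[c("A", "G", "Hx", "T", "U", "C")]),
               c(325, 104, 14, 142, 120, 119))
})

test_that("cross-tabs reproduce printed row sums and marks", {
  pt <- printed_table_records(printed_tables())
  xa <- protonation_crosstab(pt$records, "A", template = pt$template)
  expect_equal(unname(xa$row_sums["AA_fWH_(16)(67)"]), 106)
  expect_equal(unname(xa$row_sums["AA_mHH_(67)(76)"]), 86)
  expect_equal(xa$grand_total, 325)
  expect_equal(xa$table["AA_fWS_(19)(63)", "1 3 7 9R"], "NA")
  expect_equal(xa$table["AA_mWW_(12)(21)", "1H 3 7 9R"], "-")

  xu <- protonation_crosstab(pt$records, "U", template = pt$template)
  expect_equal(xu$grand_total, 120)
  expect_equal(unname(xu$col_sums), c(107, 9, 4, 0))
})

test_that("category percentages match the printed shares", {
  pt <- printed_table_records(printed_tables())
  tab <- tabulate_frequencies(pt$records)
  expect_equal(round(percentage(tab, "CC_mWW_(24)(33)(42)", "substituted"), 1), 38.6)
  expect_equal(round(percentage(tab, "CC_mWW_(34)(43)", "substituted"), 1), 42.1)
  expect_equal(round(percentage(tab, "CC_fWH_(24)(35)", "substituted"), 1), 15.8)
  expect_equal(round(percentage(tab, "CC_mWW_(24)(33)(42)", "free"), 1), 64.5)
  expect_equal(round(percentage(tab, "CC_mSS_(12)(21)", "free"), 1), 29.0)
  expect_equal(round(percentage(tab, "UU_fWH_(34)(45)", "substituted"), 2), 51.72)
  expect_equal(round(percentage(tab, "UU_mWW_(34)(43)", "substituted"), 2), 21.55)
  expect_equal(round(percentage(tab, "AA_mHH_(67)(76)", "substituted"), 2), 24.60)
  expect_equal(round(percentage(tab, "AA_mSS_(23)(32)", "substituted"), 2), 3.97)
})

test_that("percentages sum to 100 within each category", {
  pt <- printed_table_records(printed_tables())
  tab <- tabulate_frequencies(pt$records)
  for (b in c("A", "G", "T", "U", "C")) {
    rows <- tab$counts[tab$counts$base == b, ]
    for (categ in c("all", "substituted", "free")) {
      pcts <- vapply(unique(rows$pair_name), function(nm)
        tryCatch(percentage(tab, nm, categ), error = function(e) 0),
        numeric(1))
      expect_equal(sum(pcts), 100, tolerance = 1e-8,
                   label = paste(b, categ))
    }
  }
})

test_that("geometry statistics pool depositions but respect missing H", {
  bonds <- data.frame(
    structure_id = c("S1", "S2", "S3"),
    pair_name = "AA_mWW_(16)(61)",
    bond = "16", class = "N-H...N",
    d_a = c(2.8, 2.9, 3.0),
    d_h = c(1.009, 1.009, NA), h_a = c(1.9, 2.0, NA),
    dha = c(170, 165, NA),  # S3 has no modelled hydrogens
    interplanar = 0, c1_c1 = c(8.8, 9.0, 9.2),
    stringsAsFactors = FALSE)
  st <- geometry_stats(bonds, "AA_mWW_(16)(61)")
  da <- st$by_class[st$by_class$metric == "d_a", ]
  expect_equal(da$n, 3)
  expect_equal(da$mean, 2.9)
  expect_equal(da$min, 2.8)
  expect_equal(da$max, 3.0)
  dha <- st$by_class[st$by_class$metric == "dha", ]
  expect_equal(dha$n, 2)  # the H-less deposition is excluded here
  expect_equal(st$c1_c1[["n"]], 3)
  expect_equal(st$c1_c1[["mean"]], 9.0)

  one <- geometry_stats(bonds[1, ], "AA_mWW_(16)(61)")
  expect_true(is.na(one$by_class$sd[one$by_class$metric == "d_a"]))
  expect_error(geometry_stats(bonds, "GG_mWW_(16)(61)"), "no geometry")
})

test_that("survey_scan flattens detected pairs into records", {
  sv <- survey_scan(list(build_pair("AA_mWW_(16)(61)"),
                         build_pair("CC_mWW_(23)(32)")))
  expect_equal(nrow(sv$records), 2)
  expect_setequal(sv$records$pair_name,
                  c("AA_mWW_(16)(61)", "CC_mWW_(23)(32)"))
  expect_equal(sv$records$charge_state[sv$records$base == "A"], "neutral")
  # both cytosines are N3-protonated cations
  expect_equal(sv$records$charge_state[sv$records$base == "C"], "charged")
  expect_equal(sv$records$pattern_class[sv$records$base == "C"], "1R 3H")
  expect_true(all(c("d_a", "dha", "c1_c1") %in% names(sv$bonds)))
})
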