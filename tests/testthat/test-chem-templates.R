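test_that("templates have the right ring systems and glycosidic atoms", {
  for (code in c("A", "G", "Hx")) {
    tpl <- get_template(code)
    expect_equal(sum(tpl$atoms$ring), 9)
    expect_equal(tpl$glycosidic, "9")
  }
  for (code in c("T", "U", "C")) {
    tpl <- get_template(code)
    expect_equal(sum(tpl$atoms$ring), 6)
    expect_equal(tpl$glycosidic, "1")
  }
  # hexagon circuit closes: bond 6-1 present in every template
  for (code in base_codes()) {
    b <- get_template(code)$bonds
    expect_true(any((b[, 1] == "6" & b[, 2] == "1") |
                      (b[, 1] == "1" & b[, 2] == "6")))
  }
  expect_error(get_template("X"), "unsupported base")
})

test_that("edge memberships match the figure conventions", {
  expect_equal(edges_of_atom("A", 1), "W")
  expect_setequal(edges_of_atom("U", 4), c("W", "H"))
  expect_setequal(edges_of_atom("Hx", 8), c("H", "S"))
  # purine C4/C5 sit on no edge
  expect_length(edges_of_atom("A", 4), 0)
  expect_length(edges_of_atom("G", 5), 0)
  expect_equal(assign_edge("G", c(2, 1, 6)), "W")
  expect_equal(assign_edge("Hx", c(8, 9)), "S")
  # shared atom resolved by W > H > S precedence
  expect_equal(assign_edge("A", 6), "W")
})

test_that("every catalogued pair name is edge-consistent", {
  cat <- pair_catalog()
  expect_equal(nrow(cat), 47)
  for (nm in cat$name) {
    pn <- parse_name(nm)
    for (side in 1:2) {
      atoms <- unique(pn$bonds[, side])
      e <- assign_edge(pn$codes[side], atoms)
      expect_equal(e, pn$edges[side],
                   label = paste(nm, "side", side))
      for (a in atoms)
        expect_true(pn$edges[side] %in% edges_of_atom(pn$codes[side], a),
                    label = paste(nm, "atom", a))
    }
  }
})

test_that("donor/acceptor roles follow protonation", {
  r <- donor_acceptor_roles("1H 3 7 9R", "A")
  expect_true(r$donor[r$n == 1])
  expect_true(r$acceptor[r$n == 3])
  expect_true(r$acceptor[r$n == 7])
  expect_true(r$donor[r$n == 6])    # amino
  expect_false(r$donor[r$n == 9])   # substituted
  expect_false(r$acceptor[r$n == 9])

  r <- donor_acceptor_roles("1R 3H", "T")
  expect_true(r$donor[r$n == 3])
  expect_true(all(r$acceptor[r$n %in% c(2, 4)]))
  # thymine position 5 donates only through the methyl hydrogens
  expect_true(r$donor[r$n == 5] && r$weak[r$n == 5] && r$element[r$n == 5] == "C")

  r <- donor_acceptor_roles("1 3H", "T")
  expect_true(r$acceptor[r$n == 1])  # deprotonated N1
  expect_true(r$donor[r$n == 3])

  # unknown protonation: ring N capability union
  r <- donor_acceptor_roles("No R?", "C")
  expect_true(r$donor[r$n == 1] && r$acceptor[r$n == 1])

  expect_error(donor_acceptor_roles("1H 3 7", "A"), "does not list")
})

test_that("neutral references give zero charge for every canonical form", {
  expect_equal(neutral_nh_reference("C", "R"), integer(0))
  expect_setequal(neutral_nh_reference("G", "free"), c(1, 9))
  expect_setequal(neutral_nh_reference("T", "free"), c(1, 3))
  for (code in base_codes()) for (sub in c("R", "free")) {
    pat <- make_protonation(code, neutral_nh_reference(code, sub), sub)
    expect_equal(pattern_charge(code, pat), 0,
                 label = paste(code, sub, pat))
  }
})

test_that("protonation pattern charges match the survey conventions", {
  expect_equal(pattern_charge("A", "1H 3 7 9H"), 1L)
  expect_equal(pattern_charge("A", "1H 3 7H 9H"), 2L)
  expect_equal(pattern_charge("T", "1 3H"), -1L)
  expect_equal(pattern_charge("C", "1R 3H"), 1L)
  expect_equal(pattern_charge("G", "1 3H 7H 9R"), 1L)
  expect_true(is.na(pattern_charge("C", "R?")))
  expect_true(is.na(pattern_charge("A", "No R?")))
})
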