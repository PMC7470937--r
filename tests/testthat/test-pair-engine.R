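test_that("face-labelled plane normals follow the ring circuit", {
  s <- ideal_base("A", "R", "1 3 7 9R")
  b <- find_bases(s)[[1]]
  expect_equal(base_plane(b)$normal, c(0, 0, 1), tolerance = 1e-9)
  # reflect through z = 0: the face flips
  s2 <- s
  s2$atoms$z <- -s2$atoms$z
  s2$atoms$y <- -s2$atoms$y  # proper rotation about x, flips the circuit
  b2 <- find_bases(crystal_structure("flip", s2$atoms))[[1]]
  expect_equal(base_plane(b2)$normal, c(0, 0, -1), tolerance = 1e-9)
  # mild puckering noise: normal still close to z (SVD plane-fit oracle)
  set.seed(7)
  s3 <- s
  s3$atoms$z <- s3$atoms$z + rnorm(nrow(s3$atoms), 0, 0.05)
  b3 <- find_bases(crystal_structure("noisy", s3$atoms))[[1]]
  expect_gt(abs(base_plane(b3)$normal[3]), 0.99)
  ring <- coords(s3)[unlist(b3$atom_map[as.character(1:6)]), ]
  expect_gt(abs(sum(base_plane(b3)$normal * oracle_plane(ring))), 0.999)
})

test_that("distance acceptance follows the van der Waals sum plus margin", {
  # N donor / N acceptor bound is 1.55 + 1.55 + 1.0 = 4.10 A
  near <- build_pair("AA_mWW_(16)(61)", target_da = 4.0)
  expect_length(detect_pairs(near), 1)
  far <- build_pair("AA_mWW_(16)(61)", target_da = 4.2)
  expect_length(detect_pairs(far), 0)
})

test_that("bonds below the 120 degree donor angle floor are dropped", {
  s0 <- build_pair("CC_fWH_(24)(35)")
  fix <- attr(s0, "fixture")
  ss <- infer_bonds(s0)
  inst <- find_bases(ss)
  hb0 <- detect_hbonds(ss, inst[[1]], inst[[2]])
  expect_setequal(paste(hb0$n1, hb0$n2), c("2 4", "3 5"))
  expect_true(all(hb0$dha >= 120))
  # rotate base 2 in-plane about its own C5: the C5...N3 distance is
  # unchanged but the C5-H points progressively away until the measured
  # angle drops below the floor and the bond disappears
  xyz0 <- coords(s0)
  c5 <- xyz0[fix$map2[["5"]], ]
  checked <- FALSE
  for (deg in seq(10, 90, by = 10)) {
    rot <- pairdex:::.rot_z(pairdex:::.deg2rad(deg))
    s <- s0
    xyz <- xyz0
    rows <- fix$rows2
    xyz[rows, ] <- sweep(t(rot %*% t(sweep(xyz0[rows, , drop = FALSE], 2, c5))),
                         2, c5, "+")
    s$atoms[, c("x", "y", "z")] <- xyz
    s$bonds <- NULL
    ss2 <- infer_bonds(s)
    inst2 <- find_bases(ss2)
    if (length(inst2) != 2) break
    hb <- detect_hbonds(ss2, inst2[[1]], inst2[[2]])
    h5 <- inst2[[2]]$h_map[["5"]]
    dha <- max(vapply(h5, function(h) pairdex:::.angle3(
      coords(ss2)[inst2[[2]]$atom_map[["5"]], ], coords(ss2)[h, ],
      coords(ss2)[inst2[[1]]$atom_map[["3"]], ]), 0))
    if (dha < 115) {
      expect_false("3 5" %in% paste(hb$n1, hb$n2))
      checked <- TRUE
      break
    }
  }
  expect_true(checked)
})

test_that("D-H normalization extends X-ray hydrogens without moving D...A", {
  d <- c(0, 0, 0)
  a <- c(2.9, 0, 0)
  h <- c(0.86, 0, 0)  # collinear, X-ray-like N-H
  out <- normalize_dh(d, h, a, "N")
  expect_equal(out$d_h, 1.009)
  expect_equal(out$h_a, 2.9 - 1.009)
  expect_equal(out$dha, 180)
  # idempotence at the neutron length
  out2 <- normalize_dh(d, out$h, a, "N")
  expect_equal(out2$h, out$h, tolerance = 1e-9)
  # bent geometry: angle recomputed about the new H
  h3 <- c(0.5, 0.7, 0)
  out3 <- normalize_dh(d, h3, a, "O")
  expect_equal(out3$d_h, 0.983)
  expect_equal(out3$dha, pairdex:::.angle3(d, out3$h, a))
  expect_equal(sqrt(sum((a - d)^2)), 2.9)
})

test_that("detection equals the brute-force oracle on fixture pairs", {
  for (nm in c("AA_fWH_(16)(67)", "GG_mSS_(23)(32)", "UU_fWH_(34)(45)",
               "CC_mWW_(24)(33)(42)", "HxHx_fWH_(17)(26)")) {
    s <- infer_bonds(build_pair(nm))
    inst <- find_bases(s)
    hb <- detect_hbonds(s, inst[[1]], inst[[2]])
    orc <- oracle_contacts(s, inst[[1]], inst[[2]])
    expect_setequal(paste(hb$n1, hb$n2), paste(orc$n1, orc$n2))
    expect_equal(sort(hb$d_a), sort(orc$d), tolerance = 1e-9)
  }
})

test_that("tightening the criteria never increases the pair count", {
  default <- geometry_params()
  tight_d <- geometry_params(da_margin = 0.2)
  tight_p <- geometry_params(plane_angle_max = 20)
  for (nm in c("AA_mWW_(16)(61)", "UU_fWH_(34)(45)", "GG_fWH_(26)(17)(68)")) {
    s <- build_pair(nm)
    n0 <- length(detect_pairs(s, default))
    expect_lte(length(detect_pairs(s, tight_d)), n0)
    expect_lte(length(detect_pairs(s, tight_p)), n0)
  }
})

test_that("swap-symmetric pairs have exactly equivalent bonds", {
  for (nm in c("AA_mWW_(16)(61)", "UU_mWW_(34)(43)", "CC_mSS_(12)(21)",
               "AA_mHH_(67)(76)")) {
    pr <- detect_pairs(build_pair(nm))[[1]]
    expect_equal(nrow(pr$hbonds), 2)
    expect_lt(abs(pr$hbonds$d_a[1] - pr$hbonds$d_a[2]), 1e-6)
    expect_lt(abs(pr$hbonds$dha[1] - pr$hbonds$dha[2]), 1e-4)
  }
})

test_that("rigid motions leave detection and naming unchanged", {
  set.seed(99)
  for (nm in c("AA_fWS_(19)(63)", "TT_mWW_(23)(32)")) {
    s <- build_pair(nm)
    ref <- detect_pairs(s)[[1]]
    for (k in 1:3) {
      pm <- detect_pairs(rigid_motion(s))
      expect_length(pm, 1)
      expect_true(same_pair_name(pm[[1]]$name, ref$name))
      expect_equal(sort(pm[[1]]$hbonds$d_a), sort(ref$hbonds$d_a),
                   tolerance = 1e-6)
    }
  }
})

test_that("pair geometry records C1'...C1' only for substituted pairs", {
  pr <- detect_pairs(build_pair("AA_mWW_(16)(61)"))[[1]]
  g <- pair_geometry(pr)
  s <- build_pair("AA_mWW_(16)(61)")
  fix <- attr(s, "fixture")
  c1 <- coords(s)[fix$map1$c1, ]
  c2 <- coords(s)[fix$map2$c1, ]
  expect_equal(g$c1_c1, sqrt(sum((c1 - c2)^2)), tolerance = 1e-6)
  expect_lt(g$interplanar_angle, 1)

  free <- detect_pairs(build_pair("AA_mSS_(39)(93)"))[[1]]
  expect_true(is.na(pair_geometry(free)$c1_c1))
})

test_that("orientation classifies by face-normal parallelism", {
  for (nm in c("AA_mWW_(12)(21)", "GG_mHH_(67)(76)")) {
    pr <- detect_pairs(build_pair(nm))[[1]]
    expect_equal(orientation(pr$base1, pr$base2), "m", label = nm)
  }
  for (nm in c("AA_fWH_(16)(67)", "UU_fWW_(23)(34)")) {
    pr <- detect_pairs(build_pair(nm))[[1]]
    expect_equal(orientation(pr$base1, pr$base2), "f", label = nm)
  }
})

test_that("one shared hydrogen bond does not make a pair", {
  # build the pair with one bond in range and the other beyond the vdW + 1
  # bound: a lone hydrogen bond is below the pair threshold
  s <- build_pair("GG_mWH_(16)(27)", target_da = c(2.9, 4.3))
  ss <- infer_bonds(s)
  inst <- find_bases(ss)
  expect_length(inst, 2)
  hb <- detect_hbonds(ss, inst[[1]], inst[[2]])
  expect_equal(nrow(hb), 1)
  expect_length(detect_pairs(s), 0)
})
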