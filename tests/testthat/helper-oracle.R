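# Independent brute-force oracle for hydrogen-bond and pair detection,
# written directly from the acceptance criteria (own constants, own
# geometry code) so it shares no code path with the package.

oracle_bondi <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52)

oracle_plane <- function(pts) {
  ctr <- colMeans(pts)
  prcomp(pts)$rotation[, 3]
}

oracle_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# all accepted donor->acceptor contacts between two recognized bases,
# enumerated directly: D...A within Bondi sum + 1 A, D...A vector within 45
# deg of both ring planes, D-H...A >= 120 when the donor carries hydrogen
oracle_contacts <- function(s, b1, b2) {
  xyz <- coords(s)
  roles <- list(donor_acceptor_roles(b1$protonation, b1$code),
                donor_acceptor_roles(b2$protonation, b2$code))
  inst <- list(b1, b2)
  planes <- lapply(inst, function(b) {
    ring <- b$atom_map[as.character(1:6)]
    oracle_plane(xyz[unlist(ring), , drop = FALSE])
  })
  out <- NULL
  for (ds in 1:2) {
    as_ <- 3 - ds
    rd <- roles[[ds]]; ra <- roles[[as_]]
    for (i in which(rd$donor)) for (j in which(ra$acceptor)) {
      d_idx <- inst[[ds]]$atom_map[[rd$id[i]]]
      a_idx <- inst[[as_]]$atom_map[[ra$id[j]]]
      v <- xyz[a_idx, ] - xyz[d_idx, ]
      d <- sqrt(sum(v^2))
      if (d > oracle_bondi[rd$element[i]] + oracle_bondi[ra$element[j]] + 1.0)
        next
      ok_plane <- all(vapply(planes, function(n)
        asin(min(1, abs(sum(v * n) / d))) * 180 / pi < 45, TRUE))
      if (!ok_plane) next
      hs <- inst[[ds]]$h_map[[rd$id[i]]]
      if (length(hs)) {
        # extend D-H to the neutron reference before measuring the angle
        ref <- c(C = 1.083, N = 1.009, O = 0.983)[rd$element[i]]
        best <- max(vapply(hs, function(h) {
          hv <- xyz[h, ] - xyz[d_idx, ]
          hn <- xyz[d_idx, ] + hv / sqrt(sum(hv^2)) * ref
          oracle_angle(xyz[d_idx, ], hn, xyz[a_idx, ])
        }, 0))
        if (best < 120) next
      }
      n1 <- if (ds == 1) rd$n[i] else ra$n[j]
      n2 <- if (ds == 1) ra$n[j] else rd$n[i]
      out <- rbind(out, data.frame(n1 = n1, n2 = n2, d = d))
    }
  }
  if (is.null(out)) return(out)
  out <- out[!duplicated(out[, c("n1", "n2")]), , drop = FALSE]
  # one bond per atom per side, shortest first
  out <- out[order(out$d), , drop = FALSE]
  u1 <- integer(0); u2 <- integer(0); keep <- logical(nrow(out))
  for (k in seq_len(nrow(out))) {
    if (out$n1[k] %in% u1 || out$n2[k] %in% u2) next
    keep[k] <- TRUE
    u1 <- c(u1, out$n1[k]); u2 <- c(u2, out$n2[k])
  }
  out[keep, , drop = FALSE]
}

# random rigid motion of a structure (rotation from QR of a Gaussian
# matrix, translation up to 10 A)
rigid_motion <- function(s) {
  M <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  tv <- runif(3, -10, 10)
  xyz <- sweep(coords(s) %*% t(Q), 2, tv, "+")
  s$atoms[, c("x", "y", "z")] <- xyz
  s$bonds <- NULL
  s
}

shuffle_atoms <- function(s) {
  ord <- sample(nrow(s$atoms))
  s$atoms <- s$atoms[ord, , drop = FALSE]
  rownames(s$atoms) <- NULL
  s$bonds <- NULL
  s
}

# small CIF text fixture with two disorder groups
disorder_cif <- function(path) {
  writeLines(c(
    "data_disorder_test",
    "_cell_length_a 20", "_cell_length_b 20", "_cell_length_c 20",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", "_symmetry_equiv_pos_as_xyz", "'x,y,z'",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "_atom_site_occupancy", "_atom_site_disorder_group",
    "C1 C 0.10 0.10 0.10 1.00 .",
    "N1A N 0.17 0.10 0.10 0.70 1",
    "N1B N 0.10 0.17 0.10 0.30 2"
  ), path)
  path
}
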