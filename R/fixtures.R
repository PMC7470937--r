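# Synthetic-structure generator: idealized planar nucleobases and
# constructed base pairs for every catalogued homo-pair type.
#
# Ring skeletons are regular polygons with 1.39 A sides (hexagon, and for
# purines a pentagon fused on the C4-C5 edge); exocyclic groups sit on the
# radial direction at standard lengths (C=O 1.23, C-N 1.34, C-C 1.50 A);
# hydrogens are placed at the neutron reference lengths.  The second base of
# a pair is positioned by a rigid in-plane motion (plus a flip about an
# in-plane axis for f-orientation pairs) optimized so every named
# donor/acceptor contact sits at its target distance, coplanar, clash-free,
# and with no unintended contact qualifying as a hydrogen bond.

.ring_bond <- 1.39
.len_exo <- c(carbonyl = 1.23, amino = 1.34, methyl = 1.50)
.len_c1 <- 1.47
.len_nh <- 1.009
.len_ch <- 1.083

.regular_ring <- function(n, side) {
  R <- side / (2 * sin(pi / n))
  ang <- (seq_len(n) - 1) * 2 * pi / n
  cbind(R * cos(ang), R * sin(ang), 0)
}

.rot2 <- function(v, a) {
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2], v[3])
}

# intersection points of two circles in the plane (0, 1 or 2 points)
.circle_intersect <- function(c1, r1, c2, r2) {
  dd <- sqrt(sum((c1 - c2)^2))
  if (dd < 1e-9 || dd > r1 + r2 || dd < abs(r1 - r2)) return(list())
  a <- (r1^2 - r2^2 + dd^2) / (2 * dd)
  h2 <- r1^2 - a^2
  if (h2 < 0) return(list())
  h <- sqrt(h2)
  u <- (c2 - c1) / dd
  v <- c(-u[2], u[1])
  base <- c1 + a * u
  if (h < 1e-9) list(base) else list(base + h * v, base - h * v)
}

# planar heavy-atom frame of one base: named coordinate rows (template ids)
# plus the radial centre used for each peripheral direction
.base_frame <- function(code) {
  key <- paste0("frame_", code)
  if (!is.null(.pd_cache[[key]])) return(.pd_cache[[key]])
  tpl <- get_template(code)
  hex <- .regular_ring(6, .ring_bond)
  xyz <- hex
  rownames(xyz) <- as.character(1:6)
  centers <- list(hex = c(0, 0, 0))
  if (tpl$kind == "purine") {
    p4 <- hex[4, ]; p5 <- hex[5, ]
    mid <- (p4 + p5) / 2
    u <- .unit(c(mid[1], mid[2], 0))
    pc <- mid + u * (.ring_bond / (2 * tan(pi / 5)))
    phi <- 2 * pi / 5
    if (.vnorm(.rot2(p4 - pc, 4 * phi) + pc - p5) > 1e-6) phi <- -phi
    n9 <- .rot2(p4 - pc, phi) + pc
    c8 <- .rot2(p4 - pc, 2 * phi) + pc
    n7 <- .rot2(p4 - pc, 3 * phi) + pc
    xyz <- rbind(xyz, "9" = n9, "8" = c8, "7" = n7)
    centers$pent <- pc
  }
  radial_center <- function(pos) {
    if (pos %in% c("7", "8", "9")) centers$pent else centers$hex
  }
  for (i in which(!tpl$atoms$ring)) {
    a <- tpl$atoms[i, ]
    at <- xyz[a$pos, ]
    dir <- .unit(at - radial_center(a$pos))
    xyz <- rbind(xyz, at + dir * .len_exo[[a$kind]])
    rownames(xyz)[nrow(xyz)] <- a$id
  }
  out <- list(xyz = xyz[tpl$atoms$id, , drop = FALSE], centers = centers,
              radial = function(pos) {
                .unit(xyz[pos, ] - radial_center(pos))
              })
  .pd_cache[[key]] <- out
  out
}

.methyl_h <- function(cm, attach) {
  v <- .unit(cm - attach)
  e2 <- .unit(c(-v[2], v[1], 0))
  e3 <- c(0, 0, 1)
  A <- .deg2rad(180 - 109.47)
  t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(az)
    cm + .len_ch * (cos(A) * v + sin(A) * (cos(az) * e2 + sin(az) * e3)),
    numeric(3)))
}

#' Build an idealized nucleobase
#'
#' Planar base in the z = 0 plane with standard ring geometry.  A glycosidic
#' substituent (`substitution = "R"`) is realized as a methyl carbon;
#' hydrogens are placed in-plane according to the protonation pattern (none
#' at all for the `"R?"` / `"No R?"` patterns, emulating structures without
#' determined hydrogen positions).
#'
#' @param code Base code.
#' @param substitution `"R"` or `"free"`.
#' @param protonation Pattern text consistent with `substitution`.
#' @param id Structure id.
#' @return A [crystal_structure()] without a cell.  The attribute `"rows"`
#'   maps template atom ids (plus `"c1"`) to atom rows.
#' @export
ideal_base <- function(code, substitution = c("R", "free"), protonation = NULL,
                       id = NULL) {
  substitution <- match.arg(substitution)
  tpl <- get_template(code)
  if (is.null(protonation))
    protonation <- make_protonation(
      code, neutral_nh_reference(code, substitution), substitution)
  p <- parse_protonation(protonation, code)
  if (p$substitution != substitution)
    stop("protonation pattern '", protonation, "' is inconsistent with ",
         "substitution '", substitution, "' for base ", code)
  fr <- .base_frame(code)
  xyz <- fr$xyz
  labels <- tpl$atoms$label
  elements <- tpl$atoms$element
  rows <- as.list(seq_len(nrow(xyz)))
  names(rows) <- rownames(xyz)
  add <- function(pos, el, lab) {
    xyz <<- rbind(xyz, pos)
    labels <<- c(labels, lab)
    elements <<- c(elements, el)
    nrow(xyz)
  }
  g <- tpl$glycosidic
  if (substitution == "R") {
    dir <- fr$radial(g)
    c1 <- xyz[g, ] + dir * .len_c1
    rows$c1 <- add(c1, "C", "C1'")
    for (h in seq_len(3)) {
      hp <- .methyl_h(c1, xyz[g, ])[h, ]
      add(hp, "H", paste0("H1'", letters[h]))
    }
  }
  if (!p$unknown) {
    for (n in p$protonated) {
      pos <- as.character(n)
      add(xyz[pos, ] + fr$radial(pos) * .len_nh, "H", paste0("H", n))
    }
    for (i in which(!tpl$atoms$ring)) {
      a <- tpl$atoms[i, ]
      if (a$kind == "amino") {
        v <- .unit(xyz[a$id, ] - xyz[a$pos, ])
        for (sgn in c(1, -1)) {
          hd <- .rot2(v, sgn * pi / 3)
          add(xyz[a$id, ] + hd * .len_nh, "H",
              paste0("H", sub("^[A-Z]", "", a$label), if (sgn > 0) "a" else "b"))
        }
      } else if (a$kind == "methyl") {
        hs <- .methyl_h(xyz[a$id, ], xyz[a$pos, ])
        for (h in seq_len(3)) add(hs[h, ], "H", paste0("H", a$label, letters[h]))
      }
    }
    for (pos in tpl$ch_positions)
      add(xyz[pos, ] + fr$radial(pos) * .len_ch, "H", paste0("H", pos))
  }
  atoms <- data.frame(label = labels, element = elements,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  s <- crystal_structure(id %||% paste0(code, "_", substitution), atoms)
  attr(s, "rows") <- rows
  s
}

# ---- the catalogue ----------------------------------------------------------

#' The homo-pair type catalogue
#'
#' All 47 observed homo-pair types (15 adenine, 7 guanine, 5 hypoxanthine,
#' 6 thymine, 7 uracil, 7 cytosine), each with a protonation pattern pair
#' under which the type was observed.
#'
#' @return Data.frame with columns `base`, `name`, `pattern1`, `pattern2`.
#' @export
pair_catalog <- function() {
  if (is.null(.pd_cache$catalog)) {
    path <- system.file("extdata", "pair_catalog.csv", package = "pairdex")
    .pd_cache$catalog <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .pd_cache$catalog
}

.catalog_entry <- function(pn) {
  cat <- pair_catalog()
  for (i in seq_len(nrow(cat)))
    if (same_pair_name(parse_name(cat$name[i]), pn)) return(cat[i, ])
  NULL
}

# ---- pair construction ------------------------------------------------------

.bond_plan <- function(pn, pattern1, pattern2) {
  codes <- pn$codes
  roles <- list(donor_acceptor_roles(pattern1, codes[1]),
                donor_acceptor_roles(pattern2, codes[2]))
  plan <- list()
  for (r in seq_len(nrow(pn$bonds))) {
    n1 <- pn$bonds[r, 1]; n2 <- pn$bonds[r, 2]
    r1 <- roles[[1]][roles[[1]]$n == n1, , drop = FALSE]
    r2 <- roles[[2]][roles[[2]]$n == n2, , drop = FALSE]
    if (!nrow(r1) || !nrow(r2))
      stop("bond (", n1, n2, "): no interaction atom at that position")
    if (r1$donor[1] && r2$acceptor[1]) dside <- 1L
    else if (r2$donor[1] && r1$acceptor[1]) dside <- 2L
    else stop("infeasible bond (", n1, n2, ") under patterns '",
              pattern1, "' / '", pattern2, "'")
    del <- if (dside == 1) r1$element[1] else r2$element[1]
    plan[[r]] <- list(n1 = n1, n2 = n2, id1 = r1$id[1], id2 = r2$id[1],
                      donor_side = dside, donor_element = del,
                      target = if (del == "C") 3.4 else 2.9)
  }
  plan
}

#' Construct an idealized base pair for a catalogued (or any valid) name
#'
#' The first base sits at the origin in the z = 0 plane; the second is
#' flipped for `f` names, then rotated and translated in-plane so every
#' named hydrogen bond reaches its target donor-acceptor distance
#' (residual below 0.05 A), without steric clash (heavy-atom contacts under
#' 2.4 A) and without stray contacts that would qualify as extra hydrogen
#' bonds.
#'
#' @param name Pair name text or `pair_name` (orientation must be known).
#' @param patterns Length-2 character of protonation patterns; defaults to
#'   the catalogue patterns for catalogued names.
#' @param target_da Single value or per-bond vector of target D...A
#'   distances; defaults to 2.9 A (3.4 A for carbon donors).
#' @param check Verify by running [detect_pairs()] and comparing names?
#' @param params A [geometry_params()].
#' @return A coordinate-only [crystal_structure()] containing both bases.
#'   Attribute `"fixture"` records the construction (expected name,
#'   patterns, atom rows of the second base, bond plan).
#' @export
build_pair <- function(name, patterns = NULL, target_da = NULL, check = FALSE,
                       params = geometry_params()) {
  pn <- if (is.character(name)) parse_name(name) else name
  if (is.na(pn$orientation))
    stop("cannot build '", format(pn), "': orientation unknown")
  entry <- .catalog_entry(pn)
  if (is.null(patterns)) {
    if (is.null(entry))
      stop("'", format(pn), "' is not in the catalogue; supply `patterns`")
    patterns <- c(entry$pattern1, entry$pattern2)
  }
  if (is.null(target_da) && !is.null(entry) &&
      !is.null(entry$target_da) && nzchar(entry$target_da))
    target_da <- as.numeric(strsplit(entry$target_da, ";")[[1]])
  subs <- vapply(seq_len(2), function(k)
    parse_protonation(patterns[k], pn$codes[k])$substitution, "")
  plan <- .bond_plan(pn, patterns[1], patterns[2])
  if (!is.null(target_da)) {
    target_da <- rep_len(target_da, length(plan))
    for (r in seq_along(plan)) plan[[r]]$target <- target_da[r]
  }
  b1 <- ideal_base(pn$codes[1], subs[1], patterns[1], id = "b1")
  b2 <- ideal_base(pn$codes[2], subs[2], patterns[2], id = "b2")
  X1 <- coords(b1); X2 <- coords(b2)
  rows1 <- attr(b1, "rows"); rows2 <- attr(b2, "rows")
  flip <- pn$orientation == "f"
  if (flip) { X2[, 2] <- -X2[, 2]; X2[, 3] <- -X2[, 3] }
  sol <- .place_pair(pn, plan, patterns, X1, X2, rows1, rows2,
                     b1$atoms$element, b2$atoms$element, params)
  X2p <- sol$transform(X2)
  atoms <- rbind(b1$atoms, b2$atoms)
  atoms$label <- make.unique(atoms$label, sep = "_")
  atoms[seq_len(nrow(X1)), c("x", "y", "z")] <- sol$X1
  atoms[(nrow(X1) + 1):nrow(atoms), c("x", "y", "z")] <- X2p
  s <- crystal_structure(render_name(pn), atoms)
  map2 <- lapply(rows2, function(r) r + nrow(X1))
  attr(s, "fixture") <- list(
    name = pn, patterns = patterns,
    rows1 = seq_len(nrow(X1)), rows2 = nrow(X1) + seq_len(nrow(X2)),
    map1 = rows1, map2 = map2,
    plan = plan, transform = sol$par, symmetric = sol$symmetric)
  if (check) {
    found <- detect_pairs(s, params)
    if (length(found) != 1 || !same_pair_name(found[[1]]$name, pn))
      stop("constructed pair does not round-trip to '", format(pn), "'")
  }
  s
}

# rigid placement of base 2: multi-start Nelder-Mead over (theta, tx, ty)
# (tx, ty only, theta = 180 deg, for swap-symmetric m pairs, which makes the
# two bonds exactly equivalent)
.place_pair <- function(pn, plan, patterns, X1, X2, rows1, rows2, el1, el2,
                        params) {
  heavy1 <- which(el1 != "H"); heavy2 <- which(el2 != "H")
  bkey <- .bond_set_key(pn$bonds)
  skey <- .bond_set_key(pn$bonds[, 2:1, drop = FALSE])
  symmetric <- pn$orientation == "m" && identical(bkey, skey) &&
    pn$codes[1] == pn$codes[2]
  a1 <- vapply(plan, function(b) rows1[[b$id1]], 0L)
  a2 <- vapply(plan, function(b) rows2[[b$id2]], 0L)
  targets <- vapply(plan, function(b) b$target, 0)
  # in pairs with three bonds the rigid idealized rings over-determine the
  # geometry; the long, weak C-H bond absorbs the slack (observed range for
  # such bonds is broad), while N/O bonds stay exact
  soft <- vapply(plan, function(b) b$donor_element == "C", TRUE) &
    length(plan) >= 3
  w_bond <- ifelse(soft, 3, 30)
  tol_bond <- ifelse(soft, 0.70, 0.05)
  # hydrogens available to each donor
  hrows <- lapply(plan, function(b) {
    if (b$donor_side == 1) integer(0) else {
      # attached H of the side-2 donor atom: nearest H rows in the ideal base
      hh <- which(el2 == "H")
      dd <- .cross_dist(X2[hh, , drop = FALSE],
                        X2[rows2[[b$id2]], , drop = FALSE])
      hh[dd[, 1] < 1.3]
    }
  })
  h1rows <- lapply(plan, function(b) {
    if (b$donor_side == 2) integer(0) else {
      hh <- which(el1 == "H")
      dd <- .cross_dist(X1[hh, , drop = FALSE],
                        X1[rows1[[b$id1]], , drop = FALSE])
      hh[dd[, 1] < 1.3]
    }
  })
  # unwanted donor/acceptor contacts that could become stray hydrogen bonds
  spur <- .spurious_candidates(pn, plan, patterns, rows1, rows2, params)
  hh1 <- which(el1 == "H"); hh2 <- which(el2 == "H")
  spur <- lapply(spur, function(sp) {
    if (sp$donor_side == 1 && length(hh1)) {
      dd <- .cross_dist(X1[hh1, , drop = FALSE], X1[sp$r1, , drop = FALSE])
      sp$h1 <- hh1[dd[, 1] < 1.3]
    } else if (sp$donor_side == 2 && length(hh2)) {
      dd <- .cross_dist(X2[hh2, , drop = FALSE], X2[sp$r2, , drop = FALSE])
      sp$h2 <- hh2[dd[, 1] < 1.3]
    }
    shared <- vapply(plan, function(b) b$n1 == sp$n1 || b$n2 == sp$n2, TRUE)
    sp$keepout <- if (any(shared))
      max(vapply(plan[shared], function(b) b$target, 0)) + 0.25
    else min(sp$bound + 0.1, min(vapply(plan, function(b) b$target, 0)))
    sp
  })
  obj <- function(par, wscale = 1) {
    Tfun <- .par_transform(par, symmetric)
    Q <- Tfun(X2)
    e <- 0
    for (r in seq_along(plan)) {
      d <- .vnorm(X1[a1[r], ] - Q[a2[r], ])
      e <- e + (if (soft[r]) w_bond[r] else wscale * w_bond[r]) * (d - targets[r])^2
      # keep donor hydrogens pointing at the acceptor
      ang <- NA_real_
      if (length(h1rows[[r]]))
        ang <- max(vapply(h1rows[[r]], function(h)
          .angle3(X1[a1[r], ], X1[h, ], Q[a2[r], ]), 0))
      if (length(hrows[[r]]))
        ang <- max(vapply(hrows[[r]], function(h)
          .angle3(Q[a2[r], ], Q[h, ], X1[a1[r], ]), 0))
      if (!is.na(ang)) e <- e + 8 * max(0, (140 - ang) / 30)^2
    }
    dcross <- .cross_dist(X1[heavy1, , drop = FALSE], Q[heavy2, , drop = FALSE])
    e <- e + 5 * wscale * sum(pmax(0, 2.75 - dcross)^2)
    for (sp in spur) {
      d <- .vnorm(X1[sp$r1, ] - Q[sp$r2, ])
      if (d < sp$keepout) {
        # a stray contact only matters when it can displace a named bond in
        # the shortest-first matching: keep it longer than the named bonds
        # that share one of its atoms
        w <- 1
        if (length(sp$h1))
          w <- max(0, min(1, (max(vapply(sp$h1, function(h)
            .angle3(X1[sp$r1, ], X1[h, ], Q[sp$r2, ]), 0)) - 105) / 30))
        if (length(sp$h2))
          w <- max(0, min(1, (max(vapply(sp$h2, function(h)
            .angle3(Q[sp$r2, ], Q[h, ], X1[sp$r1, ]), 0)) - 105) / 30))
        e <- e + 6 * w * (sp$keepout - d)^2
      }
    }
    e
  }
  ctr1 <- colMeans(X1[a1, , drop = FALSE])
  u <- .unit(c(ctr1[1:2], 0) + c(1e-3, 1e-3, 0))
  starts <- list()
  if (symmetric) {
    base_t <- X1[a1[1], 1:2] + X2[a2[1], 1:2]
    for (ang in seq(0, 2 * pi - 1e-9, length.out = 12))
      starts[[length(starts) + 1]] <-
        base_t + targets[1] * c(cos(ang), sin(ang))
    # exact solutions of the first two distinct bond constraints
    cc <- lapply(seq_along(plan), function(r)
      (X1[a1[r], ] + X2[a2[r], ])[1:2])
    for (r in seq_along(plan)[-1]) {
      for (pt in .circle_intersect(cc[[1]], targets[1], cc[[r]], targets[r]))
        starts[[length(starts) + 1]] <- pt
    }
  } else {
    qj <- t(vapply(seq_along(plan), function(r)
      X1[a1[r], ] + u * targets[r], numeric(3)))
    for (th in seq(0, 2 * pi - 1e-9, length.out = 12)) {
      R <- .rot_z(th)
      t0 <- colMeans(qj - t(R %*% t(X2[a2, , drop = FALSE])))
      starts[[length(starts) + 1]] <- c(th, t0[1:2])
      # exact solutions of the first two bond constraints at this rotation
      c1 <- (X1[a1[1], ] - as.vector(R %*% X2[a2[1], ]))[1:2]
      c2 <- (X1[a1[2], ] - as.vector(R %*% X2[a2[2], ]))[1:2]
      for (pt in .circle_intersect(c1, targets[1], c2, targets[2]))
        starts[[length(starts) + 1]] <- c(th, pt)
    }
  }
  fits <- lapply(starts, function(p0)
    stats::optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = 600, reltol = 1e-12)))
  fits <- fits[order(vapply(fits, `[[`, 0, "value"))]
  # polish the most promising basins with the bond terms dominating (so the
  # soft guidance penalties cannot drag the named contacts off target), and
  # keep the first solution whose geometry reproduces exactly the named
  # contact set under the detection rules
  assemble <- function(par) {
    Tfun0 <- .par_transform(par, symmetric)
    X1a <- .orient_methyl_donors(X1, Tfun0(X2), plan, rows1, rows2, el1, el2,
                                 side = 1)
    Tfun <- function(X) {
      Q <- Tfun0(X)
      .orient_methyl_donors(Q, X1a, plan, rows1, rows2, el1, el2, side = 2)
    }
    list(Tfun = Tfun, X1 = X1a, Q = Tfun(X2), par = par)
  }
  diagnose <- function(cand) {
    Q <- cand$Q; X1a <- cand$X1
    resid <- abs(vapply(seq_along(plan), function(r)
      .vnorm(X1a[a1[r], ] - Q[a2[r], ]) - targets[r], 0))
    if (any(resid > tol_bond)) {
      worst <- which.max(resid / tol_bond)
      return(paste0("bond (", plan[[worst]]$n1, plan[[worst]]$n2,
                    ") misses its target by ", round(resid[worst], 3), " A"))
    }
    if (min(.cross_dist(X1a[heavy1, , drop = FALSE],
                        Q[heavy2, , drop = FALSE])) < 2.4)
      return("steric clash between the two bases")
    # every named bond with a modelled donor hydrogen must clear the
    # detection angle floor
    for (r in seq_along(plan)) {
      hs <- if (plan[[r]]$donor_side == 1) h1rows[[r]] else hrows[[r]]
      if (!length(hs)) next
      pts <- if (plan[[r]]$donor_side == 1) X1a else Q
      dpt <- if (plan[[r]]$donor_side == 1) X1a[a1[r], ] else Q[a2[r], ]
      apt <- if (plan[[r]]$donor_side == 1) Q[a2[r], ] else X1a[a1[r], ]
      ang <- max(vapply(hs, function(h) .angle3(dpt, pts[h, ], apt), 0))
      if (ang < params$dha_min + 0.5)
        return(paste0("bond (", plan[[r]]$n1, plan[[r]]$n2,
                      ") donor hydrogen angle ", round(ang, 1),
                      " deg is below the acceptance floor"))
    }
    # detection semantics: planned plus qualifying stray contacts, greedy
    # matching shortest-first, must return the planned set
    cont <- data.frame(n1 = vapply(plan, `[[`, 0, "n1"),
                       n2 = vapply(plan, `[[`, 0, "n2"),
                       d = vapply(seq_along(plan), function(r)
                         .vnorm(X1a[a1[r], ] - Q[a2[r], ]), numeric(1)))
    for (sp in spur) {
      d <- .vnorm(X1a[sp$r1, ] - Q[sp$r2, ])
      if (d > sp$bound) next
      hs <- if (sp$donor_side == 1) sp$h1 else sp$h2
      if (length(hs)) {
        pts <- if (sp$donor_side == 1) X1a else Q
        dpt <- if (sp$donor_side == 1) X1a[sp$r1, ] else Q[sp$r2, ]
        apt <- if (sp$donor_side == 1) Q[sp$r2, ] else X1a[sp$r1, ]
        ang <- max(vapply(hs, function(h) .angle3(dpt, pts[h, ], apt), 0))
        if (ang < params$dha_min) next
      }
      cont <- rbind(cont, data.frame(n1 = sp$n1, n2 = sp$n2, d = d))
    }
    cont <- cont[order(cont$d), ]
    used1 <- integer(0); used2 <- integer(0); kept <- character(0)
    for (k in seq_len(nrow(cont))) {
      if (cont$n1[k] %in% used1 || cont$n2[k] %in% used2) next
      used1 <- c(used1, cont$n1[k]); used2 <- c(used2, cont$n2[k])
      kept <- c(kept, paste(cont$n1[k], cont$n2[k]))
    }
    planned <- paste(vapply(plan, `[[`, 0, "n1"), vapply(plan, `[[`, 0, "n2"))
    if (!setequal(kept, planned))
      return(paste0("stray contact displaces a named bond (got ",
                    paste(setdiff(kept, planned), collapse = ","), ")"))
    ""
  }
  failure <- NULL
  seen_par <- list()
  for (fit in fits[seq_len(min(6, length(fits)))]) {
    pol <- stats::optim(fit$par, obj, wscale = 100, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-14))
    if (any(vapply(seen_par, function(p) max(abs(p - pol$par)) < 1e-4, TRUE)))
      next
    seen_par[[length(seen_par) + 1]] <- pol$par
    cand <- assemble(pol$par)
    msg <- diagnose(cand)
    if (msg == "")
      return(list(transform = cand$Tfun, par = cand$par,
                  symmetric = symmetric, X1 = cand$X1))
    if (is.null(failure)) failure <- msg
  }
  # fall back to a dense sweep along the exact-solution family of the first
  # two bond constraints (tight geometries can hide in narrow windows)
  if (!symmetric && length(plan) >= 2) {
    for (th in seq(0, 2 * pi, length.out = 241)) {
      R <- .rot_z(th)
      c1 <- (X1[a1[1], ] - as.vector(R %*% X2[a2[1], ]))[1:2]
      c2 <- (X1[a1[2], ] - as.vector(R %*% X2[a2[2], ]))[1:2]
      for (pt in .circle_intersect(c1, targets[1], c2, targets[2])) {
        cand <- assemble(c(th, pt))
        if (diagnose(cand) == "")
          return(list(transform = cand$Tfun, par = cand$par,
                      symmetric = symmetric, X1 = cand$X1))
      }
    }
  }
  stop("infeasible geometry for '", format(pn), "': ", failure)
}

# rotate the hydrogens of a donating methyl group about its C-C axis so the
# best-placed hydrogen maximizes the D-H...A angle
.orient_methyl_donors <- function(Xd, Xa, plan, rows1, rows2, el1, el2, side) {
  for (b in plan) {
    if (b$donor_side != side || b$donor_element != "C") next
    id <- if (side == 1) b$id1 else b$id2
    if (!grepl("x$", id)) next  # ring C-H, not a methyl
    rowsd <- if (side == 1) rows1 else rows2
    eld <- if (side == 1) el1 else el2
    cm <- Xd[rowsd[[id]], ]
    acc <- Xa[(if (side == 1) rows2 else rows1)[[
      if (side == 1) b$id2 else b$id1]], ]
    hh <- which(eld == "H")
    dd <- .cross_dist(Xd[hh, , drop = FALSE], matrix(cm, 1))
    hrows <- hh[dd[, 1] < 1.3]
    if (length(hrows) < 2) next
    # axis: from the attached ring atom through the methyl carbon
    heavy <- which(eld != "H")
    dh <- .cross_dist(Xd[heavy, , drop = FALSE], matrix(cm, 1))
    att <- heavy[dh[, 1] > 0.1 & dh[, 1] < 1.8][1]
    axis <- .unit(cm - Xd[att, ])
    best_ang <- -Inf; best_X <- Xd
    for (th in seq(0, 2 * pi - 1e-9, length.out = 36)) {
      R <- .rot_axis(axis, th)
      Xt <- Xd
      Xt[hrows, ] <- sweep(t(R %*% t(sweep(Xd[hrows, , drop = FALSE], 2, cm))),
                           2, cm, "+")
      ang <- max(vapply(hrows, function(h)
        .angle3(cm, Xt[h, ], acc), 0))
      if (ang > best_ang) { best_ang <- ang; best_X <- Xt }
    }
    Xd <- best_X
  }
  Xd
}

.par_transform <- function(par, symmetric) {
  if (symmetric) {
    # in-plane rotation by 180 deg plus translation: x -> t - x, z kept
    function(X) cbind(par[1] - X[, 1], par[2] - X[, 2], X[, 3])
  } else {
    R <- .rot_z(par[1])
    tv <- c(par[2], par[3], 0)
    function(X) sweep(t(R %*% t(X)), 2, tv, "+")
  }
}

.spurious_candidates <- function(pn, plan, patterns, rows1, rows2, params) {
  roles1 <- donor_acceptor_roles(patterns[1], pn$codes[1])
  roles2 <- donor_acceptor_roles(patterns[2], pn$codes[2])
  wanted <- paste(pn$bonds[, 1], pn$bonds[, 2])
  out <- list()
  addc <- function(rd, ra, dside) {
    key <- if (dside == 1) paste(rd$n, ra$n) else paste(ra$n, rd$n)
    if (key %in% wanted) return()
    out[[length(out) + 1]] <<- list(
      n1 = if (dside == 1) rd$n else ra$n,
      n2 = if (dside == 1) ra$n else rd$n,
      r1 = if (dside == 1) rows1[[rd$id]] else rows1[[ra$id]],
      r2 = if (dside == 1) rows2[[ra$id]] else rows2[[rd$id]],
      bound = .vdw(params, rd$element) + .vdw(params, ra$element) +
        params$da_margin,
      h1 = integer(0), h2 = integer(0), donor_side = dside)
  }
  for (i in which(roles1$donor)) for (j in which(roles2$acceptor))
    addc(roles1[i, ], roles2[j, ], 1)
  for (i in which(roles2$donor)) for (j in which(roles1$acceptor))
    addc(roles2[i, ], roles1[j, ], 2)
  out
}

# ---- perturbation -----------------------------------------------------------

#' Perturb a constructed fixture
#'
#' Adds isotropic Gaussian coordinate noise and/or tilts the second base out
#' of the pairing plane: the tilt rotates base 2 about the in-plane axis
#' perpendicular to the pairing direction through its bond-atom centroid, so
#' a 60 degree tilt drives the donor-acceptor vectors far beyond the
#' 45 degree ring-plane criterion while barely changing their lengths.
#'
#' @param s A structure from [build_pair()].
#' @param noise_sigma Standard deviation of the coordinate noise (angstrom).
#' @param tilt Rotation of the second base in degrees.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return The perturbed structure.
#' @export
perturb <- function(s, noise_sigma = 0, tilt = 0, seed = NULL) {
  stopifnot(inherits(s, "crystal_structure"))
  fix <- attr(s, "fixture")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  xyz <- coords(s)
  if (tilt != 0) {
    if (is.null(fix)) stop("tilt needs a structure built by build_pair()")
    a1 <- vapply(fix$plan, function(b) fix$map1[[b$id1]], 0L)
    a2 <- vapply(fix$plan, function(b) fix$map2[[b$id2]], 0L)
    c1 <- colMeans(xyz[a1, , drop = FALSE])
    c2 <- colMeans(xyz[a2, , drop = FALSE])
    v <- .unit(c2 - c1)
    heavy2 <- fix$rows2[s$atoms$element[fix$rows2] != "H"]
    pts <- xyz[heavy2, , drop = FALSE]
    sv <- svd(sweep(pts, 2, colMeans(pts)))
    n2 <- sv$v[, 3]
    w <- .unit(c(n2[2] * v[3] - n2[3] * v[2],
                 n2[3] * v[1] - n2[1] * v[3],
                 n2[1] * v[2] - n2[2] * v[1]))
    R <- .rot_axis(w, .deg2rad(tilt))
    rows <- fix$rows2
    xyz[rows, ] <- sweep(t(R %*% t(sweep(xyz[rows, , drop = FALSE], 2, c2))),
                         2, c2, "+")
  }
  if (noise_sigma > 0)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_sigma), ncol = 3)
  s$atoms[, c("x", "y", "z")] <- xyz
  s$bonds <- NULL
  s
}

# ---- fixture sets -----------------------------------------------------------

#' Build the full fixture set
#'
#' One constructed pair per catalogued homo-pair type (47 entries), built
#' with the catalogue's protonation patterns.  Results are cached for the
#' session.
#'
#' @param names Optional subset of catalogue names.
#' @return List of entries: `name` (text), `patterns`, `structure`.
#' @export
fixture_set <- function(names = NULL) {
  cat <- pair_catalog()
  if (is.null(.pd_cache$fixture_set)) .pd_cache$fixture_set <- list()
  want <- names %||% cat$name
  out <- vector("list", length(want))
  for (k in seq_along(want)) {
    nm <- want[k]
    if (is.null(.pd_cache$fixture_set[[nm]])) {
      row <- cat[cat$name == nm, ]
      if (!nrow(row)) stop("not a catalogue name: ", nm)
      .pd_cache$fixture_set[[nm]] <- list(
        name = nm, patterns = c(row$pattern1, row$pattern2),
        structure = build_pair(nm))
    }
    out[[k]] <- .pd_cache$fixture_set[[nm]]
  }
  out
}

#' Wrap a centrosymmetric fixture into a P-1 cell
#'
#' For m-orientation pairs with a swap-symmetric bond list the two bases are
#' related by an inversion centre; this keeps only the first base in the
#' asymmetric unit of a triclinic P-1 cell with the inversion centre at the
#' origin, so [expand_symmetry()] must regenerate the partner.
#'
#' @param name A catalogue name of a swap-symmetric m pair.
#' @param cell_length Cubic-cell edge in angstroms.
#' @return A `crystal_structure` with cell, symmetry operators and half the
#'   pair in the asymmetric unit.
#' @export
build_pair_p1bar <- function(name, cell_length = 20) {
  s <- build_pair(name)
  fix <- attr(s, "fixture")
  if (!fix$symmetric || fix$patterns[1] != fix$patterns[2])
    stop("'", name, "' is not centrosymmetric; cannot wrap in P-1")
  ctr <- c(fix$transform / 2, 0)
  atoms <- s$atoms[fix$rows1, , drop = FALSE]
  atoms$x <- atoms$x - ctr[1]
  atoms$y <- atoms$y - ctr[2]
  atoms$z <- atoms$z - ctr[3]
  cell <- list(a = cell_length, b = cell_length, c = cell_length,
               alpha = 90, beta = 90, gamma = 90,
               symops = list(list(R = diag(3), t = c(0, 0, 0)),
                             list(R = -diag(3), t = c(0, 0, 0))))
  crystal_structure(paste0(s$id, "_P-1"), atoms, cell = cell)
}

#' Write fixture CIF files plus a manifest
#'
#' @param dir Output directory (created when missing).
#' @param names Optional subset of catalogue names.
#' @param noise_sigma,tilt,seed Passed to [perturb()] when nonzero.
#' @return Path of the manifest TSV, invisibly.
#' @export
write_fixtures <- function(dir, names = NULL, noise_sigma = 0, tilt = 0,
                           seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- fixture_set(names)
  rows <- lapply(entries, function(e) {
    s <- e$structure
    if (noise_sigma > 0 || tilt != 0)
      s <- perturb(s, noise_sigma, tilt, seed = seed)
    fn <- paste0(gsub("[^A-Za-z0-9_-]", "", gsub("\\)\\(", "-", e$name)), ".cif")
    write_structure(s, file.path(dir, fn), format = "cif")
    ch <- vapply(seq_len(2), function(k)
      pattern_charge(parse_name(e$name)$codes[k], e$patterns[k]), 0L)
    data.frame(file = fn, expected_name = e$name,
               pattern1 = e$patterns[1], pattern2 = e$patterns[2],
               charge1 = ch[1], charge2 = ch[2])
  })
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
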