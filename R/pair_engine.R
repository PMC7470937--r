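# Detection of planar, doubly hydrogen-bonded base pairs.
#
# Acceptance of a donor...acceptor contact requires (i) role compatibility
# under the instances' protonation, (ii) D...A within the van der Waals sum
# plus a margin, (iii) the D...A vector within `plane_angle_max` of BOTH
# ring planes (the stricter, symmetric reading of the planarity criterion),
# and (iv) D-H...A of at least `dha_min` whenever the donor hydrogen is
# modelled.  Two accepted bonds make a pair.

#' Ring plane of a base instance
#'
#' Least-squares plane of the ring heavy atoms.  The normal's sign follows
#' the canonical ring circuit (right-hand rule over N1 to C6), so it labels
#' a face of the base: two stacked bases with the same face up have parallel
#' normals.
#'
#' @param b A `base_instance`.
#' @return List with `centroid` and unit `normal`.
#' @export
base_plane <- function(b) {
  stopifnot(inherits(b, "base_instance"))
  b$plane
}

# angle (deg) between a vector and a plane with unit normal n
.plane_angle <- function(v, n) {
  .rad2deg(asin(min(1, abs(sum(.unit(v) * n)))))
}

#' Detect hydrogen bonds between two base instances
#'
#' @param s The [crystal_structure()] both instances live in.
#' @param b1,b2 Distinct `base_instance` objects (possibly symmetry mates of
#'   the same moiety).
#' @param params A [geometry_params()].
#' @return Data.frame with one row per accepted bond: canonical numbers
#'   `n1`/`n2`, `donor_side`, bond `class` (e.g. `"N-H...O"`), `d_a`, `d_h`,
#'   `h_a`, `dha` (normalized to neutron D-H lengths; `NA` without a
#'   modelled hydrogen) and the two plane angles.
#' @export
detect_hbonds <- function(s, b1, b2, params = geometry_params()) {
  stopifnot(inherits(b1, "base_instance"), inherits(b2, "base_instance"))
  xyz <- coords(s)
  roles <- list(donor_acceptor_roles(b1$protonation, b1$code),
                donor_acceptor_roles(b2$protonation, b2$code))
  inst <- list(b1, b2)
  rows <- list()
  for (dside in 1:2) {
    aside <- 3 - dside
    rd <- roles[[dside]]; ra <- roles[[aside]]
    bd <- inst[[dside]]; ba <- inst[[aside]]
    for (i in which(rd$donor)) for (j in which(ra$acceptor)) {
      d_idx <- bd$atom_map[[rd$id[i]]]
      a_idx <- ba$atom_map[[ra$id[j]]]
      v <- xyz[a_idx, ] - xyz[d_idx, ]
      d_a <- .vnorm(v)
      if (d_a > .vdw(params, rd$element[i]) + .vdw(params, ra$element[j]) +
          params$da_margin) next
      pa1 <- .plane_angle(v, b1$plane$normal)
      pa2 <- .plane_angle(v, b2$plane$normal)
      if (pa1 >= params$plane_angle_max || pa2 >= params$plane_angle_max) next
      h_cand <- bd$h_map[[rd$id[i]]]
      d_h <- h_a <- dha <- NA_real_
      if (length(h_cand)) {
        angs <- vapply(h_cand, function(h)
          .angle3(xyz[d_idx, ], xyz[h, ], xyz[a_idx, ]), numeric(1))
        best <- which.max(angs)
        nrm <- normalize_dh(xyz[d_idx, ], xyz[h_cand[best], ], xyz[a_idx, ],
                            rd$element[i], params)
        if (nrm$dha < params$dha_min) next
        d_h <- nrm$d_h; h_a <- nrm$h_a; dha <- nrm$dha
      }
      rows[[length(rows) + 1]] <- data.frame(
        n1 = if (dside == 1) rd$n[i] else ra$n[j],
        n2 = if (dside == 1) ra$n[j] else rd$n[i],
        donor_side = dside,
        class = paste0(rd$element[i], "-H...", ra$element[j]),
        d_a = d_a, d_h = d_h, h_a = h_a, dha = dha,
        plane_angle1 = pa1, plane_angle2 = pa2,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(n1 = integer(0), n2 = integer(0), donor_side = integer(0),
                      class = character(0), d_a = numeric(0), d_h = numeric(0),
                      h_a = numeric(0), dha = numeric(0),
                      plane_angle1 = numeric(0), plane_angle2 = numeric(0)))
  hb <- do.call(rbind, rows)
  # one bond per unordered atom pair: when both directions qualify (e.g.
  # undetermined protonation) keep the better-defined direction
  hb <- hb[order(hb$n1, hb$n2, is.na(hb$dha), -ifelse(is.na(hb$dha), 0, hb$dha)), ]
  hb <- hb[!duplicated(hb[, c("n1", "n2")]), , drop = FALSE]
  # every interaction atom serves at most one bond per pair (true of every
  # catalogued pair type): greedy matching, shortest D...A first, so a
  # bifurcated donor keeps only its primary contact
  hb <- hb[order(hb$d_a, -ifelse(is.na(hb$dha), 0, hb$dha)), ]
  used1 <- integer(0); used2 <- integer(0); keep <- logical(nrow(hb))
  for (k in seq_len(nrow(hb))) {
    if (hb$n1[k] %in% used1 || hb$n2[k] %in% used2) next
    keep[k] <- TRUE
    used1 <- c(used1, hb$n1[k]); used2 <- c(used2, hb$n2[k])
  }
  hb <- hb[keep, , drop = FALSE]
  hb <- hb[order(hb$n1, hb$n2), , drop = FALSE]
  rownames(hb) <- NULL
  hb
}

#' Normalize a donor-hydrogen bond to its neutron reference length
#'
#' X-ray refinement places hydrogen about 0.2 A too close to the donor; the
#' hydrogen is moved along the D-H direction so the bond matches the
#' averaged neutron length for the donor element, and H...A and D-H...A are
#' recomputed.  D...A never changes; a collinear D-H...A stays at 180
#' degrees.
#'
#' @param d,h,a Cartesian coordinates (length-3) of donor, hydrogen,
#'   acceptor.
#' @param donor_element Element symbol of the donor (`"C"`, `"N"`, `"O"`).
#' @param params A [geometry_params()] (source of the reference lengths).
#' @return List with the new `h` position, `d_h`, `h_a` and `dha`.
#' @export
normalize_dh <- function(d, h, a, donor_element, params = geometry_params()) {
  len <- params$neutron_dh[donor_element]
  if (is.na(len)) len <- .vnorm(h - d)
  h_new <- d + .unit(h - d) * len
  list(h = h_new, d_h = unname(len), h_a = .vnorm(a - h_new),
       dha = .angle3(d, h_new, a))
}

#' Detect all base pairs in a structure
#'
#' Runs the full pipeline: bond inference, symmetry expansion (when a cell
#' is present), base recognition, pairwise hydrogen-bond detection, and
#' collapse of symmetry-equivalent duplicates via a canonical signature
#' (pair name + bond-distance multiset quantized to 0.01 A).
#'
#' @param s A [crystal_structure()].
#' @param params A [geometry_params()].
#' @param expand Apply symmetry expansion when a cell is present?
#' @return List of `base_pair` objects.
#' @export
detect_pairs <- function(s, params = geometry_params(), expand = TRUE) {
  stopifnot(inherits(s, "crystal_structure"))
  if (is.null(s$bonds)) s <- infer_bonds(s, params = params)
  if (expand && !is.null(s$cell) && !isTRUE(s$meta$expanded))
    s <- expand_symmetry(s, params = params)
  bases <- find_bases(s, params)
  if (length(bases) < 2) return(list())
  pairs <- list()
  for (i in seq_along(bases)[-length(bases)]) for (j in seq(i + 1, length(bases))) {
    b1 <- bases[[i]]; b2 <- bases[[j]]
    if (.vnorm(b1$plane$centroid - b2$plane$centroid) > 12) next
    hb <- detect_hbonds(s, b1, b2, params)
    if (nrow(hb) < params$min_hbonds) next
    pairs[[length(pairs) + 1]] <- .make_pair(s, b1, b2, hb)
  }
  if (!length(pairs)) return(list())
  # prefer pairs anchored in the asymmetric unit, then deduplicate
  n_mates <- vapply(pairs, function(p) p$base1$is_mate + p$base2$is_mate, 0)
  pairs <- pairs[order(n_mates)]
  sig <- vapply(pairs, function(p) paste(
    format(p$name), paste(sort(round(p$hbonds$d_a, 2)), collapse = ","),
    round(p$interplanar_angle, 1)), "")
  pairs <- pairs[!duplicated(sig)]
  pairs
}

.make_pair <- function(s, b1, b2, hb) {
  dot <- sum(b1$plane$normal * b2$plane$normal)
  cn <- .canonical_name(b1$code, b2$code,
                        cbind(hb$n1, hb$n2), dot)
  if (cn$swapped) {
    tmp <- b1; b1 <- b2; b2 <- tmp
    hb[, c("n1", "n2")] <- hb[, c("n2", "n1")]
    hb$donor_side <- 3 - hb$donor_side
    hb[, c("plane_angle1", "plane_angle2")] <- hb[, c("plane_angle2", "plane_angle1")]
  }
  hb <- hb[order(hb$n1, hb$n2), ]
  rownames(hb) <- NULL
  c1c1 <- if (!is.na(b1$c1_atom) && !is.na(b2$c1_atom))
    .vnorm(as.numeric(coords(s)[b1$c1_atom, ] - coords(s)[b2$c1_atom, ]))
  else NA_real_
  structure(list(
    base1 = b1, base2 = b2, hbonds = hb, name = cn$name,
    interplanar_angle = .rad2deg(acos(min(1, abs(dot)))),
    c1_c1 = c1c1,
    symmetry_generated = b1$is_mate || b2$is_mate,
    structure_id = s$id
  ), class = "base_pair")
}

#' @export
print.base_pair <- function(x, ...) {
  cat(sprintf("<base_pair> %s  (%d H-bonds, interplanar %.1f deg%s)%s\n",
              format(x$name), nrow(x$hbonds), x$interplanar_angle,
              if (!is.na(x$c1_c1)) sprintf(", C1'...C1' %.2f A", x$c1_c1) else "",
              if (x$symmetry_generated) " [symmetry-generated]" else ""))
  invisible(x)
}

#' Geometry record of a detected pair
#'
#' @param pr A `base_pair`.
#' @return List with `bonds` (per-bond class and normalized D...A, D-H,
#'   H...A, D-H...A), `interplanar_angle`, `c1_c1` (`NA` for free bases) and
#'   the protonation of both bases.
#' @export
pair_geometry <- function(pr) {
  stopifnot(inherits(pr, "base_pair"))
  list(bonds = pr$hbonds[, c("n1", "n2", "class", "d_a", "d_h", "h_a", "dha")],
       interplanar_angle = pr$interplanar_angle,
       c1_c1 = pr$c1_c1,
       protonation = c(pr$base1$protonation, pr$base2$protonation),
       charge = c(pr$base1$charge, pr$base2$charge))
}

#' Orientation letter of two paired bases
#'
#' `"m"` (moved: in-plane rotation, same face up, parallel face normals)
#' when the face-labelled normals have a non-negative dot product, `"f"`
#' (flipped, antiparallel normals) otherwise.  `f` corresponds to *cis* and
#' `m` to *trans* in the Leontis-Westhof strand nomenclature.
#'
#' @param b1,b2 `base_instance` objects.
#' @return `"f"` or `"m"`.
#' @export
orientation <- function(b1, b2) {
  stopifnot(inherits(b1, "base_instance"), inherits(b2, "base_instance"))
  if (sum(b1$plane$normal * b2$plane$normal) >= 0) "m" else "f"
}

#' Canonical name of a detected pair
#'
#' @param pr A `base_pair`.
#' @return The `pair_name` (already canonical: edge precedence W > H > S
#'   decides the first molecule, bonds are sorted, swapping the input bases
#'   gives the identical name).
#' @export
canonical_name <- function(pr) {
  stopifnot(inherits(pr, "base_pair"))
  pr$name
}
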