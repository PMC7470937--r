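# Locating nucleobase moieties in a bonded structure.
#
# Heavy-atom subgraph matching (igraph VF2, element-coloured vertices)
# against the six templates, followed by the survey's exclusion rules:
# substituents other than hydrogen are allowed only at the glycosidic
# nitrogen, and bases bonded to a metal are rejected.

#' Find nucleobase instances in a structure
#'
#' @param s A [crystal_structure()] (bonds are inferred when missing).
#' @param params A [geometry_params()].
#' @return List of `base_instance` objects.  Each carries the canonical atom
#'   map, substitution state (`"R"`/`"free"`), protonation pattern text
#'   (`"1H 3 7 9R"` style, or `"R?"`/`"No R?"` when hydrogens are not
#'   modelled), formal charge, ring plane and molecule id.
#' @export
find_bases <- function(s, params = geometry_params()) {
  stopifnot(inherits(s, "crystal_structure"))
  if (is.null(s$bonds)) s <- infer_bonds(s, params = params)
  el <- s$atoms$element
  mol <- .molecule_ids(s)
  heavy <- which(el != "H")
  if (!length(heavy)) return(list())
  # adjacency lists over all atoms
  nb <- vector("list", nrow(s$atoms))
  if (nrow(s$bonds)) for (r in seq_len(nrow(s$bonds))) {
    i <- s$bonds[r, 1]; j <- s$bonds[r, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  elements_seen <- unique(el)
  col_of <- stats::setNames(seq_along(elements_seen), elements_seen)
  out <- list()
  for (m in unique(mol[heavy])) {
    comp <- heavy[mol[heavy] == m]
    if (length(comp) < 6) next
    # heavy-atom graph of this molecule
    pairsel <- s$bonds[s$bonds[, 1] %in% comp & s$bonds[, 2] %in% comp, , drop = FALSE]
    gt <- igraph::make_graph(
      edges = as.vector(t(matrix(match(pairsel, comp), ncol = 2))),
      n = length(comp), directed = FALSE)
    igraph::V(gt)$color <- unname(col_of[el[comp]])
    for (code in base_codes()) {
      tpl <- get_template(code)
      if (length(comp) < nrow(tpl$atoms)) next
      if (!all(tpl$atoms$element %in% el[comp])) next
      gp <- igraph::make_graph(
        edges = as.vector(t(matrix(match(tpl$bonds, tpl$atoms$id), ncol = 2))),
        n = nrow(tpl$atoms), directed = FALSE)
      igraph::V(gp)$color <- unname(col_of[tpl$atoms$element])
      maps <- igraph::subgraph_isomorphisms(gp, gt, method = "vf2")
      if (!length(maps)) next
      # global atom indices per mapping, deduplicated by matched set
      cand <- lapply(maps, function(mp) comp[as.integer(mp)])
      keys <- vapply(cand, function(v) paste(sort(v), collapse = ","), "")
      cand <- lapply(split(cand, keys), function(group) {
        ks <- vapply(group, function(v) paste(sprintf("%06d", v), collapse = ","), "")
        group[[order(ks)[1]]]
      })
      for (idx in cand) {
        inst <- .make_instance(s, code, tpl, idx, nb, el, mol, params)
        if (!is.null(inst)) out[[length(out) + 1]] <- inst
      }
    }
  }
  out
}

.make_instance <- function(s, code, tpl, idx, nb, el, mol, params) {
  names(idx) <- tpl$atoms$id
  matched <- unname(idx)
  g_id <- tpl$glycosidic
  c1 <- NA_integer_
  substitution <- "free"
  for (k in seq_along(idx)) {
    a <- idx[[k]]
    outside <- setdiff(nb[[a]], matched)
    outside_heavy <- outside[el[outside] != "H"]
    if (!length(outside_heavy)) next
    if (names(idx)[k] == g_id) {
      if (length(outside_heavy) > 1 || el[outside_heavy] != "C")
        return(NULL)  # glycosidic N bonded to a non-carbon heavy atom
      substitution <- "R"
      c1 <- outside_heavy
    } else {
      return(NULL)  # substituted in a place other than the glycosidic bond
    }
  }
  # organometallic exclusion
  for (a in matched) {
    nbs <- nb[[a]]
    if (any(!el[nbs] %in% params$nonmetals)) return(NULL)
  }
  h_map <- lapply(seq_along(idx), function(k) {
    nbs <- nb[[idx[[k]]]]
    nbs[el[nbs] == "H"]
  })
  names(h_map) <- names(idx)
  base_h <- sum(lengths(h_map))
  nonstandard <- character(0)
  carbonyls <- tpl$atoms$id[tpl$atoms$kind == "carbonyl"]
  for (cid in carbonyls) if (length(h_map[[cid]])) {
    nonstandard <- c(nonstandard, paste0("H on carbonyl ", tpl$atoms$label[tpl$atoms$id == cid]))
    warning("nonstandard protonation in ", s$id, ": ", tail(nonstandard, 1))
  }
  if (base_h == 0) {
    protonation <- if (substitution == "R") "R?" else "No R?"
    charge <- NA_integer_
  } else {
    prot_pos <- ring_n_positions(code)
    has_h <- vapply(as.character(prot_pos), function(p) length(h_map[[p]]) > 0,
                    logical(1))
    protonation <- make_protonation(code, prot_pos[has_h], substitution)
    charge <- pattern_charge(code, protonation)
  }
  ring_idx <- idx[tpl$atoms$id[tpl$atoms$ring]]
  plane <- .ring_plane(coords(s), ring_idx, idx[as.character(1:6)])
  structure(list(
    code = code,
    atom_map = idx,
    h_map = h_map,
    substitution = substitution,
    protonation = protonation,
    charge = charge,
    plane = plane,
    molecule_id = mol[matched[1]],
    c1_atom = c1,
    is_mate = any(s$atoms$is_mate[matched]),
    nonstandard = nonstandard,
    atoms_idx = matched,
    structure_id = s$id
  ), class = "base_instance")
}

# least-squares ring plane with the normal oriented by the canonical
# hexagon circuit (right-hand rule over positions 1..6), making it a face
# label rather than an arbitrary fit direction
.ring_plane <- function(xyz, ring_idx, hex_idx) {
  pts <- xyz[ring_idx, , drop = FALSE]
  centroid <- colMeans(pts)
  sv <- svd(sweep(pts, 2, centroid))
  if (sv$d[2] < 1e-6) stop("degenerate geometry: ring atoms are collinear")
  normal <- sv$v[, 3]
  hex <- xyz[hex_idx, , drop = FALSE]
  hc <- colMeans(hex)
  circ <- c(0, 0, 0)
  for (k in 1:6) {
    a <- hex[k, ] - hc
    b <- hex[(k %% 6) + 1, ] - hc
    circ <- circ + c(a[2] * b[3] - a[3] * b[2],
                     a[3] * b[1] - a[1] * b[3],
                     a[1] * b[2] - a[2] * b[1])
  }
  if (sum(normal * circ) < 0) normal <- -normal
  list(centroid = centroid, normal = .unit(normal))
}

#' @export
print.base_instance <- function(x, ...) {
  cat(sprintf("<base_instance %s> %s, '%s', charge %s%s\n", x$code,
              x$substitution, x$protonation,
              ifelse(is.na(x$charge), "?", sprintf("%+d", x$charge)),
              if (x$is_mate) " (symmetry mate)" else ""))
  invisible(x)
}

#' Substitution state of a base instance
#'
#' `"R"` when the glycosidic nitrogen carries a carbon substituent, `"free"`
#' when it carries only hydrogen or nothing.  Matches with a non-carbon
#' heavy substituent at the glycosidic nitrogen are rejected during
#' recognition and never reach this point.
#'
#' @param b A `base_instance`.
#' @return `"R"` or `"free"`.
#' @export
classify_substitution <- function(b) {
  stopifnot(inherits(b, "base_instance"))
  b$substitution
}

#' Protonation pattern of a base instance
#'
#' Purines report positions 1, 3, 7, 9 and pyrimidines 1, 3; the glycosidic
#' position shows `R` when substituted.  When no hydrogen is modelled on the
#' base the pattern is `"R?"` or `"No R?"` -- hydrogen positions are never
#' imputed from chemical intuition.
#'
#' @param b A `base_instance`.
#' @return Pattern text.
#' @export
classify_protonation <- function(b) {
  stopifnot(inherits(b, "base_instance"))
  b$protonation
}

#' Formal charge of a base instance
#'
#' Observed ring N-H count minus the neutral reference for the base and
#' substitution state.
#'
#' @param b A `base_instance`.
#' @return Integer charge, `NA` when the protonation is undetermined.
#' @export
formal_charge <- function(b) {
  stopifnot(inherits(b, "base_instance"))
  b$charge
}
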