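# Crystal-structure container and I/O.
#
# Small-molecule CIF (fractional coordinates, `_symmetry_equiv_pos_as_xyz`)
# and coordinate PDB are supported.  Coordinate-only inputs (no unit cell)
# are legal and simply disable symmetry expansion, which keeps the geometry
# core usable on idealized fixtures.

#' Construct a crystal structure
#'
#' @param id Structure identifier (refcode or filename stem).
#' @param atoms Data.frame with columns `label`, `element`, `x`, `y`, `z`
#'   and optionally `occ`, `is_mate`, `source_op`.
#' @param cell `NULL` or a list with `a`, `b`, `c`, `alpha`, `beta`, `gamma`
#'   and `symops` (list of `list(R = 3x3, t = length-3)` fractional
#'   operators; the identity is added when missing).
#' @param bonds `NULL` or a two-column integer matrix of atom indices.
#' @param meta List of optional metadata (`r_factor`, ...).
#' @return An object of class `crystal_structure`.
#' @export
crystal_structure <- function(id, atoms, cell = NULL, bonds = NULL, meta = list()) {
  stopifnot(is.data.frame(atoms),
            all(c("label", "element", "x", "y", "z") %in% names(atoms)))
  if (!nrow(atoms)) stop("empty structure: no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atomic coordinates")
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$is_mate)) atoms$is_mate <- FALSE
  if (is.null(atoms$source_op)) atoms$source_op <- NA_integer_
  rownames(atoms) <- NULL
  if (!is.null(cell)) {
    stopifnot(all(c("a", "b", "c", "alpha", "beta", "gamma") %in% names(cell)))
    if (is.null(cell$symops) || !length(cell$symops))
      cell$symops <- list(list(R = diag(3), t = c(0, 0, 0)))
    has_id <- any(vapply(cell$symops, function(op)
      all(abs(op$R - diag(3)) < 1e-9) && all(abs(op$t %% 1) < 1e-9), logical(1)))
    if (!has_id)
      cell$symops <- c(list(list(R = diag(3), t = c(0, 0, 0))), cell$symops)
    if (.cell_volume(cell) <= 0) stop("unit cell volume must be positive")
  }
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (nrow(bonds) && (max(bonds) > nrow(atoms) || min(bonds) < 1))
      stop("bond indices out of range")
  }
  meta$has_hydrogens <- any(atoms$element == "H")
  structure(list(id = id, atoms = atoms, cell = cell, bonds = bonds, meta = meta),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("<crystal_structure %s> %d atoms (%d H)%s%s\n", x$id,
              nrow(x$atoms), sum(x$atoms$element == "H"),
              if (is.null(x$cell)) ", no cell" else
                sprintf(", cell %.2f %.2f %.2f A, %d symop(s)",
                        x$cell$a, x$cell$b, x$cell$c, length(x$cell$symops)),
              if (any(x$atoms$is_mate)) sprintf(", %d symmetry-mate atoms",
                                                sum(x$atoms$is_mate)) else ""))
  invisible(x)
}

#' Cartesian coordinates of a structure
#' @param s A `crystal_structure`.
#' @return Numeric matrix with one row per atom.
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

# ---- cell algebra -----------------------------------------------------------

# orthogonalization matrix: cart = M %*% frac (a along x, b in xy plane)
.cell_matrix <- function(cell) {
  al <- .deg2rad(cell$alpha); be <- .deg2rad(cell$beta); ga <- .deg2rad(cell$gamma)
  cx <- cell$c * cos(be)
  cy <- cell$c * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(cell$c^2 - cx^2 - cy^2, 0))
  matrix(c(cell$a, 0, 0,
           cell$b * cos(ga), cell$b * sin(ga), 0,
           cx, cy, cz), 3, 3)
}

.cell_volume <- function(cell) det(.cell_matrix(cell))

#' Parse a symmetry operator string
#'
#' Converts an `xyz`-style operator such as `"-x, y+1/2, -z+1/2"` into a
#' fractional rotation matrix and translation vector.
#'
#' @param txt Operator text.
#' @return List with `R` (3x3) and `t` (length 3).
#' @export
parse_symop <- function(txt) {
  parts <- strsplit(tolower(gsub("\\s", "", txt)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry operator: '", txt, "'")
  evalp <- function(expr, x, y, z) {
    if (grepl("[^xyz0-9+/*.()-]", expr))
      stop("unexpected token in symmetry operator: '", expr, "'")
    eval(parse(text = expr), list(x = x, y = y, z = z))
  }
  t <- vapply(parts, evalp, numeric(1), x = 0, y = 0, z = 0)
  R <- cbind(vapply(parts, evalp, numeric(1), x = 1, y = 0, z = 0) - t,
             vapply(parts, evalp, numeric(1), x = 0, y = 1, z = 0) - t,
             vapply(parts, evalp, numeric(1), x = 0, y = 0, z = 1) - t)
  dimnames(R) <- NULL
  list(R = R, t = unname(t))
}

# ---- CIF --------------------------------------------------------------------

.cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  toks <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

.cif_num <- function(x) {
  x[x %in% c(".", "?")] <- NA
  suppressWarnings(as.numeric(sub("\\(\\d+\\)$", "", x)))
}

# minimal small-molecule CIF reader: key-value pairs and loops
.parse_cif <- function(lines) {
  lines <- sub("^#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  singles <- list()
  loops <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (grepl("^data_", line) || grepl("^;", line)) { i <- i + 1; next }
    if (tolower(line) == "loop_") {
      i <- i + 1
      tags <- character(0)
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        tags <- c(tags, .cif_tokens(trimws(lines[i]))[1])
        i <- i + 1
      }
      rows <- list()
      buf <- character(0)
      while (i <= n) {
        line <- trimws(lines[i])
        if (grepl("^(_|loop_|data_)", line, ignore.case = TRUE)) break
        buf <- c(buf, .cif_tokens(line))
        while (length(buf) >= length(tags)) {
          rows[[length(rows) + 1]] <- buf[seq_along(tags)]
          buf <- buf[-seq_along(tags)]
        }
        i <- i + 1
      }
      if (length(rows)) {
        tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
        names(tab) <- tolower(tags)
        loops[[length(loops) + 1]] <- tab
      }
      next
    }
    if (grepl("^_", line)) {
      toks <- .cif_tokens(line)
      if (length(toks) >= 2)
        singles[[tolower(toks[1])]] <- paste(toks[-1], collapse = " ")
      i <- i + 1
      next
    }
    i <- i + 1
  }
  list(singles = singles, loops = loops)
}

.read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cif <- tryCatch(.parse_cif(lines), error = function(e)
    stop("CIF parse failure in '", path, "': ", conditionMessage(e)))
  sg <- cif$singles
  cell <- NULL
  if (!is.null(sg[["_cell_length_a"]])) {
    cell <- list(a = .cif_num(sg[["_cell_length_a"]]),
                 b = .cif_num(sg[["_cell_length_b"]]),
                 c = .cif_num(sg[["_cell_length_c"]]),
                 alpha = .cif_num(sg[["_cell_angle_alpha"]] %||% "90"),
                 beta  = .cif_num(sg[["_cell_angle_beta"]] %||% "90"),
                 gamma = .cif_num(sg[["_cell_angle_gamma"]] %||% "90"))
    symtags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
    ops <- character(0)
    for (lp in cif$loops) {
      hit <- intersect(symtags, names(lp))
      if (length(hit)) ops <- c(ops, lp[[hit[1]]])
    }
    for (tg in symtags) if (!is.null(sg[[tg]])) ops <- c(ops, sg[[tg]])
    if (length(ops)) cell$symops <- lapply(ops, parse_symop)
  }
  atom_lp <- NULL
  for (lp in cif$loops)
    if ("_atom_site_label" %in% names(lp)) { atom_lp <- lp; break }
  if (is.null(atom_lp) || !nrow(atom_lp))
    stop("empty structure: no _atom_site loop in '", path, "'")
  lab <- atom_lp[["_atom_site_label"]]
  el <- atom_lp[["_atom_site_type_symbol"]]
  if (is.null(el)) el <- .element_from_label(lab)
  occ <- .cif_num(atom_lp[["_atom_site_occupancy"]] %||% rep("1", length(lab)))
  occ[is.na(occ)] <- 1
  if (!is.null(atom_lp[["_atom_site_fract_x"]]) && !is.null(cell)) {
    fr <- cbind(.cif_num(atom_lp[["_atom_site_fract_x"]]),
                .cif_num(atom_lp[["_atom_site_fract_y"]]),
                .cif_num(atom_lp[["_atom_site_fract_z"]]))
    xyz <- t(.cell_matrix(cell) %*% t(fr))
  } else if (!is.null(atom_lp[["_atom_site_cartn_x"]])) {
    xyz <- cbind(.cif_num(atom_lp[["_atom_site_cartn_x"]]),
                 .cif_num(atom_lp[["_atom_site_cartn_y"]]),
                 .cif_num(atom_lp[["_atom_site_cartn_z"]]))
  } else stop("no fractional or Cartesian coordinates in '", path, "'")
  atoms <- data.frame(label = lab, element = el,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occ = occ, stringsAsFactors = FALSE)
  # disorder: keep the majority-occupancy group of each disorder assembly
  dg <- atom_lp[["_atom_site_disorder_group"]]
  if (!is.null(dg)) {
    dg[dg %in% c(".", "?")] <- NA
    grp <- suppressWarnings(abs(as.integer(dg)))
    if (any(!is.na(grp))) {
      occ_by_grp <- tapply(atoms$occ[!is.na(grp)], grp[!is.na(grp)], mean)
      keep_grp <- as.integer(names(which.max(occ_by_grp)))
      atoms <- atoms[is.na(grp) | grp == keep_grp, , drop = FALSE]
    }
  }
  bonds <- NULL
  for (lp in cif$loops) {
    if (all(c("_geom_bond_atom_site_label_1", "_geom_bond_atom_site_label_2")
            %in% names(lp))) {
      i1 <- match(lp[["_geom_bond_atom_site_label_1"]], atoms$label)
      i2 <- match(lp[["_geom_bond_atom_site_label_2"]], atoms$label)
      ok <- !is.na(i1) & !is.na(i2)
      if (any(ok)) bonds <- cbind(i1[ok], i2[ok])
      break
    }
  }
  meta <- list(bonds_explicit = !is.null(bonds))
  rf <- sg[["_refine_ls_r_factor_gt"]] %||% sg[["_refine_ls_r_factor_all"]]
  if (!is.null(rf)) meta$r_factor <- .cif_num(rf)
  crystal_structure(id = sub("\\.cif$", "", basename(path)),
                    atoms = atoms, cell = cell, bonds = bonds, meta = meta)
}

.write_cif <- function(s, path) {
  if (!nrow(s$atoms)) stop("empty structure: nothing to write")
  cell <- s$cell
  lines <- c(paste0("data_", gsub("[^A-Za-z0-9_]", "_", s$id)))
  if (is.null(cell)) {
    span <- max(apply(coords(s), 2, function(v) diff(range(v)))) + 20
    cell <- list(a = span, b = span, c = span,
                 alpha = 90, beta = 90, gamma = 90,
                 symops = list(list(R = diag(3), t = c(0, 0, 0))))
    lines <- c(lines, "# no experimental cell; dummy P1 cell for transport")
  }
  lines <- c(lines,
             sprintf("_cell_length_a %.6f", cell$a),
             sprintf("_cell_length_b %.6f", cell$b),
             sprintf("_cell_length_c %.6f", cell$c),
             sprintf("_cell_angle_alpha %.4f", cell$alpha),
             sprintf("_cell_angle_beta %.4f", cell$beta),
             sprintf("_cell_angle_gamma %.4f", cell$gamma),
             "loop_", "_symmetry_equiv_pos_as_xyz",
             vapply(cell$symops %||% list(list(R = diag(3), t = c(0, 0, 0))),
                    function(op) paste0("'", .symop_text(op), "'"), ""))
  M <- .cell_matrix(cell)
  fr <- t(solve(M) %*% t(coords(s)))
  lines <- c(lines, "loop_", "_atom_site_label", "_atom_site_type_symbol",
             "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
             "_atom_site_occupancy",
             sprintf("%s %s %.6f %.6f %.6f %.4f",
                     make.unique(s$atoms$label, sep = "_"), s$atoms$element,
                     fr[, 1], fr[, 2], fr[, 3], s$atoms$occ))
  writeLines(lines, path)
  invisible(path)
}

.symop_text <- function(op) {
  term <- function(coef, t) {
    v <- c("x", "y", "z")
    out <- ""
    for (k in 1:3) {
      if (abs(coef[k]) > 1e-9) {
        sgn <- if (coef[k] > 0 && nzchar(out)) "+" else if (coef[k] < 0) "-" else ""
        out <- paste0(out, sgn, v[k])
      }
    }
    if (abs(t) > 1e-9) {
      fr <- c("1/2" = 0.5, "1/3" = 1 / 3, "2/3" = 2 / 3,
              "1/4" = 0.25, "3/4" = 0.75, "1/6" = 1 / 6, "5/6" = 5 / 6)
      hit <- names(fr)[which(abs(fr - abs(t)) < 1e-6)]
      txt <- if (length(hit)) hit[1] else format(abs(t))
      out <- paste0(out, if (t > 0) "+" else "-", txt)
    }
    if (out == "") "0" else out
  }
  paste(vapply(1:3, function(r) term(op$R[r, ], op$t[r]), ""), collapse = ",")
}

# ---- PDB --------------------------------------------------------------------

.read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (!nrow(at)) stop("empty structure: no atoms in '", path, "'")
  if (!is.null(at$alt)) {
    alt <- at$alt
    at <- at[is.na(alt) | alt %in% c("", " ", "A"), , drop = FALSE]
  }
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(!nzchar(trimws(el))))
    el <- .element_from_label(at$elety)
  el <- trimws(el)
  el <- paste0(toupper(substring(el, 1, 1)), tolower(substring(el, 2)))
  atoms <- data.frame(label = trimws(at$elety), element = el,
                      x = at$x, y = at$y, z = at$z,
                      occ = at$o %||% 1, stringsAsFactors = FALSE)
  cell <- NULL
  cl <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cl)) {
    f <- suppressWarnings(as.numeric(c(
      substr(cl[1], 7, 15), substr(cl[1], 16, 24), substr(cl[1], 25, 33),
      substr(cl[1], 34, 40), substr(cl[1], 41, 47), substr(cl[1], 48, 54))))
    if (!anyNA(f) && all(f[1:3] > 0))
      cell <- list(a = f[1], b = f[2], c = f[3],
                   alpha = f[4], beta = f[5], gamma = f[6],
                   symops = list(list(R = diag(3), t = c(0, 0, 0))))
  }
  crystal_structure(id = sub("\\.pdb$", "", basename(path)),
                    atoms = atoms, cell = cell)
}

.write_pdb <- function(s, path) {
  if (!nrow(s$atoms)) stop("empty structure: nothing to write")
  lines <- character(0)
  if (!is.null(s$cell))
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     s$cell$a, s$cell$b, s$cell$c,
                     s$cell$alpha, s$cell$beta, s$cell$gamma)
  lab <- make.unique(s$atoms$label, sep = "")
  lines <- c(lines, sprintf(
    "HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(s$atoms)), substr(lab, 1, 4),
    s$atoms$x, s$atoms$y, s$atoms$z, s$atoms$occ, 0,
    toupper(s$atoms$element)), "END")
  writeLines(lines, path)
  invisible(path)
}

# ---- public I/O -------------------------------------------------------------

#' Read a crystal structure
#'
#' @param path File path (small-molecule CIF or PDB).
#' @param format `"cif"`, `"pdb"` or `"auto"` (by extension).
#' @return A [crystal_structure()].  Atoms are in Cartesian angstroms; cell
#'   and symmetry operators are kept when present; for disordered models the
#'   highest-occupancy alternative is retained.
#' @export
read_structure <- function(path, format = c("auto", "cif", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "cif"
  if (format == "cif") .read_cif(path) else .read_pdb(path)
}

#' Write a crystal structure
#'
#' Round trip preserves elements, coordinates (to 1e-3 A) and the unit
#' cell.  Structures without a cell are written with a generous dummy P1
#' cell (flagged by a comment in CIF output).
#'
#' @param s A `crystal_structure`.
#' @param path Output path.
#' @param format `"cif"`, `"pdb"` or `"auto"` (by extension).
#' @return The path, invisibly.
#' @export
write_structure <- function(s, path, format = c("auto", "cif", "pdb")) {
  stopifnot(inherits(s, "crystal_structure"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "cif"
  if (format == "cif") .write_cif(s, path) else .write_pdb(s, path)
}

# ---- bonds ------------------------------------------------------------------

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their separation does not exceed the sum of
#' their covalent radii plus `tol`.  Hydrogens are attached to exactly one
#' heavy atom (the nearest within 1.3 A); hydrogens with no heavy partner
#' are dropped with a warning.  When the input carries an explicit bond
#' table (CIF `_geom_bond_*`), it is used verbatim and inference is skipped.
#'
#' @param s A `crystal_structure`.
#' @param tol Distance tolerance in angstroms.
#' @param params A [geometry_params()] object (for the covalent radii).
#' @return The structure with a `bonds` matrix.
#' @export
infer_bonds <- function(s, tol = NULL, params = geometry_params()) {
  stopifnot(inherits(s, "crystal_structure"))
  if (isTRUE(s$meta$bonds_explicit) && !is.null(s$bonds)) return(s)
  tol <- tol %||% params$covalent_tolerance
  xyz <- coords(s)
  el <- s$atoms$element
  r <- .covr(params, el)
  d <- .cross_dist(xyz, xyz)
  lim <- outer(r, r, "+") + tol
  adj <- d <= lim & d > 0.4
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  if (nrow(idx)) {
    is_h <- el == "H"
    keep <- rep(TRUE, nrow(idx))
    # no H-H bonds
    keep[is_h[idx[, 1]] & is_h[idx[, 2]]] <- FALSE
    idx <- idx[keep, , drop = FALSE]
  }
  # each H keeps only its nearest heavy atom (within 1.3 A)
  drop_atom <- logical(nrow(s$atoms))
  for (h in which(el == "H")) {
    heavy <- which(el != "H")
    dh <- d[h, heavy]
    if (!length(heavy) || min(dh) > 1.3) {
      warning("orphan hydrogen '", s$atoms$label[h], "' dropped (no heavy atom within 1.3 A)")
      drop_atom[h] <- TRUE
      next
    }
    best <- heavy[which.min(dh)]
    inv <- (idx[, 1] == h & idx[, 2] != best) | (idx[, 2] == h & idx[, 1] != best)
    idx <- idx[!inv, , drop = FALSE]
    if (!any((idx[, 1] == h & idx[, 2] == best) | (idx[, 2] == h & idx[, 1] == best)))
      idx <- rbind(idx, c(h, best))
  }
  if (any(drop_atom)) {
    remap <- cumsum(!drop_atom)
    idx <- idx[!drop_atom[idx[, 1]] & !drop_atom[idx[, 2]], , drop = FALSE]
    idx <- cbind(remap[idx[, 1]], remap[idx[, 2]])
    s$atoms <- s$atoms[!drop_atom, , drop = FALSE]
    rownames(s$atoms) <- NULL
  }
  s$bonds <- matrix(as.integer(idx), ncol = 2)
  s
}

# connected components of the covalent graph (molecule ids)
.molecule_ids <- function(s) {
  if (is.null(s$bonds)) stop("bonds not inferred")
  g <- igraph::make_graph(edges = as.vector(t(s$bonds)), n = nrow(s$atoms),
                          directed = FALSE)
  unname(igraph::components(g)$membership)
}

# ---- symmetry expansion -----------------------------------------------------

#' Generate symmetry-mate molecules around the asymmetric unit
#'
#' Applies every symmetry operator (plus lattice translations) to whole
#' covalent molecules and keeps each copy that brings any atom within
#' `radius` of the asymmetric unit.  Identity images are excluded; mates are
#' flagged (`is_mate`, `source_op`).  Expanding an already expanded
#' structure adds no atoms.
#'
#' @param s A `crystal_structure` with a cell.
#' @param radius Contact envelope in angstroms (default 6, comfortably above
#'   the largest donor-acceptor cutoff of about 4.4 A).
#' @param params A [geometry_params()].
#' @return The expanded structure.
#' @export
expand_symmetry <- function(s, radius = NULL, params = geometry_params()) {
  stopifnot(inherits(s, "crystal_structure"))
  if (is.null(s$cell)) stop("no unit cell: symmetry expansion impossible")
  radius <- radius %||% params$contact_radius
  if (radius <= 0) { s$meta$expanded <- TRUE; return(s) }
  if (is.null(s$bonds)) s <- infer_bonds(s, params = params)
  M <- .cell_matrix(s$cell)
  Minv <- solve(M)
  au <- which(!s$atoms$is_mate)
  xyz_all <- coords(s)
  xyz_au <- xyz_all[au, , drop = FALSE]
  fr_au <- t(Minv %*% t(xyz_au))
  mol <- .molecule_ids(s)[au]
  diam <- max(.cross_dist(xyz_au, xyz_au))
  nmax <- pmin(pmax(ceiling((radius + diam) / c(s$cell$a, s$cell$b, s$cell$c)), 1), 3)
  new_atoms <- list()
  new_bonds <- list()
  n_existing <- nrow(s$atoms)
  au_bonds <- s$bonds[s$bonds[, 1] %in% au & s$bonds[, 2] %in% au, , drop = FALSE]
  seen <- xyz_all
  for (k in seq_along(s$cell$symops)) {
    op <- s$cell$symops[[k]]
    for (n1 in -nmax[1]:nmax[1]) for (n2 in -nmax[2]:nmax[2])
      for (n3 in -nmax[3]:nmax[3]) {
        is_identity <- all(abs(op$R - diag(3)) < 1e-9) &&
          all(abs(op$t + c(n1, n2, n3)) < 1e-9)
        if (is_identity) next
        fr_new <- t(op$R %*% t(fr_au)) +
          matrix(op$t + c(n1, n2, n3), nrow(fr_au), 3, byrow = TRUE)
        xyz_new <- t(M %*% t(fr_new))
        d <- .cross_dist(xyz_new, xyz_au)
        for (m in unique(mol)) {
          rows <- which(mol == m)
          if (min(d[rows, ]) > radius) next
          # skip exact duplicates of anything already present
          dup <- .cross_dist(xyz_new[rows, , drop = FALSE], seen)
          if (max(apply(dup, 1, min)) < 1e-3) next
          a <- s$atoms[au[rows], , drop = FALSE]
          a$x <- xyz_new[rows, 1]; a$y <- xyz_new[rows, 2]; a$z <- xyz_new[rows, 3]
          a$is_mate <- TRUE
          a$source_op <- k
          offset <- n_existing + sum(vapply(new_atoms, nrow, 0L))
          new_atoms[[length(new_atoms) + 1]] <- a
          old_idx <- au[rows]
          bsel <- au_bonds[au_bonds[, 1] %in% old_idx & au_bonds[, 2] %in% old_idx,
                           , drop = FALSE]
          if (nrow(bsel))
            new_bonds[[length(new_bonds) + 1]] <-
              cbind(match(bsel[, 1], old_idx), match(bsel[, 2], old_idx)) + offset
          seen <- rbind(seen, xyz_new[rows, , drop = FALSE])
        }
      }
  }
  if (length(new_atoms)) {
    s$atoms <- rbind(s$atoms, do.call(rbind, new_atoms))
    rownames(s$atoms) <- NULL
    s$bonds <- rbind(s$bonds, do.call(rbind, new_bonds))
  }
  s$meta$expanded <- TRUE
  s
}
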