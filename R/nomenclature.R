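# Canonical base-pair names.
#
# A full name reads <codes>_<orientation><edge1><edge2>_(ab)(cd)...:
# "AA_fWH_(16)(67)" is an adenine-adenine pair, second base flipped (f),
# Watson-Crick edge of the first base against the Hoogsteen edge of the
# second, hydrogen bonds N1(1)...N6(2) and N6(1)...N7(2).  In every
# parenthesis the first digit belongs to the first molecule.  The middle
# block is redundant ("AA_(16)(67)" is already unique) and is regenerated
# from the bond list on request.

.code_regex <- "(Hx|A|G|T|U|C)"

#' Parse a canonical pair name
#'
#' Accepts the full form (`"AA_fWH_(16)(67)"`) and the short form
#' (`"AA_(16)(67)"`).  For the short form the edges are reconstructed from
#' the atom numbers; the orientation letter is recovered from the built-in
#' catalogue when the bond list matches a known pair type, otherwise left
#' `NA`.
#'
#' @param text Name text.
#' @return An object of class `pair_name`: list with `codes` (length-2
#'   character), `orientation` (`"f"`, `"m"` or `NA`), `edges` (length-2),
#'   `bonds` (two-column integer matrix, first-molecule atom first, rows
#'   sorted ascending).
#' @export
parse_name <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  full <- paste0("^", .code_regex, .code_regex,
                 "_([fm])([WHS])([WHS])_((?:\\(\\d\\d\\))+)$")
  short <- paste0("^", .code_regex, .code_regex, "_((?:\\(\\d\\d\\))+)$")
  if (grepl(full, text)) {
    m <- regmatches(text, regexec(full, text))[[1]]
    codes <- m[2:3]; orientation <- m[4]; edges <- m[5:6]; bond_txt <- m[7]
  } else if (grepl(short, text)) {
    m <- regmatches(text, regexec(short, text))[[1]]
    codes <- m[2:3]; orientation <- NA_character_; edges <- NULL
    bond_txt <- m[4]
  } else {
    bad <- if (grepl("_[^fm_]?[WHS]{2}_", text)) "orientation letter" else "name"
    stop("cannot parse pair ", bad, " in '", text, "'")
  }
  digs <- regmatches(bond_txt, gregexpr("\\d\\d", bond_txt))[[1]]
  bonds <- cbind(as.integer(substring(digs, 1, 1)),
                 as.integer(substring(digs, 2, 2)))
  # validate atom numbers against the templates
  for (i in seq_len(nrow(bonds))) {
    .interaction_id(codes[1], bonds[i, 1])
    .interaction_id(codes[2], bonds[i, 2])
  }
  if (is.null(edges)) {
    edges <- c(assign_edge(codes[1], unique(bonds[, 1])),
               assign_edge(codes[2], unique(bonds[, 2])))
    hit <- .catalog_lookup(codes, bonds)
    if (!is.na(hit)) orientation <- hit
  }
  .new_pair_name(codes, orientation, edges, bonds)
}

.new_pair_name <- function(codes, orientation, edges, bonds) {
  o <- order(bonds[, 1], bonds[, 2])
  structure(list(codes = codes, orientation = orientation,
                 edges = edges, bonds = bonds[o, , drop = FALSE]),
            class = "pair_name")
}

# orientation letter of a catalogue entry with the same codes and bond set
.catalog_lookup <- function(codes, bonds) {
  cat <- pair_catalog()
  key <- .bond_set_key(bonds)
  for (i in seq_len(nrow(cat))) {
    pn <- parse_name(cat$name[i])
    if (identical(pn$codes, codes) && identical(.bond_set_key(pn$bonds), key))
      return(pn$orientation)
  }
  NA_character_
}

.bond_set_key <- function(bonds) {
  paste(sort(paste0(bonds[, 1], bonds[, 2])), collapse = "|")
}

#' Render a pair name
#'
#' The renderer applies the stated ordering rule: parentheses arranged by
#' increasing first-molecule atom number, then second.  (One printed
#' catalogue spelling, `GG_fWH_(26)(17)(68)`, deviates from that rule; use
#' [same_pair_name()] to compare names as bond sets.)
#'
#' @param x A `pair_name`.
#' @param short Drop the orientation/edge block?
#' @return Name text.
#' @export
render_name <- function(x, short = FALSE) {
  stopifnot(inherits(x, "pair_name"))
  bonds <- paste0("(", x$bonds[, 1], x$bonds[, 2], ")", collapse = "")
  if (short) return(paste0(paste0(x$codes, collapse = ""), "_", bonds))
  if (is.na(x$orientation))
    stop("orientation unknown; render with short = TRUE")
  paste0(paste0(x$codes, collapse = ""), "_",
         x$orientation, x$edges[1], x$edges[2], "_", bonds)
}

#' @export
print.pair_name <- function(x, ...) {
  txt <- if (is.na(x$orientation)) render_name(x, short = TRUE) else render_name(x)
  cat("<pair_name>", txt, "\n")
  invisible(x)
}

#' @export
format.pair_name <- function(x, ...) {
  if (is.na(x$orientation)) render_name(x, short = TRUE) else render_name(x)
}

#' Compare two pair names as bond sets
#'
#' Names are equal when codes, orientation and edges agree and the bond
#' lists are equal as sets, so alias spellings of the same pair (bond
#' parentheses in a different order) compare equal.
#'
#' @param a,b `pair_name` objects or name strings.
#' @return Logical.
#' @export
same_pair_name <- function(a, b) {
  if (is.character(a)) a <- parse_name(a)
  if (is.character(b)) b <- parse_name(b)
  identical(a$codes, b$codes) &&
    identical(a$edges, b$edges) &&
    (is.na(a$orientation) || is.na(b$orientation) ||
       identical(a$orientation, b$orientation)) &&
    identical(.bond_set_key(a$bonds), .bond_set_key(b$bonds))
}

# Canonical name construction from a detected contact list.
#
# contacts: two-column integer matrix, column 1 = canonical numbers on side
# 1, column 2 on side 2.  normal_dot: dot product of the two face-labelled
# plane normals.  Molecule order: higher-precedence edge (W > H > S) first;
# for equal edges the molecule with the lexicographically smaller sorted
# atom-number list first.
.canonical_name <- function(code1, code2, contacts, normal_dot) {
  e1 <- assign_edge(code1, unique(contacts[, 1]))
  e2 <- assign_edge(code2, unique(contacts[, 2]))
  orientation <- if (normal_dot >= 0) "m" else "f"
  swap <- FALSE
  if (is.na(e1) || is.na(e2)) {
    # unclassifiable: keep input order, edges as-is
  } else {
    rank <- c(W = 1, H = 2, S = 3)
    if (rank[e2] < rank[e1]) swap <- TRUE
    else if (rank[e2] == rank[e1] && !identical(code1, code2)) {
      kind <- vapply(c(code1, code2), function(cc) get_template(cc)$kind, "")
      if (kind[2] == "purine" && kind[1] == "pyrimidine") swap <- TRUE
      else if (kind[1] == kind[2] && code2 < code1) swap <- TRUE
    } else if (rank[e2] == rank[e1]) {
      a1 <- sort(contacts[, 1]); a2 <- sort(contacts[, 2])
      n <- max(length(a1), length(a2))
      a1 <- c(a1, rep(10L, n - length(a1)))
      a2 <- c(a2, rep(10L, n - length(a2)))
      cmp <- a2 - a1
      nz <- which(cmp != 0)
      if (length(nz) && cmp[nz[1]] < 0) swap <- TRUE
      else if (!length(nz)) {
        # identical first-molecule atom lists; fall back to full bond tuples
        k1 <- paste(sort(paste0(contacts[, 1], contacts[, 2])), collapse = "")
        k2 <- paste(sort(paste0(contacts[, 2], contacts[, 1])), collapse = "")
        if (k2 < k1) swap <- TRUE
      }
    }
  }
  if (swap) {
    contacts <- contacts[, 2:1, drop = FALSE]
    tmp <- e1; e1 <- e2; e2 <- tmp
    tmp <- code1; code1 <- code2; code2 <- tmp
  }
  list(name = .new_pair_name(c(code1, code2), orientation, c(e1, e2), contacts),
       swapped = swap)
}

#' Map a pair name to Leontis-Westhof style annotation
#'
#' The flipped/moved orientation letter corresponds to the cis/trans strand
#' orientation of the RNA nomenclature: `f` maps to *cis*, `m` to *trans*;
#' edges pass through unchanged.
#'
#' @param x A `pair_name` or name string.
#' @return List with `orientation` (`"cis"`/`"trans"`), `edges`, and `lw`
#'   (compact text such as `"tWW"`).
#' @examples
#' lw_map("UU_mWW_(34)(43)")$lw  # "tWW"
#' @export
lw_map <- function(x) {
  if (is.character(x)) x <- parse_name(x)
  if (is.na(x$orientation)) stop("orientation unknown; cannot map to cis/trans")
  ori <- if (x$orientation == "f") "cis" else "trans"
  list(orientation = ori, edges = x$edges,
       lw = paste0(substring(ori, 1, 1), x$edges[1], x$edges[2]))
}
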