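# Static chemical knowledge: nucleobase templates, edge maps, donor/acceptor
# roles, neutral protonation references and geometric constants.
#
# All of it is read once from inst/extdata/chem_templates.yaml (human
# editable) and cached for the session.

.pd_cache <- new.env(parent = emptyenv())

.chem_data <- function() {
  if (is.null(.pd_cache$chem)) {
    path <- system.file("extdata", "chem_templates.yaml", package = "pairdex")
    if (path == "") stop("chem_templates.yaml not found; is pairdex installed?")
    .pd_cache$chem <- yaml::read_yaml(path)
  }
  .pd_cache$chem
}

#' Supported nucleobase codes
#'
#' @return Character vector of the six supported base codes:
#'   `"A"`, `"G"`, `"Hx"`, `"T"`, `"U"`, `"C"`.
#' @export
base_codes <- function() names(.chem_data()$bases)

.check_code <- function(code) {
  if (length(code) != 1 || !code %in% base_codes())
    stop("unsupported base code: ", paste(code, collapse = ","),
         " (supported: ", paste(base_codes(), collapse = ", "), ")")
  invisible(code)
}

#' Retrieve the chemical template of a nucleobase
#'
#' A template describes the heavy-atom topology of one nucleobase: the ring
#' circuit with canonical position numbers (purines `N1,C2,N3,C4,C5,C6` fused
#' with `N7,C8,N9`; pyrimidines `N1..C6`), the exocyclic groups (amino,
#' carbonyl, methyl), the glycosidic nitrogen, the edge membership map and
#' the ring nitrogens protonated in the canonical neutral forms.
#'
#' Template atoms are addressed by ids: ring atoms by their position number
#' (`"1"`..`"9"`), exocyclic atoms by the position they are attached to plus
#' an `"x"` suffix (adenine N6 is `"6x"`).
#'
#' @param code A base code, see [base_codes()].
#' @return An object of class `base_template`: a list with elements `code`,
#'   `full_name`, `kind`, `glycosidic`, `atoms` (data.frame of id, element,
#'   ring flag, kind, attachment position, conventional label), `bonds`
#'   (character matrix of template-atom id pairs), `edges`, `ch_positions`
#'   and `neutral_nh`.
#' @examples
#' tpl <- get_template("A")
#' nrow(tpl$atoms[tpl$atoms$ring, ])  # 9 ring atoms for a purine
#' @export
get_template <- function(code) {
  .check_code(code)
  key <- paste0("tpl_", code)
  if (!is.null(.pd_cache[[key]])) return(.pd_cache[[key]])
  b <- .chem_data()$bases[[code]]
  ring_ids <- names(b$ring)
  atoms <- data.frame(
    id = ring_ids,
    element = unlist(b$ring, use.names = FALSE),
    ring = TRUE,
    kind = "ring",
    pos = ring_ids,
    label = paste0(unlist(b$ring, use.names = FALSE), ring_ids),
    stringsAsFactors = FALSE
  )
  for (ex in b$exocyclic) {
    atoms <- rbind(atoms, data.frame(
      id = ex$id, element = ex$element, ring = FALSE, kind = ex$kind,
      pos = ex$pos, label = ex$label, stringsAsFactors = FALSE
    ))
  }
  bonds <- do.call(rbind, lapply(b$ring_bonds, unlist))
  for (ex in b$exocyclic) bonds <- rbind(bonds, c(ex$pos, ex$id))
  tpl <- structure(list(
    code = code,
    full_name = b$full_name,
    kind = b$kind,
    glycosidic = as.character(b$glycosidic),
    atoms = atoms,
    bonds = bonds,
    edges = lapply(b$edges, as.integer),
    ch_positions = as.character(b$ch_positions %||% character(0)),
    neutral_nh = lapply(b$neutral_nh, as.integer)
  ), class = "base_template")
  .pd_cache[[key]] <- tpl
  tpl
}

#' @export
print.base_template <- function(x, ...) {
  cat(sprintf("<base_template %s (%s, %s)> %d heavy atoms, glycosidic N%s\n",
              x$code, x$full_name, x$kind, nrow(x$atoms), x$glycosidic))
  invisible(x)
}

#' Ring positions carrying a nitrogen that can be (de)protonated
#'
#' @param code A base code.
#' @return Integer vector: `c(1, 3, 7, 9)` for purines, `c(1, 3)` for
#'   pyrimidines.
#' @export
ring_n_positions <- function(code) {
  tpl <- get_template(code)
  ring <- tpl$atoms[tpl$atoms$ring & tpl$atoms$element == "N", "pos"]
  sort(as.integer(ring))
}

# id of the atom a canonical number refers to in a pair name: the exocyclic
# atom when one is attached at that position, otherwise the ring atom.
.interaction_id <- function(code, n) {
  tpl <- get_template(code)
  n <- as.character(n)
  exo <- tpl$atoms[!tpl$atoms$ring & tpl$atoms$pos == n, "id"]
  if (length(exo)) exo[[1]] else if (n %in% tpl$atoms$id) n else
    stop("base ", code, " has no canonical atom number ", n)
}

#' Edges a canonical atom number belongs to
#'
#' Edge membership follows the Watson-Crick / Hoogsteen / Sugar partition of
#' the base periphery.  Shared atoms (purine 2, 6, 8; pyrimidine 2, 4 and the
#' sugar-edge positions) belong to more than one edge; purine C4/C5 belong to
#' none.
#'
#' @param code A base code.
#' @param n Canonical atom number (integer).
#' @return Character vector, a subset of `c("W", "H", "S")` (possibly empty).
#' @examples
#' edges_of_atom("A", 1)  # "W"
#' edges_of_atom("U", 4)  # "W" "H"
#' @export
edges_of_atom <- function(code, n) {
  tpl <- get_template(code)
  n <- as.integer(n)
  names(which(vapply(tpl$edges, function(e) n %in% e, logical(1))))
}

#' Assign the edge used by a set of interacting atoms
#'
#' Returns the unique edge whose member set contains every atom; when more
#' than one edge qualifies, precedence Watson-Crick > Hoogsteen > Sugar
#' applies.
#'
#' @param code A base code.
#' @param atoms Integer vector of canonical atom numbers (nonempty).
#' @return `"W"`, `"H"` or `"S"`, or `NA_character_` when no single edge
#'   contains all atoms (an unclassifiable contact).
#' @export
assign_edge <- function(code, atoms) {
  tpl <- get_template(code)
  atoms <- as.integer(atoms)
  if (!length(atoms)) stop("empty atom set")
  for (e in c("W", "H", "S"))
    if (all(atoms %in% tpl$edges[[e]])) return(e)
  NA_character_
}

#' Ring nitrogens protonated in the canonical neutral form
#'
#' The neutral reference against which formal charges are counted: e.g. free
#' guanine is neutral with N1-H and N9-H, an N9-substituted guanine with
#' N1-H only; cytosine is neutral with no ring N-H when N1 is substituted.
#'
#' @param code A base code.
#' @param substitution `"R"` (glycosidic substituent) or `"free"`.
#' @return Integer vector of ring positions.
#' @export
neutral_nh_reference <- function(code, substitution = c("R", "free")) {
  substitution <- match.arg(substitution)
  get_template(code)$neutral_nh[[substitution]]
}

# ---- protonation pattern strings --------------------------------------------

#' Parse a protonation pattern string
#'
#' Patterns list the ring-nitrogen positions in ascending order; a position
#' followed by `H` is protonated, by `R` substituted: `"1H 3 7 9R"` is an
#' N1-protonated N9-derivative of a purine.  `"R?"` and `"No R?"` mark
#' structures whose hydrogen positions were not determined.
#'
#' @param pattern Pattern text.
#' @param code A base code (used for validation).
#' @return A list with `unknown` (logical), `substitution` (`"R"` or
#'   `"free"`), and when known, `protonated` (integer positions with H).
#' @export
parse_protonation <- function(pattern, code) {
  .check_code(code)
  pattern <- trimws(pattern)
  if (pattern %in% c("R?", "No R?")) {
    return(list(unknown = TRUE,
                substitution = if (pattern == "R?") "R" else "free",
                protonated = NA_integer_))
  }
  toks <- strsplit(pattern, "\\s+")[[1]]
  pos <- suppressWarnings(as.integer(sub("[HR]$", "", toks)))
  if (anyNA(pos)) stop("malformed protonation pattern: '", pattern, "'")
  want <- ring_n_positions(code)
  if (!identical(sort(pos), want) || is.unsorted(pos))
    stop("pattern '", pattern, "' does not list ring nitrogens ",
         paste(want, collapse = ","), " of base ", code, " in order")
  has_h <- grepl("H$", toks)
  has_r <- grepl("R$", toks)
  g <- as.integer(get_template(code)$glycosidic)
  if (any(has_r & pos != g))
    stop("pattern '", pattern, "': R allowed only at the glycosidic position N", g)
  list(unknown = FALSE,
       substitution = if (any(has_r)) "R" else "free",
       protonated = pos[has_h])
}

#' Build a protonation pattern string
#'
#' @param code A base code.
#' @param protonated Integer vector of ring-N positions carrying H.
#' @param substitution `"R"` or `"free"`.
#' @return Pattern text such as `"1H 3 7 9R"`.
#' @export
make_protonation <- function(code, protonated, substitution = c("R", "free")) {
  substitution <- match.arg(substitution)
  pos <- ring_n_positions(code)
  g <- as.integer(get_template(code)$glycosidic)
  protonated <- as.integer(protonated)
  if (substitution == "R" && g %in% protonated)
    stop("glycosidic N", g, " cannot carry both H and a substituent")
  toks <- vapply(pos, function(p) {
    if (substitution == "R" && p == g) paste0(p, "R")
    else if (p %in% protonated) paste0(p, "H")
    else as.character(p)
  }, character(1))
  paste(toks, collapse = " ")
}

#' Formal charge implied by a protonation pattern
#'
#' The charge is the number of observed ring N-H minus the size of the
#' neutral reference set for the base and substitution state: an extra
#' proton gives +1, a missing one -1.
#'
#' @param code A base code.
#' @param pattern Pattern text (see [parse_protonation()]).
#' @return Integer charge, or `NA` for `"R?"` / `"No R?"` patterns.
#' @examples
#' pattern_charge("A", "1H 3 7 9H")  # +1
#' pattern_charge("T", "1 3H")       # -1
#' @export
pattern_charge <- function(code, pattern) {
  p <- parse_protonation(pattern, code)
  if (p$unknown) return(NA_integer_)
  length(p$protonated) - length(neutral_nh_reference(code, p$substitution))
}

# ---- donor / acceptor roles -------------------------------------------------

#' Hydrogen-bond roles of the canonical interaction atoms
#'
#' For a given protonation pattern: a ring N carrying H donates, a free ring
#' N accepts, a substituted glycosidic N does neither; amino nitrogens always
#' donate (two protons), carbonyl oxygens always accept; peripheral ring C-H
#' groups are weak donors (for thymine, position 5 donates through its methyl
#' hydrogens).  When the pattern is unknown (`"R?"`, `"No R?"`), ring
#' nitrogens get the union of both capabilities.
#'
#' @param pattern Protonation pattern text.
#' @param code A base code.
#' @return A data.frame with columns `n` (canonical number), `id` (template
#'   atom id), `element`, `donor`, `acceptor`, `weak` (C-H donor flag).
#' @export
donor_acceptor_roles <- function(pattern, code) {
  tpl <- get_template(code)
  p <- parse_protonation(pattern, code)
  rows <- list()
  g <- as.integer(tpl$glycosidic)
  for (n in ring_n_positions(code)) {
    id <- as.character(n)
    exo_here <- tpl$atoms[!tpl$atoms$ring & tpl$atoms$pos == id, , drop = FALSE]
    if (nrow(exo_here)) next  # position is represented by its exocyclic atom
    if (p$unknown) {
      subst <- p$substitution == "R" && n == g
      rows[[length(rows) + 1]] <- data.frame(
        n = n, id = id, element = "N",
        donor = !subst, acceptor = !subst, weak = FALSE)
    } else {
      subst <- p$substitution == "R" && n == g
      has_h <- n %in% p$protonated
      rows[[length(rows) + 1]] <- data.frame(
        n = n, id = id, element = "N",
        donor = !subst && has_h, acceptor = !subst && !has_h, weak = FALSE)
    }
  }
  exo <- tpl$atoms[!tpl$atoms$ring, , drop = FALSE]
  for (i in seq_len(nrow(exo))) {
    e <- exo[i, ]
    rows[[length(rows) + 1]] <- data.frame(
      n = as.integer(e$pos), id = e$id, element = e$element,
      donor = e$kind %in% c("amino", "methyl"),
      acceptor = e$kind == "carbonyl",
      weak = e$kind == "methyl")
  }
  for (cpos in tpl$ch_positions) {
    rows[[length(rows) + 1]] <- data.frame(
      n = as.integer(cpos), id = cpos, element = "C",
      donor = TRUE, acceptor = FALSE, weak = TRUE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$n), ]
  rownames(out) <- NULL
  out
}

# ---- geometry parameters ----------------------------------------------------

#' Geometric criteria used in pair detection
#'
#' Defaults implement the survey criteria: donor...acceptor separation within
#' the Bondi van der Waals radius sum plus 1 A, D...A vector within 45 deg of
#' both ring planes, D-H...A of at least 120 deg when hydrogens are modelled,
#' at least two hydrogen bonds per pair, and D-H bond lengths normalized to
#' averaged neutron values (C-H 1.083, N-H 1.009, O-H 0.983 A).
#'
#' @param ... Named overrides of any default (`da_margin`, `plane_angle_max`,
#'   `dha_min`, `covalent_tolerance`, `min_hbonds`, `contact_radius`,
#'   `vdw_radii`, `covalent_radii`, `neutron_dh`, `nonmetals`).
#' @return An object of class `geometry_params`.
#' @examples
#' p <- geometry_params(plane_angle_max = 30)
#' p$plane_angle_max
#' @export
geometry_params <- function(...) {
  p <- .chem_data()$params
  p$vdw_radii <- unlist(p$vdw_radii)
  p$covalent_radii <- unlist(p$covalent_radii)
  p$neutron_dh <- unlist(p$neutron_dh)
  p$nonmetals <- unlist(p$nonmetals)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown geometry parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  stopifnot(p$da_margin >= 0, p$plane_angle_max > 0, p$plane_angle_max < 180,
            p$dha_min > 0, p$dha_min < 180, p$covalent_tolerance > 0,
            p$min_hbonds >= 1)
  structure(p, class = "geometry_params")
}

.vdw <- function(p, element) {
  r <- p$vdw_radii[element]
  if (anyNA(r)) r[is.na(r)] <- 1.7
  unname(r)
}

.covr <- function(p, element) {
  r <- p$covalent_radii[element]
  if (anyNA(r)) r[is.na(r)] <- 1.5
  unname(r)
}
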