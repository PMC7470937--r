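# Survey statistics: refcode-family deduplication, frequency tables,
# protonation cross-tabs and hydrogen-bond geometry summaries.
#
# Frequencies count one occurrence per refcode family and pair type;
# geometry statistics use every deposition and every unique hydrogen bond.

#' Refcode family of a structure id
#'
#' CSD re-depositions share a six-letter refcode with a numeric suffix
#' (`ABCDEF01`, `ABCDEF02`, ...) and count once for frequencies.  Ids not
#' matching that pattern are their own family.
#'
#' @param structure_id Character vector of ids.
#' @return Character vector of family keys.
#' @examples
#' family_key(c("ABCDEF01", "URACIL", "fixture_7.cif"))
#' @export
family_key <- function(structure_id) {
  stopifnot(is.character(structure_id), all(nzchar(structure_id)))
  sub("^([A-Z]{6})\\d{2,}$", "\\1", structure_id)
}

# one pattern-class label per pair: single pattern when both bases agree,
# otherwise the two patterns sorted and joined, matching the two-line table
# headers
.pattern_class <- function(p1, p2) {
  ifelse(p1 == p2, p1,
         paste(pmin(p1, p2), pmax(p1, p2), sep = " / "))
}

# substitution category of a pattern class: classes containing R (including
# "R?") are substituted; "No R?" and R-less patterns are free
.class_substituted <- function(class) {
  grepl("R", class) & !grepl("No R", class)
}

# prefer the catalogue's printed spelling for catalogued bond sets
.catalog_name_of <- function(pn) {
  entry <- .catalog_entry(pn)
  if (!is.null(entry)) entry$name else render_name(pn)
}

#' Scan structures into survey records
#'
#' Runs [detect_pairs()] on each structure and flattens the result into the
#' two tables the survey statistics consume.
#'
#' @param structures List of [crystal_structure()] objects or file paths.
#' @param params A [geometry_params()].
#' @return List of class `pair_survey`: `records` (one row per detected
#'   pair: `structure_id`, `family`, `base`, `pair_name`, `pattern_class`,
#'   `substitution_class`, `charge_state`) and `bonds` (one row per
#'   hydrogen bond with normalized geometry plus `interplanar` and `c1_c1`).
#' @export
survey_scan <- function(structures, params = geometry_params()) {
  if (inherits(structures, "crystal_structure")) structures <- list(structures)
  recs <- list(); bnds <- list()
  for (s in structures) {
    if (is.character(s)) s <- read_structure(s)
    for (pr in detect_pairs(s, params)) {
      b1 <- pr$base1; b2 <- pr$base2
      subs <- c(b1$substitution, b2$substitution)
      sub_class <- if (all(subs == "R")) "both R"
        else if (all(subs == "free")) "both free" else "mixed"
      ch <- c(b1$charge, b2$charge)
      charge_state <- if (anyNA(ch)) {
        if (any(!is.na(ch) & ch != 0)) "charged" else "unknown"
      } else if (any(ch != 0)) "charged" else "neutral"
      nm <- .catalog_name_of(pr$name)
      recs[[length(recs) + 1]] <- data.frame(
        structure_id = s$id, family = family_key(s$id),
        base = b1$code, pair_name = nm,
        pattern_class = .pattern_class(b1$protonation, b2$protonation),
        substitution_class = sub_class, charge_state = charge_state,
        stringsAsFactors = FALSE)
      g <- pr$hbonds
      bnds[[length(bnds) + 1]] <- data.frame(
        structure_id = s$id, pair_name = nm, bond = paste0(g$n1, g$n2),
        class = g$class, d_a = g$d_a, d_h = g$d_h, h_a = g$h_a, dha = g$dha,
        interplanar = pr$interplanar_angle, c1_c1 = pr$c1_c1,
        stringsAsFactors = FALSE)
    }
  }
  empty_rec <- data.frame(structure_id = character(0), family = character(0),
                          base = character(0), pair_name = character(0),
                          pattern_class = character(0),
                          substitution_class = character(0),
                          charge_state = character(0), stringsAsFactors = FALSE)
  structure(list(records = if (length(recs)) do.call(rbind, recs) else empty_rec,
                 bonds = if (length(bnds)) do.call(rbind, bnds) else NULL),
            class = "pair_survey")
}

#' @export
print.pair_survey <- function(x, ...) {
  cat(sprintf("<pair_survey> %d pair record(s), %d hydrogen bond(s)\n",
              nrow(x$records), if (is.null(x$bonds)) 0L else nrow(x$bonds)))
  invisible(x)
}

#' Tabulate frequencies of occurrence
#'
#' One count per refcode family and pair type: re-depositions collapse, and
#' a family contributes to every pair type it contains.
#'
#' @param records A records data.frame (from [survey_scan()] or
#'   [printed_table_records()]).
#' @return Object of class `survey_table`: `counts` (base, pair_name,
#'   pattern_class, n over unique families), `totals` per base, and
#'   `category_totals` per base and substitution category.
#' @export
tabulate_frequencies <- function(records) {
  if (inherits(records, "pair_survey")) records <- records$records
  stopifnot(is.data.frame(records))
  if (!nrow(records)) {
    counts <- data.frame(base = character(0), pair_name = character(0),
                         pattern_class = character(0), n = integer(0))
    return(structure(list(counts = counts,
                          totals = integer(0), category_totals = NULL),
                     class = "survey_table"))
  }
  # one occurrence per (family, pair type)
  uniq <- records[!duplicated(records[, c("family", "pair_name")]), , drop = FALSE]
  key <- paste(uniq$base, uniq$pair_name, uniq$pattern_class, sep = "\r")
  agg <- as.data.frame(table(factor(key, levels = unique(key))),
                       stringsAsFactors = FALSE)
  parts <- strsplit(agg$Var1, "\r", fixed = TRUE)
  counts <- data.frame(base = vapply(parts, `[`, "", 1),
                       pair_name = vapply(parts, `[`, "", 2),
                       pattern_class = vapply(parts, `[`, "", 3),
                       n = agg$Freq, stringsAsFactors = FALSE)
  totals <- vapply(split(counts$n, counts$base), sum, numeric(1))
  subst <- .class_substituted(counts$pattern_class)
  category_totals <- stats::aggregate(
    counts$n, list(base = counts$base,
                   category = ifelse(subst, "substituted", "free")), sum)
  names(category_totals)[3] <- "n"
  structure(list(counts = counts, totals = totals,
                 category_totals = category_totals),
            class = "survey_table")
}

#' @export
print.survey_table <- function(x, ...) {
  cat("<survey_table>\n")
  if (length(x$totals))
    for (b in names(x$totals))
      cat(sprintf("  %-3s %4d pairs in %d type/protonation cells\n",
                  b, x$totals[[b]], sum(x$counts$base == b)))
  invisible(x)
}

#' Expand a transcription of a printed protonation table into records
#'
#' Each numeric cell of a transcribed table (columns `base`, `pair_name`,
#' `pattern_class`, `count`) becomes `count` records with synthetic
#' one-member families, so [tabulate_frequencies()] reproduces the printed
#' cells exactly.  Cells marked `-` (protonation impossible) or `NA`
#' (blocked by the substituent) yield no records but are kept as marks.
#'
#' @param counts Transcription data.frame.
#' @return List with `records` and `template` (the full cell grid with
#'   marks, for [protonation_crosstab()]).
#' @export
printed_table_records <- function(counts) {
  stopifnot(all(c("base", "pair_name", "pattern_class", "count") %in%
                  names(counts)))
  counts$count <- as.character(counts$count)
  n <- suppressWarnings(as.integer(counts$count))
  recs <- list()
  for (i in which(!is.na(n) & n > 0)) {
    k <- n[i]
    recs[[length(recs) + 1]] <- data.frame(
      structure_id = sprintf("%s|%s|%s|%03d", counts$base[i],
                             counts$pair_name[i], counts$pattern_class[i],
                             seq_len(k)),
      family = sprintf("%s|%s|%s|%03d", counts$base[i], counts$pair_name[i],
                       counts$pattern_class[i], seq_len(k)),
      base = counts$base[i], pair_name = counts$pair_name[i],
      pattern_class = counts$pattern_class[i],
      substitution_class = NA_character_, charge_state = NA_character_,
      stringsAsFactors = FALSE)
  }
  template <- counts[, c("base", "pair_name", "pattern_class")]
  template$mark <- ifelse(is.na(n), counts$count, "")
  empty_rec <- data.frame(structure_id = character(0), family = character(0),
                          base = character(0), pair_name = character(0),
                          pattern_class = character(0),
                          substitution_class = character(0),
                          charge_state = character(0), stringsAsFactors = FALSE)
  list(records = if (length(recs)) do.call(rbind, recs) else empty_rec,
       template = template)
}

#' Load the bundled transcription of the printed protonation tables
#'
#' @return Data.frame with columns `base`, `pair_name`, `pattern_class`,
#'   `count` (`-` marks a protonation that cannot form the pair, `NA` a
#'   pair blocked by the substituent).
#' @export
printed_tables <- function() {
  path <- system.file("extdata", "protonation_tables.csv", package = "pairdex")
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = NULL,
                  colClasses = c("character", "character", "character",
                                 "character"))
}

#' Protonation cross-tab for one base
#'
#' Rows are pair types, columns protonation-pair classes; cells count unique
#' families, with row and column sums.  A `template` (from
#' [printed_table_records()]) fixes the full grid and re-applies the
#' impossibility marks.
#'
#' @param records Records data.frame (filtered internally to `base`).
#' @param base Base code.
#' @param template Optional cell grid with marks.
#' @return List of class `protonation_crosstab`: `table` (character matrix
#'   with counts and marks), `n` (numeric matrix), `row_sums`, `col_sums`,
#'   `grand_total`.
#' @export
protonation_crosstab <- function(records, base, template = NULL) {
  if (inherits(records, "pair_survey")) records <- records$records
  tab <- tabulate_frequencies(records[records$base == base, , drop = FALSE])
  cnt <- tab$counts
  if (!is.null(template)) {
    template <- template[template$base == base, , drop = FALSE]
    rows <- unique(template$pair_name)
    cols <- unique(template$pattern_class)
  } else {
    rows <- unique(cnt$pair_name)
    cols <- unique(cnt$pattern_class)
  }
  n <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  disp <- matrix("0", length(rows), length(cols), dimnames = list(rows, cols))
  if (!is.null(template))
    for (i in seq_len(nrow(template)))
      if (nzchar(template$mark[i]))
        disp[template$pair_name[i], template$pattern_class[i]] <- template$mark[i]
  for (i in seq_len(nrow(cnt))) {
    if (!cnt$pair_name[i] %in% rows || !cnt$pattern_class[i] %in% cols) next
    n[cnt$pair_name[i], cnt$pattern_class[i]] <- cnt$n[i]
    disp[cnt$pair_name[i], cnt$pattern_class[i]] <- as.character(cnt$n[i])
  }
  structure(list(table = disp, n = n,
                 row_sums = rowSums(n), col_sums = colSums(n),
                 grand_total = sum(n)),
            class = "protonation_crosstab")
}

#' @export
print.protonation_crosstab <- function(x, ...) {
  m <- cbind(x$table, Sum = x$row_sums)
  m <- rbind(m, Sum = c(x$col_sums, x$grand_total))
  print(as.data.frame(m), ...)
  invisible(x)
}

#' Share of a pair type within a category
#'
#' `100 * count(pair type in category) / total(category)`, where the
#' substituted category collects the pattern classes containing `R`
#' (including `"R?"`) and the free category the rest (including
#' `"No R?"`).
#'
#' @param t A `survey_table`.
#' @param pair_name Pair name text (catalogue spelling or alias).
#' @param category `"all"`, `"substituted"` or `"free"`.
#' @return Percentage (full precision; round at render time).
#' @export
percentage <- function(t, pair_name, category = c("all", "substituted", "free")) {
  stopifnot(inherits(t, "survey_table"))
  category <- match.arg(category)
  cnt <- t$counts
  hit <- cnt$pair_name == pair_name
  if (!any(hit)) {
    pn <- parse_name(pair_name)
    hit <- vapply(cnt$pair_name, function(x)
      same_pair_name(parse_name(x), pn), logical(1))
  }
  if (!any(hit)) stop("pair type '", pair_name, "' not present in the table")
  base <- cnt$base[hit][1]
  inbase <- cnt$base == base
  incat <- switch(category,
                  all = inbase,
                  substituted = inbase & .class_substituted(cnt$pattern_class),
                  free = inbase & !.class_substituted(cnt$pattern_class))
  denom <- sum(cnt$n[incat])
  if (denom == 0) stop("category '", category, "' is empty for base ", base)
  100 * sum(cnt$n[hit & incat]) / denom
}

#' Hydrogen-bond geometry summaries for a pair type
#'
#' Per bond class: count, mean, sd, min and max of the normalized D...A,
#' D-H, H...A and D-H...A values over every deposition and every unique
#' bond.  Structures without modelled hydrogens contribute to the D...A
#' statistics only.  The C1'...C1' distance is summarized per pair.
#'
#' @param bonds Bonds data.frame from [survey_scan()].
#' @param pair_name Pair name text.
#' @return List with `by_class` (data.frame of per-class summaries) and
#'   `c1_c1` (summary or `NULL` when absent).
#' @export
geometry_stats <- function(bonds, pair_name) {
  if (inherits(bonds, "pair_survey")) bonds <- bonds$bonds
  stopifnot(is.data.frame(bonds))
  sel <- bonds[bonds$pair_name == pair_name, , drop = FALSE]
  if (!nrow(sel)) stop("no geometry records for '", pair_name, "'")
  summ <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(n = 0, mean = NA, sd = NA, min = NA, max = NA))
    c(n = length(v), mean = mean(v),
      sd = if (length(v) > 1) stats::sd(v) else NA,
      min = min(v), max = max(v))
  }
  out <- list()
  for (cl in unique(sel$class)) {
    sc <- sel[sel$class == cl, , drop = FALSE]
    out[[length(out) + 1]] <- data.frame(
      class = cl, metric = c("d_a", "d_h", "h_a", "dha"),
      rbind(summ(sc$d_a), summ(sc$d_h), summ(sc$h_a), summ(sc$dha)),
      stringsAsFactors = FALSE)
  }
  by_class <- do.call(rbind, out)
  rownames(by_class) <- NULL
  pairs <- sel[!duplicated(sel$structure_id), , drop = FALSE]
  c1 <- pairs$c1_c1[!is.na(pairs$c1_c1)]
  list(by_class = by_class,
       c1_c1 = if (length(c1)) summ(c1) else NULL)
}
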