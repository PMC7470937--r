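# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.vnorm <- function(v) sqrt(sum(v^2))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# angle at `b` of the path a-b-c, in degrees
.angle3 <- function(a, b, c) {
  u <- a - b
  v <- c - b
  ct <- sum(u * v) / (.vnorm(u) * .vnorm(v))
  .rad2deg(acos(max(-1, min(1, ct))))
}

# rotation matrix about z by theta radians
.rot_z <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), 3, 3)
}

# rotation about arbitrary unit axis (Rodrigues)
.rot_axis <- function(axis, theta) {
  a <- .unit(axis)
  ct <- cos(theta); st <- sin(theta)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * ct + st * K + (1 - ct) * (a %o% a)
}

# pairwise distance matrix between rows of two coordinate matrices
.cross_dist <- function(xa, xb) {
  sq <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(pmax(sq, 0))
}

.element_from_label <- function(label) {
  m <- regmatches(label, regexpr("^[A-Za-z]{1,2}", label))
  el <- vapply(m, function(x) {
    x <- sub("'.*$", "", x)
    paste0(toupper(substring(x, 1, 1)), tolower(substring(x, 2)))
  }, character(1))
  known2 <- c("Cl", "Br", "Na", "Mg", "Ca", "Fe", "Cu", "Zn", "Mn", "Co",
              "Ni", "Pt", "Au", "Hg", "Pb", "Ag", "Cd", "Ru", "Pd", "Si")
  ifelse(nchar(el) == 2 & !(el %in% known2), substring(el, 1, 1), el)
}
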