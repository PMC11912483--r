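# Geometry ingestion. Atomic units everywhere inside the package: the XYZ
# boundary is the only place Angstrom appears.

# nuclear charges; "X" is the generic heavy atom of the synthetic chain units
ELEMENT_Z <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L,
  F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Ar = 18L, X = 6L
)

#' Atoms from standard XYZ
#'
#' Reads a standard XYZ file (count line, comment line, then
#' `element x y z` in Angstrom) and returns atoms with positions converted
#' to Bohr.
#'
#' @param path XYZ file path.
#' @return data.frame of class `bupo_atoms` with columns `element`, `x`,
#'   `y`, `z` (Bohr), atom order preserved.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) <= 2L]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("read_xyz(): malformed atom count on line 1 of ", path)
  body <- lines[-(1:2)]
  body <- body[!grepl("^\\s*$", body)]
  if (length(body) < n) {
    stop("read_xyz(): count line promises ", n, " atoms but only ",
         length(body), " coordinate lines found in ", path)
  }
  el <- character(n); pos <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    if (length(tok) < 4L) stop("read_xyz(): malformed coordinate line ", i + 2L, " in ", path)
    el[i] <- tok[1L]
    pos[i, ] <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(pos[i, ])) stop("read_xyz(): non-numeric coordinate on line ", i + 2L, " in ", path)
    if (!el[i] %in% names(ELEMENT_Z)) stop("read_xyz(): unknown element '", el[i], "' on line ", i + 2L)
  }
  atoms(el, pos * ANGSTROM_TO_BOHR)
}

#' @rdname read_xyz
#' @param atoms atoms object.
#' @param comment comment line content.
#' @export
write_xyz <- function(atoms, path, comment = "") {
  pos <- as.matrix(atoms[, c("x", "y", "z")]) / ANGSTROM_TO_BOHR
  lines <- c(
    format(nrow(atoms)), comment,
    sprintf("%s %.17g %.17g %.17g", atoms$element, pos[, 1], pos[, 2], pos[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Construct atoms in Bohr
#'
#' @param element character vector of element symbols.
#' @param pos numeric matrix `n x 3` of positions in Bohr.
#' @return data.frame of class `bupo_atoms`.
#' @export
atoms <- function(element, pos) {
  pos <- matrix(pos, ncol = 3L)
  stopifnot(length(element) == nrow(pos), all(is.finite(pos)))
  bad <- setdiff(unique(element), names(ELEMENT_Z))
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  out <- data.frame(element = element, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("bupo_atoms", class(out))
  out
}

#' @export
print.bupo_atoms <- function(x, ...) {
  cat(nrow(x), "atoms (positions in Bohr)\n")
  NextMethod()
}
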