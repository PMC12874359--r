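#' Read an XYZ file
#'
#' Standard XYZ: atom-count line, comment line, then one `El x y z` record
#' per atom (Angstrom). Multiple concatenated frames are read as a list of
#' geometries. A comment line containing `E=<value>` has the energy parsed
#' into the `energy` attribute of the corresponding geometry.
#'
#' @param file path to an XYZ file.
#' @param multi if `TRUE` return a list of geometries (one per frame);
#'   if `FALSE` (default) return the first frame only.
#' @return a [geometry()] or a list of them; each carries attributes
#'   `comment` and (when present) `energy`.
#' @export
read_xyz <- function(file, multi = FALSE) {
  lines <- readLines(file)
  lines <- lines[!(seq_along(lines) > 1 & lines == "" &
                     seq_along(lines) == length(lines))]  # tolerate one trailing blank
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("malformed XYZ: bad atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("malformed XYZ: truncated frame at line ", i)
    comment <- lines[i + 1L]
    rec <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(rec), "[[:space:]]+")
    sym <- vapply(tok, `[[`, character(1L), 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3L)))
    if (anyNA(xyz)) stop("malformed XYZ: non-numeric coordinates at line ", i)
    g <- geometry(sym, xyz)
    attr(g, "comment") <- comment
    m <- regmatches(comment, regexpr("E=\\s*[-+0-9.eEdD]+", comment))
    if (length(m) == 1L)
      attr(g, "energy") <- as.numeric(gsub("[dD]", "e", sub("E=\\s*", "", m)))
    frames[[length(frames) + 1L]] <- g
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("no XYZ frames found in ", file)
  if (multi) frames else frames[[1L]]
}

#' Write geometries to an XYZ file
#'
#' Writes one or more frames in standard XYZ format. When an energy is
#' supplied (or stored in the geometry's `energy` attribute) it is emitted
#' in the comment line as `E=<value>`.
#'
#' @param x a [geometry()], a list of geometries, or an [fsm_path()].
#' @param file output path.
#' @param energies optional numeric vector of per-frame energies.
#' @param comments optional character vector of per-frame comments.
#' @return the file path, invisibly.
#' @export
write_xyz <- function(x, file, energies = NULL, comments = NULL) {
  if (inherits(x, "fsm_geometry")) x <- list(x)
  if (inherits(x, "fsm_path")) x <- x$nodes
  out <- character(0L)
  for (k in seq_along(x)) {
    g <- x[[k]]
    e <- if (!is.null(energies)) energies[k] else attr(g, "energy")
    cm <- if (!is.null(comments)) comments[k] else ""
    if (!is.null(e) && is.finite(e))
      cm <- trimws(paste(cm, sprintf("E=%.12g", e)))
    out <- c(out, as.character(g$natoms), cm,
             sprintf("%-3s % 18.12f % 18.12f % 18.12f",
                     g$symbols, g$coords[, 1L], g$coords[, 2L], g$coords[, 3L]))
  }
  writeLines(out, file)
  invisible(file)
}
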