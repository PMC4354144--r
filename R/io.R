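#' Read and write chain coordinate files
#'
#' `read_xyz()` reads whitespace-separated `x y z` lines (blank lines and
#' `#` comments ignored) as a closed polygon or an open chain.  `write_xyz()`
#' writes coordinates with 17 significant digits, so a written chain reads
#' back bit-identically and classifications are reproducible.
#'
#' `read_vect()` reads a single-component polyline from a Geomview VECT file,
#' the format emitted by ropelength-minimization tools; closed polylines
#' (negative vertex count in the VECT header) become polygons.
#'
#' @param path file path.
#' @param closed interpret the vertex list as a closed polygon.
#' @return a [polygon3()] or [open_chain()].
#' @export
read_xyz <- function(path, closed = FALSE) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t,]+")
  bad <- which(lengths(parts) != 3)
  if (length(bad))
    abort(paste0("parse error in ", path, " line ", bad[1],
                 ": expected 3 coordinates"))
  v <- matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE)
  if (anyNA(v)) abort(paste0("non-numeric coordinate in ", path))
  if (closed) polygon3(v) else open_chain(v)
}

#' @rdname read_xyz
#' @param x a [polygon3()] or [open_chain()].
#' @export
write_xyz <- function(x, path) {
  v <- unclass(x)
  writeLines(apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             path)
  invisible(path)
}

#' @rdname read_xyz
#' @export
read_vect <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(toks) < 4 || toks[1] != "VECT")
    abort(paste0(path, " is not a Geomview VECT file"))
  ncomp <- as.integer(toks[2])
  nvert <- as.integer(toks[3])
  ncol_ <- as.integer(toks[4])
  if (ncomp != 1)
    abort("only single-component VECT polylines are supported")
  nv <- as.integer(toks[5])              # negative marks a closed polyline
  closed <- nv < 0
  nv <- abs(nv)
  if (nv != nvert) abort("inconsistent VECT vertex counts")
  coords_at <- 4 + 2 * ncomp             # after per-component vertex+color counts
  xyz <- as.numeric(toks[coords_at + seq_len(3 * nv)])
  if (anyNA(xyz)) abort("non-numeric VECT coordinates")
  v <- matrix(xyz, ncol = 3, byrow = TRUE)
  if (closed) polygon3(v) else open_chain(v)
  # trailing color data (ncol_ * 4 floats) is ignored
}

#' Read a protein C-alpha trace from a PDB file
#'
#' Extracts the C-alpha coordinates of one chain of a PDB structure as an
#' [open_chain()].  Residue-numbering gaps (missing residues) break the
#' physical backbone; by default they raise an error, because silently joining
#' across a gap can change the topology of the trace.  With
#' `allow_gaps = TRUE` the trace is joined across gaps and the gap positions
#' are recorded in the `gaps` attribute.
#'
#' @param path PDB file path.
#' @param chain chain identifier; defaults to the first chain present.
#' @param allow_gaps join across missing residues instead of failing.
#' @return an [open_chain()] with attributes `chain` and `gaps`.
#' @export
read_pdb_chain <- function(path, chain = NULL, allow_gaps = FALSE) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    abort("reading PDB files requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  atoms <- pdb$atom
  ca <- atoms[atoms$elety == "CA", ]
  if (is.null(chain)) chain <- ca$chain[1]
  ca <- ca[ca$chain == chain, ]
  if (nrow(ca) < 2) abort(paste0("no C-alpha trace for chain ", chain))
  ca <- ca[!duplicated(ca$resno), ]      # drop altloc duplicates
  gaps <- which(diff(ca$resno) != 1)
  if (length(gaps) > 0 && !allow_gaps)
    abort(paste0("chain ", chain, " has residue gaps after resno ",
                 paste(ca$resno[gaps], collapse = ", "),
                 "; use allow_gaps = TRUE to join across them"))
  out <- open_chain(cbind(ca$x, ca$y, ca$z))
  attr(out, "chain") <- chain
  attr(out, "gaps") <- ca$resno[gaps]
  out
}

#' Serialize spectra, matrices and reports as JSON / CSV
#'
#' Stable on-disk forms of the package's tabular results.  `write_spectrum()`
#' emits `{"n_seg": ..., "types": {name: weight}}`; matrices are written as
#' `start,nseg,knot,freq` CSV or as JSON with their host metadata.
#'
#' @param x the object to write.
#' @param path output path.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "knot_spectrum"))
  jsonlite::write_json(
    list(n_seg = attr(x, "nseg"),
         start = attr(x, "start"),
         types = as.list(setNames(x$weight, x$type))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  j <- jsonlite::read_json(path)
  out <- tibble::tibble(type = names(j$types),
                        weight = as.numeric(unlist(j$types)))
  class(out) <- c("knot_spectrum", class(out))
  attr(out, "nseg") <- j$n_seg
  attr(out, "failures") <- 0L
  out
}

#' @rdname write_spectrum
#' @export
write_matrix_csv <- function(x, path) {
  write.table(as.data.frame(x[, c("start", "nseg", "knot", "freq")]), path,
              sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
write_matrix_json <- function(x, path) {
  meta <- if (inherits(x, "disk_matrix")) {
    list(kind = "disk", n = attr(x, "n"), global_type = attr(x, "global_type"))
  } else {
    list(kind = "triangular", m = attr(x, "m"))
  }
  jsonlite::write_json(
    c(meta, list(cells = as.list(as.data.frame(x[, c("start", "nseg", "knot", "freq")])))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
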