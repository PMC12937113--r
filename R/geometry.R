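#' Read a single-frame XYZ file
#'
#' Standard XYZ: atom count, comment line, then `element x y z` in Angstrom.
#'
#' @param path file path.
#' @return list with `elements`, `positions_ang` (n x 3, Angstrom),
#'   `positions` (n x 3, Bohr), `comment`.
#' @export
read_xyz <- function(path) {
  frames <- read_xyz_frames(path)
  if (length(frames) != 1L)
    warning("multi-frame XYZ read with read_xyz(); returning first frame")
  frames[[1L]]
}

#' Read a multi-frame (concatenated) XYZ file
#'
#' @param path file path.
#' @return list of frames, each as in [read_xyz()].
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("malformed XYZ atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("truncated XYZ frame at line ", i)
    comment <- lines[i + 1L]
    block <- lines[i + 1L + seq_len(n)]
    toks <- strsplit(trimws(block), "\\s+")
    elements <- vapply(toks, `[[`, "", 1L)
    pos <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (any(!is.finite(pos))) stop("non-numeric coordinate in XYZ frame")
    frames[[length(frames) + 1L]] <- list(
      elements = elements, positions_ang = pos,
      positions = pos * ANGSTROM_TO_BOHR, comment = comment)
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("no frames found in ", path)
  frames
}

#' Write frames to an XYZ file
#'
#' @param frames a single frame (list with elements/positions_ang) or a list
#'   of frames.
#' @param path output path.
#' @export
write_xyz <- function(frames, path) {
  if (!is.null(frames$elements)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(as.character(length(fr$elements)), con)
    writeLines(fr$comment %||% "", con)
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f", fr$elements,
                       fr$positions_ang[, 1], fr$positions_ang[, 2],
                       fr$positions_ang[, 3]), con)
  }
  invisible(path)
}
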