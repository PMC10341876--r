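# Standard XYZ archive I/O: per frame a count line, a comment line, then one
# "element x y z" line per atom. 2D configurations are serialised with z = 0.

#' Read a (multi-frame) XYZ file
#'
#' @param path file path.
#' @return list of frames; each frame is a list with `coords` (n x 3 matrix),
#'   `elements` (character), and `comment`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop(sprintf("XYZ line %d: expected an atom count", i), call. = FALSE)
    if (i + 1L + n > length(lines))
      stop(sprintf("XYZ frame starting at line %d is truncated", i),
           call. = FALSE)
    comment <- lines[i + 1L]
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    if (any(lengths(parts) < 4L))
      stop(sprintf("XYZ frame at line %d: atom line with fewer than 4 fields", i),
           call. = FALSE)
    elements <- vapply(parts, `[[`, character(1), 1L)
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(coords))
      stop(sprintf("XYZ frame at line %d: non-numeric coordinate", i),
           call. = FALSE)
    frames[[length(frames) + 1L]] <- list(coords = coords, elements = elements,
                                          comment = comment)
    i <- i + 2L + n
  }
  frames
}

#' Write a (multi-frame) XYZ file
#'
#' @param frames list of n x 2 or n x 3 coordinate matrices, or of frame lists
#'   as returned by [read_xyz()]. Two-column matrices get z = 0.
#' @param path output path (written atomically).
#' @param comments per-frame comment lines (recycled).
#' @param elements per-atom element labels (recycled; default "C").
#' @export
write_xyz <- function(frames, path, comments = "", elements = "C") {
  if (is.matrix(frames)) frames <- list(frames)
  comments <- rep_len(comments, length(frames))
  out <- character(0)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    m <- if (is.list(f) && !is.null(f$coords)) f$coords else f
    if (is.numeric(m) && is.null(dim(m))) m <- coords_matrix(m, 3L)
    if (ncol(m) == 2L) m <- cbind(m, 0)
    el <- if (is.list(f) && !is.null(f$elements)) f$elements else
      rep_len(elements, nrow(m))
    el <- rep_len(el, nrow(m))
    cm <- if (is.list(f) && !is.null(f$comment)) f$comment else comments[k]
    out <- c(out, as.character(nrow(m)), cm,
             sprintf("%s %s %s %s", el, fmt17(m[, 1]), fmt17(m[, 2]),
                     fmt17(m[, 3])))
  }
  write_atomic(out, path)
}
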