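#' Stationary-point databases
#'
#' A stationary-point database collects the local minima and index-1 saddles
#' (transition states) of a potential-energy surface: per minimum its energy,
#' the log-product of its positive normal-mode frequencies, and a degeneracy
#' order (a single multiplicative permutation-inversion weight); per transition
#' state the same quantities plus the ids of the two minima it connects.
#' `kappa` is the number of vibrational degrees of freedom, shared by every
#' minimum in one database. Ids are 1-based row indices, matching the 1-based
#' min.data/ts.data file convention.
#'
#' @param minima data frame with columns `energy`, `log_freq_product`,
#'   `horder`.
#' @param ts optional data frame with columns `energy`, `log_freq_product`,
#'   `horder`, `min1`, `min2`.
#' @param kappa vibrational degrees of freedom (>= 1).
#' @param coords optional list of flat coordinate vectors, one per minimum.
#' @param ts_coords optional list of coordinates, one per transition state.
#' @param metadata named list (title, units, provenance); units default to
#'   "reduced".
#' @return an object of class `elcv_spdb`.
#' @export
spdb <- function(minima, ts = NULL, kappa, coords = NULL, ts_coords = NULL,
                 metadata = list()) {
  stopifnot(is.data.frame(minima),
            all(c("energy", "log_freq_product", "horder") %in% names(minima)))
  if (nrow(minima) < 1) stop("database needs at least one minimum", call. = FALSE)
  if (!(kappa >= 1)) stop("kappa must be >= 1", call. = FALSE)
  if (any(!is.finite(minima$energy)))
    stop("non-finite minimum energies", call. = FALSE)
  if (any(minima$horder <= 0))
    stop("degeneracy orders must be positive", call. = FALSE)
  if (is.null(ts)) {
    ts <- data.frame(energy = numeric(0), log_freq_product = numeric(0),
                     horder = numeric(0), min1 = integer(0), min2 = integer(0))
  }
  stopifnot(is.data.frame(ts),
            all(c("energy", "log_freq_product", "horder", "min1", "min2") %in%
                  names(ts)))
  nmin <- nrow(minima)
  bad <- which(ts$min1 < 1 | ts$min1 > nmin | ts$min2 < 1 | ts$min2 > nmin)
  if (length(bad))
    stop("transition state(s) ", paste(bad, collapse = ", "),
         " reference minima outside 1..", nmin, call. = FALSE)
  if (!is.null(coords) && length(coords) != nmin)
    stop("need one coordinate set per minimum", call. = FALSE)
  meta <- utils::modifyList(list(units = "reduced"), metadata)
  structure(list(minima = minima, ts = ts, kappa = as.integer(kappa),
                 coords = coords, ts_coords = ts_coords, metadata = meta),
            class = "elcv_spdb")
}

#' @export
print.elcv_spdb <- function(x, ...) {
  cat(sprintf(
    "<stationary-point database: %d minima, %d transition states, kappa = %d%s>\n",
    nrow(x$minima), nrow(x$ts), x$kappa,
    if (!is.null(x$coords)) ", with coordinates" else ""))
  if (nrow(x$minima)) {
    cat(sprintf("  global minimum: id %d, E = %.8g\n",
                which.min(x$minima$energy), min(x$minima$energy)))
  }
  invisible(x)
}

#' Number of minima / transition states
#' @param db an `elcv_spdb`.
#' @export
n_minima <- function(db) nrow(db$minima)

#' @rdname n_minima
#' @export
n_ts <- function(db) nrow(db$ts)

#' Validate a stationary-point database
#'
#' Report-based validation of the database invariants: resolvable transition
#' state endpoints, barrier positivity (E_ts >= max of the connected minima,
#' tolerance 1e-8), consistent kappa, and a well-defined global minimum
#' (no second minimum within the 1e-6 deduplication tolerance of the lowest).
#'
#' @param db an `elcv_spdb`.
#' @param barrier_tol tolerance for barrier positivity.
#' @return data frame with columns `check`, `id`, `message`; zero rows for a
#'   clean database.
#' @export
validate_database <- function(db, barrier_tol = 1e-8) {
  bad <- list()
  nmin <- n_minima(db)
  if (nrow(db$ts)) {
    for (i in seq_len(nrow(db$ts))) {
      t <- db$ts[i, ]
      if (t$min1 < 1 || t$min1 > nmin || t$min2 < 1 || t$min2 > nmin) {
        bad[[length(bad) + 1L]] <- data.frame(
          check = "ts_reference", id = i,
          message = sprintf("ts %d references missing minimum", i))
        next
      }
      hi <- max(db$minima$energy[t$min1], db$minima$energy[t$min2])
      if (t$energy < hi - barrier_tol) {
        bad[[length(bad) + 1L]] <- data.frame(
          check = "barrier_positivity", id = i,
          message = sprintf("ts %d energy %.8g below connected minimum %.8g",
                            i, t$energy, hi))
      }
    }
  }
  if (db$kappa < 1) {
    bad[[length(bad) + 1L]] <- data.frame(
      check = "kappa", id = NA_integer_, message = "kappa < 1")
  }
  es <- sort(db$minima$energy)
  if (length(es) >= 2 && (es[2] - es[1]) < 1e-6) {
    bad[[length(bad) + 1L]] <- data.frame(
      check = "global_minimum", id = NA_integer_,
      message = "global minimum not unique within deduplication tolerance")
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(check = character(0), id = integer(0), message = character(0))
}

## ---- flat-text formats ---------------------------------------------------

# Atomic write: temp file in the destination directory, then rename.
write_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path, call. = FALSE)
  invisible(path)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Read/write minima in the min.data flat-text convention
#'
#' One minimum per line: energy, log frequency product, degeneracy order, and
#' three placeholder fields (moments-of-inertia slots in the ecosystem format;
#' written as 1.0 and ignored on read). Round-trips are value-exact at 17
#' significant digits.
#'
#' @param path file path.
#' @return `read_min_data`: data frame with columns `energy`,
#'   `log_freq_product`, `horder`.
#' @export
read_min_data <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(energy = numeric(0), log_freq_product = numeric(0),
                      horder = numeric(0)))
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  nc <- lengths(parts)
  if (any(nc != 6L)) {
    i <- which(nc != 6L)[1]
    stop(sprintf("min.data line %d: expected 6 columns, found %d", i, nc[i]),
         call. = FALSE)
  }
  vals <- suppressWarnings(lapply(parts, as.numeric))
  if (any(vapply(vals, anyNA, logical(1)))) {
    i <- which(vapply(vals, anyNA, logical(1)))[1]
    stop(sprintf("min.data line %d: non-numeric field", i), call. = FALSE)
  }
  m <- do.call(rbind, vals)
  data.frame(energy = m[, 1], log_freq_product = m[, 2], horder = m[, 3])
}

#' @rdname read_min_data
#' @param minima data frame with columns `energy`, `log_freq_product`,
#'   `horder`.
#' @export
write_min_data <- function(minima, path) {
  lines <- sprintf("%s %s %s 1.0 1.0 1.0",
                   fmt17(minima$energy), fmt17(minima$log_freq_product),
                   fmt17(minima$horder))
  write_atomic(lines, path)
}

#' Read/write transition states in the ts.data flat-text convention
#'
#' One transition state per line: energy, log frequency product, degeneracy
#' order, the two connected minimum ids (1-based), and three placeholder
#' fields.
#' @param path file path.
#' @export
read_ts_data <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(energy = numeric(0), log_freq_product = numeric(0),
                      horder = numeric(0), min1 = integer(0), min2 = integer(0)))
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  nc <- lengths(parts)
  if (any(nc != 8L)) {
    i <- which(nc != 8L)[1]
    stop(sprintf("ts.data line %d: expected 8 columns, found %d", i, nc[i]),
         call. = FALSE)
  }
  vals <- suppressWarnings(lapply(parts, as.numeric))
  if (any(vapply(vals, anyNA, logical(1)))) {
    i <- which(vapply(vals, anyNA, logical(1)))[1]
    stop(sprintf("ts.data line %d: non-numeric field", i), call. = FALSE)
  }
  m <- do.call(rbind, vals)
  if (any(m[, 4] < 1 | m[, 5] < 1)) {
    i <- which(m[, 4] < 1 | m[, 5] < 1)[1]
    stop(sprintf("ts.data line %d: minimum ids are 1-based; got %g and %g",
                 i, m[i, 4], m[i, 5]), call. = FALSE)
  }
  data.frame(energy = m[, 1], log_freq_product = m[, 2], horder = m[, 3],
             min1 = as.integer(m[, 4]), min2 = as.integer(m[, 5]))
}

#' @rdname read_ts_data
#' @param ts data frame with columns `energy`, `log_freq_product`, `horder`,
#'   `min1`, `min2`.
#' @export
write_ts_data <- function(ts, path) {
  lines <- sprintf("%s %s %s %d %d 1.0 1.0 1.0",
                   fmt17(ts$energy), fmt17(ts$log_freq_product),
                   fmt17(ts$horder), as.integer(ts$min1), as.integer(ts$min2))
  write_atomic(lines, path)
}

#' Read or write a whole database directory
#'
#' `write_database` writes `min.data` and `ts.data` (and `points.xyz` when the
#' database carries coordinates) into a directory; `read_database` assembles
#' an `elcv_spdb` back from one.
#' @param db an `elcv_spdb`.
#' @param dir directory path.
#' @param kappa vibrational degrees of freedom for the assembled database.
#' @export
write_database <- function(db, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_min_data(db$minima, file.path(dir, "min.data"))
  write_ts_data(db$ts, file.path(dir, "ts.data"))
  if (!is.null(db$coords)) {
    frames <- lapply(db$coords, coords_matrix)
    write_xyz(frames, file.path(dir, "points.xyz"),
              comments = sprintf("minimum %d energy %s",
                                 seq_along(db$coords), fmt17(db$minima$energy)))
  }
  invisible(dir)
}

#' @rdname write_database
#' @export
read_database <- function(dir, kappa) {
  minima <- read_min_data(file.path(dir, "min.data"))
  tsp <- file.path(dir, "ts.data")
  ts <- if (file.exists(tsp)) read_ts_data(tsp) else NULL
  coords <- NULL
  xyzp <- file.path(dir, "points.xyz")
  if (file.exists(xyzp)) {
    frames <- read_xyz(xyzp)
    coords <- lapply(frames, function(f) coords_flat(f$coords))
  }
  spdb(minima, ts, kappa = kappa, coords = coords)
}
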