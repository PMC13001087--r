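#' Particle coordinate set
#'
#' The pipeline's universal currency: an N x 3 matrix of particle centroid
#' coordinates (nm) inside a [box_geometry()], plus sample metadata.
#'
#' @param coordinates numeric N x 3 matrix (columns x, y, z in nm).
#' @param box a [box_geometry()].
#' @param temperature sample temperature in kelvin (default 293.15, i.e.
#'   20 degrees C).
#' @param molecular_weight optional molecular weight in g/mol; required for
#'   mass-concentration output.
#' @param label free-text label, e.g. the nominal concentration.
#' @param validate if `TRUE` (default), reject non-finite coordinates and
#'   coordinates outside the box on non-periodic axes.
#' @return An object of class `particle_set`.
#' @export
particle_set <- function(coordinates, box, temperature = 293.15,
                         molecular_weight = NULL, label = NULL,
                         validate = TRUE) {
  stopifnot(inherits(box, "box_geometry"))
  coordinates <- as.matrix(coordinates)
  if (length(coordinates) == 0)
    coordinates <- matrix(numeric(0), 0, 3)
  if (ncol(coordinates) != 3)
    stop("`coordinates` must have three columns (x, y, z)")
  storage.mode(coordinates) <- "double"
  dimnames(coordinates) <- NULL
  if (validate && nrow(coordinates) > 0) {
    if (any(!is.finite(coordinates)))
      stop("coordinates contain non-finite values")
    bad <- !.inside_box(coordinates, box)
    if (any(bad))
      stop(sprintf("%d coordinate(s) lie outside the box (first: row %d)",
                   sum(bad), which(bad)[1]))
  }
  if (!is.null(temperature) && (!is.finite(temperature) || temperature <= 0))
    stop("`temperature` must be a positive number of kelvin")
  structure(list(coordinates = coordinates, box = box,
                 temperature = temperature,
                 molecular_weight = molecular_weight, label = label),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> N = %d, T = %.2f K%s\n", nrow(x$coordinates),
              x$temperature,
              if (!is.null(x$label)) paste0(", label: ", x$label) else ""))
  print(x$box)
  invisible(x)
}

#' Number of particles in a set
#' @param ps a [particle_set()].
#' @return Integer particle count.
#' @export
n_particles <- function(ps) {
  stopifnot(inherits(ps, "particle_set"))
  nrow(ps$coordinates)
}

#' Bulk number density of a particle set in nm^-3
#' @param ps a [particle_set()].
#' @return `N / V` in nm^-3.
#' @export
number_density <- function(ps) {
  n_particles(ps) / box_volume(ps$box)
}

.parse_numbers <- function(fields, lineno, path) {
  vals <- suppressWarnings(as.numeric(fields))
  if (length(vals) < 3 || anyNA(vals) || any(!is.finite(vals)))
    stop(sprintf("cannot parse line %d of '%s' as three finite coordinates",
                 lineno, path))
  vals[1:3]
}

#' Read particle coordinates from CSV or XYZ
#'
#' CSV files carry a header `x_nm,y_nm,z_nm` and one particle per row; XYZ
#' files use the standard count/comment/records dialect with the element
#' field ignored.  Coordinates are interpreted as nanometres.
#'
#' @param path file to read.
#' @param format `"csv"` or `"xyz"`.
#' @param box the [box_geometry()] the coordinates live in.
#' @param strict what to do with records outside the box: `"error"`
#'   (default) aborts, `"drop"` removes them with a warning, `"keep"`
#'   retains them unvalidated.
#' @inheritParams particle_set
#' @return A [particle_set()].
#' @export
load_particles <- function(path, format = c("csv", "xyz"), box,
                           temperature = 293.15, molecular_weight = NULL,
                           label = NULL, strict = c("error", "drop", "keep")) {
  format <- match.arg(format)
  strict <- match.arg(strict)
  if (!file.exists(path))
    stop(sprintf("coordinate file '%s' does not exist", path))
  lines <- readLines(path)
  if (format == "csv") {
    if (length(lines) < 1) stop(sprintf("'%s' is empty", path))
    rows <- lines[-1]
    rows <- rows[nzchar(trimws(rows))]
    if (length(rows) == 0)
      stop(sprintf("'%s' contains zero coordinate records", path))
    coords <- t(vapply(seq_along(rows), function(i) {
      .parse_numbers(strsplit(rows[i], ",", fixed = TRUE)[[1]], i + 1L, path)
    }, numeric(3)))
  } else {
    if (length(lines) < 3)
      stop(sprintf("'%s' is not a valid XYZ file", path))
    ncount <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(ncount))
      stop(sprintf("line 1 of '%s' is not an atom count", path))
    rows <- lines[-(1:2)]
    rows <- rows[nzchar(trimws(rows))]
    if (length(rows) != ncount)
      stop(sprintf("'%s': header declares %d records but %d found",
                   path, ncount, length(rows)))
    if (ncount == 0)
      stop(sprintf("'%s' contains zero coordinate records", path))
    coords <- t(vapply(seq_along(rows), function(i) {
      f <- strsplit(trimws(rows[i]), "[[:space:]]+")[[1]]
      .parse_numbers(f[-1], i + 2L, path)
    }, numeric(3)))
  }
  if (any(!is.finite(coords))) {
    bad <- which(apply(coords, 1, function(r) any(!is.finite(r))))[1]
    stop(sprintf("non-finite coordinate in record %d of '%s'", bad, path))
  }
  outside <- !.inside_box(coords, box)
  if (any(outside)) {
    if (strict == "error")
      stop(sprintf("%d record(s) of '%s' lie outside the declared box (first: record %d)",
                   sum(outside), path, which(outside)[1]))
    if (strict == "drop") {
      warning(sprintf("dropping %d record(s) of '%s' outside the declared box",
                      sum(outside), path))
      coords <- coords[!outside, , drop = FALSE]
      if (nrow(coords) == 0)
        stop(sprintf("'%s' contains zero records inside the box", path))
    }
  }
  particle_set(coords, box, temperature = temperature,
               molecular_weight = molecular_weight, label = label,
               validate = strict != "keep")
}

#' Write particle coordinates to CSV or XYZ
#'
#' Numbers are written with 17 significant digits so coordinates
#' round-trip bit-exactly through [load_particles()].
#'
#' @param ps a [particle_set()].
#' @param path output file.
#' @param format `"csv"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_particles <- function(ps, path, format = c("csv", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(ps, "particle_set"))
  xyz <- ps$coordinates
  if (format == "csv") {
    rows <- sprintf("%.17g,%.17g,%.17g", xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(c("x_nm,y_nm,z_nm", rows), path)
  } else {
    rows <- sprintf("P %.17g %.17g %.17g", xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(c(as.character(nrow(xyz)), "tomopip particle set", rows), path)
  }
  invisible(path)
}
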