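#' Read an antenna event log
#'
#' Reads a CSV log of directional antenna detections: one row per passage of
#' a tagged animal through a site entrance, with the reader pair resolving
#' whether the animal entered or left the site. Timestamps may be given as
#' epoch seconds or as ISO-8601 date-times; both are normalised to epoch
#' seconds (numeric). Events are returned in chronological order, stable on
#' ties.
#'
#' @param path Path to a CSV file.
#' @param delim Field delimiter (default `","`).
#' @param col_animal,col_site,col_direction,col_time Column names in the file
#'   holding the animal identifier, site identifier, direction token and
#'   timestamp.
#' @param tz Time zone used when timestamps are ISO-8601 strings.
#'
#' @return A tibble with columns `animal_id`, `site_id`, `direction`
#'   (`"enter"` or `"exit"`) and `timestamp` (seconds, numeric), sorted by
#'   `timestamp`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("animal_id,site_id,direction,timestamp",
#'              "a,B1,enter,0", "a,B1,exit,10"), f)
#' read_event_log(f)
read_event_log <- function(path, delim = ",",
                           col_animal = "animal_id", col_site = "site_id",
                           col_direction = "direction", col_time = "timestamp",
                           tz = "UTC") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  assert_columns(raw, c(col_animal, col_site, col_direction, col_time),
                 what = basename(path))
  direction <- tolower(trimws(raw[[col_direction]]))
  bad_dir <- which(!direction %in% c("enter", "exit"))
  if (length(bad_dir) > 0) {
    abort(sprintf("Unknown direction token in row(s) %s of %s (expected 'enter' or 'exit').",
                  paste(head(bad_dir, 5), collapse = ", "), basename(path)))
  }
  ts <- parse_timestamps(raw[[col_time]], tz = tz, file = basename(path))
  events <- tibble(
    animal_id = raw[[col_animal]],
    site_id = raw[[col_site]],
    direction = direction,
    timestamp = ts
  )
  bad <- which(is.na(events$animal_id) | is.na(events$site_id))
  if (length(bad) > 0) {
    abort(sprintf("Malformed row(s) %s in %s: missing animal or site identifier.",
                  paste(head(bad, 5), collapse = ", "), basename(path)))
  }
  events[order_stable(events$timestamp), ]
}

parse_timestamps <- function(x, tz, file = "input") {
  x <- trimws(x)
  suppressWarnings(num <- as.numeric(x))
  if (!anyNA(num[!is.na(x)])) {
    out <- num
  } else {
    parsed <- suppressWarnings(
      readr::parse_datetime(x, locale = readr::locale(tz = tz))
    )
    out <- as.numeric(parsed)
  }
  bad <- which(!is.finite(out))
  if (length(bad) > 0) {
    abort(sprintf("Malformed timestamp in row(s) %s of %s.",
                  paste(head(bad, 5), collapse = ", "), file))
  }
  out
}

#' Write an antenna event log
#'
#' Inverse of [read_event_log()]; timestamps are written as epoch seconds at
#' full precision so that `read_event_log(write_event_log(x))` is an
#' identity.
#'
#' @param events Tibble with columns `animal_id`, `site_id`, `direction`,
#'   `timestamp`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  assert_columns(events, c("animal_id", "site_id", "direction", "timestamp"))
  readr::write_csv(events, path, progress = FALSE)
  invisible(path)
}

#' Read or write a stay table
#'
#' A stay is one continuous interval an animal spends inside one site,
#' treated as half-open `[t_in, t_out)`. Rows violating `t_out > t_in` are
#' an error.
#'
#' @param path CSV path with columns `animal_id`, `site_id`, `t_in`, `t_out`
#'   (seconds).
#' @return A tibble with those columns.
#' @export
read_stay_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  stays <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             animal_id = readr::col_character(),
                             site_id = readr::col_character(),
                             t_in = readr::col_double(),
                             t_out = readr::col_double()
                           ))
  assert_columns(stays, c("animal_id", "site_id", "t_in", "t_out"),
                 what = basename(path))
  validate_stays(stays, what = basename(path))
  stays
}

#' @rdname read_stay_table
#' @param stays Tibble with columns `animal_id`, `site_id`, `t_in`, `t_out`.
#' @export
write_stay_table <- function(stays, path) {
  assert_columns(stays, c("animal_id", "site_id", "t_in", "t_out"))
  validate_stays(stays)
  readr::write_csv(stays, path, progress = FALSE)
  invisible(path)
}

validate_stays <- function(stays, what = "stays") {
  bad <- which(!(stays$t_out > stays$t_in))
  if (length(bad) > 0) {
    abort(sprintf("Invalid stay(s) in %s at row(s) %s: t_out must exceed t_in.",
                  what, paste(head(bad, 10), collapse = ", ")))
  }
  invisible(stays)
}

#' Read or write a site layout
#'
#' A site layout gives each discrete sampling site (nest box) an identifier,
#' planar coordinates in metres (x right, y up) and a well radius in metres
#' used both as the positional uncertainty scale of bridge endpoints and as
#' the radius of the site's potential well.
#'
#' @param path CSV path with columns `site_id`, `x`, `y`, `radius`.
#' @return Tibble with those columns.
#' @export
read_site_layout <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  layout <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                            col_types = readr::cols(
                              site_id = readr::col_character(),
                              x = readr::col_double(),
                              y = readr::col_double(),
                              radius = readr::col_double()
                            ))
  assert_columns(layout, c("site_id", "x", "y", "radius"), what = basename(path))
  validate_layout(layout)
  layout
}

#' @rdname read_site_layout
#' @param layout Tibble with columns `site_id`, `x`, `y`, `radius`.
#' @export
write_site_layout <- function(layout, path) {
  validate_layout(layout)
  readr::write_csv(layout, path, progress = FALSE)
  invisible(path)
}

validate_layout <- function(layout) {
  assert_columns(layout, c("site_id", "x", "y", "radius"))
  if (anyDuplicated(layout$site_id) > 0) abort("Duplicated site_id in layout.")
  if (anyDuplicated(layout[, c("x", "y")]) > 0) {
    abort("Site positions must be unique.")
  }
  if (any(!is.finite(layout$x)) || any(!is.finite(layout$y))) {
    abort("Site coordinates must be finite.")
  }
  if (any(!is.finite(layout$radius)) || any(layout$radius <= 0)) {
    abort("Site radius must be > 0.")
  }
  invisible(layout)
}

# ---- landscape grid -------------------------------------------------------

#' Landscape grid
#'
#' A rasterised potential surface. `values` is a numeric matrix whose rows
#' run south to north (row 1 is the southernmost row) and whose columns run
#' west to east; `x0`, `y0` is the lower-left corner of the raster and cells
#' are squares of side `cellsize`, with values attached to cell centres.
#' `NA` cells mark locations outside the domain mask.
#'
#' @param values Numeric matrix of heights (dimensionless potential,
#'   `k_B T = 1` units).
#' @param x0,y0 Coordinates of the lower-left raster corner, metres.
#' @param cellsize Cell side, metres.
#' @return An object of class `landscape_grid`.
#' @export
landscape_grid <- function(values, x0, y0, cellsize) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  assert_scalar_number(cellsize, "cellsize", positive = TRUE)
  assert_scalar_number(x0, "x0")
  assert_scalar_number(y0, "y0")
  if (any(is.infinite(values) | is.nan(values))) {
    abort("Grid values must be finite or NA (NA marks cells outside the domain).")
  }
  structure(list(values = values, x0 = x0, y0 = y0, cellsize = cellsize),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid> %d x %d cells of %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$x0, x$y0))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  height range: [%.4g, %.4g], %d masked cell(s)\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.landscape_grid <- function(x) dim(x$values)

# Cell-centre coordinates (vectors, south->north rows / west->east cols).
grid_axes <- function(grid) {
  list(
    x = grid$x0 + (seq_len(ncol(grid$values)) - 0.5) * grid$cellsize,
    y = grid$y0 + (seq_len(nrow(grid$values)) - 0.5) * grid$cellsize
  )
}

#' Write a landscape grid as an ESRI ASCII raster
#'
#' The on-disk format is the plain-text ESRI ASCII grid (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header followed by the
#' matrix, northernmost row first). Values are written at full double
#' precision so the reader inverts the writer exactly. `NA` cells are
#' written as the NODATA value; non-finite cells that are not `NA` are an
#' error.
#'
#' @param grid A [landscape_grid()].
#' @param path Output path (conventionally `.asc`).
#' @param nodata Sentinel written for masked cells.
#' @return `path`, invisibly.
#' @export
write_landscape_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "landscape_grid"))
  v <- grid$values
  if (any(is.infinite(v) | is.nan(v))) {
    abort("Grid contains non-finite cells; NODATA is reserved for NA (masked) cells.")
  }
  header <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", grid$x0),
    sprintf("yllcorner %.17g", grid$y0),
    sprintf("cellsize %.17g", grid$cellsize),
    sprintf("NODATA_value %.17g", nodata)
  )
  # ESRI rows are written north->south: flip our south->north storage.
  rows <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1, function(r) {
    r[is.na(r)] <- nodata
    paste(sprintf("%.17g", r), collapse = " ")
  })
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII raster as a landscape grid
#'
#' @param path Path to an ESRI ASCII grid file.
#' @return A [landscape_grid()]; NODATA cells become `NA`.
#' @export
read_landscape_grid <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 7) abort(sprintf("%s is not an ESRI ASCII grid.", basename(path)))
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    abort(sprintf("%s: incomplete ESRI ASCII header.", basename(path)))
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  body <- scan(text = lines[-(1:6)], what = double(), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(body) != nr * nc) {
    abort(sprintf("%s: expected %d values, found %d.", basename(path), nr * nc, length(body)))
  }
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  landscape_grid(m[rev(seq_len(nr)), , drop = FALSE],
                 x0 = hdr$xllcorner, y0 = hdr$yllcorner, cellsize = hdr$cellsize)
}
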