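# Plain-text readers and writers for head points, fiducials, sensors and
# 2D layouts.

# Whitespace- or comma-delimited numeric table with optional header.
.read_delim_auto <- function(path, min_cols) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  probe <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(probe[length(probe) - min_cols + 2]))))
  read.table(path, sep = sep, header = header, stringsAsFactors = FALSE,
             strip.white = TRUE)
}

#' Read head-shape points from a delimited text file
#'
#' Accepts whitespace- or comma-delimited text with three numeric columns
#' (x, y, z in mm) and an optional header line.
#'
#' @param path file path.
#' @return An n x 3 numeric matrix.
#' @export
read_points <- function(path) {
  tb <- .read_delim_auto(path, 3)
  num <- tb[vapply(tb, is.numeric, TRUE)]
  if (ncol(num) < 3) stop_input("%s: expected three numeric columns x y z", path)
  .as_matrix3(as.matrix(num[, 1:3]), "head points")
}

#' Read fiducials from JSON or labelled TSV
#'
#' JSON form: an object `{"NAS": [x,y,z], "LPA": ..., "RPA": ..., "INI": ...}`
#' (INI optional). Text form: rows of `label x y z`.
#'
#' @param path file path.
#' @return Named list of 3D coordinates.
#' @export
read_fiducials <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
    return(lapply(raw, .as_xyz, what = "fiducial"))
  }
  tb <- .read_delim_auto(path, 4)
  labs <- as.character(tb[[1]])
  out <- lapply(seq_len(nrow(tb)), function(i) as.numeric(tb[i, 2:4]))
  setNames(out, labs)
}

#' Read labelled sensor positions
#'
#' TSV/CSV with columns `label, x, y, z` (mm); header optional.
#'
#' @param path file path.
#' @return data.frame with columns `label`, `x`, `y`, `z`.
#' @export
read_sensors <- function(path) {
  tb <- .read_delim_auto(path, 4)
  if (ncol(tb) < 4) stop_input("%s: expected columns label x y z", path)
  out <- data.frame(label = as.character(tb[[1]]),
                    x = as.numeric(tb[[2]]), y = as.numeric(tb[[3]]),
                    z = as.numeric(tb[[4]]), stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(out[, 2:4]))))
    stop_input("%s: non-numeric sensor coordinates", path)
  out
}

#' Read head points and fiducials into a head_scan
#'
#' @param points_path head points file, see [read_points()].
#' @param fiducials_path fiducials file, see [read_fiducials()].
#' @return A [head_scan()].
#' @export
read_head_scan <- function(points_path, fiducials_path) {
  head_scan(read_points(points_path), read_fiducials(fiducials_path))
}

#' Write a 2D layout in FieldTrip-style .lay text format
#'
#' One row per channel: `index x y width height label`, numbers with six
#' decimal places and LF line endings.
#'
#' @param layout a `layout_2d`.
#' @param path output path.
#' @param width,height box size stored per channel (display hint).
#' @return `path`, invisibly.
#' @export
write_layout_lay <- function(layout, path, width = 0.08, height = 0.08) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f %s", seq_len(nrow(layout)),
                   layout$x, layout$y, width, height, layout$label)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write a 2D layout as JSON
#'
#' Stores per-channel eccentricity/angle/xy (rounded to six decimals) plus
#' the outline metadata (unit circle, nose direction at the NAS side, ear
#' directions at T3/T4).
#'
#' @param layout a `layout_2d`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  chans <- lapply(seq_len(nrow(layout)), function(i) {
    list(label = layout$label[i],
         eccentricity = round(layout$eccentricity[i], 6),
         angle = round(layout$angle[i], 6),
         x = round(layout$x[i], 6), y = round(layout$y[i], 6))
  })
  obj <- list(method = attr(layout, "method"),
              outline = attr(layout, "outline"),
              channels = chans)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             con, sep = "\n")
  invisible(path)
}

#' Read a layout written by [write_layout_lay()] or [write_layout_json()]
#'
#' @param path `.lay` or `.json` file.
#' @return A `layout_2d` data.frame (for `.lay`, eccentricity/angle are
#'   reconstructed from x, y).
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- obj$channels
    rows <- lapply(seq_len(nrow(df)), function(i)
      data.frame(label = df$label[i], eccentricity = df$eccentricity[i],
                 angle = df$angle[i], x = df$x[i], y = df$y[i],
                 stringsAsFactors = FALSE))
    out <- .layout_from_rows(rows, obj$method)
    attr(out, "outline") <- obj$outline
    return(out)
  }
  tb <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tb) < 6) stop_input("%s: not a .lay file", path)
  ecc <- sqrt(tb[[2]]^2 + tb[[3]]^2)
  ang <- (atan2(tb[[3]], tb[[2]]) * 180 / pi) %% 360
  ang[ecc == 0] <- 0
  rows <- lapply(seq_len(nrow(tb)), function(i)
    data.frame(label = as.character(tb[[6]][i]), eccentricity = ecc[i],
               angle = ang[i], x = tb[[2]][i], y = tb[[3]][i],
               stringsAsFactors = FALSE))
  .layout_from_rows(rows, "unknown")
}
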