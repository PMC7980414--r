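#' Localization tables
#'
#' The primary data product of SMLM imaging is a table of fitted fluorophore
#' positions. `loc_table()` builds the in-memory representation used
#' throughout: a data frame with columns `x`, `y` (nm, sample-plane frame
#' shared by all channels of a nucleus after registration), `frame`
#' (acquisition frame index) and `intensity` (photons or a.u., > 0).
#'
#' @param x,y numeric, coordinates in nm.
#' @param frame integer acquisition frame (>= 0); recycled if length 1.
#' @param intensity positive numeric; recycled if length 1.
#' @param channel_id,nucleus_id labels attached as attributes.
#' @param source_pixel_size camera pixel size in nm/px (metadata only).
#' @return A data frame of class `loc_table`.
#' @export
loc_table <- function(x, y, frame = 0L, intensity = 1,
                      channel_id = "ch", nucleus_id = "nucleus",
                      source_pixel_size = NA_real_) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  d <- data.frame(x = as.numeric(x), y = as.numeric(y),
                  frame = rep_len(as.integer(frame), n),
                  intensity = rep_len(as.numeric(intensity), n))
  if (n > 0L) {
    if (any(!is.finite(d$x)) || any(!is.finite(d$y)))
      stopf("localization coordinates must be finite")
    if (any(!is.finite(d$intensity)) || any(d$intensity <= 0))
      stopf("localization intensities must be positive")
    if (any(d$frame < 0L)) stopf("frame indices must be >= 0")
  }
  structure(d, channel_id = channel_id, nucleus_id = nucleus_id,
            source_pixel_size = source_pixel_size,
            class = c("loc_table", "data.frame"))
}

#' Column-mapping dialect for localization files
#'
#' SMLM software writes localization tables with varying headers
#' (`"x [nm]"`, `"Xc"`, ...) and units (nm or camera pixels). A dialect
#' names the columns to use and declares their unit.
#'
#' @param x,y names of the coordinate columns in the file.
#' @param frame,intensity optional column names; defaults used when absent.
#' @param unit `"nm"` or `"px"`; with `"px"`, `pixel_size` (nm/px) is
#'   required and coordinates are converted to nm on read.
#' @param pixel_size camera pixel size in nm/px (required for `unit="px"`).
#' @param sep field separator of the file (`","` or `"\t"`).
#' @return A list of class `loc_dialect`.
#' @export
loc_dialect <- function(x = "x", y = "y", frame = "frame",
                        intensity = "intensity",
                        unit = c("nm", "px"), pixel_size = NA_real_,
                        sep = ",") {
  unit <- match.arg(unit)
  if (unit == "px" && (!is.finite(pixel_size) || pixel_size <= 0))
    stopf("unit 'px' requires a positive pixel_size (nm/px)")
  structure(list(x = x, y = y, frame = frame, intensity = intensity,
                 unit = unit, pixel_size = pixel_size, sep = sep),
            class = "loc_dialect")
}

#' Read a localization table
#'
#' Reads a delimited localization file under a column-mapping dialect and
#' returns coordinates in nm. Row order is preserved; unmapped columns are
#' ignored. Missing optional columns default to `frame = 0`,
#' `intensity = 1`.
#'
#' @param path file path.
#' @param dialect a [loc_dialect()].
#' @inheritParams loc_table
#' @return A [loc_table()].
#' @export
read_localizations <- function(path, dialect = loc_dialect(),
                               channel_id = "ch", nucleus_id = "nucleus") {
  if (!file.exists(path)) stopf("localization file not found: %s", path)
  d <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                         check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("x", "y")) {
    nm <- dialect[[col]]
    if (!nm %in% names(d))
      stopf("required column '%s' (mapped to %s) missing from %s",
            nm, col, path)
  }
  num <- function(col) {
    raw <- d[[dialect[[col]]]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw))
    if (length(bad))
      stopf("non-numeric %s value at data row %d of %s", col, bad[1L], path)
    v
  }
  x <- num("x"); y <- num("y")
  if (dialect$unit == "px") {
    x <- x * dialect$pixel_size
    y <- y * dialect$pixel_size
  }
  fr <- if (dialect$frame %in% names(d)) as.integer(d[[dialect$frame]]) else 0L
  it <- if (dialect$intensity %in% names(d)) num("intensity") else 1
  loc_table(x, y, frame = fr, intensity = it,
            channel_id = channel_id, nucleus_id = nucleus_id,
            source_pixel_size = if (dialect$unit == "px") dialect$pixel_size
                                else NA_real_)
}

#' Write a localization table
#'
#' Writes `x`, `y` (nm), `frame`, `intensity` as delimited text with full
#' double precision, so that write-then-read is the identity.
#'
#' @param table a [loc_table()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, sep = ",") {
  d <- as.data.frame(table)[, c("x", "y", "frame", "intensity")]
  d$x <- format(d$x, digits = 17, trim = TRUE, scientific = FALSE)
  d$y <- format(d$y, digits = 17, trim = TRUE, scientific = FALSE)
  d$intensity <- format(d$intensity, digits = 17, trim = TRUE,
                        scientific = FALSE)
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table: %d localizations, channel '%s', nucleus '%s'>\n",
              nrow(x), attr(x, "channel_id"), attr(x, "nucleus_id")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5L))
  invisible(x)
}
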