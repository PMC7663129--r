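#' Construct a pressure-mat recording
#'
#' A `mat_recording` holds a time-ordered set of activated cells on a fixed
#' rectangular sensor grid, together with the geometry and timing metadata
#' needed to convert cell indices to physical coordinates. The mat's short
#' ("horizontal") axis carries coordinate `a` (columns) and its long
#' ("vertical") axis coordinate `b` (rows); by default the direction of
#' progression is increasing `b`.
#'
#' @param cells data.frame with columns `frame` (integer, 0-based),
#'   `row`, `col` (integer, 0-based cell indices) and `pressure`
#'   (non-negative). Rows are sorted by frame on construction.
#' @param sampling_rate frames per second. Default 240.
#' @param cell_pitch physical cell spacing in mm. Default 12.7.
#' @param grid_rows,grid_cols grid dimensions in cells.
#' @param walking_axis `"+b"` (progression along increasing rows, default)
#'   or `"-b"` for recordings captured walking the other way.
#'
#' @return An object of class `mat_recording`: a list with the fields above.
#' @seealso [read_recording()], [write_recording()], [detect_footfalls()]
#' @export
mat_recording <- function(cells = empty_cells(),
                          sampling_rate = 240,
                          cell_pitch = 12.7,
                          grid_rows = 288,
                          grid_cols = 48,
                          walking_axis = c("+b", "-b")) {
  walking_axis <- match.arg(walking_axis)
  cells <- as.data.frame(cells)
  if (!all(c("frame", "row", "col", "pressure") %in% names(cells))) {
    stop("`cells` must have columns frame, row, col, pressure")
  }
  cells <- cells[order(cells$frame, cells$row, cells$col),
                 c("frame", "row", "col", "pressure"), drop = FALSE]
  rownames(cells) <- NULL
  rec <- structure(
    list(cells = cells,
         sampling_rate = sampling_rate,
         cell_pitch = cell_pitch,
         grid_rows = as.integer(grid_rows),
         grid_cols = as.integer(grid_cols),
         walking_axis = walking_axis),
    class = "mat_recording")
  validate_recording(rec)
  rec
}

empty_cells <- function() {
  data.frame(frame = integer(), row = integer(), col = integer(),
             pressure = numeric())
}

#' Validate a mat recording against its invariants
#'
#' Checks grid bounds, non-negative pressures, positive sampling rate and
#' cell pitch, and monotone frame ordering. Called by the constructor and by
#' [read_recording()]; exported so externally assembled objects can be
#' checked too.
#'
#' @param rec a `mat_recording`.
#' @return `rec`, invisibly. Errors on the first violated invariant.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "mat_recording"))
  if (!is.numeric(rec$sampling_rate) || rec$sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  if (!is.numeric(rec$cell_pitch) || rec$cell_pitch <= 0)
    stop("cell_pitch must be > 0")
  if (rec$grid_rows < 1 || rec$grid_cols < 1)
    stop("grid dimensions must be >= 1")
  cl <- rec$cells
  if (nrow(cl)) {
    if (any(cl$pressure < 0)) stop("pressure must be non-negative")
    if (any(cl$row < 0 | cl$row >= rec$grid_rows |
            cl$col < 0 | cl$col >= rec$grid_cols))
      stop("cell indices out of grid bounds")
    if (is.unsorted(cl$frame)) stop("frame indices must be non-decreasing")
    if (any(cl$frame < 0)) stop("frame indices must be >= 0")
  }
  invisible(rec)
}

#' @export
print.mat_recording <- function(x, ...) {
  nf <- if (nrow(x$cells)) length(unique(x$cells$frame)) else 0L
  cat(sprintf(
    "<mat_recording> %d x %d cells @ %.1f mm, %g Hz, %d active frames, %d cell samples\n",
    x$grid_rows, x$grid_cols, x$cell_pitch, x$sampling_rate, nf,
    nrow(x$cells)))
  invisible(x)
}

#' Physical center of a grid cell
#'
#' Cell `(row, col)` occupies the square `[col, col+1) x [row, row+1)` in
#' cell units; its center is offset by half a pitch from the grid origin at
#' the corner where row 0 and column 0 meet.
#'
#' @param row,col 0-based cell indices (vectorized).
#' @param cell_pitch cell spacing in mm.
#' @return A two-column matrix with columns `a` (from col) and `b` (from
#'   row), in mm.
#' @examples
#' cell_center(0, 0, 12.7)   # a = b = 6.35
#' @export
cell_center <- function(row, col, cell_pitch) {
  cbind(a = (col + 0.5) * cell_pitch, b = (row + 0.5) * cell_pitch)
}

#' Read a mat recording from interchange CSV
#'
#' The interchange format is a plain-text CSV: a header block of
#' `#key=value` lines (`sampling_rate`, `cell_pitch_mm`, `grid_rows`,
#' `grid_cols`, `walking_axis`), a column-header line
#' `frame,row,col,pressure`, then one row per active cell per frame. Frames
#' with no active cells simply have no rows; they are implied by the frame
#' numbering.
#'
#' @param path file to read.
#' @param meta optional named list overriding header metadata
#'   (e.g. `list(sampling_rate = 120)`).
#' @return A validated [mat_recording()].
#' @export
read_recording <- function(path, meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && !identical(hdr_idx, seq_along(hdr_idx)))
    stop("header lines (#key=value) must precede the data block")
  hdr <- parse_header(lines[hdr_idx])
  body <- lines[-seq_len(length(hdr_idx))]
  body <- body[nzchar(body)]
  if (!length(body))
    stop("missing column header line 'frame,row,col,pressure'")
  if (gsub("\\s", "", body[1]) != "frame,row,col,pressure")
    stop("unexpected column header: ", body[1])
  data_lines <- body[-1]
  if (length(data_lines)) {
    parts <- strsplit(data_lines, ",", fixed = TRUE)
    bad <- which(lengths(parts) != 4)
    if (length(bad))
      stop("malformed row at line ",
           length(hdr_idx) + 1 + bad[1], ": ", data_lines[bad[1]])
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 4, byrow = TRUE)
    bad <- which(!stats::complete.cases(m))
    if (length(bad))
      stop("malformed row at line ",
           length(hdr_idx) + 1 + bad[1], ": ", data_lines[bad[1]])
    cells <- data.frame(frame = as.integer(m[, 1]), row = as.integer(m[, 2]),
                        col = as.integer(m[, 3]), pressure = m[, 4])
    if (is.unsorted(cells$frame))
      stop("frame indices must be non-decreasing in the file")
  } else {
    cells <- empty_cells()
  }
  args <- utils::modifyList(hdr, meta)
  mat_recording(cells,
                sampling_rate = args$sampling_rate %||% 240,
                cell_pitch = args$cell_pitch %||% 12.7,
                grid_rows = args$grid_rows %||% 288,
                grid_cols = args$grid_cols %||% 48,
                walking_axis = args$walking_axis %||% "+b")
}

parse_header <- function(hlines) {
  hdr <- list()
  for (h in hlines) {
    kv <- sub("^#", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) stop("malformed header line: ", h)
    key <- trimws(substr(kv, 1, eq - 1))
    val <- trimws(substr(kv, eq + 1, nchar(kv)))
    hdr[[key]] <- val
  }
  out <- list()
  if (!is.null(hdr$sampling_rate)) out$sampling_rate <- as.numeric(hdr$sampling_rate)
  if (!is.null(hdr$cell_pitch_mm)) out$cell_pitch <- as.numeric(hdr$cell_pitch_mm)
  if (!is.null(hdr$grid_rows)) out$grid_rows <- as.integer(hdr$grid_rows)
  if (!is.null(hdr$grid_cols)) out$grid_cols <- as.integer(hdr$grid_cols)
  if (!is.null(hdr$walking_axis)) out$walking_axis <- hdr$walking_axis
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a mat recording to interchange CSV
#'
#' Inverse of [read_recording()]: `read_recording(write_recording(rec, p))`
#' reproduces `rec` exactly. Numeric pressures are written with up to 15
#' significant digits so round-trips are lossless; identical recordings
#' produce byte-identical files.
#'
#' @param rec a [mat_recording()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  hdr <- c(
    sprintf("#sampling_rate=%s", format(rec$sampling_rate, digits = 15)),
    sprintf("#cell_pitch_mm=%s", format(rec$cell_pitch, digits = 15)),
    sprintf("#grid_rows=%d", rec$grid_rows),
    sprintf("#grid_cols=%d", rec$grid_cols),
    sprintf("#walking_axis=%s", rec$walking_axis),
    "frame,row,col,pressure")
  body <- if (nrow(rec$cells)) {
    sprintf("%d,%d,%d,%s", rec$cells$frame, rec$cells$row, rec$cells$col,
            vapply(rec$cells$pressure, format, "", digits = 15))
  } else character()
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Construct a static footprint grid
#'
#' A single-foot occupancy/pressure grid used for arch-index computation.
#' An optional toe mask flags cells that belong to the toes and must be
#' excluded before the arch index is measured.
#'
#' @param cells data.frame with columns `row`, `col`, `pressure` and
#'   optionally logical `is_toe`.
#' @param cell_pitch cell spacing in mm.
#' @return An object of class `footprint_grid`.
#' @seealso [exclude_toes()], [compute_arch_index()]
#' @export
footprint_grid <- function(cells, cell_pitch = 12.7) {
  cells <- as.data.frame(cells)
  if (!all(c("row", "col", "pressure") %in% names(cells)))
    stop("`cells` must have columns row, col, pressure")
  if (is.null(cells$is_toe)) cells$is_toe <- FALSE
  if (!nrow(cells)) stop("footprint must be non-empty")
  if (any(cells$pressure < 0)) stop("pressure must be non-negative")
  if (anyDuplicated(cells[c("row", "col")]))
    stop("duplicate cells in footprint")
  if (cell_pitch <= 0) stop("cell_pitch must be > 0")
  cells <- cells[order(cells$row, cells$col), ]
  rownames(cells) <- NULL
  structure(list(cells = cells, cell_pitch = cell_pitch),
            class = "footprint_grid")
}

#' Read / write a footprint grid CSV
#'
#' Format: optional `#cell_pitch_mm=` header, a `row,col,pressure,is_toe`
#' column header, then one line per occupied cell (`is_toe` is 0/1 and may
#' be omitted on read).
#'
#' @param path file path.
#' @param cell_pitch fallback pitch when the file has no header.
#' @return [footprint_grid()] for `read_footprint`; `path` invisibly for
#'   `write_footprint`.
#' @export
read_footprint <- function(path, cell_pitch = 12.7) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  hdr <- parse_header(lines[hdr_idx])
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(body)]
  df <- utils::read.csv(text = body)
  if (is.null(df$is_toe)) df$is_toe <- FALSE
  df$is_toe <- as.logical(df$is_toe)
  footprint_grid(df, cell_pitch = hdr$cell_pitch %||% cell_pitch)
}

#' @rdname read_footprint
#' @param fp a [footprint_grid()].
#' @export
write_footprint <- function(fp, path) {
  stopifnot(inherits(fp, "footprint_grid"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("#cell_pitch_mm=%s", format(fp$cell_pitch, digits = 15)),
             con)
  writeLines("row,col,pressure,is_toe", con)
  writeLines(sprintf("%d,%d,%s,%d", fp$cells$row, fp$cells$col,
                     vapply(fp$cells$pressure, format, "", digits = 15),
                     as.integer(fp$cells$is_toe)), con)
  invisible(path)
}
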