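#' Regular elevation grid for a tooth-row occlusal surface
#'
#' A height map is the raster on which orientation patch counts are computed:
#' a rectangular grid of elevations (mm) with a validity mask. The row axis is
#' the mesiodistal (anteroposterior) axis along which teeth succeed one
#' another; the column axis is buccolingual. Grid "north" is the +row
#' direction.
#'
#' @param values numeric matrix of elevations in mm; `NA` entries are treated
#'   as masked.
#' @param spacing_row,spacing_col grid step along the row / column axis (mm),
#'   both > 0.
#' @param mask logical matrix, `TRUE` where the cell holds a valid elevation.
#'   Defaults to `!is.na(values)`.
#' @param origin length-2 numeric, offset (mm) of the first cell centre.
#' @return An object of class `height_map` with fields `values`,
#'   `spacing_row`, `spacing_col`, `mask`, `origin`.
#' @examples
#' hm <- height_map(matrix(0, 5, 5), spacing_row = 0.1, spacing_col = 0.1)
#' dim(hm$values)
#' @export
height_map <- function(values, spacing_row = 1, spacing_col = spacing_row,
                       mask = NULL, origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(spacing_row) || length(spacing_row) != 1 || spacing_row <= 0 ||
      !is.numeric(spacing_col) || length(spacing_col) != 1 || spacing_col <= 0)
    stop("grid spacing must be a positive scalar", call. = FALSE)
  if (is.null(mask)) mask <- !is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    stop("`mask` must be a logical matrix with the dimensions of `values`",
         call. = FALSE)
  mask <- mask & !is.na(values) & is.finite(ifelse(is.na(values), 0, values))
  if (any(!is.finite(values[mask])))
    stop("masked-in elevations must be finite", call. = FALSE)
  structure(
    list(values = values, spacing_row = spacing_row, spacing_col = spacing_col,
         mask = mask, origin = as.numeric(origin)),
    class = "height_map"
  )
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d cells, spacing %.4g x %.4g mm, %d masked\n",
              nrow(x$values), ncol(x$values), x$spacing_row, x$spacing_col,
              sum(!x$mask)))
  invisible(x)
}

is_height_map <- function(x) inherits(x, "height_map")

#' Standardized tooth-row grid
#'
#' Couples a [height_map()] with the number of teeth it spans. The grid is
#' standardized so that each tooth contributes a fixed number of data rows
#' along the mesiodistal axis (50 by default): a row of 4 teeth has 200 data
#' rows, a row of 1 tooth has 50.
#'
#' @param heightmap a [height_map()].
#' @param n_teeth integer, number of teeth in the row (>= 1).
#' @param rows_per_tooth integer, data rows per tooth (default 50).
#' @return An object of class `tooth_row_grid`.
#' @seealso [standardize_tooth_row()] to build one from an arbitrary grid.
#' @export
tooth_row_grid <- function(heightmap, n_teeth, rows_per_tooth = 50L) {
  if (!is_height_map(heightmap))
    stop("`heightmap` must be a height_map", call. = FALSE)
  n_teeth <- check_count(n_teeth, "n_teeth")
  rows_per_tooth <- check_count(rows_per_tooth, "rows_per_tooth")
  if (nrow(heightmap$values) != n_teeth * rows_per_tooth)
    stop(sprintf("height map has %d rows; expected n_teeth * rows_per_tooth = %d",
                 nrow(heightmap$values), n_teeth * rows_per_tooth), call. = FALSE)
  structure(list(heightmap = heightmap, n_teeth = n_teeth,
                 rows_per_tooth = rows_per_tooth),
            class = "tooth_row_grid")
}

#' @export
print.tooth_row_grid <- function(x, ...) {
  cat(sprintf("<tooth_row_grid> %d teeth x %d rows/tooth (%d x %d cells)\n",
              x$n_teeth, x$rows_per_tooth, nrow(x$heightmap$values),
              ncol(x$heightmap$values)))
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 ||
      x != round(x))
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  as.integer(x)
}
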