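## Surface I/O: PLY meshes, XYZ point clouds, Surfer ASCII (DSAA) grids, and
## conversion of point clouds into standardized tooth-row height maps.
## Coordinates are millimetres throughout; units are preserved as stored.

#' Read a PLY (Stanford Triangle Format) surface mesh
#'
#' Supports `ascii 1.0` and `binary_little_endian 1.0` PLY files with a
#' vertex element carrying `x`, `y`, `z` properties (other vertex properties
#' are skipped) and an optional face element with a vertex-index list.
#' Non-triangular faces are triangulated as fans, with a warning.
#'
#' @param path path to a `.ply` file.
#' @return An object of class `surface_mesh`: list with `vertices` (n x 3
#'   numeric matrix, mm), `faces` (m x 3 integer matrix of 1-based vertex
#'   indices, zero rows if the file stores none) and `provenance`.
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- read_bin_line(con)
    if (is.null(line))
      stop("malformed PLY header: end of file before 'end_header'", call. = FALSE)
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(header) > 1000)
      stop("malformed PLY header: no 'end_header' in first 1000 lines", call. = FALSE)
  }
  if (!identical(header[1], "ply"))
    stop(sprintf("malformed PLY header at line 1: expected 'ply', got '%s'",
                 header[1]), call. = FALSE)
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1)
    stop("malformed PLY header: missing 'format' line", call. = FALSE)
  fmt <- strsplit(trimws(fmt_line), "[[:space:]]+")[[1]]
  if (length(fmt) < 3 || !fmt[2] %in% c("ascii", "binary_little_endian"))
    stop(sprintf("malformed PLY header at line '%s': unsupported format", fmt_line),
         call. = FALSE)
  elements <- parse_ply_elements(header)
  vi <- which(vapply(elements, function(e) e$name == "vertex", TRUE))
  if (length(vi) != 1)
    stop("malformed PLY header: no vertex element", call. = FALSE)
  data <- if (fmt[2] == "ascii") read_ply_ascii(con, elements)
          else read_ply_binary(con, elements)
  verts <- data[[vi]]
  need <- c("x", "y", "z")
  if (!all(need %in% colnames(verts)))
    stop("malformed PLY header: vertex element lacks x/y/z properties", call. = FALSE)
  vertices <- unname(as.matrix(verts[, need, drop = FALSE]))
  if (nrow(vertices) < 3)
    stop("PLY mesh must carry at least 3 vertices", call. = FALSE)
  if (any(!is.finite(vertices)))
    stop("PLY vertex coordinates must be finite", call. = FALSE)
  fi <- which(vapply(elements, function(e) e$name == "face", TRUE))
  faces <- matrix(integer(), 0, 3)
  if (length(fi) == 1 && elements[[fi]]$count > 0) {
    faces <- triangulate_faces(data[[fi]], nrow(vertices))
  }
  structure(list(vertices = vertices, faces = faces,
                 provenance = list(path = path, format = fmt[2])),
            class = "surface_mesh")
}

read_bin_line <- function(con) {
  bytes <- raw()
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0) return(if (length(bytes)) rawToChar(bytes) else NULL)
    if (b == as.raw(10L)) break
    bytes <- c(bytes, b)
  }
  sub("\r$", "", rawToChar(bytes))
}

parse_ply_elements <- function(header) {
  elements <- list()
  cur <- NULL
  for (i in seq_along(header)) {
    line <- trimws(header[i])
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (tok[1] == "element") {
      if (length(tok) != 3 || is.na(suppressWarnings(as.integer(tok[3]))))
        stop(sprintf("malformed PLY header at line %d: '%s'", i, line), call. = FALSE)
      if (!is.null(cur)) elements[[length(elements) + 1]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur))
        stop(sprintf("malformed PLY header at line %d: property outside element", i),
             call. = FALSE)
      if (tok[2] == "list") {
        if (length(tok) != 5)
          stop(sprintf("malformed PLY header at line %d: '%s'", i, line), call. = FALSE)
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], type = tok[4], list = TRUE, count_type = tok[3])
      } else {
        if (length(tok) != 3)
          stop(sprintf("malformed PLY header at line %d: '%s'", i, line), call. = FALSE)
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], type = tok[2], list = FALSE)
      }
    }
  }
  if (!is.null(cur)) elements[[length(elements) + 1]] <- cur
  elements
}

ply_type_size <- function(type) {
  switch(type,
         char = , int8 = , uchar = , uint8 = 1L,
         short = , int16 = , ushort = , uint16 = 2L,
         int = , int32 = , uint = , uint32 = 4L, float = , float32 = 4L,
         double = , float64 = 8L,
         stop(sprintf("unsupported PLY property type '%s'", type), call. = FALSE))
}

read_ply_scalar <- function(con, type) {
  sz <- ply_type_size(type)
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", 1L, size = sz, endian = "little")
  else {
    signed <- !grepl("^u", type)
    readBin(con, "integer", 1L, size = sz, signed = if (sz < 4) signed else TRUE,
            endian = "little")
  }
}

read_ply_ascii <- function(con, elements) {
  rest <- readLines(con, warn = FALSE)
  rest <- rest[nzchar(trimws(rest))]
  ptr <- 0L
  out <- list()
  for (e in elements) {
    has_list <- any(vapply(e$props, `[[`, TRUE, "list"))
    if (!has_list) {
      nm <- vapply(e$props, `[[`, "", "name")
      m <- matrix(NA_real_, e$count, length(nm), dimnames = list(NULL, nm))
      for (r in seq_len(e$count)) {
        ptr <- ptr + 1L
        fields <- suppressWarnings(as.numeric(
          strsplit(trimws(rest[ptr]), "[[:space:]]+")[[1]]))
        if (length(fields) < length(nm) || anyNA(fields[seq_along(nm)]))
          stop(sprintf("malformed PLY body: element '%s' row %d", e$name, r),
               call. = FALSE)
        m[r, ] <- fields[seq_along(nm)]
      }
      out[[length(out) + 1]] <- as.data.frame(m)
    } else {
      lst <- vector("list", e$count)
      for (r in seq_len(e$count)) {
        ptr <- ptr + 1L
        fields <- suppressWarnings(as.numeric(
          strsplit(trimws(rest[ptr]), "[[:space:]]+")[[1]]))
        k <- fields[1]
        if (is.na(k) || length(fields) < 1 + k)
          stop(sprintf("malformed PLY body: face row %d", r), call. = FALSE)
        lst[[r]] <- as.integer(fields[2:(1 + k)])
      }
      out[[length(out) + 1]] <- lst
    }
  }
  out
}

read_ply_binary <- function(con, elements) {
  out <- list()
  for (e in elements) {
    has_list <- any(vapply(e$props, `[[`, TRUE, "list"))
    if (!has_list) {
      nm <- vapply(e$props, `[[`, "", "name")
      m <- matrix(NA_real_, e$count, length(nm), dimnames = list(NULL, nm))
      for (r in seq_len(e$count))
        for (j in seq_along(e$props))
          m[r, j] <- read_ply_scalar(con, e$props[[j]]$type)
      out[[length(out) + 1]] <- as.data.frame(m)
    } else {
      lst <- vector("list", e$count)
      for (r in seq_len(e$count)) {
        row <- NULL
        for (p in e$props) {
          if (p$list) {
            k <- read_ply_scalar(con, p$count_type)
            row <- vapply(seq_len(k), function(i) read_ply_scalar(con, p$type), 0)
          } else read_ply_scalar(con, p$type)
        }
        lst[[r]] <- as.integer(row)
      }
      out[[length(out) + 1]] <- lst
    }
  }
  out
}

triangulate_faces <- function(face_list, n_vertices) {
  non_tri <- any(lengths(face_list) > 3)
  tris <- lapply(face_list, function(idx) {
    if (length(idx) < 3)
      stop("PLY face with fewer than 3 vertices", call. = FALSE)
    if (any(idx < 0 | idx >= n_vertices))
      stop(sprintf("PLY face index %d out of range (0..%d)",
                   idx[which(idx < 0 | idx >= n_vertices)[1]], n_vertices - 1L),
           call. = FALSE)
    if (length(idx) == 3) matrix(idx + 1L, 1, 3)
    else do.call(rbind, lapply(2:(length(idx) - 1),
                               function(i) idx[c(1, i, i + 1)] + 1L))
  })
  if (non_tri)
    warning("non-triangular PLY faces triangulated as fans", call. = FALSE)
  do.call(rbind, tris)
}

#' Write a surface mesh as a PLY file
#'
#' @param mesh a `surface_mesh` (or list with `vertices` and `faces`).
#' @param path output path.
#' @param format `"ascii"` or `"binary_little_endian"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, format = c("ascii", "binary_little_endian")) {
  format <- match.arg(format)
  v <- mesh$vertices
  f <- mesh$faces
  header <- c("ply", paste("format", format, "1.0"),
              sprintf("element vertex %d", nrow(v)),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", if (is.null(f)) 0L else nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (format == "ascii") {
    writeLines(apply(v, 1, function(r) paste(format(r, digits = 9), collapse = " ")),
               con, sep = "\n")
    if (!is.null(f) && nrow(f))
      writeLines(apply(f, 1, function(r) paste(c(3L, r - 1L), collapse = " ")),
                 con, sep = "\n")
  } else {
    for (i in seq_len(nrow(v)))
      writeBin(as.numeric(v[i, ]), con, size = 4L, endian = "little")
    if (!is.null(f) && nrow(f))
      for (i in seq_len(nrow(f))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
      }
  }
  invisible(path)
}

#' Read an XYZ point cloud
#'
#' Whitespace- or comma-delimited triples, one point per line; `#` starts a
#' comment line.
#'
#' @param path path to the text file.
#' @return An object of class `point_cloud`: list with `points`, an n x 3
#'   numeric matrix (mm).
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop("XYZ file holds no points", call. = FALSE)
  pts <- matrix(NA_real_, length(idx), 3)
  for (k in seq_along(idx)) {
    fields <- strsplit(trimws(lines[idx[k]]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 3 || anyNA(vals) || any(!is.finite(vals)))
      stop(sprintf("XYZ parse error at line %d: expected 3 numeric fields",
                   idx[k]), call. = FALSE)
    pts[k, ] <- vals
  }
  structure(list(points = pts), class = "point_cloud")
}

#' Write an XYZ point cloud
#' @param cloud a `point_cloud` or an n x 3 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path) {
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  writeLines(apply(pts, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), path)
  invisible(path)
}

## Surfer ASCII grid blank sentinel (Golden Software convention).
SURFER_BLANK <- 1.70141e38

#' Read a Surfer ASCII grid (DSAA dialect)
#'
#' The DSAA layout is: magic `DSAA`; `ncol nrow`; `xmin xmax`; `ymin ymax`;
#' `zmin zmax`; then `nrow` grid rows of `ncol` elevations starting at `ymin`.
#' Cells holding the Surfer blank sentinel (1.70141e38) are masked.
#'
#' @param path path to a `.grd` file.
#' @return A [height_map()]; rows run south to north (`ymin` first), columns
#'   west to east.
#' @export
read_surfer_grid <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  toks <- scan(path, what = character(), quiet = TRUE)
  if (!length(toks) || toks[1] != "DSAA")
    stop("not a Surfer ASCII grid: missing DSAA magic", call. = FALSE)
  hd <- suppressWarnings(as.numeric(toks[2:9]))
  if (anyNA(hd)) stop("malformed DSAA header", call. = FALSE)
  nc <- as.integer(hd[1]); nr <- as.integer(hd[2])
  xmin <- hd[3]; xmax <- hd[4]; ymin <- hd[5]; ymax <- hd[6]
  z <- suppressWarnings(as.numeric(toks[-(1:9)]))
  if (length(z) != nr * nc || anyNA(z))
    stop(sprintf("DSAA grid size mismatch: header says %d x %d, found %d values",
                 nr, nc, length(z)), call. = FALSE)
  vals <- matrix(z, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- vals < SURFER_BLANK * (1 - 1e-12)
  vals[!mask] <- NA_real_
  height_map(vals,
             spacing_row = if (nr > 1) (ymax - ymin) / (nr - 1) else 1,
             spacing_col = if (nc > 1) (xmax - xmin) / (nc - 1) else 1,
             mask = mask, origin = c(ymin, xmin))
}

#' Write a height map as a Surfer ASCII grid (DSAA)
#' @param hm a [height_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surfer_grid <- function(hm, path) {
  stopifnot(is_height_map(hm))
  v <- hm$values
  v[!hm$mask] <- NA_real_
  nr <- nrow(v); nc <- ncol(v)
  ymin <- hm$origin[1]; xmin <- hm$origin[2]
  ymax <- ymin + (nr - 1) * hm$spacing_row
  xmax <- xmin + (nc - 1) * hm$spacing_col
  zr <- range(v, na.rm = !all(is.na(v)))
  if (anyNA(zr)) zr <- c(0, 0)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("DSAA",
               paste(nc, nr),
               paste(sprintf("%.17g", c(xmin, xmax)), collapse = " "),
               paste(sprintf("%.17g", c(ymin, ymax)), collapse = " "),
               paste(sprintf("%.17g", zr), collapse = " ")), con)
  for (r in seq_len(nr)) {
    row <- v[r, ]
    row[is.na(row)] <- SURFER_BLANK
    writeLines(paste(sprintf("%.17g", row), collapse = " "), con)
  }
  invisible(path)
}

#' Rasterize a point cloud into an occlusal height map
#'
#' Bins points on a regular grid whose row axis is the mesiodistal axis and
#' takes the per-cell maximum elevation (the upper, occlusal envelope).
#' Empty cells are masked; masked holes of at most `fill_holes` cells that do
#' not touch the grid border are filled with the mean of their valid
#' 4-neighbours.
#'
#' @param cloud a `point_cloud` or n x 3 matrix; columns x (buccolingual),
#'   y (mesiodistal), z (elevation) unless `row_axis = "x"`.
#' @param target_rows number of grid rows along the mesiodistal axis.
#' @param row_axis which input axis runs mesiodistally: `"y"` (default) or
#'   `"x"` for pre-rotated clouds.
#' @param fill_holes largest masked hole (cells) filled by neighbourhood mean.
#' @return A [height_map()]. The column count is chosen to preserve the
#'   cloud's aspect ratio.
#' @export
grid_point_cloud <- function(cloud, target_rows, row_axis = c("y", "x"),
                             fill_holes = 2L) {
  row_axis <- match.arg(row_axis)
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  if (!is.matrix(pts) || ncol(pts) != 3 || nrow(pts) < 1 || any(!is.finite(pts)))
    stop("point cloud must be a finite n x 3 matrix", call. = FALSE)
  target_rows <- check_count(target_rows, "target_rows")
  rc <- if (row_axis == "y") pts[, 2] else pts[, 1]
  cc <- if (row_axis == "y") pts[, 1] else pts[, 2]
  z <- pts[, 3]
  ext_r <- diff(range(rc)); ext_c <- diff(range(cc))
  if (ext_r <= 0 || ext_c <= 0)
    stop("degenerate point cloud: zero extent along a grid axis", call. = FALSE)
  nr <- target_rows
  nc <- max(1L, as.integer(round(target_rows * ext_c / ext_r)))
  ri <- pmin(nr, 1L + as.integer(floor((rc - min(rc)) / ext_r * nr)))
  ci <- pmin(nc, 1L + as.integer(floor((cc - min(cc)) / ext_c * nc)))
  vals <- matrix(NA_real_, nr, nc)
  idx <- (ci - 1L) * nr + ri
  agg <- tapply(z, idx, max)
  vals[as.integer(names(agg))] <- agg
  hm <- height_map(vals, spacing_row = ext_r / nr, spacing_col = ext_c / nc,
                   origin = c(min(rc) + ext_r / nr / 2, min(cc) + ext_c / nc / 2))
  fill_small_holes(hm, max_cells = fill_holes)
}

## Fill interior masked clusters of at most `max_cells` cells with the mean of
## their valid 4-neighbours; larger holes and border holes stay masked.
fill_small_holes <- function(hm, max_cells = 2L) {
  if (max_cells < 1L || all(hm$mask)) return(hm)
  m <- hm$mask
  nr <- nrow(m); nc <- ncol(m)
  holes <- which(!m)
  if (!length(holes)) return(hm)
  lab <- label_components(!m, connectivity = 4L)
  for (id in setdiff(unique(lab[holes]), 0L)) {
    cells <- which(lab == id)
    if (length(cells) > max_cells) next
    r <- (cells - 1L) %% nr + 1L
    c <- (cells - 1L) %/% nr + 1L
    if (any(r == 1L | r == nr | c == 1L | c == nc)) next
    for (k in seq_along(cells)) {
      nb <- c(if (r[k] > 1) cells[k] - 1L, if (r[k] < nr) cells[k] + 1L,
              if (c[k] > 1) cells[k] - nr, if (c[k] < nc) cells[k] + nr)
      nb <- nb[hm$mask[nb]]
      if (length(nb)) {
        hm$values[cells[k]] <- mean(hm$values[nb])
        hm$mask[cells[k]] <- TRUE
      }
    }
  }
  hm
}

#' Standardize a tooth-row height map to a fixed number of rows per tooth
#'
#' Resamples the grid bilinearly so the mesiodistal axis spans
#' `n_teeth * rows_per_tooth` data rows (a 4-tooth row becomes 200 rows, a
#' 1-tooth row 50). Columns are rescaled by the same factor, preserving the
#' aspect ratio. The mask is resampled conservatively: an output cell is
#' masked if any input cell contributing to its interpolation is masked.
#'
#' @param hm a [height_map()].
#' @param n_teeth number of teeth spanned by the grid rows.
#' @param rows_per_tooth data rows per tooth after standardization.
#' @return A [tooth_row_grid()].
#' @export
standardize_tooth_row <- function(hm, n_teeth, rows_per_tooth = 50L) {
  stopifnot(is_height_map(hm))
  n_teeth <- check_count(n_teeth, "n_teeth")
  rows_per_tooth <- check_count(rows_per_tooth, "rows_per_tooth")
  if (sum(rowSums(hm$mask) > 0) < 3)
    stop("height map needs at least 3 valid rows", call. = FALSE)
  nr_in <- nrow(hm$values); nc_in <- ncol(hm$values)
  nr_out <- n_teeth * rows_per_tooth
  factor <- nr_out / nr_in
  nc_out <- max(3L, as.integer(round(nc_in * factor)))
  u <- pmin(pmax((seq_len(nr_out) - 0.5) / factor + 0.5, 1), nr_in)
  v <- pmin(pmax((seq_len(nc_out) - 0.5) / (nc_out / nc_in) + 0.5, 1), nc_in)
  i0 <- pmin(floor(u), nr_in - ifelse(nr_in > 1, 1, 0)); i1 <- pmin(i0 + 1, nr_in)
  j0 <- pmin(floor(v), nc_in - ifelse(nc_in > 1, 1, 0)); j1 <- pmin(j0 + 1, nc_in)
  wu <- u - i0; wv <- v - j0
  z <- hm$values
  z[!hm$mask] <- NA_real_
  W00 <- outer(1 - wu, 1 - wv); W01 <- outer(1 - wu, wv)
  W10 <- outer(wu, 1 - wv);     W11 <- outer(wu, wv)
  zf <- z; zf[is.na(zf)] <- 0
  vals <- W00 * zf[i0, j0, drop = FALSE] + W01 * zf[i0, j1, drop = FALSE] +
          W10 * zf[i1, j0, drop = FALSE] + W11 * zf[i1, j1, drop = FALSE]
  m <- hm$mask
  mask_out <- m[i0, j0, drop = FALSE] & m[i0, j1, drop = FALSE] &
              m[i1, j0, drop = FALSE] & m[i1, j1, drop = FALSE]
  vals[!mask_out] <- NA_real_
  out <- height_map(vals,
                    spacing_row = hm$spacing_row * nr_in / nr_out,
                    spacing_col = hm$spacing_col * nc_in / nc_out,
                    mask = mask_out, origin = hm$origin)
  tooth_row_grid(out, n_teeth, rows_per_tooth)
}
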