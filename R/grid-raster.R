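#' Lightweight single-band raster grid
#'
#' A `grid_raster` wraps a numeric matrix in a north-up, row-major,
#' projected-metre georeference: row 1 is the northern edge, column 1 the
#' western edge, and cell values refer to cell centres. This is the common
#' container for predictor bands, dominance maps, carbon maps and binary
#' extent masks.
#'
#' @param values numeric matrix (rows = north to south).
#' @param cell_size_m cell edge length in metres (> 0).
#' @param origin numeric length-2, (x, y) of the *outer* south-west corner
#'   in projected metres.
#' @param nodata value standing for missing cells in serialized form;
#'   in memory missing cells are `NA`.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, cell_size_m = 5, origin = c(0, 0),
                        nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(cell_size_m), length(cell_size_m) == 1L,
            cell_size_m > 0, length(origin) == 2L)
  structure(
    list(values = values, cell_size_m = as.numeric(cell_size_m),
         origin = as.numeric(origin), nodata = nodata),
    class = "grid_raster"
  )
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' @export
print.grid_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "grid_raster: %d rows x %d cols, cell %.3g m, origin (%.6g, %.6g)\n",
    d[1], d[2], x$cell_size_m, x$origin[1], x$origin[2]))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: min %.4g, max %.4g, NA cells %d\n",
                min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' Cell area in hectares
#' @param grid a `grid_raster`.
#' @return scalar, hectares per cell.
#' @export
cell_area_ha <- function(grid) {
  stopifnot(inherits(grid, "grid_raster"))
  grid$cell_size_m^2 / 1e4
}

#' Test that two grids share shape and georeference
#' @param a,b `grid_raster` objects.
#' @return logical scalar.
#' @export
grids_aligned <- function(a, b) {
  inherits(a, "grid_raster") && inherits(b, "grid_raster") &&
    identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size_m, b$cell_size_m)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Write a grid as an ESRI ASCII raster (.asc)
#'
#' Plain-text interchange format readable by standard GIS tools. `NA`
#' cells are written as the grid's nodata value.
#'
#' @param grid a `grid_raster`.
#' @param path output file path.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_grid_asc <- function(grid, path, digits = 8) {
  stopifnot(inherits(grid, "grid_raster"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size_m),
    sprintf("NODATA_value %.10g", grid$nodata))
  body <- apply(signif(v, digits), 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster (.asc) into a grid_raster
#' @param path file written by [write_grid_asc()] (or any ESRI ASCII grid).
#' @return a `grid_raster`; nodata cells become `NA`.
#' @export
read_grid_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- val("ncols"); nrows <- val("nrows")
  m <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"),
                   quiet = TRUE),
              nrow = nrows, ncol = ncols, byrow = TRUE)
  nodata <- val("NODATA_value")
  m[m == nodata] <- NA
  grid_raster(m, cell_size_m = val("cellsize"),
              origin = c(val("xllcorner"), val("yllcorner")),
              nodata = nodata)
}

#' Map projected coordinates to grid row/column indices
#'
#' Points outside the grid return `NA` indices.
#'
#' @param grid a `grid_raster`.
#' @param x,y coordinate vectors in projected metres.
#' @return data.frame with columns `row`, `col`.
#' @export
grid_cell_index <- function(grid, x, y) {
  stopifnot(inherits(grid, "grid_raster"), length(x) == length(y))
  d <- dim(grid$values)
  col <- floor((x - grid$origin[1]) / grid$cell_size_m) + 1L
  # row 1 is the north edge
  row <- d[1] - floor((y - grid$origin[2]) / grid$cell_size_m)
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Sample grid values at point locations (nearest cell)
#' @inheritParams grid_cell_index
#' @return numeric vector of cell values (`NA` outside the grid).
#' @export
grid_sample <- function(grid, x, y) {
  ix <- grid_cell_index(grid, x, y)
  out <- rep(NA_real_, nrow(ix))
  ok <- !is.na(ix$row)
  out[ok] <- grid$values[cbind(ix$row[ok], ix$col[ok])]
  out
}

# binary morphology on 0/1 matrices, square structuring element ----------

shift_mat <- function(m, dr, dc, fill) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Binary erosion with a square structuring element
#' @param m 0/1 matrix.
#' @param width side of the square element in cells (>= 1).
#' @return 0/1 matrix of the same shape.
#' @export
binary_erode <- function(m, width) {
  stopifnot(width >= 1)
  if (width == 1) return(m)
  offs <- seq_len(width) - 1L - (width %/% 2L)
  out <- m
  for (dr in offs) for (dc in offs)
    out <- out * shift_mat(m, dr, dc, fill = 0)
  out
}

#' Binary dilation with a square structuring element
#' @inheritParams binary_erode
#' @return 0/1 matrix of the same shape.
#' @export
binary_dilate <- function(m, width) {
  stopifnot(width >= 1)
  if (width == 1) return(m)
  offs <- seq_len(width) - 1L - (width %/% 2L)
  out <- matrix(0, nrow(m), ncol(m))
  # reflected element relative to erosion so that opening is exact on
  # features at least as wide as the element
  for (dr in offs) for (dc in offs)
    out <- pmax(out, shift_mat(m, -dr, -dc, fill = 0))
  out
}

#' Binary opening (erosion then dilation)
#'
#' Removes connected features narrower than the structuring element;
#' used to discount sliver change strips below a minimum mapping width.
#'
#' @inheritParams binary_erode
#' @return 0/1 matrix of the same shape.
#' @export
binary_open <- function(m, width) binary_dilate(binary_erode(m, width), width)
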