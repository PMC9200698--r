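#' Raster elevation grid
#'
#' Light-weight container for a square-celled, north-up elevation raster.
#' Row 1 is the northern (top) edge; cell centres sit at half-integer
#' multiples of the cell size, with the origin at the lower-left corner.
#'
#' @param z numeric matrix of elevations (m); no `NA` allowed inside the
#'   modelled domain.
#' @param cellsize cell edge length (m).
#' @param xll,yll coordinates of the lower-left corner of the grid (m).
#' @return An object of class `dem_grid`.
#' @export
dem_grid <- function(z, cellsize = 2, xll = 0, yll = 0) {
  stopifnot(is.matrix(z), is.numeric(z), cellsize > 0)
  if (anyNA(z)) stop("DEM contains undefined cells")
  structure(list(z = z, cellsize = cellsize, xll = xll, yll = yll),
            class = "dem_grid")
}

#' @export
print.dem_grid <- function(x, ...) {
  cat(sprintf("<dem_grid> %d x %d cells, cellsize %g m, z in [%.2f, %.2f] m\n",
              nrow(x$z), ncol(x$z), x$cellsize, min(x$z), max(x$z)))
  invisible(x)
}

#' @export
dim.dem_grid <- function(x) dim(x$z)

#' Cell-centre coordinates
#'
#' @param dem a [dem_grid()].
#' @param row,col cell indices (row 1 = top).
#' @return Two-column matrix of x/y coordinates in metres.
#' @export
cell_xy <- function(dem, row, col) {
  cs <- dem$cellsize
  cbind(x = dem$xll + (col - 0.5) * cs,
        y = dem$yll + (nrow(dem$z) - row + 0.5) * cs)
}

#' Map planar coordinates to cell indices
#' @inheritParams cell_xy
#' @param x,y coordinates (m).
#' @return Two-column matrix of row/col indices; coordinates outside the
#'   grid give `NA`.
#' @export
xy_cell <- function(dem, x, y) {
  cs <- dem$cellsize
  col <- floor((x - dem$xll) / cs) + 1L
  row <- nrow(dem$z) - floor((y - dem$yll) / cs)
  bad <- col < 1L | col > ncol(dem$z) | row < 1L | row > nrow(dem$z)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# Shift a matrix by (dr, dc), padding with `fill`. dr > 0 pulls values from
# rows further down, i.e. result[i,j] = M[i+dr, j+dc].
shift_mat <- function(m, dr, dc, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1L, 1L - dr):min(nr, nr - dr)
  sc <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(sr) > 0 && length(sc) > 0)
    out[sr, sc] <- m[sr + dr, sc + dc]
  out
}

# 8-neighbour offsets in Tarboton facet order: E, NE, N, NW, W, SW, S, SE
# (dr is the row offset in matrix convention: north = -1).
NEIGHBOUR_OFFSETS <- cbind(
  dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
  dc = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
)

#' Point-in-polygon test
#'
#' Even-odd ray casting. Points exactly on an edge are treated as inside.
#'
#' @param px,py point coordinates.
#' @param ring two-column matrix of polygon vertices (closed or open ring).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, ring) {
  ring <- close_ring(ring)
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  on_edge <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    d <- dist_point_segment(px, py, ring[i, 1], ring[i, 2],
                            ring[i + 1L, 1], ring[i + 1L, 2])
    on_edge <- on_edge | d < 1e-9
  }
  inside | on_edge
}

close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

#' Distance from points to a segment
#' @param px,py point coordinates.
#' @param x1,y1,x2,y2 segment end points.
#' @return Numeric vector of Euclidean distances.
#' @export
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Distance from a point to a polygon boundary (0 if inside)
#' @param px,py point coordinates (scalars or vectors).
#' @param ring polygon ring as in [point_in_polygon()].
#' @export
dist_point_polygon <- function(px, py, ring) {
  ring <- close_ring(ring)
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(ring) - 1L)) {
    d <- pmin(d, dist_point_segment(px, py, ring[i, 1], ring[i, 2],
                                    ring[i + 1L, 1], ring[i + 1L, 2]))
  }
  d[point_in_polygon(px, py, ring)] <- 0
  d
}

#' Rasterise a polygon onto a grid
#'
#' Cells whose centres fall inside the ring are selected.
#'
#' @param dem a [dem_grid()].
#' @param ring polygon ring (metres, same frame as the grid).
#' @return Integer matrix with columns `row`, `col`.
#' @export
rasterize_polygon <- function(dem, ring) {
  bb <- apply(close_ring(ring), 2, range)
  lo <- xy_cell(dem, bb[1, 1], bb[2, 2])  # min x, max y -> top-left cell
  hi <- xy_cell(dem, bb[2, 1], bb[1, 2])
  r0 <- max(1L, lo[1, "row"], na.rm = TRUE)
  r1 <- min(nrow(dem$z), hi[1, "row"], na.rm = TRUE)
  c0 <- max(1L, lo[1, "col"], na.rm = TRUE)
  c1 <- min(ncol(dem$z), hi[1, "col"], na.rm = TRUE)
  if (is.na(r0) || is.na(r1) || r0 > r1 || c0 > c1)
    return(cbind(row = integer(0), col = integer(0)))
  cells <- expand.grid(row = r0:r1, col = c0:c1)
  xy <- cell_xy(dem, cells$row, cells$col)
  keep <- point_in_polygon(xy[, 1], xy[, 2], ring)
  cbind(row = as.integer(cells$row[keep]), col = as.integer(cells$col[keep]))
}

#' Rasterise polyline segments onto a grid
#'
#' Samples each segment at half-cell steps and collects the traversed cells.
#'
#' @param dem a [dem_grid()].
#' @param segments data frame with columns `x0`, `y0`, `x1`, `y1`.
#' @return Integer matrix with columns `row`, `col`, `segment` (row index
#'   into `segments`), de-duplicated per segment.
#' @export
rasterize_segments <- function(dem, segments) {
  out <- vector("list", nrow(segments))
  step <- dem$cellsize / 2
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    len <- sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2)
    n <- max(2L, ceiling(len / step) + 1L)
    t <- seq(0, 1, length.out = n)
    rc <- xy_cell(dem, s$x0 + t * (s$x1 - s$x0), s$y0 + t * (s$y1 - s$y0))
    rc <- rc[!is.na(rc[, 1]) & !is.na(rc[, 2]), , drop = FALSE]
    rc <- unique(rc)
    if (nrow(rc) > 0)
      out[[i]] <- cbind(rc, segment = i)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) cbind(row = integer(0), col = integer(0), segment = integer(0))
  else res
}

# Derive a reproducible child seed (< 2^31) from a master seed and a label.
child_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1009
  as.integer((as.numeric(seed) * 1013 + h * 7919) %% .Machine$integer.max)
}
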