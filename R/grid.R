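#' Gridded raster containers
#'
#' `grid()` wraps a numeric matrix as a single-band raster with explicit
#' validity, `categorical_grid()` wraps an integer code matrix plus a class
#' table, and `grid_stack()` bundles co-registered grids. Row 1 is the
#' northernmost row; a cell value refers to the cell center. Geometry follows
#' the ESRI ASCII grid convention: `xll`/`yll` are the coordinates of the
#' lower-left corner of the grid and `cellsize` is the (square) cell edge
#' length in map units.
#'
#' Invalid (nodata) cells are carried as an explicit logical mask and are
#' excluded from every statistic downstream; the nodata sentinel is only used
#' at the file boundary.
#'
#' @param values Numeric matrix, row 1 = north.
#' @param valid Logical matrix of the same shape; defaults to `is.finite(values)`.
#' @param xll,yll Map coordinates of the lower-left grid corner.
#' @param cellsize Cell edge length (> 0).
#' @param crs Free-text CRS label used only for co-registration checks.
#' @param nodata Sentinel written to files for invalid cells.
#' @return An object of class `"siterep_grid"`.
#' @export
grid <- function(values, valid = NULL, xll = 0, yll = 0, cellsize = 1,
                 crs = "", nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(valid)) valid <- is.finite(values)
  valid <- as.matrix(valid)
  if (!identical(dim(values), dim(valid)))
    stop("values and valid must have identical shape")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("cellsize must be strictly positive")
  if (any(!is.finite(values[valid])))
    stop("non-finite value on a valid cell")
  structure(
    list(values = values, valid = valid, xll = xll, yll = yll,
         cellsize = cellsize, crs = crs, nodata = nodata),
    class = "siterep_grid"
  )
}

#' @rdname grid
#' @param codes Integer matrix of small non-negative class codes.
#' @param class_table Named character vector mapping code (as name) to class
#'   name; every code present in `codes` must appear.
#' @export
categorical_grid <- function(codes, class_table, valid = NULL, xll = 0, yll = 0,
                             cellsize = 1, crs = "", nodata = 255) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(valid)) valid <- !is.na(codes)
  valid <- as.matrix(valid)
  if (!identical(dim(codes), dim(valid)))
    stop("codes and valid must have identical shape")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("cellsize must be strictly positive")
  present <- sort(unique(codes[valid]))
  if (any(present < 0L)) stop("class codes must be non-negative")
  missing <- setdiff(as.character(present), names(class_table))
  if (length(missing) > 0L)
    stop("codes present but absent from class_table: ",
         paste(missing, collapse = ", "))
  structure(
    list(codes = codes, class_table = class_table, valid = valid,
         xll = xll, yll = yll, cellsize = cellsize, crs = crs,
         nodata = nodata),
    class = c("siterep_categorical_grid", "siterep_grid")
  )
}

#' @rdname grid
#' @param layers List of `siterep_grid` objects sharing one geometry.
#' @param names Layer names; defaults to names of `layers` or `layer_1`, ...
#' @export
grid_stack <- function(layers, names = NULL) {
  if (length(layers) < 1L) stop("a grid stack needs at least one layer")
  if (is.null(names)) {
    names <- base::names(layers)
    if (is.null(names)) names <- paste0("layer_", seq_along(layers))
  }
  stopifnot(length(names) == length(layers))
  st <- structure(list(layers = layers, names = names),
                  class = "siterep_grid_stack")
  if (length(layers) > 1L)
    assert_coregistered(st)
  st
}

n_layers <- function(stack) length(stack$layers)

grid_dim <- function(g) dim(if (is_categorical(g)) g$codes else g$values)

is_categorical <- function(g) inherits(g, "siterep_categorical_grid")

#' Joint validity mask of a stack
#'
#' Logical AND of the per-layer validity masks: a cell enters downstream
#' statistics only if every layer is valid there (the strictest nodata rule).
#'
#' @param stack A `siterep_grid_stack`.
#' @return Logical matrix.
#' @export
joint_valid <- function(stack) {
  Reduce(`&`, lapply(stack$layers, function(g) g$valid))
}

# matrix (n_cells x n_layers) of layer values at the given cell indices
# (column-major indices into the grid matrices)
values_matrix <- function(stack, cells) {
  vapply(stack$layers, function(g) g$values[cells],
         numeric(length(cells)))
}

#' Check that grids share one geometry
#'
#' Passes silently iff all grids agree on shape, transform (xll, yll,
#' cellsize; relative tolerance 1e-9) and CRS label; otherwise stops naming
#' the offending pair and the differing field.
#'
#' @param stack A `siterep_grid_stack` (its layers are checked pairwise
#'   against the first layer).
#' @param others Optional list of additional `siterep_grid` /
#'   `siterep_categorical_grid` objects checked against the stack.
#' @return Invisibly `TRUE`.
#' @export
assert_coregistered <- function(stack, others = list()) {
  gs <- stack$layers
  nms <- stack$names
  if (length(others) > 0L) {
    onms <- names(others)
    if (is.null(onms)) onms <- paste0("other_", seq_along(others))
    gs <- c(gs, others)
    nms <- c(nms, onms)
  }
  if (length(gs) < 1L) stop("at least one layer required")
  ref <- gs[[1L]]
  rdim <- grid_dim(ref)
  rtol <- 1e-9
  near <- function(a, b) {
    s <- max(abs(a), abs(b), 1)
    abs(a - b) <= rtol * s
  }
  for (i in seq_along(gs)[-1L]) {
    g <- gs[[i]]
    pair <- sprintf("'%s' vs '%s'", nms[1L], nms[i])
    if (!identical(rdim, grid_dim(g)))
      stop("co-registration failure (", pair, "): shape differs (",
           paste(rdim, collapse = "x"), " vs ",
           paste(grid_dim(g), collapse = "x"), ")")
    if (!near(ref$xll, g$xll) || !near(ref$yll, g$yll) ||
        !near(ref$cellsize, g$cellsize))
      stop("co-registration failure (", pair, "): transform differs")
    if (!identical(ref$crs, g$crs))
      stop("co-registration failure (", pair, "): crs differs")
  }
  invisible(TRUE)
}

#' Map coordinates of cell centers
#'
#' @param g A grid.
#' @param row,col Cell indices (1-based, row 1 = north).
#' @return List with vectors `x`, `y`.
#' @export
cell_center <- function(g, row, col) {
  nr <- grid_dim(g)[1L]
  list(x = g$xll + (col - 0.5) * g$cellsize,
       y = g$yll + (nr - row + 0.5) * g$cellsize)
}

#' Locate points on the grid
#'
#' Half-open cell membership: a point on a shared edge belongs to the cell to
#' its east/south, i.e. the west and north edges of a cell are inclusive.
#' Points outside the grid get `NA` indices.
#'
#' @param g A grid.
#' @param x,y Map coordinates.
#' @return List with integer vectors `row`, `col` (`NA` outside the extent).
#' @export
point_to_cell <- function(g, x, y) {
  d <- grid_dim(g)
  ytop <- g$yll + d[1L] * g$cellsize
  col <- floor((x - g$xll) / g$cellsize) + 1
  row <- floor((ytop - y) / g$cellsize) + 1
  bad <- row < 1 | row > d[1L] | col < 1 | col > d[2L]
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Dominant-type (modal) resampling of a categorical grid
#'
#' Aggregates `factor` x `factor` blocks of fine cells into one coarse cell
#' carrying the most frequent code in the block. Ties are broken toward the
#' lowest code, deterministically. Trailing rows/columns that do not fill a
#' complete block are dropped with a warning. Blocks containing any invalid
#' fine cell stay valid as long as at least one fine cell is valid; the mode
#' is taken over valid cells only.
#'
#' @param fine A `siterep_categorical_grid`.
#' @param factor Positive integer aggregation factor.
#' @return A `siterep_categorical_grid` at the coarser resolution.
#' @export
dominant_type_resample <- function(fine, factor) {
  if (!is_categorical(fine)) stop("fine must be a categorical grid")
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  d <- grid_dim(fine)
  nr2 <- d[1L] %/% factor
  nc2 <- d[2L] %/% factor
  if (nr2 < 1L || nc2 < 1L) stop("factor larger than grid")
  if (nr2 * factor != d[1L] || nc2 * factor != d[2L])
    warning(sprintf("dropping trailing partial blocks: %d row(s), %d col(s)",
                    d[1L] - nr2 * factor, d[2L] - nc2 * factor))
  rows <- seq_len(nr2 * factor)
  cols <- seq_len(nc2 * factor)
  codes <- fine$codes[rows, cols, drop = FALSE]
  valid <- fine$valid[rows, cols, drop = FALSE]
  # aggregation matrices: block sums via crossproducts
  Ra <- matrix(0, nr2 * factor, nr2)
  Ra[cbind(seq_len(nr2 * factor), rep(seq_len(nr2), each = factor))] <- 1
  Ca <- matrix(0, nc2 * factor, nc2)
  Ca[cbind(seq_len(nc2 * factor), rep(seq_len(nc2), each = factor))] <- 1
  lvls <- sort(unique(codes[valid]))
  counts <- lapply(lvls, function(cd) {
    ind <- (codes == cd) & valid
    t(Ra) %*% ind %*% Ca
  })
  nvalid <- t(Ra) %*% valid %*% Ca
  out <- matrix(lvls[1L], nr2, nc2)
  if (length(lvls) > 0L) {
    best <- counts[[1L]]
    for (i in seq_along(lvls)[-1L]) {
      take <- counts[[i]] > best          # strict: ties keep the lower code
      out[take] <- lvls[i]
      best[take] <- counts[[i]][take]
    }
  }
  vout <- nvalid > 0
  out[!vout] <- NA_integer_
  # the coarse grid keeps the fine grid's lower-left origin; dropped trailing
  # rows shift the effective yll upward by the dropped height
  yll2 <- fine$yll + (d[1L] - nr2 * factor) * fine$cellsize
  categorical_grid(out, fine$class_table, valid = vout,
                   xll = fine$xll, yll = yll2,
                   cellsize = fine$cellsize * factor, crs = fine$crs,
                   nodata = fine$nodata)
}

#' @export
print.siterep_grid <- function(x, ...) {
  d <- grid_dim(x)
  kind <- if (is_categorical(x)) "categorical grid" else "grid"
  cat(sprintf("siterep %s: %d x %d cells, cellsize %g, %d valid\n",
              kind, d[1L], d[2L], x$cellsize, sum(x$valid)))
  if (is_categorical(x)) {
    tb <- table(factor(x$codes[x$valid], levels = names(x$class_table),
                       labels = x$class_table))
    print(tb)
  } else {
    v <- x$values[x$valid]
    if (length(v))
      cat(sprintf("  values: [%.4g, %.4g], mean %.4g\n",
                  min(v), max(v), mean(v)))
  }
  invisible(x)
}

#' @export
print.siterep_grid_stack <- function(x, ...) {
  d <- grid_dim(x$layers[[1L]])
  cat(sprintf("siterep grid stack: %d layer(s), %d x %d cells\n",
              n_layers(x), d[1L], d[2L]))
  cat("  layers:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Display a grid with image()
#'
#' @param x Grid to display.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly `x`.
#' @export
plot.siterep_grid <- function(x, main = NULL, ...) {
  vals <- if (is_categorical(x)) x$codes else x$values
  vals[!x$valid] <- NA
  d <- dim(vals)
  # image() draws column-major from bottom-left; transpose and flip rows so
  # row 1 renders at the top (north)
  z <- t(vals[rev(seq_len(d[1L])), , drop = FALSE])
  xs <- x$xll + (seq_len(d[2L]) - 0.5) * x$cellsize
  ys <- x$yll + (seq_len(d[1L]) - 0.5) * x$cellsize
  graphics::image(xs, ys, z, asp = 1, xlab = "x", ylab = "y",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}
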