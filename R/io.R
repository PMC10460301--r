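#' Read a single-band raster from the portable ASCII grid dialect
#'
#' The on-disk format is the 6-line ESRI ASCII grid header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`) followed by rows of
#' whitespace-separated values, north row first. Cells equal to the nodata
#' sentinel are marked invalid. Values are written with 17 significant digits
#' so that a write/read round trip reproduces doubles bit-exactly.
#'
#' @param path Path to a `.asc` / text grid file.
#' @param categorical If `TRUE`, return a [categorical_grid()]; `class_table`
#'   must then be supplied (or a `<path>.classes.yaml` sidecar must exist).
#' @param class_table Named character vector mapping code to class name.
#' @return A `siterep_grid` or `siterep_categorical_grid`.
#' @export
read_grid <- function(path, categorical = FALSE, class_table = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("GeoTIFF input is not supported; supply the ASCII grid dialect")
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]", tok[1L])) {
      hdr[[tolower(tok[1L])]] <- as.numeric(tok[2L])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed grid header in ", path, ": need ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc,
                 length(vals), path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  valid <- !(m == nodata) & !is.na(m)
  bad <- which(valid & !is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite value at cell (%d, %d) in %s",
                 bad[1L, 1L], bad[1L, 2L], path))
  if (categorical) {
    if (is.null(class_table)) {
      side <- paste0(path, ".classes.yaml")
      if (!file.exists(side))
        stop("categorical read needs class_table or sidecar ", side)
      class_table <- read_class_table(side)
    }
    mi <- m
    mi[!valid] <- NA
    categorical_grid(mi, class_table, valid = valid, xll = hdr$xllcorner,
                     yll = hdr$yllcorner, cellsize = hdr$cellsize,
                     nodata = nodata)
  } else {
    m[!valid] <- NA_real_
    grid(m, valid = valid, xll = hdr$xllcorner, yll = hdr$yllcorner,
         cellsize = hdr$cellsize, nodata = nodata)
  }
}

#' Write a grid to the portable ASCII grid dialect
#'
#' @param g A `siterep_grid` or `siterep_categorical_grid`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_grid <- function(g, path) {
  d <- grid_dim(g)
  vals <- if (is_categorical(g)) g$codes else g$values
  out <- vals
  out[!g$valid] <- g$nodata
  fmt <- function(x) {
    s <- formatC(x, digits = 17, format = "g")
    gsub(" ", "", s)
  }
  hdr <- c(
    paste("ncols", d[2L]),
    paste("nrows", d[1L]),
    paste("xllcorner", fmt(g$xll)),
    paste("yllcorner", fmt(g$yll)),
    paste("cellsize", fmt(g$cellsize)),
    paste("nodata_value", fmt(g$nodata))
  )
  body <- apply(out, 1L, function(r) paste(fmt(r), collapse = " "))
  writeLines(c(hdr, body), path)
  if (is_categorical(g))
    write_class_table(g$class_table, paste0(path, ".classes.yaml"))
  invisible(path)
}

#' Read/write a class table (code to class name) as YAML
#'
#' @param path YAML file path.
#' @return Named character vector (names are code strings).
#' @export
read_class_table <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- vapply(raw, as.character, character(1L))
  names(out) <- names(raw)
  out
}

#' @rdname read_class_table
#' @param class_table Named character vector.
#' @export
write_class_table <- function(class_table, path) {
  yaml::write_yaml(as.list(class_table), path)
  invisible(path)
}

#' Read site features from GeoJSON
#'
#' Accepts a FeatureCollection of Point, Polygon or MultiPolygon features,
#' each carrying a `site` property and optionally `centroid_id`. The parsed
#' feature list is the input to [polygons_to_centroids()].
#'
#' @param path GeoJSON file.
#' @return List of features (class `"siterep_features"`).
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$features)) stop("not a GeoJSON FeatureCollection: ", path)
  structure(js$features, class = "siterep_features")
}

#' Write a site network as GeoJSON points
#'
#' @param net A `siterep_network`.
#' @param path Output path.
#' @export
write_network <- function(net, path) {
  cen <- net$centroids
  feats <- lapply(seq_len(nrow(cen)), function(i) {
    list(type = "Feature",
         properties = list(site = cen$site[i],
                           centroid_id = cen$centroid_id[i]),
         geometry = list(type = "Point",
                         coordinates = c(cen$x[i], cen$y[i])))
  })
  fc <- list(type = "FeatureCollection", name = net$name, features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
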