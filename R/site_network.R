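#' Construct a site network
#'
#' A network is a named collection of sites, each holding one or more
#' experimental centroids. Per-centroid values are kept (rather than site
#' means) so that the within-site environmental diversity enters the
#' analysis. After [sample_centroids()] each centroid additionally carries
#' its containing grid cell and its feature-space (PC) vector.
#'
#' @param centroids Data frame with columns `site`, `centroid_id`, `x`, `y`
#'   and optionally `row`, `col`.
#' @param name Network name.
#' @param pc Optional numeric matrix (one row per centroid) of sampled PC
#'   values.
#' @return Object of class `"siterep_network"`.
#' @export
site_network <- function(centroids, name = "network", pc = NULL) {
  need <- c("site", "centroid_id", "x", "y")
  if (!all(need %in% names(centroids)))
    stop("centroids must have columns ", paste(need, collapse = ", "))
  if (nrow(centroids) < 1L) stop("empty network")
  if (anyNA(centroids$site)) stop("centroid with missing site")
  if (anyDuplicated(centroids$centroid_id))
    stop("duplicate centroid_id")
  if (!is.null(pc)) {
    pc <- as.matrix(pc)
    stopifnot(nrow(pc) == nrow(centroids))
  }
  rownames(centroids) <- NULL
  structure(list(name = name, centroids = centroids, pc = pc),
            class = "siterep_network")
}

#' @export
print.siterep_network <- function(x, ...) {
  cat(sprintf("siterep network '%s': %d site(s), %d centroid(s)%s\n",
              x$name, length(unique(x$centroids$site)),
              nrow(x$centroids),
              if (is.null(x$pc)) " (unsampled)" else
                sprintf(", sampled in %d PC dims", ncol(x$pc))))
  invisible(x)
}

#' Sites of a network, in order of first appearance
#' @param net A `siterep_network`.
#' @export
network_sites <- function(net) unique(net$centroids$site)

# signed shoelace area and area-weighted centroid of one linear ring
ring_centroid <- function(ring) {
  xy <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
  n <- nrow(xy)
  if (n < 3L) return(list(area = 0, cx = NA_real_, cy = NA_real_))
  # close the ring if needed
  if (any(xy[1L, ] != xy[n, ])) xy <- rbind(xy, xy[1L, ])
  x <- xy[, 1L]; y <- xy[, 2L]
  i <- seq_len(nrow(xy) - 1L)
  cr <- x[i] * y[i + 1L] - x[i + 1L] * y[i]
  a <- sum(cr) / 2
  if (a == 0) return(list(area = 0, cx = NA_real_, cy = NA_real_))
  list(area = a,
       cx = sum((x[i] + x[i + 1L]) * cr) / (6 * a),
       cy = sum((y[i] + y[i + 1L]) * cr) / (6 * a))
}

# area-weighted centroid across rings/polygons (holes carry negative signed
# area when rings follow the GeoJSON winding convention)
geometry_centroid <- function(geom) {
  type <- geom$type
  if (identical(type, "Point")) {
    return(c(geom$coordinates[[1L]], geom$coordinates[[2L]]))
  }
  rings <- switch(type,
    "Polygon" = geom$coordinates,
    "MultiPolygon" = do.call(c, geom$coordinates),
    stop("unsupported geometry type: ", type)
  )
  if (length(rings) == 0L) stop("empty geometry")
  parts <- lapply(rings, ring_centroid)
  A <- sum(vapply(parts, `[[`, numeric(1L), "area"))
  if (!is.finite(A) || A == 0) stop("empty geometry (zero area)")
  cx <- sum(vapply(parts, function(p) p$area * p$cx, numeric(1L))) / A
  cy <- sum(vapply(parts, function(p) p$area * p$cy, numeric(1L))) / A
  c(cx, cy)
}

#' Reduce vector features to site centroids
#'
#' Polygon features are replaced by their area-weighted geometric centroid
#' (which may fall outside the polygon); point features pass through
#' unchanged. A missing `centroid_id` is assigned deterministically as the
#' site name plus the feature's ordinal within its site, in file order.
#'
#' @param features A `siterep_features` list (see [read_network()]) or any
#'   list of GeoJSON-style features.
#' @param name Network name.
#' @return A `siterep_network` (unsampled).
#' @export
polygons_to_centroids <- function(features, name = "network") {
  if (length(features) == 0L) stop("no features")
  site <- character(length(features))
  cid <- character(length(features))
  x <- numeric(length(features))
  y <- numeric(length(features))
  counter <- new.env(parent = emptyenv())
  for (i in seq_along(features)) {
    f <- features[[i]]
    s <- f$properties$site
    if (is.null(s) || is.na(s) || !nzchar(s))
      stop("feature ", i, " has no 'site' property")
    site[i] <- s
    if (is.null(f$geometry)) stop("feature ", i, " has empty geometry")
    p <- geometry_centroid(f$geometry)
    x[i] <- p[1L]; y[i] <- p[2L]
    given <- f$properties$centroid_id
    if (!is.null(given) && !is.na(given) && nzchar(as.character(given))) {
      cid[i] <- as.character(given)
    } else {
      k <- (get0(s, envir = counter, ifnotfound = 0L)) + 1L
      assign(s, k, envir = counter)
      cid[i] <- sprintf("%s_%03d", s, k)
    }
  }
  site_network(data.frame(site = site, centroid_id = cid, x = x, y = y,
                          stringsAsFactors = FALSE), name = name)
}

#' Sample feature-space values at centroid cells
#'
#' Each centroid is intersected with the score grid; its cell indices and the
#' cell's PC score vector are attached. Centroids sharing a cell get
#' identical PC values. Centroids outside the grid extent are a hard error
#' (they indicate mis-registration); centroids on invalid (nodata) cells are
#' dropped with a warning reporting the count. Sampling is idempotent.
#'
#' @param net A `siterep_network`.
#' @param fs A fitted [fit_pca()] feature space.
#' @return The network with `row`, `col` and `pc` filled in.
#' @export
sample_centroids <- function(net, fs) {
  stopifnot(inherits(fs, "siterep_feature_space"))
  ref <- fs$scores$layers[[1L]]
  cen <- net$centroids
  rc <- point_to_cell(ref, cen$x, cen$y)
  outside <- is.na(rc$row)
  if (any(outside))
    stop("centroid(s) outside grid extent: ",
         paste(cen$centroid_id[outside], collapse = ", "))
  jv <- joint_valid(fs$scores)
  idx <- cbind(rc$row, rc$col)
  on_invalid <- !jv[idx]
  if (any(on_invalid)) {
    warning(sprintf("dropping %d centroid(s) on invalid cells", sum(on_invalid)))
    keep <- !on_invalid
    cen <- cen[keep, , drop = FALSE]
    rc$row <- rc$row[keep]; rc$col <- rc$col[keep]
    idx <- idx[keep, , drop = FALSE]
    if (nrow(cen) == 0L) stop("all centroids fell on invalid cells")
  }
  cells <- (idx[, 2L] - 1L) * nrow(jv) + idx[, 1L]
  pc <- values_matrix(fs$scores, cells)
  pc <- matrix(pc, nrow = length(cells),
               dimnames = list(NULL, fs$scores$names))
  cen$row <- rc$row
  cen$col <- rc$col
  site_network(cen, name = net$name, pc = pc)
}
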