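#' Normalization constant for representativeness
#'
#' Representativeness is one minus a normalized Euclidean distance in the
#' selected PC space; this chooses the divisor. The default,
#' `"bbox_diameter"`, is the Euclidean length of the per-component
#' (max - min) range vector over valid cells. It is independent of the site
#' set, which guarantees both the \[0, 1\] bound and monotonicity of network
#' representativeness as sites are added, and makes values comparable across
#' networks. `"observed_max"` is the exact maximum (centroid, cell) distance
#' for a given network (two-pass; provided for fidelity experiments).
#'
#' @param fs A fitted feature space (scores present, >= 2 valid cells).
#' @param method `"bbox_diameter"` (default) or `"observed_max"`.
#' @param net Sampled network; required for `"observed_max"`.
#' @return Object of class `"siterep_norm"` with `value` and `method`.
#' @export
normalization_constant <- function(fs,
                                   method = c("bbox_diameter", "observed_max"),
                                   net = NULL) {
  method <- match.arg(method)
  sm <- score_matrix(fs)
  if (nrow(sm$S) < 2L) stop("need at least two valid cells")
  if (method == "bbox_diameter") {
    rng <- apply(sm$S, 2L, function(v) max(v) - min(v))
    value <- sqrt(sum(rng^2))
  } else {
    if (is.null(net) || is.null(net$pc))
      stop("observed_max requires a sampled network")
    if (ncol(net$pc) != ncol(sm$S))
      stop("dimension mismatch between centroid pc values and scores")
    value <- 0
    for (i in seq_len(nrow(net$pc))) {
      d2 <- dist2_to_point(sm$S, net$pc[i, ])
      value <- max(value, sqrt(max(d2)))
    }
  }
  if (!is.finite(value) || value <= 0)
    stop("representativeness undefined: all cells identical in PC space")
  structure(list(value = value, method = method), class = "siterep_norm")
}

# squared Euclidean distance from every row of S to point v, accumulated
# component-wise so results are independent of how cells are partitioned
dist2_to_point <- function(S, v) {
  d2 <- 0
  for (j in seq_len(ncol(S)))
    d2 <- d2 + (S[, j] - v[j])^2
  d2
}

#' Representativeness map of a single centroid
#'
#' Per valid cell, `r = 1 - d / norm$value` where `d` is the Euclidean
#' distance between the centroid's PC vector and the cell's PC score vector.
#' Values are clipped to \[0, 1\]; with the bounding-box divisor the clip can
#' only trigger at floating-point edges, and any clipping is reported via a
#' message. Invalid cells stay invalid.
#'
#' @param pc Numeric vector: the centroid's sampled PC values (length equals
#'   the number of selected components).
#' @param fs A fitted feature space.
#' @param norm A [normalization_constant()].
#' @return A `siterep_grid` in \[0, 1\].
#' @export
centroid_representativeness <- function(pc, fs, norm) {
  stopifnot(inherits(norm, "siterep_norm"))
  sm <- score_matrix(fs)
  if (length(pc) != ncol(sm$S))
    stop("dimension mismatch: centroid has ", length(pc),
         " pc values, scores have ", ncol(sm$S), " components")
  r <- 1 - sqrt(dist2_to_point(sm$S, as.numeric(pc))) / norm$value
  nclip <- sum(r < 0 | r > 1)
  if (nclip > 0L)
    message("clipped ", nclip, " cell(s) to [0, 1]")
  r <- pmin(1, pmax(0, r))
  m <- matrix(NA_real_, nrow(sm$valid), ncol(sm$valid))
  m[sm$cells] <- r
  template <- fs$scores$layers[[1L]]
  grid(m, valid = sm$valid, xll = template$xll, yll = template$yll,
       cellsize = template$cellsize, crs = template$crs)
}

#' Site and network representativeness layers
#'
#' Computes every (centroid, cell) representativeness and aggregates: the
#' per-site layer is the cellwise max (default), mean, or sum over that
#' site's centroid maps; the network layer is always the cellwise max over
#' all centroid maps of the network, so every cell reports how well its
#' single best centroid matches it. With `"sum"`, per-site values may exceed
#' 1 and a warning is raised.
#'
#' Cells are processed in blocks of `tile` raster rows under a bounded-memory
#' contract; because every cell is handled independently with the same
#' accumulation order, results are identical for any tile size.
#'
#' @param net A sampled `siterep_network`.
#' @param fs A fitted feature space.
#' @param norm A [normalization_constant()].
#' @param aggregation `"max"` (default), `"mean"` or `"sum"`.
#' @param tile Number of raster rows per processing block (`NULL` = whole
#'   grid at once).
#' @return Object of class `"siterep_representativeness"` with `per_site`
#'   (named list of grids), `network` (grid), `norm`, `aggregation`.
#' @export
site_representativeness <- function(net, fs, norm,
                                    aggregation = c("max", "mean", "sum"),
                                    tile = NULL) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(norm, "siterep_norm"))
  if (is.null(net$pc)) stop("network is not sampled; run sample_centroids()")
  if (nrow(net$centroids) == 0L) stop("empty network")
  sm <- score_matrix(fs)
  if (ncol(net$pc) != ncol(sm$S))
    stop("dimension mismatch between centroid pc values and scores")
  sites <- network_sites(net)
  site_of <- match(net$centroids$site, sites)
  n <- nrow(sm$S)
  acc <- matrix(if (aggregation == "max") -Inf else 0, n, length(sites))
  netmax <- rep(-Inf, n)
  cell_rows <- ((sm$cells - 1L) %% nrow(sm$valid)) + 1L
  blocks <- if (is.null(tile)) list(seq_len(n)) else {
    grp <- (cell_rows - 1L) %/% as.integer(tile)
    split(seq_len(n), grp)
  }
  nclip <- 0L
  for (blk in blocks) {
    Sb <- sm$S[blk, , drop = FALSE]
    for (i in seq_len(nrow(net$pc))) {
      r <- 1 - sqrt(dist2_to_point(Sb, net$pc[i, ])) / norm$value
      nclip <- nclip + sum(r < 0 | r > 1)
      r <- pmin(1, pmax(0, r))
      s <- site_of[i]
      if (aggregation == "max") {
        acc[blk, s] <- pmax(acc[blk, s], r)
      } else {
        acc[blk, s] <- acc[blk, s] + r
      }
      netmax[blk] <- pmax(netmax[blk], r)
    }
  }
  if (aggregation == "mean") {
    counts <- tabulate(site_of, nbins = length(sites))
    acc <- sweep(acc, 2L, counts, `/`)
  }
  if (aggregation == "sum" && any(acc > 1))
    warning("aggregation 'sum': per-site values exceed 1; not a normalized representativeness")
  if (nclip > 0L) message("clipped ", nclip, " value(s) to [0, 1]")
  template <- fs$scores$layers[[1L]]
  as_grid <- function(v) {
    m <- matrix(NA_real_, nrow(sm$valid), ncol(sm$valid))
    m[sm$cells] <- v
    grid(m, valid = sm$valid, xll = template$xll, yll = template$yll,
         cellsize = template$cellsize, crs = template$crs)
  }
  per_site <- lapply(seq_along(sites), function(s) as_grid(acc[, s]))
  names(per_site) <- sites
  structure(list(per_site = per_site, network = as_grid(netmax),
                 norm = norm, aggregation = aggregation, sites = sites,
                 network_name = net$name),
            class = "siterep_representativeness")
}

#' @export
print.siterep_representativeness <- function(x, ...) {
  v <- x$network$values[x$network$valid]
  cat(sprintf(
    "siterep representativeness ('%s', %d site(s), agg = %s, norm = %s %.4g)\n",
    x$network_name, length(x$sites), x$aggregation, x$norm$method,
    x$norm$value))
  cat(sprintf("  network layer: mean %.3f, median %.3f, min %.3f\n",
              mean(v), stats::median(v), min(v)))
  invisible(x)
}
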