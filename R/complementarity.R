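#' Restrict a network to centroids on eligible mask classes
#'
#' Used before cross-network comparison so that sister networks only
#' contribute sites located on the land classes under study. Filtering uses
#' the mask class at each centroid's cell.
#'
#' @param net A `siterep_network` (sampled or not, with `row`/`col` set or
#'   resolvable from a reference grid).
#' @param mask A `siterep_categorical_grid`.
#' @param classes Eligible class names.
#' @return The filtered network, or `NULL` if no centroid survives.
#' @export
filter_network_by_class <- function(net, mask,
                                    classes = c("cropland", "grazingland",
                                                "mixed")) {
  cen <- net$centroids
  if (is.null(cen$row) || anyNA(cen$row)) {
    rc <- point_to_cell(mask, cen$x, cen$y)
    cen$row <- rc$row; cen$col <- rc$col
  }
  codes <- mask$codes[cbind(cen$row, cen$col)]
  keep <- !is.na(codes) &
    unname(mask$class_table[as.character(codes)]) %in% classes
  if (!any(keep)) return(NULL)
  site_network(cen[keep, , drop = FALSE], name = net$name,
               pc = if (is.null(net$pc)) NULL else
                 net$pc[keep, , drop = FALSE])
}

#' Best-network map and cross-network complementarity
#'
#' Given a home network and one or more sister networks sampled on the same
#' feature space, computes for every cell which network's best centroid
#' represents it best, how the home network alone performs (`home_rep`), how
#' the pooled union of all centroids performs (`combined_rep`), and the
#' non-negative `improvement = combined_rep - home_rep` that borrowing
#' sister sites would bring. One shared normalization constant makes the
#' values commensurable across networks; ties resolve to the home network
#' first, then to list order.
#'
#' @param networks List of sampled `siterep_network`s; the first is the home
#'   network.
#' @param fs A fitted feature space.
#' @param norm A shared [normalization_constant()] (bbox method recommended:
#'   site-set independent).
#' @param mask Optional categorical grid: sister networks are first
#'   restricted to centroids on `classes` cells.
#' @param classes Eligible classes for sister sites.
#' @return Object of class `"siterep_multi_network"`: `best_network`
#'   (categorical grid of network codes), `home_rep`, `combined_rep`,
#'   `improvement` (grids), `borrowed_sites` (data frame).
#' @export
best_network_map <- function(networks, fs, norm, mask = NULL,
                             classes = c("cropland", "grazingland", "mixed")) {
  if (length(networks) < 2L) stop("need at least two networks")
  nms <- vapply(networks, function(n) n$name, character(1L))
  if (anyDuplicated(nms)) nms <- make.unique(nms)
  if (!is.null(mask)) {
    for (i in seq_along(networks)[-1L]) {
      f <- filter_network_by_class(networks[[i]], mask, classes)
      if (is.null(f)) {
        warning("sister network '", nms[i],
                "' has no centroid on eligible classes; dropped")
      }
      networks[[i]] <- f
    }
    keep <- !vapply(networks, is.null, logical(1L))
    networks <- networks[keep]
    nms <- nms[keep]
    if (length(networks) < 2L)
      stop("fewer than two networks remain after class filtering")
  }
  reps <- lapply(networks, site_representativeness, fs = fs, norm = norm,
                 aggregation = "max")
  sm <- score_matrix(fs)
  cells <- sm$cells
  NW <- vapply(reps, function(r) r$network$values[cells],
               numeric(length(cells)))
  NW <- matrix(NW, nrow = length(cells))
  # argmax with home-first tie preference: max.col("first") scans left to
  # right, so with the home network in column 1 ties resolve to home, then
  # to list order
  best <- max.col(NW, ties.method = "first")
  home <- NW[, 1L]
  combined <- do.call(pmax, lapply(seq_len(ncol(NW)), function(j) NW[, j]))
  improvement <- combined - home
  template <- fs$scores$layers[[1L]]
  as_grid <- function(v) {
    m <- matrix(NA_real_, nrow(sm$valid), ncol(sm$valid))
    m[cells] <- v
    grid(m, valid = sm$valid, xll = template$xll, yll = template$yll,
         cellsize = template$cellsize, crs = template$crs)
  }
  codes <- matrix(NA_integer_, nrow(sm$valid), ncol(sm$valid))
  codes[cells] <- best
  best_grid <- categorical_grid(
    codes, stats::setNames(nms, as.character(seq_along(nms))),
    valid = sm$valid, xll = template$xll, yll = template$yll,
    cellsize = template$cellsize, crs = template$crs)
  # which sister site wins where borrowing helps
  gain_cells <- which(improvement > 0)
  borrowed <- NULL
  if (length(gain_cells) > 0L) {
    rows <- list()
    for (j in seq_along(networks)[-1L]) {
      ps <- reps[[j]]$per_site
      for (s in names(ps)) {
        v <- ps[[s]]$values[cells][gain_cells]
        wins <- v >= combined[gain_cells] - 1e-15
        if (any(wins))
          rows[[length(rows) + 1L]] <- data.frame(
            network = nms[j], site = s, cells_winning = sum(wins),
            mean_gain = mean(improvement[gain_cells][wins]),
            stringsAsFactors = FALSE)
      }
    }
    if (length(rows) > 0L) borrowed <- do.call(rbind, rows)
  }
  if (is.null(borrowed))
    borrowed <- data.frame(network = character(0), site = character(0),
                           cells_winning = integer(0),
                           mean_gain = numeric(0))
  structure(list(best_network = best_grid, home_rep = as_grid(home),
                 combined_rep = as_grid(combined),
                 improvement = as_grid(improvement),
                 borrowed_sites = borrowed, networks = nms),
            class = "siterep_multi_network")
}

#' Candidate locations for new sites: representativeness gaps
#'
#' Returns the `k` lowest-representativeness eligible cells, greedily spaced
#' so that no two candidates lie within `min_sep` cells of each other —
#' candidates mark distinct poorly-represented pockets rather than one deep
#' pocket. The scan order (ascending representativeness, then cell index) is
#' deterministic.
#'
#' @param rep A [site_representativeness()] result.
#' @param mask Optional categorical grid restricting eligibility.
#' @param k Number of candidates (>= 1).
#' @param classes Eligible classes when `mask` is given.
#' @param min_sep Minimum separation between candidates, in cells.
#' @return Data frame: row, col, x, y, representativeness.
#' @export
candidate_gaps <- function(rep, mask = NULL, k = 5L,
                           classes = c("cropland", "grazingland", "mixed"),
                           min_sep = 5) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  g <- rep$network
  sel <- g$valid
  if (!is.null(mask)) {
    eligible_codes <- as.integer(names(mask$class_table)[
      mask$class_table %in% classes])
    sel <- sel & mask$valid &
      matrix(mask$codes %in% eligible_codes, nrow(mask$codes))
  }
  cells <- which(sel)
  v <- g$values[cells]
  nr <- nrow(g$values)
  rows <- ((cells - 1L) %% nr) + 1L
  cols <- ((cells - 1L) %/% nr) + 1L
  ord <- order(v, cells)
  picked <- integer(0)
  for (i in ord) {
    if (length(picked) == 0L) {
      picked <- i
    } else {
      d2 <- (rows[i] - rows[picked])^2 + (cols[i] - cols[picked])^2
      if (min(d2) >= min_sep^2) picked <- c(picked, i)
    }
    if (length(picked) >= k) break
  }
  ctr <- cell_center(g, rows[picked], cols[picked])
  data.frame(row = rows[picked], col = cols[picked],
             x = ctr$x, y = ctr$y, representativeness = v[picked])
}

#' Add a site to a network at given cells
#'
#' Convenience for gap-filling experiments: appends a new single-site set of
#' centroids (at cell centers) to a sampled network and re-samples it.
#'
#' @param net A sampled `siterep_network`.
#' @param fs The feature space.
#' @param row,col Cell indices of the new site's centroids.
#' @param site Name for the new site.
#' @return The extended, sampled network.
#' @export
add_site <- function(net, fs, row, col, site = "NEW") {
  template <- fs$scores$layers[[1L]]
  ctr <- cell_center(template, row, col)
  add <- data.frame(site = site,
                    centroid_id = sprintf("%s_%03d", site, seq_along(row)),
                    x = ctr$x, y = ctr$y, row = row, col = col,
                    stringsAsFactors = FALSE)
  cen <- rbind(net$centroids[, c("site", "centroid_id", "x", "y", "row", "col")],
               add)
  sample_centroids(site_network(cen, name = net$name), fs)
}
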