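#' Assign every masked cell to its best-representing site
#'
#' The winner at a cell is the site with the highest per-site
#' representativeness there (exhaustive argmax; no spatial smoothing or
#' contiguity enforcement — any contiguity in the result emerges from the
#' spatial autocorrelation of the drivers). Ties are broken toward the
#' earlier-listed site, deterministically. A ranked top-`top_n` list of
#' sites is kept per cell.
#'
#' @param rep A [site_representativeness()] result (aggregation must keep
#'   per-site layers in \[0, 1\]).
#' @param mask A co-registered `siterep_categorical_grid`; required — the
#'   constituency of an unmasked landscape is not defined here.
#' @param classes Mask classes eligible for assignment; default all classes
#'   except `"non-working"`.
#' @param top_n Ranked sites kept per cell (default 3).
#' @return Object of class `"siterep_constituency"`: `winner` (categorical
#'   grid of site codes), `ranks` (data frame row, col, rank, site,
#'   representativeness), plus what the summary functions need.
#' @export
assign_constituency <- function(rep, mask, classes = NULL, top_n = 3L) {
  stopifnot(inherits(rep, "siterep_representativeness"))
  if (missing(mask) || is.null(mask))
    stop("constituency requires a mask; supply a categorical grid")
  if (!is_categorical(mask)) stop("mask must be a categorical grid")
  assert_coregistered(grid_stack(list(network = rep$network)),
                      list(mask = mask))
  if (is.null(classes))
    classes <- setdiff(unname(mask$class_table), "non-working")
  classes <- intersect(classes, unname(mask$class_table))
  if (length(classes) == 0L) stop("empty class selection")
  eligible_codes <- as.integer(names(mask$class_table)[
    mask$class_table %in% classes])
  sel <- rep$network$valid & mask$valid &
    matrix(mask$codes %in% eligible_codes, nrow(mask$codes))
  cells <- which(sel)
  if (length(cells) == 0L) stop("no eligible cells under the mask")
  sites <- rep$sites
  R <- vapply(rep$per_site, function(g) g$values[cells],
              numeric(length(cells)))
  R <- matrix(R, nrow = length(cells))
  win <- max.col(R, ties.method = "first")
  nr <- nrow(sel)
  rows <- ((cells - 1L) %% nr) + 1L
  cols <- ((cells - 1L) %/% nr) + 1L
  top_n <- min(as.integer(top_n), length(sites))
  ord <- apply(R, 1L, function(v) order(v, decreasing = TRUE)[seq_len(top_n)])
  ord <- matrix(ord, nrow = top_n)
  ranks <- data.frame(
    row = rep(rows, each = top_n),
    col = rep(cols, each = top_n),
    rank = rep(seq_len(top_n), times = length(cells)),
    site = sites[as.vector(ord)],
    representativeness = R[cbind(rep(seq_along(cells), each = top_n),
                                 as.vector(ord))],
    stringsAsFactors = FALSE
  )
  codes <- matrix(NA_integer_, nr, ncol(sel))
  codes[cells] <- win
  winner <- categorical_grid(
    codes, stats::setNames(sites, as.character(seq_along(sites))),
    valid = sel, xll = mask$xll, yll = mask$yll, cellsize = mask$cellsize,
    crs = mask$crs)
  structure(list(winner = winner, ranks = ranks, sites = sites,
                 cells = cells, win = win,
                 network_rep = rep$network$values[cells],
                 mask_class = unname(
                   mask$class_table[as.character(mask$codes[cells])]),
                 classes = classes),
            class = "siterep_constituency")
}

#' Constituency areas and representativeness distributions
#'
#' Per (site, mask class): cell count, area, and the distribution (mean,
#' median, p10, p90, min, max) of network representativeness over the
#' constituency. Sites with an empty constituency get a zero-area row with
#' `empty = TRUE`. Cell counts partition the masked valid area exactly.
#'
#' @param cr A [assign_constituency()] result.
#' @param cell_area_ha Area of one cell in hectares; default derived from
#'   the cell size assuming map units of meters (`cellsize^2 / 1e4`).
#' @return Data frame, one row per site x class (plus empty-site rows).
#' @export
constituency_areas <- function(cr, cell_area_ha = NULL) {
  stopifnot(inherits(cr, "siterep_constituency"))
  if (is.null(cell_area_ha))
    cell_area_ha <- cr$winner$cellsize^2 / 1e4
  site <- cr$sites[cr$win]
  df <- data.frame(site = site, class = cr$mask_class,
                   r = cr$network_rep, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(df, list(df$site, df$class), drop = TRUE),
    function(d) {
      q <- stats::quantile(d$r, c(0.1, 0.9), names = FALSE)
      data.frame(site = d$site[1L], class = d$class[1L],
                 n_cells = nrow(d), area_ha = nrow(d) * cell_area_ha,
                 mean = mean(d$r), median = stats::median(d$r),
                 p10 = q[1L], p90 = q[2L], min = min(d$r), max = max(d$r),
                 empty = FALSE, stringsAsFactors = FALSE)
    }))
  missing_sites <- setdiff(cr$sites, unique(site))
  if (length(missing_sites) > 0L)
    out <- rbind(out, data.frame(
      site = missing_sites, class = NA_character_, n_cells = 0L,
      area_ha = 0, mean = NA_real_, median = NA_real_, p10 = NA_real_,
      p90 = NA_real_, min = NA_real_, max = NA_real_, empty = TRUE,
      stringsAsFactors = FALSE))
  out <- out[order(match(out$site, cr$sites), out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Environmental gradient ranges sampled at each site
#'
#' Per site and principal component: min, p10, median, mean, p90 and max of
#' the centroid PC values — the spread of environmental conditions a site's
#' experimental centroids actually sample.
#'
#' @param net A sampled `siterep_network`.
#' @param fs The feature space the network was sampled on.
#' @return Data frame, one row per site x component.
#' @export
site_gradient_ranges <- function(net, fs) {
  if (is.null(net$pc)) stop("network is not sampled")
  sites <- network_sites(net)
  comps <- colnames(net$pc)
  if (is.null(comps)) comps <- paste0("PC", seq_len(ncol(net$pc)))
  out <- do.call(rbind, lapply(sites, function(s) {
    P <- net$pc[net$centroids$site == s, , drop = FALSE]
    do.call(rbind, lapply(seq_len(ncol(P)), function(j) {
      v <- P[, j]
      q <- stats::quantile(v, c(0.1, 0.9), names = FALSE)
      data.frame(site = s, component = comps[j], n_centroids = length(v),
                 min = min(v), p10 = q[1L], median = stats::median(v),
                 mean = mean(v), p90 = q[2L], max = max(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Generalist / specialist / double-duty site taxonomy
#'
#' An operationalization of a qualitative taxonomy: a *generalist* has a
#' large constituency (total area at or above the `area_quantile` across
#' sites) represented well (mean representativeness >= `rep_floor`); a
#' *specialist* has a smaller but still well-represented constituency; a
#' *double-duty* site is the best available representative for part of its
#' constituency yet fits it poorly (10th percentile of constituency
#' representativeness below `rep_floor - 0.2`). The thresholds are
#' conventions, configurable, not measured constants.
#'
#' @param cr A [assign_constituency()] result.
#' @param area_quantile Area split across sites (default 0.5 = median).
#' @param rep_floor Mean-representativeness floor (default 0.8).
#' @return Data frame: site, area_ha, mean, p10, label.
#' @export
classify_sites <- function(cr, area_quantile = 0.5, rep_floor = 0.8) {
  if (!is.numeric(area_quantile) || area_quantile <= 0 || area_quantile >= 1)
    stop("area_quantile must lie in (0, 1)")
  if (!is.numeric(rep_floor) || rep_floor <= 0 || rep_floor >= 1)
    stop("rep_floor must lie in (0, 1)")
  cell_area_ha <- cr$winner$cellsize^2 / 1e4
  site <- cr$sites[cr$win]
  per_site <- lapply(cr$sites, function(s) cr$network_rep[site == s])
  area <- vapply(per_site, length, integer(1L)) * cell_area_ha
  mu <- vapply(per_site, function(v) if (length(v)) mean(v) else NA_real_,
               numeric(1L))
  p10 <- vapply(per_site,
                function(v) if (length(v))
                  stats::quantile(v, 0.1, names = FALSE) else NA_real_,
                numeric(1L))
  thr <- stats::quantile(area, area_quantile, names = FALSE)
  label <- ifelse(is.na(mu), "empty",
           ifelse(p10 < rep_floor - 0.2, "double-duty",
           ifelse(area >= thr & mu >= rep_floor, "generalist", "specialist")))
  data.frame(site = cr$sites, area_ha = area, mean = mu, p10 = p10,
             label = label, stringsAsFactors = FALSE)
}
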