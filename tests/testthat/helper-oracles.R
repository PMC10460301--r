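# Independent brute-force oracles and tiny fixture builders. The oracles are
# deliberately naive (explicit double loops) so they share no code path with
# the implementation they check.

# stack from a list of matrices
mk_stack <- function(mats, cellsize = 1, xll = 0, yll = 0) {
  grid_stack(lapply(mats, grid, cellsize = cellsize, xll = xll, yll = yll))
}

# single-class "cropland" mask covering a whole grid
all_working_mask <- function(template) {
  d <- dim(template$values)
  categorical_grid(matrix(1L, d[1L], d[2L]),
                   c("0" = "non-working", "1" = "cropland"),
                   valid = template$valid,
                   xll = template$xll, yll = template$yll,
                   cellsize = template$cellsize, crs = template$crs)
}

# representativeness map of one centroid: explicit per-cell loop
oracle_centroid_rep <- function(S, pc, D) {
  r <- numeric(nrow(S))
  for (i in seq_len(nrow(S))) {
    d2 <- 0
    for (j in seq_len(ncol(S))) d2 <- d2 + (S[i, j] - pc[j])^2
    r[i] <- 1 - sqrt(d2) / D
  }
  pmin(1, pmax(0, r))
}

# per-site aggregation + network max, cell by cell
oracle_site_rep <- function(S, C, site_of, D, agg = "max") {
  sites <- unique(site_of)
  n <- nrow(S)
  per_site <- matrix(NA_real_, n, length(sites))
  network <- numeric(n)
  for (i in seq_len(n)) {
    rs <- numeric(nrow(C))
    for (m in seq_len(nrow(C))) {
      d2 <- 0
      for (j in seq_len(ncol(S))) d2 <- d2 + (S[i, j] - C[m, j])^2
      rs[m] <- min(1, max(0, 1 - sqrt(d2) / D))
    }
    network[i] <- max(rs)
    for (s in seq_along(sites)) {
      v <- rs[site_of == sites[s]]
      per_site[i, s] <- switch(agg, max = max(v), mean = mean(v),
                               sum = sum(v))
    }
  }
  list(per_site = per_site, network = network, sites = sites)
}

# exhaustive max distance over (centroid, cell) pairs
oracle_observed_max <- function(S, C) {
  best <- 0
  for (m in seq_len(nrow(C)))
    for (i in seq_len(nrow(S))) {
      d2 <- 0
      for (j in seq_len(ncol(S))) d2 <- d2 + (S[i, j] - C[m, j])^2
      best <- max(best, sqrt(d2))
    }
  best
}

# per-cell argmax over sites with first-wins ties, plus full ranking
oracle_argmax <- function(per_site) {
  n <- nrow(per_site)
  win <- integer(n)
  for (i in seq_len(n)) {
    best <- 1L
    for (s in seq_len(ncol(per_site))[-1L])
      if (per_site[i, s] > per_site[i, best]) best <- s
    win[i] <- best
  }
  win
}

# per-block modal code with lowest-code tie break, by explicit counting
oracle_block_mode <- function(codes, f) {
  nr2 <- nrow(codes) %/% f
  nc2 <- ncol(codes) %/% f
  out <- matrix(NA_integer_, nr2, nc2)
  for (i in seq_len(nr2)) for (j in seq_len(nc2)) {
    blk <- codes[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)]
    tb <- table(blk)
    best <- names(tb)[tb == max(tb)]
    out[i, j] <- min(as.integer(best))
  }
  out
}

# a small random landscape with its fitted feature space (all components)
tiny_landscape <- function(seed, nrows = 10, ncols = nrows, n_layers = 3,
                           rho = 0.5, L = 3) {
  spec <- landscape_spec(nrows = nrows, ncols = ncols, n_layers = n_layers,
                         correlation_length = L,
                         cross_corr = cs_cross_corr(n_layers, rho),
                         seed = seed)
  st <- generate_fields(spec)
  fs <- select_components(fit_pca(st), 1.0)
  list(stack = st, fs = fs)
}

# GeoJSON text for a feature collection
write_geojson <- function(features, path) {
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

poly_feature <- function(site, coords, centroid_id = NULL) {
  props <- list(site = site)
  if (!is.null(centroid_id)) props$centroid_id <- centroid_id
  list(type = "Feature", properties = props,
       geometry = list(type = "Polygon", coordinates = list(coords)))
}

point_feature <- function(site, x, y, centroid_id = NULL) {
  props <- list(site = site)
  if (!is.null(centroid_id)) props$centroid_id <- centroid_id
  list(type = "Feature", properties = props,
       geometry = list(type = "Point", coordinates = c(x, y)))
}

# top-n ranking by repeated strict-max selection (first index wins ties)
oracle_rank_topn <- function(v, n) {
  left <- seq_along(v)
  out <- integer(0)
  for (k in seq_len(n)) {
    best <- left[1L]
    for (i in left) if (v[i] > v[best]) best <- i
    out <- c(out, best)
    left <- setdiff(left, best)
  }
  out
}
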