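#' Specification of a synthetic environmental landscape
#'
#' The generator emulates a stack of cross-correlated, spatially
#' autocorrelated environmental driver layers. The default cross-correlation
#' structure is a single common factor (compound symmetry, pairwise r = 0.9):
#' one dominant environmental gradient — think of a temperature-moisture
#' continuum — plus layer-specific noise. That regime yields the
#' ecoregion-like constituency structure the analysis assumes; richer
#' structures (e.g. [ar1_cross_corr()]) are supported but dilute the dominant
#' gradient.
#'
#' @param nrows,ncols Grid size in cells.
#' @param n_layers Number of environmental layers (default 15).
#' @param correlation_length Spatial autocorrelation e-folding scale, in
#'   cells (default 12).
#' @param cross_corr Target inter-layer correlation matrix (symmetric PSD,
#'   unit diagonal). Default [cs_cross_corr()]`(n_layers, 0.9)`.
#' @param seed Integer seed; all generator output is a pure function of the
#'   spec including its seed.
#' @return A `siterep_landscape_spec`.
#' @export
landscape_spec <- function(nrows = 128, ncols = nrows, n_layers = 15,
                           correlation_length = 12, cross_corr = NULL,
                           seed = 1) {
  stopifnot(nrows >= 2, ncols >= 2, n_layers >= 1, correlation_length > 0)
  n_layers <- as.integer(n_layers)
  if (is.null(cross_corr)) cross_corr <- cs_cross_corr(n_layers, 0.9)
  cross_corr <- as.matrix(cross_corr)
  if (!identical(dim(cross_corr), c(n_layers, n_layers)))
    stop("cross_corr must be n_layers x n_layers")
  if (max(abs(diag(cross_corr) - 1)) > 1e-8)
    stop("cross_corr diagonal must be 1")
  if (max(abs(cross_corr - t(cross_corr))) > 1e-8)
    stop("cross_corr must be symmetric")
  ev <- eigen(cross_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("cross_corr is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  structure(list(nrows = as.integer(nrows), ncols = as.integer(ncols),
                 n_layers = as.integer(n_layers),
                 correlation_length = correlation_length,
                 cross_corr = cross_corr, seed = as.integer(seed)),
            class = "siterep_landscape_spec")
}

#' Cross-correlation matrix templates
#'
#' `cs_cross_corr()` is compound symmetry (one common factor);
#' `ar1_cross_corr()` decays as `rho^|i-j|` with layer separation.
#'
#' @param n Number of layers.
#' @param rho Pairwise (or lag-1) correlation.
#' @export
cs_cross_corr <- function(n, rho = 0.9) {
  m <- matrix(rho, n, n)
  diag(m) <- 1
  m
}

#' @rdname cs_cross_corr
#' @export
ar1_cross_corr <- function(n, rho = 0.78) {
  outer(seq_len(n), seq_len(n), function(i, j) rho^abs(i - j))
}

# one standardized Gaussian random field by spectral synthesis: white noise,
# squared-exponential low-pass in the frequency domain, inverse FFT.
# Periodic boundaries are an accepted artifact of the FFT route.
grf_field <- function(nrows, ncols, L) {
  z <- matrix(stats::rnorm(nrows * ncols), nrows, ncols)
  fy <- ifelse(0:(nrows - 1) > nrows / 2, 0:(nrows - 1) - nrows,
               0:(nrows - 1)) / nrows
  fx <- ifelse(0:(ncols - 1) > ncols / 2, 0:(ncols - 1) - ncols,
               0:(ncols - 1)) / ncols
  rho <- sqrt(outer(fy^2, fx^2, `+`))
  H <- exp(-0.5 * (2 * pi * rho * L)^2)
  f <- Re(stats::fft(stats::fft(z) * H, inverse = TRUE)) / (nrows * ncols)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic environmental layer stack
#'
#' Builds `n_layers` stationary Gaussian random fields by spectral synthesis
#' (white noise, squared-exponential low-pass filter with e-folding scale
#' `correlation_length`, standardization), then imposes the target
#' inter-layer correlation with the symmetric square root of `cross_corr`
#' (negative eigenvalues clipped at zero, tolerating near-PSD input). Each
#' output layer is re-standardized to mean 0, sd 1, which leaves
#' correlations unchanged. Reproducible per seed.
#'
#' @param spec A [landscape_spec()].
#' @return A `siterep_grid_stack` of `n_layers` grids.
#' @export
generate_fields <- function(spec) {
  stopifnot(inherits(spec, "siterep_landscape_spec"))
  set.seed(spec$seed)
  nr <- spec$nrows; nc <- spec$ncols; p <- spec$n_layers
  Z <- vapply(seq_len(p),
              function(i) as.vector(grf_field(nr, nc, spec$correlation_length)),
              numeric(nr * nc))
  E <- eigen(spec$cross_corr, symmetric = TRUE)
  M <- E$vectors %*% diag(sqrt(pmax(E$values, 0)), p) %*% t(E$vectors)
  Y <- Z %*% t(M)
  Y <- scale(Y)
  grids <- lapply(seq_len(p), function(j) {
    grid(matrix(Y[, j], nr, nc), xll = 0, yll = 0, cellsize = 1)
  })
  grid_stack(grids, names = sprintf("env_%02d", seq_len(p)))
}

#' Generate a categorical working-lands mask from a latent layer
#'
#' Thresholds a designated latent layer of the stack into four spatially
#' coherent classes (coherence is inherited from the latent field's spatial
#' autocorrelation). By default the thresholds are latent quantiles chosen to
#' hit the target class proportions; explicit `thresholds` (three strictly
#' increasing numbers) map the four intervals, lowest first, to
#' non-working, grazingland, cropland and mixed.
#'
#' @param stack A `siterep_grid_stack`.
#' @param thresholds Optional strictly increasing numeric vector of length 3.
#' @param proportions Target class proportions (sum to 1) used when
#'   `thresholds` is `NULL`; the defaults follow the approximate CONUS shares
#'   of non-working, grazing, crop and mixed lands.
#' @param latent_layer Index of the latent layer (default 1).
#' @return A `siterep_categorical_grid` with classes `non-working` (0),
#'   `cropland` (1), `grazingland` (2), `mixed` (3).
#' @export
generate_mask <- function(stack, thresholds = NULL,
                          proportions = c("non-working" = 0.35,
                                          grazingland = 0.44,
                                          cropland = 0.195,
                                          mixed = 0.015),
                          latent_layer = 1L) {
  stopifnot(n_layers(stack) >= 1L)
  g <- stack$layers[[latent_layer]]
  v <- g$values[g$valid]
  class_table <- c("0" = "non-working", "1" = "cropland",
                   "2" = "grazingland", "3" = "mixed")
  # interval order along the latent gradient, low to high
  interval_codes <- c(0L, 2L, 1L, 3L)
  if (is.null(thresholds)) {
    if (abs(sum(proportions) - 1) > 1e-6)
      stop("proportions must sum to 1")
    if (diff(range(v)) == 0) {
      warning("constant latent layer: single-class mask")
      thresholds <- v[1L] + c(1, 2, 3)   # everything falls below
    } else {
      thresholds <- unname(stats::quantile(v, cumsum(proportions)[1:3]))
    }
  }
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0))
    stop("thresholds must be three strictly increasing numbers")
  codes <- matrix(NA_integer_, nrow(g$values), ncol(g$values))
  bin <- findInterval(g$values[g$valid], thresholds, left.open = TRUE) + 1L
  codes[g$valid] <- interval_codes[bin]
  categorical_grid(codes, class_table, valid = g$valid, xll = g$xll,
                   yll = g$yll, cellsize = g$cellsize, crs = g$crs)
}

#' Specification of a synthetic site network
#'
#' @param n_sites Number of sites (default 18).
#' @param centroids_per_site Integer range `c(lo, hi)`, lower bound >= 1
#'   (default 5 to 50 clustered centroids per site).
#' @param centroid_jitter Standard deviation, in cells, of the Gaussian
#'   offsets that scatter a site's centroids around its anchor (default 2).
#' @param placement `"random"` anchors, or `"stratified"`: one anchor per
#'   quantile stratum of a designated layer, placed at the stratum's
#'   environmental prototype cell (the valid cell nearest the stratum's
#'   component-wise median vector).
#' @param stratify_layer Designated layer index for stratified placement.
#' @param seed Integer seed.
#' @param name Network name.
#' @return A `siterep_network_spec`.
#' @export
network_spec <- function(n_sites = 18, centroids_per_site = c(5, 50),
                         centroid_jitter = 2,
                         placement = c("random", "stratified"),
                         stratify_layer = 1L, seed = 1, name = "network") {
  placement <- match.arg(placement)
  stopifnot(n_sites >= 1, length(centroids_per_site) == 2L,
            centroids_per_site[1L] >= 1,
            centroids_per_site[2L] >= centroids_per_site[1L],
            centroid_jitter >= 0)
  structure(list(n_sites = as.integer(n_sites),
                 centroids_per_site = as.integer(centroids_per_site),
                 centroid_jitter = centroid_jitter, placement = placement,
                 stratify_layer = as.integer(stratify_layer),
                 seed = as.integer(seed), name = name),
            class = "siterep_network_spec")
}

#' Generate a synthetic site network on a landscape
#'
#' Places one anchor cell per site (random over valid cells, or stratified:
#' see [network_spec()]), then scatters each site's centroids around its
#' anchor with Gaussian jitter, re-drawing any offset that lands outside the
#' grid or on an invalid cell (bounded retries). Centroid coordinates are
#' cell centers. PC values are left unsampled; sampling against a fitted
#' feature space is [sample_centroids()]'s job. For planted-gradient
#' experiments pass the PC score stack (`fs$scores`) so strata follow the
#' dominant feature-space gradient.
#'
#' @param stack A `siterep_grid_stack` (environmental layers or PC scores).
#' @param spec A [network_spec()].
#' @return An unsampled `siterep_network`. Stratified networks carry the
#'   stratum quantile breaks in attribute `"strata"`.
#' @export
generate_network <- function(stack, spec) {
  stopifnot(inherits(spec, "siterep_network_spec"))
  set.seed(spec$seed)
  jv <- joint_valid(stack)
  valid_cells <- which(jv)
  if (length(valid_cells) < spec$n_sites)
    stop("not enough valid cells for ", spec$n_sites, " sites")
  nr <- nrow(jv)
  breaks <- NULL
  if (spec$placement == "random") {
    anchors <- sample(valid_cells, spec$n_sites)
  } else {
    Y <- values_matrix(stack, valid_cells)
    Y <- matrix(Y, nrow = length(valid_cells))
    gl <- Y[, spec$stratify_layer]
    breaks <- stats::quantile(gl, seq(0, 1, length.out = spec$n_sites + 1L))
    stratum <- cut(gl, breaks, include.lowest = TRUE, labels = FALSE)
    anchors <- vapply(seq_len(spec$n_sites), function(s) {
      idx <- which(stratum == s)
      proto <- apply(Y[idx, , drop = FALSE], 2L, stats::median)
      d2 <- colSums((t(Y[idx, , drop = FALSE]) - proto)^2)
      valid_cells[idx[which.min(d2)]]
    }, numeric(1L))
  }
  template <- stack$layers[[1L]]
  lo <- spec$centroids_per_site[1L]; hi <- spec$centroids_per_site[2L]
  rows <- integer(0); cols <- integer(0); sites <- character(0)
  for (s in seq_len(spec$n_sites)) {
    site_name <- sprintf("S%02d", s)
    nc_s <- if (lo == hi) lo else sample(lo:hi, 1L)
    ar <- (anchors[s] - 1L) %% nr + 1L
    ac <- (anchors[s] - 1L) %/% nr + 1L
    for (i in seq_len(nc_s)) {
      placed <- FALSE
      for (try in seq_len(100L)) {
        r <- ar + as.integer(round(stats::rnorm(1L) * spec$centroid_jitter))
        cc <- ac + as.integer(round(stats::rnorm(1L) * spec$centroid_jitter))
        if (r >= 1L && r <= nrow(jv) && cc >= 1L && cc <= ncol(jv) &&
            jv[r, cc]) {
          rows <- c(rows, r); cols <- c(cols, cc)
          sites <- c(sites, site_name)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("no valid cell found near site ", site_name,
             " after bounded retries; jitter too large?")
    }
  }
  ctr <- cell_center(template, rows, cols)
  ord <- stats::ave(seq_along(sites), sites, FUN = seq_along)
  net <- site_network(
    data.frame(site = sites,
               centroid_id = sprintf("%s_%03d", sites, ord),
               x = ctr$x, y = ctr$y, row = rows, col = cols,
               stringsAsFactors = FALSE),
    name = spec$name
  )
  attr(net, "strata") <- breaks
  net
}

#' Write a full synthetic landscape to a directory
#'
#' Emits the layer stack and mask as ASCII grids, the network as GeoJSON
#' points, and a YAML manifest recording the specs and seeds.
#'
#' @param stack,mask,net Generator outputs.
#' @param dir Output directory (created if needed).
#' @param manifest Extra fields stored in the manifest.
#' @return Invisibly the manifest list.
#' @export
write_landscape <- function(stack, mask, net, dir, manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n_layers(stack)))
    write_grid(stack$layers[[i]],
               file.path(dir, paste0(stack$names[i], ".asc")))
  write_grid(mask, file.path(dir, "mask.asc"))
  write_network(net, file.path(dir, "network.geojson"))
  man <- c(list(layers = stack$names, n_centroids = nrow(net$centroids)),
           manifest)
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(man)
}
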