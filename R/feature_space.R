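#' Fit a principal-component feature space on a raster stack
#'
#' Layer values at jointly valid cells are centered (and, by default, scaled
#' to unit variance — a correlation PCA, appropriate when the layers carry
#' incommensurable units) and decomposed with [stats::prcomp()] (SVD).
#' Components are ordered by decreasing explained variance and each loading
#' column is sign-fixed so its largest-magnitude entry is positive, making
#' results reproducible across linear-algebra backends. Per-cell component
#' scores are returned as a grid stack whose validity equals the input joint
#' validity.
#'
#' All statistics are computed over valid cells only.
#'
#' @param stack A `siterep_grid_stack` with at least two layers.
#' @param standardize Scale each layer to unit variance before the
#'   decomposition (default `TRUE`).
#' @return Object of class `"siterep_feature_space"` with elements `means`,
#'   `sds`, `loadings` (layers x components), `variance_fraction`,
#'   `n_selected`, and `scores` (a grid stack of the selected components).
#' @export
fit_pca <- function(stack, standardize = TRUE) {
  p <- n_layers(stack)
  if (p < 2L) stop("need at least two layers")
  jv <- joint_valid(stack)
  cells <- which(jv)
  if (length(cells) < p)
    stop("need at least as many valid cells as layers")
  X <- values_matrix(stack, cells)
  colnames(X) <- stack$names
  means <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  if (standardize && any(sds <= .Machine$double.eps))
    stop("zero-variance layer cannot be standardized: ",
         paste(stack$names[sds <= .Machine$double.eps], collapse = ", "))
  Xs <- sweep(X, 2L, means, `-`)
  if (standardize) Xs <- sweep(Xs, 2L, sds, `/`)
  pr <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  loadings <- pr$rotation
  ev <- pr$sdev^2
  vf <- ev / sum(ev)
  # deterministic sign convention
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  scores <- Xs %*% loadings
  template <- stack$layers[[1L]]
  score_grids <- lapply(seq_len(ncol(scores)), function(j) {
    m <- matrix(NA_real_, nrow(jv), ncol(jv))
    m[cells] <- scores[, j]
    grid(m, valid = jv, xll = template$xll, yll = template$yll,
         cellsize = template$cellsize, crs = template$crs,
         nodata = template$nodata)
  })
  fs <- structure(
    list(means = means, sds = sds, standardize = standardize,
         loadings = loadings, variance_fraction = vf,
         n_selected = length(vf),
         scores = grid_stack(score_grids,
                             names = paste0("PC", seq_along(score_grids))),
         layer_names = stack$names),
    class = "siterep_feature_space"
  )
  fs
}

#' Truncate a feature space by cumulative explained variance
#'
#' Keeps the smallest leading set of components whose cumulative variance
#' fraction reaches `threshold`; the score stack is truncated accordingly.
#'
#' @param fs A fitted feature space.
#' @param threshold Fraction in (0, 1].
#' @return The feature space with `n_selected` components.
#' @export
select_components <- function(fs, threshold = 0.90) {
  stopifnot(inherits(fs, "siterep_feature_space"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  cs <- cumsum(fs$variance_fraction)
  k <- which(cs >= threshold - 1e-9)[1L]
  if (is.na(k)) k <- length(cs)
  fs$n_selected <- k
  fs$scores <- grid_stack(fs$scores$layers[seq_len(k)],
                          names = fs$scores$names[seq_len(k)])
  fs
}

# score matrix over jointly valid cells (cells in column-major order)
score_matrix <- function(fs) {
  jv <- joint_valid(fs$scores)
  cells <- which(jv)
  S <- values_matrix(fs$scores, cells)
  S <- matrix(S, nrow = length(cells),
              dimnames = list(NULL, fs$scores$names))
  list(S = S, cells = cells, valid = jv)
}

#' @export
print.siterep_feature_space <- function(x, ...) {
  cs <- cumsum(x$variance_fraction)
  cat(sprintf("siterep feature space: %d layer(s), %d of %d component(s) selected (%.1f%% variance)\n",
              length(x$layer_names), x$n_selected,
              length(x$variance_fraction), 100 * cs[x$n_selected]))
  invisible(x)
}

#' Scree table of a feature space
#'
#' @param fs A fitted feature space.
#' @return Data frame with `component`, `variance_fraction`, `cumulative`.
#' @export
scree_table <- function(fs) {
  data.frame(component = seq_along(fs$variance_fraction),
             variance_fraction = fs$variance_fraction,
             cumulative = cumsum(fs$variance_fraction))
}
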