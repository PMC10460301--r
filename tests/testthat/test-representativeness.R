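test_that("bounding-box diameter follows range arithmetic", {
  # 1-D scores spanning [-2, 3] -> diameter 5
  m <- matrix(seq(-2, 3, length.out = 9), 3, 3)
  st <- mk_stack(list(a = m, b = m * 2))   # rank 1: one effective component
  fs <- select_components(fit_pca(st), 0.99)
  expect_equal(fs$n_selected, 1L)
  rng <- diff(range(fs$scores$layers[[1L]]$values))
  expect_equal(normalization_constant(fs)$value, rng, tolerance = 1e-12)

  # 2-D: component ranges 3 and 4 give diameter 5 (hand-built scores)
  fs2 <- fs
  s1 <- grid(matrix(c(0, 3, 0, 0), 2, 2))
  s2 <- grid(matrix(c(0, 0, 4, 0), 2, 2))
  fs2$scores <- grid_stack(list(s1, s2), names = c("PC1", "PC2"))
  fs2$n_selected <- 2L
  expect_equal(normalization_constant(fs2)$value, 5)
})

test_that("observed-max normalization equals the exhaustive pair maximum", {
  lnd <- tiny_landscape(51, nrows = 10, n_layers = 3)
  fs <- lnd$fs
  net <- sample_centroids(
    generate_network(lnd$stack, network_spec(n_sites = 3,
                                             centroids_per_site = c(1, 2),
                                             centroid_jitter = 1, seed = 52)),
    fs)
  sm <- siterep:::score_matrix(fs)
  ora <- oracle_observed_max(sm$S, net$pc)
  expect_equal(normalization_constant(fs, "observed_max", net)$value, ora,
               tolerance = 1e-14)
  # degenerate feature space: identical cells have no usable diameter
  flat <- fs
  flat$scores <- grid_stack(list(grid(matrix(1, 4, 4))), names = "PC1")
  expect_error(normalization_constant(flat), "undefined")
})

test_that("centroid maps satisfy the defining identities and match the oracle", {
  lnd <- tiny_landscape(53, nrows = 5, n_layers = 3)
  fs <- lnd$fs
  norm <- normalization_constant(fs)
  sm <- siterep:::score_matrix(fs)
  pc <- sm$S[7L, ]
  g <- centroid_representativeness(pc, fs, norm)
  # own cell: zero distance, r = 1 exactly
  expect_identical(g$values[sm$cells[7L]], 1)
  # full 5x5 map against the double-loop oracle
  ora <- oracle_centroid_rep(sm$S, pc, norm$value)
  expect_equal(g$values[sm$cells], ora, tolerance = 1e-12)
  expect_error(centroid_representativeness(pc[1:2], fs, norm),
               "dimension mismatch")
})

test_that("a cell at normalization distance scores zero", {
  m <- matrix(seq(-2, 3, length.out = 16), 4, 4)
  st <- mk_stack(list(a = m, b = 3 * m - 1))
  fs <- select_components(fit_pca(st), 0.99)
  norm <- normalization_constant(fs)
  s <- fs$scores$layers[[1L]]$values
  pc_min <- min(s)
  g <- centroid_representativeness(pc_min, fs, norm)
  expect_equal(g$values[which.max(s)], 0, tolerance = 1e-12)
})

test_that("site and network aggregation match cellwise oracles", {
  lnd <- tiny_landscape(54, nrows = 8, n_layers = 4)
  fs <- lnd$fs
  net <- sample_centroids(
    generate_network(lnd$stack, network_spec(n_sites = 3,
                                             centroids_per_site = c(2, 4),
                                             centroid_jitter = 2, seed = 55)),
    fs)
  norm <- normalization_constant(fs)
  sm <- siterep:::score_matrix(fs)
  site_of <- net$centroids$site
  for (agg in c("max", "mean")) {
    rep <- site_representativeness(net, fs, norm, aggregation = agg)
    ora <- oracle_site_rep(sm$S, net$pc, site_of, norm$value, agg)
    for (s in seq_along(ora$sites))
      expect_equal(rep$per_site[[ora$sites[s]]]$values[sm$cells],
                   ora$per_site[, s], tolerance = 1e-12)
    expect_equal(rep$network$values[sm$cells], ora$network,
                 tolerance = 1e-12)
  }
  # one site, one centroid: per-site map is the centroid map, network equals it
  one <- sample_centroids(
    generate_network(lnd$stack, network_spec(n_sites = 1,
                                             centroids_per_site = c(1, 1),
                                             centroid_jitter = 0, seed = 56)),
    fs)
  r1 <- site_representativeness(one, fs, norm)
  cmap <- centroid_representativeness(one$pc[1L, ], fs, norm)
  expect_equal(r1$per_site[[1L]]$values, cmap$values)
  expect_equal(r1$network$values, cmap$values)
})

test_that("sum aggregation doubles duplicated centroids and warns above 1", {
  lnd <- tiny_landscape(57, nrows = 5, n_layers = 3)
  fs <- lnd$fs
  norm <- normalization_constant(fs)
  ctr <- cell_center(fs$scores$layers[[1L]], 2, 2)
  cen <- data.frame(site = "A", centroid_id = c("c1", "c2"),
                    x = ctr$x, y = ctr$y)
  net <- sample_centroids(site_network(cen), fs)
  expect_warning(rs <- site_representativeness(net, fs, norm,
                                               aggregation = "sum"),
                 "exceed 1")
  cmap <- centroid_representativeness(net$pc[1L, ], fs, norm)
  expect_equal(rs$per_site[["A"]]$values, 2 * cmap$values)
  # network layer stays a max regardless of site aggregation
  expect_equal(rs$network$values, cmap$values)
})

test_that("results are invariant to the processing tile size", {
  lnd <- tiny_landscape(58, nrows = 32, n_layers = 4, rho = 0.6, L = 5)
  fs <- lnd$fs
  net <- sample_centroids(
    generate_network(lnd$stack, network_spec(n_sites = 4,
                                             centroids_per_site = c(2, 5),
                                             centroid_jitter = 2, seed = 59)),
    fs)
  norm <- normalization_constant(fs)
  full <- site_representativeness(net, fs, norm)
  for (tile in c(5L, 16L)) {
    tiled <- site_representativeness(net, fs, norm, tile = tile)
    expect_identical(tiled$network$values, full$network$values)
    for (s in names(full$per_site))
      expect_identical(tiled$per_site[[s]]$values, full$per_site[[s]]$values)
  }
})

test_that("adding a centroid never decreases the network layer", {
  lnd <- tiny_landscape(60, nrows = 12, n_layers = 3)
  fs <- lnd$fs
  norm <- normalization_constant(fs)   # site-set independent divisor
  net <- sample_centroids(
    generate_network(lnd$stack, network_spec(n_sites = 2,
                                             centroids_per_site = c(2, 3),
                                             centroid_jitter = 1, seed = 61)),
    fs)
  before <- site_representativeness(net, fs, norm)$network
  bigger <- add_site(net, fs, row = 6L, col = 6L, site = "NEW")
  after <- site_representativeness(bigger, fs, norm)$network
  expect_true(all(after$values[after$valid] >=
                  before$values[before$valid] - 1e-15))
})
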