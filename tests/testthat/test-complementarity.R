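setup_nets <- function(seed = 91, nrows = 10, n_layers = 3) {
  lnd <- tiny_landscape(seed, nrows = nrows, n_layers = n_layers)
  fs <- lnd$fs
  home <- sample_centroids(
    generate_network(lnd$stack, network_spec(n_sites = 2,
                                             centroids_per_site = c(1, 3),
                                             centroid_jitter = 1,
                                             seed = seed + 1, name = "home")),
    fs)
  norm <- normalization_constant(fs)
  list(lnd = lnd, fs = fs, home = home, norm = norm)
}

test_that("an identical sister brings no improvement and ties resolve to home", {
  x <- setup_nets(91)
  twin <- x$home
  twin$name <- "twin"
  bn <- best_network_map(list(x$home, twin), x$fs, x$norm)
  v <- bn$improvement$values[bn$improvement$valid]
  expect_true(all(v == 0))
  expect_true(all(bn$best_network$codes[bn$best_network$valid] == 1L))
  expect_equal(nrow(bn$borrowed_sites), 0L)
  expect_error(best_network_map(list(x$home), x$fs, x$norm),
               "at least two")
})

test_that("a sister centroid on a poorly-covered cell lifts combined_rep to 1 there", {
  x <- setup_nets(92)
  home_rep <- site_representativeness(x$home, x$fs, x$norm)
  g <- home_rep$network
  cells <- which(g$valid)
  target <- cells[which.min(g$values[cells])]
  expect_lt(g$values[target], 1)
  nr <- nrow(g$values)
  trow <- ((target - 1L) %% nr) + 1L
  tcol <- ((target - 1L) %/% nr) + 1L
  ctr <- cell_center(g, trow, tcol)
  sister <- sample_centroids(site_network(
    data.frame(site = "S", centroid_id = "s1", x = ctr$x, y = ctr$y),
    name = "sister"), x$fs)
  bn <- best_network_map(list(x$home, sister), x$fs, x$norm)
  expect_equal(bn$combined_rep$values[target], 1)
  expect_equal(bn$best_network$codes[target], 2L)
  expect_equal(bn$home_rep$values[target], g$values[target])
})

test_that("multi-network best map and improvement match the exhaustive oracle", {
  x <- setup_nets(93)
  nets <- list(x$home)
  for (i in 1:2)
    nets[[i + 1L]] <- sample_centroids(
      generate_network(x$lnd$stack,
                       network_spec(n_sites = 2, centroids_per_site = c(1, 2),
                                    centroid_jitter = 1, seed = 200 + i,
                                    name = paste0("sister", i))),
      x$fs)
  bn <- best_network_map(nets, x$fs, x$norm)
  sm <- siterep:::score_matrix(x$fs)
  NW <- vapply(nets, function(n) {
    oracle_site_rep(sm$S, n$pc, n$centroids$site, x$norm$value)$network
  }, numeric(length(sm$cells)))
  expect_equal(bn$best_network$codes[sm$cells], oracle_argmax(NW))
  cmb <- apply(NW, 1L, max)
  expect_equal(bn$combined_rep$values[sm$cells], cmb, tolerance = 1e-12)
  expect_equal(bn$improvement$values[sm$cells], cmb - NW[, 1L],
               tolerance = 1e-12)
  expect_true(all(bn$improvement$values[sm$cells] >= 0))
  # gains are exactly where a sister wins (up to exact ties)
  gain <- bn$improvement$values[sm$cells] > 0
  sister_best <- oracle_argmax(NW) > 1L
  expect_true(all(gain == sister_best |
                  (NW[, 1L] == cmb)))   # tie cells stay with home
})

test_that("sister networks are filtered to eligible mask classes", {
  x <- setup_nets(94)
  g <- x$fs$scores$layers[[1L]]
  d <- dim(g$values)
  # left half cropland (1), right half non-working (0)
  codes <- matrix(0L, d[1L], d[2L])
  codes[, seq_len(d[2L] %/% 2)] <- 1L
  mask <- categorical_grid(codes, c("0" = "non-working", "1" = "cropland"),
                           xll = g$xll, yll = g$yll, cellsize = g$cellsize,
                           crs = g$crs)
  ctr_in <- cell_center(g, 2, 2)
  ctr_out <- cell_center(g, 2, d[2L])
  sister <- sample_centroids(site_network(
    data.frame(site = c("in", "out"), centroid_id = c("i", "o"),
               x = c(ctr_in$x, ctr_out$x), y = c(ctr_in$y, ctr_out$y)),
    name = "sister"), x$fs)
  filt <- filter_network_by_class(sister, mask, "cropland")
  expect_equal(filt$centroids$site, "in")
  bn <- best_network_map(list(x$home, sister), x$fs, x$norm, mask = mask,
                         classes = "cropland")
  expect_false("out" %in% bn$borrowed_sites$site)
  # a sister with no eligible centroid is dropped (leaving < 2 networks errors)
  only_out <- sample_centroids(site_network(
    data.frame(site = "out", centroid_id = "o", x = ctr_out$x, y = ctr_out$y),
    name = "allout"), x$fs)
  expect_warning(
    expect_error(best_network_map(list(x$home, only_out), x$fs, x$norm,
                                  mask = mask, classes = "cropland"),
                 "fewer than two"),
    "dropped")
})

test_that("candidate gaps scan lowest values first with spatial separation", {
  x <- setup_nets(95, nrows = 12)
  rep <- site_representativeness(x$home, x$fs, x$norm)
  gaps <- candidate_gaps(rep, k = 3, min_sep = 3)
  g <- rep$network
  expect_equal(gaps$representativeness[1L], min(g$values[g$valid]))
  expect_true(all(diff(gaps$representativeness) >= 0))
  if (nrow(gaps) > 1L) {
    d2 <- as.matrix(dist(gaps[, c("row", "col")]))^2
    expect_true(all(d2[upper.tri(d2)] >= 9))
  }
  expect_error(candidate_gaps(rep, k = 0), ">= 1")
  # uniform surface: deterministic scan order (cell index order)
  u <- rep
  u$network$values[u$network$valid] <- 0.5
  gu1 <- candidate_gaps(u, k = 4, min_sep = 2)
  gu2 <- candidate_gaps(u, k = 4, min_sep = 2)
  expect_identical(gu1, gu2)
})
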