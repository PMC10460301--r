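make_cr <- function(seed = 71, nrows = 10, n_sites = 3, classes = NULL) {
  lnd <- tiny_landscape(seed, nrows = nrows, n_layers = 3)
  fs <- lnd$fs
  net <- sample_centroids(
    generate_network(lnd$stack, network_spec(n_sites = n_sites,
                                             centroids_per_site = c(1, 4),
                                             centroid_jitter = 2,
                                             seed = seed + 1)),
    fs)
  norm <- normalization_constant(fs)
  rep <- site_representativeness(net, fs, norm)
  mask <- all_working_mask(rep$network)
  list(fs = fs, net = net, rep = rep, mask = mask,
       cr = assign_constituency(rep, mask, classes = classes))
}

test_that("every masked cell gets exactly one winner matching the argmax oracle", {
  x <- make_cr(71)
  sm <- siterep:::score_matrix(x$fs)
  R <- vapply(x$cr$sites,
              function(s) x$rep$per_site[[s]]$values[sm$cells],
              numeric(length(sm$cells)))
  win_oracle <- oracle_argmax(R)
  expect_identical(x$cr$win, win_oracle)
  # partition: every eligible cell assigned, none twice
  expect_equal(length(x$cr$win), sum(x$mask$valid))
  # winner's representativeness equals the network layer everywhere
  Rwin <- R[cbind(seq_along(x$cr$win), x$cr$win)]
  expect_equal(Rwin, x$rep$network$values[sm$cells], tolerance = 1e-15)
  # dominance: no site beats the winner anywhere
  expect_true(all(R <= Rwin + 1e-15))
})

test_that("single-site networks win everywhere; ties go to the earlier site", {
  x <- make_cr(72, n_sites = 1)
  expect_true(all(x$cr$win == 1L))

  # two sites with identical centroids: exact ties everywhere, first wins
  lnd <- tiny_landscape(73, nrows = 6, n_layers = 3)
  fs <- lnd$fs
  ctr <- cell_center(fs$scores$layers[[1L]], 3, 3)
  cen <- data.frame(site = c("A", "B"), centroid_id = c("a", "b"),
                    x = ctr$x, y = ctr$y)
  net <- sample_centroids(site_network(cen), fs)
  rep <- site_representativeness(net, fs, normalization_constant(fs))
  cr <- assign_constituency(rep, all_working_mask(rep$network))
  expect_true(all(cr$sites[cr$win] == "A"))
})

test_that("ranked lists are consistent: rank 1 is the winner, values non-increasing", {
  x <- make_cr(74, n_sites = 4)
  rk <- x$cr$ranks
  first <- rk[rk$rank == 1L, ]
  expect_equal(first$site, x$cr$sites[x$cr$win])
  by_cell <- split(rk$representativeness, paste(rk$row, rk$col))
  expect_true(all(vapply(by_cell, function(v) all(diff(v) <= 1e-15),
                         logical(1L))))
  expect_error(assign_constituency(x$rep, x$mask, classes = "wetland"),
               "empty class selection")
  expect_error(assign_constituency(x$rep, NULL), "mask")
})

test_that("constituency areas partition the masked area and report distributions", {
  x <- make_cr(75, n_sites = 3)
  areas <- constituency_areas(x$cr, cell_area_ha = 100)
  expect_equal(sum(areas$n_cells), sum(x$mask$valid))
  expect_equal(sum(areas$area_ha), 100 * sum(x$mask$valid))
  # 100 cells of 100 ha each under one site -> 10,000 ha
  one <- make_cr(76, nrows = 10, n_sites = 1)
  a1 <- constituency_areas(one$cr, cell_area_ha = 100)
  expect_equal(a1$area_ha[!a1$empty], 10000)
  # stats match a direct recomputation
  s1 <- x$cr$sites[1L]
  v <- x$cr$network_rep[x$cr$sites[x$cr$win] == s1]
  row1 <- areas[areas$site == s1 & !areas$empty, ]
  expect_equal(row1$mean, mean(v))
  expect_equal(row1$median, median(v))
  expect_equal(row1$min, min(v))
})

test_that("empty constituencies are flagged rather than dropped", {
  # a duplicated site can never win (ties go to the first); its row is empty
  lnd <- tiny_landscape(77, nrows = 6, n_layers = 3)
  fs <- lnd$fs
  ctr <- cell_center(fs$scores$layers[[1L]], 2, 2)
  cen <- data.frame(site = c("A", "B"), centroid_id = c("a", "b"),
                    x = ctr$x, y = ctr$y)
  net <- sample_centroids(site_network(cen), fs)
  rep <- site_representativeness(net, fs, normalization_constant(fs))
  cr <- assign_constituency(rep, all_working_mask(rep$network))
  areas <- constituency_areas(cr)
  brow <- areas[areas$site == "B", ]
  expect_true(brow$empty)
  expect_equal(brow$area_ha, 0)
  expect_true(is.na(brow$mean))
})

test_that("gradient ranges summarize the centroid PC values per site", {
  x <- make_cr(78, n_sites = 3)
  gr <- site_gradient_ranges(x$net, x$fs)
  # direct recomputation for one site/component
  s <- x$cr$sites[2L]
  v <- x$net$pc[x$net$centroids$site == s, 1L]
  row <- gr[gr$site == s & gr$component == "PC1", ]
  expect_equal(row$mean, mean(v))
  expect_equal(row$min, min(v))
  expect_equal(row$max, max(v))
  # single-centroid site: all stats collapse to its value
  one <- tiny_landscape(79, nrows = 6, n_layers = 3)
  ctr <- cell_center(one$fs$scores$layers[[1L]], 2, 2)
  n1 <- sample_centroids(site_network(
    data.frame(site = "A", centroid_id = "a", x = ctr$x, y = ctr$y)), one$fs)
  g1 <- site_gradient_ranges(n1, one$fs)
  expect_true(all(g1$min == g1$max & g1$min == g1$mean))
  # symmetric triple {-1, 0, 1}: mean 0, range 2
  fake <- n1
  fake$pc <- matrix(c(-1, 0, 1), 3, 1, dimnames = list(NULL, "PC1"))
  fake$centroids <- data.frame(site = "A", centroid_id = c("a", "b", "c"),
                               x = 0, y = 0)
  g3 <- site_gradient_ranges(fake, one$fs)
  expect_equal(g3$mean, 0)
  expect_equal(g3$max - g3$min, 2)
})

test_that("the site taxonomy applies its thresholds as documented", {
  x <- make_cr(80, n_sites = 3)
  base <- classify_sites(x$cr)
  expect_true(all(base$label %in% c("generalist", "specialist",
                                    "double-duty", "empty")))
  # synthetic two-site cr: areas {90, 10}, both well represented
  fake <- x$cr
  fake$sites <- c("big", "small")
  fake$win <- rep(c(1L, 2L), c(90L, 10L))
  fake$network_rep <- rep(0.9, 100L)
  fake$winner$cellsize <- 1000   # 100 ha cells
  lab <- classify_sites(fake)
  expect_equal(lab$label, c("generalist", "specialist"))
  # low lower-tail representativeness forces double-duty
  fake$network_rep <- c(rep(0.9, 90L), rep(0.4, 10L))
  lab2 <- classify_sites(fake)
  expect_equal(lab2$label[2L], "double-duty")
  # all-identical sites receive one label
  fake$win <- rep(c(1L, 2L), 50L)
  fake$network_rep <- rep(0.9, 100L)
  lab3 <- classify_sites(fake)
  expect_equal(length(unique(lab3$label)), 1L)
  expect_error(classify_sites(x$cr, area_quantile = 1.2), "\\(0, 1\\)")
  expect_error(classify_sites(x$cr, rep_floor = 0), "\\(0, 1\\)")
})
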