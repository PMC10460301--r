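#' Pipeline configuration
#'
#' One nested list drives the whole analysis. Defaults run a self-contained
#' synthetic demonstration: generate a landscape, fit the feature space,
#' compute representativeness, constituency and (optionally) cross-network
#' complementarity, and write all tabular reports as CSV. The config
#' round-trips losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' Seed substreams, derived from `seed` in this order: landscape fields use
#' `seed`, the home network `seed + 1`, sister network `i` uses
#' `seed + 1 + i`.
#'
#' @param seed Master seed.
#' @param out Output directory.
#' @param synth Synthetic-landscape settings (set `enabled = FALSE` and fill
#'   `paths` to run on files instead).
#' @param paths Input paths used when `synth$enabled` is `FALSE`: `stack`
#'   (directory of `.asc` layers), `mask` (`.asc`), `network` (GeoJSON),
#'   `sisters` (list of GeoJSON paths).
#' @param pca,representativeness,constituency,complementarity Stage settings.
#' @return A `siterep_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            out = file.path(tempdir(), "siterep_out"),
                            synth = list(),
                            paths = list(),
                            pca = list(),
                            representativeness = list(),
                            constituency = list(),
                            complementarity = list()) {
  merge_defaults <- function(user, def) {
    for (k in names(user)) def[k] <- list(user[[k]])  # NULL-preserving
    def
  }
  cfg <- list(
    seed = as.integer(seed),
    out = out,
    synth = merge_defaults(synth, list(
      enabled = TRUE, nrows = 128, ncols = 128, n_layers = 15,
      correlation_length = 12, cross_corr_rho = 0.9,
      n_sites = 18, centroids_per_site = c(5, 50), centroid_jitter = 2,
      placement = "random")),
    paths = merge_defaults(paths, list(
      stack = NULL, mask = NULL, network = NULL, sisters = list())),
    pca = merge_defaults(pca, list(standardize = TRUE, threshold = 0.90)),
    representativeness = merge_defaults(representativeness, list(
      aggregation = "max", norm_method = "bbox_diameter", tile = NULL)),
    constituency = merge_defaults(constituency, list(
      top_n = 3, area_quantile = 0.5, rep_floor = 0.8,
      classes = c("cropland", "grazingland", "mixed"))),
    complementarity = merge_defaults(complementarity, list(
      enabled = FALSE, n_sister_networks = 2, sister_n_sites = 10,
      sister_centroids_per_site = c(1, 3)))
  )
  stopifnot(cfg$pca$threshold > 0, cfg$pca$threshold <= 1)
  class(cfg) <- c("siterep_config", "list")
  cfg
}

#' @rdname pipeline_config
#' @param cfg A `siterep_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw),
    names(formals(pipeline_config)))])
}

write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Summarize network representativeness by mask class
#'
#' Per mask class: cell count, mean, median and standard deviation of the
#' network representativeness, plus a kernel density estimate of its
#' distribution (Gaussian kernel, Silverman's rule-of-thumb bandwidth).
#' Classes with no cells get a row flagged `empty`.
#'
#' @param rep A [site_representativeness()] result.
#' @param mask A co-registered `siterep_categorical_grid`.
#' @return List with `table` (data frame) and `densities` (named list of
#'   [stats::density()] objects).
#' @export
summarize_by_class <- function(rep, mask) {
  assert_coregistered(grid_stack(list(network = rep$network)),
                      list(mask = mask))
  g <- rep$network
  classes <- unique(unname(mask$class_table))
  densities <- list()
  rows <- lapply(classes, function(cl) {
    codes <- as.integer(names(mask$class_table)[mask$class_table == cl])
    sel <- g$valid & mask$valid &
      matrix(mask$codes %in% codes, nrow(mask$codes))
    v <- g$values[sel]
    if (length(v) == 0L)
      return(data.frame(class = cl, n_cells = 0L, mean = NA_real_,
                        median = NA_real_, sd = NA_real_, empty = TRUE,
                        stringsAsFactors = FALSE))
    if (length(v) >= 2L && stats::sd(v) > 0)
      densities[[cl]] <<- stats::density(v, bw = "nrd0")
    data.frame(class = cl, n_cells = length(v), mean = mean(v),
               median = stats::median(v), sd = stats::sd(v), empty = FALSE,
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), densities = densities)
}

#' Run the full analysis pipeline
#'
#' Executes synth (optional), PCA, representativeness, constituency and
#' complementarity (optional), writing every tabular report as CSV and the
#' main grids as ASCII rasters under `cfg$out`, plus a JSON manifest with
#' the config, input checksums, per-stage wall times and output checksums.
#' The same config and seed reproduce byte-identical CSV outputs. On stage
#' failure the manifest records the failing stage and the error is re-thrown
#' naming it.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly; its `results` element carries the main
#'   in-memory objects (feature space, representativeness, constituency...).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "siterep_config"))
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg),
                   r_version = R.version.string,
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list(), files = list())
  res <- list()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      manifest$status <<- "failed"
      jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }

  inputs <- stage("synth", function() {
    if (isTRUE(cfg$synth$enabled)) {
      ls_spec <- landscape_spec(
        nrows = cfg$synth$nrows, ncols = cfg$synth$ncols,
        n_layers = cfg$synth$n_layers,
        correlation_length = cfg$synth$correlation_length,
        cross_corr = cs_cross_corr(cfg$synth$n_layers,
                                   cfg$synth$cross_corr_rho),
        seed = cfg$seed)
      stack <- generate_fields(ls_spec)
      mask <- generate_mask(stack)
      net_spec <- network_spec(
        n_sites = cfg$synth$n_sites,
        centroids_per_site = cfg$synth$centroids_per_site,
        centroid_jitter = cfg$synth$centroid_jitter,
        placement = cfg$synth$placement,
        seed = cfg$seed + 1L, name = "home")
      net <- generate_network(stack, net_spec)
      sisters <- list()
      if (isTRUE(cfg$complementarity$enabled)) {
        for (i in seq_len(cfg$complementarity$n_sister_networks)) {
          sspec <- network_spec(
            n_sites = cfg$complementarity$sister_n_sites,
            centroids_per_site = cfg$complementarity$sister_centroids_per_site,
            centroid_jitter = cfg$synth$centroid_jitter,
            seed = cfg$seed + 1L + i, name = paste0("sister_", i))
          sisters[[i]] <- generate_network(stack, sspec)
        }
      }
      list(stack = stack, mask = mask, net = net, sisters = sisters)
    } else {
      if (is.null(cfg$paths$stack) || is.null(cfg$paths$network))
        stop("synth disabled but paths$stack / paths$network not set")
      files <- sort(list.files(cfg$paths$stack, pattern = "\\.asc$",
                               full.names = TRUE))
      files <- files[!grepl("mask", basename(files))]
      stack <- grid_stack(lapply(files, read_grid),
                          names = sub("\\.asc$", "", basename(files)))
      mask <- if (!is.null(cfg$paths$mask))
        read_grid(cfg$paths$mask, categorical = TRUE) else NULL
      net <- polygons_to_centroids(read_network(cfg$paths$network),
                                   name = "home")
      sisters <- lapply(seq_along(cfg$paths$sisters), function(i)
        polygons_to_centroids(read_network(cfg$paths$sisters[[i]]),
                              name = paste0("sister_", i)))
      for (f in c(files, cfg$paths$mask, cfg$paths$network))
        manifest$files[[basename(f)]] <<- unname(tools::md5sum(f))
      list(stack = stack, mask = mask, net = net, sisters = sisters)
    }
  })

  fs <- stage("pca", function() {
    fs <- fit_pca(inputs$stack, standardize = cfg$pca$standardize)
    fs <- select_components(fs, cfg$pca$threshold)
    write_table(scree_table(fs), cfg$out, "scree.csv")
    ld <- as.data.frame(fs$loadings)
    ld <- cbind(layer = fs$layer_names, ld)
    write_table(ld, cfg$out, "loadings.csv")
    fs
  })

  rep <- stage("represent", function() {
    net <- sample_centroids(inputs$net, fs)
    res$net <<- net
    norm <- normalization_constant(
      fs, method = cfg$representativeness$norm_method, net = net)
    rep <- site_representativeness(
      net, fs, norm, aggregation = cfg$representativeness$aggregation,
      tile = cfg$representativeness$tile)
    cen <- cbind(net$centroids, as.data.frame(net$pc))
    write_table(cen, cfg$out, "centroids.csv")
    write_grid(rep$network, file.path(cfg$out, "network_representativeness.asc"))
    if (!is.null(inputs$mask)) {
      sm <- summarize_by_class(rep, inputs$mask)
      write_table(sm$table, cfg$out, "summary_by_class.csv")
      res$class_summary <<- sm
    }
    rep
  })

  cr <- stage("constituency", function() {
    if (is.null(inputs$mask))
      stop("no mask configured; constituency needs a working-lands mask")
    cr <- assign_constituency(rep, inputs$mask,
                              classes = cfg$constituency$classes,
                              top_n = cfg$constituency$top_n)
    write_grid(cr$winner, file.path(cfg$out, "constituency.asc"))
    write_table(constituency_areas(cr), cfg$out, "constituency_areas.csv")
    write_table(site_gradient_ranges(res$net, fs), cfg$out,
                "gradient_ranges.csv")
    write_table(classify_sites(cr,
                               area_quantile = cfg$constituency$area_quantile,
                               rep_floor = cfg$constituency$rep_floor),
                cfg$out, "site_classification.csv")
    write_table(cr$ranks, cfg$out, "constituency_ranks.csv")
    write_table(candidate_gaps(rep, inputs$mask,
                               classes = cfg$constituency$classes),
                cfg$out, "candidate_gaps.csv")
    cr
  })

  comp <- NULL
  if (isTRUE(cfg$complementarity$enabled)) {
    comp <- stage("complement", function() {
      if (length(inputs$sisters) < 1L)
        stop("complementarity enabled but no sister networks")
      sampled <- lapply(inputs$sisters, sample_centroids, fs = fs)
      comp <- best_network_map(c(list(res$net), sampled), fs, rep$norm,
                               mask = inputs$mask)
      write_grid(comp$improvement, file.path(cfg$out, "improvement.asc"))
      write_grid(comp$best_network, file.path(cfg$out, "best_network.asc"))
      write_table(comp$borrowed_sites, cfg$out, "borrowed_sites.csv")
      comp
    })
  }

  csvs <- list.files(cfg$out, pattern = "\\.(csv|asc)$", full.names = TRUE)
  for (f in csvs) manifest$files[[basename(f)]] <- unname(tools::md5sum(f))
  manifest$status <- "ok"
  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  manifest$results <- c(list(fs = fs, rep = rep, constituency = cr,
                             complementarity = comp, mask = inputs$mask,
                             stack = inputs$stack), res)
  invisible(manifest)
}
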