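#' Derive a per-stage RNG seed from the run seed
#'
#' Each pipeline stage draws its randomness from a substream keyed by
#' the global run seed and a fixed stage label, so enabling or
#' disabling one stage never perturbs another stage's random numbers.
#'
#' @param seed integer run seed.
#' @param label stage label string.
#' @return integer seed below 2^28.
#' @export
seedForStage <- function(seed, label) {
  strtoi(substr(digest::digest(paste0(seed, ":", label)), 1, 7), 16L)
}

.defaultRunConfig <- function() {
  list(seed = 1,
       stages = c("simulate", "link", "diffusion", "tessellate", "report"),
       simulate = list(),
       link = list(source = "linked", min_steps = 7),
       diffusion = list(n_points = 4, threshold = 0.01, log_base = 2,
                        binwidth = 1),
       tessellate = list(),
       report = list())
}

#' Run the analysis pipeline from a configuration
#'
#' Orchestrates simulate -> link -> diffusion + tessellation -> report
#' over a YAML (or list) configuration. Every output file is listed in
#' \code{manifest.json} together with its MD5, the configuration hash
#' and the run seed; rerunning with an identical configuration and seed
#' reproduces every CSV byte-identically. A failing stage leaves a
#' manifest marked \code{"incomplete"}.
#'
#' @param config path to a YAML file or a configuration list. Top-level
#'   keys: \code{seed}, \code{stages} (subset of simulate, link,
#'   diffusion, tessellate, report), \code{input} (paths when the
#'   simulate stage is off), and one block per stage with that stage's
#'   parameters (see [sptSimConfig()], [linkConfig()], [tessConfig()]).
#'   \code{link$source} is "linked" (link the localization table),
#'   "truth" (group by simulated molecule ids) or "detected" (render
#'   the simulated emission with the \code{render} block's parameters,
#'   detect spots, link the detections — the full image path).
#' @param out_dir output directory (created).
#' @param seed overrides the configuration seed when not NULL.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  base <- .defaultRunConfig()
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- utils::modifyList(base[[nm]], config[[nm]])
    else base[[nm]] <- config[[nm]]
  }
  cfg <- base
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "sptnano",
                   version = as.character(utils::packageVersion("sptnano")),
                   seed = cfg$seed,
                   config_hash = digest::digest(cfg),
                   stages = cfg$stages, status = "incomplete",
                   files = list())
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    manifest$files[[name]] <<- digest::digest(file = path)
    path
  }
  report <- list()
  locs <- NULL; truth <- NULL; tracks <- NULL
  sim_cfg <- NULL

  run <- function() {
    if ("simulate" %in% cfg$stages) {
      sim_cfg <<- do.call(sptSimConfig,
                          c(cfg$simulate,
                            list(seed = seedForStage(cfg$seed, "simulate"))))
      sim <- simulateTracks(sim_cfg)
      locs <<- sim$localizations
      truth <<- sim$truth
      emit("localizations.csv", function(p) writeLocalizations(locs, p))
      emit("ground_truth_molecules.csv", function(p)
        utils::write.csv(.sig9(truth$molecules), p, row.names = FALSE,
                         quote = FALSE))
    } else if (!is.null(cfg$input$localizations)) {
      locs <<- readLocalizations(cfg$input$localizations,
                                 column_map = cfg$input$column_map)
    }

    if ("link" %in% cfg$stages) {
      if (is.null(locs)) stop("link stage needs localizations")
      largs <- cfg$link[setdiff(names(cfg$link), c("source", "min_steps"))]
      lcfg <- do.call(linkConfig, largs)
      link_input <- locs
      if (identical(cfg$link$source, "detected")) {
        ## exercise the full image path: render the simulated emission,
        ## detect spots, and link the detections
        rargs <- if (is.null(cfg$render)) list() else cfg$render
        set.seed(seedForStage(cfg$seed, "render"))
        stack <- do.call(renderFrames, c(list(locs = locs), rargs))
        link_input <- detectSpots(stack, lcfg)
        emit("detections.csv", function(p)
          writeLocalizations(link_input, p))
      }
      all_tracks <- if (identical(cfg$link$source, "truth"))
        trueTracks(locs, max_gap = lcfg$max_gap)
      else linkTracks(link_input, lcfg)
      tracks <<- filterTracks(all_tracks, min_steps = cfg$link$min_steps)
      report$n_tracks_all <- nTracks(all_tracks)
      report$n_tracks_filtered <- nTracks(tracks)
      emit("tracks.csv", function(p) writeTracks(tracks, p))
      manifest$files[["tracks.json"]] <<-
        digest::digest(file = file.path(out_dir, "tracks.json"))
    }

    if ("diffusion" %in% cfg$stages) {
      if (is.null(tracks)) stop("diffusion stage needs tracks")
      dcfg <- cfg$diffusion
      dt <- if (!is.null(sim_cfg)) sim_cfg$frame_interval_s
            else cfg$diffusion$frame_interval_s
      if (is.null(dt)) stop("diffusion stage needs frame_interval_s")
      est <- fitTracksDiffusion(tracks, dt_s = dt,
                                n_points = dcfg$n_points,
                                threshold = dcfg$threshold)
      emit("diffusion.csv", function(p)
        utils::write.csv(.sig9(est), p, row.names = FALSE, quote = FALSE))
      if (nrow(est)) {
        frac <- immobileFraction(est, threshold = dcfg$threshold)
        report$immobile_fraction <- frac$overall
        report$n_tracks_fitted <- frac$n
        h <- diffusionHistogram(est$d_um2_s, log_base = dcfg$log_base,
                                binwidth = dcfg$binwidth)
        emit("diffusion_histogram.csv", function(p)
          utils::write.csv(.sig9(h), p, row.names = FALSE, quote = FALSE))
      }
    }

    if ("tessellate" %in% cfg$stages) {
      if (is.null(locs)) stop("tessellate stage needs localizations")
      targs <- cfg$tessellate[setdiff(names(cfg$tessellate), "region")]
      tcfg <- do.call(tessConfig, targs)
      merged <- mergeBlinkingDetections(locs, tcfg)
      region <- if (!is.null(cfg$tessellate$region))
        as.numeric(cfg$tessellate$region)
      else if (!is.null(sim_cfg)) c(0, sim_cfg$fov_um, 0, sim_cfg$fov_um)
      else NULL
      vmap <- voronoiDensities(merged, region = region,
                               avg_mode = tcfg$avg_mode)
      nds <- segmentNanodomains(vmap, tcfg)
      met <- nanodomainMetrics(nds, vmap)
      report$n_domains <- met$n_domains
      report$relative_count <- met$relative_count
      report$domain_density_um2 <- met$domain_density_um2
      report$mean_diameter_um <- met$mean_diameter_um
      emit("voronoi_density.csv", function(p)
        utils::write.csv(.sig9(data.frame(x_um = vmap@points[, 1],
                                          y_um = vmap@points[, 2],
                                          area_um2 = vmap@area,
                                          density_um2 = vmap@density,
                                          border = vmap@border)),
                         p, row.names = FALSE, quote = FALSE))
      emit("nanodomains.csv", function(p)
        utils::write.csv(.sig9(domains(nds)), p, row.names = FALSE,
                         quote = FALSE))
    }

    if ("report" %in% cfg$stages && length(report)) {
      rep_df <- data.frame(metric = names(report),
                           value = vapply(report, function(v)
                             signif(as.numeric(v), 9), numeric(1)))
      emit("report.csv", function(p)
        utils::write.csv(rep_df, p, row.names = FALSE, quote = FALSE))
    }
  }

  ok <- tryCatch({ run(); TRUE },
                 error = function(e) { manifest$error <<- conditionMessage(e)
                                       FALSE })
  manifest$status <- if (ok) "complete" else "incomplete"
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!ok) stop("pipeline failed: ", manifest$error)
  invisible(manifest)
}

## brute-force oracles used to compute fixture expectations; deliberately
## naive and independent of the analysis implementations
.bruteMSD <- function(frame, x, y, dt_s) {
  ks <- sort(unique(as.vector(outer(frame, frame, "-"))))
  ks <- ks[ks > 0]
  res <- lapply(ks, function(k) {
    s <- 0; n <- 0L
    for (i in seq_along(frame)) for (j in seq_along(frame)) {
      if (frame[j] - frame[i] == k) {
        s <- s + (x[j] - x[i])^2 + (y[j] - y[i])^2
        n <- n + 1L
      }
    }
    c(lag_s = k * dt_s, msd_um2 = s / n, n_pairs = n)
  })
  as.data.frame(do.call(rbind, res))
}

#' Generate the deterministic toy fixtures used in examples and tests
#'
#' Writes small instances with expected values computed by brute-force
#' oracles (exhaustive pair enumeration, closed forms, construction
#' ground truth): a square grid pattern, a ballistic track, a
#' two-molecule linking case, a single clustered blob and a 25-spot
#' rendered image.
#'
#' @param out_dir writable output directory.
#' @return invisibly, the vector of written file paths.
#' @export
makeFixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(name) { p <- file.path(out_dir, name)
                          paths <<- c(paths, p); p }

  ## 1. square grid: interior Voronoi cells are s x s squares
  s <- 0.5
  g <- expand.grid(x = s / 2 + s * 0:5, y = s / 2 + s * 0:5)
  grid_locs <- data.frame(frame = 0L, x_um = g$x, y_um = g$y,
                          intensity = 1, sigma_um = 0, molecule_id = -1L)
  writeLocalizations(grid_locs, put("grid_pattern.csv"))
  jsonlite::write_json(list(spacing_um = s, region = c(0, 6 * s, 0, 6 * s),
                            interior_cell_area_um2 = s^2,
                            interior_density_um2 = 1 / s^2),
                       put("grid_expected.json"), auto_unbox = TRUE,
                       digits = NA)

  ## 2. ballistic track x = v t, v = 1 um/s, dt = 30 ms
  dt <- 0.03; v <- 1
  bt <- data.frame(frame = 0:8, x_um = v * (0:8) * dt, y_um = 0,
                   intensity = 1, sigma_um = 0, molecule_id = 1L)
  writeLocalizations(bt, put("ballistic_track.csv"))
  jsonlite::write_json(.bruteMSD(bt$frame, bt$x_um, bt$y_um, dt),
                       put("ballistic_msd_expected.json"),
                       auto_unbox = TRUE, digits = NA)

  ## 3. two parallel molecules separated by 10x the linking radius
  max_disp <- 0.4
  tm <- data.frame(frame = rep(0:99, 2),
                   x_um = c(0.05 * 0:99, 0.05 * 0:99),
                   y_um = rep(c(1, 1 + 10 * max_disp), each = 100),
                   intensity = 1, sigma_um = 0,
                   molecule_id = rep(1:2, each = 100))
  writeLocalizations(tm, put("two_molecule_linking.csv"))
  jsonlite::write_json(list(max_disp_um = max_disp, n_tracks = 2,
                            n_locs_per_track = 100),
                       put("two_molecule_expected.json"),
                       auto_unbox = TRUE, digits = NA)

  ## 4. one dense blob over sparse background
  blob <- simulatePattern(patternSimConfig(mode = "thomas",
                                           region_um = c(0, 4, 0, 4),
                                           background_intensity = 2,
                                           n_clusters = 1,
                                           points_per_cluster_mean = 60,
                                           cluster_sigma_um = 0.04,
                                           seed = 421))
  writeLocalizations(blob$localizations, put("single_blob.csv"))
  jsonlite::write_json(list(n_true_clusters = 1,
                            n_blob_points =
                              sum(blob$truth$points$cluster_id == 1),
                            region = c(0, 4, 0, 4)),
                       put("single_blob_expected.json"),
                       auto_unbox = TRUE, digits = NA)

  ## 5. 25 well-separated rendered spots, noise-free
  gs <- expand.grid(x = 1 + 0:4 * 1.2, y = 1 + 0:4 * 1.2)
  spots <- data.frame(frame = 0L, x_um = gs$x, y_um = gs$y,
                      intensity = 1, sigma_um = 0, molecule_id = -1L)
  stack <- renderFrames(spots, psf_sigma_um = 0.15, photons = 500,
                        bg_level = 0, pixel_um = 0.1, dims = c(72, 72),
                        noise = FALSE)
  writeImageStack(stack, put("spots25.tif"))
  writeLocalizations(spots, put("spots25_truth.csv"))
  jsonlite::write_json(list(n_spots = 25, photons = 500,
                            psf_sigma_um = 0.15, pixel_um = 0.1),
                       put("spots25_expected.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
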