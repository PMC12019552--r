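## Plain-text interchange. All floating point CSV output is rounded to 9
## significant digits so that identical runs are byte-identical.

.sig9 <- function(df) {
  for (nm in names(df)) if (is.double(df[[nm]])) df[[nm]] <- signif(df[[nm]], 9)
  df
}

.LOC_COLS <- c("frame", "x_um", "y_um", "intensity", "sigma_um",
               "molecule_id")

#' Write / read localization tables
#'
#' CSV with header \code{frame,x_um,y_um,intensity,sigma_um,molecule_id}
#' (molecule_id = -1 when unknown). \code{readLocalizations} accepts
#' foreign spot exports (e.g. TrackMate CSVs) through \code{column_map},
#' a named character vector mapping package column names to file column
#' names; unmapped optional columns get defaults.
#'
#' @param locs localization data.frame.
#' @param path file path.
#' @param column_map named character vector, e.g.
#'   \code{c(frame = "FRAME", x_um = "POSITION_X", y_um = "POSITION_Y")}.
#' @return \code{readLocalizations}: a localization data.frame.
#' @export
writeLocalizations <- function(locs, path) {
  utils::write.csv(.sig9(locs[, intersect(c(.LOC_COLS, "track_id",
                                            "n_merged"), names(locs)),
                              drop = FALSE]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLocalizations
#' @export
readLocalizations <- function(path, column_map = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      if (!column_map[[nm]] %in% names(raw))
        stop("mapped column '", column_map[[nm]], "' not found in ", path)
      raw[[nm]] <- raw[[column_map[[nm]]]]
    }
  }
  need <- c("frame", "x_um", "y_um")
  if (!all(need %in% names(raw)))
    stop("localization table must provide columns: ",
         paste(need, collapse = ", "), " (use column_map for foreign files)")
  out <- data.frame(frame = as.integer(raw$frame), x_um = raw$x_um,
                    y_um = raw$y_um)
  out$intensity <- if ("intensity" %in% names(raw)) raw$intensity else 1
  out$sigma_um <- if ("sigma_um" %in% names(raw)) raw$sigma_um else 0
  out$molecule_id <- if ("molecule_id" %in% names(raw))
    as.integer(raw$molecule_id) else -1L
  out
}

#' Write / read track sets
#'
#' Tracks travel as a CSV of \code{track_id,frame,x_um,y_um} plus an
#' optional JSON sidecar holding per-track metadata (step counts and
#' bridged gap lengths). Without the sidecar, metadata is rebuilt from
#' the CSV (gaps inferred from missing frames).
#'
#' @param tracks a [TrackSet-class].
#' @param path CSV path; the sidecar defaults to the same path with a
#'   ".json" extension.
#' @param json_path sidecar path or NULL to skip/derive.
#' @return \code{readTracks}: a [TrackSet-class].
#' @export
writeTracks <- function(tracks, path, json_path = sub("\\.csv$", ".json",
                                                      path)) {
  stopifnot(is(tracks, "TrackSet"))
  locs <- localizations(tracks)
  linked <- locs[!is.na(locs$track_id), , drop = FALSE]
  out <- .sig9(linked[order(linked$track_id, linked$frame),
                      c("track_id", "frame", "x_um", "y_um"), drop = FALSE])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    info <- trackInfo(tracks)
    meta <- lapply(seq_len(nrow(info)), function(i)
      list(track_id = info$track_id[i], n_locs = info$n_locs[i],
           n_steps = info$n_steps[i],
           gaps = as.integer(info$gaps[[i]])))
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeTracks
#' @export
readTracks <- function(path, json_path = sub("\\.csv$", ".json", path)) {
  tab <- utils::read.csv(path)
  tab <- tab[order(tab$track_id, tab$frame), , drop = FALSE]
  locs <- data.frame(frame = as.integer(tab$frame), x_um = tab$x_um,
                     y_um = tab$y_um, intensity = 1, sigma_um = 0,
                     molecule_id = -1L,
                     track_id = as.integer(tab$track_id))
  ids <- sort(unique(locs$track_id))
  gap_rec <- vector("list", if (length(ids)) max(ids) else 0L)
  if (!is.null(json_path) && file.exists(json_path)) {
    meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    if (is.data.frame(meta)) for (i in seq_len(nrow(meta)))
      gap_rec[[meta$track_id[i]]] <- as.integer(unlist(meta$gaps[i]))
  } else {
    for (id in ids) {
      g <- diff(locs$frame[locs$track_id == id]) - 1L
      gap_rec[[id]] <- g[g > 0]
    }
  }
  for (i in seq_along(gap_rec))
    if (is.null(gap_rec[[i]])) gap_rec[[i]] <- integer(0)
  .makeTrackSet(locs, locs$track_id, gap_rec)
}

#' Read / write image stacks as multi-page TIFF
#'
#' Pixel values are stored as 16-bit unsigned integers; intensities
#' above 65535 are clipped on write with a warning.
#'
#' @param path TIFF path.
#' @param pixel_um physical pixel size, µm.
#' @param channel channel label.
#' @param stack an [ImageStack-class].
#' @return \code{readImageStack}: an [ImageStack-class].
#' @export
readImageStack <- function(path, pixel_um = 0.1, channel = "unknown") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                          length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  methods::new("ImageStack", data = arr, pixelUm = pixel_um,
               channel = channel)
}

#' @rdname readImageStack
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  d <- stack@data
  if (any(d > 65535)) {
    warning("intensities above 65535 clipped on 16-bit write")
    d[d > 65535] <- 65535
  }
  pages <- lapply(seq_len(dim(d)[3]), function(i)
    round(d[, , i]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read / write run configuration as YAML
#'
#' @param path YAML file path.
#' @param config a configuration list.
#' @return \code{readRunConfig}: the configuration list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
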