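## Blinking-tolerant trajectory linking. Assignment is greedy by globally
## shortest link first within each frame: all admissible (track end, new
## localization) pairs are ranked by distance and consumed in order. Track
## ends left unmatched stay open for up to max_gap dark frames, with a
## search radius growing with the gap length.

#' Link localizations into trajectories
#'
#' Frame-to-frame nearest-neighbour linking with gap closing: a track
#' end unmatched for g dark frames (g <= \code{max_gap}) may capture a
#' localization within \code{max_disp_um * (g + 1)} (linear scaling;
#' "sqrt" scaling available via the config). Ambiguities are resolved by
#' assigning the globally shortest admissible link first. Duplicate
#' (frame, x, y) rows are collapsed with a warning.
#'
#' @param locs localization data.frame (\code{frame, x_um, y_um}, other
#'   columns carried through).
#' @param cfg a [linkConfig()].
#' @return a [TrackSet-class]; track ids are dense integers starting at
#'   1, in order of track creation.
#' @export
linkTracks <- function(locs, cfg = linkConfig()) {
  stopifnot(is.data.frame(locs),
            all(c("frame", "x_um", "y_um") %in% names(locs)))
  dup <- duplicated(locs[, c("frame", "x_um", "y_um")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (frame, position) row(s) collapsed")
    locs <- locs[!dup, , drop = FALSE]
  }
  locs$frame <- as.integer(locs$frame)
  locs <- locs[order(locs$frame), , drop = FALSE]
  rownames(locs) <- NULL
  n <- nrow(locs)
  track_of <- rep(NA_integer_, n)
  if (n == 0L)
    return(.makeTrackSet(locs, track_of, list()))

  frames <- unique(locs$frame)
  ## open track ends
  end_x <- end_y <- numeric(0)
  end_f <- end_tid <- integer(0)
  n_tracks <- 0L
  gap_rec <- list()   # per-track integer vector of bridged gap lengths

  radius <- function(gap) {
    if (cfg$gap_radius_scaling == "linear") cfg$max_disp_um * (gap + 1)
    else cfg$max_disp_um * sqrt(gap + 1)
  }

  for (f in frames) {
    rows <- which(locs$frame == f)
    px <- locs$x_um[rows]; py <- locs$y_um[rows]
    live <- which(end_f >= f - 1L - cfg$max_gap)
    assigned_pt <- rep(FALSE, length(rows))
    if (length(live)) {
      gaps <- f - end_f[live] - 1L
      dmat <- sqrt(outer(end_x[live], px, "-")^2 +
                     outer(end_y[live], py, "-")^2)
      dmat[dmat > matrix(radius(gaps), length(live), length(rows))] <- Inf
      while (any(is.finite(dmat))) {
        k <- arrayInd(which.min(dmat), dim(dmat))
        e <- k[1]; p <- k[2]
        tid <- end_tid[live[e]]
        track_of[rows[p]] <- tid
        g <- f - end_f[live[e]] - 1L
        if (g > 0L) gap_rec[[tid]] <- c(gap_rec[[tid]], g)
        end_x[live[e]] <- px[p]; end_y[live[e]] <- py[p]
        end_f[live[e]] <- f
        assigned_pt[p] <- TRUE
        dmat[e, ] <- Inf; dmat[, p] <- Inf
      }
    }
    new_pts <- which(!assigned_pt)
    if (length(new_pts)) {
      ids <- n_tracks + seq_along(new_pts)
      n_tracks <- n_tracks + length(new_pts)
      for (tid in ids) gap_rec[[tid]] <- integer(0)
      track_of[rows[new_pts]] <- ids
      end_x <- c(end_x, px[new_pts]); end_y <- c(end_y, py[new_pts])
      end_f <- c(end_f, rep(f, length(new_pts)))
      end_tid <- c(end_tid, ids)
    }
    ## ends stale beyond the gap tolerance can never match again
    fresh <- end_f >= f - cfg$max_gap
    end_x <- end_x[fresh]; end_y <- end_y[fresh]
    end_f <- end_f[fresh]; end_tid <- end_tid[fresh]
  }
  .makeTrackSet(locs, track_of, gap_rec)
}

.makeTrackSet <- function(locs, track_of, gap_rec) {
  locs$track_id <- track_of
  n_tracks <- length(gap_rec)
  if (n_tracks) {
    cnt <- tabulate(track_of[!is.na(track_of)], nbins = n_tracks)
    info <- data.frame(track_id = seq_len(n_tracks), n_locs = cnt,
                       n_steps = cnt - 1L)
    info$gaps <- unname(gap_rec)
  } else {
    info <- data.frame(track_id = integer(), n_locs = integer(),
                       n_steps = integer())
    info$gaps <- list()
  }
  methods::new("TrackSet", localizations = locs, trackInfo = info)
}

#' Build ground-truth tracks from simulated molecule identities
#'
#' Groups localizations by their true molecule id (ignoring rows with
#' molecule_id < 1), optionally splitting a molecule's trajectory where
#' the dark gap exceeds \code{max_gap} — the same contract the linker
#' obeys, so ground-truth and linked tracks are comparable.
#'
#' @param locs localization data.frame with a valid \code{molecule_id}.
#' @param max_gap split tracks at dark gaps longer than this
#'   (default Inf: one track per molecule).
#' @return a [TrackSet-class].
#' @export
trueTracks <- function(locs, max_gap = Inf) {
  locs <- locs[order(locs$molecule_id, locs$frame), , drop = FALSE]
  rownames(locs) <- NULL
    locs$frame <- as.integer(locs$frame)
  known <- !is.na(locs$molecule_id) & locs$molecule_id >= 1
  track_of <- rep(NA_integer_, nrow(locs))
  tid <- 0L
  gap_rec <- list()
  idx <- which(known)
  if (length(idx)) {
    mol <- locs$molecule_id[idx]
    frm <- locs$frame[idx]
    new_mol <- c(TRUE, mol[-1] != mol[-length(mol)])
    gap <- c(0L, diff(frm)) - 1L
    brk <- new_mol | gap > max_gap
    ids <- cumsum(brk)
    track_of[idx] <- ids
    tid <- max(ids)
    for (t in seq_len(tid)) {
      g <- gap[ids == t & !brk]
      gap_rec[[t]] <- as.integer(g[g > 0])
    }
  }
  .makeTrackSet(locs, track_of, gap_rec)
}

#' Filter tracks by minimum step count
#'
#' Keeps exactly the tracks with at least \code{min_steps} links
#' (a 7-step track has 8 localizations); order and track ids are
#' preserved. Localizations of removed tracks are dropped.
#'
#' @param tracks a [TrackSet-class].
#' @param min_steps minimum number of inter-localization links.
#' @return the filtered [TrackSet-class].
#' @export
filterTracks <- function(tracks, min_steps = 7) {
  stopifnot(is(tracks, "TrackSet"))
  info <- trackInfo(tracks)
  keep <- info$n_steps >= min_steps
  info <- info[keep, , drop = FALSE]
  rownames(info) <- NULL
  locs <- localizations(tracks)
  locs <- locs[!is.na(locs$track_id) & locs$track_id %in% info$track_id, ,
               drop = FALSE]
  rownames(locs) <- NULL
  methods::new("TrackSet", localizations = locs, trackInfo = info)
}

#' Extract one track's localizations
#'
#' @param tracks a [TrackSet-class].
#' @param id track id.
#' @return data.frame of the track's localizations, ordered by frame.
#' @export
getTrack <- function(tracks, id) {
  locs <- localizations(tracks)
  out <- locs[!is.na(locs$track_id) & locs$track_id == id, , drop = FALSE]
  out[order(out$frame), , drop = FALSE]
}
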