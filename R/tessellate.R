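#' Merge repeated detections of blinking emitters
#'
#' A single fluorophore localized in several consecutive (or
#' gap-bridged, up to \code{merge_max_gap_frames} dark frames) frames
#' within \code{merge_radius_um} is collapsed to one molecule position:
#' the intensity-weighted mean of its detections. Detections in the
#' same frame never merge. The output has at most as many rows as the
#' input.
#'
#' @param locs localization data.frame (\code{frame, x_um, y_um,
#'   intensity}; \code{molecule_id} carried from the first detection).
#' @param cfg a [tessConfig()].
#' @return merged localization data.frame, one row per emitter, with
#'   \code{frame} = first detection frame, \code{intensity} = summed
#'   weight and \code{n_merged} = number of collapsed detections.
#' @export
mergeBlinkingDetections <- function(locs, cfg = tessConfig()) {
  n <- nrow(locs)
  if (n == 0L) return(cbind(locs, n_merged = integer(0)))
  o <- order(locs$frame)
  frame <- locs$frame[o]; x <- locs$x_um[o]; y <- locs$y_um[o]
  w <- locs$intensity[o]
  w[!is.finite(w) | w <= 0] <- 1
  sig <- if ("sigma_um" %in% names(locs)) locs$sigma_um[o] else rep(0, n)
  mol <- if ("molecule_id" %in% names(locs)) locs$molecule_id[o] else
    rep(-1L, n)

  mx <- my <- mw <- msig <- numeric(n)   # emitter accumulators
  first_f <- last_f <- integer(n)
  mmol <- integer(n); nm <- integer(n)
  n_em <- 0L
  act <- integer(0)   # indices of emitters still eligible for merging

  for (f in unique(frame)) {
    rows <- which(frame == f)
    act <- act[last_f[act] >= f - 1L - cfg$merge_max_gap_frames]
    taken <- rep(FALSE, length(act))
    new_em <- integer(0)
    for (p in rows) {
      merged <- FALSE
      if (length(act)) {
        cand <- which(!taken & last_f[act] < f)
        if (length(cand)) {
          d2 <- (mx[act[cand]] / mw[act[cand]] - x[p])^2 +
            (my[act[cand]] / mw[act[cand]] - y[p])^2
          j <- cand[which.min(d2)]
          if (min(d2) <= cfg$merge_radius_um^2) {
            e <- act[j]
            mx[e] <- mx[e] + w[p] * x[p]
            my[e] <- my[e] + w[p] * y[p]
            mw[e] <- mw[e] + w[p]
            msig[e] <- msig[e] + sig[p]
            last_f[e] <- f
            nm[e] <- nm[e] + 1L
            taken[j] <- TRUE
            merged <- TRUE
          }
        }
      }
      if (!merged) {
        n_em <- n_em + 1L
        mx[n_em] <- w[p] * x[p]; my[n_em] <- w[p] * y[p]; mw[n_em] <- w[p]
        msig[n_em] <- sig[p]
        first_f[n_em] <- f; last_f[n_em] <- f
        mmol[n_em] <- mol[p]; nm[n_em] <- 1L
        new_em <- c(new_em, n_em)
      }
    }
    act <- c(act, new_em)
  }
  i <- seq_len(n_em)
  out <- data.frame(frame = first_f[i], x_um = mx[i] / mw[i],
                    y_um = my[i] / mw[i], intensity = mw[i],
                    sigma_um = msig[i] / nm[i], molecule_id = mmol[i],
                    n_merged = nm[i])
  rownames(out) <- NULL
  out
}

#' Voronoi tessellation and per-localization local density
#'
#' Tessellates the plane over the analysis rectangle; every cell is
#' clipped to the rectangle, so the clipped areas sum exactly to the
#' region area and sparse edge molecules still contribute. The local
#' density of localization i is 1/area of its clipped cell; the average
#' density is N / region area by default ("global"), or the mean of the
#' local densities ("per_point").
#'
#' @param locs localization data.frame (\code{x_um, y_um}) or a
#'   two-column matrix.
#' @param region rectangle \code{c(xmin, xmax, ymin, ymax)} in µm;
#'   default: bounding box of the points.
#' @param avg_mode "global" or "per_point".
#' @return a [VoronoiMap-class]. Duplicated positions are collapsed
#'   with a warning (merge detections first); all-collinear input is
#'   rejected.
#' @export
voronoiDensities <- function(locs, region = NULL,
                             avg_mode = c("global", "per_point")) {
  avg_mode <- match.arg(avg_mode)
  xy <- if (is.matrix(locs)) locs else cbind(locs$x_um, locs$y_um)
  if (anyDuplicated(xy)) {
    warning(sum(duplicated(xy)),
            " duplicated position(s) collapsed before tessellation")
    xy <- xy[!duplicated(xy), , drop = FALSE]
  }
  n <- nrow(xy)
  if (n < 3L) stop("at least 3 points required for a tessellation")
  sv <- svd(scale(xy, center = TRUE, scale = FALSE))$d
  if (sv[2] < 1e-12 * max(sv[1], 1))
    stop("all points are collinear; tessellation undefined")
  if (is.null(region))
    region <- c(min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2]))
  if (any(xy[, 1] < region[1] | xy[, 1] > region[2] |
          xy[, 2] < region[3] | xy[, 2] > region[4]))
    stop("points outside the analysis region")

  dd <- deldir::deldir(xy[, 1], xy[, 2], rw = region)
  area <- dd$summary$dir.area
  seg <- dd$dirsgs
  on_border <- unique(c(seg$ind1[seg$bp1 | seg$bp2],
                        seg$ind2[seg$bp1 | seg$bp2]))
  border <- seq_len(n) %in% on_border
  density <- 1 / area
  region_area <- (region[2] - region[1]) * (region[4] - region[3])
  avg <- if (avg_mode == "global") n / region_area else mean(density)
  methods::new("VoronoiMap", points = unname(xy), area = area,
               density = density, border = border, region = region,
               avgDensity = avg, avgMode = avg_mode,
               adjacency = cbind(seg$ind1, seg$ind2))
}

#' Segment nanodomains from a Voronoi density map
#'
#' Seed localizations are those whose local density exceeds
#' \code{density_factor} times the average density of the region.
#' Nanodomains are the connected components of the seed set under
#' Voronoi-cell adjacency, kept when they contain at least
#' \code{min_detections} localizations. Domain area is the sum of
#' member cell areas and the size measure is the equivalent circular
#' diameter 2 sqrt(area / pi).
#'
#' @param vmap a [VoronoiMap-class].
#' @param cfg a [tessConfig()].
#' @return a [NanodomainSet-class] (possibly empty).
#' @export
segmentNanodomains <- function(vmap, cfg = tessConfig()) {
  stopifnot(is(vmap, "VoronoiMap"))
  n <- nrow(vmap@points)
  seeds <- which(vmap@density > cfg$density_factor * vmap@avgDensity)
  assignment <- rep(NA_integer_, n)
  empty <- data.frame(domain_id = integer(), n_detections = integer(),
                      area_um2 = numeric(), equiv_diameter_um = numeric(),
                      cx_um = numeric(), cy_um = numeric())
  if (!length(seeds))
    return(methods::new("NanodomainSet", domains = empty, members = list(),
                        assignment = assignment, region = vmap@region,
                        config = unclass(cfg)))
  adj <- vmap@adjacency
  in_seed <- adj[, 1] %in% seeds & adj[, 2] %in% seeds
  edges <- adj[in_seed, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]),
               to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(seeds)))
  comp <- igraph::components(g)$membership
  comp_of <- comp[as.character(seeds)]

  members <- split(seeds, comp_of)
  members <- members[lengths(members) >= cfg$min_detections]
  if (!length(members))
    return(methods::new("NanodomainSet", domains = empty, members = list(),
                        assignment = assignment, region = vmap@region,
                        config = unclass(cfg)))
  ## stable ordering: by first member index
  members <- members[order(vapply(members, min, numeric(1)))]
  names(members) <- NULL
  areas <- vapply(members, function(m) sum(vmap@area[m]), numeric(1))
  dom <- data.frame(domain_id = seq_along(members),
                    n_detections = lengths(members),
                    area_um2 = areas,
                    equiv_diameter_um = 2 * sqrt(areas / pi),
                    cx_um = vapply(members, function(m)
                      mean(vmap@points[m, 1]), numeric(1)),
                    cy_um = vapply(members, function(m)
                      mean(vmap@points[m, 2]), numeric(1)))
  for (i in seq_along(members)) assignment[members[[i]]] <- i
  methods::new("NanodomainSet", domains = dom, members = members,
               assignment = assignment, region = vmap@region,
               config = unclass(cfg))
}

#' Summary metrics of a nanodomain segmentation
#'
#' The three per-region readouts: mean equivalent diameter of the
#' domains (size; NA when no domain), relative number of molecules in
#' domains (summed domain detections over all tessellated
#' localizations), and domain density (domains per µm² of analysis
#' region).
#'
#' @param nds a [NanodomainSet-class].
#' @param vmap the [VoronoiMap-class] the segmentation was derived from.
#' @return one-row data.frame \code{n_domains, mean_diameter_um,
#'   relative_count, domain_density_um2}.
#' @export
nanodomainMetrics <- function(nds, vmap) {
  stopifnot(is(nds, "NanodomainSet"), is(vmap, "VoronoiMap"))
  if (length(nds@assignment) != nrow(vmap@points))
    stop("segmentation and density map refer to different point sets")
  n_total <- nrow(vmap@points)
  r <- vmap@region
  region_area <- (r[2] - r[1]) * (r[4] - r[3])
  nd <- nrow(nds@domains)
  data.frame(n_domains = nd,
             mean_diameter_um = if (nd) mean(nds@domains$equiv_diameter_um)
                                else NA_real_,
             relative_count = if (nd) sum(nds@domains$n_detections) / n_total
                              else 0,
             domain_density_um2 = nd / region_area)
}
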