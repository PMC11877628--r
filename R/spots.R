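#' Spot detection and photometry parameters
#'
#' @param min_peak_prominence Minimum height of a local maximum above the
#'   frame's median background, in counts. The default (150) sits more than
#'   ten shot-noise standard deviations above the default simulated
#'   background (2 x 100 counts in the summed frame), so pure-noise maxima
#'   essentially never qualify, yet it is less than half the peak amplitude
#'   of the dimmest particle of the default population at the default
#'   photon budget.
#' @param local_max_window Odd window size (pixels) within which a peak must
#'   be the brightest pixel.
#' @param measure_radius Radius (pixels) of the photometry disk.
#' @param background_annulus Inner and outer radii (pixels) of the local
#'   background annulus; the inner radius must exceed `measure_radius`.
#' @param max_area Pixel-area threshold above which a spot is excluded as an
#'   aggregate. `NULL` means "not yet calibrated"; see
#'   [calibrate_max_area()]. The recommended value is the 99.5th percentile
#'   of single-particle areas measured on an aggregate-free negative-control
#'   render.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(min_peak_prominence = 150, local_max_window = 5,
                             measure_radius = 5,
                             background_annulus = c(7, 10),
                             max_area = NULL) {
  local_max_window <- as.integer(local_max_window)
  if (local_max_window < 3L || local_max_window %% 2L == 0L) {
    stop("local_max_window must be an odd integer >= 3", call. = FALSE)
  }
  if (!(background_annulus[1] > measure_radius &&
        background_annulus[2] > background_annulus[1])) {
    stop("radii must satisfy measure_radius < inner < outer", call. = FALSE)
  }
  structure(
    list(min_peak_prominence = min_peak_prominence,
         local_max_window = local_max_window,
         measure_radius = measure_radius,
         background_annulus = as.numeric(background_annulus),
         max_area = max_area),
    class = "detection_params"
  )
}

# shift a matrix by (dr, dc), padding with -Inf
.shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(-Inf, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# grey dilation: maximum over a w x w window, via shifted pmax
.local_max_filter <- function(m, w) {
  h <- (w - 1L) %/% 2L
  # separable: max over rows then columns
  rowmax <- m
  for (dr in seq_len(h)) {
    rowmax <- pmax(rowmax, .shift_matrix(m, dr, 0), .shift_matrix(m, -dr, 0))
  }
  out <- rowmax
  for (dc in seq_len(h)) {
    out <- pmax(out, .shift_matrix(rowmax, 0, dc), .shift_matrix(rowmax, 0, -dc))
  }
  out
}

#' Detect candidate nanoparticle spots in a summed frame
#'
#' Finds local maxima of the (R+G) frame: pixels that equal the maximum of
#' their `local_max_window` neighbourhood and rise at least
#' `min_peak_prominence` counts above the frame's median (a robust estimate
#' of the empty background, since spots occupy a small fraction of the
#' field). Flat plateaus of tied maxima and maxima closer together than the
#' window are merged to their intensity-weighted centroid. Peaks are
#' returned sorted by intensity, brightest first.
#'
#' @param sum_frame Numeric matrix (typically R + G).
#' @param params A [detection_params()].
#' @return Data frame with `row`, `col` (pixel positions, 1-based) and
#'   `value` (peak counts), possibly empty.
#' @export
detect_spots <- function(sum_frame, params = detection_params()) {
  stopifnot(is.matrix(sum_frame))
  if (any(!is.finite(sum_frame))) {
    stop("frame must be finite", call. = FALSE)
  }
  bg <- stats::median(sum_frame)
  dil <- .local_max_filter(sum_frame, params$local_max_window)
  cand <- which(sum_frame == dil &
                  (sum_frame - bg) >= params$min_peak_prominence,
                arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(data.frame(row = numeric(0), col = numeric(0), value = numeric(0)))
  }
  vals <- sum_frame[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  # greedy clustering: merge candidates within the window of a brighter one
  w <- params$local_max_window
  keep_row <- numeric(0)
  keep_col <- numeric(0)
  keep_val <- numeric(0)
  grp_w <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]
    cc <- cand[i, 2]
    v <- vals[i]
    merged <- FALSE
    if (length(keep_row) > 0L) {
      j <- which(abs(keep_row / grp_w - r) < w & abs(keep_col / grp_w - cc) < w)
      if (length(j) > 0L) {
        j <- j[1L]
        keep_row[j] <- keep_row[j] + r * v
        keep_col[j] <- keep_col[j] + cc * v
        grp_w[j] <- grp_w[j] + v
        merged <- TRUE
      }
    }
    if (!merged) {
      keep_row <- c(keep_row, r * v)
      keep_col <- c(keep_col, cc * v)
      grp_w <- c(grp_w, v)
      keep_val <- c(keep_val, v)
    }
  }
  data.frame(row = round(keep_row / grp_w), col = round(keep_col / grp_w),
             value = keep_val)
}

# offsets of pixels within a radius (and an annulus) of a centre pixel;
# memoised, since they only depend on the radii
.disk_offsets <- function(radius) {
  key <- paste0("disk_", radius)
  hit <- .nanochrome_cache$offsets[[key]]
  if (!is.null(hit)) return(hit)
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  out <- g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
  if (is.null(.nanochrome_cache$offsets)) .nanochrome_cache$offsets <- list()
  .nanochrome_cache$offsets[[key]] <- out
  out
}

.annulus_offsets <- function(inner, outer) {
  key <- paste0("ann_", inner, "_", outer)
  hit <- .nanochrome_cache$offsets[[key]]
  if (!is.null(hit)) return(hit)
  r <- ceiling(outer)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  d2 <- g$dr^2 + g$dc^2
  out <- g[d2 > inner^2 & d2 <= outer^2, , drop = FALSE]
  if (is.null(.nanochrome_cache$offsets)) .nanochrome_cache$offsets <- list()
  .nanochrome_cache$offsets[[key]] <- out
  out
}

#' Photometer one detected spot in both channels
#'
#' Sums pixel counts within `measure_radius` of the peak in each channel and
#' subtracts the local background, estimated as the median of the
#' surrounding annulus times the disk area. The spot's pixel area is its
#' half-maximum footprint: the number of disk pixels (in the summed frame)
#' exceeding the annulus median plus half the background-subtracted peak
#' amplitude. Thresholding at half maximum rather than at a fixed multiple
#' of the background noise makes the area measure the spot's spatial extent
#' independently of its brightness -- essential here, because single-
#' particle brightness spans two orders of magnitude (d^6) while aggregates
#' differ from singles in footprint, not only in intensity. The centroid is
#' intensity-weighted over the background-subtracted disk. Peaks too close
#' to the frame edge for a complete annulus are flagged `excluded` with
#' reason `"edge"`; spots with non-positive total intensity are flagged
#' `"nonpositive"`.
#'
#' @param r_frame,g_frame Numeric matrices of the two channels.
#' @param peak One-row data frame (or list) with `row` and `col`.
#' @param params A [detection_params()].
#' @return One-row data frame: `row`, `col` (sub-pixel centroid), `area`
#'   (pixels), `r_scat`, `g_scat` (background-subtracted counts), `gamma`,
#'   `excluded`, `reason`.
#' @export
measure_spot <- function(r_frame, g_frame, peak, params = detection_params()) {
  m <- .measure_peaks(r_frame, g_frame,
                      data.frame(row = peak$row, col = peak$col), params)
  m
}

# batch photometry of all peaks in one frame; returns a data frame
.measure_peaks <- function(r_frame, g_frame, peaks, params) {
  n <- nrow(peaks)
  outer <- params$background_annulus[2]
  disk <- .disk_offsets(params$measure_radius)
  ann <- .annulus_offsets(params$background_annulus[1],
                          params$background_annulus[2])
  n_px <- nrow(disk)
  row_c <- col_c <- area <- r_s <- g_s <- gam <- rep(NA_real_, n)
  excl <- rep(FALSE, n)
  reason <- rep("", n)
  nr <- nrow(r_frame)
  nc <- ncol(r_frame)
  for (i in seq_len(n)) {
    r0 <- peaks$row[i]
    c0 <- peaks$col[i]
    row_c[i] <- r0
    col_c[i] <- c0
    if (r0 - outer < 1 || r0 + outer > nr || c0 - outer < 1 ||
        c0 + outer > nc) {
      excl[i] <- TRUE
      reason[i] <- "edge"
      next
    }
    di <- (c0 + disk$dc - 1L) * nr + (r0 + disk$dr)
    ai <- (c0 + ann$dc - 1L) * nr + (r0 + ann$dr)
    rv <- r_frame[di]
    gv <- g_frame[di]
    ra <- r_frame[ai]
    ga <- g_frame[ai]
    r_scat <- sum(rv) - n_px * stats::median(ra)
    g_scat <- sum(gv) - n_px * stats::median(ga)
    sv <- rv + gv
    s_ann <- ra + ga
    s_bg <- stats::median(s_ann)
    amp <- max(sv) - s_bg
    area[i] <- if (amp > 0) sum(sv > s_bg + amp / 2) else 0
    wts <- pmax(sv - s_bg, 0)
    sw <- sum(wts)
    if (sw > 0) {
      row_c[i] <- sum((r0 + disk$dr) * wts) / sw
      col_c[i] <- sum((c0 + disk$dc) * wts) / sw
    }
    if (!is.finite(r_scat + g_scat) || (r_scat + g_scat) <= 0) {
      excl[i] <- TRUE
      reason[i] <- "nonpositive"
      next
    }
    r_s[i] <- max(r_scat, 0)
    g_s[i] <- max(g_scat, 0)
    gam[i] <- (r_scat - g_scat) / (r_scat + g_scat)
  }
  data.frame(row = row_c, col = col_c, area = area, r_scat = r_s,
             g_scat = g_s, gamma = gam, excluded = excl, reason = reason)
}

#' Flag oversized spots as aggregates
#'
#' Spots whose pixel area exceeds `max_area` are flagged `excluded` with
#' reason `"oversize"` and dropped from the analysis set; exclusion counts
#' are reported alongside.
#'
#' @param spots Data frame of measured spots (see [measure_spot()]).
#' @param params A [detection_params()] with a non-`NULL` `max_area`.
#' @return List of class `spot_filter`: `kept` (data frame), `flagged`
#'   (all spots with flags) and `counts` (named totals by reason).
#' @export
filter_spots <- function(spots, params) {
  if (is.null(params$max_area)) {
    stop("max_area is not set; calibrate it first (see calibrate_max_area)",
         call. = FALSE)
  }
  over <- !spots$excluded & !is.na(spots$area) & spots$area > params$max_area
  spots$excluded[over] <- TRUE
  spots$reason[over] <- "oversize"
  kept <- spots[!spots$excluded, , drop = FALSE]
  counts <- c(
    detected = nrow(spots),
    kept = nrow(kept),
    excluded_edge = sum(spots$reason == "edge"),
    excluded_oversize = sum(spots$reason == "oversize"),
    excluded_nonpositive = sum(spots$reason == "nonpositive")
  )
  structure(list(kept = kept, flagged = spots, counts = counts),
            class = "spot_filter")
}

#' Analyse a two-channel frame stack into a per-spot gamma table
#'
#' Runs detect -> measure -> filter over every frame of the stacks. Spots
#' are ordered by frame index, then by peak rank (brightest first) within
#' each frame, so repeated runs on the same input give identical tables.
#'
#' @param r_stack,g_stack Lists of numeric matrices with identical shapes.
#' @param params A [detection_params()]; if `max_area` is `NULL` it is set
#'   to the 99.5th percentile of the measured areas of this dataset (only
#'   appropriate for aggregate-free calibration data; prefer
#'   [calibrate_max_area()]).
#' @return List of class `spot_analysis`: `spots` (kept spots with `frame`
#'   and `rank` columns), `all` (every detected spot with exclusion flags),
#'   `counts` (totals by reason) and `params` (with the resolved
#'   `max_area`).
#' @export
analyze_frames <- function(r_stack, g_stack, params = detection_params()) {
  if (length(r_stack) != length(g_stack)) {
    stop("channel stacks differ in length", call. = FALSE)
  }
  rows <- vector("list", length(r_stack))
  for (f in seq_along(r_stack)) {
    rf <- r_stack[[f]]
    gf <- g_stack[[f]]
    if (!all(dim(rf) == dim(gf))) {
      stop("channel stacks differ in frame shape", call. = FALSE)
    }
    peaks <- detect_spots(rf + gf, params)
    if (nrow(peaks) == 0L) next
    meas <- .measure_peaks(rf, gf, peaks, params)
    meas$frame <- f
    meas$rank <- seq_len(nrow(meas))
    rows[[f]] <- meas
  }
  all_spots <- do.call(rbind, rows)
  if (is.null(all_spots)) {
    all_spots <- data.frame(row = numeric(0), col = numeric(0),
                            area = numeric(0), r_scat = numeric(0),
                            g_scat = numeric(0), gamma = numeric(0),
                            excluded = logical(0), reason = character(0),
                            frame = integer(0), rank = integer(0))
  }
  if (is.null(params$max_area)) {
    ok <- !all_spots$excluded & is.finite(all_spots$area)
    params$max_area <- if (any(ok)) {
      as.numeric(stats::quantile(all_spots$area[ok], 0.995, names = FALSE))
    } else {
      Inf
    }
  }
  filt <- filter_spots(all_spots, params)
  structure(
    list(spots = filt$kept, all = filt$flagged, counts = filt$counts,
         params = params),
    class = "spot_analysis"
  )
}

#' @export
print.spot_analysis <- function(x, ...) {
  cat(sprintf(
    "<spot_analysis> %d detected, %d kept (edge %d, oversize %d, nonpositive %d)\n",
    x$counts["detected"], x$counts["kept"], x$counts["excluded_edge"],
    x$counts["excluded_oversize"], x$counts["excluded_nonpositive"]))
  invisible(x)
}

#' Calibrate the oversize (aggregate) area threshold
#'
#' Renders an aggregate-free negative-control dataset under the given
#' configuration, measures all spots, and returns the 99.5th percentile of
#' their pixel areas: the default aggregate-exclusion threshold. Calibrating
#' on aggregate-free data keeps doublets from inflating the threshold.
#'
#' @param pop A [population_config()]; its `aggregate_fraction` is forced
#'   to 0.
#' @param img An [imaging_config()].
#' @param bands A [band_set()].
#' @param params A [detection_params()].
#' @param n Number of calibration spots.
#' @param seed Integer seed.
#' @param constants Material table for the core.
#' @return The calibrated `max_area` in pixels (numeric scalar).
#' @export
calibrate_max_area <- function(pop = population_config(),
                               img = imaging_config(),
                               bands = nonadjacent_bands(),
                               params = detection_params(),
                               n = 2000, seed = 99L,
                               constants = gold_johnson_christy()) {
  pop$aggregate_fraction <- 0
  ds <- generate_dataset(0, n_spots = n, pop = pop,
                         img = img, bands = bands, seed = seed,
                         constants = constants)
  params$max_area <- Inf
  res <- analyze_frames(ds$frames$r, ds$frames$g, params)
  ok <- is.finite(res$spots$area)
  as.numeric(stats::quantile(res$spots$area[ok], 0.995, names = FALSE))
}

#' Analyse a dataset directory written by [generate_dataset()]
#'
#' Reads `r_channel.tif` and `g_channel.tif`, runs [analyze_frames()], and
#' writes `spots.csv` (one row per detected spot, with exclusion flags) and
#' `analysis_summary.json` (counts and resolved parameters) into the
#' directory.
#'
#' @param dir Dataset directory.
#' @param params A [detection_params()].
#' @return The `spot_analysis` object, invisibly.
#' @export
analyze_dataset <- function(dir, params = detection_params()) {
  r_stack <- read_stack(file.path(dir, "r_channel.tif"))
  g_stack <- read_stack(file.path(dir, "g_channel.tif"))
  res <- analyze_frames(r_stack, g_stack, params)
  out <- res$all
  out <- out[, c("frame", "rank", "row", "col", "area", "r_scat", "g_scat",
                 "gamma", "excluded", "reason")]
  utils::write.csv(out, file.path(dir, "spots.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(counts = as.list(res$counts),
         params = res$params[!vapply(res$params, is.null, logical(1))]),
    file.path(dir, "analysis_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
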