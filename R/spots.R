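# FISH spot detection on the FAM (telomeric probe) and TAMRA (5S rDNA)
# channels, assignment of spots to segmented chromosomes, and localization
# of each spot on the long or short arm.

#' Spot-detection parameters
#'
#' @param threshold_k Spots are connected components above
#'   `median + threshold_k * mad` of the channel (default 8, a robust
#'   background-relative cut).
#' @param min_spot_area Minimum component area in pixels (default 4).
#' @param weak_fraction A spot is classed `"weak"` when its summed
#'   background-subtracted intensity falls below `weak_fraction` times the
#'   median spot intensity of its channel (default 0.5). The paper-free
#'   choice of this cut is documented in the methods vignette.
#' @param assign_radius Maximum centroid-to-mask distance in pixels for
#'   assigning a spot to a nearby (non-containing) chromosome (default 6).
#' @return Named list of class `spot_params`.
#' @export
spot_params <- function(threshold_k = 8, min_spot_area = 4L,
                        weak_fraction = 0.5, assign_radius = 6) {
  structure(as.list(environment()), class = "spot_params")
}

#' Detect FISH signal spots and assign them to chromosomes
#'
#' Per channel, spots are connected components above a robust
#' background-relative threshold. Each spot is assigned to the chromosome
#' mask containing its intensity-weighted centroid, or to the nearest mask
#' within `assign_radius` pixels; spots assignable to no chromosome are
#' reported in the `"unassigned"` attribute, not dropped. Spot intensity
#' class is `"weak"` iff its summed intensity is below `weak_fraction`
#' times the channel's median spot intensity. When `measurements` are
#' supplied, each site also gets its arm (`long`/`short`), its
#' `position_fraction` (arc distance from the centromere as a fraction of
#' arm length), and its position `category`.
#'
#' @param image A `metaphase_image`.
#' @param masks List of `chromosome_mask` objects (see
#'   [segment_chromosomes()]).
#' @param params A [spot_params()] list.
#' @param measurements Optional list of `chromosome_measurement` objects
#'   parallel to `masks` (see [measure_spread()]).
#' @param channels Channels to scan (default FAM and TAMRA); a requested
#'   channel absent from the image is an error naming the channel.
#' @return Data frame of signal sites with columns `chromosome_id`,
#'   `channel`, `row`, `col`, `raw_intensity`, `intensity`, `arm`,
#'   `position_fraction`, `category`; unassigned spots in
#'   `attr(, "unassigned")`.
#' @export
detect_signals <- function(image, masks, params = spot_params(),
                           measurements = NULL,
                           channels = c("FAM", "TAMRA")) {
  rows <- list()
  un <- list()
  for (ch in channels) {
    mat <- image$channels[[ch]]
    if (is.null(mat))
      kf_validation_error("channel absent from image: %s", ch)
    med <- stats::median(mat)
    # floor the scale estimate: a mostly-dark channel can have mad ~ 0
    thr <- med + params$threshold_k * max(stats::mad(mat), 0.005)
    bw <- mat > thr
    if (!any(bw)) next
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
    nlab <- max(lab)
    for (l in seq_len(nlab)) {
      idx <- which(lab == l, arr.ind = TRUE)
      if (nrow(idx) < params$min_spot_area) next
      v <- mat[idx] - med
      ctr <- c(sum(idx[, 1] * v), sum(idx[, 2] * v)) / sum(v)
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, row = ctr[1], col = ctr[2],
        raw_intensity = sum(v), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- cbind(empty_sites()[0, c("chromosome_id", "channel", "row", "col")],
                 data.frame(raw_intensity = numeric(0),
                            intensity = character(0), arm = character(0),
                            position_fraction = numeric(0),
                            category = character(0)))
    attr(out, "unassigned") <- out
    return(out)
  }
  spots <- do.call(rbind, rows)

  # weak/strong per channel
  spots$intensity <- "strong"
  for (ch in unique(spots$channel)) {
    sel <- spots$channel == ch
    medi <- stats::median(spots$raw_intensity[sel])
    spots$intensity[sel] <- ifelse(
      spots$raw_intensity[sel] < params$weak_fraction * medi, "weak", "strong")
  }

  # assignment to masks
  dims <- dim(image$channels$DAPI %||% image$channels[[channels[1]]])
  spots$chromosome_id <- NA_character_
  spots$mask_index <- NA_integer_
  ids <- if (length(masks))
    vapply(seq_along(masks), function(i) sprintf("obj%03d", i), "") else
      character(0)
  for (si in seq_len(nrow(spots))) {
    r <- spots$row[si]; c <- spots$col[si]
    ri <- round(r); ci <- round(c)
    best <- NA_integer_; best_d <- Inf
    for (mi in seq_along(masks)) {
      b <- masks[[mi]]$bbox
      if (ri >= b["r0"] && ri <= b["r1"] && ci >= b["c0"] && ci <= b["c1"] &&
          masks[[mi]]$mask[ri - b["r0"] + 1, ci - b["c0"] + 1]) {
        best <- mi; best_d <- 0
        break
      }
      # distance to bbox as a cheap lower bound before exact pixel search
      dr <- max(b["r0"] - r, 0, r - b["r1"])
      dc <- max(b["c0"] - c, 0, c - b["c1"])
      if (sqrt(dr^2 + dc^2) > params$assign_radius) next
      idx <- which(masks[[mi]]$mask, arr.ind = TRUE)
      d <- min(sqrt((idx[, 1] + b["r0"] - 1 - r)^2 +
                      (idx[, 2] + b["c0"] - 1 - c)^2))
      if (d <= params$assign_radius && d < best_d) {
        best <- mi; best_d <- d
      }
    }
    if (!is.na(best)) {
      spots$mask_index[si] <- best
      spots$chromosome_id[si] <- ids[best]
    }
  }

  spots$arm <- NA_character_
  spots$position_fraction <- NA_real_
  spots$category <- NA_character_
  if (!is.null(measurements)) {
    for (si in which(!is.na(spots$mask_index))) {
      loc <- locate_on_measurement(spots$row[si], spots$col[si],
                                   measurements[[spots$mask_index[si]]])
      spots$arm[si] <- loc$arm
      spots$position_fraction[si] <- loc$position_fraction
      spots$category[si] <- loc$category
    }
  }

  assigned <- spots[!is.na(spots$chromosome_id), , drop = FALSE]
  unassigned <- spots[is.na(spots$chromosome_id), , drop = FALSE]
  rownames(assigned) <- NULL
  cols <- c("chromosome_id", "channel", "row", "col", "raw_intensity",
            "intensity", "arm", "position_fraction", "category")
  out <- assigned[, cols]
  attr(out, "unassigned") <- unassigned
  out
}

# Project an image point onto a measured chromosome's medial axis and
# express it as (arm, fraction-from-centromere, category).
locate_on_measurement <- function(row, col, meas) {
  sk <- meas$skeleton
  if (is.null(sk) || is.na(meas$centromere_index))
    return(list(arm = NA_character_, position_fraction = NA_real_,
                category = NA_character_))
  d2 <- (sk$row - row)^2 + (sk$col - col)^2
  j <- which.min(d2)
  k <- meas$centromere_index
  s <- sk$s; px <- meas$pixel_size
  np <- length(s)
  arm_arc_start <- s[k]
  arm_arc_end <- s[np] - s[k]
  # arm lengths include the tip caps beyond the skeleton endpoints
  if (meas$short_is_start) {
    arm_start <- meas$short_arm / px
    arm_end <- meas$long_arm / px
  } else {
    arm_start <- meas$long_arm / px
    arm_end <- meas$short_arm / px
  }
  # spots beyond a skeleton endpoint (e.g. telomeric caps): add their
  # projection onto the outward tangent to the arc position
  extra <- 0
  if (j == 1 || j == np) {
    look <- min(8L, np)
    ref <- if (j == 1) c(sk$row[look], sk$col[look])
           else c(sk$row[np - look + 1], sk$col[np - look + 1])
    u <- c(sk$row[j], sk$col[j]) - ref
    nu <- sqrt(sum(u^2))
    if (nu > 1e-9) {
      u <- u / nu
      extra <- max(0, (row - sk$row[j]) * u[1] + (col - sk$col[j]) * u[2])
    }
  }
  if (j <= k) {
    frac <- (s[k] - s[j] + extra) / max(arm_start, 1e-9)
    arm <- if (arm_start >= arm_end) "long" else "short"
  } else {
    frac <- (s[j] - s[k] + extra) / max(arm_end, 1e-9)
    arm <- if (arm_end > arm_start) "long" else "short"
  }
  frac <- min(max(frac, 0), 1)
  list(arm = arm, position_fraction = frac,
       category = position_category(frac))
}

#' Categorize a signal site's position on its arm
#'
#' Maps a located site to one of the arm-position categories
#' (`centromeric`, `interstitial`, `proximal-telomeric`, `telomeric`) via
#' the package thresholds (see [position_category()]). The site must carry
#' a `position_fraction`, or one is computed by projecting the site onto
#' the supplied measurement's medial axis.
#'
#' @param site One signal site (a one-row data frame or list with
#'   `position_fraction`, or `row`/`col` when `measurement` is given).
#' @param measurement Optional `chromosome_measurement` the site lies on.
#' @return Single category string.
#' @examples
#' locate_signal_on_arm(list(position_fraction = 0.95))  # "telomeric"
#' @export
locate_signal_on_arm <- function(site, measurement = NULL) {
  pf <- site$position_fraction
  if ((is.null(pf) || is.na(pf)) && !is.null(measurement))
    pf <- locate_on_measurement(site$row, site$col,
                                measurement)$position_fraction
  if (is.null(pf) || is.na(pf))
    kf_validation_error("site has no position_fraction and no measurement given")
  position_category(pf)
}
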