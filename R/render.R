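# Synthetic metaphase spread renderer: chromosomes as smoothly bent capsules
# with a centromeric constriction, telomeric FAM spots at both chromatid
# ends, and locus-specific TAMRA (5S) spots at assigned arm positions.

#' Rendering parameters for synthetic metaphase spreads
#'
#' All lengths are in micrometres unless noted.
#'
#' @param pixel_size Length per pixel (default 0.04 um, i.e. 25 px/um).
#' @param chrom_halfwidth Chromosome half-width (default 0.20 um).
#' @param constriction_depth Fractional width reduction at the centromere
#'   (default 0.6: the capsule narrows to 40% of its width).
#' @param constriction_sigma Gaussian half-width of the constriction
#'   (default 0.15 um).
#' @param bend_fraction Maximum random bow of the centerline, as a fraction
#'   of chromosome length (default 0.08).
#' @param spot_sigma Gaussian sigma of probe spots (default 0.08 um).
#' @param spot_amplitude Peak intensity of a strong spot on the [0, 1]
#'   scale (default 0.75).
#' @param weak_fraction_render Peak intensity of a weak spot as a fraction
#'   of a strong one (default 0.4).
#' @param dapi_amplitude DAPI plateau intensity (default 0.65).
#' @param background_level Constant background offset per channel
#'   (default 0.05), emulating autofluorescence / camera offset.
#' @param background_sd Gaussian background noise standard deviation per
#'   channel (default 0.02).
#' @param margin Minimum clearance between chromosome footprints
#'   (default 0.4 um).
#' @param canvas Optional `c(height, width)` in micrometres. `NULL` (the
#'   default) sizes a placement grid automatically so that overlap-free
#'   placement always succeeds.
#' @param overlap `"forbid"` (default) or `"allow"`.
#' @param max_retries Placement attempts per chromosome when `canvas` is
#'   fixed (default 200).
#' @return Named list of class `render_params`.
#' @export
render_params <- function(pixel_size = 0.04,
                          chrom_halfwidth = 0.20,
                          constriction_depth = 0.6,
                          constriction_sigma = 0.15,
                          bend_fraction = 0.08,
                          spot_sigma = 0.08,
                          spot_amplitude = 0.75,
                          weak_fraction_render = 0.4,
                          dapi_amplitude = 0.65,
                          background_level = 0.05,
                          background_sd = 0.02,
                          margin = 0.4,
                          canvas = NULL,
                          overlap = c("forbid", "allow"),
                          max_retries = 200L) {
  overlap <- match.arg(overlap)
  p <- as.list(environment())
  if (pixel_size <= 0 || chrom_halfwidth <= 0)
    kf_validation_error("pixel_size and chrom_halfwidth must be positive")
  if (constriction_depth < 0 || constriction_depth >= 1)
    kf_validation_error("constriction_depth must lie in [0, 1)")
  structure(p, class = "render_params")
}

# Arc-length parametrized bent centerline in local um coordinates.
# Returns n x 2 matrix (x along the chromosome, y the bow) with total arc
# length len_um, plus cumulative arc positions.
bent_centerline <- function(len_um, bow_um, step_um) {
  n0 <- max(50L, ceiling(len_um / step_um) * 3L)
  t <- seq(0, len_um, length.out = n0)
  pts <- cbind(t, bow_um * sin(pi * t / len_um))
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  pts <- pts * (len_um / arc[n0])  # rescale so arc length == len_um
  arc <- arc * (len_um / arc[n0])
  s <- seq(0, len_um, by = step_um)
  if (s[length(s)] < len_um) s <- c(s, len_um)
  cbind(x = stats::approx(arc, pts[, 1], xout = s)$y,
        y = stats::approx(arc, pts[, 2], xout = s)$y,
        s = s)
}

# Distance-field rasterization of one capsule into a local bbox.
# cl: matrix with columns row, col (px, canvas coordinates), s (um).
# width_um: halfwidth at each centerline sample. Returns list(r0, c0, F)
# where F[i, j] = min over samples of (pixel distance - local halfwidth),
# in pixels; mask is F <= 0.
raster_capsule <- function(cl, width_um, pixel_size, pad_px = 3L) {
  w_px <- width_um / pixel_size
  r0 <- floor(min(cl[, "row"]) - max(w_px)) - pad_px
  c0 <- floor(min(cl[, "col"]) - max(w_px)) - pad_px
  r1 <- ceiling(max(cl[, "row"]) + max(w_px)) + pad_px
  c1 <- ceiling(max(cl[, "col"]) + max(w_px)) + pad_px
  H <- r1 - r0 + 1L; W <- c1 - c0 + 1L
  F <- matrix(Inf, H, W)
  for (j in seq_len(nrow(cl))) {
    r <- cl[j, "row"] - r0 + 1
    c <- cl[j, "col"] - c0 + 1
    rad <- ceiling(w_px[j]) + pad_px
    rr <- max(1L, floor(r - rad)):min(H, ceiling(r + rad))
    cc <- max(1L, floor(c - rad)):min(W, ceiling(c + rad))
    if (!length(rr) || !length(cc)) next
    d <- sqrt(outer((rr - r)^2, (cc - c)^2, `+`))
    F[rr, cc] <- pmin(F[rr, cc], d - w_px[j])
  }
  list(r0 = r0, c0 = c0, F = F)
}

interp_centerline <- function(cl, s) {
  cbind(row = stats::approx(cl[, "s"], cl[, "row"], xout = s, rule = 2)$y,
        col = stats::approx(cl[, "s"], cl[, "col"], xout = s, rule = 2)$y)
}

add_gaussian_spot <- function(mat, row, col, amp, sigma_px) {
  H <- nrow(mat); W <- ncol(mat)
  rad <- ceiling(5 * sigma_px)
  rr <- max(1L, floor(row - rad)):min(H, ceiling(row + rad))
  cc <- max(1L, floor(col - rad)):min(W, ceiling(col + rad))
  if (!length(rr) || !length(cc)) return(mat)
  g <- amp * exp(-outer((rr - row)^2, (cc - col)^2, `+`) / (2 * sigma_px^2))
  mat[rr, cc] <- mat[rr, cc] + g
  mat
}

# Expand signal assignments to per-homolog site requests.
expand_assignments <- function(signals) {
  if (is.null(signals) || !length(signals)) return(list())
  out <- list()
  oh_seen <- character(0)
  for (sp in signals) {
    if (identical(sp$zygosity, "one-homolog")) {
      key <- paste(sp$pair_index, sp$channel, sep = "/")
      hom <- if (sum(oh_seen == key) %% 2 == 0) "a" else "b"
      oh_seen <- c(oh_seen, key)
      out[[length(out) + 1L]] <- c(sp, list(homolog = hom))
    } else {
      for (h in c("a", "b"))
        out[[length(out) + 1L]] <- c(sp, list(homolog = h))
    }
  }
  out
}

#' Render a synthetic three-channel metaphase FISH image
#'
#' Draws every chromosome of a measurement table as a smoothly bent capsule
#' with a width minimum (primary constriction) at the centromere position
#' implied by its arm lengths, stamps FAM telomere spots at both chromatid
#' ends of every chromosome, places TAMRA (5S) spots at the arm positions of
#' the supplied signal assignments (weak spots at a documented fraction of
#' strong intensity), and adds Gaussian background noise to all three
#' channels. With the default automatic canvas and `overlap = "forbid"`,
#' chromosomes are placed on a jittered grid with randomized order and
#' orientation, guaranteeing pairwise disjoint footprints; with a fixed
#' `canvas`, rejection sampling is used and a placement error is raised
#' after bounded retries.
#'
#' @param table Measurement table (may be empty: blank channels result).
#' @param signals List of signal assignments (fixture `signal_pairs`
#'   entries), or `NULL` for none.
#' @param seed Integer seed; identical seed and parameters give
#'   bit-identical images.
#' @param params A [render_params()] list.
#' @return A list of class `metaphase_image`: `channels` (named list of
#'   DAPI, FAM, TAMRA matrices in `[0, 1]`, identical dimensions),
#'   `pixel_size`, and `ground_truth` (chromosome placements and true
#'   signal sites).
#' @export
render_metaphase_image <- function(table, signals = NULL, seed = 1L,
                                   params = render_params()) {
  with_seed(seed, render_metaphase_image_impl(table, signals, params))
}

render_metaphase_image_impl <- function(table, signals, p) {
  px <- p$pixel_size
  n <- if (is.null(table)) 0L else nrow(table)

  if (n == 0) {
    side <- if (is.null(p$canvas)) 256L else ceiling(p$canvas / px)
    if (length(side) == 1) side <- c(side, side)
    ch <- lapply(1:3, function(i) clamp01(
      matrix(p$background_level + stats::rnorm(prod(side), 0, p$background_sd),
             side[1], side[2])))
    names(ch) <- c("DAPI", "FAM", "TAMRA")
    return(structure(list(channels = ch, pixel_size = px,
                          ground_truth = list(chromosomes = list(),
                                              sites = empty_sites()),
                          params = p),
                     class = "metaphase_image"))
  }
  validate_measurement_table(table)

  tot <- table$long_arm + table$short_arm
  w_eff <- pmin(p$chrom_halfwidth, 0.3 * tot)
  len_cl <- tot - 2 * w_eff                     # centerline length, um
  max_ext_px <- max(tot) / px

  if (is.null(p$canvas)) {
    cell <- ceiling(max_ext_px + 2 * p$margin / px + 4)
    ncol_g <- ceiling(sqrt(n))
    nrow_g <- ceiling(n / ncol_g)
    H <- max(256L, nrow_g * cell); W <- max(256L, ncol_g * cell)
    grid_mode <- TRUE
  } else {
    H <- ceiling(p$canvas[1] / px)
    W <- ceiling(p$canvas[length(p$canvas)] / px)
    grid_mode <- FALSE
    cell <- NA
  }

  dapi <- matrix(0, H, W)
  fam <- matrix(0, H, W)
  tamra <- matrix(0, H, W)
  occ <- matrix(FALSE, H, W)
  margin_px <- p$margin / px

  order_idx <- sample.int(n)
  cells <- sample.int(if (grid_mode) nrow_g * ncol_g else n)
  chrom_gt <- vector("list", n)
  centerlines <- vector("list", n)

  for (k in seq_len(n)) {
    i <- order_idx[k]
    theta <- stats::runif(1, 0, pi)
    bow <- stats::runif(1, -p$bend_fraction, p$bend_fraction) * len_cl[i]
    cl0 <- bent_centerline(len_cl[i], bow, step_um = 0.5 * px)
    rot <- cbind(cl0[, "x"] * cos(theta) - cl0[, "y"] * sin(theta),
                 cl0[, "x"] * sin(theta) + cl0[, "y"] * cos(theta))
    rot <- sweep(rot, 2, colMeans(rot))         # center on origin (um)

    sc <- min(max(table$short_arm[i] - w_eff[i], 0.02 * len_cl[i]),
              0.98 * len_cl[i])                  # centromere, centerline s
    wprof <- w_eff[i] * (1 - p$constriction_depth *
                           exp(-(cl0[, "s"] - sc)^2 /
                                 (2 * p$constriction_sigma^2)))
    # keep the neck at least ~2 px wide so the mask cannot pinch apart
    wprof <- pmax(wprof, 2 * px)

    half_px <- (max(abs(rot)) + w_eff[i]) / px + 2
    placed <- FALSE
    tries <- if (grid_mode) 1L else p$max_retries
    for (tr in seq_len(tries)) {
      if (grid_mode) {
        cell_id <- cells[k] - 1L
        gr <- cell_id %/% ncol_g; gc <- cell_id %% ncol_g
        ctr_r <- gr * cell + cell / 2
        ctr_c <- gc * cell + cell / 2
        jit <- max(0, cell / 2 - half_px - margin_px / 2)
        ctr_r <- ctr_r + stats::runif(1, -jit, jit)
        ctr_c <- ctr_c + stats::runif(1, -jit, jit)
      } else {
        ctr_r <- stats::runif(1, half_px + 1, H - half_px - 1)
        ctr_c <- stats::runif(1, half_px + 1, W - half_px - 1)
      }
      cl <- cbind(row = rot[, 2] / px + ctr_r,
                  col = rot[, 1] / px + ctr_c, s = cl0[, "s"])
      pad <- if (grid_mode || p$overlap != "forbid") 3L
             else ceiling(margin_px) + 2L
      ras <- raster_capsule(cl, wprof, px, pad_px = pad)
      rr <- ras$r0:(ras$r0 + nrow(ras$F) - 1L)
      cc <- ras$c0:(ras$c0 + ncol(ras$F) - 1L)
      rok <- rr >= 1 & rr <= H; cok <- cc >= 1 & cc <= W
      Fv <- ras$F[rok, cok, drop = FALSE]
      rr <- rr[rok]; cc <- cc[cok]
      if (p$overlap == "forbid" && !grid_mode) {
        near <- Fv <= margin_px
        if (any(occ[rr, cc] & near)) next
      }
      inside <- Fv <= 0
      occ[rr, cc] <- occ[rr, cc] | inside
      dapi[rr, cc] <- pmax(dapi[rr, cc],
                           p$dapi_amplitude * pmin(1, pmax(0, -Fv)))
      centerlines[[i]] <- cl
      chrom_gt[[i]] <- list(
        chromosome_id = table$chromosome_id[i],
        pair_index = if (!is.null(table$pair_index)) table$pair_index[i] else NA,
        total_length = tot[i],
        long_arm = table$long_arm[i],
        short_arm = table$short_arm[i],
        halfwidth = w_eff[i],
        centromere_s = sc,
        centroid = c(row = mean(cl[, "row"]), col = mean(cl[, "col"])),
        theta = theta, bow = bow)
      placed <- TRUE
      break
    }
    if (!placed)
      kf_placement_error(
        "could not place chromosome %s without overlap after %d retries (canvas too small?)",
        table$chromosome_id[i], p$max_retries)
  }

  # --- probe spots -------------------------------------------------------
  sites <- list()
  sig_px <- p$spot_sigma / px
  for (i in seq_len(n)) {
    cl <- centerlines[[i]]
    ends <- interp_centerline(cl, c(0, max(cl[, "s"])))
    for (e in 1:2) {
      fam <- add_gaussian_spot(fam, ends[e, "row"], ends[e, "col"],
                               p$spot_amplitude, sig_px)
      sites[[length(sites) + 1L]] <- data.frame(
        chromosome_id = table$chromosome_id[i], channel = "FAM",
        row = ends[e, "row"], col = ends[e, "col"],
        arm = if (e == 1) "short" else "long",
        position_fraction = 1.0, intensity = "strong",
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(table$pair_index)) {
    hom <- ifelse(grepl("a$", table$chromosome_id), "a", "b")
    for (req in expand_assignments(signals)) {
      sel <- which(table$pair_index == req$pair_index & hom == req$homolog)
      for (i in sel) {
        if (req$channel == "FAM") next  # telomeric FAM handled above
        cl <- centerlines[[i]]
        gt <- chrom_gt[[i]]
        s_pos <- if (req$arm == "short")
          gt$short_arm * (1 - req$position_fraction) - gt$halfwidth
        else
          gt$short_arm + req$position_fraction * gt$long_arm - gt$halfwidth
        s_pos <- min(max(s_pos, 0), max(cl[, "s"]))
        pt <- interp_centerline(cl, s_pos)
        amp <- p$spot_amplitude *
          if (identical(req$intensity, "weak")) p$weak_fraction_render else 1
        tamra <- add_gaussian_spot(tamra, pt[1, "row"], pt[1, "col"],
                                   amp, sig_px)
        sites[[length(sites) + 1L]] <- data.frame(
          chromosome_id = table$chromosome_id[i], channel = "TAMRA",
          row = pt[1, "row"], col = pt[1, "col"], arm = req$arm,
          position_fraction = req$position_fraction,
          intensity = req$intensity, stringsAsFactors = FALSE)
      }
    }
  }
  site_df <- if (length(sites)) do.call(rbind, sites) else empty_sites()

  noise <- function(m) clamp01(m + p$background_level +
                                 matrix(stats::rnorm(length(m), 0,
                                                     p$background_sd),
                                        nrow(m)))
  structure(list(
    channels = list(DAPI = noise(dapi), FAM = noise(fam),
                    TAMRA = noise(tamra)),
    pixel_size = px,
    ground_truth = list(chromosomes = chrom_gt, sites = site_df),
    params = p
  ), class = "metaphase_image")
}

clamp01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

empty_sites <- function() {
  data.frame(chromosome_id = character(0), channel = character(0),
             row = numeric(0), col = numeric(0), arm = character(0),
             position_fraction = numeric(0), intensity = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.metaphase_image <- function(x, ...) {
  d <- dim(x$channels$DAPI)
  cat(sprintf("<metaphase_image> %d x %d px (%.3f um/px), %d chromosome(s), %d true site(s)\n",
              d[1], d[2], x$pixel_size,
              length(x$ground_truth$chromosomes),
              nrow(x$ground_truth$sites)))
  invisible(x)
}

#' Write a metaphase image to disk
#'
#' Writes one 16-bit grayscale TIFF per channel, an 8-bit RGB PNG preview
#' (TAMRA red, FAM green, DAPI blue), and the ground truth as a JSON
#' sidecar.
#'
#' @param image A `metaphase_image`.
#' @param prefix Output path prefix; files are
#'   `<prefix>_<CHANNEL>.tif`, `<prefix>_preview.png`,
#'   `<prefix>_ground_truth.json`.
#' @return Character vector of paths written, invisibly.
#' @export
write_metaphase_image <- function(image, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ch in names(image$channels)) {
    path <- sprintf("%s_%s.tif", prefix, ch)
    tiff::writeTIFF(image$channels[[ch]], path, bits.per.sample = 16)
    paths <- c(paths, path)
  }
  arr <- array(0, c(dim(image$channels$DAPI), 3))
  arr[, , 1] <- image$channels$TAMRA
  arr[, , 2] <- image$channels$FAM
  arr[, , 3] <- image$channels$DAPI
  png_path <- sprintf("%s_preview.png", prefix)
  png::writePNG(arr, png_path)
  gt_path <- sprintf("%s_ground_truth.json", prefix)
  gt <- list(
    pixel_size = image$pixel_size,
    chromosomes = lapply(image$ground_truth$chromosomes, function(g)
      g[c("chromosome_id", "pair_index", "total_length", "long_arm",
          "short_arm", "halfwidth", "centromere_s")]),
    sites = image$ground_truth$sites)
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, png_path, gt_path))
}

#' Read a metaphase image written by [write_metaphase_image()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `metaphase_image` (ground truth restored from the sidecar if
#'   present).
#' @export
read_metaphase_image <- function(prefix) {
  chans <- list()
  for (ch in c("DAPI", "FAM", "TAMRA")) {
    path <- sprintf("%s_%s.tif", prefix, ch)
    if (!file.exists(path)) kf_io_error("missing channel file: %s", path)
    chans[[ch]] <- tiff::readTIFF(path)
  }
  if (length(unique(lapply(chans, dim))) != 1)
    kf_validation_error("channel dimensions differ")
  gt_path <- sprintf("%s_ground_truth.json", prefix)
  gt <- if (file.exists(gt_path))
    jsonlite::fromJSON(gt_path, simplifyDataFrame = TRUE)
  else NULL
  structure(list(channels = chans, pixel_size = gt$pixel_size %||% NA,
                 ground_truth = gt, params = NULL),
            class = "metaphase_image")
}
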