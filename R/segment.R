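# DAPI-channel chromosome segmentation: Otsu threshold, connected-component
# labelling, area filtering, and watershed splitting of touching clusters.

#' Segmentation parameters
#'
#' @param min_area Minimum chromosome area in pixels (default 60).
#' @param max_area Maximum single-chromosome area in pixels; larger
#'   components are treated as touching clusters (default 8000).
#' @param threshold Foreground threshold on the DAPI channel, or `NULL`
#'   (default) for Otsu's method.
#' @param min_contrast Minimum bright-tail contrast (99.9th percentile
#'   minus median) for the image to count as containing foreground at all;
#'   below it an empty mask list is returned (default 0.1). This keeps
#'   Otsu's method from splitting pure background noise.
#' @param split_touching Attempt a distance-transform watershed split of
#'   over-size components (default `TRUE`); unsplittable clusters are
#'   returned whole and flagged.
#' @return Named list of class `seg_params`.
#' @export
seg_params <- function(min_area = 60L, max_area = 8000L, threshold = NULL,
                       min_contrast = 0.1, split_touching = TRUE) {
  structure(as.list(environment()), class = "seg_params")
}

#' Segment chromosomes from the DAPI channel
#'
#' Thresholds the DAPI counterstain (Otsu by default), labels connected
#' components, drops components below `min_area`, and attempts a watershed
#' split (seeded from distance-transform maxima) of components above
#' `max_area`; clusters that cannot be split are returned whole with
#' `flagged = TRUE`. Masks are pairwise disjoint and ordered stably by
#' centroid (row, then column).
#'
#' @param image A `metaphase_image` (the DAPI channel must be present).
#' @param params A [seg_params()] list.
#' @return List of `chromosome_mask` objects: `label`, `bbox`
#'   (`r0, r1, c0, c1`), `mask` (logical matrix cropped to the bbox),
#'   `area`, `centroid`, `flagged`. A blank image yields an empty list.
#' @export
segment_chromosomes <- function(image, params = seg_params()) {
  dapi <- image$channels$DAPI
  if (is.null(dapi)) kf_validation_error("DAPI channel absent")
  if (stats::quantile(dapi, 0.999) - stats::median(dapi) < params$min_contrast)
    return(list())
  thr <- params$threshold
  if (is.null(thr)) thr <- EBImage::otsu(EBImage::Image(dapi), range = c(0, 1))
  fg <- dapi > thr
  if (!any(fg)) return(list())
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  areas <- tabulate(lab[lab > 0])
  out <- list()
  for (l in seq_along(areas)) {
    a <- areas[l]
    if (a < params$min_area) next
    comp <- lab == l
    if (a <= params$max_area) {
      out[[length(out) + 1L]] <- mask_object(comp, flagged = FALSE)
    } else if (params$split_touching) {
      parts <- watershed_split(comp)
      kept <- Filter(function(m) sum(m) >= params$min_area, parts)
      if (length(kept) >= 2) {
        for (m in kept)
          out[[length(out) + 1L]] <- mask_object(m, flagged = FALSE)
      } else {
        out[[length(out) + 1L]] <- mask_object(comp, flagged = TRUE)
      }
    } else {
      out[[length(out) + 1L]] <- mask_object(comp, flagged = TRUE)
    }
  }
  if (!length(out)) return(list())
  cent <- t(vapply(out, `[[`, numeric(2), "centroid"))
  ord <- order(cent[, 1], cent[, 2])
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$label <- i
  out
}

watershed_split <- function(comp) {
  d <- EBImage::distmap(EBImage::Image(comp * 1))
  ws <- EBImage::imageData(EBImage::watershed(d, tolerance = 1, ext = 1))
  labs <- setdiff(unique(as.vector(ws)), 0)
  lapply(labs, function(l) ws == l & comp)
}

mask_object <- function(full_mask, flagged = FALSE) {
  idx <- which(full_mask, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  structure(list(
    label = NA_integer_,
    bbox = c(r0 = r0, r1 = r1, c0 = c0, c1 = c1),
    mask = full_mask[r0:r1, c0:c1, drop = FALSE],
    area = nrow(idx),
    centroid = c(row = mean(idx[, 1]), col = mean(idx[, 2])),
    flagged = flagged
  ), class = "chromosome_mask")
}

#' Reconstruct a full-canvas logical mask from a `chromosome_mask`
#'
#' @param mask A `chromosome_mask`.
#' @param dim Canvas dimensions `c(rows, cols)`.
#' @return Logical matrix.
#' @export
mask_on_canvas <- function(mask, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  b <- mask$bbox
  m[b["r0"]:b["r1"], b["c0"]:b["c1"]] <- mask$mask
  m
}
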