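#' B-mode envelope image in dB
#'
#' Per-line analytic-signal magnitude, normalised to the brightest pixel of
#' the whole scan and expressed in dB (`20 log10`). The brightest pixel is 0
#' dB; zero-amplitude pixels map to `-Inf`.
#'
#' @param scan A `bscan`.
#' @return An `envelope_image`: list with `db` (matrix, lines x samples) and
#'   the geometry copied from the source scan.
#' @export
compute_envelope <- function(scan) {
  stopifnot(inherits(scan, "bscan"))
  if (length(scan$rf) == 0) abort("Empty scan.")
  if (all(scan$rf == 0)) {
    abort("All-zero scan: no brightest echo exists to normalise against.")
  }
  env <- t(apply(scan$rf, 1, envelope_mag))
  if (nrow(scan$rf) == 1L) env <- matrix(env, nrow = 1L)
  db <- 20 * log10(env / max(env))
  structure(
    list(
      db = db, sampling_rate = scan$sampling_rate,
      line_pitch = scan$line_pitch,
      sound_speed_assumed = scan$sound_speed_assumed,
      depth_origin = scan$depth_origin
    ),
    class = "envelope_image"
  )
}

#' Threshold an envelope image
#'
#' Keeps pixels at or above `threshold_db` relative to the brightest echo of
#' the whole scan (inclusive comparison: a pixel exactly at the threshold
#' belongs to the echo region).
#'
#' @param env An `envelope_image` from [compute_envelope()].
#' @param threshold_db Threshold in dB below the brightest pixel; must be
#'   negative. Default -26 dB.
#' @return A logical matrix of the same shape.
#' @export
threshold_mask <- function(env, threshold_db = -26) {
  stopifnot(inherits(env, "envelope_image"))
  if (!(is.numeric(threshold_db) && length(threshold_db) == 1 && threshold_db < 0)) {
    abort("`threshold_db` must be a single negative number.")
  }
  env$db >= threshold_db
}

# elliptical structuring element; radii = c(axial samples, lateral lines)
ellipse_kernel <- function(radius_axial, radius_lateral) {
  rr <- seq(-radius_lateral, radius_lateral)
  cc <- seq(-radius_axial, radius_axial)
  rterm <- if (radius_lateral > 0) (rr / radius_lateral)^2 else ifelse(rr == 0, 0, Inf)
  cterm <- if (radius_axial > 0) (cc / radius_axial)^2 else ifelse(cc == 0, 0, Inf)
  (outer(rterm, cterm, "+") <= 1 + 1e-9) * 1
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with an elliptical structuring element
#' (default radii 3 samples axially by 2 lines laterally). The mask is padded
#' with background by the kernel radius before the operation so the closing
#' has infinite-plane semantics and is therefore extensive
#' (`clean_mask(m) >= m` pixelwise). Radius 0 in both directions returns the
#' input unchanged.
#'
#' @param mask Logical matrix (lines x samples).
#' @param closing_radius Radii `c(axial, lateral)` in pixels; a single number
#'   is used for both.
#' @return Logical matrix, a superset of `mask`.
#' @export
clean_mask <- function(mask, closing_radius = c(3, 2)) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (length(closing_radius) == 1) closing_radius <- rep(closing_radius, 2)
  ra <- as.integer(closing_radius[1])
  rl <- as.integer(closing_radius[2])
  if (ra < 0 || rl < 0) abort("Closing radii must be >= 0.")
  if (ra == 0 && rl == 0) return(mask)
  pad <- matrix(0, nrow(mask) + 2 * rl, ncol(mask) + 2 * ra)
  pad[rl + seq_len(nrow(mask)), ra + seq_len(ncol(mask))] <- mask * 1
  kern <- ellipse_kernel(ra, rl)
  closed <- EBImage::closing(pad, kern)
  out <- as.matrix(closed)[rl + seq_len(nrow(mask)), ra + seq_len(ncol(mask)),
                           drop = FALSE] > 0.5
  dimnames(out) <- NULL
  out
}

# connected-component labelling on a binary matrix via a lattice graph;
# connectivity 4 or 8
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  id <- matrix(NA_integer_, nrow(mask), ncol(mask))
  k <- sum(mask)
  if (k == 0) return(list(labels = id, n = 0L, sizes = integer(0)))
  id[mask] <- seq_len(k)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  nr <- nrow(mask); nc <- ncol(mask)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + dr, c1 + dc, drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    if (any(keep)) edges[[length(edges) + 1]] <- cbind(a[keep], b[keep])
  }
  if (length(edges) > 0) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, k - igraph::vcount(g)))
  } else {
    g <- igraph::make_empty_graph(n = k, directed = FALSE)
  }
  comp <- igraph::components(g)
  lab <- matrix(NA_integer_, nr, nc)
  lab[mask] <- comp$membership
  list(labels = lab, n = comp$no, sizes = as.integer(comp$csize))
}

#' Select the largest connected echo region as the ROI
#'
#' Labels the connected components of a binary mask (8-connectivity by
#' default), keeps the component with the most pixels, and records the region
#' count before selection plus the depth geometry of the kept region: the
#' whole-mask minimum and maximum depths `d1`/`d2` and per-line top/bottom
#' depths, with depth computed as
#' `depth_origin + sample_index * c_assumed / (2 sampling_rate)` (0-based
#' sample indexing, depth measured from the transducer-side image top).
#'
#' @param mask Logical matrix (lines x samples) with at least one TRUE pixel.
#' @param scan The source `bscan` (or an `envelope_image`) supplying the depth
#'   geometry.
#' @param connectivity 4 or 8 (default 8).
#' @return A `roi_mask`: list with `mask`, `region_count_before_selection`,
#'   `d1`, `d2` (mm), `per_line_depths` (tibble: line, top_mm, bottom_mm) and
#'   the geometry fields.
#' @export
select_largest_region <- function(mask, scan, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) abort("Empty mask: no echo region to select.")
  lab <- label_components(mask, connectivity)
  keep <- which.max(lab$sizes)
  sel <- !is.na(lab$labels) & lab$labels == keep
  roi_mask(sel, scan, region_count = lab$n)
}

# build the roi_mask record (geometry bookkeeping shared with sub-segmentation)
roi_mask <- function(mask, scan, region_count) {
  fs <- scan$sampling_rate
  cs <- scan$sound_speed_assumed
  d0 <- scan$depth_origin
  per_line <- purrr::map_dfr(seq_len(nrow(mask)), function(li) {
    idx <- which(mask[li, ])
    if (length(idx) == 0) {
      tibble(line = li, top_mm = NA_real_, bottom_mm = NA_real_)
    } else {
      tibble(
        line = li,
        top_mm = sample_depth_mm(min(idx), fs, cs, d0),
        bottom_mm = sample_depth_mm(max(idx), fs, cs, d0)
      )
    }
  })
  d1 <- suppressWarnings(min(per_line$top_mm, na.rm = TRUE))
  d2 <- suppressWarnings(max(per_line$bottom_mm, na.rm = TRUE))
  if (!is.finite(d1)) d1 <- NA_real_
  if (!is.finite(d2)) d2 <- NA_real_
  structure(
    list(
      mask = mask, region_count_before_selection = as.integer(region_count),
      d1 = d1, d2 = d2, per_line_depths = per_line,
      sampling_rate = fs, sound_speed_assumed = cs, depth_origin = d0,
      line_pitch = scan$line_pitch
    ),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf(
    "<roi_mask> %d px, depths %.2f-%.2f mm, %d region(s) before selection\n",
    sum(x$mask), x$d1, x$d2, x$region_count_before_selection
  ))
  invisible(x)
}

#' Apply an ROI mask to a B-scan
#'
#' Zeroes the RF outside the ROI; inside the ROI the samples are bit-identical
#' to the source. Idempotent.
#'
#' @param scan A `bscan`.
#' @param roi A `roi_mask` (or a bare logical matrix of the same shape).
#' @return A `segmented_scan`: list with `rf_masked`, `mask` (the `roi_mask`)
#'   and `source` (the input scan).
#' @export
apply_mask <- function(scan, roi) {
  stopifnot(inherits(scan, "bscan"))
  m <- if (inherits(roi, "roi_mask")) roi$mask else roi
  if (!all(dim(m) == dim(scan$rf))) {
    abort("Mask shape does not match the scan.")
  }
  if (!inherits(roi, "roi_mask")) {
    roi <- roi_mask(m, scan, region_count = NA_integer_)
  }
  rf_masked <- scan$rf
  rf_masked[!m] <- 0
  structure(
    list(rf_masked = rf_masked, mask = roi, source = scan),
    class = "segmented_scan"
  )
}

#' @export
print.segmented_scan <- function(x, ...) {
  cat("<segmented_scan>\n")
  print(x$mask)
  invisible(x)
}

#' Segment the mucosa/submucosa ROI of a B-scan
#'
#' The full digital-segmentation pipeline: envelope in dB, inclusive threshold
#' at `threshold_db` relative to the brightest echo, morphological closing,
#' largest-connected-region selection, and masking of the original RF.
#'
#' @inheritParams compute_envelope
#' @inheritParams threshold_mask
#' @inheritParams clean_mask
#' @inheritParams select_largest_region
#' @return A `segmented_scan`.
#' @export
segment_roi <- function(scan, threshold_db = -26, closing_radius = c(3, 2),
                        connectivity = 8) {
  env <- compute_envelope(scan)
  m <- threshold_mask(env, threshold_db)
  m <- clean_mask(m, closing_radius)
  roi <- select_largest_region(m, scan, connectivity)
  apply_mask(scan, roi)
}

#' Trim a segmented scan to a fixed tissue thickness
#'
#' Per line, retains ROI samples from the ROI top surface down to `thickness`
#' mm below it; lines whose ROI is thinner keep their full ROI. Used for the
#' variable-thickness impedance analysis.
#'
#' @param segmented A `segmented_scan`.
#' @param thickness Retained thickness in mm (> 0).
#' @return A `segmented_scan` with the trimmed mask and recomputed depth
#'   bookkeeping.
#' @export
sub_segment_by_thickness <- function(segmented, thickness) {
  stopifnot(inherits(segmented, "segmented_scan"))
  assert_scalar_number(thickness, "thickness", positive = TRUE)
  scan <- segmented$source
  m <- segmented$mask$mask
  fs <- scan$sampling_rate
  cs <- scan$sound_speed_assumed
  d0 <- scan$depth_origin
  depths <- sample_depth_mm(seq_len(ncol(m)), fs, cs, d0)
  out <- m
  for (li in seq_len(nrow(m))) {
    idx <- which(m[li, ])
    if (length(idx) == 0) next
    top <- depths[min(idx)]
    out[li, ] <- m[li, ] & depths <= top + thickness
  }
  roi <- roi_mask(out, scan,
                  region_count = segmented$mask$region_count_before_selection)
  res <- apply_mask(scan, roi)
  res$segmentation_thickness <- thickness
  res
}
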