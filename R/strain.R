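#' Segment the tissue area of a frame
#'
#' Global Otsu thresholding over the frame's intensity histogram, keeping
#' the largest connected foreground component with holes filled. The
#' threshold is computed on the frame's own intensity range, so the mask is
#' invariant to adding a constant to all pixels.
#'
#' @param frame Intensity matrix.
#' @param min_area_px Minimum acceptable foreground area in pixels.
#' @return A logical mask matrix.
#' @export
segment_tissue <- function(frame, min_area_px = 64) {
  rng <- range(frame)
  if (diff(rng) < 1e-10)
    stop("frame has no separable foreground (uniform intensities)",
         call. = FALSE)
  thr <- EBImage::otsu(EBImage::Image(frame), range = rng, levels = 256)
  bw <- frame > thr
  lbl <- EBImage::bwlabel(EBImage::Image(bw))
  counts <- table(as.integer(lbl)[as.integer(lbl) > 0])
  if (length(counts) == 0)
    stop("segmentation found no foreground component", call. = FALSE)
  biggest <- as.integer(names(counts)[which.max(counts)])
  comp <- lbl == biggest
  filled <- EBImage::fillHull(EBImage::Image(comp))
  mask <- matrix(as.logical(as.integer(filled) > 0), nrow(frame), ncol(frame))
  if (sum(mask) < min_area_px)
    stop(sprintf("largest segmented component (%d px) below min_area_px (%d)",
                 sum(mask), min_area_px), call. = FALSE)
  mask
}

#' Select the Up and Down frames of a recording
#'
#' The Up frame is the frame at the global maximum of the movement trace
#' among detected peaks (most distended tissue) and the Down frame the
#' global minimum among valleys (least distended). Each detected extremum
#' is first re-located to the local extremum of the supplied trace within
#' `refine_w` samples, so peaks found on a low-pass-filtered trace (whose
#' crests shift slightly on asymmetric waveforms) can be pinned on the
#' unfiltered signal.
#'
#' @param trace The [motion_trace()] used to rank the extrema (typically
#'   the detrended trace without low-pass filtering).
#' @param peaks A `ctcm_peaks` from [detect_peaks_valleys()].
#' @param refine_w Re-location half-window in samples (default 3).
#' @return A list with integer `up_frame` and `down_frame` (1-based).
#' @export
select_extreme_frames <- function(trace, peaks, refine_w = 3L) {
  stopifnot(inherits(trace, "ctcm_trace"), inherits(peaks, "ctcm_peaks"))
  if (length(peaks$peak_indices) == 0 || length(peaks$valley_indices) == 0)
    stop("peak set has no peaks or no valleys; cannot pick Up/Down frames",
         call. = FALSE)
  x <- trace$value
  n <- length(x)
  relocate <- function(idx, maximum) {
    vapply(idx, function(i) {
      j <- max(1, i - refine_w):min(n, i + refine_w)
      j[if (maximum) which.max(x[j]) else which.min(x[j])]
    }, integer(1))
  }
  pk <- relocate(peaks$peak_indices, TRUE)
  vl <- relocate(peaks$valley_indices, FALSE)
  list(up_frame = pk[which.max(x[pk])], down_frame = vl[which.min(x[vl])])
}

#' Shape-from-shading surface reconstruction
#'
#' Iterative linearised shape from shading under the Lambertian
#' image-irradiance equation
#' `I = (lz - p lx - q ly) / sqrt(1 + p^2 + q^2)` with a known light
#' direction `(lx, ly, lz)`. The solver works in gradient space: each sweep
#' applies a minimal-norm Gauss-Newton update of the surface gradients
#' `(p, q)` towards the photometric constraint, followed by a
#' Frankot-Chellappa integrability projection (a Poisson solve in the
#' Fourier domain) that keeps the gradient field consistent with a single
#' surface. Because the projection is smoothing, a final photometric
#' refinement of the gradients (without projection) restores the local
#' slope magnitudes, and the returned height field is built by integrating
#' the refined row gradients along each image row, anchored to the
#' projected surface's row means. Heights are relative (global offset
#' removed; a shared scale error remains when the true albedo is not
#' uniform). Deterministic for fixed inputs and iteration counts.
#'
#' @param frame Intensity matrix in [0, 1].
#' @param mask Logical matrix; reconstruction is confined to `TRUE` pixels.
#' @param light_direction Unit 3-vector towards the light (normalised if
#'   not).
#' @param n_iter Number of projection sweeps (default 200).
#' @param mm_per_px Pixel pitch; gradients are expressed per this unit.
#' @param n_refine Number of final projection-free photometric refinement
#'   sweeps (default 40).
#' @return Height matrix (same units as `mm_per_px`; `NA` outside the
#'   mask), minimum 0 inside the mask.
#' @export
shape_from_shading <- function(frame, mask, light_direction, n_iter = 200,
                               mm_per_px = 1, n_refine = 40) {
  if (!is.logical(mask)) mask <- mask > 0
  stopifnot(identical(dim(mask), dim(frame)))
  L <- light_direction / sqrt(sum(light_direction^2))
  nr <- nrow(frame); nc <- ncol(frame)
  E <- frame
  # Fourier frequency grids for the Poisson (integrability) solve
  ky <- 0:(nr - 1); ky[ky > nr / 2] <- ky[ky > nr / 2] - nr
  kx <- 0:(nc - 1); kx[kx > nc / 2] <- kx[kx > nc / 2] - nc
  WY <- matrix(2 * pi * ky / (nr * mm_per_px), nr, nc)
  WX <- matrix(2 * pi * kx / (nc * mm_per_px), nr, nc, byrow = TRUE)
  D <- WX^2 + WY^2; D[1, 1] <- 1

  p <- matrix(0, nr, nc); q <- matrix(0, nr, nc)
  Zp <- matrix(0, nr, nc)
  photometric_step <- function(p, q, eps) {
    num <- L[3] - p * L[1] - q * L[2]
    W <- sqrt(1 + p^2 + q^2)
    R <- num / W
    R[R < 0] <- 0
    f <- E - R
    gp <- -L[1] / W - num * p / W^3
    gq <- -L[2] / W - num * q / W^3
    gp[num < 0] <- 0; gq[num < 0] <- 0   # shadowed: no photometric gradient
    g2 <- gp^2 + gq^2 + eps
    dp <- f * gp / g2; dq <- f * gq / g2
    dp[!mask] <- 0; dq[!mask] <- 0
    list(p = p + dp, q = q + dq)
  }
  for (it in seq_len(n_iter)) {
    st <- photometric_step(p, q, eps = 1e-6)
    p <- st$p; q <- st$q
    p[!mask] <- 0; q[!mask] <- 0
    Zhat <- (-1i * WX * fft(p) - 1i * WY * fft(q)) / D
    Zhat[1, 1] <- 0
    Zp <- Re(fft(Zhat, inverse = TRUE)) / (nr * nc)
    p <- Re(fft(1i * WX * Zhat, inverse = TRUE)) / (nr * nc)
    q <- Re(fft(1i * WY * Zhat, inverse = TRUE)) / (nr * nc)
    if (!all(is.finite(Zp)))
      stop(sprintf("shape-from-shading diverged at projection sweep %d", it),
           call. = FALSE)
  }
  for (it in seq_len(n_refine)) {
    st <- photometric_step(p, q, eps = 1e-9)
    p <- st$p; q <- st$q
    if (!all(is.finite(p[mask])) || !all(is.finite(q[mask])))
      stop(sprintf("shape-from-shading diverged at refinement sweep %d", it),
           call. = FALSE)
  }
  # integrate the refined row gradients along each row; anchor row offsets
  # to the projected surface so cross-row structure is preserved
  Z <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    idx <- which(mask[r, ])
    if (length(idx) == 0) next
    if (length(idx) == 1) { Z[r, idx] <- Zp[r, idx]; next }
    zi <- cumsum(c(0, p[r, idx[-length(idx)]])) * mm_per_px
    Z[r, idx] <- zi - mean(zi) + mean(Zp[r, idx])
  }
  Z[mask] <- Z[mask] - min(Z[mask])
  Z
}

#' Partition a mask into ordered sub-surface regions
#'
#' Divides the mask into `n` equal-width bands perpendicular to its
#' principal axis (from the second moments of the pixel coordinates),
#' labelled 1..n along the axis. Every mask pixel receives exactly one
#' label. The axis sign is canonicalised (positive column component, or
#' positive row component when the axis is vertical) so the labelling is
#' reproducible.
#'
#' @param mask Logical matrix.
#' @param n Number of regions (default 10).
#' @return Integer label matrix (0 outside the mask) of class
#'   `ctcm_regions`, with attributes `axis` (unit 2-vector, (col, row)
#'   pixel coordinates) and `scan` (`"horizontal"` or `"vertical"`, the
#'   transect direction used for surface distances).
#' @export
partition_regions <- function(mask, n = 10) {
  if (!is.logical(mask)) mask <- mask > 0
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  ij <- which(mask, arr.ind = TRUE)
  xy <- cbind(col = ij[, 2] - mean(ij[, 2]), row = ij[, 1] - mean(ij[, 1]))
  if (nrow(xy) < 2) stop("mask too small to partition", call. = FALSE)
  cv <- crossprod(xy) / nrow(xy)
  ax <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  if (abs(ax[1]) >= abs(ax[2])) {
    if (ax[1] < 0) ax <- -ax
    scan <- "horizontal"
  } else {
    if (ax[2] < 0) ax <- -ax
    scan <- "vertical"
  }
  s <- xy %*% ax
  if (diff(range(s)) < n)
    stop(sprintf("mask spans fewer than n = %d pixels along its axis", n),
         call. = FALSE)
  breaks <- seq(min(s), max(s), length.out = n + 1)
  breaks[n + 1] <- breaks[n + 1] + 1e-9
  lab <- findInterval(s, breaks, rightmost.closed = TRUE)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[mask] <- 0L
  labels[cbind(ij[, 1], ij[, 2])] <- as.integer(lab)
  if (any(tabulate(lab, n) == 0))
    stop("partition produced an empty region", call. = FALSE)
  structure(labels, class = c("ctcm_regions", class(labels)),
            axis = as.numeric(ax), scan = scan)
}

#' Mean transect surface distance of a region
#'
#' The per-region "surface distance" used by the strain formula: for each
#' scan line (image row for a horizontal principal axis, column for a
#' vertical one) crossing the region, the 3-D polyline length
#' `sum(sqrt(dxy^2 + dz^2))` over adjacent in-region pixels; the region's
#' distance is the mean over scan lines with at least two adjacent pixels.
#' In the planar limit this is the region's in-plane width.
#'
#' @param height Height matrix (same length unit as `mm_per_px`).
#' @param region_mask Logical matrix of the region's pixels.
#' @param mm_per_px In-plane pixel pitch.
#' @param scan `"horizontal"` (walk along rows) or `"vertical"`.
#' @return Mean transect length (length units of `mm_per_px`).
#' @export
regional_surface_distance <- function(height, region_mask, mm_per_px,
                                      scan = "horizontal") {
  if (!is.logical(region_mask)) region_mask <- region_mask > 0
  stopifnot(identical(dim(region_mask), dim(height)))
  if (scan == "vertical") {
    height <- t(height); region_mask <- t(region_mask)
  }
  lengths <- numeric(0)
  for (r in seq_len(nrow(height))) {
    cols <- which(region_mask[r, ])
    if (length(cols) < 2) next
    adj <- which(diff(cols) == 1)
    if (!length(adj)) next
    z1 <- height[r, cols[adj]]
    z2 <- height[r, cols[adj + 1]]
    lengths <- c(lengths, sum(sqrt(mm_per_px^2 + (z2 - z1)^2)))
  }
  if (!length(lengths))
    stop("region has no scan line with two adjacent pixels", call. = FALSE)
  mean(lengths)
}

#' Regional strain between Up and Down height fields
#'
#' For each region the strain is `(S_up - S_down) / S_down` where `S_up`
#' and `S_down` are the region's mean transect surface distances in the Up
#' (most distended) and Down (least distended) reconstructions. Both fields
#' must come from the same reconstruction settings on the same mask so any
#' unknown global height scale is shared and partially cancels in the
#' ratio.
#'
#' @param h_up,h_down Height matrices on the same mask.
#' @param regions A `ctcm_regions` label matrix from [partition_regions()].
#' @param mm_per_px In-plane pixel pitch.
#' @return A data frame of class `ctcm_strain` with columns `region`,
#'   `S_up`, `S_down`, `strain`.
#' @export
regional_strain <- function(h_up, h_down, regions, mm_per_px) {
  stopifnot(inherits(regions, "ctcm_regions"),
            identical(dim(h_up), dim(h_down)))
  scan <- attr(regions, "scan")
  ids <- sort(unique(regions[regions > 0]))
  res <- lapply(ids, function(k) {
    rmask <- regions == k
    s_up <- regional_surface_distance(h_up, rmask, mm_per_px, scan)
    s_down <- regional_surface_distance(h_down, rmask, mm_per_px, scan)
    if (s_down <= 0) stop("S_down is zero in region ", k, call. = FALSE)
    data.frame(region = k, S_up = s_up, S_down = s_down,
               strain = (s_up - s_down) / s_down)
  })
  out <- do.call(rbind, res)
  class(out) <- c("ctcm_strain", "data.frame")
  out
}

#' Compare regional strains with and without stimulation
#'
#' Per-region percent difference of the group means,
#' `100 (mean_stim - mean_unstim) / mean_unstim`, with a paired two-tailed
#' Student t-test across slices. Swapping the two groups flips the sign of
#' the percent differences.
#'
#' @param strains_stim,strains_nostim Per-slice regional strains: either
#'   matrices (regions x slices) or lists of equal-length numeric vectors,
#'   paired slice by slice.
#' @return A data frame of class `ctcm_stim_comparison` with columns
#'   `region`, `strain_stim`, `strain_nostim`, `pct_difference`, `t`, `p`
#'   (`t`/`p` are `NA` with a single slice pair).
#' @export
compare_stim <- function(strains_stim, strains_nostim) {
  as_mat <- function(x) {
    if (is.list(x)) x <- do.call(cbind, x)
    as.matrix(x)
  }
  ms <- as_mat(strains_stim); mn <- as_mat(strains_nostim)
  if (!identical(dim(ms), dim(mn)))
    stop("stimulated and unstimulated inputs must be paired with equal sizes",
         call. = FALSE)
  nregion <- nrow(ms); nslice <- ncol(ms)
  mean_s <- rowMeans(ms); mean_n <- rowMeans(mn)
  pct <- 100 * (mean_s - mean_n) / mean_n
  tt <- rep(NA_real_, nregion); pp <- rep(NA_real_, nregion)
  for (r in seq_len(nregion)) {
    d <- ms[r, ] - mn[r, ]
    if (all(d == 0)) { tt[r] <- 0; pp[r] <- 1 }
    else if (nslice >= 2 && stats::sd(d) > 0) {
      ht <- stats::t.test(ms[r, ], mn[r, ], paired = TRUE)
      tt[r] <- unname(ht$statistic); pp[r] <- ht$p.value
    }
  }
  out <- data.frame(region = seq_len(nregion), strain_stim = mean_s,
                    strain_nostim = mean_n, pct_difference = pct,
                    t = tt, p = pp)
  class(out) <- c("ctcm_stim_comparison", "data.frame")
  out
}

#' Full optical strain analysis of one recording
#'
#' Runs the complete chain on a video: movement trace, filtering,
#' detrending, peak detection, Up/Down frame selection, tissue segmentation
#' (on the Up frame, unless a mask is supplied), shape-from-shading
#' reconstruction of both frames, partition into sub-surface regions, and
#' per-region strain.
#'
#' @param video A `ctcm_video`.
#' @param light_direction Light direction for shape from shading.
#' @param mask Optional precomputed tissue mask; segmented from the Down
#'   frame when `NULL` (the near-flat tissue has no shading-darkened rim,
#'   so the threshold recovers the full outline). Supplying the same mask
#'   to paired recordings keeps their regions aligned.
#' @param n_regions Number of sub-surface regions (default 10).
#' @param n_iter Shape-from-shading iterations.
#' @param albedo_normalize If `TRUE` (default), estimate the per-pixel
#'   albedo from the Down frame — the least-distended tissue is taken as
#'   near-planar, so `albedo = I_down / lz` — and divide it out of both
#'   frames before reconstruction. This cancels the (unknown) surface
#'   texture that shape from shading would otherwise mistake for slopes;
#'   strain is then measured relative to the assumed-planar Down
#'   configuration.
#' @param cutoff_hz,detrend_order,min_prominence_frac,min_separation_s
#'   Movement-trace stage parameters.
#' @return A list with `trace` (stage list from [analyze_trace()]),
#'   `up_frame`, `down_frame`, `mask`, `regions`, `h_up`, `h_down`, and
#'   `strain` (the [regional_strain()] table).
#' @export
analyze_strain <- function(video, light_direction, mask = NULL,
                           n_regions = 10, n_iter = 200,
                           albedo_normalize = TRUE, cutoff_hz = 5,
                           detrend_order = 6, min_prominence_frac = 0.3,
                           min_separation_s = 0.4) {
  full <- matrix(TRUE, nrow(video$frames[[1]]), ncol(video$frames[[1]]))
  tr <- movement_trace(video, full)
  stages <- analyze_trace(tr, cutoff_hz, detrend_order, min_prominence_frac,
                          min_separation_s)
  # rank the detected extrema on the raw trace: both the low-pass filter
  # and (on short clips) the polynomial fit shift the crest of the
  # asymmetric cycle by a frame or two
  ud <- select_extreme_frames(tr, stages$peaks)
  if (is.null(mask)) mask <- segment_tissue(video$frames[[ud$down_frame]])
  regions <- partition_regions(mask, n_regions)
  frame_up <- video$frames[[ud$up_frame]]
  frame_down <- video$frames[[ud$down_frame]]
  if (albedo_normalize) {
    L <- light_direction / sqrt(sum(light_direction^2))
    albedo_est <- pmax(frame_down / L[3], 1e-3)
    frame_up <- frame_up / albedo_est
    frame_up[frame_up > 1] <- 1
    frame_down <- matrix(L[3], nrow(frame_down), ncol(frame_down))
  }
  h_up <- shape_from_shading(frame_up, mask, light_direction, n_iter,
                             video$mm_per_px)
  h_down <- shape_from_shading(frame_down, mask, light_direction, n_iter,
                               video$mm_per_px)
  strain <- regional_strain(h_up, h_down, regions, video$mm_per_px)
  list(trace = stages, up_frame = ud$up_frame, down_frame = ud$down_frame,
       mask = mask, regions = regions, h_up = h_up, h_down = h_down,
       strain = strain)
}
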