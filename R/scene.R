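#' Scene parameters for synthetic beating-tissue recordings
#'
#' Describes the virtual camera/stage used by the synthetic-data generator:
#' image geometry, light direction for Lambertian shading, albedo texture,
#' sensor noise, frame rate, and optional slow baseline drift of the
#' illumination. The defaults emulate a top-down macro view of a 7-mm
#' ring-mounted slice filmed at 30 fps: a field of view slightly wider than
#' the ring, a light tilted 51 degrees from vertical (the obliquity of the
#' recording rig) at 45 degrees azimuth so both surface-gradient components
#' are constrained by shading, a mild smooth albedo texture (10% contrast —
#' heart-slice surfaces are fairly uniform at macro scale), and 1% additive
#' Gaussian sensor noise.
#'
#' @param image_size_px Integer `(rows, cols)` of each frame.
#' @param mm_per_px Pixel pitch in mm. Default `NULL` picks a 9-mm field of
#'   view across the smaller image dimension so the 7-mm ring fits with
#'   margin.
#' @param light_direction Unit 3-vector pointing towards the light, positive
#'   z (vertical) component. Non-unit inputs are normalised.
#' @param albedo_texture_seed Integer seed for the albedo texture (kept
#'   separate from the recording seed so the same virtual slice can be
#'   filmed under different noise realisations).
#' @param texture_contrast Relative amplitude of the smooth albedo texture.
#' @param tissue_albedo,background_albedo Mean albedo inside / outside the
#'   ring aperture.
#' @param noise_sd Additive Gaussian noise standard deviation as a fraction
#'   of the [0, 1] dynamic range.
#' @param fps Frame rate in Hz (default 30).
#' @param drift_coeffs Polynomial coefficients (intercept first, in
#'   normalised time `t / duration`) of a slow additive intensity drift.
#' @param camera_tilt_deg Optional oblique-camera approximation: frames are
#'   foreshortened by `cos(tilt)` along the image rows (an affine shear
#'   stand-in for the recording rig's 51-degree camera; default 0, the
#'   orthographic top-down view).
#' @param ring_radius_mm Support ring aperture radius in mm.
#' @return An object of class `ctcm_scene`.
#' @export
scene_params <- function(image_size_px = c(128L, 128L),
                         mm_per_px = NULL,
                         light_direction = c(sin(51 * pi / 180) * cos(pi / 4),
                                             sin(51 * pi / 180) * sin(pi / 4),
                                             cos(51 * pi / 180)),
                         albedo_texture_seed = 1L,
                         texture_contrast = 0.10,
                         tissue_albedo = 0.90,
                         background_albedo = 0.08,
                         noise_sd = 0.01,
                         fps = 30,
                         drift_coeffs = numeric(0),
                         camera_tilt_deg = 0,
                         ring_radius_mm = 3.5) {
  image_size_px <- as.integer(image_size_px)
  if (length(image_size_px) != 2 || any(image_size_px < 8))
    stop("`image_size_px` must be two integers >= 8", call. = FALSE)
  if (is.null(mm_per_px)) mm_per_px <- 9 / min(image_size_px)
  L <- as.numeric(light_direction)
  if (length(L) != 3 || !all(is.finite(L)) || L[3] <= 0)
    stop("`light_direction` must be a 3-vector with positive vertical component",
         call. = FALSE)
  L <- L / sqrt(sum(L^2))
  if (!is.finite(fps) || fps <= 0) stop("`fps` must be positive", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(list(
    image_size_px = image_size_px, mm_per_px = mm_per_px,
    light_direction = L, albedo_texture_seed = as.integer(albedo_texture_seed),
    texture_contrast = texture_contrast, tissue_albedo = tissue_albedo,
    background_albedo = background_albedo, noise_sd = noise_sd, fps = fps,
    drift_coeffs = as.numeric(drift_coeffs),
    camera_tilt_deg = camera_tilt_deg, ring_radius_mm = ring_radius_mm
  ), class = "ctcm_scene")
}

# Evaluate a polynomial with intercept-first coefficients at x.
polyval_drift <- function(coeffs, x) {
  if (length(coeffs) == 0) return(rep(0, length(x)))
  out <- rep(0, length(x))
  for (k in seq_along(coeffs)) out <- out + coeffs[k] * x^(k - 1)
  out
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Pixel-centre coordinate grids (mm), image centre at the ring centre.
scene_grid <- function(scene) {
  nr <- scene$image_size_px[1]; nc <- scene$image_size_px[2]
  x <- (seq_len(nc) - (nc + 1) / 2) * scene$mm_per_px
  y <- (seq_len(nr) - (nr + 1) / 2) * scene$mm_per_px
  list(x = matrix(x, nr, nc, byrow = TRUE),
       y = matrix(y, nr, nc, byrow = FALSE))
}

#' Ring-aperture mask for a scene
#'
#' Logical matrix marking pixels inside the support-ring aperture.
#'
#' @param scene A [scene_params()] object.
#' @return A logical matrix of the scene's image size.
#' @export
ring_mask <- function(scene) {
  g <- scene_grid(scene)
  sqrt(g$x^2 + g$y^2) <= scene$ring_radius_mm
}

#' Render the membrane height field of a spherical cap
#'
#' Samples the cap surface on the scene's pixel grid:
#' `z = sqrt(R^2 - r^2) - (R - h)` for radial distance `r <= a` from the
#' ring centre, 0 outside the aperture.
#'
#' @param cap A [cap_from_height()] geometry.
#' @param scene A [scene_params()] object; the ring must fit inside the
#'   image.
#' @return A numeric matrix of heights in mm with attribute `mm_per_px`.
#' @export
render_height_field <- function(cap, scene) {
  stopifnot(inherits(cap, "ctcm_cap"), inherits(scene, "ctcm_scene"))
  half_extent <- (min(scene$image_size_px) / 2) * scene$mm_per_px
  if (cap$a > half_extent)
    stop("ring aperture larger than the imaged field of view", call. = FALSE)
  g <- scene_grid(scene)
  r2 <- g$x^2 + g$y^2
  z <- matrix(0, scene$image_size_px[1], scene$image_size_px[2])
  if (cap$h > 0) {
    inside <- r2 <= cap$a^2
    z[inside] <- sqrt(cap$R^2 - r2[inside]) - (cap$R - cap$h)
  }
  attr(z, "mm_per_px") <- scene$mm_per_px
  z
}

# Central-difference gradients of a height matrix (one-sided at edges).
height_gradients <- function(z, mm_per_px) {
  nr <- nrow(z); nc <- ncol(z)
  zx <- matrix(0, nr, nc); zy <- matrix(0, nr, nc)
  zx[, 2:(nc - 1)] <- (z[, 3:nc] - z[, 1:(nc - 2)]) / (2 * mm_per_px)
  zx[, 1] <- (z[, 2] - z[, 1]) / mm_per_px
  zx[, nc] <- (z[, nc] - z[, nc - 1]) / mm_per_px
  zy[2:(nr - 1), ] <- (z[3:nr, ] - z[1:(nr - 2), ]) / (2 * mm_per_px)
  zy[1, ] <- (z[2, ] - z[1, ]) / mm_per_px
  zy[nr, ] <- (z[nr, ] - z[nr - 1, ]) / mm_per_px
  list(zx = zx, zy = zy)
}

#' Lambertian shading of a height field
#'
#' Renders image intensity `I = albedo * max(0, n . L)` where `n` is the
#' unit surface normal from central-difference gradients of the height field
#' and `L` the scene light direction; the result is clipped to [0, 1].
#'
#' @param height Height matrix in mm (e.g. from [render_height_field()]).
#' @param scene A [scene_params()] object.
#' @param albedo Albedo matrix (or scalar) in [0, 1]; default 1.
#' @return Intensity matrix in [0, 1].
#' @export
lambertian_render <- function(height, scene, albedo = 1) {
  stopifnot(inherits(scene, "ctcm_scene"))
  if (!all(is.finite(height))) stop("height field must be finite", call. = FALSE)
  g <- height_gradients(height, scene$mm_per_px)
  L <- scene$light_direction
  # surface normal is (-zx, -zy, 1) / |.|
  ndotl <- (L[3] - g$zx * L[1] - g$zy * L[2]) / sqrt(1 + g$zx^2 + g$zy^2)
  ndotl[ndotl < 0] <- 0
  img <- albedo * ndotl
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

# Smooth band-limited albedo texture: coarse white noise bilinearly
# upsampled to frame size, scaled to +/- texture_contrast about the tissue
# albedo inside the ring; constant background albedo outside.
make_albedo <- function(scene) {
  nr <- scene$image_size_px[1]; nc <- scene$image_size_px[2]
  coarse <- max(4L, round(min(nr, nc) / 16))
  tex <- with_seed(scene$albedo_texture_seed,
                   matrix(stats::rnorm(coarse * coarse), coarse, coarse))
  tex <- as.matrix(EBImage::resize(EBImage::Image(tex), w = nr, h = nc))
  tex <- tex / max(abs(tex), 1e-12)
  alb <- scene$tissue_albedo * (1 + scene$texture_contrast * tex)
  alb <- pmin(pmax(alb, 0.01), 1)
  alb[!ring_mask(scene)] <- scene$background_albedo
  alb
}

# Affine oblique-camera approximation: foreshorten rows by cos(tilt).
apply_camera_tilt <- function(frame, scene) {
  if (scene$camera_tilt_deg == 0) return(frame)
  nr <- nrow(frame)
  nr_out <- max(2L, round(nr * cos(scene$camera_tilt_deg * pi / 180)))
  sq <- as.matrix(EBImage::resize(EBImage::Image(frame), w = nr_out,
                                  h = ncol(frame)))
  out <- matrix(0, nr, ncol(frame))
  r0 <- floor((nr - nr_out) / 2)
  out[(r0 + 1):(r0 + nr_out), ] <- sq
  out
}
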