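# Synthetic cell tracks from the forward model and a minimal
# moments-based ellipse fit on binary masks.

#' Frame-noise specification for synthetic tracks
#'
#' @param axis_sd Additive Gaussian noise standard deviation on each axis
#'   per frame, in m (>= 0).
#' @param frame_rate Camera frame rate in Hz (default 100).
#' @param seed Optional integer seed; a fixed seed makes the track
#'   reproducible.
#'
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(axis_sd = 0, frame_rate = 100, seed = NULL) {
  if (!is.finite(axis_sd) || axis_sd < 0)
    stop("'axis_sd' must be >= 0", call. = FALSE)
  if (!is.finite(frame_rate) || frame_rate <= 0)
    stop("'frame_rate' must be > 0", call. = FALSE)
  structure(list(axis_sd = axis_sd, frame_rate = frame_rate, seed = seed),
            class = "noise_spec")
}

# evaluate fn() under a temporary RNG state seeded with 'seed'
with_local_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic noisy cell track from the forward model
#'
#' Runs the Kelvin-Voigt forward model under a loading profile, maps the
#' extension ratio to ellipse axes by `b(t) = b0 / lambda(t)` and
#' `a(t) = a0 * lambda(t)`, samples at the camera frame rate, and adds
#' i.i.d. Gaussian noise per frame on each axis. With a fixed
#' `noise$seed` the track is fully deterministic.
#'
#' @param material A [material_model].
#' @param profile A [loading_profile].
#' @param law A [stress_law].
#' @param b0,a0 Undeformed minor and major semi-axes in m.
#' @param noise A [noise_spec].
#' @param ... Passed to [simulate_cell()] (e.g. `rtol`).
#'
#' @return A [cell_track].
#' @export
generate_track <- function(material, profile, law = stress_law(),
                           b0 = 3.9e-6, a0 = 3.9e-6,
                           noise = noise_spec(), ...) {
  stopifnot(inherits(noise, "noise_spec"))
  if (b0 <= 0 || a0 <= 0) stop("'a0' and 'b0' must be > 0", call. = FALSE)
  dt <- 1 / noise$frame_rate
  sim <- simulate_cell(material, profile, law, output_dt = dt, ...)
  a <- a0 * sim$lambda
  b <- b0 / sim$lambda
  if (noise$axis_sd > 0) {
    n <- length(a)
    noise_ab <- with_local_seed(noise$seed,
                                function() stats::rnorm(2 * n, 0,
                                                        noise$axis_sd))
    a <- a + noise_ab[seq_len(n)]
    b <- b + noise_ab[n + seq_len(n)]
  }
  b <- pmax(b, 1e-9)  # noise must not produce nonpositive axes
  a <- pmax(a, 1e-9)
  cell_track(sim$time, a, b, b0 = b0)
}

#' Equivalent-ellipse fit of a binary mask by image moments
#'
#' Computes the semi-axes and orientation of the ellipse with the same
#' second central moments as the foreground region of a binary mask
#' (the equivalent-ellipse convention; a filled ellipse of semi-axes a, b
#' has second central moments a^2/4 and b^2/4 along its principal axes).
#' A 1/12-pixel variance term accounts for the finite pixel footprint, so
#' a single foreground pixel yields axes at the pixel scale rather than
#' zero.
#'
#' @param mask Logical or 0/1 matrix; rows index x, columns y.
#' @param pixel_size Pixel edge length in m.
#'
#' @return List with `a`, `b` (semi-axes in m, `a >= b`) and `orientation`
#'   (radians, major axis against the row direction).
#' @export
ellipse_from_mask <- function(mask, pixel_size = 1) {
  m <- as.matrix(mask)
  fg <- which(m != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("mask has no foreground pixels", call. = FALSE)
  xy <- fg - rep(colMeans(fg), each = nrow(fg))
  cov2 <- crossprod(xy) / nrow(fg) + diag(1 / 12, 2)
  ei <- eigen(cov2, symmetric = TRUE)
  axes <- 2 * sqrt(ei$values)
  v <- ei$vectors[, 1]
  ang <- atan2(v[2], v[1]) %% pi          # axis direction: fold to (-pi/2, pi/2]
  if (ang > pi / 2) ang <- ang - pi
  list(a = axes[1] * pixel_size, b = axes[2] * pixel_size,
       orientation = ang)
}

#' Rasterize a filled ellipse into a binary mask
#'
#' Utility for testing the moments-based ellipse fit: a pixel is foreground
#' when its centre lies inside the ellipse.
#'
#' @param a,b Semi-axes in pixels.
#' @param orientation Rotation in radians.
#' @param pad Margin in pixels around the bounding box.
#'
#' @return A logical matrix.
#' @export
ellipse_mask <- function(a, b, orientation = 0, pad = 3) {
  r <- ceiling(max(a, b)) + pad
  n <- 2L * r + 1L
  ctr <- r + 1
  x <- matrix(seq_len(n) - ctr, n, n)
  y <- t(x)
  xr <- cos(orientation) * x + sin(orientation) * y
  yr <- -sin(orientation) * x + cos(orientation) * y
  (xr / a)^2 + (yr / b)^2 <= 1
}
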