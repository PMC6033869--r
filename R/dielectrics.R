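# Single-shell ellipsoid dielectric model: complex permittivities,
# depolarization factors, Clausius-Mossotti factor.

#' Vacuum permittivity (F/m)
#'
#' @keywords internal
#' @noRd
.EPS0 <- 8.8541878128e-12

#' Dielectric properties of a single material layer
#'
#' @param rel_permittivity Dimensionless relative permittivity (>= 0).
#' @param conductivity Electrical conductivity in S/m (>= 0).
#'
#' @return An object of class `dielectric_spec`.
#' @examples
#' pbs_sucrose <- dielectric_spec(rel_permittivity = 78, conductivity = 0.018)
#' @export
dielectric_spec <- function(rel_permittivity, conductivity) {
  stopifnot(is.numeric(rel_permittivity), length(rel_permittivity) == 1L,
            is.numeric(conductivity), length(conductivity) == 1L)
  if (!is.finite(rel_permittivity) || rel_permittivity < 0)
    stop("'rel_permittivity' must be finite and >= 0", call. = FALSE)
  if (!is.finite(conductivity) || conductivity < 0)
    stop("'conductivity' must be finite and >= 0", call. = FALSE)
  structure(list(rel_permittivity = rel_permittivity,
                 conductivity = conductivity),
            class = "dielectric_spec")
}

#' @export
print.dielectric_spec <- function(x, ...) {
  cat(sprintf("<dielectric_spec> eps_r = %g, sigma = %g S/m\n",
              x$rel_permittivity, x$conductivity))
  invisible(x)
}

#' Membrane and cytoplasm dielectrics of a shelled cell
#'
#' The cell is modelled as a homogeneous cytoplasm core wrapped in a thin
#' membrane shell of uniform thickness.
#'
#' @param membrane,cytoplasm [dielectric_spec] objects for shell and core.
#' @param membrane_thickness Shell thickness in m (default 4.5e-9).
#'
#' @return An object of class `cell_dielectrics`.
#' @export
cell_dielectrics <- function(membrane, cytoplasm, membrane_thickness = 4.5e-9) {
  stopifnot(inherits(membrane, "dielectric_spec"),
            inherits(cytoplasm, "dielectric_spec"))
  if (!is.numeric(membrane_thickness) || length(membrane_thickness) != 1L ||
      !is.finite(membrane_thickness) || membrane_thickness <= 0)
    stop("'membrane_thickness' must be a single positive number (m)",
         call. = FALSE)
  structure(list(membrane = membrane, cytoplasm = cytoplasm,
                 membrane_thickness = membrane_thickness),
            class = "cell_dielectrics")
}

#' Triaxial ellipsoid geometry of the deformed cell
#'
#' Semi-axes of the ellipsoid model: `a` along the stretch direction (x),
#' `b` the in-plane minor semi-axis (y), `c` the out-of-plane semi-axis (z),
#' which for a trapped red blood cell is taken constant at 1.3 um.
#'
#' @param a,b,c Semi-axes in m; all must be positive.
#'
#' @return An object of class `ellipsoid_geometry`.
#' @examples
#' ellipsoid_geometry(a = 4.2e-6, b = 2.6e-6)
#' @export
ellipsoid_geometry <- function(a, b, c = 1.3e-6) {
  ax <- c(a = a, b = b, c = c)
  if (!all(is.finite(ax)) || any(ax <= 0))
    stop("all semi-axes must be finite and > 0", call. = FALSE)
  structure(list(a = a, b = b, c = c), class = "ellipsoid_geometry")
}

#' @export
print.ellipsoid_geometry <- function(x, ...) {
  cat(sprintf("<ellipsoid_geometry> a = %g um, b = %g um, c = %g um\n",
              x$a * 1e6, x$b * 1e6, x$c * 1e6))
  invisible(x)
}

#' Excitation context: carrier frequency and suspending medium
#'
#' @param frequency Carrier frequency in Hz (> 0); the experiments use
#'   1.58 MHz.
#' @param medium [dielectric_spec] of the suspending medium.
#'
#' @return An object of class `excitation_context`.
#' @export
excitation_context <- function(frequency, medium) {
  if (!is.numeric(frequency) || length(frequency) != 1L ||
      !is.finite(frequency) || frequency <= 0)
    stop("'frequency' must be a single positive number (Hz)", call. = FALSE)
  stopifnot(inherits(medium, "dielectric_spec"))
  structure(list(frequency = frequency, medium = medium),
            class = "excitation_context")
}

#' Complex relative permittivity of a lossy dielectric
#'
#' Returns `eps - j * sigma / (omega * eps0)` in relative-permittivity units,
#' with `omega = 2 * pi * frequency`. Lossy media have a negative imaginary
#' part under this sign convention.
#'
#' @param spec A [dielectric_spec].
#' @param frequency Frequency in Hz (> 0).
#'
#' @return A complex scalar (relative units).
#' @examples
#' complex_permittivity(dielectric_spec(78, 0.018), 1.58e6)
#' @export
complex_permittivity <- function(spec, frequency) {
  stopifnot(inherits(spec, "dielectric_spec"))
  if (!is.numeric(frequency) || length(frequency) != 1L ||
      !is.finite(frequency) || frequency <= 0)
    stop("'frequency' must be a single positive number (Hz)", call. = FALSE)
  omega <- 2 * pi * frequency
  complex(real = spec$rel_permittivity,
          imaginary = -spec$conductivity / (omega * .EPS0))
}

#' Depolarization factors of a triaxial ellipsoid
#'
#' Computes the three depolarization factors
#' \deqn{A_i = \frac{abc}{2} \int_0^\infty \frac{ds}{(s + a_i^2)
#'   \sqrt{(s+a^2)(s+b^2)(s+c^2)}}}
#' by adaptive quadrature after the substitution `s = a_i^2 * u / (1 - u)`,
#' which maps the infinite range onto (0, 1). The three factors sum to 1.
#'
#' @param geom An [ellipsoid_geometry].
#'
#' @return Named numeric vector `c(A_a, A_b, A_c)`, each in (0, 1).
#' @examples
#' depolarization_factors(ellipsoid_geometry(1e-6, 1e-6, 1e-6)) # 1/3 each
#' @export
depolarization_factors <- function(geom) {
  stopifnot(inherits(geom, "ellipsoid_geometry"))
  # the factors are scale invariant; normalise to unit scale for conditioning
  scale <- (geom$a * geom$b * geom$c)^(1 / 3)
  ax <- c(geom$a, geom$b, geom$c) / scale
  one <- function(i) {
    ai2 <- ax[i]^2
    # s = ai2 * u/(1-u), ds = ai2 du/(1-u)^2
    f <- function(u) {
      s <- ai2 * u / (1 - u)
      B <- sqrt((s + ax[1]^2) * (s + ax[2]^2) * (s + ax[3]^2))
      ai2 / (1 - u)^2 / ((s + ai2) * B)
    }
    val <- stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 0,
                            subdivisions = 500L)
    prod(ax) / 2 * val$value
  }
  out <- c(A_a = one(1), A_b = one(2), A_c = one(3))
  out
}

#' Clausius-Mossotti factor of a single-shell ellipsoid
#'
#' Evaluates the single-shell (membrane-covered) ellipsoid Clausius-Mossotti
#' factor along one principal axis, using complex permittivities of membrane,
#' cytoplasm and medium. The shell volume fraction is
#' `rho = (a-t)(b-t)(c-t) / (abc)`; `A1` is the depolarization factor of the
#' outer ellipsoid and `A2` that of the inner (core) ellipsoid with all
#' semi-axes reduced by the membrane thickness `t`.
#'
#' @param geom Outer [ellipsoid_geometry].
#' @param cell [cell_dielectrics] (membrane, cytoplasm, thickness).
#' @param ctx [excitation_context] (frequency, medium).
#' @param axis Which principal axis factor to return: `"a"` (stretch
#'   direction, the one entering the DEP force), `"b"` or `"c"`.
#'
#' @return A complex scalar.
#' @examples
#' geom <- ellipsoid_geometry(4.2e-6, 2.6e-6)
#' cell <- cell_dielectrics(dielectric_spec(4.44, 10),
#'                          dielectric_spec(59, 0.31))
#' ctx <- excitation_context(1.58e6, dielectric_spec(78, 0.018))
#' cm_factor(geom, cell, ctx, axis = "a")
#' @export
cm_factor <- function(geom, cell, ctx, axis = c("a", "b", "c")) {
  stopifnot(inherits(geom, "ellipsoid_geometry"),
            inherits(cell, "cell_dielectrics"),
            inherits(ctx, "excitation_context"))
  axis <- match.arg(axis)
  t <- cell$membrane_thickness
  if (t >= min(geom$a, geom$b, geom$c))
    stop("membrane thickness must be smaller than every semi-axis",
         call. = FALSE)
  inner <- ellipsoid_geometry(geom$a - t, geom$b - t, geom$c - t)
  idx <- match(axis, c("a", "b", "c"))
  A1 <- depolarization_factors(geom)[idx]
  A2 <- depolarization_factors(inner)[idx]
  rho <- (inner$a * inner$b * inner$c) / (geom$a * geom$b * geom$c)
  e_mem <- complex_permittivity(cell$membrane, ctx$frequency)
  e_cyt <- complex_permittivity(cell$cytoplasm, ctx$frequency)
  e_med <- complex_permittivity(ctx$medium, ctx$frequency)
  num <- (e_mem - e_med) * (e_mem + A1 * (e_cyt - e_mem)) +
    rho * (e_cyt - e_mem) * (e_mem - A1 * (e_mem - e_med))
  den <- (e_med + A1 * (e_mem - e_med)) * (e_mem + A1 * (e_cyt - e_mem)) +
    rho * A2 * (1 - A2) * (e_cyt - e_mem) * (e_mem - e_med)
  unname(num / den / 3)
}
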