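# Voxelized slab phantoms: a homogeneous "chicken-breast-like" background
# with an embedded strongly absorbing rod as imaging target, plus the
# illumination beam description.

#' Construct an optical phantom
#'
#' A voxel grid of optical properties. Coordinates: x and y are lateral
#' (origin at the slab centre), z increases downward from the illuminated
#' top face. Voxel `[i, j, k]` has its centre at
#' `((i - 1/2) h - Lx/2, (j - 1/2) h - Ly/2, (k - 1/2) h)` with `h` the
#' voxel size.
#'
#' @param mu_a,mu_s 3-D arrays of absorption / scattering coefficients
#'   (1/cm), non-negative.
#' @param g 3-D array (or scalar) of scattering anisotropy in \[-1, 1\].
#' @param labels 3-D integer array of region ids: 0 = intermediate medium,
#'   1 = target.
#' @param voxel_mm Voxel edge length in mm.
#' @return An object of class `optical_phantom`.
#' @export
optical_phantom <- function(mu_a, mu_s, g, labels, voxel_mm) {
  d <- dim(mu_a)
  if (length(d) != 3L) stop("`mu_a` must be a 3-D array")
  if (length(g) == 1L) g <- array(g, dim = d)
  if (!identical(dim(mu_s), d) || !identical(dim(g), d) ||
      !identical(dim(labels), d))
    stop("all property arrays must share the same dimensions")
  if (any(mu_a < 0) || any(mu_s < 0)) stop("mu_a and mu_s must be non-negative")
  if (any(abs(g) > 1)) stop("anisotropy g must lie in [-1, 1]")
  if (!is.numeric(voxel_mm) || voxel_mm <= 0) stop("`voxel_mm` must be positive")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g,
                 labels = array(as.integer(labels), dim = d),
                 voxel_mm = voxel_mm),
            class = "optical_phantom")
}

#' @export
print.optical_phantom <- function(x, ...) {
  d <- dim(x$mu_a)
  cat(sprintf("optical_phantom: %d x %d x %d voxels at %.3g mm (%.3g x %.3g x %.3g mm)\n",
              d[1], d[2], d[3], x$voxel_mm,
              d[1] * x$voxel_mm, d[2] * x$voxel_mm, d[3] * x$voxel_mm))
  cat(sprintf("  target voxels: %d of %d\n", sum(x$labels == 1L), length(x$labels)))
  invisible(x)
}

#' Voxel-centre coordinate arrays for a phantom (mm)
#'
#' @param phantom An `optical_phantom`.
#' @return List with vectors `x`, `y` (lateral, centred) and `z` (depth).
#' @export
phantom_coords <- function(phantom) {
  d <- dim(phantom$mu_a)
  h <- phantom$voxel_mm
  list(x = (seq_len(d[1]) - 0.5) * h - d[1] * h / 2,
       y = (seq_len(d[2]) - 0.5) * h - d[2] * h / 2,
       z = (seq_len(d[3]) - 0.5) * h)
}

#' Recipe for a slab-with-rod phantom
#'
#' Captures the simulation-study geometry: a homogeneous tissue slab
#' (default mu_a = 0.3 1/cm, mus' = 10 1/cm, chicken-breast-like) with a
#' 1 mm square-section rod of mu_a = 30 1/cm embedded at a given depth,
#' illuminated from the top by a uniform 1 cm diameter beam.
#'
#' @param target_depth Depth of the rod axis below the illuminated face (mm).
#' @param slab_mm Slab extent `c(Lx, Ly, Lz)` in mm. The default is wide
#'   enough laterally (64 mm) that the hemispherical shell through the
#'   deepest target (30 mm) lies entirely inside the slab; the shell noise
#'   model is only meaningful in that regime.
#' @param voxel_mm Voxel edge (mm).
#' @param rod_thickness Rod thickness (mm); 0 removes the target entirely
#'   (background-only phantom for noise runs).
#' @param rod_length Rod length along its axis (mm); defaults to the beam
#'   diameter.
#' @param rod_axis `"y"` (default) or `"x"`: lateral direction of the rod axis.
#' @param mu_a_bg,mus_prime_bg Background absorption / reduced scattering (1/cm).
#' @param mu_a_target Target absorption (1/cm).
#' @param g Scattering anisotropy used everywhere; mu_s = mus' / (1 - g).
#' @param beam_diameter_cm Illumination beam diameter (cm).
#' @param seed Integer carried along for provenance of downstream draws.
#' @return An object of class `phantom_recipe`.
#' @export
phantom_recipe <- function(target_depth = 20, slab_mm = c(64, 64, 32),
                           voxel_mm = 0.5, rod_thickness = 1,
                           rod_length = 10, rod_axis = c("y", "x"),
                           mu_a_bg = 0.3, mus_prime_bg = 10, mu_a_target = 30,
                           g = 0.9, beam_diameter_cm = 1, seed = 1L) {
  rod_axis <- match.arg(rod_axis)
  stopifnot(length(slab_mm) == 3L, all(slab_mm > 0), voxel_mm > 0,
            rod_thickness >= 0, rod_length > 0,
            mu_a_bg >= 0, mus_prime_bg > 0, mu_a_target >= 0,
            abs(g) < 1, beam_diameter_cm > 0)
  if (rod_thickness > 0) {
    if (target_depth - rod_thickness / 2 < 0 ||
        target_depth + rod_thickness / 2 > slab_mm[3])
      stop("rod extends outside the slab in depth")
    lat <- if (rod_axis == "y") slab_mm[1] else slab_mm[2]
    axl <- if (rod_axis == "y") slab_mm[2] else slab_mm[1]
    if (rod_thickness > lat || rod_length > axl)
      stop("rod extends outside the slab laterally")
  }
  if (beam_diameter_cm * 10 > min(slab_mm[1:2]))
    stop("beam footprint exceeds the top face")
  structure(list(target_depth = target_depth, slab_mm = slab_mm,
                 voxel_mm = voxel_mm, rod_thickness = rod_thickness,
                 rod_length = rod_length, rod_axis = rod_axis,
                 mu_a_bg = mu_a_bg, mus_prime_bg = mus_prime_bg,
                 mu_a_target = mu_a_target, g = g,
                 beam_diameter_cm = beam_diameter_cm, seed = as.integer(seed)),
            class = "phantom_recipe")
}

#' Build the slab-with-rod phantom from a recipe
#'
#' @param recipe A [phantom_recipe()].
#' @return An `optical_phantom` in reference thermal state (no `gamma` set;
#'   apply [apply_temperature()] before acoustic modelling).
#' @export
build_slab_rod_phantom <- function(recipe) {
  stopifnot(inherits(recipe, "phantom_recipe"))
  h <- recipe$voxel_mm
  d <- as.integer(round(recipe$slab_mm / h))
  mu_s_bg <- recipe$mus_prime_bg / (1 - recipe$g)

  mu_a <- array(recipe$mu_a_bg, dim = d)
  mu_s <- array(mu_s_bg, dim = d)
  labels <- array(0L, dim = d)

  if (recipe$rod_thickness > 0) {
    x <- (seq_len(d[1]) - 0.5) * h - d[1] * h / 2
    y <- (seq_len(d[2]) - 0.5) * h - d[2] * h / 2
    z <- (seq_len(d[3]) - 0.5) * h
    half_t <- recipe$rod_thickness / 2
    half_l <- recipe$rod_length / 2
    in_z <- abs(z - recipe$target_depth) <= half_t
    if (recipe$rod_axis == "y") {
      in_lat <- abs(x) <= half_t; in_ax <- abs(y) <= half_l
      rod <- outer(in_lat, in_ax) # nx x ny
    } else {
      in_ax <- abs(x) <= half_l; in_lat <- abs(y) <= half_t
      rod <- outer(in_ax, in_lat)
    }
    sel <- array(rep(rod, times = d[3]), dim = d) &
      array(rep(in_z, each = d[1] * d[2]), dim = d)
    mu_a[sel] <- recipe$mu_a_target
    labels[sel] <- 1L
  }
  optical_phantom(mu_a, mu_s, recipe$g, labels, voxel_mm = h)
}

#' Illumination beam specification
#'
#' Uniform circular beam at normal incidence on the top face, centred on
#' the slab axis by default.
#'
#' @param diameter_cm Beam diameter in cm (0 gives a pencil beam on axis).
#' @param center_mm Lateral offset `c(x, y)` of the beam centre (mm).
#' @param total_energy Launched energy; results are per unit launched
#'   energy so the default 1 is rarely changed.
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(diameter_cm = 1, center_mm = c(0, 0), total_energy = 1) {
  stopifnot(diameter_cm >= 0, length(center_mm) == 2L, total_energy > 0)
  structure(list(profile = "uniform_disk", diameter_cm = diameter_cm,
                 center_mm = center_mm, total_energy = total_energy),
            class = "beam_spec")
}
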