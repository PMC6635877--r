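#' Optical model of the imaging system
#'
#' Bundles the point-spread-function and camera parameters used by the
#' simulator and by photometric oracles. The PSF is modelled as a 3D
#' Gaussian: lateral sigma `psf_sigma_lateral`, axial sigma
#' `psf_sigma_axial`. An emitter displaced axially by `z` contributes its
#' photons attenuated by `exp(-z^2 / (2 sigma_axial^2))` while keeping the
#' lateral width fixed; this is the standard Gaussian surrogate where the
#' true PSF form is not modelled.
#'
#' @param psf_sigma_lateral Lateral PSF standard deviation in nm. The
#'   default 160 nm gives fitted focus widths of roughly 250 nm full sigma
#'   on 80 nm pixels, matching diffraction-limited spots of yellow
#'   fluorescent protein imaged at high numerical aperture.
#' @param psf_sigma_axial Axial PSF standard deviation in nm.
#' @param pixel_size Pixel size in nm/pixel (80 for Slimfield EMCCD
#'   acquisition, 41.5 for the confocal acquisitions).
#' @param counts_per_photon Linear camera gain, counts per detected photon.
#' @param baseline Camera offset in counts.
#' @param exposure Exposure time per frame in ms.
#' @return An object of class `optical_model`.
#' @export
optical_model <- function(psf_sigma_lateral = 160, psf_sigma_axial = 400,
                          pixel_size = 80, counts_per_photon = 10,
                          baseline = 100, exposure = 5) {
  if (psf_sigma_lateral <= 0 || psf_sigma_axial <= 0 || pixel_size <= 0)
    stop("PSF sigmas and pixel size must be positive", call. = FALSE)
  if (counts_per_photon <= 0)
    stop("counts_per_photon must be positive", call. = FALSE)
  if (baseline < 0) stop("baseline must be non-negative", call. = FALSE)
  if (exposure <= 0) stop("exposure must be positive", call. = FALSE)
  structure(list(psf_sigma_lateral = psf_sigma_lateral,
                 psf_sigma_axial = psf_sigma_axial,
                 pixel_size = pixel_size,
                 counts_per_photon = counts_per_photon,
                 baseline = baseline,
                 exposure = exposure),
            class = "optical_model")
}

#' Spherocylindrical cell geometry
#'
#' A rod-shaped cell is modelled as a cylinder of the given radius capped
#' by hemispheres (a spherocylinder), with its long axis along x and its
#' centre at the origin. A thylakoid membrane shell of thickness
#' `thylakoid_thickness` lines the inside of the cell envelope; the volume
#' inside the shell is cytosol. Both compartments emit background photons
#' at the given volumetric densities, which emulates cytosolic fluorescence
#' and chlorophyll bleed-through into the detection channel.
#'
#' @param length Total cell length in µm (tip to tip); must be at least
#'   one diameter.
#' @param radius Cell half-width in µm.
#' @param thylakoid_thickness Thickness of the thylakoid shell in µm.
#' @param thylakoid_photon_density Photons per µm^3 per frame emitted from
#'   the thylakoid shell.
#' @param cytosol_photon_density Photons per µm^3 per frame emitted from
#'   the cytosol.
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(length = 3, radius = 0.5,
                          thylakoid_thickness = 0.1,
                          thylakoid_photon_density = 0,
                          cytosol_photon_density = 0) {
  if (length < 2 * radius)
    stop("cell length must be at least one diameter (2 * radius)",
         call. = FALSE)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (thylakoid_thickness < 0 || thylakoid_thickness > radius)
    stop("thylakoid_thickness must lie in [0, radius]", call. = FALSE)
  if (thylakoid_photon_density < 0 || cytosol_photon_density < 0)
    stop("photon densities must be non-negative", call. = FALSE)
  structure(list(length = length, radius = radius,
                 thylakoid_thickness = thylakoid_thickness,
                 thylakoid_photon_density = thylakoid_photon_density,
                 cytosol_photon_density = cytosol_photon_density),
            class = "cell_geometry")
}

#' Specification of one fluorescent organelle
#'
#' @param position Numeric length-3, (x, y, z) in µm relative to the cell
#'   centre.
#' @param diameter Organelle diameter in nm (rendered as a point emitter by
#'   default since typical organelle diameters are below twice the PSF
#'   sigma).
#' @param copy_number Integer number of fluorophores in the organelle.
#' @param photons_per_fluorophore Photons emitted per fluorophore per frame.
#' @param bleach_rate Per-frame photobleaching rate (1/frame); each
#'   fluorophore bleaches independently at an exponentially distributed
#'   frame.
#' @param diffusion_coefficient Diffusion coefficient in µm^2/s.
#' @return An object of class `organelle_spec`.
#' @export
organelle_spec <- function(position = c(0, 0, 0), diameter = 200,
                           copy_number = 1, photons_per_fluorophore = 100,
                           bleach_rate = 0, diffusion_coefficient = 0) {
  if (length(position) != 3) stop("position must be (x, y, z)", call. = FALSE)
  if (copy_number < 0) stop("copy_number must be >= 0", call. = FALSE)
  if (diameter < 0) stop("diameter must be >= 0", call. = FALSE)
  if (bleach_rate < 0) stop("bleach_rate must be >= 0", call. = FALSE)
  if (diffusion_coefficient < 0)
    stop("diffusion_coefficient must be >= 0", call. = FALSE)
  structure(list(position = as.numeric(position), diameter = diameter,
                 copy_number = as.integer(copy_number),
                 photons_per_fluorophore = photons_per_fluorophore,
                 bleach_rate = bleach_rate,
                 diffusion_coefficient = diffusion_coefficient),
            class = "organelle_spec")
}

#' Test whether points lie inside the spherocylindrical cell
#'
#' @param pos Numeric `(x, y, z)` position in µm, or a matrix with one
#'   point per row.
#' @param geometry A [cell_geometry()].
#' @return Logical vector.
#' @export
inside_cell <- function(pos, geometry) {
  pos <- matrix(pos, ncol = 3)
  half_axis <- geometry$length / 2 - geometry$radius
  ax <- pmax(abs(pos[, 1]) - half_axis, 0)
  ax^2 + pos[, 2]^2 + pos[, 3]^2 <= geometry$radius^2
}

# distance from the cell axis (capsule core segment), vectorised
.capsule_radial_dist <- function(x, y, geometry) {
  half_axis <- geometry$length / 2 - geometry$radius
  ax <- pmax(abs(x) - half_axis, 0)
  sqrt(ax^2 + y^2)
}
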