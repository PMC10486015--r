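#' Bundled reference cohort of paired alveolar and fibula bone samples
#'
#' Per-sample morphometric values from a published cohort of eight patients
#' with paired alveolar (AB, recipient-site jaw) and fibula (FB, donor-site)
#' cortical bone samples imaged by synchrotron micro-CT at two voxel sizes
#' (2.27 um and 640 nm). Five tables are bundled as plain CSV:
#'
#' * `gross` - gross bone morphology at 2.27 um (vessel porosity, lacunar
#'   density, mineral/vessel cumulative distances, mineral volume, vessel
#'   surface ratios), four patient pairs.
#' * `shape` - lacunar shape descriptors at 640 nm (counts, density, volume
#'   mean/SD, axis-ratio means/SDs, vessel porosity), seven patient pairs.
#' * `resolution` - lacunar density of the six scans measured at both voxel
#'   sizes.
#' * `orientation` - vessel-network orientation-histogram amplitude
#'   variances (s_phi, s_theta), the printed LOA values and FB/AB ratios.
#' * `permeability` - permeability-tensor eigenvalue ratios and the printed
#'   inverse values.
#'
#' These tables drive the statistics stage without requiring the original
#' scans.
#'
#' @return named list of data frames.
#' @examples
#' ct <- cohort_tables()
#' group_summary(ct$gross, "lacunar_density_per_mm3")
#' @export
cohort_tables <- function() {
  dir <- system.file("extdata", package = "cortmorph")
  rd <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                             colClasses = c(patient_id = "character"))
  list(gross = rd("cohort_gross_2p27um.csv"),
       shape = rd("cohort_lacunae_640nm.csv"),
       resolution = rd("cohort_density_resolution.csv"),
       orientation = rd("cohort_orientation_loa.csv"),
       permeability = rd("cohort_permeability.csv"))
}
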