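#' Dissolution concentration of the pyruvate preparation
#'
#' Molar concentration obtained when a weighed amount of [1-13C]pyruvic acid
#' is dissolved to a final volume, as in dissolution dynamic nuclear
#' polarization: 26.7 mg at 89.07 g/mol into 3.8 mL gives 79 mM.
#'
#' @param mass_mg mass of pyruvic acid in mg
#' @param volume_ml final dissolution volume in mL
#' @param molar_mass molar mass in g/mol (default [1-13C]pyruvic acid,
#'   89.07 g/mol)
#' @return concentration in mM
#' @examples
#' round(dissolution_concentration_mM(26.7, 3.8))  # 79 mM
#' @export
dissolution_concentration_mM <- function(mass_mg, volume_ml,
                                         molar_mass = 89.07) {
  stopifnot(mass_mg > 0, volume_ml > 0, molar_mass > 0)
  (mass_mg / 1000 / molar_mass) / (volume_ml / 1000) * 1000
}

#' In-plane resolution of a CSI acquisition
#'
#' Elementwise field-of-view over matrix size, in mm per voxel: an
#' 18 x 24 mm field of view at matrix 18 x 24 gives 1 x 1 mm.
#'
#' @param fov field of view `c(row_mm, col_mm)`
#' @param matrix_size acquisition matrix `c(nrow, ncol)`
#' @return numeric length-2 in-plane resolution in mm
#' @examples
#' csi_resolution(c(18, 24), c(18, 24))
#' @export
csi_resolution <- function(fov, matrix_size) {
  stopifnot(length(fov) == 2, length(matrix_size) == 2,
            all(fov > 0), all(matrix_size > 0))
  as.numeric(fov) / as.numeric(matrix_size)
}
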