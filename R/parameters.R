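#' @keywords internal
la_regions <- function() c("anterior", "posterior", "septum", "lateral", "roof")

# mmHg -> kPa conversion, applied exactly once at the equilibrium
# interface (pressure-unit discipline).
MMHG_TO_KPA <- 0.133322

#' Calibratable simulator input ranges
#'
#' The exploration box of the calibration study: per-region bulk
#' stiffness C (kPa) and anisotropic scaling alpha, end-diastolic and
#' end-systolic cavity pressures EDP/ESP (mmHg), pericardial spring
#' stiffness k_peri (kPa/um) and the pericardial penalty threshold PTH.
#'
#' In the 14-parameter mode all regional C and alpha values vary; in the
#' 9-parameter mode (used after the sensitivity analysis) C_region is
#' fixed at 1.7 kPa and only the five alphas plus EDP, ESP, k_peri and
#' PTH remain.
#'
#' @param mode `"14"` (full) or `"9"` (C fixed)
#' @return data.frame with columns `name`, `lower`, `upper`, `unit`
#' @export
param_ranges <- function(mode = c("9", "14")) {
  mode <- match.arg(mode)
  regions <- la_regions()
  ranges <- list()
  if (mode == "14") {
    for (r in regions) {
      ranges[[length(ranges) + 1L]] <-
        data.frame(name = paste0("C_", r), lower = 0.2, upper = 6.8, unit = "kPa")
      ranges[[length(ranges) + 1L]] <-
        data.frame(name = paste0("alpha_", r), lower = 0.125, upper = 4.0, unit = "-")
    }
  } else {
    for (r in regions) {
      ranges[[length(ranges) + 1L]] <-
        data.frame(name = paste0("alpha_", r), lower = 0.125, upper = 4.0, unit = "-")
    }
  }
  ranges[[length(ranges) + 1L]] <-
    data.frame(name = "EDP", lower = 1, upper = 12, unit = "mmHg")
  ranges[[length(ranges) + 1L]] <-
    data.frame(name = "ESP", lower = 13, upper = 37, unit = "mmHg")
  ranges[[length(ranges) + 1L]] <-
    data.frame(name = "k_peri", lower = 1e-4, upper = 5e-3, unit = "kPa/um")
  ranges[[length(ranges) + 1L]] <-
    data.frame(name = "PTH", lower = 0.50, upper = 0.95, unit = "-")
  out <- do.call(rbind, ranges)
  rownames(out) <- NULL
  out
}

#' Assemble a full 14-parameter input vector
#'
#' Expands a named parameter vector (9- or 14-parameter mode) into the
#' full named input set consumed by the forward model, filling fixed
#' C_region values where absent.
#'
#' @param x named numeric vector of inputs
#' @param C_fixed value used for any missing regional C (kPa)
#' @return named numeric vector with the 14 canonical entries
#' @export
simulation_inputs <- function(x, C_fixed = 1.7) {
  x <- unlist(x)
  stopifnot(!is.null(names(x)), all(is.finite(x)))
  regions <- la_regions()
  need <- c(paste0("C_", regions), paste0("alpha_", regions),
            "EDP", "ESP", "k_peri", "PTH")
  full <- setNames(numeric(length(need)), need)
  for (r in regions) full[paste0("C_", r)] <- C_fixed
  full[names(x)[names(x) %in% need]] <- x[names(x) %in% need]
  miss <- setdiff(setdiff(need, paste0("C_", regions)), names(x))
  if (length(miss)) stop("missing inputs: ", paste(miss, collapse = ", "))
  if (full["EDP"] > full["ESP"]) stop("EDP must not exceed ESP")
  full
}

#' Ground-truth inputs of the verification study
#'
#' The synthetic-truth parameter set near the centre of the input space
#' used to verify the calibration pipeline (9-parameter mode, C fixed
#' at 1.7 kPa): alpha = 2.12, 1.42, 2.57, 2.71, 2.78 for anterior,
#' posterior, septum, lateral and roof; EDP = 4.50 mmHg, ESP = 29.6
#' mmHg, k_peri = 0.003 kPa/um, PTH = 0.60.
#'
#' @return named numeric vector of the 9 calibratable inputs
#' @export
verification_truth <- function() {
  c(alpha_anterior = 2.12, alpha_posterior = 1.42, alpha_septum = 2.57,
    alpha_lateral = 2.71, alpha_roof = 2.78,
    EDP = 4.50, ESP = 29.6, k_peri = 0.003, PTH = 0.60)
}

#' Names of the seven output features
#'
#' End-systolic volume (ml) followed by the global and five regional
#' end-systolic endocardial displacements (mm), in the canonical order
#' used throughout the package.
#'
#' @return character vector of length 7
#' @export
feature_names <- function() {
  c("ESV", "d_global", paste0("d_", la_regions()))
}
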