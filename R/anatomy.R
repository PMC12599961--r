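#' Regional anatomy of the reduced left-atrial model
#'
#' Per-region scalar anatomy standing in for a patient mesh in the
#' five-region decomposition (anterior, posterior, septum, lateral,
#' roof):
#' \describe{
#'   \item{R_ED}{end-diastolic endocardial radius, mm}
#'   \item{h}{wall thickness, mm}
#'   \item{a}{area fraction of the endocardium (sums to 1)}
#'   \item{psi}{"roofness" coordinate in \[0,1\] driving the pericardial
#'     penalty map; maximal on the roof}
#'   \item{c_mv}{mitral-annulus coupling weight in \[0,1\]; minimal on
#'     the roof}
#'   \item{eat}{epicardial adipose tissue volume, ml — carried as a
#'     covariate only, never mechanical}
#' }
#'
#' @param R_ED,h,a,psi,c_mv,eat numeric vectors of length 5 named (or
#'   ordered) as the regions
#' @param A_MV peak mitral-annulus displacement, mm
#' @return an object of class `la_anatomy`: a data.frame with one row
#'   per region plus an `A_MV` attribute
#' @export
regional_anatomy <- function(R_ED, h, a, psi, c_mv, eat = rep(2, 5),
                             A_MV = 8) {
  regions <- la_regions()
  as5 <- function(v) {
    if (!is.null(names(v))) v <- v[regions]
    stopifnot(length(v) == 5, all(is.finite(v)))
    unname(v)
  }
  R_ED <- as5(R_ED); h <- as5(h); a <- as5(a)
  psi <- as5(psi); c_mv <- as5(c_mv); eat <- as5(eat)
  stopifnot(all(R_ED > 0), all(h > 0), all(a > 0),
            abs(sum(a) - 1) < 1e-8,
            all(psi >= 0), all(psi <= 1),
            all(c_mv >= 0), all(c_mv <= 1),
            all(eat >= 0), A_MV >= 0)
  if (psi[5] < max(psi)) stop("psi must be maximal on the roof")
  if (c_mv[5] > min(c_mv)) stop("c_mv must be minimal on the roof")
  out <- data.frame(region = regions, R_ED = R_ED, h = h, a = a,
                    psi = psi, c_mv = c_mv, eat = eat,
                    stringsAsFactors = FALSE)
  attr(out, "A_MV") <- A_MV
  class(out) <- c("la_anatomy", class(out))
  out
}

#' Default reduced-model anatomy
#'
#' A generic left atrium with a 90 ml end-diastolic cavity volume.
#' Regional ED radii are the equivalent-sphere radius perturbed by
#' +/- 5% fixed regional factors; thickness, area fractions, pericardial
#' roofness, mitral coupling and EAT volumes are plausible mid-cohort
#' values. All are configuration, not constants of the method.
#'
#' @param V_ED end-diastolic volume, ml
#' @param A_MV peak mitral-annulus displacement, mm
#' @return an `la_anatomy` object
#' @export
default_anatomy <- function(V_ED = 90, A_MV = 8) {
  a <- c(0.25, 0.25, 0.15, 0.15, 0.20)
  R_base <- (3 * V_ED * 1000 / (4 * pi))^(1 / 3)  # ml -> mm^3
  pert <- c(1.03, 0.97, 1.05, 0.95, 1.00)
  # rescale so the area-weighted sphere volume matches V_ED exactly
  R_ED <- R_base * pert
  scale <- (V_ED * 1000 / (4 * pi / 3 * sum(a * R_ED^3)))^(1 / 3)
  regional_anatomy(
    R_ED = R_ED * scale,
    h = c(2.0, 1.8, 2.5, 1.6, 2.2),
    a = a,
    psi = c(0.5, 0.7, 0.6, 0.4, 1.0),
    c_mv = c(0.8, 0.5, 0.6, 0.7, 0.1),
    eat = c(2.5, 3.0, 1.5, 2.0, 1.0),
    A_MV = A_MV)
}

#' End-diastolic cavity volume of an anatomy
#'
#' Area-fraction-weighted sphere volume (4 pi / 3) sum(a_r R_r^3) in ml.
#'
#' @param anatomy an `la_anatomy` object
#' @param R optional radii (mm) overriding the ED radii
#' @return volume in ml
#' @export
cavity_volume <- function(anatomy, R = anatomy$R_ED) {
  4 * pi / 3 * sum(anatomy$a * R^3) / 1000
}
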