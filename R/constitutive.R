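#' Guccione material parameters
#'
#' Container for the transversely isotropic Guccione law with an
#' anisotropic scaling factor. `C` is the bulk stiffness (kPa); `b_f`,
#' `b_t` and `b_ft` govern the response along the fibre direction,
#' across the transverse planes and in the fibre-transverse shear
#' planes; `alpha` scales all three anisotropy exponents jointly;
#' `kappa` is the bulk modulus (kPa) penalising volume change.
#'
#' Defaults are the healthy-ventricle reference values C = 1.7 kPa,
#' b_f = 8, b_ft = 4, b_t = 3 with kappa = 1000 kPa.
#'
#' @param C bulk stiffness, kPa (> 0)
#' @param b_f,b_t,b_ft dimensionless anisotropy exponents (>= 0)
#' @param alpha dimensionless anisotropic scaling (> 0)
#' @param kappa bulk modulus, kPa (> 0)
#' @return an object of class `guccione_params`
#' @export
guccione_params <- function(C = 1.7, b_f = 8, b_t = 3, b_ft = 4,
                            alpha = 1, kappa = 1000) {
  stopifnot(is.finite(C), C > 0,
            is.finite(b_f), b_f >= 0,
            is.finite(b_t), b_t >= 0,
            is.finite(b_ft), b_ft >= 0,
            is.finite(alpha), alpha > 0,
            is.finite(kappa), kappa > 0)
  structure(list(C = C, b_f = b_f, b_t = b_t, b_ft = b_ft,
                 alpha = alpha, kappa = kappa),
            class = "guccione_params")
}

#' Green-Lagrange strain state in the fibre frame
#'
#' Strain components in the fibre (f) / sheet (s) / normal (n) frame.
#' Each shear component is stored once; the factors of two required by
#' the strain-energy exponent are applied inside [guccione_Q()], never
#' by the caller.
#'
#' @param E_ff,E_ss,E_nn normal strain components (dimensionless)
#' @param E_fs,E_fn,E_sn shear strain components (dimensionless)
#' @param J volume ratio (> 0)
#' @return an object of class `green_strain`
#' @export
green_strain <- function(E_ff = 0, E_ss = 0, E_nn = 0,
                         E_fs = 0, E_fn = 0, E_sn = 0, J = 1) {
  stopifnot(is.finite(J), J > 0,
            all(is.finite(c(E_ff, E_ss, E_nn, E_fs, E_fn, E_sn))))
  structure(list(E_ff = E_ff, E_ss = E_ss, E_nn = E_nn,
                 E_fs = E_fs, E_fn = E_fn, E_sn = E_sn, J = J),
            class = "green_strain")
}

#' Neo-Hookean material parameters
#'
#' Isotropic law used for non-myocardial tissue (valve planes, vein and
#' appendage rings), where fibre effects are ignored.
#'
#' @param c stiffness, kPa (> 0); 7.45 kPa is the vein/appendage value
#' @param kappa bulk modulus, kPa (> 0)
#' @return an object of class `neo_hookean_params`
#' @export
neo_hookean_params <- function(c = 7.45, kappa = 1000) {
  stopifnot(is.finite(c), c > 0, is.finite(kappa), kappa > 0)
  structure(list(c = c, kappa = kappa), class = "neo_hookean_params")
}

#' Anisotropic strain-energy exponent Q
#'
#' Q = alpha * (b_f E_ff^2 + 2 b_ft (E_fs^2 + E_fn^2)
#'              + b_t (E_ss^2 + E_nn^2 + 2 E_sn^2)).
#' With alpha = 1 this is the classical Guccione exponent; alpha scales
#' the anisotropic stiffness parameters jointly so that
#' Q(alpha, b) == Q(1, alpha * b) identically.
#'
#' @param strain a [green_strain()] object
#' @param params a [guccione_params()] object
#' @return dimensionless exponent, >= 0
#' @export
guccione_Q <- function(strain, params) {
  stopifnot(inherits(strain, "green_strain"),
            inherits(params, "guccione_params"))
  with(strain, params$alpha *
    (params$b_f * E_ff^2 +
     2 * params$b_ft * (E_fs^2 + E_fn^2) +
     params$b_t * (E_ss^2 + E_nn^2 + 2 * E_sn^2)))
}

#' Guccione strain-energy density
#'
#' Psi = (C / 2) (exp(Q) - 1) + (kappa / 2) ln(J)^2, in kPa.
#' Zero exactly at the undeformed state (zero strain, J = 1).
#'
#' @inheritParams guccione_Q
#' @return energy density in kPa, >= 0
#' @export
guccione_energy <- function(strain, params) {
  stopifnot(inherits(strain, "green_strain"))
  if (strain$J <= 0) stop("invalid deformation state: J must be positive")
  Q <- guccione_Q(strain, params)
  params$C / 2 * (exp(Q) - 1) + params$kappa / 2 * log(strain$J)^2
}

#' Neo-Hookean strain-energy density
#'
#' Psi = c (I1 - 3) + (kappa / 2) ln(J)^2, in kPa.
#'
#' @param I1 first invariant of the right Cauchy-Green tensor (>= 3 for
#'   admissible incompressible states)
#' @param J volume ratio (> 0)
#' @param params a [neo_hookean_params()] object
#' @return energy density in kPa
#' @export
neo_hookean_energy <- function(I1, J = 1, params = neo_hookean_params()) {
  stopifnot(inherits(params, "neo_hookean_params"))
  if (any(J <= 0)) stop("invalid deformation state: J must be positive")
  params$c * (I1 - 3) + params$kappa / 2 * log(J)^2
}

#' Equibiaxial membrane energy along the stretch path
#'
#' Reduction of the Guccione law to the incompressible thin-membrane
#' state used by the regional equilibrium solver: equal in-plane
#' stretches lambda with through-thickness contraction lambda^-2, so
#' E_ff = E_ss = (lambda^2 - 1)/2, E_nn = (lambda^-4 - 1)/2, all shears
#' zero and J = 1 (the kappa penalty vanishes identically on this path).
#'
#' @param lambda in-plane stretch (> 0); vectorised
#' @param params a [guccione_params()] object
#' @return energy density in kPa, one value per stretch
#' @export
equibiaxial_energy <- function(lambda, params) {
  stopifnot(all(is.finite(lambda)), all(lambda > 0),
            inherits(params, "guccione_params"))
  E_in <- (lambda^2 - 1) / 2
  E_nn <- (lambda^-4 - 1) / 2
  Q <- params$alpha * (params$b_f * E_in^2 +
                       params$b_t * (E_in^2 + E_nn^2))
  params$C / 2 * (exp(Q) - 1)
}

# dPsi/dlambda on the equibiaxial path by central differences.
# Step 1e-6 on lambda; avoids hand-derived closed forms and is checked
# against them in tests.
equibiaxial_denergy <- function(lambda, params, h = 1e-6) {
  (equibiaxial_energy(lambda + h, params) -
   equibiaxial_energy(lambda - h, params)) / (2 * h)
}
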