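#' Synthetic verification observations with known ground truth
#'
#' Runs the forward model at a known truth and adds zero-mean Gaussian
#' observation noise at one of the two study noise levels: baseline
#' (displacement SD 0.2 mm, ESV SD 5% of the noiseless simulated ESV)
#' or high (1.0 mm, 20%). The returned provenance records the truth,
#' seed and noise level so a run is exactly reproducible.
#'
#' @param truth named input vector (within the design ranges); defaults
#'   to the central verification target set
#' @param noise_level `"baseline"` or `"high"`
#' @param seed integer seed for the noise draw
#' @param anatomy,grid forward-model setting
#' @param noiseless if TRUE, return the noiseless features as targets
#'   (the sigma -> 0 limit, with the nominal SDs retained)
#' @return an [observations()] object
#' @export
make_verification_observations <- function(truth = verification_truth(),
                                           noise_level = c("baseline", "high"),
                                           seed = 1L,
                                           anatomy = default_anatomy(),
                                           grid = time_grid(),
                                           noiseless = FALSE) {
  noise_level <- match.arg(noise_level)
  f <- forward_features(truth, anatomy, grid)
  sd_d <- if (noise_level == "baseline") 0.2 else 1.0
  frac_esv <- if (noise_level == "baseline") 0.05 else 0.20
  sigma <- c(frac_esv * f[["ESV"]], rep(sd_d, 6))
  names(sigma) <- feature_names()
  mu <- if (noiseless) f else
    f + with_seed(seed, stats::rnorm(7, 0, sigma))
  observations(mu, sigma,
               provenance = list(truth = truth, seed = seed,
                                 noise_level = noise_level,
                                 noiseless = noiseless,
                                 sd_displacement_mm = sd_d,
                                 sd_esv_fraction = frac_esv,
                                 noiseless_features = f,
                                 generator = "lascal make_verification_observations"))
}

#' Effect specification for the synthetic cohort generator
#'
#' Coefficients of the linear model that generates regional end-systolic
#' displacements:
#' Y = beta0 + region effect + beta_alpha * alpha
#'     + beta_thickness * thickness + beta_eat * EAT + u_patient + eps,
#' with u_patient ~ N(0, tau^2) and eps ~ N(0, sigma^2). The roof
#' carries the most negative region effect, so the roof deforming least
#' is reproducible by default. Thickness and EAT couplings are zero
#' (null) unless configured.
#'
#' @param beta0 intercept, mm
#' @param region_effects named length-5 vector of region offsets, mm
#' @param beta_alpha displacement change per unit stiffness scaling,
#'   mm (negative: stiffer deforms less)
#' @param beta_thickness,beta_eat covariate couplings (default null)
#' @param tau between-patient SD, mm
#' @param sigma residual SD, mm
#' @return list of class `cohort_effect_spec`
#' @export
cohort_effect_spec <- function(beta0 = 5,
                               region_effects = c(anterior = 0,
                                                  posterior = -0.6,
                                                  septum = -1.0,
                                                  lateral = -0.4,
                                                  roof = -3.0),
                               beta_alpha = -0.5,
                               beta_thickness = 0,
                               beta_eat = 0,
                               tau = 0.5, sigma = 0.3) {
  stopifnot(tau >= 0, sigma >= 0,
            all(la_regions() %in% names(region_effects)))
  if (region_effects[["roof"]] > min(region_effects))
    stop("the roof must carry the most negative region effect")
  structure(list(beta0 = beta0,
                 region_effects = region_effects[la_regions()],
                 beta_alpha = beta_alpha,
                 beta_thickness = beta_thickness, beta_eat = beta_eat,
                 tau = tau, sigma = sigma),
            class = "cohort_effect_spec")
}

#' Generate a synthetic patient cohort table
#'
#' One row per patient and region (5 rows per patient, no missing
#' cells): regional end-systolic displacement generated from the linear
#' random-intercept model of [cohort_effect_spec()], with per-region
#' stiffness scaling alpha drawn uniformly over the calibration range
#' and wall thickness / EAT covariates drawn independently around
#' plausible regional anatomy.
#'
#' @param n_patients number of patients (>= 2)
#' @param effect_spec a [cohort_effect_spec()]
#' @param seed integer seed
#' @return data.frame of class `cohort_table` with columns `patient`,
#'   `region`, `d_ES`, `thickness`, `eat`, `alpha` and a `provenance`
#'   attribute
#' @export
make_cohort <- function(n_patients = 10,
                        effect_spec = cohort_effect_spec(),
                        seed = 1L) {
  stopifnot(n_patients >= 2, inherits(effect_spec, "cohort_effect_spec"))
  regions <- la_regions()
  base_h <- c(2.0, 1.8, 2.5, 1.6, 2.2)
  base_eat <- c(2.5, 3.0, 1.5, 2.0, 1.0)
  es <- effect_spec
  tab <- with_seed(seed, {
    u <- stats::rnorm(n_patients, 0, es$tau)
    rows <- lapply(seq_len(n_patients), function(j) {
      alpha <- stats::runif(5, 0.5, 4)
      thickness <- pmax(stats::rnorm(5, base_h, 0.3), 0.5)
      eat <- pmax(stats::rnorm(5, base_eat, 0.8), 0)
      d <- es$beta0 + es$region_effects + es$beta_alpha * alpha +
        es$beta_thickness * thickness + es$beta_eat * eat +
        u[j] + stats::rnorm(5, 0, es$sigma)
      data.frame(patient = sprintf("case%02d", j), region = regions,
                 d_ES = d, thickness = thickness, eat = eat,
                 alpha = alpha, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(tab) <- NULL
  attr(tab, "provenance") <- list(seed = seed, effect_spec = es,
                                  n_patients = n_patients,
                                  generator = "lascal make_cohort")
  class(tab) <- c("cohort_table", class(tab))
  tab
}
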