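#' Random-intercept linear mixed-effects fit
#'
#' Fits Y = beta0 + region effects + beta * covariate + u_patient + eps
#' with a random intercept per patient, by REML (the fitting engine is
#' lme4). Wald p-values compare each fixed coefficient with its
#' standard error against the normal reference distribution. The
#' significance convention of the downstream analysis is 0.05; the fit
#' reports, never interprets, borderline values.
#'
#' @param table a [make_cohort()]-style data.frame with columns
#'   `patient`, `region`, the response and the covariate
#' @param response name of the response column (default `"d_ES"`)
#' @param covariate name of the continuous covariate column (e.g.
#'   `"alpha"`, `"thickness"`, `"eat"`), or NULL for a region-only model
#' @param standardize if TRUE, z-scale the covariate before fitting
#'   (default keeps raw units)
#' @return object of class `lmm_fit`: list with `coefficients`
#'   (data.frame: term, estimate, se, z, p_wald), `tau2`, `sigma2`,
#'   `logLik`, `method`, and the underlying `model`
#' @export
fit_lmm <- function(table, response = "d_ES", covariate = "alpha",
                    standardize = FALSE) {
  stopifnot(all(c("patient", "region", response) %in% names(table)))
  if (length(unique(table$patient)) < 2)
    stop("need at least 2 patients (grouping levels)")
  dat <- as.data.frame(table)
  dat$region <- factor(dat$region, levels = la_regions())
  rhs <- "region"
  if (!is.null(covariate)) {
    stopifnot(covariate %in% names(dat))
    if (standardize)
      dat[[covariate]] <- as.numeric(scale(dat[[covariate]]))
    rhs <- paste(rhs, "+", covariate)
  }
  fml <- stats::as.formula(paste(response, "~", rhs, "+ (1 | patient)"))
  fit <- lme4::lmer(fml, data = dat, REML = TRUE)
  sm <- summary(fit)$coefficients
  z <- sm[, "Estimate"] / sm[, "Std. Error"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    coefficients = data.frame(term = rownames(sm),
                              estimate = sm[, "Estimate"],
                              se = sm[, "Std. Error"], z = z,
                              p_wald = 2 * stats::pnorm(-abs(z)),
                              row.names = NULL,
                              stringsAsFactors = FALSE),
    tau2 = vc$vcov[vc$grp == "patient"],
    sigma2 = vc$vcov[vc$grp == "Residual"],
    logLik = as.numeric(stats::logLik(fit)),
    method = "REML", covariate = covariate, model = fit),
    class = "lmm_fit")
}

#' @method print lmm_fit
#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed-effects fit (random intercept per patient,",
      x$method, ")\n")
  print(transform(x$coefficients,
                  estimate = signif(estimate, 4), se = signif(se, 3),
                  z = signif(z, 3), p_wald = signif(p_wald, 3)))
  cat("  tau2 =", signif(x$tau2, 4), " sigma2 =", signif(x$sigma2, 4), "\n")
  invisible(x)
}

#' Wald p-value of the continuous covariate
#'
#' @param fit an `lmm_fit`
#' @return the Wald p-value of the covariate term
#' @export
covariate_p_value <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"), !is.null(fit$covariate))
  fit$coefficients$p_wald[fit$coefficients$term == fit$covariate]
}

#' Paired t-tests across regions with Bonferroni correction
#'
#' Tests every pair of regions on paired per-patient differences and
#' multiplies each raw p-value by the number of comparisons (10 for 5
#' regions), capping at 1. A zero-variance difference yields p = 1 by
#' convention (with a message).
#'
#' @param regional matrix of values, patients x regions (named columns)
#' @return list with symmetric matrices `p_raw` and `p_adjusted` and
#'   `n_comparisons`
#' @export
paired_t_bonferroni <- function(regional) {
  regional <- as.matrix(regional)
  stopifnot(nrow(regional) >= 3, !anyNA(regional))
  k <- ncol(regional)
  nm <- colnames(regional) %||% paste0("r", seq_len(k))
  n_comp <- k * (k - 1) / 2
  p_raw <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    diffs <- regional[, i] - regional[, j]
    if (stats::sd(diffs) == 0) {
      message("zero-variance paired difference (", nm[i], " vs ", nm[j],
              "): p = 1 by convention")
      p <- 1
    } else {
      p <- stats::t.test(regional[, i], regional[, j], paired = TRUE)$p.value
    }
    p_raw[i, j] <- p_raw[j, i] <- p
  }
  list(p_raw = p_raw, p_adjusted = pmin(p_raw * n_comp, 1),
       n_comparisons = n_comp)
}
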