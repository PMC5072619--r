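#' Fractal dimension from the subdiffusion exponent
#'
#' Inverts \eqn{\beta = 2\alpha/(2+d_f)} to
#' \deqn{d_f = c\,(2\alpha/\beta - 2),}
#' where the optional coefficient `c` (1 <= c < 1.09) applies the
#' surface-monomer hydrodynamic correction.  The medium exponent `alpha`
#' cannot be determined from a single short-time MSD fit and must be supplied
#' as an assumption.
#'
#' @param alpha assumed memory exponent in (0, 1].
#' @param beta fitted subdiffusion exponent; must satisfy `beta < alpha` so
#'   that the result is positive.
#' @param c surface-monomer correction coefficient, in [1, 1.09).
#' @return the fractal dimension (possibly outside the model's valid range
#'   (1, 3]; see [estimate_domain()] which flags such values).
#' @examples
#' fractal_dimension_from_exponent(0.8, 0.44)   # 1.64, HeLa interior
#' fractal_dimension_from_exponent(1, 0.4)      # 3, fractal globule
#' @export
fractal_dimension_from_exponent <- function(alpha, beta, c = 1) {
  check_alpha(alpha)
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0) {
    stop("`beta` must be a single positive number", call. = FALSE)
  }
  if (c < 1 || c >= 1.09) {
    stop("`c` must be in [1, 1.09)", call. = FALSE)
  }
  if (beta >= alpha) {
    stop(sprintf(paste0("beta = %.3g >= alpha = %.3g yields a non-positive ",
                        "fractal dimension; the assumed alpha is too small ",
                        "for this exponent"), beta, alpha), call. = FALSE)
  }
  c * (2 * alpha / beta - 2)
}

#' RMS domain size from a power-law fit
#'
#' Inverts the apparent diffusion coefficient into the RMS domain size:
#' \deqn{\langle R \rangle_{CD} =
#'   \left(\frac{D_{app}}{C_{d_f,\alpha}}\right)^{\frac{2+d_f}{2 d_f}}
#'   \left(\frac{4 \langle N\rangle_{CD}}{3 D_{EGFP}}\right)^{1/d_f},}
#' with \eqn{d_f} obtained from the fitted exponent.  Inputs are in um and
#' seconds; the result is returned in nanometres.
#'
#' @param fit a [power_law_fit()] (fitted or constructed from reported
#'   values).
#' @param alpha assumed memory exponent.
#' @param n_cd assumed number of nucleosomes per domain (default 5000,
#'   i.e. a 1-Mb domain at 200 bp per nucleosome).
#' @param d_egfp reference diffusivity, um^2/s.
#' @param c surface-monomer correction passed to
#'   [fractal_dimension_from_exponent()].
#' @return RMS domain size in nm.
#' @examples
#' domain_size_from_fit(power_law_fit(0.013, 0.39), alpha = 0.8)
#' @export
domain_size_from_fit <- function(fit, alpha, n_cd = 5000, d_egfp = 20.6,
                                 c = 1) {
  fit <- as_power_law_fit(fit)
  d_f <- fractal_dimension_from_exponent(alpha, fit$beta, c)
  check_df(d_f)
  1000 * rms_size_um(fit$d_app, d_f, alpha, n_cd, d_egfp)
}

rms_size_um <- function(d_app, d_f, alpha, n_cd, d_egfp) {
  (d_app / dapp_constant_C(d_f, alpha))^((2 + d_f) / (2 * d_f)) *
    (4 * n_cd / (3 * d_egfp))^(1 / d_f)
}

as_power_law_fit <- function(fit) {
  if (inherits(fit, "power_law_fit")) return(fit)
  if (is.numeric(fit) && length(fit) == 2L) {
    return(power_law_fit(fit[1], fit[2]))
  }
  stop("`fit` must be a power_law_fit or a numeric c(d_app, beta)",
       call. = FALSE)
}

#' Estimate chromatin-domain structure from a fitted MSD power law
#'
#' Composes the full inversion: fractal dimension from the exponent, RMS
#' domain size from the apparent diffusion coefficient, and the relaxation
#' time of nucleosome fluctuations from the reconstructed model.  The medium
#' exponent `alpha`, the domain occupancy `n_cd` and the reference
#' diffusivity `d_egfp` are assumptions, recorded in the result.
#'
#' When the fit carries a standard error on beta, a delta-method standard
#' error on d_f is propagated (`d d_f / d beta = -2 c alpha / beta^2`).
#'
#' @inheritParams domain_size_from_fit
#' @return an object of class `"domain_estimate"`: fields `d_f`, `r_cd_nm`,
#'   `tau_s`, `valid` (is d_f inside the model's (1, 3] range), `d_f_stderr`,
#'   and `assumptions`.
#' @examples
#' estimate_domain(power_law_fit(0.018, 0.44), alpha = 0.8)
#' @export
estimate_domain <- function(fit, alpha, n_cd = 5000, d_egfp = 20.6, c = 1) {
  fit <- as_power_law_fit(fit)
  d_f <- fractal_dimension_from_exponent(alpha, fit$beta, c)
  valid <- d_f > 1 && d_f <= 3
  r_um <- if (valid) rms_size_um(fit$d_app, d_f, alpha, n_cd, d_egfp)
          else NA_real_
  tau <- if (valid) {
    relaxation_time(fractal_domain_model(alpha, d_f, n_cd, r_um, d_egfp))
  } else NA_real_
  d_f_se <- if (is.finite(fit$beta_stderr)) {
    abs(-2 * c * alpha / fit$beta^2) * fit$beta_stderr
  } else NA_real_
  structure(
    list(d_f = d_f, r_cd_nm = 1000 * r_um, tau_s = tau, valid = valid,
         d_f_stderr = d_f_se,
         assumptions = list(alpha = alpha, n_cd = n_cd, d_egfp = d_egfp,
                            c_correction = c),
         fit = fit),
    class = "domain_estimate")
}

#' @export
print.domain_estimate <- function(x, ...) {
  a <- x$assumptions
  cat("Chromatin-domain estimate\n")
  cat(sprintf("  from fit: D_app = %.4g um^2/s^beta, beta = %.4g\n",
              x$fit$d_app, x$fit$beta))
  cat(sprintf("  assuming: alpha = %.3g, N = %g, D_EGFP = %.3g um^2/s%s\n",
              a$alpha, a$n_cd, a$d_egfp,
              if (a$c_correction != 1)
                sprintf(", c = %.3g", a$c_correction) else ""))
  cat(sprintf("  d_f    = %s%s\n", signif(x$d_f, 3),
              if (is.finite(x$d_f_stderr))
                sprintf(" (se %.2g)", x$d_f_stderr) else ""))
  if (x$valid) {
    cat(sprintf("  <R>_CD = %.0f nm\n", x$r_cd_nm))
    cat(sprintf("  tau    = %s s\n", signif(x$tau_s, 3)))
  } else {
    cat("  [flagged: d_f outside the model's valid range (1, 3];",
        "size and relaxation time not defined]\n")
  }
  invisible(x)
}

#' @export
as.data.frame.domain_estimate <- function(x, ...) {
  data.frame(alpha = x$assumptions$alpha, d_f = x$d_f,
             r_cd_nm = x$r_cd_nm, tau_s = x$tau_s,
             valid = x$valid)
}

#' Sweep the assumed medium exponent
#'
#' Recomputes the domain estimate over a grid of assumed `alpha` values,
#' since a short-time MSD fit constrains only the relationship between
#' `alpha` and `d_f`, not either one alone.  Rows whose fractal dimension
#' falls outside (1, 3] are flagged, not dropped.
#'
#' @inheritParams domain_size_from_fit
#' @param alphas vector of assumed exponents in (0, 1].
#' @return data frame with columns `alpha`, `d_f`, `r_cd_nm`, `tau_s`,
#'   `valid`.
#' @examples
#' alpha_sweep(power_law_fit(0.018, 0.44), alphas = seq(0.6, 1, by = 0.1))
#' @export
alpha_sweep <- function(fit, alphas = seq(0.6, 1, by = 0.05), n_cd = 5000,
                        d_egfp = 20.6, c = 1) {
  fit <- as_power_law_fit(fit)
  if (any(alphas <= 0 | alphas > 1)) {
    stop("`alphas` must lie in (0, 1]", call. = FALSE)
  }
  rows <- lapply(alphas, function(a) {
    d_f <- c * (2 * a / fit$beta - 2)
    if (d_f <= 1 || d_f > 3) {
      data.frame(alpha = a, d_f = d_f, r_cd_nm = NA_real_, tau_s = NA_real_,
                 valid = FALSE)
    } else {
      as.data.frame(estimate_domain(fit, a, n_cd, d_egfp, c))
    }
  })
  do.call(rbind, rows)
}

#' Sweep the assumed domain occupancy
#'
#' Recomputes domain size and relaxation time over a grid of assumed
#' nucleosome counts per domain (genomic domain sizes), at fixed `alpha`.
#'
#' @inheritParams domain_size_from_fit
#' @param n_cds vector of nucleosome counts (e.g.
#'   `nucleosomes_from_kb(c(200, 1000, 4000))` for 200 kb to 4 Mb).
#' @return data frame with columns `n_cd`, `kb`, `d_f`, `r_cd_nm`, `tau_s`.
#' @export
ncd_sweep <- function(fit, alpha, n_cds, d_egfp = 20.6) {
  fit <- as_power_law_fit(fit)
  if (any(n_cds <= 0)) stop("`n_cds` must be positive", call. = FALSE)
  rows <- lapply(n_cds, function(n) {
    est <- estimate_domain(fit, alpha, n, d_egfp)
    data.frame(n_cd = n, kb = kb_from_nucleosomes(n), d_f = est$d_f,
               r_cd_nm = est$r_cd_nm, tau_s = est$tau_s)
  })
  do.call(rbind, rows)
}

#' Genomic length to nucleosome count conversion
#'
#' One nucleosome per 200 bp of genomic DNA, so 1 Mb corresponds to 5000
#' nucleosomes.
#'
#' @param kb genomic length in kilobases.
#' @return nucleosome count.
#' @export
nucleosomes_from_kb <- function(kb) kb * 5

#' @rdname nucleosomes_from_kb
#' @param n nucleosome count.
#' @return genomic length in kilobases.
#' @export
kb_from_nucleosomes <- function(n) n / 5
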