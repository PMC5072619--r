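#' Fractal chromatin-domain model
#'
#' Constructs the full parameterization of one chromatin domain (CD): a chain
#' of `n_nucleosomes` beads folded into a domain whose equilibrium size obeys
#' the fractal scaling \eqn{\langle R \rangle_{CD} \sim N^{1/d_f}}, fluctuating
#' in a viscoelastic medium whose memory friction decays as \eqn{t^{-\alpha}}.
#' All dynamic quantities of the theory (mode variances, mode relaxation,
#' center-of-mass motion, the subdiffusive nucleosome MSD and its apparent
#' diffusion coefficient) are functions of this object.
#'
#' Friction enters every formula only through the reference diffusivity
#' `d_egfp`: the per-nucleosome friction is taken as
#' \eqn{\gamma_\alpha = 4 k_B T / D_{EGFP}} (a nucleosome bead with its
#' fluorescent tag has about four times the hydrodynamic radius of an EGFP
#' monomer), so `k_B T` always cancels and no temperature parameter is
#' exposed.  The same numerical value of \eqn{\gamma_\alpha} is used for all
#' `alpha`; this is the convention under which the reference measurement was
#' made and it is deliberately not "corrected" here.
#'
#' @param alpha memory exponent of the medium, in (0, 1].  `alpha = 1` is an
#'   ordinary viscous fluid.
#' @param d_f fractal dimension of the domain, in (1, 3].  `d_f = 2` is the
#'   ideal chain (Rouse) limit, `d_f = 3` the fractal globule.  `d_f = 1`
#'   (straight line) is excluded: the mode-variance constant vanishes there
#'   and the theory degenerates.
#' @param n_nucleosomes number of nucleosome beads N in the domain (>= 2).
#' @param r_rms RMS domain size \eqn{\langle R \rangle_{CD} =
#'   \sqrt{\langle R^2 \rangle_{CD}}} in micrometres.
#' @param d_egfp reference diffusivity \eqn{D_{EGFP}} in um^2/s
#'   (default 20.6, the EGFP-monomer value measured around interphase
#'   chromatin).
#' @return an object of class `"fractal_domain_model"`.
#' @examples
#' m <- fractal_domain_model(alpha = 0.8, d_f = 1.64, n_nucleosomes = 5000,
#'                           r_rms = 0.358)
#' relaxation_time(m)
#' apparent_diffusion_coefficient(m)
#' @export
fractal_domain_model <- function(alpha, d_f, n_nucleosomes, r_rms,
                                 d_egfp = 20.6) {
  check_alpha(alpha)
  check_df(d_f)
  if (!is.numeric(n_nucleosomes) || length(n_nucleosomes) != 1L ||
      is.na(n_nucleosomes) || n_nucleosomes < 2) {
    stop("`n_nucleosomes` must be a single number >= 2", call. = FALSE)
  }
  if (!is.numeric(r_rms) || length(r_rms) != 1L || is.na(r_rms) || r_rms <= 0) {
    stop("`r_rms` must be a single positive number (um)", call. = FALSE)
  }
  if (!is.numeric(d_egfp) || length(d_egfp) != 1L || is.na(d_egfp) ||
      d_egfp <= 0) {
    stop("`d_egfp` must be a single positive number (um^2/s)", call. = FALSE)
  }
  structure(
    list(alpha = alpha, d_f = d_f,
         n_nucleosomes = as.numeric(n_nucleosomes),
         r_rms = r_rms, d_egfp = d_egfp,
         b_eff = r_rms * n_nucleosomes^(-1 / d_f)),
    class = "fractal_domain_model")
}

check_df <- function(d_f) {
  if (!is.numeric(d_f) || length(d_f) != 1L || is.na(d_f) ||
      d_f <= 1 || d_f > 3) {
    stop("`d_f` must be a single value in (1, 3]", call. = FALSE)
  }
  invisible(d_f)
}

#' @export
print.fractal_domain_model <- function(x, ...) {
  cat("Fractal chromatin-domain model\n")
  cat(sprintf("  alpha (medium memory exponent): %.4g\n", x$alpha))
  cat(sprintf("  d_f (fractal dimension):        %.4g\n", x$d_f))
  cat(sprintf("  N (nucleosomes):                %g\n", x$n_nucleosomes))
  cat(sprintf("  <R>_CD (RMS size):              %.4g um (%.0f nm)\n",
              x$r_rms, 1000 * x$r_rms))
  cat(sprintf("  D_EGFP (reference diffusivity): %.4g um^2/s\n", x$d_egfp))
  cat(sprintf("  b_eff (effective bond length):  %.4g um\n", x$b_eff))
  cat(sprintf("  derived: beta = %.4g, D_app = %.4g um^2/s^beta, tau = %.4g s\n",
              subdiffusion_exponent(x$alpha, x$d_f),
              apparent_diffusion_coefficient(x),
              relaxation_time(x)))
  invisible(x)
}

#' @export
coef.fractal_domain_model <- function(object, ...) {
  c(alpha = object$alpha, d_f = object$d_f,
    n_nucleosomes = object$n_nucleosomes,
    r_rms = object$r_rms, d_egfp = object$d_egfp)
}

as_fdm <- function(model) {
  if (!inherits(model, "fractal_domain_model")) {
    stop("`model` must be a fractal_domain_model object", call. = FALSE)
  }
  model
}

# ---- dimensionless constants of the theory --------------------------------

#' Mode-variance scaling constant A
#'
#' Dimensionless constant relating the equilibrium normal-mode variances to
#' the domain size:
#' \deqn{A_{d_f} = \pi^{1 + 2/d_f}\, \Gamma(1 + 2/d_f)\, \sin(\pi/d_f).}
#' It vanishes as \eqn{d_f \to 1} (the sine factor), which is why `d_f = 1`
#' is outside the valid domain.
#'
#' @param d_f fractal dimension in (1, 3].
#' @return positive scalar; `A = pi^2` at `d_f = 2`.
#' @export
scaling_constant_A <- function(d_f) {
  check_df(d_f)
  pi^(1 + 2 / d_f) * gamma(1 + 2 / d_f) * sin(pi / d_f)
}

#' Short-time MSD prefactor constant B
#'
#' Dimensionless constant in the asymptotic nucleosome MSD, obtained by
#' converting the relaxed-mode sum into an integral:
#' \deqn{B_{d_f,\alpha} = \frac{d_f}{2}\,
#'   [\Gamma(1+\alpha)]^{d_f/(2+d_f)}\, \Gamma\!\big(d_f/(2+d_f)\big).}
#' The grouping (both Gamma factors multiplicative) is fixed by re-deriving
#' the integral and is confirmed numerically against the brute-force mode sum
#' ([msd_mode_sum()]); see the methods vignette.
#'
#' @param d_f fractal dimension in (1, 3].
#' @param alpha memory exponent in (0, 1].
#' @return positive scalar; `B = sqrt(pi)` at `d_f = 2, alpha = 1`.
#' @export
msd_constant_B <- function(d_f, alpha) {
  check_df(d_f)
  check_alpha(alpha)
  (d_f / 2) * gamma(1 + alpha)^(d_f / (2 + d_f)) * gamma(d_f / (2 + d_f))
}

#' Apparent-diffusion constant C
#'
#' Dimensionless constant in the apparent diffusion coefficient:
#' \deqn{C_{d_f,\alpha} = \frac{2 B_{d_f,\alpha}}
#'   {A_{d_f}^{d_f/(2+d_f)}\, \Gamma(1+\alpha)}.}
#' `alpha` has only a slight effect on C over the physically relevant range.
#'
#' @inheritParams msd_constant_B
#' @return positive scalar.
#' @export
dapp_constant_C <- function(d_f, alpha) {
  2 * msd_constant_B(d_f, alpha) /
    (scaling_constant_A(d_f)^(d_f / (2 + d_f)) * gamma(1 + alpha))
}

# ---- normal-mode statics and dynamics -------------------------------------

#' Equilibrium variance of normal mode p
#'
#' Large-p asymptotic form of the 3D equilibrium mode variance,
#' \eqn{\langle X_p^2 \rangle = \langle R^2 \rangle_{CD} / (2 A_{d_f})
#' \cdot p^{-1-2/d_f}} (um^2).  The p = 0 mode is the center of mass and has
#' no restoring force; use [com_msd()] for its dynamics.
#'
#' @param model a [fractal_domain_model()].
#' @param p mode index vector, integers >= 1.
#' @return numeric vector of variances in um^2, strictly decreasing in p.
#' @export
mode_variance <- function(model, p) {
  model <- as_fdm(model)
  if (any(p < 1) || any(p != floor(p))) {
    stop("`p` must contain integers >= 1 (p = 0 is the center of mass)",
         call. = FALSE)
  }
  model$r_rms^2 / (2 * scaling_constant_A(model$d_f)) *
    p^(-1 - 2 / model$d_f)
}

#' Effective stiffness of normal mode p
#'
#' The linearization (preaveraging) approximation replaces the nonlinear
#' long-range interactions by harmonic mode stiffnesses chosen to reproduce
#' the equilibrium mode variances: \eqn{k_p = 3 k_B T / (2 N \langle X_p^2
#' \rangle)} for p >= 1 and \eqn{k_0 = 0}.  Returned in units where
#' \eqn{k_B T = 1}, i.e. 1/um^2; the product `mode_stiffness * mode_variance`
#' is `3 / (2 N)` for every p >= 1.
#'
#' @inheritParams mode_variance
#' @param p mode index vector, integers >= 0.
#' @return numeric vector; zero at p = 0, increasing in p.
#' @export
mode_stiffness <- function(model, p) {
  model <- as_fdm(model)
  if (any(p < 0) || any(p != floor(p))) {
    stop("`p` must contain non-negative integers", call. = FALSE)
  }
  k <- numeric(length(p))
  pos <- p >= 1
  k[pos] <- 3 / (2 * model$n_nucleosomes * mode_variance(model, p[pos]))
  k
}

#' Relaxation time of nucleosome fluctuations in the domain
#'
#' Slowest internal relaxation time
#' \deqn{\tau = \left[\frac{4 N \langle R^2\rangle_{CD}}
#'   {A_{d_f}\, 3 D_{EGFP}}\right]^{1/\alpha} \quad (s).}
#' Beyond \eqn{\tau} the nucleosome MSD crosses over to center-of-mass motion
#' with exponent \eqn{\alpha}.
#'
#' @inheritParams mode_variance
#' @return positive scalar, seconds.
#' @export
relaxation_time <- function(model) {
  model <- as_fdm(model)
  (4 * model$n_nucleosomes * model$r_rms^2 /
     (scaling_constant_A(model$d_f) * 3 * model$d_egfp))^(1 / model$alpha)
}

#' Normal-mode autocorrelation function
#'
#' \deqn{C_p(t) = \langle X_p^2 \rangle\,
#'   E_\alpha\!\big(-p^{1+2/d_f} (t/\tau)^\alpha\big),}
#' the 3D autocovariance of mode p at lag t, decaying from the equilibrium
#' variance through the Mittag-Leffler function (exactly exponential when
#' `alpha = 1`).
#'
#' @inheritParams mode_variance
#' @param p single mode index >= 1.
#' @param t lag times in seconds (vector).
#' @param kernel `"exact"` for the Mittag-Leffler kernel, `"exp_approx"` for
#'   the short-time exponential approximation.
#' @return numeric vector of autocovariances in um^2.
#' @export
mode_correlation <- function(model, p, t, kernel = c("exact", "exp_approx")) {
  model <- as_fdm(model)
  kernel <- match.arg(kernel)
  if (length(p) != 1L || p < 1 || p != floor(p)) {
    stop("`p` must be a single integer >= 1", call. = FALSE)
  }
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  tau <- relaxation_time(model)
  z <- -p^(1 + 2 / model$d_f) * (t / tau)^model$alpha
  E <- switch(kernel,
              exact = mittag_leffler(model$alpha, z),
              exp_approx = mittag_leffler_exp_approx(model$alpha, z))
  mode_variance(model, p) * E
}

#' Center-of-mass MSD of the domain
#'
#' The domain's center of mass subdiffuses with the medium exponent:
#' \deqn{\langle [X_0(t) - X_0(0)]^2 \rangle =
#'   \frac{2 \langle R^2 \rangle_{CD}}{A_{d_f}\,\Gamma(1+\alpha)}
#'   \left(\frac{t}{\tau}\right)^{\alpha} \quad (\mu m^2, 3D).}
#'
#' @inheritParams mode_variance
#' @param t times in seconds (vector).
#' @return numeric vector, um^2.
#' @export
com_msd <- function(model, t) {
  model <- as_fdm(model)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  tau <- relaxation_time(model)
  2 * model$r_rms^2 / (scaling_constant_A(model$d_f) * gamma(1 + model$alpha)) *
    (t / tau)^model$alpha
}

#' Asymptotic internal nucleosome MSD (short times)
#'
#' Closed-form short-time MSD of a nucleosome inside the domain,
#' \deqn{\mathrm{MSD}(t) = \frac{2 B_{d_f,\alpha} \langle R^2\rangle_{CD}}
#'   {A_{d_f}\,\Gamma(1+\alpha)} \left(\frac{t}{\tau}\right)^{\beta},
#'   \qquad \beta = \frac{2\alpha}{2+d_f},}
#' valid for \eqn{t \ll \tau} (position-averaged over the domain, center of
#' mass excluded).  Identical to `apparent_diffusion_coefficient(model) * t^beta`.
#'
#' @inheritParams com_msd
#' @return numeric vector, um^2.
#' @export
internal_msd_asymptotic <- function(model, t) {
  model <- as_fdm(model)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  tau <- relaxation_time(model)
  2 * msd_constant_B(model$d_f, model$alpha) * model$r_rms^2 /
    (scaling_constant_A(model$d_f) * gamma(1 + model$alpha)) *
    (t / tau)^(model$alpha * 2 / (2 + model$d_f))
}

#' Brute-force normal-mode sum for the nucleosome MSD
#'
#' Numerically evaluates the full mode expansion of the MSD of the n-th
#' nucleosome,
#' \deqn{\phi(n,t) = \mathrm{CoM}(t) + 8 \sum_{p=1}^{P} \cos^2(p\pi n/N)\,
#'   [\langle X_p^2\rangle - C_p(t)],}
#' optionally replacing \eqn{\cos^2} by its position average 1/2.  This is
#' the independent oracle against which the closed-form asymptotic MSD and
#' its prefactor constant are validated, and the reference curve for the
#' mode-space simulator.
#'
#' @inheritParams com_msd
#' @param bead `"averaged"` (replace cos^2 by 1/2) or a single bead index in
#'   `[0, N]`.
#' @param max_modes number of modes P retained in the sum.
#' @param kernel relaxation kernel, `"exact"` (Mittag-Leffler) or
#'   `"exp_approx"`.
#' @param include_com if `TRUE`, add the center-of-mass MSD.
#' @return numeric vector, um^2.  Warns when the retained modes cannot bound
#'   the truncated tail below 1% of the result at the largest requested time.
#' @export
msd_mode_sum <- function(model, t, bead = "averaged", max_modes = 4000L,
                         kernel = c("exact", "exp_approx"),
                         include_com = FALSE) {
  model <- as_fdm(model)
  kernel <- match.arg(kernel)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  if (max_modes < 1) stop("`max_modes` must be >= 1", call. = FALSE)
  P <- as.integer(max_modes)
  p <- seq_len(P)
  w <- if (identical(bead, "averaged")) {
    rep(0.5, P)
  } else {
    if (!is.numeric(bead) || length(bead) != 1L || bead < 0 ||
        bead > model$n_nucleosomes) {
      stop("`bead` must be \"averaged\" or a single index in [0, N]",
           call. = FALSE)
    }
    cos(p * pi * bead / model$n_nucleosomes)^2
  }
  Ad <- scaling_constant_A(model$d_f)
  tau <- relaxation_time(model)
  Xp2 <- model$r_rms^2 / (2 * Ad) * p^(-1 - 2 / model$d_f)
  ga1 <- gamma(1 + model$alpha)
  out <- vapply(t, function(tt) {
    z <- -p^(1 + 2 / model$d_f) * (tt / tau)^model$alpha
    E <- switch(kernel,
                exact = mittag_leffler(model$alpha, z),
                exp_approx = mittag_leffler_exp_approx(model$alpha, z))
    8 * sum(w * Xp2 * (1 - E))
  }, numeric(1))
  # tail bound: (<X_p^2> - C_p) <= <X_p^2> * min(1, p^(1+2/df) (t/tau)^a / G(1+a))
  tmax <- max(t)
  if (tmax > 0) {
    wbar <- mean(w)
    cfac <- (tmax / tau)^model$alpha / ga1
    pstar <- if (cfac > 0) cfac^(-model$d_f / (2 + model$d_f)) else Inf
    pref <- model$r_rms^2 / (2 * Ad)
    tail <- if (pstar > P) {
      # unrelaxed band (P, pstar]: summand ~ pref * cfac each
      8 * wbar * (pref * cfac * (pstar - P) +
                    pref * (model$d_f / 2) * pstar^(-2 / model$d_f))
    } else {
      8 * wbar * pref * (model$d_f / 2) * P^(-2 / model$d_f)
    }
    ref <- out[which.max(t)]
    if (is.finite(tail) && ref > 0 && tail > 0.01 * ref) {
      warning(sprintf(paste0("mode-sum truncation: tail bound is %.2g%% of the",
                             " MSD at t = %.3g s; increase `max_modes`"),
                      100 * tail / ref, tmax))
    }
  }
  if (include_com) out <- out + com_msd(model, t)
  out
}

# ---- forward map to the empirical power law -------------------------------

#' Subdiffusion exponent of the nucleosome MSD
#'
#' \deqn{\beta = \frac{2\alpha}{2 + d_f}} without hydrodynamic interactions.
#' With intra-domain hydrodynamic coupling the size scaling cancels out of
#' the exponent and \eqn{\beta = 2\alpha/3} independent of `d_f`.
#'
#' @param alpha memory exponent in (0, 1].
#' @param d_f fractal dimension in (1, 3].
#' @param hydrodynamics if `TRUE`, use the hydrodynamic-interaction variant.
#' @return scalar in (0, 1).
#' @examples
#' subdiffusion_exponent(1, 3)   # 0.4, fractal globule in a viscous medium
#' subdiffusion_exponent(1, 2)   # 0.5, classical Rouse
#' @export
subdiffusion_exponent <- function(alpha, d_f, hydrodynamics = FALSE) {
  check_alpha(alpha)
  if (hydrodynamics) return(alpha * 2 / 3)
  check_df(d_f)
  alpha * 2 / (2 + d_f)
}

#' Apparent diffusion coefficient of nucleosomes in the domain
#'
#' Prefactor of the empirical subdiffusion law
#' \eqn{\mathrm{MSD}(t) = D_{app} t^\beta}:
#' \deqn{D_{app} = C_{d_f,\alpha}\left[\frac{3 D_{EGFP}}{4N}\right]^{2/(2+d_f)}
#'   \big(\langle R^2\rangle_{CD}\big)^{d_f/(2+d_f)},}
#' where \eqn{3 D_{EGFP}/(4N) = 3 k_B T/(N \gamma_\alpha)} under the
#' package's friction convention.
#'
#' @inheritParams mode_variance
#' @return positive scalar, um^2/s^beta.
#' @export
apparent_diffusion_coefficient <- function(model) {
  model <- as_fdm(model)
  dapp_constant_C(model$d_f, model$alpha) *
    (3 * model$d_egfp / (4 * model$n_nucleosomes))^(2 / (2 + model$d_f)) *
    (model$r_rms^2)^(model$d_f / (2 + model$d_f))
}

#' Model-predicted MSD curves
#'
#' @param object a [fractal_domain_model()].
#' @param t times in seconds.
#' @param type which theoretical curve: `"asymptotic"` (closed-form
#'   short-time law), `"mode_sum"` (numerical mode sum), or `"com"`
#'   (center-of-mass MSD).
#' @param ... passed on to [msd_mode_sum()] for `type = "mode_sum"`.
#' @return numeric vector of MSD values in um^2.
#' @export
predict.fractal_domain_model <- function(object, t,
                                         type = c("asymptotic", "mode_sum",
                                                  "com"), ...) {
  type <- match.arg(type)
  switch(type,
         asymptotic = internal_msd_asymptotic(object, t),
         mode_sum = msd_mode_sum(object, t, ...),
         com = com_msd(object, t))
}
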