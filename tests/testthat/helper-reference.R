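# reference values for the published HeLa single-nucleosome analysis:
# fitted (D_app, beta) per nuclear region and the printed domain estimates
# for assumed alpha = 0.8 / 0.9 (N = 5000 nucleosomes, D_EGFP = 20.6 um^2/s)
hela_fits <- list(interior = c(d_app = 0.018, beta = 0.44),
                  periphery = c(d_app = 0.013, beta = 0.39))

table1_printed <- data.frame(
  region = rep(c("interior", "periphery"), each = 2),
  alpha  = rep(c(0.8, 0.9), 2),
  d_f    = c(1.64, 2.09, 2.10, 2.62),
  r_cd_nm = c(358, 268, 191, 166),
  tau_s  = c(4.65, 2.69, 1.31, 1.01))

# interior-like reference model used across simulator tests
interior_model <- function(alpha = 0.9, d_f = 2.09, n = 5000, r = 0.268,
                           d_egfp = 20.6) {
  fractal_domain_model(alpha, d_f, n, r, d_egfp)
}

# small deterministic ensemble: straight-line and stationary tracks
toy_tracks <- function(frame_interval = 0.05) {
  track_ensemble(list(
    cbind(x = c(0, 3), y = c(0, 4)),
    cbind(x = rep(0.5, 5), y = rep(-0.2, 5))),
    frame_interval = frame_interval)
}
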