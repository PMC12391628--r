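# Shared fixtures and independent oracles for the test suite.

# Sort-based oracle for the top-fraction mean (ceiling rule).
oracle_top_mean <- function(values, fraction = 0.1) {
  k <- ceiling(fraction * length(values))
  mean(rev(sort(values))[seq_len(k)])
}

# Exhaustive two-stage grid search oracle for 2-component NNLS:
# coarse sweep over [0, hi], then refinement at the fine step around the
# coarse optimum. Residuals are evaluated directly from the quadratic.
oracle_grid_nnls2 <- function(C, d, hi = 1.5, coarse = 0.01,
                              fine = 0.001) {
  sweep_grid <- function(a1s, a2s) {
    c1 <- C[, 1L]; c2 <- C[, 2L]
    dd <- sum(d^2); c1d <- sum(c1 * d); c2d <- sum(c2 * d)
    c11 <- sum(c1^2); c22 <- sum(c2^2); c12 <- sum(c1 * c2)
    r2 <- outer(a1s, a2s, function(a1, a2)
      dd - 2 * a1 * c1d - 2 * a2 * c2d +
        a1^2 * c11 + a2^2 * c22 + 2 * a1 * a2 * c12)
    i <- which(r2 == min(r2), arr.ind = TRUE)[1L, ]
    c(a1s[i[1L]], a2s[i[2L]])
  }
  co <- sweep_grid(seq(0, hi, by = coarse), seq(0, hi, by = coarse))
  a1s <- seq(max(0, co[1L] - 2 * coarse), co[1L] + 2 * coarse, by = fine)
  a2s <- seq(max(0, co[2L] - 2 * coarse), co[2L] + 2 * coarse, by = fine)
  sweep_grid(a1s, a2s)
}

# A small, well-separated two-component dictionary on the in vivo grid.
tiny_refset <- function() {
  make_reference_spectra(wavelengths_in_vivo(),
                         list(spectrum_config("aunr_cell", "lorentzian",
                                              center = 900, width = 60),
                              spectrum_config("hbo2", "monotone",
                                              anchors = cbind(c(600, 1100),
                                                              c(0.3, 1)))))
}

# Manually built posterior_draws object with constant chains at given
# group x time means (for exercising the linear functionals alone).
constant_draws <- function(mu, sigma = 1, n = 200L, chains = 2L) {
  groups <- c("treated", "control")
  times <- colnames(mu)
  pars <- c(t(outer(groups, times, function(g, t)
    paste0("mu_", g, "_", t))), paste0("sigma_", groups))
  arr <- array(NA_real_, dim = c(n, chains, length(pars)),
               dimnames = list(NULL, NULL, pars))
  for (g in groups) for (t in times)
    arr[, , paste0("mu_", g, "_", t)] <- mu[g, t]
  for (g in groups) arr[, , paste0("sigma_", g)] <- sigma
  structure(list(draws = arr, parameters = pars, groups = groups,
                 times = times,
                 spec = model_spec(), config = sampler_config(seed = 1),
                 accept_rate = rep(NA_real_, chains)),
            class = "posterior_draws")
}

# Random 2-component unmixing problem built from the spectral shape
# families (a random-peak lorentzian and a random monotone ramp) — the
# kind of distinct chromophore pair the dictionary is meant to separate.
random_unmix_problem <- function() {
  wl <- wavelengths_in_vivo()
  lor <- 1 / (1 + ((wl - runif(1, 850, 950)) / runif(1, 20, 60))^2)
  ramp <- exp(log(runif(1, 0.1, 0.6)) +
                (log(1) - log(0.3)) * (wl - 600) / 500 * runif(1, 0.5, 2))
  C <- cbind(lor / max(lor), ramp / max(ramp))
  a_true <- runif(2, 0, 1)
  d <- as.numeric(C %*% a_true) + abs(rnorm(6, sd = 0.02))
  list(C = C, d = d)
}

# Wrap a raw dictionary matrix as a ref_spectra on the in vivo grid.
new_refset3 <- function(C) {
  ref_spectra(wavelengths_in_vivo(), c("c1", "c2", "c3")[seq_len(ncol(C))],
              C)
}

new_ref_spectra_public <- function(wavelengths, components, spectra) {
  ref_spectra(wavelengths, components, spectra)
}

# NNLS abundances for a raw (already unit-max) 2-column dictionary.
nnls_abundances <- function(C, d) {
  rs <- ref_spectra(wavelengths_in_vivo(), c("A", "B"), C)
  unname(unmix_voxel(pa_spectrum(wavelengths_in_vivo(), d),
                     rs)$abundances)
}

# A tiny measurement table with both groups at three time points.
tiny_table <- function(values_treated = c(27, 29, 31),
                       values_control = c(18, 17.5, 17)) {
  rbind(
    data.frame(tumor_id = "tr_01", group = "treated",
               time_label = c("T0", "T1", "T2"), day = c(0, 1, 3),
               pa_value = values_treated),
    data.frame(tumor_id = "ct_01", group = "control",
               time_label = c("T0", "T1", "T2"), day = c(0, 1, 3),
               pa_value = values_control))
}
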