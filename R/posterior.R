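#' Longitudinal change and treatment effect functionals
#'
#' For every posterior draw, the within-group change from baseline is
#' `Delta[g,t] = mu[g,t] - mu[g,0]` for the follow-up time points, and
#' the treatment effect is `Effect[t] = Delta[treated,t] -
#' Delta[control,t]`. Both identities hold exactly per draw (they are
#' linear functionals of the draws, not Monte Carlo estimates).
#'
#' @param draws A `posterior_draws` object containing both groups and at
#'   least two time points.
#' @param mass Credible mass for the interval summaries.
#' @return An `effect_estimate` object: per-draw vectors in `draws` (named
#'   `delta_<group>_<t>` and `effect_<t>`) and a `summary` data.frame with
#'   posterior mean, equal-tailed interval, HDI and P(> 0) per functional.
#' @export
delta_and_effect <- function(draws, mass = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  groups <- c("treated", "control")
  if (!all(groups %in% draws$groups))
    stop("draws must contain both treated and control groups")
  times <- draws$times
  if (length(times) < 2L)
    stop("need at least two time points for change functionals")
  base <- times[1L]
  per_draw <- list()
  for (t in times[-1L]) {
    tnum <- match(t, times) - 1L
    for (g in groups) {
      d <- draws_of(draws, paste0("mu_", g, "_", t)) -
        draws_of(draws, paste0("mu_", g, "_", base))
      per_draw[[paste0("delta_", g, "_", tnum)]] <- d
    }
    per_draw[[paste0("effect_", tnum)]] <-
      per_draw[[paste0("delta_treated_", tnum)]] -
      per_draw[[paste0("delta_control_", tnum)]]
  }
  summ <- do.call(rbind, lapply(names(per_draw), function(nm) {
    s <- summarize_posterior(per_draw[[nm]], mass = mass)
    data.frame(functional = nm, mean = s$mean,
               et_lower = s$et[1], et_upper = s$et[2],
               hdi_lower = s$hdi[1], hdi_upper = s$hdi[2],
               p_gt0 = s$p_gt0, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(draws = per_draw, summary = summ, mass = mass),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat("<effect_estimate> ", 100 * x$mass,
      "% intervals (equal-tailed and HDI)\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Summarize a vector of posterior draws
#'
#' Reports the posterior mean, the equal-tailed credible interval (from
#' the `(1 - mass)/2` and `1 - (1 - mass)/2` empirical quantiles), the
#' highest-density interval (the shortest contiguous interval containing
#' `ceiling(mass * n)` sorted draws), and the posterior probability of
#' exceeding zero.
#'
#' @param samples Numeric vector of at least 100 finite draws.
#' @param mass Credible mass in (0, 1).
#' @return List with `mean`, `et` (length-2), `hdi` (length-2), `p_gt0`.
#' @export
summarize_posterior <- function(samples, mass = 0.95) {
  if (length(samples) < 100L)
    stop("need >= 100 draws to summarize, got ", length(samples))
  if (any(!is.finite(samples))) stop("draws must be finite")
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  alpha <- (1 - mass) / 2
  list(mean = mean(samples),
       et = unname(stats::quantile(samples, c(alpha, 1 - alpha))),
       hdi = hdi_interval(samples, mass),
       p_gt0 = mean(samples > 0))
}

#' Highest-density interval of a sample
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws.
#'
#' @param samples Numeric draws.
#' @param mass Credible mass in (0, 1).
#' @return Length-2 numeric vector `(lower, upper)`.
#' @export
hdi_interval <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1L], x[n]))
  starts <- seq_len(n - k + 1L)
  widths <- x[starts + k - 1L] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + k - 1L])
}
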