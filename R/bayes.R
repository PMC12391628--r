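#' Hierarchical Gaussian model specification
#'
#' The longitudinal model: within each group g (treated, control) and
#' time point t, per-tumor signals are Normal(mu\[g,t\], sigma\[g\]) with
#' weakly informative priors mu ~ Normal(0, 100) and sigma ~
#' HalfNormal(50). The variance is shared across time points within a
#' group (`"per-group"`, the default); `"pooled"` shares a single sigma
#' across both groups.
#'
#' @param prior_mean,prior_sd Normal prior location and scale (sd) for
#'   every group-by-time mean (a.u.).
#' @param sigma_scale Half-normal prior scale for sigma (a.u.).
#' @param sigma_sharing `"per-group"` or `"pooled"`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(prior_mean = 0, prior_sd = 100, sigma_scale = 50,
                       sigma_sharing = c("per-group", "pooled")) {
  sigma_sharing <- match.arg(sigma_sharing)
  if (prior_sd <= 0 || sigma_scale <= 0)
    stop("prior scales must be > 0")
  structure(list(prior_mean = prior_mean, prior_sd = prior_sd,
                 sigma_scale = sigma_scale, sigma_sharing = sigma_sharing),
            class = "model_spec")
}

#' MCMC sampler configuration
#'
#' @param chains Number of chains (>= 2 so convergence diagnostics are
#'   defined).
#' @param tune Tuning (warm-up) iterations per chain, discarded.
#' @param draws Kept draws per chain.
#' @param seed Master seed; per-chain seeds are derived from it.
#' @param prop_scale Initial random-walk scale on log sigma (adapted
#'   during tuning toward 0.4 acceptance, then frozen).
#' @return A `sampler_config` object.
#' @export
sampler_config <- function(chains = 4L, tune = 1000L, draws = 2000L,
                           seed = 1L, prop_scale = 0.5) {
  if (chains < 2L) stop("need >= 2 chains for convergence diagnostics")
  if (draws < 1L) stop("need >= 1 kept draw")
  if (tune < 0L) stop("tuning iterations must be >= 0")
  structure(list(chains = as.integer(chains), tune = as.integer(tune),
                 draws = as.integer(draws), seed = as.integer(seed),
                 prop_scale = prop_scale), class = "sampler_config")
}

half_normal_logpdf <- function(x, scale) {
  ifelse(x <= 0, -Inf,
         log(2) + stats::dnorm(x, 0, scale, log = TRUE))
}

# Summarize a measurement table into per-cell sufficient statistics.
cohort_suffstats <- function(data) {
  data <- validate_measurement_table(data, require_both_groups = FALSE)
  groups <- c("treated", "control")
  times <- sort(unique(data$time_label))
  if (length(times) == 0L) times <- c("T0", "T1", "T2")
  cells <- expand.grid(group = groups, time_label = times,
                       stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$group, groups), cells$time_label), ]
  st <- lapply(seq_len(nrow(cells)), function(i) {
    y <- data$pa_value[data$group == cells$group[i] &
                         data$time_label == cells$time_label[i]]
    list(n = length(y), sum = sum(y), sumsq = sum(y^2))
  })
  list(groups = groups, times = times, cells = cells,
       n = vapply(st, `[[`, numeric(1), "n"),
       sum = vapply(st, `[[`, numeric(1), "sum"),
       sumsq = vapply(st, `[[`, numeric(1), "sumsq"))
}

#' Log posterior density of the hierarchical model
#'
#' Sum of the Gaussian log-likelihood over all observations plus the
#' Normal log-priors on each group-by-time mean and the half-normal
#' log-prior on each sigma. Returns `-Inf` for non-positive sigma (the
#' sampler rejects such states).
#'
#' @param params List with `mu` (matrix, rows `treated`/`control`,
#'   columns time labels) and `sigma` (named per-group vector, or a
#'   single value under pooled sharing).
#' @param data Measurement table.
#' @param spec A [model_spec].
#' @return Scalar log posterior (unnormalized).
#' @export
log_posterior <- function(params, data, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  ss <- cohort_suffstats(data)
  mu <- params$mu
  sigma <- params$sigma
  if (spec$sigma_sharing == "pooled") {
    sigma <- rep(unname(sigma[1]), 2)
    names(sigma) <- ss$groups
  } else {
    sigma <- sigma[ss$groups]
  }
  if (any(is.na(sigma))) stop("sigma must be named for both groups")
  if (any(sigma <= 0)) return(-Inf)
  lp <- 0
  for (i in seq_len(nrow(ss$cells))) {
    g <- ss$cells$group[i]; t <- ss$cells$time_label[i]
    m <- mu[g, t]; s <- sigma[[g]]
    n <- ss$n[i]
    if (n > 0) {
      # sum of Normal(m, s) log densities via sufficient statistics
      lp <- lp - n * log(s) - n * 0.5 * log(2 * pi) -
        (ss$sumsq[i] - 2 * m * ss$sum[i] + n * m^2) / (2 * s^2)
    }
  }
  lp <- lp + sum(stats::dnorm(mu, spec$prior_mean, spec$prior_sd,
                              log = TRUE))
  sig_unique <- if (spec$sigma_sharing == "pooled") sigma[1] else sigma
  lp + sum(half_normal_logpdf(sig_unique, spec$sigma_scale))
}

#' Closed-form Normal–Normal conjugate update with fixed sigma
#'
#' Oracle for sampler validation: with a Normal(prior_mean, prior_sd)
#' prior and n observations of known sd `sigma`, the posterior for the
#' mean is Normal with precision `1/prior_sd^2 + n/sigma^2`.
#'
#' @param values Observed data values (may be empty).
#' @param sigma Known observation sd (> 0).
#' @param prior_mean,prior_sd Prior location and scale (> 0).
#' @return Named vector `c(mean =, sd =)` of the posterior.
#' @examples
#' conjugate_posterior_fixed_sigma(numeric(0), 10)  # the prior itself
#' @export
conjugate_posterior_fixed_sigma <- function(values, sigma,
                                            prior_mean = 0,
                                            prior_sd = 100) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (prior_sd <= 0) stop("prior sd must be > 0")
  n <- length(values)
  prec <- 1 / prior_sd^2 + n / sigma^2
  m <- (prior_mean / prior_sd^2 + sum(values) / sigma^2) / prec
  c(mean = m, sd = sqrt(1 / prec))
}

#' Sample the posterior by Metropolis-within-Gibbs
#'
#' Each group-by-time mean is updated with an exact draw from its Normal
#' full conditional (conjugate given sigma); each sigma is updated by
#' adaptive random-walk Metropolis on log sigma (target acceptance 0.4,
#' adaptation frozen after tuning). Cells with no observations fall back
#' to the prior. Identical data, spec and config (including seed) give
#' identical draws.
#'
#' @param data Measurement table (both groups present; empty cells
#'   allowed).
#' @param spec A [model_spec].
#' @param cfg A [sampler_config].
#' @param sigma_fixed Optional known sigma (scalar or per-group named
#'   vector); when given, the sigma Metropolis step is skipped and sigma
#'   is held at this value.
#' @return A `posterior_draws` object: 3D array `draws` indexed
#'   `(iteration, chain, parameter)` with parameters
#'   `mu_<group>_<time>` and `sigma_<group>` (or `sigma` when pooled),
#'   plus the spec/config echo and mean acceptance rates.
#' @export
sample_posterior <- function(data, spec = model_spec(),
                             cfg = sampler_config(),
                             sigma_fixed = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(cfg, "sampler_config"))
  if (any(!is.finite(data$pa_value))) stop("non-finite data values")
  ss <- cohort_suffstats(data)
  groups <- ss$groups
  times <- ss$times
  pooled <- spec$sigma_sharing == "pooled"
  sig_names <- if (pooled) "sigma" else paste0("sigma_", groups)
  mu_names <- paste0("mu_", ss$cells$group, "_", ss$cells$time_label)
  par_names <- c(mu_names, sig_names)
  cell_group <- match(ss$cells$group, groups)

  fixed <- !is.null(sigma_fixed)
  if (fixed) {
    sf <- if (length(sigma_fixed) == 1L && is.null(names(sigma_fixed))) {
      stats::setNames(rep(sigma_fixed, length(sig_names)), sig_names)
    } else {
      sf0 <- sigma_fixed[if (pooled) "sigma" else sub("sigma_", "",
                                                      sig_names)]
      stats::setNames(unname(sf0), sig_names)
    }
    if (any(is.na(sf)) || any(sf <= 0))
      stop("sigma_fixed must be > 0 and cover every sigma parameter")
  }

  set.seed(cfg$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, cfg$chains)

  n_keep <- cfg$draws
  out <- array(NA_real_,
               dim = c(n_keep, cfg$chains, length(par_names)),
               dimnames = list(NULL, NULL, par_names))
  accept <- numeric(cfg$chains)

  # per-group aggregates for the sigma update
  grp_n <- vapply(seq_along(groups),
                  function(g) sum(ss$n[cell_group == g]), numeric(1))

  for (ch in seq_len(cfg$chains)) {
    set.seed(chain_seeds[ch])
    nsig <- length(sig_names)
    mu <- rep(spec$prior_mean, nrow(ss$cells))
    sigma <- if (fixed) unname(sf) else rep(spec$sigma_scale / 2, nsig)
    ls_scale <- rep(log(cfg$prop_scale), nsig)
    n_acc <- 0L; n_prop <- 0L
    total_iter <- cfg$tune + n_keep
    for (it in seq_len(total_iter)) {
      tuning <- it <= cfg$tune
      # --- Gibbs update of every cell mean (vectorized) ---
      sig_cell <- if (pooled) rep(sigma[1], nrow(ss$cells)) else
        sigma[cell_group]
      prec <- 1 / spec$prior_sd^2 + ss$n / sig_cell^2
      cmean <- (spec$prior_mean / spec$prior_sd^2 +
                  ss$sum / sig_cell^2) / prec
      mu <- stats::rnorm(length(mu), cmean, 1 / sqrt(prec))
      # --- Metropolis update of log sigma ---
      if (!fixed) {
        # residual sum of squares per group given current means
        rss_cell <- ss$sumsq - 2 * mu * ss$sum + ss$n * mu^2
        for (j in seq_len(nsig)) {
          if (pooled) {
            rss <- sum(rss_cell); n_obs <- sum(ss$n)
          } else {
            rss <- sum(rss_cell[cell_group == j]); n_obs <- grp_n[j]
          }
          lsig <- log(sigma[j])
          lsig_new <- lsig + stats::rnorm(1, 0, exp(ls_scale[j]))
          s_new <- exp(lsig_new)
          logr <- (-n_obs * lsig_new - rss / (2 * s_new^2) -
                     s_new^2 / (2 * spec$sigma_scale^2) + lsig_new) -
                  (-n_obs * lsig - rss / (2 * sigma[j]^2) -
                     sigma[j]^2 / (2 * spec$sigma_scale^2) + lsig)
          acc <- log(stats::runif(1)) < logr
          if (acc) sigma[j] <- s_new
          if (tuning) {
            ls_scale[j] <- ls_scale[j] +
              (min(1, exp(logr)) - 0.4) * it^-0.6
          } else {
            n_prop <- n_prop + 1L
            n_acc <- n_acc + as.integer(acc)
          }
        }
      }
      if (!tuning) {
        k <- it - cfg$tune
        out[k, ch, ] <- c(mu, sigma)
      }
    }
    accept[ch] <- if (n_prop > 0) n_acc / n_prop else NA_real_
  }

  structure(list(draws = out, parameters = par_names,
                 groups = groups, times = times,
                 mu_index = stats::setNames(mu_names,
                   paste(ss$cells$group, ss$cells$time_label, sep = ".")),
                 spec = spec, config = cfg,
                 sigma_fixed = if (fixed) sf else NULL,
                 accept_rate = accept),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("<posterior_draws> ", d[2], " chains x ", d[1], " draws, ",
      d[3], " parameters\n  parameters: ",
      paste(x$parameters, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract one parameter's draws
#'
#' `draws_of` flattens a parameter across chains into a single vector;
#' `chains_of` returns it as an iterations-by-chains matrix (the layout
#' the convergence diagnostics take).
#'
#' @param draws A `posterior_draws` object.
#' @param parameter Parameter name (see `draws$parameters`).
#' @return Numeric vector (`draws_of`) or matrix (`chains_of`).
#' @export
draws_of <- function(draws, parameter) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!parameter %in% draws$parameters)
    stop("unknown parameter: ", parameter)
  as.numeric(draws$draws[, , parameter])
}

#' @rdname draws_of
#' @export
chains_of <- function(draws, parameter) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!parameter %in% draws$parameters)
    stop("unknown parameter: ", parameter)
  draws$draws[, , parameter]
}
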