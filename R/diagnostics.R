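# MCMC convergence diagnostics: rank-normalized split R-hat and bulk
# effective sample size, following the modern (split, rank-normalized,
# Geyer-truncated) formulation used across current MCMC software.

split_chains <- function(mat) {
  n <- nrow(mat)
  if (n %% 2L == 1L) mat <- mat[-1L, , drop = FALSE]
  half <- nrow(mat) %/% 2L
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[half + seq_len(half), , drop = FALSE])
}

# Rank-normalize all draws jointly (fractional offset 3/8).
z_scale <- function(mat) {
  r <- rank(mat, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(mat) + 1 / 4))
  matrix(z, nrow = nrow(mat))
}

# Classic potential scale reduction on an iterations x chains matrix.
rhat_basic <- function(mat) {
  n <- nrow(mat)
  w <- mean(apply(mat, 2L, stats::var))
  b <- n * stats::var(colMeans(mat))
  var_hat <- (n - 1) / n * w + b / n
  sqrt(var_hat / w)
}

# Autocorrelation-based ESS on an iterations x chains matrix
# (Geyer initial monotone positive sequence truncation).
ess_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  acov <- apply(mat, 2L, function(x) {
    stats::acf(x, lag.max = n - 1L, plot = FALSE, type = "covariance",
               demean = TRUE)$acf[, 1L, 1L]
  })
  acov <- matrix(acov, nrow = n)
  mean_var <- mean(acov[1L, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1L) var_plus <- var_plus + stats::var(colMeans(mat))
  rho <- rep.int(0, n)
  t <- 0L
  rho_even <- 1
  rho[1L] <- 1
  rho_odd <- 1 - (mean_var - mean(acov[2L, ])) / var_plus
  rho[2L] <- rho_odd
  while (t < n - 5L && !is.nan(rho_even + rho_odd) &&
         (rho_even + rho_odd > 0)) {
    t <- t + 2L
    rho_even <- 1 - (mean_var - mean(acov[t + 1L, ])) / var_plus
    rho_odd <- 1 - (mean_var - mean(acov[t + 2L, ])) / var_plus
    if ((rho_even + rho_odd) >= 0) {
      rho[t + 1L] <- rho_even
      rho[t + 2L] <- rho_odd
    }
  }
  max_t <- t
  if (rho_even > 0) rho[max_t + 1L] <- rho_even
  # enforce monotone non-increasing pair sums
  t <- 0L
  while (t <= max_t - 4L) {
    t <- t + 2L
    if (rho[t + 1L] + rho[t + 2L] > rho[t - 1L] + rho[t]) {
      rho[t + 1L] <- (rho[t - 1L] + rho[t]) / 2
      rho[t + 2L] <- rho[t + 1L]
    }
  }
  total <- m * n
  tau <- -1 + 2 * sum(rho[seq_len(max_t)]) + rho[max_t + 1L]
  tau <- max(tau, 1 / log10(total))
  total / tau
}

#' Split R-hat of a set of chains
#'
#' Rank-normalized split potential scale reduction: chains are split in
#' half, all draws are jointly rank-normalized, and the classic
#' between/within variance ratio is computed on both the rank-normalized
#' draws and their folded (absolute deviation from the median) version;
#' the larger of the two is reported. Zero-variance chains return 1 by
#' convention.
#'
#' @param mat Iterations-by-chains numeric matrix (>= 2 chains, >= 4
#'   iterations).
#' @return Scalar R-hat (>= 1 up to numerical tolerance).
#' @export
split_rhat <- function(mat) {
  mat <- as_chain_matrix(mat)
  if (stats::sd(mat) == 0) return(1)
  s <- split_chains(mat)
  bulk <- rhat_basic(z_scale(s))
  folded <- rhat_basic(z_scale(abs(s - stats::median(s))))
  max(bulk, folded)
}

#' Bulk effective sample size of a set of chains
#'
#' Autocorrelation-based ESS computed on the split, rank-normalized
#' draws. Returns `NA` for zero-variance chains.
#'
#' @inheritParams split_rhat
#' @return Scalar bulk ESS.
#' @export
bulk_ess <- function(mat) {
  mat <- as_chain_matrix(mat)
  if (stats::sd(mat) == 0) return(NA_real_)
  ess_basic(z_scale(split_chains(mat)))
}

as_chain_matrix <- function(mat) {
  if (is.list(mat)) {
    len <- unique(lengths(mat))
    if (length(len) != 1L) stop("chains must have equal lengths")
    mat <- do.call(cbind, mat)
  }
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need >= 2 chains for diagnostics")
  if (nrow(mat) < 4L) stop("need >= 4 iterations per chain")
  if (any(!is.finite(mat))) stop("chains contain non-finite values")
  mat
}

#' Convergence diagnostics report for a posterior sample
#'
#' Per-parameter split R-hat and bulk ESS with pass flags at the
#' conventional gates (R-hat <= 1.01, ESS >= 400). Parameters whose
#' chains have zero variance are flagged degenerate and reported with
#' R-hat 1 (convention) and ESS `NA`.
#'
#' @param draws A `posterior_draws` object, or a named list of
#'   iterations-by-chains matrices.
#' @param rhat_max,ess_min Pass thresholds.
#' @return A `data.frame` with columns `parameter`, `rhat`, `ess_bulk`,
#'   `rhat_ok`, `ess_ok`, `degenerate`.
#' @export
rhat_and_ess <- function(draws, rhat_max = 1.01, ess_min = 400) {
  mats <- if (inherits(draws, "posterior_draws")) {
    stats::setNames(lapply(draws$parameters, chains_of, draws = draws),
                    draws$parameters)
  } else {
    draws
  }
  res <- do.call(rbind, lapply(names(mats), function(nm) {
    m <- as_chain_matrix(mats[[nm]])
    degen <- stats::sd(m) == 0
    r <- split_rhat(m)
    e <- bulk_ess(m)
    data.frame(parameter = nm, rhat = r, ess_bulk = e,
               rhat_ok = r <= rhat_max,
               ess_ok = !is.na(e) && e >= ess_min,
               degenerate = degen, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}
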