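#' Core of the learning region
#'
#' Filters sweep results to the ensembles that converge reliably: at least
#' `rho_min` of repeats produce the correct topological signature and the
#' relative variability of the learning time does not exceed `xi_max`. Both
#' thresholds are inclusive.
#'
#' @param results data frame with columns `rho` and `xi` (e.g. from
#'   [run_sweep()]).
#' @param rho_min minimal convergence rate (default 0.7).
#' @param xi_max maximal relative variability (default 0.3).
#' @return the filtered subset (possibly empty).
#' @export
core_filter <- function(results, rho_min = 0.7, xi_max = 0.3) {
  stopifnot(is.data.frame(results))
  keep <- !is.na(results$rho) & results$rho >= rho_min &
    !is.na(results$xi) & results$xi <= xi_max
  results[keep, , drop = FALSE]
}

#' Generalized extreme value density
#'
#' @param x quantiles.
#' @param loc,scale,shape GEV location, scale (> 0) and shape parameters;
#'   `shape = 0` is the Gumbel limit.
#' @param log return the log-density.
#' @return density values (0 outside the support).
#' @export
dgev <- function(x, loc = 0, scale = 1, shape = 0, log = FALSE) {
  stopifnot(scale > 0)
  z <- (x - loc) / scale
  if (abs(shape) < 1e-9) {
    ld <- -z - exp(-z) - base::log(scale)
  } else {
    u <- 1 + shape * z
    ld <- ifelse(u > 0,
                 -(1 / shape + 1) * base::log(pmax(u, 1e-300)) -
                   pmax(u, 1e-300)^(-1 / shape) - base::log(scale),
                 -Inf)
  }
  if (log) ld else exp(ld)
}

#' Random GEV deviates
#'
#' @param n number of draws.
#' @inheritParams dgev
#' @return numeric vector.
#' @export
rgev <- function(n, loc = 0, scale = 1, shape = 0) {
  u <- runif(n)
  if (abs(shape) < 1e-9) loc - scale * base::log(-base::log(u))
  else loc + scale * ((-base::log(u))^(-shape) - 1) / shape
}

gev_mode <- function(loc, scale, shape) {
  if (abs(shape) < 1e-9) return(loc)
  if (shape <= -1) return(loc + scale * (0 - 1) / shape)  # support edge
  loc + scale * ((1 + shape)^(-shape) - 1) / shape
}

fit_gev_mle <- function(x) {
  # moment-style start (Gumbel): scale from sd, location from mean
  s0 <- sd(x) * sqrt(6) / pi
  m0 <- mean(x) - 0.57722 * s0
  nll <- function(p) {
    sc <- exp(p[2])
    -sum(dgev(x, p[1], sc, p[3], log = TRUE))
  }
  best <- NULL
  for (sh0 in c(0, 0.2, -0.2)) {
    fit <- try(optim(c(m0, base::log(s0), sh0), nll, method = "Nelder-Mead",
                     control = list(maxit = 2000)), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("GEV fit failed")
  list(loc = best$par[1], scale = exp(best$par[2]), shape = best$par[3],
       loglik = -best$value)
}

#' Fit a distribution family to a sample by maximum likelihood
#'
#' Supported families: `"gev"` (generalized extreme value, fit by direct
#' likelihood optimisation), `"gamma"` and `"normal"`. The mode of the
#' fitted density is reported as the "typical" value of the sample.
#'
#' @param x numeric sample (>= 10 values; strictly positive for gamma).
#' @param family one of `"gev"`, `"gamma"`, `"normal"`.
#' @return object of class `fit_result`: `family`, `params` (named), `mode`,
#'   `loglik`, `aic`, `n`.
#' @export
fit_distribution <- function(x, family = c("gev", "gamma", "normal")) {
  family <- match.arg(family)
  x <- x[is.finite(x)]
  if (length(x) < 10) stop("need at least 10 finite samples")
  if (sd(x) == 0) stop("degenerate (constant) sample")
  if (family == "gamma" && any(x <= 0))
    stop("gamma family requires strictly positive samples")
  if (family == "gev") {
    f <- fit_gev_mle(x)
    params <- c(loc = f$loc, scale = f$scale, shape = f$shape)
    mode <- gev_mode(f$loc, f$scale, f$shape)
    ll <- f$loglik
    k <- 3
  } else if (family == "gamma") {
    # MLE via optimisation of (log shape, log rate), moment start
    m <- mean(x); v <- var(x)
    p0 <- c(base::log(m^2 / v), base::log(m / v))
    nll <- function(p) -sum(dgamma(x, exp(p[1]), exp(p[2]), log = TRUE))
    fit <- optim(p0, nll, method = "Nelder-Mead")
    shape <- exp(fit$par[1]); rate <- exp(fit$par[2])
    params <- c(shape = shape, rate = rate)
    mode <- if (shape >= 1) (shape - 1) / rate else 0
    ll <- -fit$value
    k <- 2
  } else {
    params <- c(mean = mean(x), sd = sqrt(mean((x - mean(x))^2)))
    mode <- params[["mean"]]
    ll <- sum(dnorm(x, params[1], params[2], log = TRUE))
    k <- 2
  }
  structure(list(family = family, params = params, mode = mode,
                 loglik = ll, aic = 2 * k - 2 * ll, n = length(x)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): %s; mode = %.4g\n", x$family, x$n,
              paste(names(x$params), signif(x$params, 4), sep = " = ",
                    collapse = ", "), x$mode))
  invisible(x)
}

#' Pairwise Kolmogorov-Smirnov comparison matrix
#'
#' Two-sample KS tests for all pairs of labelled sample groups, with a
#' significance mask at `alpha` (no multiplicity correction, matching the
#' field's raw-alpha convention for these diagrams).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with at
#'   least 5 values).
#' @param alpha significance level (default 0.05).
#' @return list with `p` (symmetric matrix, diagonal 1) and `significant`
#'   (logical matrix, `p < alpha` off-diagonal).
#' @export
ks_matrix <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two sample groups")
  if (any(vapply(groups, length, 0L) < 5))
    stop("each group needs at least 5 samples")
  k <- length(groups)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("g", seq_len(k))
  p <- matrix(1, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pv <- suppressWarnings(
        ks.test(groups[[i]], groups[[j]], exact = FALSE)$p.value)
      p[i, j] <- pv; p[j, i] <- pv
    }
  }
  sig <- p < alpha
  diag(sig) <- FALSE
  list(p = p, significant = sig)
}
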