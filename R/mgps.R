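#' Fit the DuMouchel gamma-Poisson shrinkage prior
#'
#' The multi-item gamma Poisson shrinker models each observed co-report
#' count `a` as Poisson with mean `lambda * E`, where `E` is the expected
#' count under independence and `lambda` follows a two-component gamma
#' mixture prior `p Gamma(alpha1, beta1) + (1-p) Gamma(alpha2, beta2)`
#' (shape/rate). Marginally each count is negative binomial, and the five
#' hyperparameters are estimated by maximum marginal likelihood over all
#' drug-event tables, with multi-start quasi-Newton optimization from fixed
#' starting points (including DuMouchel's canonical
#' `(0.2, 0.1, 2, 4, 1/3)`).
#'
#' @param tables list of `contingency` objects, or a data.frame with cell
#'   columns `a`, `b`, `c`, `d` (one row per drug-event pair), or a
#'   data.frame with columns `a` and `E`.
#' @param starts optional list of numeric length-5 start vectors
#'   `(alpha1, beta1, alpha2, beta2, p)`.
#' @return an `mgps_prior`: list with `alpha1`, `beta1`, `alpha2`, `beta2`,
#'   `mix_p`, the achieved `loglik`, number of pairs `n`, and `convergence`.
#' @export
fit_mgps_prior <- function(tables, starts = NULL) {
  ae <- .as_a_e(tables)
  if (nrow(ae) < 2L) {
    stop("MGPS prior fitting needs at least 2 drug-event tables")
  }
  if (nrow(ae) < 50L) {
    warning("fewer than 50 tables: hyperparameter estimates may be unstable")
  }
  a <- ae$a; E <- ae$E
  nll <- function(theta) {
    if (any(abs(theta) > 50)) return(.Machine$double.xmax)  # optim excursions
    a1 <- exp(theta[1]); b1 <- exp(theta[2])
    a2 <- exp(theta[3]); b2 <- exp(theta[4])
    p <- stats::plogis(theta[5])
    l1 <- suppressWarnings(
      stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)) +
      log(p)
    l2 <- suppressWarnings(
      stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)) +
      log1p(-p)
    m <- pmax(l1, l2)
    v <- -sum(m + log(exp(l1 - m) + exp(l2 - m)))
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  if (is.null(starts)) {
    starts <- list(c(0.2, 0.1, 2, 4, 1 / 3),
                   c(1, 1, 1, 1, 0.5),
                   c(0.5, 2, 3, 1, 0.2),
                   c(2, 4, 0.2, 0.1, 2 / 3))
  }
  best <- NULL
  for (s in starts) {
    theta0 <- c(log(s[1:4]), stats::qlogis(s[5]))
    fit <- tryCatch(
      stats::optim(theta0, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        stats::optim(theta0, nll, method = "Nelder-Mead",
                     control = list(maxit = 2000)),
        error = function(e) NULL)
    }
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("MGPS prior optimization failed from all starts")
  th <- best$par
  structure(list(alpha1 = exp(th[1]), beta1 = exp(th[2]),
                 alpha2 = exp(th[3]), beta2 = exp(th[4]),
                 mix_p = stats::plogis(th[5]),
                 loglik = -best$value, n = nrow(ae),
                 convergence = best$convergence),
            class = "mgps_prior")
}

#' Construct an MGPS prior from known hyperparameters
#' @param alpha1,beta1,alpha2,beta2 positive gamma shape/rate parameters.
#' @param mix_p mixing weight of the first component, in (0, 1).
#' @return an `mgps_prior`.
#' @export
mgps_prior <- function(alpha1, beta1, alpha2, beta2, mix_p) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0,
            mix_p > 0, mix_p < 1)
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, mix_p = mix_p, loglik = NA_real_,
                 n = NA_integer_, convergence = NA_integer_),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf(paste0("<mgps_prior> Gamma(%.3g, %.3g) w=%.3f | ",
                     "Gamma(%.3g, %.3g) w=%.3f"),
              x$alpha1, x$beta1, x$mix_p, x$alpha2, x$beta2, 1 - x$mix_p))
  if (is.finite(x$loglik)) cat(sprintf("  (logLik %.2f, n=%d)", x$loglik, x$n))
  cat("\n")
  invisible(x)
}

.as_a_e <- function(tables) {
  if (is.data.frame(tables)) {
    if (all(c("a", "E") %in% names(tables))) {
      return(data.frame(a = tables$a, E = tables$E))
    }
    return(data.frame(a = tables$a, E = expected_count(tables)))
  }
  stopifnot(is.list(tables))
  data.frame(a = vapply(tables, function(t) .cells(t)$a, numeric(1)),
             E = vapply(tables, expected_count, numeric(1)))
}

#' Empirical Bayes geometric mean and its 5th posterior percentile
#'
#' Under the gamma mixture prior the posterior of `lambda` given `a` is
#' again a two-gamma mixture with shapes `alpha_i + a`, rates `beta_i + E`
#' and posterior weight proportional to the prior weight times the negative
#' binomial evidence. `EBGM = exp(E[ln lambda | a])` via digamma; `EBGM05`
#' is the 5th percentile of the posterior mixture obtained by numeric
#' root-finding on the mixture CDF.
#'
#' @param t a `contingency`, a cell data.frame (vectorized), or a
#'   data.frame with columns `a` and `E`.
#' @param prior an `mgps_prior`.
#' @param percentile lower posterior percentile reported (default 0.05).
#' @return data.frame with `ebgm`, `ebgm05`.
#' @export
compute_ebgm <- function(t, prior, percentile = 0.05) {
  stopifnot(inherits(prior, "mgps_prior"))
  ae <- .as_a_e(if (inherits(t, "contingency")) list(t) else t)
  a <- ae$a; E <- ae$E
  post <- .mgps_posterior(a, E, prior)
  meanlog <- post$q * (digamma(post$s1) - log(post$r1)) +
    (1 - post$q) * (digamma(post$s2) - log(post$r2))
  ebgm <- exp(meanlog)
  ebgm05 <- vapply(seq_along(a), function(i) {
    .mixture_quantile(percentile, post$q[i], post$s1[i], post$r1[i],
                      post$s2[i], post$r2[i])
  }, numeric(1))
  data.frame(ebgm = ebgm, ebgm05 = ebgm05)
}

# posterior mixture parameters given counts and prior
.mgps_posterior <- function(a, E, prior) {
  l1 <- stats::dnbinom(a, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + E), log = TRUE) +
    log(prior$mix_p)
  l2 <- stats::dnbinom(a, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + E), log = TRUE) +
    log1p(-prior$mix_p)
  q <- 1 / (1 + exp(l2 - l1))
  list(q = q, s1 = prior$alpha1 + a, r1 = prior$beta1 + E,
       s2 = prior$alpha2 + a, r2 = prior$beta2 + E)
}

.mixture_quantile <- function(p, q, s1, r1, s2, r2) {
  cdf <- function(x) {
    q * stats::pgamma(x, shape = s1, rate = r1) +
      (1 - q) * stats::pgamma(x, shape = s2, rate = r2)
  }
  lo <- min(stats::qgamma(p / 4, shape = s1, rate = r1),
            stats::qgamma(p / 4, shape = s2, rate = r2))
  hi <- max(stats::qgamma(1 - 1e-9, shape = s1, rate = r1),
            stats::qgamma(1 - 1e-9, shape = s2, rate = r2))
  lo <- max(lo, .Machine$double.xmin)
  if (cdf(lo) > p) return(lo)
  stats::uniroot(function(x) cdf(x) - p, lower = lo, upper = hi,
                 tol = 1e-10)$root
}
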