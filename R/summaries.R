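#' Summarise ratio-scale posterior draws for one area
#'
#' Point estimate is the posterior median (robust to MCMC outliers); the
#' 60% and 80% credible intervals are equal-tailed quantile intervals.
#' Quantiles use linear interpolation between order statistics (type 7),
#' so the summaries are equivariant under monotone maps such as `exp`.
#'
#' @param draws numeric vector of ratio-scale draws (length >= 2).
#' @return list with `point`, `cri60`, `cri80`.
#' @export
summarise_draws <- function(draws) {
  if (length(draws) < 2) stop("need at least two draws")
  q <- quantile(draws, c(0.1, 0.2, 0.5, 0.8, 0.9), names = FALSE, type = 7)
  list(point = q[3], cri60 = c(q[2], q[4]), cri80 = c(q[1], q[5]))
}

#' Posterior probability of exceeding 1, and the DPP
#'
#' \eqn{PP_{high} = M^{-1} \sum_m I(A^{(m)} > 1)} (strict inequality;
#' draws equal to 1 count as not greater) and the difference in posterior
#' probabilities \eqn{DPP = |PP_{high} - PP_{low}| = 2 |PP_{high} - 0.5|},
#' the confidence that an area genuinely differs from the national
#' average.
#'
#' @param draws numeric vector of ratio-scale draws (length >= 1).
#' @return list with `pp_high` and `dpp`, both in `[0, 1]`.
#' @export
dpp <- function(draws) {
  if (length(draws) < 1) stop("need at least one draw")
  pp_high <- mean(draws > 1)
  list(pp_high = pp_high, dpp = 2 * abs(pp_high - 0.5))
}

#' Geweke convergence flags for per-area chains
#'
#' For each retained chain the Geweke z-score compares the means of the
#' first 10% and last 50% of iterations, with variances estimated from the
#' spectral density at frequency zero (autoregressive estimator, as in the
#' classical diagnostic).  Areas with a two-sided p-value below `alpha`
#' are flagged for visual inspection.  Constant (zero-variance) chains
#' receive a distinct `"degenerate"` status instead of a p-value.
#'
#' @param chains numeric matrix, iterations by areas (named columns), or a
#'   single numeric vector.
#' @param alpha flagging threshold (default 0.01).
#' @param frac1,frac2 window fractions (classical defaults 0.1 and 0.5).
#' @return data frame with `area`, `z`, `p`, `flag`, `status`.
#' @export
geweke_flags <- function(chains, alpha = 0.01, frac1 = 0.1, frac2 = 0.5) {
  if (is.null(dim(chains))) chains <- matrix(chains, ncol = 1,
                                             dimnames = list(NULL, "chain"))
  if (nrow(chains) < 100) stop("chains must have at least 100 iterations")
  ids <- colnames(chains)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(chains)))
  res <- lapply(seq_len(ncol(chains)), function(j) {
    x <- chains[, j]
    if (stats::var(x) == 0)
      return(data.frame(area = ids[j], z = NA_real_, p = NA_real_,
                        flag = TRUE, status = "degenerate"))
    n <- length(x)
    x1 <- x[seq_len(floor(frac1 * n))]
    x2 <- x[seq.int(n - floor(frac2 * n) + 1L, n)]
    v1 <- .spectrum0_ar(x1); v2 <- .spectrum0_ar(x2)
    z <- (mean(x1) - mean(x2)) / sqrt(v1 / length(x1) + v2 / length(x2))
    p <- 2 * pnorm(-abs(z))
    data.frame(area = ids[j], z = z, p = p, flag = p < alpha, status = "ok")
  })
  do.call(rbind, res)
}

# spectral density at frequency zero via an AIC-selected AR fit
.spectrum0_ar <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(0)
  fit <- try(ar(x, aic = TRUE, order.max = min(n - 1L,
                                               floor(10 * log10(n)))),
             silent = TRUE)
  if (inherits(fit, "try-error") || length(fit$ar) == 0)
    return(stats::var(x))
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Per-area atlas estimates from ratio-scale draws
#'
#' Combines [summarise_draws()], [dpp()] and (optionally) [geweke_flags()]
#' into the per-area estimate table behind the atlas layers.
#'
#' @param ratio_draws numeric matrix, retained draws by areas (named
#'   columns), e.g. from [sir_draws()] or [ehr_draws()].
#' @param geweke logical; attach Geweke convergence flags (computed on the
#'   log-scale chains).
#' @param alpha Geweke flagging threshold.
#' @return data frame with columns `area`, `point`, `cri60_lo`, `cri60_hi`,
#'   `cri80_lo`, `cri80_hi`, `pp_high`, `dpp`, and (with `geweke = TRUE`)
#'   `geweke_p`, `geweke_flag`, `geweke_status`.
#' @export
atlas_estimates <- function(ratio_draws, geweke = TRUE, alpha = 0.01) {
  ids <- colnames(ratio_draws)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(ratio_draws)))
  q <- apply(ratio_draws, 2, quantile, probs = c(0.1, 0.2, 0.5, 0.8, 0.9),
             names = FALSE, type = 7)
  pp <- colMeans(ratio_draws > 1)
  out <- data.frame(area = ids, point = q[3, ],
                    cri60_lo = q[2, ], cri60_hi = q[4, ],
                    cri80_lo = q[1, ], cri80_hi = q[5, ],
                    pp_high = pp, dpp = 2 * abs(pp - 0.5),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (geweke) {
    g <- geweke_flags(log(ratio_draws), alpha = alpha)
    out$geweke_p <- g$p
    out$geweke_flag <- g$flag
    out$geweke_status <- g$status
  }
  out
}

#' Write an estimates table to CSV
#' @param estimates data frame from [atlas_estimates()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  write.csv(estimates, path, row.names = FALSE)
  invisible(path)
}
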