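#' MCMC schedule and prior configuration
#'
#' Defaults follow the production schedule of the Atlas models: 50,000
#' burn-in iterations, 100,000 further iterations thinned by 10, for a
#' posterior sample of 10,000 draws.  The variance hyperprior is
#' configurable as a sensitivity hook: `inverse_gamma(shape, scale)`
#' (incidence default, IG(1, 0.01)) or `half_normal(variance)` applied to
#' \eqn{\sigma_S^2} itself (survival default, variance 5).
#'
#' @param burn_in burn-in iterations.
#' @param iterations post-burn-in iterations; must be divisible by `thin`.
#' @param thin thinning interval; `iterations / thin` draws are retained.
#' @param seed integer RNG seed.
#' @param variance_prior list with `family` (`"inverse_gamma"` or
#'   `"half_normal"`) and parameters `shape`/`scale` or `variance`; `NULL`
#'   for the model's default.
#' @param fix_rho,fix_sigma2 optional fixed values (no sampling) — used for
#'   oracle comparisons and debugging.
#' @param fix_intercept optional fixed intercept (incidence model only);
#'   fixing it also disables the re-centring of the spatial effects, since
#'   the intercept no longer absorbs their mean.
#' @param intercept_prior_var prior variance of the intercept(s); `NULL`
#'   for the model default (1e5 incidence, 1000 survival).
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(burn_in = 50000, iterations = 100000, thin = 10,
                        seed = 1L, variance_prior = NULL,
                        fix_rho = NULL, fix_sigma2 = NULL,
                        fix_intercept = NULL, intercept_prior_var = NULL) {
  stopifnot(burn_in >= 0, iterations > 0, thin >= 1)
  if (iterations %% thin != 0) stop("iterations must be divisible by thin")
  if (!is.null(variance_prior)) {
    if (!variance_prior$family %in% c("inverse_gamma", "half_normal"))
      stop("variance_prior$family must be 'inverse_gamma' or 'half_normal'")
  }
  structure(list(burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations),
                 thin = as.integer(thin), seed = as.integer(seed),
                 variance_prior = variance_prior,
                 fix_rho = fix_rho, fix_sigma2 = fix_sigma2,
                 fix_intercept = fix_intercept,
                 intercept_prior_var = intercept_prior_var),
            class = "mcmc_config")
}

.variance_prior_code <- function(vp, default_family, default_a, default_b) {
  if (is.null(vp)) {
    list(family = match(default_family, c("inverse_gamma", "half_normal")) - 1L,
         a = default_a, b = default_b)
  } else if (vp$family == "inverse_gamma") {
    list(family = 0L, a = vp$shape, b = vp$scale)
  } else {
    list(family = 1L, a = vp$variance, b = 0)
  }
}

.graph_csr <- function(graph) {
  W <- graph$W
  n <- nrow(W)
  # column-compressed == row-compressed for a symmetric matrix
  list(idx = W@i, start = W@p, n = n)
}

#' Posterior draws container
#'
#' @param draws numeric matrix, retained draws by parameters (named
#'   columns).
#' @param acceptance named acceptance-rate vector.
#' @param config the [mcmc_config()] used.
#' @param area_ids area identifiers for the spatial effects.
#' @param model `"incidence"` or `"survival"`.
#' @param extra further elements stored alongside.
#' @return a `posterior_draws` object.
#' @export
posterior_draws <- function(draws, acceptance, config, area_ids, model,
                            extra = list()) {
  stopifnot(is.matrix(draws), !is.null(colnames(draws)))
  structure(c(list(draws = draws, acceptance = acceptance, config = config,
                   area_ids = area_ids, model = model), extra),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws (%s model): %d retained draws x %d parameters\n",
              x$model, nrow(x$draws), ncol(x$draws)))
  cat("acceptance:",
      paste(sprintf("%s=%.2f", names(x$acceptance), x$acceptance),
            collapse = " "), "\n")
  invisible(x)
}
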