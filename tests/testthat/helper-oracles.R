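# Independent oracles and small fixtures used across the suite.
# These deliberately re-derive quantities by brute force (dense algebra,
# quadrature, per-day discretisation) so they share no code with the
# implementation paths they check.

# chain graph 1-2-3-...-n
chain_graph <- function(n, centroids = cbind(seq_len(n), rep(0, n))) {
  edges <- data.frame(id_a = paste0("C", seq_len(n - 1)),
                      id_b = paste0("C", 2:n))
  build_adjacency(edges, area_ids = paste0("C", seq_len(n)),
                  centroids = centroids)
}

# dense Leroux covariance by direct inversion
leroux_cov_dense <- function(graph, rho, sigma2) {
  W <- as.matrix(graph$W)
  D <- diag(rowSums(W))
  solve((rho * (D - W) + (1 - rho) * diag(nrow(W))) / sigma2)
}

# repeated field draws (seed set once by caller)
field_draws <- function(graph, rho, sigma2, ndraw) {
  simulate_leroux_field(graph, rho, sigma2, n_draws = ndraw)
}

# posterior mean of theta for y ~ Poisson(E e^theta), theta ~ N(0, s2),
# by 1-D quadrature
pln_post_mean <- function(y, E, s2, lim = 10, n = 8001) {
  th <- seq(-lim, lim, length.out = n)
  lw <- y * th - E * exp(th) - th^2 / (2 * s2)
  w <- exp(lw - max(lw))
  sum(th * w) / sum(w)
}

# posterior means of theta = beta0 + S for the 3-area chain instance with
# rho, sigma2 fixed: prior on theta is exactly MVN(0, tau2 * J + Sigma_S),
# integrated on a dense 3-D grid
leroux3_post_means <- function(y, E, graph, rho, sigma2, tau2 = 1e5,
                               lim = 5, n = 121) {
  SigS <- leroux_cov_dense(graph, rho, sigma2)
  C <- tau2 * matrix(1, 3, 3) + SigS
  Ci <- solve(C)
  g <- seq(-lim, lim, length.out = n)
  G <- as.matrix(expand.grid(t1 = g, t2 = g, t3 = g))
  ll <- G %*% y - exp(G) %*% E
  qf <- rowSums((G %*% Ci) * G)
  lw <- as.numeric(ll) - qf / 2
  w <- exp(lw - max(lw))
  colSums(G * w) / sum(w)
}

# posterior mean of exp(alpha) for d ~ Poisson(dstar + y e^alpha),
# alpha ~ N(0, v), by 1-D quadrature
survival1_post_mean_exp <- function(d, y, dstar, v = 1000,
                                    lim = c(-10, 4), n = 8001) {
  a <- seq(lim[1], lim[2], length.out = n)
  mu <- dstar + y * exp(a)
  lw <- d * log(mu) - mu - a^2 / (2 * v)
  w <- exp(lw - max(lw))
  sum(exp(a) * w) / sum(w)
}

# Monte-Carlo standard error of a chain's mean via the same AR spectral
# estimator used for the Geweke diagnostic
mcse <- function(chain) {
  sqrt(atlasmooth:::.spectrum0_ar(chain) / length(chain))
}

# per-day discretised person-time oracle: total person-years per patient
# inside the window, within the first five follow-up years
person_time_oracle <- function(patients, window, step = 1 / 365) {
  total <- 0
  for (p in seq_len(nrow(patients))) {
    tt <- seq(patients$diagnosis[p], min(patients$diagnosis[p] + 5,
                                         patients$exit[p]) - step / 2,
              by = step)
    if (length(tt) == 0) next
    total <- total + step * sum(tt >= window[1] & tt < window[2])
  }
  total
}

# unit-segment rasterisation adjacency oracle for integer-lattice polygons
lattice_adjacency_oracle <- function(polygons) {
  seg_keys <- lapply(polygons, function(poly) {
    keys <- character(0)
    rings <- if (is.matrix(poly)) list(poly) else poly
    for (ring in rings) {
      for (s in seq_len(nrow(ring) - 1)) {
        a <- ring[s, ]; b <- ring[s + 1, ]
        steps <- max(abs(b - a))
        for (k in seq_len(steps)) {
          p0 <- a + (b - a) * (k - 1) / steps
          p1 <- a + (b - a) * k / steps
          key <- paste(sort(c(paste(p0, collapse = ","),
                              paste(p1, collapse = ","))), collapse = "|")
          keys <- c(keys, key)
        }
      }
    }
    keys
  })
  n <- length(polygons)
  A <- matrix(0, n, n, dimnames = list(names(polygons), names(polygons)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (length(intersect(seg_keys[[i]], seg_keys[[j]])) > 0) {
        A[i, j] <- A[j, i] <- 1
      }
    }
  }
  A
}

# small incidence fixture at the national average, ids matching chain_graph
flat_incidence <- function(n = 10, E = 1000) {
  data.frame(area = paste0("C", seq_len(n)),
             observed = rep(E, n), expected = rep(E, n))
}

quick_mcmc <- function(seed = 1L, ...) {
  mcmc_config(burn_in = 2000, iterations = 4000, thin = 4, seed = seed, ...)
}
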