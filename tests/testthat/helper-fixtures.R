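# Shared fixtures, all built in code.

# random stable Ogden parameter set (all mu, alpha > 0 => sum(mu*alpha) > 0)
rand_stable_params <- function(n_terms = 2L) {
  ogden_params(mu = exp(runif(n_terms, log(1e-4), log(0.1))),
               alpha = exp(runif(n_terms, log(0.01), log(30))))
}

# positively oriented regular tetrahedron with the given edge length
regular_tet <- function(edge = 1) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, -1, 1), c(-1, 1, -1))
  v * edge / (2 * sqrt(2))
}

# random rigid rotation (QR of a Gaussian matrix, det forced to +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# mesh of n disjoint copies of the 4x3 vertex block `tet`, translated apart
disjoint_tet_mesh <- function(tet_list, spacing = 100) {
  nodes <- do.call(rbind, lapply(seq_along(tet_list), function(i)
    sweep(tet_list[[i]], 2, c(spacing * i, 0, 0), "+")))
  tets <- t(vapply(seq_along(tet_list), function(i) (i - 1L) * 4L + 1:4,
                   integer(4)))
  tet_mesh(nodes, tets)
}

# noiseless synthetic curve sampled directly from a parameter set
law_curve <- function(params, lam_min = 1, lam_max = 1.6, n = 50,
                      id = "synthetic") {
  lam <- seq(lam_min, lam_max, length.out = n)
  stress_strain_curve(id, lam, uniaxial_nominal_stress(params, lam))
}

# independent brute-force grid-search oracle for a 1-term fit: its own
# stress formula and SSE loop, successively refined around the incumbent
grid_search_one_term <- function(curve, mu_range = c(1e-4, 0.05),
                                 alpha_range = c(1, 30), n_grid = 41L,
                                 rounds = 6L) {
  sse <- function(mu, alpha) {
    tot <- 0
    for (i in seq_along(curve$stretch)) {
      l <- curve$stretch[i]
      p <- 2 * mu * (l^(alpha - 1) - l^(-alpha / 2 - 1))
      tot <- tot + (curve$nominal_stress_mpa[i] - p)^2
    }
    tot
  }
  lo <- c(mu_range[1], alpha_range[1])
  hi <- c(mu_range[2], alpha_range[2])
  best <- c(NA, NA); best_val <- Inf
  for (r in seq_len(rounds)) {
    mus <- exp(seq(log(lo[1]), log(hi[1]), length.out = n_grid))
    als <- seq(lo[2], hi[2], length.out = n_grid)
    for (m in mus) for (a in als) {
      v <- sse(m, a)
      if (v < best_val) { best_val <- v; best <- c(m, a) }
    }
    # shrink the box around the incumbent
    span_m <- (log(hi[1]) - log(lo[1])) / 4
    span_a <- (hi[2] - lo[2]) / 4
    lo <- c(exp(log(best[1]) - span_m), max(alpha_range[1], best[2] - span_a))
    hi <- c(exp(log(best[1]) + span_m), min(alpha_range[2], best[2] + span_a))
  }
  list(mu = best[1], alpha = best[2], sse = best_val)
}
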