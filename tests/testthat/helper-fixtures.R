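# Shared fixtures and independent oracle helpers, built in code.

# A small mixed-format form: 2 x 3PL, 1 x 2PL, 2 x GPC (max score 11).
tiny_form <- function(role = "unique", prefix = "t") {
  item_params(
    item_id = paste0(prefix, 1:5),
    role = role,
    item_type = c("MC", "MC", "SR", "CR", "CR"),
    model = c("3PL", "3PL", "2PL", "GPC", "GPC"),
    a = c(0.9, 1.4, 1.1, 0.8, 1.2),
    b = c(-0.6, 0.4, 0.0, -0.2, 0.7),
    c = c(0.2, 0.15, 0, 0, 0),
    d = rbind(NA, NA, NA,
              c(0.6, 0.1, -0.2, -0.5),
              c(0.8, 0.3, -0.3, -0.8))
  )
}

# A full 39-item form with unit slopes and central difficulties, so its TCC
# saturates quickly at both ends (29 x 3PL c = 0.2, 5 x 2PL, 5 x GPC).
saturating_form <- function(role = "unique", prefix = "s") {
  n_mc <- 29; n_sr <- 5; n_cr <- 5
  item_params(
    item_id = sprintf("%s%02d", prefix, 1:39),
    role = role,
    item_type = rep(c("MC", "SR", "CR"), c(n_mc, n_sr, n_cr)),
    model = rep(c("3PL", "2PL", "GPC"), c(n_mc, n_sr, n_cr)),
    a = 1, b = 0,
    c = rep(c(0.2, 0, 0), c(n_mc, n_sr, n_cr)),
    d = rbind(matrix(NA_real_, 34, 4),
              matrix(rep(c(0.4, 0.1, -0.1, -0.4), 5), 5, 4, byrow = TRUE))
  )
}

# Independent GPC oracle: brute-force cumulative-sum numerators.
gpc_prob_oracle <- function(a, b, d, theta, D = 1.7) {
  z <- c(0, cumsum(D * a * (theta - b + d)))
  exp(z - max(z)) / sum(exp(z - max(z)))
}

# Independent dichotomous oracle.
dich_prob_oracle <- function(a, b, c, theta, D = 1.7) {
  c + (1 - c) / (1 + exp(-D * a * (theta - b)))
}

# Independent penalized expected-log-likelihood used by the M-step grid
# oracles (R re-implementation, kept apart from the package internals).
pen_obj_2pl <- function(a, b, counts, theta, prior, D = 1.7) {
  P <- pmin(pmax(dich_prob_oracle(a, b, 0, theta, D), 1e-12), 1 - 1e-12)
  f <- sum(counts[1, ] * log(1 - P) + counts[2, ] * log(P))
  if (prior$on)
    f <- f - 0.5 * ((log(a) - prior$loga_mean) / prior$loga_sd)^2 -
      0.5 * (b / prior$b_sd)^2
  f
}

# Expected counts at given parameters (an exact "dataset" for stationary
# point checks): counts r_kq = n_q * P_k(theta_q).
expected_counts_dich <- function(a, b, c, theta, n_per_node, D = 1.7) {
  P <- dich_prob_oracle(a, b, c, theta, D)
  rbind(n_per_node * (1 - P), n_per_node * P)
}
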