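# Independent oracles used across the suite.

# Closed-form transform-domain Green's function of a single homogeneous slab
# with extrapolated boundaries (hyperbolic form; overflows for large
# alpha * L, which is exactly why the package uses the exponential sweep).
slab_greens_oracle <- function(mu_a, mu_sp, L, A, s, z, z0 = 1 / mu_sp) {
  D <- 1 / (3 * mu_sp)
  zb <- 2 * A * D
  alpha <- sqrt(mu_a / D + s^2)
  den <- D * alpha * sinh(alpha * (L + 2 * zb))
  if (z >= z0) sinh(alpha * (z0 + zb)) * sinh(alpha * (L + zb - z)) / den
  else sinh(alpha * (z + zb)) * sinh(alpha * (L + zb - z0)) / den
}

# Equal-property helper media
equal_stack <- function(n_layers, L = 10, mu_a = 0.1, mu_sp = 10, radius = 20) {
  layered_medium(rep(mu_a, n_layers), rep(mu_sp, n_layers),
                 rep(L / n_layers, n_layers), radius = radius)
}

fig2_medium <- function() equal_stack(2)
fig2_semiinf <- function() semiinf_medium(0.1, 10, 1.4)

# trapezoid rule
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
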