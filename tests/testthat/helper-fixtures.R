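# Shared fixtures: all synthetic, generated in code.

# Task at the low-friction end (ideal stop-time 5 s).
fix_cfg <- function() task_config(mu = friction_set(5))

# The emulated study condition: weakly stable direction nearly tangent to the
# GEM, strongly stable transverse direction, 10 x 50-trial blocks.
fix_spec <- function(seed = 1L, ...) {
  simulation_spec(fix_cfg(), seed = seed, ...)
}

# Exact linear pairs u_{k+1} = B u_k from random starts (noise-free data for
# algebraic identities).
fix_exact_pairs <- function(B, n = 50L, seed = 1L) {
  set.seed(seed)
  cur <- matrix(rnorm(2L * n), n, 2L)
  list(cur = cur, nxt = cur %*% t(B))
}
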