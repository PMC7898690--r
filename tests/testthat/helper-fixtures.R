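# Shared fixtures: the default study conditions used across tests.

default_vif <- function() vif_model()

wm_params <- function() reference_tissue("WM")
gm_params <- function() reference_tissue("GM")

two_map_scheme <- function(last = 30) make_scheme(4.333, last, 0)

# brute-force two-sided Wilcoxon signed-rank p by enumerating all 2^n sign
# assignments of the ranked |differences| (assumes no ties, no zeros)
enumerate_wilcoxon_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  mean_v <- n * (n + 1) / 4
  p <- mean(abs(v_all - mean_v) >= abs(v_obs - mean_v) - 1e-9)
  min(1, p)
}

# dense-grid trapezoid of an arbitrary function, independent of vif_integral
brute_integral <- function(f, t, n = 20001) {
  vapply(t, function(tt) {
    g <- seq(0, tt, length.out = n)
    y <- f(g)
    sum(diff(g) * (y[-1] + y[-length(y)]) / 2)
  }, numeric(1))
}
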