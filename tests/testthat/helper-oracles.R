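# Independent oracles, kept free of the code paths they check.

# Bisection on the mass-action polynomial f(x) = x^2 - (A+B+K)x + AB over
# [0, min(A, B)]: f(0) = AB >= 0 and f(min) = -min(A,B)*K <= 0, so the
# physical root is bracketed. Plain bisection, no closed form.
bisect_equilibrium <- function(A, B, K, iters = 200) {
  f <- function(x) x * x - (A + B + K) * x + A * B
  lo <- 0
  hi <- min(A, B)
  if (hi == 0) return(0)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# log-uniform draw helper for property tests
rloguni <- function(n, lo, hi) 10^stats::runif(n, log10(lo), log10(hi))

relerr <- function(x, ref) ifelse(ref == 0, abs(x), abs(x - ref) / abs(ref))
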