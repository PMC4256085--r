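# Independent brute-force oracles used to validate the package's
# closed forms and sampling schemes.

# Difference-of-geometrics pmf via a truncated double sum over the
# joint distribution of two independent geometric(p) waiting times.
gdiff_oracle <- function(t, p, t_cap = 5000L) {
  f <- function(k) p * (1 - p)^(k - 1)  # waiting time on 1, 2, ...
  vapply(t, function(tt) {
    t2 <- seq_len(t_cap)
    t1 <- t2 + tt
    ok <- t1 >= 1
    sum(f(t1[ok]) * f(t2[ok]))
  }, numeric(1))
}

# Exact expected green-pair count under the biased placement null on a
# small window, by exhaustive recursion over placement orders: from a
# partial lower configuration the next accepted site is j with
# probability a_j / sum(a_k) over still-red sites, a_j = q if the upper
# partner is green else 1 - q.
biased_pair_oracle <- function(window, g_u, g_l, q) {
  uppers <- utils::combn(window, g_u, simplify = FALSE)
  expect_one <- function(upper_set) {
    upper <- logical(window)
    upper[upper_set] <- TRUE
    rec <- function(lower) {
      if (sum(lower) == g_l) return(sum(upper & lower))
      red <- which(!lower)
      a <- ifelse(upper[red], q, 1 - q)
      probs <- a / sum(a)
      val <- 0
      for (j in seq_along(red)) {
        nl <- lower
        nl[red[j]] <- TRUE
        val <- val + probs[j] * rec(nl)
      }
      val
    }
    rec(logical(window))
  }
  mean(vapply(uppers, expect_one, numeric(1)))
}

# Exact expected pair count under the random null by exhaustive
# enumeration of all placements of both rows.
random_pair_oracle <- function(window, g_u, g_l) {
  ups <- utils::combn(window, g_u, simplify = FALSE)
  los <- utils::combn(window, g_l, simplify = FALSE)
  mean(vapply(ups, function(u) {
    mean(vapply(los, function(l) length(intersect(u, l)), numeric(1)))
  }, numeric(1)))
}

# Literal scan of the persistence rule: earliest frame starting a full
# run of `persistence` frames with green strictly above red.
call_transition_oracle <- function(red, green, persistence) {
  n <- length(red)
  for (t in seq_len(n)) {
    if (t + persistence - 1L > n) break
    if (all(green[t:(t + persistence - 1L)] > red[t:(t + persistence - 1L)])) {
      return(t - 1L)
    }
  }
  NA_integer_
}

# Closed-form deterministic front: largest licensed cell at frame t.
front_oracle <- function(t, z, L_c = 5, lam = 4 / 3, dt = 2.5) {
  step <- L_c * z / (lam * dt)
  z * sum(seq_len(ceiling((t + 1) / step) + 1L) * step <= t + 1e-9)
}
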