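# Shared fixture builders; everything is generated in code, no stored data.

make_peptide <- function(state = "WT", start = 1L, end = 10L)
  PeptideRecord(state, start, end)

# noiseless uptake model evaluated directly (independent of simulateUptake)
uptake_truth <- function(t, A0, A, k) A0 + A * (1 - exp(-k * t))

# matched peptide panels for two states with a planted uniform %D shift
make_state_panel <- function(state, n_peptides, shift = 0, noise = 1,
                             seed0 = 0) {
  lapply(seq_len(n_peptides), function(i) {
    simulateUptake(
      uptakeSimSpec(A0 = 10 + shift, amplitudes = 55, rates = 0.008,
                    noiseSd = noise, seed = seed0 + i),
      peptide = PeptideRecord(state, i * 12L, i * 12L + 9L))
  })
}

# brute-force mixture grid search oracle for envelope deconvolution:
# exhaustive over F_f (0.01 steps) and small grids on shapes, shared
# across timepoints
grid_oracle_Ff <- function(env, cf_grid, cu_grid, w_grid) {
  envs <- lapply(env@envelopes, function(e) {
    area <- sum(diff(e[, 1]) * (head(e[, 2], -1) + tail(e[, 2], -1)) / 2)
    cbind(e[, 1], e[, 2] / area)
  })
  ff_grid <- seq(0, 1, by = 0.01)
  best <- list(rss = Inf)
  for (cf in cf_grid) for (cu in cu_grid) for (w in w_grid) {
    if (cu <= cf) next
    total <- 0
    ffs <- numeric(length(envs))
    for (i in seq_along(envs)) {
      m <- envs[[i]][, 1]; y <- envs[[i]][, 2]
      gf <- dnorm(m, cf, w); gu <- dnorm(m, cu, w)
      rs <- vapply(ff_grid, function(ff)
        sum((ff * gf + (1 - ff) * gu - y)^2), 0)
      j <- which.min(rs)
      ffs[i] <- ff_grid[j]
      total <- total + rs[j]
    }
    if (total < best$rss) best <- list(rss = total, Ff = ffs)
  }
  best$Ff
}

# adjusted Rand index between two labelings (closed-form contingency sum)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sij <- sum(choose2(tab))
  si <- sum(choose2(rowSums(tab)))
  sj <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}
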