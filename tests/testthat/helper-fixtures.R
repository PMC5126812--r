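# Fixtures built in code: a toy value set and a cohort realising the packaged
# reference (marginal) response-level counts.

toy_value_set <- function() {
  value_set(
    data.frame(
      dimension = rep(c("MO", "SC", "UA", "PD", "AD"), each = 5),
      level = rep(1:5, 5),
      decrement = rep(c(0, 0.05, 0.10, 0.15, 0.20), 5)
    ),
    name = "toy"
  )
}

# Expands the packaged reference level counts into a patient table whose
# per-dimension marginals match the counts exactly (dimensions filled
# independently; only marginals are published).
reference_cohort <- function() {
  counts <- reference_level_counts()
  pieces <- lapply(c("OI", "FD", "XLH"), function(d) {
    sub <- counts[counts$disease == d, ]
    cols <- lapply(unique(sub$dimension), function(cc) {
      s <- sub[sub$dimension == cc, ]
      rep(s$level, s$count)
    })
    names(cols) <- unique(sub$dimension)
    n <- length(cols[[1]])
    data.frame(id = sprintf("%s-%03d", d, seq_len(n)), disease = d,
               cols, stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

# Independent Monte-Carlo estimate of the two-sided Fisher p-value:
# sample fixed-margin tables with r2dtable and compare point probabilities.
mc_fisher_oracle <- function(tab, B, seed) {
  logp <- function(x) {
    sum(lgamma(rowSums(x) + 1)) + sum(lgamma(colSums(x) + 1)) -
      lgamma(sum(x) + 1) - sum(lgamma(x + 1))
  }
  set.seed(seed)
  obs <- logp(tab)
  sims <- r2dtable(B, rowSums(tab), colSums(tab))
  mean(vapply(sims, logp, numeric(1)) <= obs + 1e-7 * abs(obs))
}

# Analytic mean of a normal truncated to [lo, hi] (oracle for the mixture).
truncnorm_mean_oracle <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}
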