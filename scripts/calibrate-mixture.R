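#!/usr/bin/env Rscript
# Derivation of the default utility-mixture constants in utility_mixture().
#
# The generator must reproduce two moments of the observed utility
# distribution that the economic simulation depends on:
#   (1) overall mean utility ~ 0.65 (the published group means are 0.648-0.656)
#   (2) mean utility of the lowest 15 of a 43-person sample ~ 0.339
#       (the lower-tertile mean implied by the published QALY results:
#        a 2.47-QALY base-case gain toward target 0.745 at 75% attainment)
# subject to a bimodal two-component truncated-normal shape on the
# value-set range [-0.285, 1].
#
# This script searches the five mixture constants by Nelder-Mead with common
# random numbers, then reports the realised moments for the chosen (rounded)
# defaults. Run from the repository root: Rscript scripts/calibrate-mixture.R

suppressPackageStartupMessages(library(rareboneqol))

floorv <- -0.285
qtn <- function(u, m, s) {
  qnorm(pnorm(floorv, m, s) + u * (pnorm(1, m, s) - pnorm(floorv, m, s)), m, s)
}
tmean <- function(m, s) {
  a <- (floorv - m) / s; b <- (1 - m) / s
  m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

set.seed(42)
R <- 3000
U <- matrix(runif(R * 43), R, 43)  # common random numbers across evaluations
K <- matrix(runif(R * 43), R, 43)

moments <- function(p) {
  w <- p[1]
  x <- ifelse(K < w, qtn(U, p[2], p[3]), qtn(U, p[4], p[5]))
  c(overall = w * tmean(p[2], p[3]) + (1 - w) * tmean(p[4], p[5]),
    low15 = mean(apply(x, 1, function(r) mean(sort(r)[1:15]))))
}
objective <- function(p) {
  if (p[1] <= 0.2 || p[1] >= 0.8 || p[3] <= 0.05 || p[5] <= 0.03) return(1e6)
  m <- moments(p)
  (m["overall"] - 0.654)^2 + (m["low15"] - 0.339)^2
}

fit <- optim(c(0.45, 0.43, 0.20, 0.85, 0.12), objective,
             control = list(maxit = 400))
cat("optimum:", round(fit$par, 4), "\n")

chosen <- c(0.46, 0.43, 0.24, 0.87, 0.105)  # rounded package defaults
cat("chosen :", chosen, "-> moments:", round(moments(chosen), 4), "\n")

# large-sample confirmation with the packaged generator
mix <- utility_mixture()
u <- gen_utilities(1e6, mix, seed = 1)
low15 <- vapply(1:2000, function(i) mean(sort(gen_utilities(43, mix, seed = i))[1:15]),
                numeric(1))
cat(sprintf("packaged defaults: overall mean %.4f (sd %.4f), low-15-of-43 mean %.4f\n",
            mean(u), sd(u), mean(low15)))
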