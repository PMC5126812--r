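test_that("contingency tables collapse the reference counts correctly", {
  coh <- reference_cohort()
  mob <- build_contingency(coh, "mo")
  expect_equal(unclass(mob)[, ], rbind(OI = c(22, 10, 11), FD = c(27, 8, 7), XLH = c(13, 6, 5)),
               ignore_attr = TRUE)
  sc <- build_contingency(coh, "self_care")
  expect_equal(unclass(sc)[, ], rbind(OI = c(36, 3, 4), FD = c(37, 4, 1), XLH = c(19, 1, 4)),
               ignore_attr = TRUE)
  # grand total equals cohort size for every dimension
  for (cc in c("mo", "sc", "ua", "pd", "ad")) {
    expect_equal(sum(build_contingency(coh, cc)), nrow(coh))
  }
  expect_error(build_contingency(coh, "sleep"), "unknown dimension")
})

test_that("a single-patient cohort yields one non-empty cell", {
  one <- data.frame(id = "OI-001", disease = "OI", mo = 3, sc = 1, ua = 1, pd = 1, ad = 1)
  tab <- build_contingency(one, "mo")
  expect_equal(sum(tab), 1)
  expect_equal(tab["OI", "moderate"], 1, ignore_attr = TRUE)
})

test_that("fisher_exact matches hand enumeration on 2x2 tables", {
  # [[1,0],[0,1]]: both fixed-margin tables have probability 1/2
  expect_equal(fisher_exact(rbind(c(1, 0), c(0, 1))), 1)
  # independent oracle: direct hypergeometric enumeration over the free cell
  hyper_oracle <- function(tab) {
    m <- rowSums(tab); k <- colSums(tab)
    xs <- max(0, k[1] - m[2]):min(m[1], k[1])
    probs <- dhyper(xs, m[1], m[2], k[1])
    obs <- dhyper(tab[1, 1], m[1], m[2], k[1])
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  set.seed(19)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 6) + 1, 2, 2)
    expect_equal(fisher_exact(tab), hyper_oracle(tab), tolerance = 1e-10)
  }
})

test_that("fisher_exact agrees with a seeded fixed-margin Monte-Carlo oracle on 3x3 tables", {
  tabs <- list(
    rbind(c(22, 10, 11), c(27, 8, 7), c(13, 6, 5)),
    rbind(c(5, 3, 2), c(1, 7, 4), c(3, 3, 6)),
    rbind(c(10, 1, 1), c(2, 9, 2), c(1, 2, 8))
  )
  for (tab in tabs) {
    p_exact <- fisher_exact(tab)
    p_mc <- mc_fisher_oracle(tab, B = 4e5, seed = 77)
    expect_equal(p_exact, p_mc, tolerance = 2e-3 / max(p_exact, 0.05))
  }
  # the package's own Monte-Carlo fallback estimates the same quantity
  tab <- tabs[[1]]
  expect_equal(fisher_exact(tab, method = "monte_carlo", B = 2e5, seed = 3),
               fisher_exact(tab), tolerance = 5e-3)
})

test_that("fisher_exact is invariant under row and column permutations", {
  tab <- rbind(c(5, 3, 2), c(1, 7, 4), c(3, 3, 6))
  p <- fisher_exact(tab)
  set.seed(2)
  for (i in 1:5) {
    perm <- tab[sample(3), sample(3)]
    expect_equal(fisher_exact(perm), p, tolerance = 1e-9)
  }
  expect_error(fisher_exact(rbind(c(0, 0), c(1, 2))), "margins")
  expect_error(fisher_exact(rbind(c(0.5, 1), c(1, 2))), "integer")
})

test_that("one-way ANOVA reproduces the classical F statistic", {
  res <- anova_oneway(list(c(0, 2), c(4, 6)))
  expect_equal(res$statistic, 8)  # SSB 16 on 1 df over SSW 4 on 2 df
  expect_equal(unname(res$df), c(1, 2))
  # equal group means => F = 0
  expect_equal(anova_oneway(list(c(-1, 1), c(-5, 5)))$statistic, 0)
  expect_error(anova_oneway(list(c(1, 1), c(2, 2))), "undefined")
  expect_error(anova_oneway(list(1, 2)), "total n")
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(55)
  ps <- replicate(300, {
    anova_oneway(list(rnorm(15), rnorm(15), rnorm(15)))$p.value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("linear fits recover exact and independent relationships", {
  x <- seq(20, 70, length.out = 30)
  fit <- suppressWarnings(fit_linear(x, -0.005 * x + 0.9))  # perfect fit warns
  expect_equal(fit$slope, -0.005)
  expect_equal(fit$intercept, 0.9)
  expect_equal(fit$r, -1)
  set.seed(12)
  fit0 <- fit_linear(rnorm(10000), rnorm(10000))
  expect_lt(abs(fit0$r), 0.05)
  expect_error(fit_linear(rep(1, 10), rnorm(10)), "constant")
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})

test_that("group summaries report n, mean, sample SD and range per disease", {
  coh <- data.frame(
    id = as.character(1:5), disease = c("OI", "OI", "FD", "FD", "XLH"),
    utility = c(0, 1, 0.5, 0.7, 0.9), vas = c(50, 70, 60, 80, 90),
    age = c(30, 40, 50, 60, 70)
  )
  s <- summarize_cohort(coh, "utility")
  oi <- s[s$disease == "OI", ]
  expect_equal(oi$mean, 0.5)
  expect_equal(oi$sd, sqrt(0.5), tolerance = 1e-12)  # {0,1}: sample SD 0.7071
  xlh <- s[s$disease == "XLH", ]
  expect_equal(xlh$sd, 0)
  expect_false(xlh$sd_defined)
  expect_error(summarize_cohort(coh[coh$disease != "XLH", ], "utility"), "XLH")
})

test_that("tertile splits order by utility, break ties by id, and load the remainder low", {
  u43 <- data.frame(id = sprintf("p%02d", 1:43), utility = seq(0.1, 0.9, length.out = 43))
  s <- split_tertiles(u43)
  expect_equal(unname(attr(s, "sizes")), c(15, 14, 14))
  expect_equal(nrow(s$lower), 15)

  u6 <- data.frame(id = letters[1:6], utility = c(0.6, 0.1, 0.9, 0.3, 0.8, 0.2))
  s6 <- split_tertiles(u6)
  expect_equal(unname(attr(s6, "sizes")), c(2, 2, 2))
  expect_equal(s6$lower$id, c("b", "f"))
  expect_equal(s6$upper$id, c("e", "c"))

  ties <- data.frame(id = sprintf("p%02d", 1:43), utility = rep(0.5, 43))
  st <- split_tertiles(ties)
  expect_equal(st$lower$id, sprintf("p%02d", 1:15))  # stable id order under ties

  expect_error(split_tertiles(u6[1:2, ]), "at least 3")
})

test_that("tertile splits partition the input with ordered utilities", {
  set.seed(99)
  for (n in c(5, 17, 43, 100)) {
    d <- data.frame(id = sprintf("x%03d", 1:n), utility = runif(n))
    s <- split_tertiles(d)
    expect_setequal(c(s$lower$id, s$middle$id, s$upper$id), d$id)
    expect_lte(max(s$lower$utility), min(s$middle$utility))
    expect_lte(max(s$middle$utility), min(s$upper$utility))
    expect_lte(diff(range(attr(s, "sizes"))), 1)
  }
})
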