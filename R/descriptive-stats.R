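# Descriptive and inferential statistics for the three-disease comparison:
# collapsed contingency tables with Fisher's exact r x c test, one-way ANOVA
# on group means, Pearson correlation / simple linear regression, per-group
# summaries, and the tertile split feeding the economic simulation.

#' Build a disease-by-category contingency table
#'
#' Cross-tabulates the three disease groups against the three collapsed
#' problem categories ([collapse_level()]) of one EQ-5D-5L dimension.
#'
#' @param cohort a cohort data frame (columns `disease` and `mo,sc,ua,pd,ad`).
#' @param dimension dimension code (`mo,sc,ua,pd,ad`) or long name
#'   (`mobility`, ..., `anxiety_depression`).
#' @return Integer matrix (class `table`), diseases in rows, categories in
#'   columns; the grand total equals the cohort size.
#' @export
build_contingency <- function(cohort, dimension) {
  stopifnot(nrow(cohort) > 0)
  code <- if (dimension %in% names(EQ5D_DIMS)) {
    dimension
  } else if (dimension %in% EQ5D_DIMS) {
    names(EQ5D_DIMS)[match(dimension, EQ5D_DIMS)]
  } else {
    stop("unknown dimension: '", dimension, "'")
  }
  disease <- factor(cohort$disease, levels = DISEASES)
  if (anyNA(disease)) stop("unknown disease label(s) in cohort")
  table(disease = disease, category = collapse_level(cohort[[code]]))
}

# log point-probability of a table under the fixed-margins hypergeometric null
.log_table_prob <- function(x) {
  sum(lgamma(rowSums(x) + 1)) + sum(lgamma(colSums(x) + 1)) -
    lgamma(sum(x) + 1) - sum(lgamma(x + 1))
}

#' Fisher's exact test for r x c tables
#'
#' Two-sided exact p-value under the fixed-margins hypergeometric null: the
#' total probability of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (ties within a
#' 1e-7 relative tolerance). `method = "exact"` uses the network-algorithm
#' enumeration of [stats::fisher.test()]; `method = "monte_carlo"` estimates
#' the same quantity from `B` seeded draws of fixed-margin tables
#' ([stats::r2dtable()]), for tables too large to enumerate.
#'
#' @param table matrix of non-negative counts with positive margins.
#' @param method `"exact"` (default) or `"monte_carlo"`.
#' @param B number of Monte-Carlo draws.
#' @param seed seed for the Monte-Carlo sampler.
#' @return The p-value, in `(0, 1]`.
#' @examples
#' fisher_exact(rbind(c(1, 0), c(0, 1)))  # 1: both tables equally likely
#' @export
fisher_exact <- function(table, method = c("exact", "monte_carlo"),
                         B = 1e5, seed = 1L) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("contingency table must contain non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all row and column margins must be positive")
  }
  if (method == "exact") {
    p <- tryCatch(
      stats::fisher.test(table, workspace = 2e7)$p.value,
      error = function(e) {
        stop("exact enumeration failed for this table (", conditionMessage(e),
             "); rerun with method = \"monte_carlo\"", call. = FALSE)
      }
    )
    return(min(p, 1))
  }
  set.seed(seed)
  lp_obs <- .log_table_prob(table)
  sims <- stats::r2dtable(B, rowSums(table), colSums(table))
  lp <- vapply(sims, .log_table_prob, numeric(1))
  mean(lp <= lp_obs + 1e-7 * abs(lp_obs))
}

#' One-way analysis of variance
#'
#' Classical one-way ANOVA F test of equal group means:
#' `F = (SSB / df_b) / (SSW / df_w)` with its upper-tail p-value.
#'
#' @param groups list of two or more numeric vectors of scores.
#' @return List with `statistic` (F), `p.value`, and degrees of freedom
#'   `df` (between, within).
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  n <- lengths(groups)
  if (any(n < 1)) stop("every group needs at least one observation")
  if (sum(n) <= length(groups)) stop("total n must exceed the number of groups")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n))
  ssw <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  if (ssw == 0) stop("zero within-group variance everywhere; F is undefined")
  a <- stats::anova(stats::lm(y ~ g))
  list(statistic = a[["F value"]][1], p.value = a[["Pr(>F)"]][1],
       df = c(between = a$Df[1], within = a$Df[2]))
}

#' Simple linear regression and Pearson correlation
#'
#' Least-squares fit of `y` on `x` with the Pearson correlation coefficient
#' and the two-sided t-test p-value on the slope.
#'
#' @param x covariate values (not constant).
#' @param y response values, same length, `n >= 3`.
#' @return List with `slope`, `intercept`, `r`, `p.value`, `n`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("constant covariate: slope undefined")
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["x", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       r = stats::cor(x, y),
       p.value = unname(cf["x", "Pr(>|t|)"]),
       n = length(x))
}

#' Per-disease summaries of utility, VAS or age
#'
#' @param cohort a cohort data frame.
#' @param variable one of `"utility"`, `"vas"`, `"age"`.
#' @return Data frame with one row per disease: `disease, n, mean, sd, min,
#'   max`. For a single-observation group the SD is reported as 0 and flagged
#'   in the `sd_defined` column.
#' @export
summarize_cohort <- function(cohort, variable = c("utility", "vas", "age")) {
  variable <- match.arg(variable)
  v <- cohort[[variable]]
  present <- unique(cohort$disease)
  missing_grp <- setdiff(DISEASES, present)
  if (length(missing_grp)) {
    stop("empty disease group(s): ", paste(missing_grp, collapse = ", "))
  }
  out <- do.call(rbind, lapply(DISEASES, function(d) {
    x <- v[cohort$disease == d]
    if (all(is.na(x))) stop("no '", variable, "' values for group ", d)
    x <- x[!is.na(x)]
    data.frame(disease = d, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else 0,
               min = min(x), max = max(x),
               sd_defined = length(x) > 1, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Split patients into utility tertiles
#'
#' Patients are sorted by ascending utility (ties broken by id, a stable
#' rule) and partitioned into three contiguous blocks. When the size is not
#' divisible by 3, the remainder is allocated from the lowest tertile upward,
#' so 43 patients split as 15 / 14 / 14 - the lower tertile is the treatment
#' group of the economic simulation.
#'
#' @param patients cohort data frame (or subset) with `utility` and `id`.
#' @return List of class `tertile_split` with data frames `lower`, `middle`,
#'   `upper`.
#' @export
split_tertiles <- function(patients) {
  n <- nrow(patients)
  if (is.null(n) || n < 3) stop("need at least 3 patients to form tertiles")
  ord <- order(patients$utility, patients$id)
  sorted <- patients[ord, , drop = FALSE]
  base <- n %/% 3
  rem <- n %% 3
  sizes <- c(lower = base + (rem >= 1), middle = base + (rem >= 2), upper = base)
  idx <- rep(names(sizes), sizes)
  out <- lapply(setNames(nm = names(sizes)), function(k) {
    block <- sorted[idx == k, , drop = FALSE]
    rownames(block) <- NULL
    block
  })
  structure(out, sizes = sizes, class = "tertile_split")
}

#' @export
print.tertile_split <- function(x, ...) {
  s <- attr(x, "sizes")
  cat(sprintf("Utility tertile split: lower %d / middle %d / upper %d\n",
              s["lower"], s["middle"], s["upper"]))
  for (k in names(x)) {
    cat(sprintf("  %s: mean utility %.3f\n", k, mean(x[[k]]$utility)))
  }
  invisible(x)
}
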