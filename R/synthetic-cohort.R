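# Seeded synthetic-cohort generator. Margins (ages, response levels, VAS,
# utilities) are calibrated to the published group-level summaries of the
# 109-person OI/FD/XLH cohort; within-person dependence for OI (age vs
# usual-activity level, VAS and utility) is induced through a Gaussian copula,
# since only pairwise Pearson correlations are reported.

# Deterministic child-seed derivation: one master seed, one fixed small
# integer per random stream, so adding a stream never perturbs the others.
# Arithmetic stays exact in doubles (< 2^53) and the result fits set.seed().
.rbq_child_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  ((abs(master) %% 2147483647) * 48271 + stream * 65537) %% 2147483646 + 1
}

# Inverse-CDF truncated normal: maps uniforms on (0,1) to N(mean, sd)
# restricted to [lo, hi].
.qtruncnorm <- function(p, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

.truncnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / z
  v <- sd^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, var = v)
}

#' Two-component truncated-normal utility mixture
#'
#' Parameters of the bimodal health-utility distribution used by the
#' generator. The default calibration reproduces the two moments the
#' downstream economic simulation depends on: an overall mean utility of
#' about 0.65 and a mean of about 0.34 over the lowest 15 of a 43-person
#' sample (the lower tertile fed into the treatment simulation). The scripts
#' directory of the source package contains the calibration script.
#'
#' @param weights mixing weights (sum to 1); first component is the
#'   low-utility mode.
#' @param means,sds component means and standard deviations on the utility
#'   scale.
#' @param bounds truncation interval, `[value-set floor, 1]`.
#' @return List of class `utility_mixture`.
#' @export
utility_mixture <- function(weights = c(0.46, 0.54),
                            means = c(0.43, 0.87),
                            sds = c(0.24, 0.105),
                            bounds = c(-0.285, 1)) {
  stopifnot(length(weights) == length(means), length(means) == length(sds),
            length(bounds) == 2, bounds[1] < bounds[2])
  if (any(sds <= 0)) stop("mixture component SDs must be positive")
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (any(weights < 0)) stop("mixture weights must be non-negative")
  structure(list(weights = weights, means = means, sds = sds, bounds = bounds),
            class = "utility_mixture")
}

# Mixture CDF and (grid-interpolated) quantile function; the CDF is strictly
# increasing on the truncation interval, so linear inversion on a fine grid
# is accurate and monotone.
.pmixture <- function(q, mix) {
  lo <- mix$bounds[1]; hi <- mix$bounds[2]
  comp <- vapply(seq_along(mix$weights), function(i) {
    plo <- stats::pnorm(lo, mix$means[i], mix$sds[i])
    phi <- stats::pnorm(hi, mix$means[i], mix$sds[i])
    (stats::pnorm(pmin(pmax(q, lo), hi), mix$means[i], mix$sds[i]) - plo) / (phi - plo)
  }, numeric(length(q)))
  as.numeric(comp %*% mix$weights)
}

.qmixture <- function(p, mix, n_grid = 4096) {
  grid <- seq(mix$bounds[1], mix$bounds[2], length.out = n_grid)
  cdf <- .pmixture(grid, mix)
  stats::approx(cdf, grid, xout = p, ties = "ordered", rule = 2)$y
}

.mixture_moments <- function(mix) {
  mm <- vapply(seq_along(mix$weights), function(i) {
    .truncnorm_moments(mix$means[i], mix$sds[i], mix$bounds[1], mix$bounds[2])
  }, numeric(2))
  m <- sum(mix$weights * mm["mean", ])
  ex2 <- sum(mix$weights * (mm["var", ] + mm["mean", ]^2))
  c(mean = m, var = ex2 - m^2)
}

#' Draw utilities from the calibrated mixture
#'
#' @param n number of draws.
#' @param mixture a [utility_mixture()].
#' @param seed integer seed; draws are deterministic given the seed.
#' @return Numeric vector of `n` utilities in `mixture$bounds`.
#' @examples
#' u <- gen_utilities(43, seed = 1)
#' range(u)
#' @export
gen_utilities <- function(n, mixture = utility_mixture(), seed) {
  stopifnot(n >= 1, inherits(mixture, "utility_mixture"))
  if (any(mixture$sds <= 0)) stop("mixture component SDs must be positive")
  set.seed(seed)
  comp <- sample.int(length(mixture$weights), n, replace = TRUE, prob = mixture$weights)
  u <- stats::runif(n)
  .qtruncnorm(u, mixture$means[comp], mixture$sds[comp],
              mixture$bounds[1], mixture$bounds[2])
}

#' Reference response-level counts by disease
#'
#' The published per-dimension distribution of EQ-5D-5L response levels in
#' the 109-person cohort (43 OI, 42 FD, 24 XLH), packaged as
#' `extdata/table2_counts.csv`. These counts, normalised, are the generator's
#' default multinomial level probabilities.
#'
#' @return Data frame with columns `dimension` (codes `mo`-`ad`), `disease`,
#'   `level`, `count`.
#' @export
reference_level_counts <- function() {
  utils::read.csv(
    system.file("extdata", "table2_counts.csv", package = "rareboneqol", mustWork = TRUE),
    stringsAsFactors = FALSE
  )
}

# counts -> list(disease -> 5x5 matrix [dimension, level] of probabilities)
.level_probs_from_counts <- function(counts) {
  lapply(setNames(nm = DISEASES), function(d) {
    sub <- counts[counts$disease == d, ]
    mat <- matrix(0, 5, 5, dimnames = list(names(EQ5D_DIMS), 1:5))
    mat[cbind(sub$dimension, sub$level)] <- sub$count
    sweep(mat, 1, rowSums(mat), "/")
  })
}

#' Specify a synthetic cohort
#'
#' Collects every constant the generator needs. Defaults reproduce the study
#' cohort: 43 OI / 42 FD / 24 XLH participants; ages truncated normal at the
#' published mean/SD/range per disease; sex frequencies per disease; response
#' levels multinomial with the packaged reference frequencies; VAS truncated
#' normal on `[0, 100]`; utilities from the calibrated bimodal mixture. For
#' OI, age is coupled to usual-activity level (Pearson r = 0.39), VAS
#' (r = -0.42) and utility (via a -0.005 utility/year regression slope)
#' through a Gaussian copula.
#'
#' @param n_by_disease named counts per disease (each at least 3 so tertiles
#'   are nonempty).
#' @param age_params data frame `disease, mean, sd, min, max` (years).
#' @param sex_p_female named probability of female per disease.
#' @param level_probs list per disease of a 5 x 5 matrix (dimension x level)
#'   of multinomial probabilities, each row summing to 1.
#' @param vas_params data frame `disease, mean, sd`; VAS is truncated to
#'   `[0, 100]` and rounded to integers.
#' @param mixture a [utility_mixture()].
#' @param couplings named numeric: `age_ua` and `age_vas` (target Pearson
#'   correlations for OI) and `age_utility_slope` (target utility-on-age
#'   regression slope for OI, utility per year).
#' @param utility_mode `"mixture"` draws utilities directly from the mixture
#'   (the distribution the economic simulation assumes); `"valueset"` scores
#'   the generated responses with `value_set` instead. The two routes are
#'   deliberately independent: no joint distribution of responses and
#'   utilities is published.
#' @param value_set [value_set()] used when `utility_mode = "valueset"`.
#' @param seed master seed; all streams derive child seeds from it.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_by_disease = c(OI = 43, FD = 42, XLH = 24),
                        age_params = data.frame(
                          disease = DISEASES,
                          mean = c(40.4, 44.3, 46.3),
                          sd = c(14.4, 14.5, 16.3),
                          min = c(18, 18, 22),
                          max = c(70, 75, 78)
                        ),
                        sex_p_female = c(OI = 0.77, FD = 0.69, XLH = 0.79),
                        level_probs = NULL,
                        vas_params = data.frame(
                          disease = DISEASES,
                          mean = c(69.4, 64.1, 60.8),
                          sd = c(21.4, 23.0, 26.9)
                        ),
                        mixture = utility_mixture(),
                        couplings = c(age_ua = 0.39, age_vas = -0.42,
                                      age_utility_slope = -0.005),
                        utility_mode = c("mixture", "valueset"),
                        value_set = NULL,
                        seed = 1L) {
  utility_mode <- match.arg(utility_mode)
  if (is.null(level_probs)) level_probs <- .level_probs_from_counts(reference_level_counts())
  stopifnot(all(DISEASES %in% names(n_by_disease)),
            all(DISEASES %in% names(level_probs)),
            all(DISEASES %in% age_params$disease),
            all(DISEASES %in% vas_params$disease),
            all(DISEASES %in% names(sex_p_female)))
  if (any(n_by_disease < 3)) stop("need at least 3 patients per disease (nonempty tertiles)")
  for (d in DISEASES) {
    rs <- rowSums(level_probs[[d]])
    if (any(abs(rs - 1) > 1e-9)) {
      stop("level probabilities for ", d, " must sum to 1 per dimension")
    }
    if (any(level_probs[[d]] < 0)) stop("level probabilities must be non-negative")
  }
  if (utility_mode == "valueset" && is.null(value_set)) value_set <- value_set_england()
  structure(list(
    n_by_disease = n_by_disease, age_params = age_params,
    sex_p_female = sex_p_female, level_probs = level_probs,
    vas_params = vas_params, mixture = mixture, couplings = couplings,
    utility_mode = utility_mode, value_set = value_set, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Draw EQ-5D-5L responses from per-dimension multinomials
#'
#' Dimensions are drawn independently; empirical level frequencies converge
#' to `level_probs` as `n` grows.
#'
#' @param n number of respondents.
#' @param level_probs 5 x 5 matrix (dimension x level), rows summing to 1.
#' @param seed integer seed.
#' @return Data frame with `n` rows and columns `mo,sc,ua,pd,ad`.
#' @export
gen_responses <- function(n, level_probs, seed) {
  stopifnot(n >= 1, is.matrix(level_probs), all(dim(level_probs) == c(5, 5)))
  if (any(abs(rowSums(level_probs) - 1) > 1e-9)) {
    stop("each dimension's level probabilities must sum to 1")
  }
  set.seed(seed)
  out <- lapply(seq_len(5), function(i) {
    sample.int(5, n, replace = TRUE, prob = level_probs[i, ])
  })
  names(out) <- names(EQ5D_DIMS)
  as.data.frame(out)
}

# inverse-CDF multinomial draw from uniforms (used for copula-coupled margins)
.qmultinom <- function(p, probs) {
  findInterval(p, cumsum(probs), left.open = TRUE) + 1L
}

# latent correlation matrix for (age, ua, vas, utility); star structure
# around age, feasible iff the squared correlations with age sum to < 1
.latent_sigma <- function(r_ua, r_vas, r_util) {
  r <- c(r_ua, r_vas, r_util)
  if (any(abs(r) >= 1) || sum(r^2) >= 1) {
    stop("infeasible coupling: requested correlations with age are too strong")
  }
  s <- diag(4)
  s[1, 2:4] <- r
  s[2:4, 1] <- r
  s
}

#' Generate a synthetic cohort
#'
#' Assembles one patient table per [cohort_spec()]: demographics, EQ-5D-5L
#' responses, VAS and utility, with the OI age couplings induced through a
#' Gaussian copula. Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return Data frame of class `cohort` with columns
#'   `id,disease,age,sex,mo,sc,ua,pd,ad,vas,utility`.
#' @examples
#' coh <- gen_cohort(cohort_spec(seed = 1))
#' table(coh$disease)
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  mixm <- .mixture_moments(spec$mixture)
  out <- lapply(seq_along(DISEASES), function(di) {
    d <- DISEASES[di]
    n <- spec$n_by_disease[[d]]
    ap <- spec$age_params[spec$age_params$disease == d, ]
    vp <- spec$vas_params[spec$vas_params$disease == d, ]
    lp <- spec$level_probs[[d]]

    if (d == "OI") {
      # convert the target utility-on-age slope into a Pearson correlation
      # using the configured marginal SDs (slope = r * sd_u / sd_age)
      agem <- .truncnorm_moments(ap$mean, ap$sd, ap$min, ap$max)
      r_util <- spec$couplings[["age_utility_slope"]] *
        sqrt(agem["var"]) / sqrt(mixm["var"])
      sigma <- .latent_sigma(spec$couplings[["age_ua"]],
                             spec$couplings[["age_vas"]], unname(r_util))
    } else {
      sigma <- diag(4)
    }

    set.seed(.rbq_child_seed(spec$seed, 10L * di + 1L))  # latent stream
    z <- matrix(stats::rnorm(n * 4), n, 4) %*% chol(sigma)
    p <- stats::pnorm(z)
    age <- .qtruncnorm(p[, 1], ap$mean, ap$sd, ap$min, ap$max)
    ua <- .qmultinom(p[, 2], lp["ua", ])
    vas <- round(.qtruncnorm(p[, 3], vp$mean, vp$sd, 0, 100))
    utility <- .qmixture(p[, 4], spec$mixture)

    set.seed(.rbq_child_seed(spec$seed, 10L * di + 2L))  # response stream
    resp <- lapply(c("mo", "sc", "pd", "ad"), function(cc) {
      sample.int(5, n, replace = TRUE, prob = lp[cc, ])
    })
    names(resp) <- c("mo", "sc", "pd", "ad")

    set.seed(.rbq_child_seed(spec$seed, 10L * di + 3L))  # sex stream
    sex <- ifelse(stats::rbinom(n, 1, spec$sex_p_female[[d]]) == 1, "F", "M")

    data.frame(
      id = sprintf("%s-%03d", d, seq_len(n)), disease = d,
      age = age, sex = sex,
      mo = resp$mo, sc = resp$sc, ua = ua, pd = resp$pd, ad = resp$ad,
      vas = as.integer(vas), utility = utility,
      stringsAsFactors = FALSE
    )
  })
  coh <- do.call(rbind, out)
  rownames(coh) <- NULL
  if (spec$utility_mode == "valueset") {
    coh$utility <- apply_value_set(coh, spec$value_set)
  }
  class(coh) <- c("cohort", "data.frame")
  coh
}
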