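#' Construct an EQ-5D-5L value set
#'
#' A value set maps each (dimension, level) pair to a non-negative utility
#' decrement; the utility of a health state is 1 minus the sum of the five
#' decrements its levels select. Level 1 ("no problems") carries decrement 0
#' in every dimension, so the full-health state `11111` scores exactly 1.
#'
#' @param decrements data frame with columns `dimension` (codes `MO`, `SC`,
#'   `UA`, `PD`, `AD`, case-insensitive), `level` (1-5) and `decrement`
#'   (non-negative decimal), or a 5 x 5 numeric matrix with dimensions in rows
#'   (instrument order) and levels in columns.
#' @param name identifier for the value set.
#' @return Object of class `value_set`: a list with the decrement matrix
#'   (`$decrements`, rows `mo`-`ad`, columns levels 1-5), `$name`, and the
#'   scale `$floor` (utility of state `55555`, i.e. `1 - sum` of the level-5
#'   decrements; negative values denote states worse than dead).
#' @examples
#' vs <- value_set_england()
#' vs$floor
#' @export
value_set <- function(decrements, name = "value_set") {
  codes <- names(EQ5D_DIMS)
  if (is.data.frame(decrements)) {
    need <- c("dimension", "level", "decrement")
    if (!all(need %in% names(decrements))) {
      stop("value-set table must have columns: ", paste(need, collapse = ", "))
    }
    dim_code <- tolower(as.character(decrements$dimension))
    bad <- setdiff(unique(dim_code), codes)
    if (length(bad)) stop("unknown dimension code(s) in value set: ", paste(bad, collapse = ", "))
    mat <- matrix(NA_real_, 5, 5, dimnames = list(codes, 1:5))
    mat[cbind(dim_code, as.character(decrements$level))] <- decrements$decrement
  } else if (is.matrix(decrements) && all(dim(decrements) == c(5, 5))) {
    mat <- decrements
    dimnames(mat) <- list(codes, 1:5)
  } else {
    stop("decrements must be a data frame or a 5 x 5 matrix")
  }
  if (anyNA(mat)) {
    miss <- which(is.na(mat), arr.ind = TRUE)
    stop("value set is missing (dimension, level) entries: ",
         paste(sprintf("(%s, %d)", codes[miss[, 1]], miss[, 2]), collapse = ", "))
  }
  if (any(mat < 0)) stop("value-set decrements must be non-negative")
  if (any(abs(mat[, 1]) > 1e-12)) stop("level-1 decrements must be 0 (full-health anchor)")
  if (any(t(apply(mat, 1, diff)) < -1e-12)) {
    stop("decrements must be monotone non-decreasing in level within each dimension")
  }
  floor <- 1 - sum(mat[, 5])
  if (floor < -1) stop("value-set floor below -1; decrements implausibly large")
  structure(list(name = name, decrements = mat, floor = floor), class = "value_set")
}

#' @export
print.value_set <- function(x, ...) {
  cat("EQ-5D-5L value set:", x$name, "\n")
  cat(sprintf("  utility range [%.3f, 1.000]\n", x$floor))
  print(round(x$decrements, 3))
  invisible(x)
}

#' Read a value set from CSV
#'
#' Expects the header `dimension,level,decrement` with dimension codes
#' `MO,SC,UA,PD,AD` and levels 1-5.
#'
#' @param path CSV file path.
#' @param name identifier; defaults to the file name.
#' @return A [value_set()].
#' @export
read_value_set <- function(path, name = sub("\\.csv$", "", basename(path))) {
  value_set(utils::read.csv(path, stringsAsFactors = FALSE), name = name)
}

#' The England EQ-5D-5L value set
#'
#' Preference weights for England, packaged as `extdata/value_set_england.csv`.
#' Utilities range from the floor of -0.285 (state `55555`, worse than dead)
#' to 1 (full health).
#'
#' @return A [value_set()].
#' @export
value_set_england <- function() {
  read_value_set(
    system.file("extdata", "value_set_england.csv", package = "rareboneqol", mustWork = TRUE),
    name = "England"
  )
}

#' Score health states with a value set
#'
#' Converts EQ-5D-5L health states into health utility scores: the utility of
#' a state is `1 - sum` of the decrements selected by its five dimension
#' levels. Utilities are returned at full precision; round only for display.
#'
#' @param states data frame with integer columns `mo,sc,ua,pd,ad` (levels
#'   1-5); further columns (e.g. `vas`) are ignored.
#' @param vs a [value_set()].
#' @return Numeric vector of utilities, one per row, each in `[vs$floor, 1]`.
#' @examples
#' vs <- value_set_england()
#' apply_value_set(data.frame(mo = 1, sc = 1, ua = 1, pd = 1, ad = 1), vs)  # 1
#' @export
apply_value_set <- function(states, vs) {
  stopifnot(inherits(vs, "value_set"))
  codes <- names(EQ5D_DIMS)
  missing_cols <- setdiff(codes, names(states))
  if (length(missing_cols)) {
    stop("health states are missing dimension column(s): ",
         paste(EQ5D_DIMS[missing_cols], collapse = ", "))
  }
  for (cc in codes) {
    lev <- states[[cc]]
    if (anyNA(lev)) {
      stop("missing level in dimension '", EQ5D_DIMS[[cc]], "' (row ",
           paste(which(is.na(lev)), collapse = ", "), ")")
    }
    if (any(lev != as.integer(lev)) || any(lev < 1L | lev > 5L)) {
      stop("dimension '", EQ5D_DIMS[[cc]], "' has level(s) outside 1-5 (row ",
           paste(which(lev != as.integer(lev) | lev < 1 | lev > 5), collapse = ", "), ")")
    }
  }
  dec <- vs$decrements
  total <- Reduce(`+`, lapply(seq_along(codes), function(i) {
    dec[i, states[[codes[i]]]]
  }))
  unname(1 - total)
}

#' Enumerate all EQ-5D-5L health states
#'
#' The instrument defines five dimensions at five levels each, hence
#' 5^5 = 3125 distinct health states.
#'
#' @return Data frame with 3125 rows and columns `mo,sc,ua,pd,ad`.
#' @export
enumerate_states <- function() {
  g <- expand.grid(ad = 1:5, pd = 1:5, ua = 1:5, sc = 1:5, mo = 1:5,
                   KEEP.OUT.ATTRS = FALSE)
  g[, names(EQ5D_DIMS)]
}

#' Collapse response levels into three problem categories
#'
#' Levels 1-2 are "no and slight problems", level 3 "moderate problems" and
#' levels 4-5 "severe and extreme problems" - the 3-category grouping used
#' for between-disease contingency tables.
#'
#' @param level integer vector of levels in 1-5.
#' @return Factor with levels `no_slight`, `moderate`, `severe_extreme`.
#' @examples
#' collapse_level(c(1, 2, 3, 4, 5))
#' @export
collapse_level <- function(level) {
  if (anyNA(level) || any(level != as.integer(level)) || any(level < 1 | level > 5)) {
    stop("levels must be integers in 1-5")
  }
  factor(
    PROBLEM_CATEGORIES[findInterval(level, c(1, 3, 4))],
    levels = PROBLEM_CATEGORIES
  )
}
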