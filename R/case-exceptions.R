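#' Case-exception threshold (L) specification
#'
#' A per-matrix threshold on the number of non-active (0) cases a gene's row
#' may contain while the gene still counts as active for that matrix. The
#' threshold is given either as an absolute case count or as a percentage of
#' the matrix's cases, resolved against the actual case count with
#' [kp_resolve_l()].
#'
#' @param x A single non-negative number (absolute count), a string such as
#'   `"25%"` (percentage of cases), a plain numeric string such as `"39"`
#'   (absolute count), or an existing `kp_l` object (returned unchanged).
#' @return An object of class `kp_l` with fields `mode` (`"absolute"` or
#'   `"percent"`) and `value`.
#' @examples
#' kp_l(5)        # at most 5 non-active cases
#' kp_l("25%")    # at most 25% of the cases non-active
#' @export
kp_l <- function(x) {
  if (inherits(x, "kp_l")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- trimws(x)
    if (grepl("%$", x)) {
      value <- suppressWarnings(as.numeric(sub("%$", "", x)))
      if (is.na(value)) stop("invalid percentage: '", x, "'", call. = FALSE)
      return(kp_l_percent(value))
    }
    value <- suppressWarnings(as.numeric(x))
    if (is.na(value)) stop("invalid case-exception value: '", x, "'", call. = FALSE)
    x <- value
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("case-exception value must be a single number or a percentage string", call. = FALSE)
  }
  if (x < 0 || x != floor(x)) {
    stop("absolute case-exception value must be a non-negative integer", call. = FALSE)
  }
  structure(list(mode = "absolute", value = as.integer(x)), class = "kp_l")
}

kp_l_percent <- function(value) {
  if (value < 0 || value > 100) {
    stop("percentage case-exception value must lie in [0, 100]", call. = FALSE)
  }
  structure(list(mode = "percent", value = value), class = "kp_l")
}

#' @export
format.kp_l <- function(x, ...) {
  if (x$mode == "percent") paste0(x$value, "%") else as.character(x$value)
}

#' @export
print.kp_l <- function(x, ...) {
  cat("<case exceptions: ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Resolve a case-exception specification to a case count
#'
#' Percent thresholds resolve to the smallest integer at least as large as the
#' exact fraction of cases (ceiling); e.g. 25% of 155 cases resolves to 39 and
#' 25% of 291 cases to 73. Absolute thresholds pass through unchanged, clamped
#' to `n_cases` with a warning when larger.
#'
#' @param l A [kp_l()] specification (or something coercible by `kp_l()`).
#' @param n_cases Number of cases in the matrix (>= 1).
#' @return A single non-negative integer L with `0 <= L <= n_cases`.
#' @examples
#' kp_resolve_l(kp_l("25%"), 155)  # 39
#' kp_resolve_l(kp_l("25%"), 291)  # 73
#' @export
kp_resolve_l <- function(l, n_cases) {
  l <- kp_l(l)
  n_cases <- as.integer(n_cases)
  if (is.na(n_cases) || n_cases < 1L) stop("n_cases must be >= 1", call. = FALSE)
  if (l$mode == "percent") {
    # guard against floating-point excess just above an exact integer
    exact <- l$value * n_cases / 100
    return(as.integer(ceiling(exact - 1e-9)))
  }
  if (l$value > n_cases) {
    warning("case-exception count ", l$value, " exceeds the ", n_cases,
            " available cases; clamped", call. = FALSE)
    return(n_cases)
  }
  l$value
}
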