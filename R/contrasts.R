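#' Contrast coding scheme for two-level factors
#'
#' Three codings of a two-level factor are supported:
#' \describe{
#'   \item{\code{dummy}}{reference level 0, other level 1. Main-effect
#'     coefficients are simple effects at the other factor's reference level
#'     when an interaction is present -- a well-known pitfall in orthogonal
#'     experimental designs.}
#'   \item{\code{sum}}{-1 / +1 (the base-R \code{contr.sum} convention).
#'     Main effects are marginal, but coefficients are half the level
#'     difference (a quarter for the interaction).}
#'   \item{\code{deviation}}{-0.5 / +0.5 (the default). Main-effect
#'     coefficients equal the marginal mean difference and the interaction
#'     coefficient equals the difference of simple effects.}
#' }
#' Level order is lexicographic unless the data supply an explicit order, so
#' the second-sorted level always carries the positive code; the sign of an
#' estimate therefore states "second level minus first level".
#'
#' @param kind \code{"deviation"}, \code{"dummy"} or \code{"sum"}.
#' @param reference For dummy coding, the level label coded 0 (defaults to
#'   the first level in order).
#' @return An object of class \code{coding_scheme}.
#' @export
coding_scheme <- function(kind = c("deviation", "dummy", "sum"),
                          reference = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, reference = reference),
            class = "coding_scheme")
}

#' @export
print.coding_scheme <- function(x, ...) {
  cat("coding_scheme:", x$kind,
      if (!is.null(x$reference)) paste0("(reference = ", x$reference, ")"),
      "\n")
  invisible(x)
}

#' Numeric codes for the levels of a two-level factor
#'
#' @param levels Character vector of exactly two level labels, in order.
#' @param scheme A \code{\link{coding_scheme}}.
#' @return Named numeric vector: the code of each level.
#' @examples
#' encode_factor(c("65yr", "75yr"), coding_scheme("deviation"))
#' @export
encode_factor <- function(levels, scheme = coding_scheme()) {
  stopifnot(inherits(scheme, "coding_scheme"))
  levels <- as.character(levels)
  if (length(levels) != 2 || anyDuplicated(levels)) {
    stop("unsupported design: factors must have exactly two distinct levels",
         call. = FALSE)
  }
  codes <- switch(scheme$kind,
                  dummy = c(0, 1),
                  sum = c(-1, 1),
                  deviation = c(-0.5, 0.5))
  if (scheme$kind == "dummy" && !is.null(scheme$reference)) {
    if (!scheme$reference %in% levels) {
      stop("reference level '", scheme$reference, "' not among levels",
           call. = FALSE)
    }
    if (scheme$reference == levels[2]) codes <- rev(codes)
  }
  stats::setNames(codes, levels)
}

#' Fixed-effects design matrix under a coding scheme
#'
#' Builds the numeric design matrix for the requested fixed terms: an
#' intercept column of ones, one column per main effect (the factor's codes),
#' and interaction columns as elementwise products of their parents. Terms
#' are written as factor names, interactions as \code{"a:b"}.
#'
#' @param data A \code{\link{long_table}}.
#' @param fixed Character vector of model terms, e.g.
#'   \code{c("day", "stimtype", "day:stimtype")}.
#' @param scheme A \code{\link{coding_scheme}}.
#' @return An object of class \code{design_matrix}: list with the numeric
#'   matrix \code{X} (columns \code{"(Intercept)"} then the terms),
#'   \code{term_map} (term -> column index), and \code{codes} (per factor,
#'   the level codes used).
#' @export
build_design_matrix <- function(data, fixed, scheme = coding_scheme()) {
  stopifnot(inherits(data, "long_table"))
  main <- unique(unlist(strsplit(fixed, ":", fixed = TRUE)))
  unknown <- setdiff(main, factor_cols(data))
  if (length(unknown) > 0) {
    stop("term references unknown factor(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  codes <- lapply(main, function(f) {
    encode_factor(sort(unique(data[[f]])), scheme)
  })
  names(codes) <- main
  n <- nrow(data)
  X <- matrix(1, n, 1 + length(fixed),
              dimnames = list(NULL, c("(Intercept)", fixed)))
  for (term in fixed) {
    parents <- strsplit(term, ":", fixed = TRUE)[[1]]
    col <- rep(1, n)
    for (p in parents) col <- col * unname(codes[[p]][data[[p]]])
    X[, term] <- col
  }
  structure(list(X = X,
                 term_map = stats::setNames(seq_along(fixed) + 1L, fixed),
                 codes = codes, scheme = scheme),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("design_matrix:", nrow(x$X), "rows x", ncol(x$X), "columns (",
      paste(colnames(x$X), collapse = ", "), ")\n")
  invisible(x)
}
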