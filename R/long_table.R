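#' Long-format observation table
#'
#' The universal input container of the package: one observation per row,
#' with declared roles for the unit-identifier columns (participant and,
#' in crossed designs, stimulus), the experimental factor columns, an
#' optional replicate column (e.g. day of testing or measurement number),
#' and the numeric response.
#'
#' Validation enforces the contract the downstream models rely on:
#' the response is finite and numeric, every declared factor has at least
#' two observed levels, and the combination of unit ids, factor levels and
#' replicate identifies each row uniquely (no silent duplicates).
#'
#' @param data A data.frame in long format.
#' @param response Name of the numeric response column.
#' @param participant Name of the participant identifier column.
#' @param stimulus Optional name of the stimulus identifier column.
#' @param factors Character vector of experimental factor column names.
#' @param replicate Optional name of a replicate column.
#'
#' @return An object of class \code{long_table}: the data.frame with role
#'   attributes attached. Columns not named in any role are preserved but
#'   ignored by the models.
#' @examples
#' df <- data.frame(participant = rep(1:4, each = 2),
#'                  group = rep(c("a", "b"), each = 4),
#'                  score = rnorm(8))
#' lt <- long_table(df, response = "score", participant = "participant",
#'                  factors = "group")
#' @export
long_table <- function(data, response, participant, stimulus = NULL,
                       factors = character(), replicate = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  roles <- c(response = response, participant = participant,
             stimulus = stimulus, replicate = replicate, factors)
  missing_cols <- setdiff(unname(roles), names(data))
  if (length(missing_cols) > 0) {
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(data[[response]])) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(data[[response]])))))
    stop("response column '", response, "' is not numeric",
         if (length(bad) > 0) paste0(" (first offending row: ", bad[1], ")"),
         call. = FALSE)
  }
  if (any(!is.finite(data[[response]]))) {
    stop("response column '", response, "' contains non-finite values",
         call. = FALSE)
  }
  # factor levels are labels, never numbers
  for (f in factors) {
    data[[f]] <- as.character(data[[f]])
    if (length(unique(data[[f]])) < 2) {
      stop("factor '", f, "' has fewer than 2 observed levels", call. = FALSE)
    }
  }
  data[[participant]] <- as.character(data[[participant]])
  if (!is.null(stimulus)) data[[stimulus]] <- as.character(data[[stimulus]])
  if (!is.null(replicate)) data[[replicate]] <- as.character(data[[replicate]])

  key_cols <- c(participant, stimulus, factors, replicate)
  key <- do.call(paste, c(data[key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("rows are not uniquely identified by (",
         paste(key_cols, collapse = ", "),
         "); declare a replicate column or remove duplicates", call. = FALSE)
  }
  structure(data,
            response = response, participant = participant,
            stimulus = stimulus, factors = factors, replicate = replicate,
            class = c("long_table", "data.frame"))
}

#' @export
print.long_table <- function(x, ...) {
  cat("long_table:", nrow(x), "observations\n")
  cat("  response:   ", attr(x, "response"), "\n")
  cat("  participant:", attr(x, "participant"),
      sprintf("(%d units)", length(unique(x[[attr(x, "participant")]]))), "\n")
  if (!is.null(attr(x, "stimulus"))) {
    cat("  stimulus:   ", attr(x, "stimulus"),
        sprintf("(%d units)", length(unique(x[[attr(x, "stimulus")]]))), "\n")
  }
  if (length(attr(x, "factors")) > 0) {
    for (f in attr(x, "factors")) {
      cat("  factor:     ", f, "{", paste(sort(unique(x[[f]])), collapse = ", "),
          "}\n")
    }
  }
  if (!is.null(attr(x, "replicate"))) {
    cat("  replicate:  ", attr(x, "replicate"), "\n")
  }
  NextMethod()
}

# role accessors ------------------------------------------------------------

#' Column roles of a long_table
#'
#' @param x A \code{long_table}.
#' @return The column name holding that role (or \code{NULL}).
#' @export
response_col <- function(x) attr(x, "response")

#' @rdname response_col
#' @export
participant_col <- function(x) attr(x, "participant")

#' @rdname response_col
#' @export
stimulus_col <- function(x) attr(x, "stimulus")

#' @rdname response_col
#' @export
factor_cols <- function(x) attr(x, "factors")

#' @rdname response_col
#' @export
replicate_col <- function(x) attr(x, "replicate")

# keep attributes through [ subsetting of rows
#' @export
`[.long_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c(attr(x, "response")) %in% names(out))) {
    attributes(out)[c("response", "participant", "stimulus", "factors",
                      "replicate")] <-
      attributes(x)[c("response", "participant", "stimulus", "factors",
                      "replicate")]
    class(out) <- class(x)
  }
  out
}

#' Read a long-format CSV/TSV file
#'
#' Reads a delimited text file (UTF-8, header row required) and validates it
#' as a \code{\link{long_table}}. Factor columns are read as labels and never
#' coerced to numbers.
#'
#' @inheritParams long_table
#' @param path Path to the file.
#' @param sep Field separator; \code{","} (default) or \code{"\t"}.
#' @return A \code{long_table} with as many rows as the file has data lines.
#' @export
read_long_csv <- function(path, response, participant, stimulus = NULL,
                          factors = character(), replicate = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      colClasses = "character", check.names = FALSE,
                      fileEncoding = "UTF-8"),
    error = function(e) {
      stop("schema error: file '", path, "' has no data rows (",
           conditionMessage(e), ")", call. = FALSE)
    })
  if (nrow(df) == 0 || ncol(df) == 0) {
    stop("schema error: file '", path, "' has no data rows", call. = FALSE)
  }
  if (!response %in% names(df)) {
    stop("schema error: response column '", response, "' not present in ",
         path, call. = FALSE)
  }
  num <- suppressWarnings(as.numeric(df[[response]]))
  if (anyNA(num)) {
    stop("parse error: non-numeric response at row ",
         which(is.na(num))[1], call. = FALSE)
  }
  df[[response]] <- num
  long_table(df, response = response, participant = participant,
             stimulus = stimulus, factors = factors, replicate = replicate)
}

#' Reshape a wide table to a long_table
#'
#' Each wide column holds the response for one factor-level/replicate
#' combination; \code{mapping} says which. Values are carried over unchanged,
#' one output row per (input row, mapped column).
#'
#' @param wide A data.frame with one row per unit.
#' @param mapping Named list: for each wide column to unpivot, a named
#'   character vector giving the factor levels (and optionally a
#'   \code{replicate} entry) that column represents, e.g.
#'   \code{list(d1s1 = c(day = "day1", stimtype = "s1"))}.
#' @param id_cols Columns identifying the unit (and any unit-level factors),
#'   copied to every output row. The first is taken as the participant id
#'   unless \code{participant} says otherwise.
#' @param response Name for the response column in the output.
#' @param participant,stimulus,factors,replicate Role declarations for the
#'   result; defaults are inferred from \code{id_cols} and \code{mapping}.
#' @return A \code{long_table} with \code{nrow(wide) * length(mapping)} rows.
#' @export
wide_to_long <- function(wide, mapping, id_cols, response = "response",
                         participant = id_cols[1], stimulus = NULL,
                         factors = NULL, replicate = NULL) {
  stopifnot(is.data.frame(wide), is.list(mapping))
  cols <- names(mapping)
  missing_cols <- setdiff(cols, names(wide))
  if (length(missing_cols) > 0) {
    stop("mapping names columns absent from the wide table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keys <- vapply(mapping, function(m) paste(sort(names(m)), m[sort(names(m))],
                                            collapse = ";"), "")
  if (anyDuplicated(keys)) {
    stop("duplicate mapping: two wide columns map to the same ",
         "factor-level/replicate combination", call. = FALSE)
  }
  map_fields <- unique(unlist(lapply(mapping, names)))
  pieces <- lapply(cols, function(cn) {
    out <- wide[, id_cols, drop = FALSE]
    m <- mapping[[cn]]
    for (fld in map_fields) out[[fld]] <- unname(m[fld])
    out[[response]] <- wide[[cn]]
    out
  })
  long <- do.call(rbind, pieces)
  rownames(long) <- NULL
  if (is.null(factors)) {
    factors <- c(setdiff(id_cols, c(participant, stimulus)),
                 setdiff(map_fields, "replicate"))
  }
  if (is.null(replicate) && "replicate" %in% map_fields) replicate <- "replicate"
  # a factor with a single level in the mapping is a constant, not a factor
  factors <- factors[vapply(factors, function(f) length(unique(long[[f]])) > 1,
                            TRUE)]
  long_table(long, response = response, participant = participant,
             stimulus = stimulus, factors = factors, replicate = replicate)
}

#' Center the response within each unit
#'
#' Subtracts from every observation the plain mean of all observations of its
#' unit (participant or stimulus). Centering removes all between-unit
#' variance: after centering, the between-unit sum of squares is zero while
#' every within-stratum statistic of a repeated-measures ANOVA is unchanged,
#' which is what makes ordinary (total) eta squared on centered data equal
#' eta squared within of the uncentered analysis.
#'
#' @param data A \code{long_table}.
#' @param unit Which id column to center by: \code{"participant"},
#'   \code{"stimulus"}, or a column name.
#' @return A \code{long_table} of the same shape with the centered response.
#' @export
center_by_unit <- function(data, unit = "participant") {
  stopifnot(inherits(data, "long_table"))
  col <- switch(unit,
                participant = participant_col(data),
                stimulus = stimulus_col(data),
                unit)
  if (is.null(col) || !col %in% names(data)) {
    stop("unknown unit column: ", unit, call. = FALSE)
  }
  resp <- response_col(data)
  data[[resp]] <- data[[resp]] -
    stats::ave(data[[resp]], data[[col]], FUN = mean)
  data
}

#' Per-cell means and standard deviations
#'
#' Summarizes the response per cell of the named factors: the count, mean
#' (M) and standard deviation (SD, n - 1 denominator) that should accompany
#' any standardized effect size. With \code{collapse_replicates}, unit means
#' over the replicate column are taken first, reproducing summaries of
#' averaged tables.
#'
#' @param data A \code{long_table}.
#' @param factors Factor columns to cross; defaults to all declared factors.
#' @param collapse_replicates Average each unit's replicates within a cell
#'   before summarizing.
#' @return A data.frame with one row per observed cell: the factor levels,
#'   \code{n}, \code{mean}, \code{sd} (\code{NA} when \code{n = 1}).
#' @export
cell_summaries <- function(data, factors = NULL, collapse_replicates = FALSE) {
  stopifnot(inherits(data, "long_table"))
  if (is.null(factors)) factors <- factor_cols(data)
  if (length(factors) == 0) stop("no factors to summarize over", call. = FALSE)
  resp <- response_col(data)
  df <- as.data.frame(data)
  if (collapse_replicates) {
    units <- c(participant_col(data), stimulus_col(data))
    df <- stats::aggregate(df[[resp]],
                           by = df[c(units, factors)], FUN = mean)
    names(df)[ncol(df)] <- resp
  }
  agg <- stats::aggregate(df[[resp]], by = df[factors],
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sd = stats::sd(v)))
  out <- cbind(agg[factors], as.data.frame(agg$x))
  out$n <- as.integer(out$n)
  if (any(out$n == 1)) {
    warning("cells with a single observation: sd undefined (NA)")
  }
  out <- out[do.call(order, out[factors]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
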