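# internal: one value per unit x cell; average replicates when asked,
# error when replicates are present and averaging was not requested.
collapse_cells <- function(data, unit_cols, factors, collapse_replicates,
                           caller) {
  resp <- response_col(data)
  df <- as.data.frame(data)
  agg <- stats::aggregate(df[[resp]], by = df[c(unit_cols, factors)],
                          FUN = mean)
  cnt <- stats::aggregate(df[[resp]], by = df[c(unit_cols, factors)],
                          FUN = length)
  if (any(cnt$x > 1) && !collapse_replicates) {
    stop(caller, " needs one observation per unit and cell; found ",
         "replicates. Average them explicitly with ",
         "collapse_replicates = TRUE (note that averaging changes eta ",
         "squared), or use the mixed-model path on the raw data.",
         call. = FALSE)
  }
  names(agg)[ncol(agg)] <- resp
  agg
}

new_anova_table <- function(rows, ss_total, design) {
  rows$MS <- rows$SS / rows$df
  structure(rows, ss_total = ss_total, design = design,
            class = c("anova_table", "data.frame"))
}

#' One-way between-groups ANOVA
#'
#' Sum-of-squares decomposition for a single two-level (or k-level)
#' between-participants factor, computed from scratch: effect SS about the
#' grand mean, residual SS within groups, F = MS_effect / MS_residual. With
#' two groups, F equals the square of the Student t statistic. Requires one
#' observation per participant; replicates are averaged only on request.
#'
#' @param data A \code{\link{long_table}}.
#' @param factor Name of the grouping factor.
#' @param collapse_replicates Average each participant's replicates first.
#' @return An \code{anova_table}: data.frame with columns \code{term},
#'   \code{stratum}, \code{SS}, \code{df}, \code{MS}, \code{F}, \code{p},
#'   \code{error_term}; total SS stored as an attribute.
#' @export
anova_between <- function(data, factor, collapse_replicates = FALSE) {
  stopifnot(inherits(data, "long_table"))
  if (!factor %in% names(data)) {
    stop("unknown factor: ", factor, call. = FALSE)
  }
  subj <- participant_col(data)
  agg <- collapse_cells(data, subj, factor, collapse_replicates,
                        "anova_between")
  if (any(table(agg[[subj]]) > 1)) {
    stop("participants appear in more than one level of '", factor,
         "': not a between-groups design", call. = FALSE)
  }
  y <- agg[[response_col(data)]]
  g <- agg[[factor]]
  if (length(unique(g)) < 2) stop("factor is constant", call. = FALSE)
  grand <- mean(y)
  gm <- tapply(y, g, mean)
  gn <- tapply(y, g, length)
  ss_effect <- sum(gn * (gm - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_resid <- ss_total - ss_effect
  df_effect <- length(gm) - 1
  df_resid <- length(y) - length(gm)
  F <- (ss_effect / df_effect) / (ss_resid / df_resid)
  rows <- data.frame(
    term = c(factor, "residual"),
    stratum = "between",
    SS = c(ss_effect, ss_resid),
    df = c(df_effect, df_resid),
    F = c(F, NA),
    p = c(stats::pf(F, df_effect, df_resid, lower.tail = FALSE), NA),
    error_term = c("residual", NA),
    stringsAsFactors = FALSE)
  new_anova_table(rows, ss_total,
                  list(type = "between", factor = factor, subject = subj))
}

#' Repeated-measures ANOVA (one or two within factors)
#'
#' From-scratch sum-of-squares decomposition for balanced complete
#' fully-within designs with one value per subject and cell (replicates are
#' averaged only on explicit request, because averaging changes eta
#' squared). The table separates the between-subjects stratum (differences
#' in overall level between subjects) from the within-subjects stratum,
#' where each effect is tested against its own effect-by-subject error
#' stratum: F = MS_term / MS_(term x subject).
#'
#' Missing cells are not handled here: unbalanced data belong to the
#' mixed-model path (\code{\link{fit_lmm}}), which deals with missingness
#' naturally.
#'
#' @param data A \code{\link{long_table}}.
#' @param within One or two within-subject factor names.
#' @param subject Subject id column (defaults to the declared participant).
#' @param collapse_replicates Average replicates within each subject x cell.
#' @return An \code{anova_table} with a between-subjects row and, per
#'   within-stratum term, an effect row and its error row.
#' @export
anova_rm <- function(data, within, subject = NULL,
                     collapse_replicates = FALSE) {
  stopifnot(inherits(data, "long_table"))
  if (is.null(subject)) subject <- participant_col(data)
  if (!length(within) %in% 1:2) {
    stop("anova_rm supports one or two within factors", call. = FALSE)
  }
  if (!all(within %in% names(data))) {
    stop("unknown factor(s): ",
         paste(setdiff(within, names(data)), collapse = ", "), call. = FALSE)
  }
  agg <- collapse_cells(data, subject, within, collapse_replicates,
                        "anova_rm")
  y <- agg[[response_col(data)]]
  s <- agg[[subject]]
  cell <- interaction(agg[within], drop = TRUE)
  counts <- table(s, cell)
  if (any(counts != 1)) {
    stop("design is not balanced and complete (one value per subject and ",
         "cell); fit the mixed model instead, which handles missing data",
         call. = FALSE)
  }
  n_s <- length(unique(s))
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  n_cells <- nlevels(cell)
  sm <- tapply(y, s, mean)
  ss_subject <- n_cells * sum((sm - grand)^2)

  dev_term <- function(cols) {
    # SS of the interaction-type deviation for a crossed set of columns,
    # with all lower-order means swept out
    tab <- tapply(y, lapply(agg[cols], identity), mean)
    k <- length(dim(tab)); if (is.null(dim(tab))) k <- 1
    dev <- tab - grand
    if (k > 1) {
      # subtract main-effect deviations (two-way case only)
      m1 <- apply(tab, 1, mean) - grand
      m2 <- apply(tab, 2, mean) - grand
      dev <- sweep(sweep(tab, 1, m1 + grand), 2, m2) # tab - m1 - m2 - grand
    }
    reps <- length(y) / length(tab)
    reps * sum(dev^2)
  }

  rows <- data.frame(term = "between-subjects", stratum = "between",
                     SS = ss_subject, df = n_s - 1, F = NA, p = NA,
                     error_term = NA, stringsAsFactors = FALSE)
  add_pair <- function(rows, term_label, ss_t, df_t, ss_e, df_e) {
    F <- (ss_t / df_t) / (ss_e / df_e)
    err <- paste0(term_label, ":subject")
    rbind(rows,
          data.frame(term = c(term_label, err), stratum = "within",
                     SS = c(ss_t, ss_e), df = c(df_t, df_e),
                     F = c(F, NA),
                     p = c(stats::pf(F, df_t, df_e, lower.tail = FALSE), NA),
                     error_term = c(err, NA), stringsAsFactors = FALSE))
  }

  if (length(within) == 1) {
    A <- within
    ss_A <- dev_term(A)
    df_A <- length(unique(agg[[A]])) - 1
    ss_AS <- ss_total - ss_subject - ss_A
    rows <- add_pair(rows, A, ss_A, df_A, ss_AS, df_A * (n_s - 1))
  } else {
    A <- within[1]; B <- within[2]
    a <- length(unique(agg[[A]])); b <- length(unique(agg[[B]]))
    ss_A <- dev_term(A); ss_B <- dev_term(B)
    ss_AB <- dev_term(c(A, B))
    ss_AS <- dev_term(c(A, subject))
    ss_BS <- dev_term(c(B, subject))
    ss_ABS <- ss_total - ss_subject - ss_A - ss_B - ss_AB - ss_AS - ss_BS
    rows <- add_pair(rows, A, ss_A, a - 1, ss_AS, (a - 1) * (n_s - 1))
    rows <- add_pair(rows, B, ss_B, b - 1, ss_BS, (b - 1) * (n_s - 1))
    rows <- add_pair(rows, paste(A, B, sep = ":"), ss_AB,
                     (a - 1) * (b - 1), ss_ABS, (a - 1) * (b - 1) * (n_s - 1))
  }
  rownames(rows) <- NULL
  new_anova_table(rows, ss_total,
                  list(type = "rm", within = within, subject = subject))
}

#' @export
print.anova_table <- function(x, digits = 4, ...) {
  cat("ANOVA table (total SS about the grand mean:",
      format(attr(x, "ss_total"), digits = digits), ")\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Eta-squared family from an ANOVA table
#'
#' Three variance-explained measures per effect term:
#' \describe{
#'   \item{\code{total}}{eta squared: SS_term over the grand-total SS --
#'     the effect's share of all variance, including between-subject level
#'     differences.}
#'   \item{\code{partial}}{partial eta squared: SS_term over
#'     (SS_term + SS_error(term)). A transform of the F statistic; the
#'     denominators differ between terms, so the values are not shares of a
#'     common variance and can sum to more than 1.}
#'   \item{\code{within}}{eta squared within: SS_term over the sum of every
#'     within-stratum SS (all effects plus all their error strata) -- the
#'     effect's share of the total within-subject variance. Equal to the
#'     total eta squared of the same analysis run on unit-centered data.}
#' }
#'
#' @param table An \code{anova_table}.
#' @param variant \code{"total"}, \code{"partial"} or \code{"within"}.
#' @return Named numeric vector, one value per effect term.
#' @export
eta_squared <- function(table, variant = c("total", "partial", "within")) {
  stopifnot(inherits(table, "anova_table"))
  variant <- match.arg(variant)
  eff <- table[!is.na(table$F), , drop = FALSE]
  vals <- switch(variant,
    total = eff$SS / attr(table, "ss_total"),
    partial = {
      err_ss <- table$SS[match(eff$error_term, table$term)]
      eff$SS / (eff$SS + err_ss)
    },
    within = {
      w <- table$stratum == "within"
      if (!any(w)) {
        warning("no within stratum in a pure between design: ",
                "eta squared within undefined")
        return(stats::setNames(numeric(0), character(0)))
      }
      eff$SS / sum(table$SS[w])
    })
  stats::setNames(vals, eff$term)
}
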