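#' Independent-samples t-test
#'
#' Compares the means of two independent samples. The Welch variant (the
#' default, as it does not assume equal variances) uses the
#' Welch--Satterthwaite degrees of freedom; the Student variant pools the
#' variances and has n1 + n2 - 2 degrees of freedom. p-values are two-sided.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @param variant \code{"welch"} or \code{"student"}.
#' @param conf_level Confidence level for the mean-difference interval.
#' @return A \code{test_result}: list with \code{estimate} (mean of x minus
#'   mean of y, in response units), \code{t}, \code{df}, \code{p},
#'   \code{ci}, and the per-sample \code{n}, \code{mean}, \code{sd}.
#' @export
t_independent <- function(x, y, variant = c("welch", "student"),
                          conf_level = 0.95) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    res <- list(estimate = 0, t = 0,
                df = if (variant == "student") length(x) + length(y) - 2
                     else length(x) + length(y) - 2,
                p = 1, ci = c(0, 0))
  } else {
    ht <- stats::t.test(x, y, var.equal = (variant == "student"),
                        conf.level = conf_level)
    res <- list(estimate = unname(ht$estimate[1] - ht$estimate[2]),
                t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value, ci = unname(ht$conf.int))
  }
  structure(c(res,
              list(variant = variant, conf_level = conf_level,
                   n = c(length(x), length(y)),
                   mean = c(mean(x), mean(y)),
                   sd = c(stats::sd(x), stats::sd(y)))),
            class = "test_result")
}

#' Paired-samples t-test
#'
#' One-sample t-test of the position-wise differences against zero:
#' t = M_diff / (SD_diff / sqrt(N)), df = N - 1, two-sided p.
#'
#' @param x,y Paired numeric samples of equal length (pairing by position).
#' @param conf_level Confidence level for the mean-difference interval.
#' @return A \code{test_result} (see \code{\link{t_independent}}).
#' @export
t_paired <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  if (stats::sd(d) == 0) {
    t <- if (mean(d) == 0) 0 else stop("all differences equal but nonzero: ",
                                       "sd of differences is 0", call. = FALSE)
    res <- list(estimate = 0, t = 0, df = n - 1, p = 1, ci = c(0, 0))
  } else {
    ht <- stats::t.test(d, conf.level = conf_level)
    res <- list(estimate = mean(d), t = unname(ht$statistic),
                df = unname(ht$parameter), p = ht$p.value,
                ci = unname(ht$conf.int))
  }
  structure(c(res,
              list(variant = "paired", conf_level = conf_level,
                   n = n, mean = c(mean(x), mean(y)),
                   sd = c(stats::sd(x), stats::sd(y)),
                   sd_diff = stats::sd(d))),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s t-test: t(%.4g) = %.3f, p = %.4f, estimate = %.4g [%.4g, %.4g]\n",
              x$variant, x$df, x$t, x$p, x$estimate, x$ci[1], x$ci[2]))
  invisible(x)
}

# confidence interval for a standardized mean difference via inversion of
# the noncentral-t pivot: find ncp such that the observed t is the
# 97.5th / 2.5th percentile of t(df, ncp), then rescale by sqrt(n_tilde).
ncp_interval <- function(t_obs, df, scale, conf_level = 0.95) {
  alpha <- (1 - conf_level) / 2
  bound <- function(prob) {
    f <- function(nc) suppressWarnings(stats::pt(t_obs, df, ncp = nc)) - prob
    lo <- t_obs - 10 - 4 * abs(t_obs)
    hi <- t_obs + 10 + 4 * abs(t_obs)
    stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  }
  c(bound(1 - alpha), bound(alpha)) / scale
}

#' Cohen's d for two independent groups
#'
#' d = (M_x - M_y) / sqrt((SD_x^2 + SD_y^2) / 2), the mean difference over
#' the average standard deviation. The confidence interval inverts the
#' noncentral-t pivot of the associated t statistic.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @param conf_level Confidence level.
#' @return A \code{d_family}: list with \code{d}, \code{ci}, and the
#'   summary statistics it was computed from.
#' @export
cohens_d_independent <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  s_av <- sqrt((stats::var(x) + stats::var(y)) / 2)
  if (s_av == 0) {
    stop("both samples have zero variance: d undefined", call. = FALSE)
  }
  d <- (mean(x) - mean(y)) / s_av
  n1 <- length(x); n2 <- length(y)
  n_tilde <- n1 * n2 / (n1 + n2)
  ci <- ncp_interval(d * sqrt(n_tilde), n1 + n2 - 2, sqrt(n_tilde),
                     conf_level)
  structure(list(d = d, ci = ci, type = "independent",
                 conf_level = conf_level,
                 mean = c(mean(x), mean(y)),
                 sd = c(stats::sd(x), stats::sd(y)), n = c(n1, n2)),
            class = "d_family")
}

#' d_z and d_av for paired data
#'
#' For paired samples two standardized differences are reported:
#' d_z = M_diff / SD_diff (the mean difference relative to the variability
#' of the difference scores; the paired analogue of the t statistic), and
#' d_av = (M_x - M_y) / sqrt((SD_x^2 + SD_y^2) / 2) (relative to all
#' variability, comparable with the independent-groups d). The confidence
#' interval is for d_z, via the noncentral-t pivot.
#'
#' @param x,y Paired numeric samples of equal length.
#' @param conf_level Confidence level.
#' @return A \code{d_family} with \code{d_z}, \code{d_av}, \code{ci} (for
#'   d_z), and summary statistics.
#' @export
d_paired <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  dif <- x - y
  n <- length(dif)
  sd_diff <- stats::sd(dif)
  s_av <- sqrt((stats::var(x) + stats::var(y)) / 2)
  d_av <- if (s_av == 0 && mean(dif) == 0) 0 else (mean(x) - mean(y)) / s_av
  if (sd_diff == 0) {
    if (mean(dif) != 0) {
      stop("zero variance in difference scores: d_z undefined", call. = FALSE)
    }
    d_z <- 0
    ci <- c(0, 0)
  } else {
    d_z <- mean(dif) / sd_diff
    ci <- ncp_interval(d_z * sqrt(n), n - 1, sqrt(n), conf_level)
  }
  structure(list(d_z = d_z, d_av = d_av, ci = ci, type = "paired",
                 conf_level = conf_level,
                 mean = c(mean(x), mean(y)),
                 sd = c(stats::sd(x), stats::sd(y)),
                 sd_diff = sd_diff, n = n),
            class = "d_family")
}

#' @export
print.d_family <- function(x, ...) {
  if (x$type == "independent") {
    cat(sprintf("Cohen's d = %.3f, %g%% CI [%.3f, %.3f]\n",
                x$d, 100 * x$conf_level, x$ci[1], x$ci[2]))
  } else {
    cat(sprintf("d_z = %.3f, %g%% CI [%.3f, %.3f]; d_av = %.3f\n",
                x$d_z, 100 * x$conf_level, x$ci[1], x$ci[2], x$d_av))
  }
  invisible(x)
}

#' Convert between eta-squared and d-family effect sizes
#'
#' Closed-form (approximate) translations between the variance-explained
#' and mean-difference families:
#' \deqn{d_{av} \approx 2 \sqrt{\eta^2 / (1 - \eta^2)}}
#' \deqn{d_z \approx \sqrt{\eta^2_p / (1 - \eta^2_p)}}
#' and their exact inverses. eta squared pairs with d_av (both measure
#' against total variability); partial eta squared pairs with d_z (both
#' measure against difference-score variability). The factor 2 appears for
#' d_av because two independent distributions are compared.
#'
#' @param value The input effect size: an eta-squared-type value in
#'   \code{[0, 1)} for the \code{to_*} directions, a non-negative d for the
#'   \code{from_*} directions.
#' @param direction One of \code{"to_dav"} (eta squared to d_av),
#'   \code{"to_dz"} (partial eta squared to d_z), \code{"from_dav"},
#'   \code{"from_dz"}.
#' @return The converted effect size.
#' @examples
#' convert_eta_d(0.025, "to_dav")   # ~ 0.32
#' convert_eta_d(0.536, "to_dz")    # ~ 1.07
#' @export
convert_eta_d <- function(value,
                          direction = c("to_dav", "to_dz",
                                        "from_dav", "from_dz")) {
  direction <- match.arg(direction)
  if (direction %in% c("to_dav", "to_dz")) {
    if (any(value < 0 | value >= 1)) {
      stop("eta-squared value must lie in [0, 1)", call. = FALSE)
    }
    switch(direction,
           to_dav = 2 * sqrt(value / (1 - value)),
           to_dz = sqrt(value / (1 - value)))
  } else {
    if (any(value < 0)) stop("d value must be non-negative", call. = FALSE)
    switch(direction,
           from_dav = (value / 2)^2 / (1 + (value / 2)^2),
           from_dz = value^2 / (1 + value^2))
  }
}
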