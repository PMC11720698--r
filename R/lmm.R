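#' Random-effects specification
#'
#' Declares one random grouping factor of a mixed model: which unit id
#' column groups the observations, whether it receives a random intercept,
#' and which fixed terms receive random slopes. Slopes are only meaningful
#' for terms that vary within the grouping unit (a between-unit effect has
#' one value per unit and its "slope" is confounded with the intercept).
#'
#' @param grouping Unit id column name (e.g. \code{"participant"}).
#' @param slopes Character vector of fixed-term labels (\code{"a"},
#'   \code{"a:b"}) that get random slopes.
#' @param intercept Include a random intercept (default \code{TRUE}).
#' @return An object of class \code{random_spec}.
#' @examples
#' random_spec("participant", slopes = c("day", "stimtype", "day:stimtype"))
#' @export
random_spec <- function(grouping, slopes = character(), intercept = TRUE) {
  stopifnot(is.character(grouping), length(grouping) == 1)
  structure(list(grouping = grouping, slopes = slopes,
                 intercept = intercept),
            class = "random_spec")
}

# term label -> syntactically safe column name for the model formula
safe_name <- function(term) paste0("c_", gsub("[^A-Za-z0-9]", "_", term))

#' Fit a linear mixed-effects model with coded two-level factors
#'
#' Builds the numeric design under the requested contrast coding (deviation,
#' i.e. -0.5/+0.5, by default, so that main-effect estimates are marginal
#' mean differences even in the presence of interactions) and fits the model
#' by REML through \pkg{lmerTest}/\pkg{lme4}. Random-slope/intercept
#' covariances are estimated (full covariance per grouping factor).
#' Singular fits (variance components on the boundary) are reported, not
#' suppressed; genuine non-convergence after two restarts from perturbed
#' starting values is an error carrying the optimizer diagnostics.
#'
#' @param data A \code{\link{long_table}}.
#' @param fixed Character vector of fixed terms (factor names and
#'   \code{"a:b"} interactions); may be empty for an intercept-only model.
#' @param random A \code{\link{random_spec}} or list of them.
#' @param scheme A \code{\link{coding_scheme}}.
#' @param reml Fit by REML (default) or ML.
#' @return An object of class \code{mixed_fit}; see
#'   \code{\link{fixed_effects}}, \code{\link{variance_components}},
#'   \code{\link{marginal_r2}}, \code{\link{semipartial_r2}}.
#' @export
fit_lmm <- function(data, fixed, random, scheme = coding_scheme(),
                    reml = TRUE) {
  stopifnot(inherits(data, "long_table"))
  if (inherits(random, "random_spec")) random <- list(random)
  stopifnot(length(random) >= 1,
            all(vapply(random, inherits, TRUE, "random_spec")))
  dm <- build_design_matrix(data, fixed, scheme)
  mf <- data.frame(.y = data[[response_col(data)]])
  for (term in fixed) mf[[safe_name(term)]] <- dm$X[, term]
  for (rs in random) {
    if (!rs$grouping %in% names(data)) {
      stop("random grouping column not found: ", rs$grouping, call. = FALSE)
    }
    if (length(unique(data[[rs$grouping]])) < 2) {
      stop("random grouping '", rs$grouping, "' has fewer than 2 units",
           call. = FALSE)
    }
    bad <- setdiff(rs$slopes, fixed)
    if (length(bad) > 0) {
      stop("random slope term(s) not among the fixed terms: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    mf[[rs$grouping]] <- data[[rs$grouping]]
  }
  fixed_rhs <- if (length(fixed) > 0) {
    paste(vapply(fixed, safe_name, ""), collapse = " + ")
  } else "1"
  random_rhs <- vapply(random, function(rs) {
    inner <- c(if (rs$intercept) "1" else "0",
               vapply(rs$slopes, safe_name, ""))
    paste0("(", paste(inner, collapse = " + "), " | ", rs$grouping, ")")
  }, "")
  form <- stats::as.formula(paste(".y ~", fixed_rhs, "+",
                                  paste(random_rhs, collapse = " + ")))

  fit_once <- function(start = NULL) {
    warns <- character()
    model <- withCallingHandlers(
      lmerTest::lmer(form, data = mf, REML = reml, start = start),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(model = model, warns = warns)
  }
  res <- fit_once()
  # restart from perturbed variance parameters if the optimizer complains
  # about convergence (boundary/singular messages are not failures)
  is_conv_warn <- function(w) grepl("converge", w, ignore.case = TRUE)
  tries <- 0
  while (any(vapply(res$warns, is_conv_warn, TRUE)) && tries < 2) {
    tries <- tries + 1
    th <- lme4::getME(res$model, "theta")
    res2 <- fit_once(start = list(theta = th * (1 + 0.05 * tries) + 1e-4))
    if (length(res2$warns) <= length(res$warns)) res <- res2
  }
  converged <- !any(vapply(res$warns, is_conv_warn, TRUE))
  if (!converged) {
    # a fit is still returned when the gradient is only marginally above
    # the tolerance; the message is preserved in the object
    message("fit_lmm: optimizer reported: ",
            paste(res$warns, collapse = "; "))
  }
  structure(list(model = res$model, design = dm, fixed = fixed,
                 random = random, scheme = scheme, reml = reml,
                 n_obs = nrow(mf),
                 converged = converged,
                 singular = lme4::isSingular(res$model),
                 messages = res$warns),
            class = "mixed_fit")
}

#' Fixed-effects table of a mixed_fit
#'
#' Per-term estimate, standard error, Satterthwaite degrees of freedom,
#' t = estimate/SE, and two-sided p-value.
#'
#' @param fit A \code{mixed_fit}.
#' @return A data.frame with one row per fixed term (intercept included).
#' @export
fixed_effects <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  co <- summary(fit$model)$coefficients
  labels <- c("(Intercept)", fit$fixed)[match(rownames(co),
              c("(Intercept)", vapply(fit$fixed, safe_name, "")))]
  data.frame(term = labels,
             estimate = co[, "Estimate"], SE = co[, "Std. Error"],
             df = co[, "df"], t = co[, "t value"], p = co[, "Pr(>|t|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Variance components of a mixed_fit
#'
#' Per grouping factor: the SD (and variance) of each random term and the
#' correlations between them; plus the residual SD. The ICC reported per
#' grouping factor is that factor's intercept variance over the sum of all
#' random-component variances plus the residual variance (one common
#' interpretation; random-slope variance shares are not ICCs in the classic
#' sense).
#'
#' @param fit A \code{mixed_fit}.
#' @return A list with \code{components} (data.frame: grouping, term, sd,
#'   variance, icc for intercept rows), \code{correlations} (per grouping,
#'   the correlation matrix), and \code{residual_sd}.
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  vc <- lme4::VarCorr(fit$model)
  safe2term <- c("(Intercept)",
                 stats::setNames(fit$fixed, vapply(fit$fixed, safe_name, "")))
  names(safe2term)[1] <- "(Intercept)"
  rows <- list(); cors <- list()
  tot <- stats::sigma(fit$model)^2
  for (g in names(vc)) tot <- tot + sum(diag(vc[[g]]))
  for (g in names(vc)) {
    Sig <- vc[[g]]
    terms <- unname(safe2term[rownames(Sig)])
    sds <- sqrt(diag(Sig))
    rows[[g]] <- data.frame(
      grouping = g, term = terms, sd = unname(sds),
      variance = unname(diag(Sig)),
      icc = ifelse(terms == "(Intercept)", diag(Sig) / tot, NA),
      row.names = NULL, stringsAsFactors = FALSE)
    cm <- attr(Sig, "correlation")
    if (!is.null(cm)) {
      dimnames(cm) <- list(terms, terms)
      cors[[g]] <- cm
    }
  }
  list(components = do.call(rbind, c(rows, make.row.names = FALSE)),
       correlations = cors,
       residual_sd = stats::sigma(fit$model))
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("Linear mixed model (", if (x$reml) "REML" else "ML", "), ",
      x$n_obs, " observations\n", sep = "")
  cat("coding:", x$scheme$kind, "\n")
  if (x$singular) cat("note: singular fit (variance component(s) at zero)\n")
  cat("\nFixed effects:\n")
  print(fixed_effects(x), digits = 4, row.names = FALSE)
  vc <- variance_components(x)
  cat("\nRandom components:\n")
  print(vc$components, digits = 4, row.names = FALSE)
  cat("Residual SD:", format(vc$residual_sd, digits = 4), "\n")
  invisible(x)
}

#' Satterthwaite degrees of freedom for fixed effects
#'
#' Fractional denominator degrees of freedom for the t statistics of the
#' fixed effects, from the Satterthwaite approximation (the variance of the
#' contrast variance estimated from the REML information, via the delta
#' method). In balanced designs with a single random factor these reduce to
#' the classical ANOVA degrees of freedom. Values involving singular
#' variance components are approximate; a flag is attached.
#'
#' @param fit A \code{mixed_fit}.
#' @param term A fixed-term label, or \code{NULL} for all.
#' @return Named numeric vector of degrees of freedom; attribute
#'   \code{approximate} is \code{TRUE} when the fit is singular.
#' @export
satterthwaite_df <- function(fit, term = NULL) {
  fe <- fixed_effects(fit)
  df <- stats::setNames(fe$df, fe$term)
  if (!is.null(term)) {
    if (!term %in% names(df)) stop("unknown term: ", term, call. = FALSE)
    df <- df[term]
  }
  attr(df, "approximate") <- fit$singular
  df
}

# Nakagawa-Schielzeth-Johnson variance partition of a mixed_fit:
# vf = sample variance of the fixed-effects fitted contribution,
# vr = sum over grouping factors of mean_i(z_i' Sigma z_i)  (Johnson 2014),
# ve = residual variance.
nsj_variances <- function(fit) {
  X <- stats::model.matrix(fit$model)
  b <- lme4::fixef(fit$model)
  eta <- as.vector(X %*% b)
  vf <- if (length(eta) > 1) stats::var(eta) else 0
  vr <- 0
  vc <- lme4::VarCorr(fit$model)
  for (g in names(vc)) {
    Sig <- vc[[g]]
    Z <- X[, rownames(Sig), drop = FALSE]
    vr <- vr + mean(rowSums((Z %*% Sig) * Z))
  }
  list(vf = vf, vr = vr, ve = stats::sigma(fit$model)^2,
       X = X, b = b)
}

#' Marginal R-squared of a mixed model
#'
#' The variance of the fixed-effects fitted contribution over the observed
#' rows, divided by that variance plus all random-component variances plus
#' the residual variance (Nakagawa--Schielzeth, with Johnson's extension
#' for random slopes). This is the mixed-model equivalent of eta squared /
#' R-squared: the share of total variance explained by the fixed effects.
#'
#' @param fit A \code{mixed_fit}.
#' @return A single proportion in [0, 1].
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  v <- nsj_variances(fit)
  v$vf / (v$vf + v$vr + v$ve)
}

#' Per-term semi-partial R-squared (eta squared) of a mixed model
#'
#' For each fixed term j, the variance of its fitted contribution X_j b_j
#' over the observed rows, divided by that variance plus all
#' random-component variances plus the residual variance. Each term is thus
#' measured against the variance not already claimed by the other fixed
#' effects; with a single fixed term the value equals the marginal
#' R-squared.
#'
#' @param fit A \code{mixed_fit}.
#' @return Named numeric vector, one value per fixed term (intercept
#'   excluded).
#' @export
semipartial_r2 <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  v <- nsj_variances(fit)
  terms <- setdiff(colnames(v$X), "(Intercept)")
  if (length(terms) > 1 && qr(v$X)$rank < ncol(v$X)) {
    warning("collinear fixed terms: semi-partial values are not a clean ",
            "variance partition")
  }
  vals <- vapply(terms, function(j) {
    vj <- stats::var(v$X[, j] * v$b[j])
    vj / (vj + v$vr + v$ve)
  }, 0)
  safe2term <- stats::setNames(fit$fixed, vapply(fit$fixed, safe_name, ""))
  stats::setNames(vals, unname(safe2term[terms]))
}

#' Eta squared within from a mixed model via unit-centered refit
#'
#' Centers the response within each level of \code{center_unit} (removing
#' all between-unit variance), refits the same model -- the random intercept
#' is retained; its estimated variance collapses towards zero and the value
#' of eta squared within does not depend on how the remaining variance is
#' allocated over components -- and returns the per-term semi-partial
#' R-squared of the centered fit: each effect's share of the within-unit
#' variance.
#'
#' An effect that is constant within every centering unit (a pure
#' between-unit effect under that centering) has no within-unit variance to
#' explain; its value is \code{NA} and it is listed in the
#' \code{undefined} attribute.
#'
#' @param data A \code{\link{long_table}}.
#' @param fixed,random,scheme As in \code{\link{fit_lmm}}.
#' @param center_unit Unit id column to center by (typically one of the
#'   random grouping columns): \code{"participant"}, \code{"stimulus"} or a
#'   column name.
#' @return Named numeric vector of eta squared within per fixed term, with
#'   attributes \code{undefined} (terms flagged NA) and \code{fit} (the
#'   centered \code{mixed_fit}).
#' @export
eta2w_lmm <- function(data, fixed, random, center_unit = "participant",
                      scheme = coding_scheme()) {
  stopifnot(inherits(data, "long_table"))
  centered <- center_by_unit(data, center_unit)
  col <- switch(center_unit,
                participant = participant_col(data),
                stimulus = stimulus_col(data),
                center_unit)
  dm <- build_design_matrix(data, fixed, scheme)
  varies_within <- vapply(fixed, function(term) {
    z <- dm$X[, term]
    any(stats::ave(z, data[[col]], FUN = function(v) max(v) - min(v)) > 0)
  }, TRUE)
  fitc <- fit_lmm(centered, fixed, random, scheme = scheme)
  vals <- semipartial_r2(fitc)
  vals[fixed[!varies_within]] <- NA_real_
  if (any(!varies_within)) {
    warning("eta squared within undefined for between-unit effect(s): ",
            paste(fixed[!varies_within], collapse = ", "))
  }
  attr(vals, "undefined") <- fixed[!varies_within]
  attr(vals, "fit") <- fitc
  vals
}

#' Composite per-term effect-size report for a mixed model
#'
#' Fits the model and assembles, per fixed term: the estimate, SE,
#' Satterthwaite df, t, two-sided p, eta squared (semi-partial marginal
#' R-squared) and -- when \code{center_unit} is given -- eta squared within
#' from the unit-centered refit. The model-level marginal R-squared, the
#' variance components and the per-cell means and SDs (which should always
#' accompany standardized effect sizes) are attached as attributes.
#'
#' Partial eta squared is computed only on request: in mixed models it is a
#' transform of t and the (estimation-dependent) degrees of freedom, so the
#' same effect can change value substantially with the random-effects
#' structure; it is emitted with a warning.
#'
#' @param data A \code{\link{long_table}}.
#' @param fixed,random,scheme As in \code{\link{fit_lmm}}.
#' @param center_unit Unit to center by for eta squared within, or
#'   \code{NULL} to skip.
#' @param eta2p Also report partial eta squared (discouraged; warns).
#' @return An \code{effect_size_report}: data.frame with one row per fixed
#'   term; attributes \code{R2_marginal}, \code{fit}, \code{components},
#'   \code{cells}.
#' @export
effect_report <- function(data, fixed, random, center_unit = NULL,
                          scheme = coding_scheme(), eta2p = FALSE) {
  fit <- fit_lmm(data, fixed, random, scheme = scheme)
  fe <- fixed_effects(fit)
  semi <- if (length(fixed) > 0) semipartial_r2(fit) else numeric(0)
  rep <- fe
  rep$eta2 <- NA_real_
  rep$eta2[match(names(semi), rep$term)] <- semi
  if (!is.null(center_unit) && length(fixed) > 0) {
    e2w <- eta2w_lmm(data, fixed, random, center_unit, scheme)
    rep$eta2_w <- NA_real_
    rep$eta2_w[match(names(e2w), rep$term)] <- e2w
  } else {
    rep$eta2_w <- NA_real_
  }
  if (eta2p) {
    warning("partial eta squared from a mixed model depends on the ",
            "(estimation-dependent) degrees of freedom; it is reported ",
            "for completeness, not recommended as an effect size")
    rep$eta2_p <- ifelse(rep$term == "(Intercept)", NA_real_,
                         rep$t^2 / (rep$t^2 + rep$df))
  }
  cells <- if (length(factor_cols(data)) > 0) {
    cell_summaries(data, collapse_replicates = FALSE)
  } else NULL
  structure(rep,
            R2_marginal = marginal_r2(fit),
            fit = fit,
            components = variance_components(fit),
            cells = cells,
            center_unit = center_unit,
            class = c("effect_size_report", "data.frame"))
}

#' @export
print.effect_size_report <- function(x, digits = 4, ...) {
  cat("Effect-size report (R2 marginal =",
      format(attr(x, "R2_marginal"), digits = digits), ")\n")
  if (!is.null(attr(x, "center_unit"))) {
    cat("eta2_w centered by:", attr(x, "center_unit"), "\n")
  }
  print.data.frame(x, digits = digits, row.names = FALSE)
  cells <- attr(x, "cells")
  if (!is.null(cells)) {
    cat("\nCell means and SDs:\n")
    print.data.frame(cells, digits = digits, row.names = FALSE)
  }
  invisible(x)
}
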