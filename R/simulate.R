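#' Specification of a synthetic crossed-design dataset
#'
#' Describes the generative model the mixed-model machinery assumes: a
#' response built from fixed effects of two-level factors (true
#' coefficients on the deviation, i.e. -0.5/+0.5, scale), Gaussian random
#' intercepts and slopes per participant (and optionally per stimulus),
#' and Gaussian residual error. Every effect-size operation can then be
#' checked by parameter recovery against the closed forms of
#' \code{\link{expected_effect_sizes}}.
#'
#' Factor names are taken from the names of \code{fixed} (interactions as
#' \code{"a:b"}); each factor has levels \code{"<name>1"} / \code{"<name>2"}
#' coded -0.5 / +0.5. Factors listed in \code{between_participants} vary
#' between participants (half the participants per level); the rest are
#' crossed with participants. Likewise for \code{between_stimuli} when
#' \code{n_stimuli > 0}. Random components are independent across terms
#' (zero correlations) and named by the term they attach to
#' (\code{"(Intercept)"} or a fixed-term label).
#'
#' @param n_participants Number of participants.
#' @param n_stimuli Number of stimuli; 0 means no stimulus factor.
#' @param intercept Fixed intercept (grand mean).
#' @param fixed Named numeric vector of true fixed coefficients on the
#'   deviation scale, e.g. \code{c(a = 5, b = 2, "a:b" = 1)}.
#' @param participant_sd Named numeric vector of random-effect SDs by
#'   participant, e.g. \code{c("(Intercept)" = 10, a = 2)}.
#' @param stimulus_sd Random-effect SDs by stimulus.
#' @param residual_sd Residual SD (> 0).
#' @param replicates Observations per participant x stimulus x cell.
#' @param between_participants Factor names varying between participants.
#' @param between_stimuli Factor names varying between stimuli.
#' @param missing_rate Probability in [0, 1) that a row is dropped
#'   (missing completely at random).
#' @param seed Integer seed; mandatory, so every dataset is reproducible.
#' @return An object of class \code{sim_spec}.
#' @export
sim_spec <- function(n_participants, n_stimuli = 0, intercept = 0,
                     fixed = c(), participant_sd = c("(Intercept)" = 1),
                     stimulus_sd = c(), residual_sd = 1, replicates = 1,
                     between_participants = character(),
                     between_stimuli = character(),
                     missing_rate = 0, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_participants >= 2, n_stimuli >= 0, residual_sd >= 0,
            replicates >= 1, missing_rate >= 0, missing_rate < 1,
            all(participant_sd >= 0), all(stimulus_sd >= 0))
  factors <- unique(unlist(strsplit(names(fixed), ":", fixed = TRUE)))
  stopifnot(all(between_participants %in% factors),
            all(between_stimuli %in% factors))
  if (length(between_participants) > 0 && n_participants %% 2 != 0) {
    stop("between-participant factors need an even number of participants",
         call. = FALSE)
  }
  bad <- setdiff(names(participant_sd), c("(Intercept)", names(fixed)))
  if (length(bad) > 0) {
    stop("participant_sd names unknown term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  slope_terms <- setdiff(names(participant_sd), "(Intercept)")
  between_p_terms <- names(fixed)[vapply(names(fixed), function(t) {
    all(strsplit(t, ":", fixed = TRUE)[[1]] %in% between_participants)
  }, TRUE)]
  if (any(slope_terms %in% between_p_terms)) {
    stop("impossible design: participant slopes requested for terms that ",
         "do not vary within participants", call. = FALSE)
  }
  structure(list(n_participants = n_participants, n_stimuli = n_stimuli,
                 intercept = intercept, fixed = fixed,
                 participant_sd = participant_sd, stimulus_sd = stimulus_sd,
                 residual_sd = residual_sd, replicates = replicates,
                 between_participants = between_participants,
                 between_stimuli = between_stimuli,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 factors = factors),
            class = "sim_spec")
}

#' Simulate a crossed participants-by-stimuli dataset
#'
#' Draws a dataset from the generative model of a \code{\link{sim_spec}}:
#' response = intercept + sum of fixed contributions + participant
#' deviations + stimulus deviations + Gaussian residual. Deterministic
#' given the spec's seed; the same spec always yields a bit-identical
#' table. Rows are dropped independently with probability
#' \code{missing_rate}.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @return A \code{\link{long_table}} with columns \code{participant},
#'   (\code{stimulus},) one column per factor, \code{rep}, \code{response}.
#' @export
simulate_crossed <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  p_ids <- sprintf("p%04d", seq_len(spec$n_participants))
  s_ids <- if (spec$n_stimuli > 0) sprintf("s%04d", seq_len(spec$n_stimuli))
           else NA_character_
  within_cells <- setdiff(spec$factors,
                          c(spec$between_participants, spec$between_stimuli))
  grid_args <- c(
    stats::setNames(lapply(within_cells,
                           function(f) paste0(f, 1:2)), within_cells),
    list(stimulus = s_ids, participant = p_ids,
         rep = sprintf("r%02d", seq_len(spec$replicates))))
  df <- do.call(expand.grid,
                c(grid_args, stringsAsFactors = FALSE,
                  KEEP.OUT.ATTRS = FALSE))
  # balanced assignment of between-unit factor levels
  for (f in spec$between_participants) {
    lv <- stats::setNames(paste0(f, rep(1:2, length.out = spec$n_participants)),
                          p_ids)
    df[[f]] <- unname(lv[df$participant])
  }
  for (f in spec$between_stimuli) {
    lv <- stats::setNames(paste0(f, rep(1:2, length.out = spec$n_stimuli)),
                          s_ids)
    df[[f]] <- unname(lv[df$stimulus])
  }
  # deviation codes per term
  zcol <- function(term) {
    parents <- strsplit(term, ":", fixed = TRUE)[[1]]
    z <- rep(1, nrow(df))
    for (p in parents) z <- z * ifelse(df[[p]] == paste0(p, "2"), 0.5, -0.5)
    z
  }
  y <- rep(spec$intercept, nrow(df))
  for (term in names(spec$fixed)) y <- y + spec$fixed[[term]] * zcol(term)
  # participant deviations
  for (term in names(spec$participant_sd)) {
    u <- stats::rnorm(spec$n_participants, 0, spec$participant_sd[[term]])
    names(u) <- p_ids
    z <- if (term == "(Intercept)") 1 else zcol(term)
    y <- y + unname(u[df$participant]) * z
  }
  if (spec$n_stimuli > 0) {
    for (term in names(spec$stimulus_sd)) {
      u <- stats::rnorm(spec$n_stimuli, 0, spec$stimulus_sd[[term]])
      names(u) <- s_ids
      z <- if (term == "(Intercept)") 1 else zcol(term)
      y <- y + unname(u[df$stimulus]) * z
    }
  }
  y <- y + stats::rnorm(nrow(df), 0, spec$residual_sd)
  df$response <- y
  if (spec$n_stimuli == 0) df$stimulus <- NULL
  if (spec$missing_rate > 0) {
    keep <- stats::runif(nrow(df)) >= spec$missing_rate
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  long_table(df, response = "response", participant = "participant",
             stimulus = if (spec$n_stimuli > 0) "stimulus" else NULL,
             factors = spec$factors,
             replicate = if (spec$replicates > 1) "rep" else NULL)
}

#' Analytic effect sizes of a sim_spec
#'
#' Closed forms of the generator's own model, for parameter-recovery tests.
#' On the deviation scale a main-effect code is -0.5/+0.5, so a term with
#' coefficient beta contributes variance beta^2 * E[z^2] (beta^2/4 for a
#' main effect, beta^2/16 for a two-way interaction). Random terms
#' contribute sigma^2 * E[z^2] (sigma^2 for intercepts). Then
#' \deqn{\eta^2_j = V_j / (V_{fixed} + V_{random} + \sigma^2_\epsilon)}
#' with the per-term semi-partial convention (the denominator counts only
#' term j's own fixed variance). Eta squared within (participant centering)
#' removes the participant intercept variance and the variance of purely
#' between-participant fixed terms from the denominator; such terms have no
#' within value (NA).
#'
#' Only defined for balanced specs (\code{missing_rate = 0}).
#'
#' @param spec A \code{\link{sim_spec}}.
#' @return A data.frame with one row per fixed term: \code{term},
#'   \code{eta2}, \code{eta2_w}; marginal R-squared as attribute
#'   \code{R2_marginal}.
#' @export
expected_effect_sizes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$missing_rate > 0) {
    stop("closed form undefined for unbalanced (missing_rate > 0) specs",
         call. = FALSE)
  }
  ez2 <- function(term) {
    if (term == "(Intercept)") 1
    else 0.25^length(strsplit(term, ":", fixed = TRUE)[[1]])
  }
  v_fixed <- vapply(names(spec$fixed),
                    function(t) spec$fixed[[t]]^2 * ez2(t), 0)
  v_part <- vapply(names(spec$participant_sd),
                   function(t) spec$participant_sd[[t]]^2 * ez2(t), 0)
  v_stim <- if (length(spec$stimulus_sd) > 0) {
    vapply(names(spec$stimulus_sd),
           function(t) spec$stimulus_sd[[t]]^2 * ez2(t), 0)
  } else numeric(0)
  v_rand <- sum(v_part) + sum(v_stim)
  ve <- spec$residual_sd^2
  between_p <- vapply(names(spec$fixed), function(t) {
    all(strsplit(t, ":", fixed = TRUE)[[1]] %in% spec$between_participants)
  }, TRUE)
  # participant centering removes the participant intercept variance and
  # all between-participant fixed variance
  v_rand_w <- v_rand - sum(v_part[names(v_part) == "(Intercept)"])
  eta2 <- vapply(seq_along(v_fixed), function(j) {
    v_fixed[j] / (v_fixed[j] + v_rand + ve)
  }, 0)
  eta2_w <- vapply(seq_along(v_fixed), function(j) {
    if (between_p[j]) return(NA_real_)
    v_fixed[j] / (v_fixed[j] + v_rand_w + ve)
  }, 0)
  out <- data.frame(term = names(spec$fixed), eta2 = eta2, eta2_w = eta2_w,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "R2_marginal") <- sum(v_fixed) / (sum(v_fixed) + v_rand + ve)
  out
}
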