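# Small builders for in-code fixtures used across test files.

# balanced fully-within design: n subjects x 2-level factors, cell effects
# given as a named vector over cell labels, plus per-subject offsets
make_within_design <- function(n_subj, factors, seed = 1, noise_sd = 1,
                               subj_sd = 0) {
  set.seed(seed)
  cells <- do.call(expand.grid,
                   c(stats::setNames(lapply(factors, function(f)
                     paste0(f, 1:2)), factors),
                     list(stringsAsFactors = FALSE)))
  df <- do.call(rbind, lapply(seq_len(n_subj), function(s) {
    out <- cells
    out$participant <- sprintf("s%02d", s)
    out
  }))
  df$score <- stats::rnorm(nrow(df), sd = noise_sd) +
    rep(stats::rnorm(n_subj, sd = subj_sd), each = nrow(cells))
  long_table(df, response = "score", participant = "participant",
             factors = factors)
}

# the paired 65yr/75yr participant means of the longitudinal dataset
# (one score per participant and age, days averaged)
longitudinal_means <- function() {
  lt <- load_fixture("wm_longitudinal")
  agg <- stats::aggregate(score ~ participant + age, as.data.frame(lt),
                          mean)
  list(x = agg$score[agg$age == "yr65"][order(agg$participant[agg$age == "yr65"])],
       y = agg$score[agg$age == "yr75"][order(agg$participant[agg$age == "yr75"])])
}

# participant means of the two independent age groups (days averaged)
between_means <- function() {
  lt <- load_fixture("wm_between")
  agg <- stats::aggregate(score ~ participant + group, as.data.frame(lt),
                          mean)
  list(x = agg$score[agg$group == "65yr"],
       y = agg$score[agg$group == "75yr"])
}

# per-stimulus mean ratings of the two age groups in the face study
stimulus_means <- function() {
  lt <- load_fixture("faces")
  agg <- stats::aggregate(rating ~ stimulus + age, as.data.frame(lt), mean)
  list(x = agg$rating[agg$age == "yr18"][order(agg$stimulus[agg$age == "yr18"])],
       y = agg$rating[agg$age == "yr75"][order(agg$stimulus[agg$age == "yr75"])])
}
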