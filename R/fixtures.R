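#' Embedded toy datasets
#'
#' The five worked datasets the package's analyses are validated on, shipped
#' as plain-text transcriptions under \code{inst/extdata} and returned in
#' long format with their column roles declared:
#'
#' \describe{
#'   \item{\code{wm_between}}{Working-memory scores of two independent age
#'     groups (65yr vs 75yr), 20 participants tested on two days; 40 rows.
#'     Factor \code{group} (between participants), replicate \code{day}.}
#'   \item{\code{wm_longitudinal}}{The same 10 participants tested at age 65
#'     and again at 75, two days each time; 40 rows. Factor \code{age}
#'     (within participants), replicate \code{day}.}
#'   \item{\code{twobytwo}}{A 2 x 2 fully-within design (Day x StimulusType)
#'     with two measurements per cell; 80 rows. Replicate \code{meas}.}
#'   \item{\code{faces}}{Attractiveness ratings of 10 face stimuli by 10
#'     young and 10 old participants; 200 rows. Factor \code{age} is between
#'     participants but within stimuli.}
#'   \item{\code{reading}}{Reading times of 12 bilinguals for 20 texts in a
#'     2 x 2 Language x Background design; 240 rows. Both factors are within
#'     participants and between texts.}
#' }
#'
#' @param name One of \code{fixture_names()}.
#' @return A \code{\link{long_table}}.
#' @examples
#' load_fixture("twobytwo")
#' @export
load_fixture <- function(name) {
  if (length(name) != 1 || !name %in% fixture_names()) {
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(fixture_names(), collapse = ", "),
         call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "eta2w",
                      mustWork = TRUE)
  wide <- utils::read.csv(path, check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  switch(name,
    wm_between = {
      wide$day1 <- as.numeric(wide$day1); wide$day2 <- as.numeric(wide$day2)
      wide_to_long(wide,
                   mapping = list(day1 = c(replicate = "day1"),
                                  day2 = c(replicate = "day2")),
                   id_cols = c("participant", "group"), response = "score",
                   factors = "group")
    },
    wm_longitudinal = {
      for (j in 2:5) wide[[j]] <- as.numeric(wide[[j]])
      wide_to_long(wide,
                   mapping = list(
                     yr65_day1 = c(age = "yr65", replicate = "day1"),
                     yr65_day2 = c(age = "yr65", replicate = "day2"),
                     yr75_day1 = c(age = "yr75", replicate = "day1"),
                     yr75_day2 = c(age = "yr75", replicate = "day2")),
                   id_cols = "participant", response = "score")
    },
    twobytwo = {
      for (j in 2:9) wide[[j]] <- as.numeric(wide[[j]])
      grid <- expand.grid(meas = c("m1", "m2"), stimtype = c("s1", "s2"),
                          day = c("day1", "day2"), stringsAsFactors = FALSE)
      cols <- sprintf("%ss%sm%s", sub("day", "d", grid$day),
                      sub("s", "", grid$stimtype), sub("m", "", grid$meas))
      mapping <- stats::setNames(lapply(seq_len(nrow(grid)), function(i) {
        c(day = grid$day[i], stimtype = grid$stimtype[i],
          replicate = grid$meas[i])
      }), cols)
      wide_to_long(wide, mapping, id_cols = "participant", response = "score")
    },
    faces = {
      for (j in 3:12) wide[[j]] <- as.numeric(wide[[j]])
      mapping <- stats::setNames(lapply(sprintf("S%d", 1:10), function(s) {
        c(stimulus = s)
      }), sprintf("S%d", 1:10))
      wide_to_long(wide, mapping, id_cols = c("participant", "age"),
                   response = "rating", stimulus = "stimulus",
                   factors = "age")
    },
    reading = {
      for (j in 4:15) wide[[j]] <- as.numeric(wide[[j]])
      mapping <- stats::setNames(lapply(sprintf("p%d", 1:12), function(p) {
        c(participant = p)
      }), sprintf("p%d", 1:12))
      wide_to_long(wide, mapping,
                   id_cols = c("text", "language", "background"),
                   response = "rt", participant = "participant",
                   stimulus = "text", factors = c("language", "background"))
    })
}

#' @rdname load_fixture
#' @export
fixture_names <- function() {
  c("wm_between", "wm_longitudinal", "twobytwo", "faces", "reading")
}
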