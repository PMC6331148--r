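#' Column layout of a survey file
#'
#' The survey record structure used for calibration: one row per
#' participant with an identifier, region, age (18-89), gender, the three
#' 5-point attitude items (toward Christians, Muslims and the areligious,
#' coded 1 = strongly unfavorable to 5 = strongly favorable), a religion
#' label, a free-text "religion (other)" field, and the start/end
#' timestamps of the interview.
#'
#' @return Character vector of the eleven column names, in file order.
#' @export
survey_columns <- function() {
  c("id", "region", "age", "gender",
    "attitude_C", "attitude_M", "attitude_A",
    "religion", "religion_other", "start_time", "end_time")
}

# religion label (lower case) -> worldview group
.default_religion_map <- c(
  muslim = "M", islam = "M",
  christian = "C", catholic = "C", protestant = "C", orthodox = "C",
  areligious = "A", atheist = "A", agnostic = "A", none = "A",
  "no religion" = "A"
)

#' Map religion labels to worldview groups
#'
#' @param religion Character vector of religion labels.
#' @param map Named vector: lower-case label -> group. Labels not in the
#'   map give `NA` (unmappable; such respondents are excluded from the
#'   statistics and counted).
#' @return Character vector of groups (`"M"`, `"C"`, `"A"`) or `NA`.
#' @export
religion_group <- function(religion, map = .default_religion_map) {
  out <- unname(map[tolower(trimws(religion))])
  as.character(out)
}

#' Read a survey file
#'
#' Reads a delimited text file in the [survey_columns()] layout. The
#' delimiter is auto-detected among tab, comma and semicolon. Rows with a
#' non-integer or out-of-range attitude (outside 1..5) or an age outside
#' 18-89 are malformed: they are skipped and counted (attribute `skipped`,
#' plus a message). More than 10% malformed rows is a hard error.
#'
#' @param path Path to the survey file.
#' @param quiet Suppress the skipped-rows message.
#' @return A data frame of validated records with attribute `skipped`.
#' @export
read_survey <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  seps <- c("\t", ",", ";")
  counts <- vapply(seps, function(s) lengths(regmatches(first, gregexpr(s, first, fixed = TRUE))),
                   integer(1))
  sep <- seps[which.max(counts)]
  if (max(counts) == 0) stop("could not detect a delimiter (tab, comma or semicolon)",
                             call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          fill = TRUE)
  if (ncol(df) != length(survey_columns())) {
    stop(sprintf("expected %d columns, found %d", length(survey_columns()), ncol(df)),
         call. = FALSE)
  }
  names(df) <- survey_columns()
  att <- c("attitude_C", "attitude_M", "attitude_A")
  for (col in c(att, "age")) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  ok_att <- Reduce(`&`, lapply(df[att], function(x) !is.na(x) & x %in% 1:5))
  ok_age <- !is.na(df$age) & df$age >= 18 & df$age <= 89
  ok <- ok_att & ok_age
  skipped <- sum(!ok)
  if (skipped > 0 && !quiet) {
    message(sprintf("read_survey: skipped %d malformed row(s) of %d", skipped, nrow(df)))
  }
  if (nrow(df) > 0 && skipped / nrow(df) > 0.10) {
    stop(sprintf("more than 10%% malformed rows (%d of %d): refusing to proceed",
                 skipped, nrow(df)), call. = FALSE)
  }
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write survey records to a delimited text file
#'
#' @param records A data frame in the [survey_columns()] layout.
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_survey <- function(records, path, sep = "\t") {
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Group-attitude statistics of survey records
#'
#' Respondents are assigned to worldview groups through their religion
#' label ([religion_group()]); unmappable respondents are excluded and
#' counted. The 5-point responses are mapped linearly onto the model's
#' attitude scale, \code{(r - 3) / 2}, so 1 maps to -1, 3 to 0 and 5 to +1.
#' For every ordered pair (respondent group, target group) the mean and
#' population-style standard deviation of the normalized responses are
#' computed; group fractions are group counts over the mappable total.
#'
#' @param records A survey data frame (see [survey_columns()]).
#' @param map Religion-to-group mapping passed to [religion_group()].
#' @param quiet Suppress the unmappable-respondents message.
#' @return A [calibration_target()] (attribute `unmappable` holds the
#'   number of excluded respondents). Cells of empty groups are `NA`.
#' @export
survey_stats <- function(records, map = .default_religion_map, quiet = FALSE) {
  grp <- religion_group(records$religion, map)
  n_bad <- sum(is.na(grp))
  if (n_bad > 0 && !quiet) {
    message(sprintf("survey_stats: excluded %d unmappable respondent(s)", n_bad))
  }
  keep <- !is.na(grp)
  grp <- grp[keep]
  records <- records[keep, , drop = FALSE]
  if (!nrow(records)) stop("no mappable respondents", call. = FALSE)
  labs <- c("M", "C", "A")
  att_col <- stats::setNames(paste0("attitude_", labs), labs)
  m <- s <- matrix(NA_real_, 3, 3, dimnames = list(labs, labs))
  for (G in labs) {
    rows <- grp == G
    if (!any(rows)) next
    for (Ta in labs) {
      x <- (records[[att_col[[Ta]]]][rows] - 3) / 2
      m[G, Ta] <- mean(x)
      s[G, Ta] <- sqrt(mean((x - mean(x))^2))
    }
  }
  fraction <- vapply(stats::setNames(labs, labs),
                     function(G) mean(grp == G), numeric(1))
  out <- calibration_target(m, s, fraction)
  attr(out, "unmappable") <- n_bad
  out
}

#' Specification of a synthetic survey
#'
#' Bundles the inputs of [synth_survey()]: the sample size, the group
#' fractions and the 3 x 3 group-conditional response distributions
#' (mean and SD on the raw 1-5 scale).
#'
#' @param n Number of respondents.
#' @param fractions Named group fractions (`M`, `C`, `A`) summing to 1.
#' @param means,sds 3 x 3 numeric matrices (rows = respondent group,
#'   columns = target group, both in M, C, A order) on the 1-5 scale.
#' @return An object of class `survey_spec`.
#' @export
survey_spec <- function(n, fractions, means, sds) {
  labs <- c("M", "C", "A")
  if (!identical(sort(names(fractions)), sort(labs))) {
    stop("fractions must be named M, C, A", call. = FALSE)
  }
  fractions <- fractions[labs]
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0)) {
    stop("group fractions must be non-negative and sum to 1", call. = FALSE)
  }
  means <- as.matrix(means); sds <- as.matrix(sds)
  if (!all(dim(means) == c(3, 3)) || !all(dim(sds) == c(3, 3)) || any(sds < 0)) {
    stop("means and sds must be 3 x 3 with non-negative sds", call. = FALSE)
  }
  dimnames(means) <- dimnames(sds) <- list(labs, labs)
  if (!(n >= 1 && n == round(n))) stop("n must be a positive integer", call. = FALSE)
  structure(list(n = as.integer(n), fractions = fractions,
                 means = means, sds = sds), class = "survey_spec")
}

#' A synthetic stand-in for the calibration survey
#'
#' Default [survey_spec()] emulating the calibration survey of the French
#' population: n = 1000 respondents with group fractions 3.6% Muslim,
#' 60.6% Christian and 35.8% areligious. The 3 x 3 response distributions
#' are synthetic placeholders chosen to be sociologically plausible
#' (in-group favoritism, less favorable out-group attitudes toward the
#' minority group), NOT values taken from any published survey table.
#'
#' @param n Number of respondents (default 1000).
#' @return A [survey_spec()].
#' @export
synthetic_french_survey_spec <- function(n = 1000) {
  labs <- c("M", "C", "A")
  means <- matrix(c(
    # toward M, toward C, toward A   (rows: respondent group M, C, A)
    4.40, 3.40, 3.00,
    2.60, 4.00, 3.20,
    2.90, 3.20, 4.10
  ), nrow = 3, byrow = TRUE, dimnames = list(labs, labs))
  sds <- matrix(c(
    0.80, 1.00, 1.00,
    1.00, 0.90, 1.00,
    1.00, 1.00, 0.90
  ), nrow = 3, byrow = TRUE, dimnames = list(labs, labs))
  survey_spec(n, c(M = 0.036, C = 0.606, A = 0.358), means, sds)
}

.group_religion_label <- c(M = "muslim", C = "christian", A = "areligious")
.survey_regions <- c("Ile-de-France", "Auvergne-Rhone-Alpes", "Occitanie",
                     "Bretagne", "Grand-Est", "Nouvelle-Aquitaine")

#' Generate a synthetic survey
#'
#' Draws respondents with the given group fractions; each 5-point attitude
#' is a Gaussian draw with the group-conditional mean and SD, rounded and
#' clipped to 1..5. Record structure and column order match
#' [survey_columns()], so the output can be written with [write_survey()]
#' and re-read with [read_survey()]. Fully reproducible from `seed`.
#'
#' @param spec A [survey_spec()].
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A data frame of `spec$n` survey records.
#' @export
synth_survey <- function(spec, seed) {
  stopifnot(inherits(spec, "survey_spec"))
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  labs <- c("M", "C", "A")
  n <- spec$n
  grp <- sample(labs, n, replace = TRUE, prob = spec$fractions)
  draw <- function(target) {
    r <- stats::rnorm(n, spec$means[grp, target], spec$sds[grp, target])
    pmin(pmax(round(r), 1), 5)
  }
  data.frame(
    id = sprintf("P%04d", seq_len(n)),
    region = sample(.survey_regions, n, replace = TRUE),
    age = sample(18:89, n, replace = TRUE),
    gender = sample(c("female", "male"), n, replace = TRUE),
    attitude_C = draw("C"),
    attitude_M = draw("M"),
    attitude_A = draw("A"),
    religion = unname(.group_religion_label[grp]),
    religion_other = "",
    start_time = "2014-06-01T09:00:00",
    end_time = "2014-06-01T09:12:00",
    stringsAsFactors = FALSE
  )
}
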