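#' Define a cause group by code prefixes
#'
#' A cause group collects all codes beginning with any of its prefixes, on
#' the normalized dotless token ("beginning with F11" covers F11 and
#' F110-F119).
#'
#' @param name Group label.
#' @param prefixes Non-empty character vector of code prefixes.
#' @return Object of class `ucd_cause_group`.
#' @export
cause_group <- function(name, prefixes) {
  if (length(prefixes) == 0) stop("a cause group needs at least one prefix")
  structure(list(name = as.character(name),
                 prefixes = toupper(gsub(".", "", prefixes, fixed = TRUE))),
            class = "ucd_cause_group")
}

#' The overdose-monitoring cause groups
#'
#' The six underlying-cause groupings used for overdose-related death
#' surveillance: opioid- and cannabis-related disorders (F11, F12);
#' cocaine-, hallucinogen- and other stimulant-related disorders (F14-F16);
#' other psychoactive-substance-related disorders (F19); accidental
#' poisoning by narcotics and psychodysleptics (X42); intentional
#' self-poisoning (X62); and poisoning with undetermined intent (Y12).
#' Note F13 (sedative-hypnotics) is deliberately not part of any group.
#'
#' @return List of six [cause_group()] objects.
#' @export
overdose_groups <- function() {
  list(
    cause_group("opioid_cannabis", c("F11", "F12")),
    cause_group("cocaine_stimulants", c("F14", "F15", "F16")),
    cause_group("other_psychoactive", "F19"),
    cause_group("accidental_poisoning", "X42"),
    cause_group("intentional_poisoning", "X62"),
    cause_group("undetermined_poisoning", "Y12")
  )
}

group_matches <- function(codes, group) {
  stopifnot(inherits(group, "ucd_cause_group"))
  m <- rep(FALSE, length(codes))
  for (p in group$prefixes) m <- m | startsWith(codes, p)
  m
}

#' Recode certificates with the year covariate fixed
#'
#' Re-predicts the underlying cause of every certificate with the year of
#' coding overridden to one reference year, so that all certificates are
#' coded under the same (learned) rule regime -- the temporal harmonization
#' used to smooth coding-rule drift out of cause-specific time series. The
#' input certificates are not modified.
#'
#' @param coder Trained `ucd_coder`.
#' @param certs Certificates to recode.
#' @param vocab The vocabulary.
#' @param fixed_year Calendar year within the coder's modelled range.
#' @return Character vector of recoded UCDs, aligned with `certs`.
#' @export
recode_certificates <- function(coder, certs, vocab, fixed_year) {
  cfg <- coder$config
  if (fixed_year < cfg$base_year || fixed_year > cfg$base_year + cfg$Y - 1) {
    stop(sprintf("fixed_year %d outside the modelled range %d-%d",
                 fixed_year, cfg$base_year, cfg$base_year + cfg$Y - 1))
  }
  shifted <- lapply(certs, function(ct) { ct$year <- as.integer(fixed_year); ct })
  predict_ucd(coder, shifted, vocab)
}

#' Cause-group death counts per year
#'
#' Counts, for each year and cause group, the deaths whose UCD matches the
#' group. A UCD matching several groups counts once per matching group, but
#' only once in the deduplicated `total` series.
#'
#' @param ucds Character vector of underlying causes.
#' @param years Aligned integer vector of calendar years.
#' @param groups List of [cause_group()].
#' @param year_range Optional integer vector fixing the year axis (defaults
#'   to the observed span).
#' @param source Label, e.g. `"original"` or `"recoded"`.
#' @return Object of class `ucd_timeseries`: list with `years`,
#'   `group_names`, `counts` (group x year), `total` (per-year deduplicated
#'   count), `source`.
#' @export
count_by_group <- function(ucds, years, groups, year_range = NULL,
                           source = "original") {
  if (length(ucds) != length(years)) stop("ucds and years are not aligned")
  if (is.null(year_range)) {
    year_range <- if (length(years)) seq(min(years), max(years)) else integer(0)
  }
  gnames <- vapply(groups, `[[`, "", "name")
  counts <- matrix(0L, length(groups), length(year_range),
                   dimnames = list(gnames, year_range))
  any_match <- rep(FALSE, length(ucds))
  for (gi in seq_along(groups)) {
    m <- group_matches(ucds, groups[[gi]])
    any_match <- any_match | m
    t <- table(factor(years[m], levels = year_range))
    counts[gi, ] <- as.integer(t)
  }
  total <- as.integer(table(factor(years[any_match], levels = year_range)))
  structure(
    list(years = as.integer(year_range), group_names = gnames,
         counts = counts, total = stats::setNames(total, year_range),
         source = source),
    class = "ucd_timeseries"
  )
}

#' @export
print.ucd_timeseries <- function(x, ...) {
  cat(sprintf("<ucd_timeseries '%s'> %d groups x %d years, %d matching deaths\n",
              x$source, length(x$group_names), length(x$years), sum(x$total)))
  invisible(x)
}

#' @export
as.data.frame.ucd_timeseries <- function(x, ...) {
  data.frame(
    year = rep(x$years, each = length(x$group_names)),
    group = rep(x$group_names, times = length(x$years)),
    source = x$source,
    count = as.integer(x$counts),
    stringsAsFactors = FALSE
  )
}

#' Compare original and recoded cause-group trajectories
#'
#' Produces the per-year count differences and, as a smoothness surrogate,
#' the maximum absolute year-over-year change of each source's grouped
#' total: a coding-rule discontinuity shows up as a large jump in the
#' original series that harmonized recoding removes.
#'
#' @param original,recoded `ucd_timeseries` on the same years and groups.
#' @return List with `deltas` (recoded - original counts), `yoy_original`,
#'   `yoy_recoded` (named absolute year-over-year changes of the totals),
#'   `jump_original`, `jump_recoded` (their maxima).
#' @export
trajectory_comparison <- function(original, recoded) {
  stopifnot(inherits(original, "ucd_timeseries"),
            inherits(recoded, "ucd_timeseries"))
  if (!identical(original$years, recoded$years) ||
      !identical(original$group_names, recoded$group_names)) {
    stop("time series do not share years and groups")
  }
  yoy <- function(x) {
    if (length(x) < 2) return(stats::setNames(numeric(0), character(0)))
    stats::setNames(abs(diff(x)), original$years[-1])
  }
  yo <- yoy(unname(original$total))
  yr <- yoy(unname(recoded$total))
  list(
    deltas = recoded$counts - original$counts,
    yoy_original = yo,
    yoy_recoded = yr,
    jump_original = if (length(yo)) max(yo) else 0,
    jump_recoded = if (length(yr)) max(yr) else 0
  )
}
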