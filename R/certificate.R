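#' Age binning for the demographic covariate
#'
#' Age is factorized into 25 bins: bin 0 covers neonatal deaths (< 28 days,
#' which follow a distinct set of coding rules), bin 1 the remainder of the
#' first year of life, bin 2 ages 1-4, bins 3..23 the 5-year intervals 5-9
#' through 105-109, and bin 24 ages 110 and over. The 25 bins tile
#' `[0, Inf)` without gaps or overlap.
#'
#' @param age_value Nonnegative age value(s).
#' @param age_unit `"years"` or `"days"` (recycled).
#' @return Integer bin(s) in 0..24.
#' @examples
#' bin_age(10, "days")   # 0, neonatal
#' bin_age(200, "days")  # 1
#' bin_age(7, "years")   # 3
#' @export
bin_age <- function(age_value, age_unit = "years") {
  if (any(is.na(age_value)) || any(age_value < 0)) {
    stop("age_value must be nonnegative")
  }
  age_unit <- match.arg(age_unit, c("years", "days"), several.ok = TRUE)
  age_unit <- rep_len(age_unit, length(age_value))
  days <- ifelse(age_unit == "days", age_value, age_value * 365.25)
  years <- days / 365.25
  bin <- integer(length(age_value))
  bin[days < 28] <- 0L
  bin[days >= 28 & years < 1] <- 1L
  bin[years >= 1 & years < 5] <- 2L
  mid <- years >= 5 & years < 110
  bin[mid] <- 3L + as.integer(floor((years[mid] - 5) / 5))
  bin[years >= 110] <- 24L
  bin
}

#' Construct a death certificate record
#'
#' A certificate holds up to four Part I lines (the causal chain of death in
#' inverse causal order: immediate cause on line 1, underlying causes on the
#' last used lines) and up to two Part II lines (other significant conditions
#' contributing to death), plus demographics and, optionally, the gold
#' underlying cause of death.
#'
#' @param id Identifier string.
#' @param part1 List of up to 4 character vectors of ICD-10 codes (written
#'   order preserved); empty vectors denote empty lines.
#' @param part2 List of up to 2 character vectors.
#' @param sex `"M"`/`"F"` (or 0/1, or the French CSV tokens 1/2).
#' @param age_value,age_unit Age at death (see [bin_age()]).
#' @param year Calendar year of death.
#' @param gold_ucd Optional gold underlying cause code.
#' @param rejected Optional logical: whether a rule-based coder rejected the
#'   certificate as too complex.
#' @return Object of class `ucd_certificate`.
#' @export
new_certificate <- function(id, part1, part2 = list(), sex, age_value,
                            age_unit = "years", year, gold_ucd = NA_character_,
                            rejected = NA) {
  if (!is.list(part1)) part1 <- list(part1)
  if (!is.list(part2)) part2 <- list(part2)
  if (length(part1) > 4) stop("Part I has at most 4 lines")
  if (length(part2) > 2) stop("Part II has at most 2 lines")
  canon <- function(lines) {
    lines <- lapply(unname(lines),
                    function(l) if (length(l)) parse_code(l) else character(0))
    # trailing empty lines are indistinguishable from absent lines
    while (length(lines) && length(lines[[length(lines)]]) == 0) {
      lines[[length(lines)]] <- NULL
    }
    lines
  }
  part1 <- canon(part1)
  part2 <- canon(part2)
  if (sum(lengths(part1)) + sum(lengths(part2)) == 0) {
    stop("certificate must contain at least one code")
  }
  sex <- parse_sex(sex)
  age_unit <- match.arg(age_unit, c("years", "days"))
  if (age_value < 0) stop("age_value must be nonnegative")
  if (!is.na(gold_ucd)) gold_ucd <- parse_code(gold_ucd)
  structure(
    list(
      id = as.character(id), part1 = part1, part2 = part2, sex = sex,
      age_value = as.numeric(age_value), age_unit = age_unit,
      year = as.integer(year), gold_ucd = gold_ucd,
      rejected = as.logical(rejected)
    ),
    class = "ucd_certificate"
  )
}

parse_sex <- function(sex) {
  s <- as.character(sex)
  out <- c("M" = 0L, "F" = 1L, "0" = 0L, "1" = 0L, "2" = 1L)[toupper(s)]
  # plain 0/1 integers: 0 = male, 1 = female
  if (is.numeric(sex) && sex %in% c(0, 1)) out <- as.integer(sex)
  if (is.na(out)) stop(sprintf("unrecognized sex token '%s'", s))
  unname(out)
}

#' @export
print.ucd_certificate <- function(x, ...) {
  fmt_line <- function(l) if (length(l)) paste(l, collapse = " ") else "-"
  cat(sprintf("<ucd_certificate %s> %s, age %g %s, year %d\n", x$id,
              c("male", "female")[x$sex + 1L], x$age_value, x$age_unit, x$year))
  for (i in seq_along(x$part1)) cat(sprintf("  I.%d : %s\n", i, fmt_line(x$part1[[i]])))
  for (i in seq_along(x$part2)) cat(sprintf("  II.%d: %s\n", i, fmt_line(x$part2[[i]])))
  if (!is.na(x$gold_ucd)) cat(sprintf("  UCD : %s%s\n", x$gold_ucd,
                                      if (isTRUE(x$rejected)) " (rejected)" else ""))
  invisible(x)
}

#' Demographic factorization of a certificate
#'
#' @param cert A `ucd_certificate`.
#' @param base_year First calendar year of the modelled period.
#' @param n_years Number of year states (default 16, i.e. 2000-2015).
#' @return List with integer `age_bin` (0..24), `gender` (0 = male,
#'   1 = female) and `year_index` (0..n_years-1).
#' @export
demographics <- function(cert, base_year = 2000L, n_years = 16L) {
  stopifnot(inherits(cert, "ucd_certificate"))
  yi <- cert$year - as.integer(base_year)
  if (yi < 0 || yi >= n_years) {
    stop(sprintf("year %d outside modelled range %d-%d", cert$year,
                 base_year, base_year + n_years - 1))
  }
  list(
    age_bin = bin_age(cert$age_value, cert$age_unit),
    gender = cert$sex,
    year_index = as.integer(yi)
  )
}

#' Encode a certificate as a padded code-index grid
#'
#' The causal chain is laid out on a fixed `L x W` grid (default 6-by-20):
#' Part I lines occupy rows 1-4 and Part II lines rows 5-6, each line
#' left-justified in written order with the remainder padding. Codes absent
#' from the vocabulary map to `unknown_index`.
#'
#' @param cert A `ucd_certificate`.
#' @param vocab A `ucd_vocabulary`.
#' @param L,W Grid dimensions; `L >= 6`, and every line must fit in `W`.
#' @return Integer `L x W` matrix of vocabulary indices (pad cells = 0).
#' @export
encode_grid <- function(cert, vocab, L = 6L, W = 20L) {
  stopifnot(inherits(cert, "ucd_certificate"), inherits(vocab, "ucd_vocabulary"))
  if (L < 6) stop("L must be at least 6 (4 Part I rows + 2 Part II rows)")
  g <- matrix(vocab$pad_index, nrow = L, ncol = W)
  lines <- c(cert$part1, rep(list(character(0)), 4 - length(cert$part1)),
             cert$part2, rep(list(character(0)), 2 - length(cert$part2)))
  for (r in seq_along(lines)) {
    l <- lines[[r]]
    if (length(l) > W) {
      stop(sprintf(
        "line %d holds %d codes but the grid width is %d; bigger certificates can be processed with an appropriately larger code matrix encoding (enlarge W)",
        r, length(l), W))
    }
    if (length(l)) g[r, seq_along(l)] <- index_of(vocab, l)
  }
  g
}

#' Decode a code-index grid back into certificate lines
#'
#' Row-wise scan recovering the input lines; inverse of [encode_grid()] for
#' certificates whose codes are all in the vocabulary (unknown cells decode
#' to `NA`).
#'
#' @param grid Integer matrix from [encode_grid()].
#' @param vocab The matching `ucd_vocabulary`.
#' @return List with `part1` (4 character vectors) and `part2` (2).
#' @export
decode_grid <- function(grid, vocab) {
  stopifnot(inherits(vocab, "ucd_vocabulary"))
  row_codes <- function(r) {
    idx <- grid[r, ]
    idx <- idx[seq_len(max(0, max(c(0, which(idx != vocab$pad_index)))))]
    out <- ifelse(idx == vocab$unknown_index, NA_character_, vocab$codes[idx])
    out
  }
  list(part1 = lapply(1:4, row_codes), part2 = lapply(5:6, row_codes))
}

cert_columns <- c("id", "year", "sex", "age_value", "age_unit",
                  "l1", "l2", "l3", "l4", "p2l1", "p2l2", "ucd", "rejected")

#' Read certificates from the certificate CSV dialect
#'
#' Comma-separated with header
#' `id,year,sex,age_value,age_unit,l1,l2,l3,l4,p2l1,p2l2,ucd,rejected`;
#' line cells hold space-separated ICD-10 codes, an empty cell is an empty
#' line; `ucd` and `rejected` are optional columns.
#'
#' @param path File path.
#' @param base_year,n_years Modelled year range used for validation.
#' @return List of `ucd_certificate`.
#' @export
read_certificates <- function(path, base_year = 2000L, n_years = 16L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  req <- setdiff(cert_columns, c("ucd", "rejected"))
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop(sprintf("certificate file missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  has_ucd <- "ucd" %in% names(df)
  has_rej <- "rejected" %in% names(df)
  split_line <- function(s) {
    if (is.na(s) || !nzchar(trimws(s))) character(0)
    else strsplit(trimws(s), "\\s+")[[1]]
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    cert <- tryCatch({
      year <- as.integer(df$year[i])
      if (is.na(year) || year < base_year || year > base_year + n_years - 1) {
        stop(sprintf("year '%s' outside modelled range %d-%d", df$year[i],
                     base_year, base_year + n_years - 1))
      }
      ucd <- if (has_ucd && nzchar(df$ucd[i])) df$ucd[i] else NA_character_
      rej <- if (has_rej && nzchar(df$rejected[i])) df$rejected[i] == "1" else NA
      new_certificate(
        id = df$id[i],
        part1 = lapply(df[i, c("l1", "l2", "l3", "l4")], split_line),
        part2 = lapply(df[i, c("p2l1", "p2l2")], split_line),
        sex = df$sex[i], age_value = as.numeric(df$age_value[i]),
        age_unit = df$age_unit[i], year = year, gold_ucd = ucd, rejected = rej
      )
    }, error = function(e) {
      stop(sprintf("row %d of '%s': %s", i, path, conditionMessage(e)),
           call. = FALSE)
    })
    out[[i]] <- cert
  }
  out
}

#' Write certificates in the certificate CSV dialect
#'
#' @param certs List of `ucd_certificate`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_certificates <- function(certs, path) {
  join <- function(l) if (length(l)) paste(l, collapse = " ") else ""
  line_of <- function(cert, part, k) {
    lines <- cert[[part]]
    if (k <= length(lines)) join(lines[[k]]) else ""
  }
  df <- data.frame(
    id = vapply(certs, `[[`, "", "id"),
    year = vapply(certs, `[[`, 0L, "year"),
    sex = c("M", "F")[vapply(certs, `[[`, 0L, "sex") + 1L],
    age_value = vapply(certs, `[[`, 0, "age_value"),
    age_unit = vapply(certs, `[[`, "", "age_unit"),
    l1 = vapply(certs, line_of, "", "part1", 1),
    l2 = vapply(certs, line_of, "", "part1", 2),
    l3 = vapply(certs, line_of, "", "part1", 3),
    l4 = vapply(certs, line_of, "", "part1", 4),
    p2l1 = vapply(certs, line_of, "", "part2", 1),
    p2l2 = vapply(certs, line_of, "", "part2", 2),
    ucd = vapply(certs, function(c) if (is.na(c$gold_ucd)) "" else c$gold_ucd, ""),
    rejected = vapply(certs, function(c) {
      if (is.na(c$rejected)) "" else if (c$rejected) "1" else "0"
    }, ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
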