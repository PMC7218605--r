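#' Parse and normalize an ICD-10 code token
#'
#' ICD-10 codes are one uppercase letter followed by 2 or 3 digits. Tokens are
#' normalized to the canonical dotless, uppercase form used throughout the
#' package (`"f11.2"` becomes `"F112"`).
#'
#' @param token Character vector of raw code tokens.
#' @return Character vector of normalized codes.
#' @examples
#' parse_code("F11")
#' parse_code("f11.2")
#' @export
parse_code <- function(token) {
  if (length(token) == 0) stop("no code token supplied")
  if (!is.character(token)) token <- as.character(token)
  norm <- toupper(gsub(".", "", trimws(token), fixed = TRUE))
  bad <- !grepl("^[A-Z][0-9]{2,3}$", norm)
  if (any(bad)) {
    stop(sprintf(
      "malformed ICD-10 code token(s): %s",
      paste(sprintf("'%s'", token[bad]), collapse = ", ")
    ))
  }
  norm
}

icd10_chapter_table_env <- new.env(parent = emptyenv())

#' ICD-10 chapter range table
#'
#' The 22 ICD-10 chapters as letter + numeric code ranges, read from the
#' bundled fixture (`inst/extdata/icd10_chapters.csv`).
#'
#' @return A data.frame with columns `start`, `end`, `chapter`, `description`.
#' @export
icd10_chapters <- function() {
  if (is.null(icd10_chapter_table_env$table)) {
    path <- system.file("extdata", "icd10_chapters.csv", package = "ucdcoder")
    if (path == "") {
      # during in-source development
      path <- file.path("inst", "extdata", "icd10_chapters.csv")
    }
    icd10_chapter_table_env$table <-
      utils::read.csv(path, stringsAsFactors = FALSE)
  }
  icd10_chapter_table_env$table
}

# numeric sort key: letter rank * 100 + first two digits
code_sort_key <- function(codes) {
  (match(substr(codes, 1, 1), LETTERS)) * 100L +
    as.integer(substr(codes, 2, 3))
}

#' Map ICD-10 codes to their chapter
#'
#' For real ICD-10 codes, the chapter is looked up in the bundled chapter
#' range table; for codes of a synthetic vocabulary the chapter declared at
#' vocabulary construction is used. Codes falling in ranges the classification
#' leaves unassigned map to `NA`.
#'
#' @param code Character vector of (normalizable) code tokens.
#' @param vocab Optional [build_vocabulary()] vocabulary whose declared
#'   chapter map takes precedence.
#' @return Character vector of chapter labels (Roman numerals).
#' @examples
#' chapter_of("H00")  # "VII", diseases of the eye and adnexa
#' chapter_of("X42")  # "XX", external causes
#' @export
chapter_of <- function(code, vocab = NULL) {
  code <- parse_code(code)
  out <- rep(NA_character_, length(code))
  if (!is.null(vocab)) {
    stopifnot(inherits(vocab, "ucd_vocabulary"))
    hit <- match(code, names(vocab$chapters))
    out[!is.na(hit)] <- unname(vocab$chapters[hit[!is.na(hit)]])
    if (!anyNA(out)) return(out)
    todo <- is.na(out)
  } else {
    todo <- rep(TRUE, length(code))
  }
  tab <- icd10_chapters()
  key <- code_sort_key(code[todo])
  lo <- code_sort_key(tab$start)
  hi <- code_sort_key(tab$end)
  idx <- vapply(key, function(k) {
    w <- which(k >= lo & k <= hi)
    if (length(w) == 0) NA_integer_ else w[1]
  }, integer(1))
  out[todo] <- ifelse(is.na(idx), NA_character_, tab$chapter[idx])
  out
}

#' Build a code vocabulary
#'
#' Deduplicates and lexicographically orders the codes observed in a corpus,
#' assigning each the integer index `1..V` used by the grid encoding and the
#' coder's embedding table. Index 0 is reserved for padding and `V + 1` for
#' codes unseen at training time.
#'
#' @param codes Character vector of code tokens (normalized on entry).
#' @param chapters Optional named character vector declaring the chapter of
#'   each code (used by synthetic vocabularies); when `NULL` chapters are
#'   derived from the ICD-10 chapter range table.
#' @return An object of class `ucd_vocabulary` with fields `codes`, `index`
#'   (named integer vector), `V`, `pad_index`, `unknown_index`, `chapters`.
#' @export
build_vocabulary <- function(codes, chapters = NULL) {
  if (length(codes) == 0) stop("cannot build a vocabulary from an empty code list")
  codes <- sort(unique(parse_code(codes)))
  V <- length(codes)
  if (is.null(chapters)) {
    chap <- chapter_of(codes)
  } else {
    hit <- match(codes, names(chapters))
    if (anyNA(hit)) {
      stop(sprintf("no declared chapter for code(s): %s",
                   paste(codes[is.na(hit)], collapse = ", ")))
    }
    chap <- unname(chapters[hit])
  }
  names(chap) <- codes
  structure(
    list(
      codes = codes,
      index = stats::setNames(seq_len(V), codes),
      V = V,
      pad_index = 0L,
      unknown_index = V + 1L,
      chapters = chap
    ),
    class = "ucd_vocabulary"
  )
}

#' @export
print.ucd_vocabulary <- function(x, ...) {
  cat(sprintf("<ucd_vocabulary> %d codes, %d chapters (pad=%d, unknown=%d)\n",
              x$V, length(unique(x$chapters)), x$pad_index, x$unknown_index))
  invisible(x)
}

#' Map codes to vocabulary indices
#'
#' Codes absent from the vocabulary map to `unknown_index` rather than
#' erroring: certificates seen at inference time routinely contain codes
#' unseen in training.
#'
#' @param vocab A `ucd_vocabulary`.
#' @param codes Character vector of normalized codes.
#' @return Integer vector of indices in `1..V` or `unknown_index`.
#' @export
index_of <- function(vocab, codes) {
  stopifnot(inherits(vocab, "ucd_vocabulary"))
  if (length(codes) == 0) return(integer(0))
  i <- unname(vocab$index[codes])
  i[is.na(i)] <- vocab$unknown_index
  i
}

#' Generate a synthetic vocabulary
#'
#' Synthetic codes are one letter per chapter plus a zero-padded 2-digit
#' number drawn without replacement, so they satisfy the ICD-10 token shape
#' and carry a declared chapter map. Deterministic for a fixed seed.
#'
#' @param n_chapters Number of chapters (2..26).
#' @param codes_per_chapter Codes per chapter (2..100).
#' @param seed Integer seed controlling which code numbers are drawn.
#' @return A `ucd_vocabulary` with `n_chapters * codes_per_chapter` codes.
#' @export
make_synthetic_vocabulary <- function(n_chapters, codes_per_chapter, seed = 1L) {
  if (n_chapters < 2 || n_chapters > 26) stop("n_chapters must be in 2..26")
  if (codes_per_chapter < 2 || codes_per_chapter > 100) {
    stop("codes_per_chapter must be in 2..100")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  codes <- character(0)
  chapters <- character(0)
  for (i in seq_len(n_chapters)) {
    nums <- sort(sample.int(100L, codes_per_chapter) - 1L)
    ch_codes <- sprintf("%s%02d", LETTERS[i], nums)
    codes <- c(codes, ch_codes)
    chapters <- c(chapters,
                  stats::setNames(rep(as.character(utils::as.roman(i)),
                                      codes_per_chapter), ch_codes))
  }
  build_vocabulary(codes, chapters = chapters)
}

#' Read / write a code-list file
#'
#' Two-column CSV `code,chapter` with header, UTF-8.
#'
#' @param path File path.
#' @return `read_code_list()` returns a `ucd_vocabulary`.
#' @export
read_code_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "chapter") %in% names(df))) {
    stop("code-list file must have columns 'code' and 'chapter'")
  }
  codes <- parse_code(df$code)
  build_vocabulary(codes, chapters = stats::setNames(df$chapter, codes))
}

#' @rdname read_code_list
#' @param vocab A `ucd_vocabulary` to serialize.
#' @export
write_code_list <- function(vocab, path) {
  stopifnot(inherits(vocab, "ucd_vocabulary"))
  utils::write.csv(
    data.frame(code = vocab$codes, chapter = unname(vocab$chapters)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Fingerprint of a vocabulary
#'
#' 32-bit FNV-1a hash of the ordered code list, stored in trained coders and
#' checked at inference so a model is never silently applied with the wrong
#' index mapping.
#'
#' @param vocab A `ucd_vocabulary`.
#' @return Hex string.
#' @export
vocab_fingerprint <- function(vocab) {
  stopifnot(inherits(vocab, "ucd_vocabulary"))
  fnv1a32(paste(vocab$codes, collapse = ","))
}
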