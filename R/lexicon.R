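#' Word-category lexicons
#'
#' A `lexicon` is a named category of words used for dictionary-based
#' (LIWC-style) text scoring. Entries are either literal tokens
#' (`"heureux"`) or stem patterns with a trailing `*` (`"content*"`)
#' that match any token starting with the stem.
#'
#' @param name Category label, e.g. `"posemo"`.
#' @param entries Character vector of entries; a trailing `*` marks a stem.
#' @param source Free-text provenance note.
#'
#' @return An object of class `lexicon` with elements `name`, `literals`,
#'   `stems` (both lowercase, `*` removed from stems) and `source`.
#' @examples
#' lex <- lexicon("posemo", c("heureux", "content*"))
#' indicator_fraction(tokenize("je suis content aujourd'hui"), lex)
#' @export
lexicon <- function(name, entries, source = "user") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  entries <- unique(tolower(trimws(entries)))
  entries <- entries[nzchar(entries)]
  if (length(entries) == 0L)
    stop("lexicon '", name, "': entries must be non-empty")
  is_stem <- endsWith(entries, "*")
  stems <- sub("\\*$", "", entries[is_stem])
  literals <- entries[!is_stem]
  stems <- stems[nzchar(stems)]
  # a literal that is also one of its own stems is redundant; keep the stem
  literals <- setdiff(literals, literals[vapply(
    literals, function(w) any(stems == w), logical(1))])
  structure(
    list(name = name, literals = literals, stems = stems, source = source),
    class = "lexicon"
  )
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon> ", x$name, ": ", length(x$literals), " literal, ",
      length(x$stems), " stem entries (", x$source, ")\n", sep = "")
  invisible(x)
}

#' @rdname lexicon
#' @param x Object to test.
#' @export
is_lexicon <- function(x) inherits(x, "lexicon")

#' All entries of a lexicon in writable form
#' @param lex A [lexicon()].
#' @return Character vector; stems carry their trailing `*`.
#' @export
lexicon_entries <- function(lex) {
  stopifnot(is_lexicon(lex))
  c(lex$literals, if (length(lex$stems)) paste0(lex$stems, "*"))
}

#' Test whether a single lexicon entry matches a token
#'
#' Literal entries require exact equality; stem entries (trailing `*`)
#' match any token that starts with the stem, including the stem itself.
#'
#' @param entry Entry string, with trailing `*` for stems.
#' @param token Lowercase token.
#' @return Logical.
#' @examples
#' matches("solidar*", "solidarité")  # TRUE
#' matches("ami", "amis")                  # FALSE
#' @export
matches <- function(entry, token) {
  if (endsWith(entry, "*")) {
    startsWith(token, sub("\\*$", "", entry))
  } else {
    token == entry
  }
}

#' Vectorized membership of tokens in a lexicon
#'
#' For each token, whether it matches any entry (literal or stem) of
#' the lexicon. The workhorse behind all scoring.
#'
#' @param tokens Character vector of lowercase tokens.
#' @param lex A [lexicon()].
#' @return Logical vector, one element per token.
#' @export
match_tokens <- function(tokens, lex) {
  hit <- tokens %in% lex$literals
  for (s in lex$stems) hit <- hit | startsWith(tokens, s)
  hit
}

#' Tokenize raw tweet text
#'
#' Deterministic, accent-preserving, social-media-aware tokenization:
#' text is lowercased; URLs and `@`-mentions are removed entirely; the
#' `#` of a hashtag is stripped so the hashtag word remains; tokens are
#' maximal runs of Unicode letters, possibly joined by internal
#' apostrophes (`l'égalité` stays one token). Digit-only
#' strings and punctuation never form tokens.
#'
#' @param text Character vector of raw texts.
#' @return For length-1 input, a character vector of tokens; otherwise a
#'   list of token vectors (see [tokenize_all()]).
#' @examples
#' tokenize("Je suis à #Paris http://t.co/x @ami")
#' @export
tokenize <- function(text) {
  out <- tokenize_all(text)
  if (length(out) == 1L) out[[1L]] else out
}

#' @rdname tokenize
#' @export
tokenize_all <- function(text) {
  text <- as.character(text)
  n <- length(text)
  if (n == 0L) return(list())
  x <- stringi::stri_trans_tolower(text)
  x <- stringi::stri_replace_all_regex(x, "(https?://|www\\.)\\S+", " ")
  x <- stringi::stri_replace_all_regex(x, "@[A-Za-z0-9_]+", " ")
  x <- stringi::stri_replace_all_fixed(x, "#", "")
  toks <- stringi::stri_extract_all_regex(
    x, "\\p{L}+(?:['’]\\p{L}+)*", omit_no_match = TRUE)
  toks[is.na(text)] <- list(character(0))
  toks
}

#' Fraction of a text's tokens that belong to a word category
#'
#' The lexical indicator of a text: the share of its tokens matching any
#' entry of the lexicon. A token matching several entries counts once.
#'
#' @param tokens Character vector of lowercase tokens (as produced by
#'   [tokenize()]).
#' @param lex A [lexicon()].
#' @return Fraction in `[0, 1]`, or `NA_real_` for an empty token vector.
#' @export
indicator_fraction <- function(tokens, lex) {
  stopifnot(is_lexicon(lex))
  if (length(tokens) == 0L) return(NA_real_)
  sum(match_tokens(tokens, lex)) / length(tokens)
}

#' Per-text indicator fractions over a corpus
#'
#' Vectorized scoring of many texts against one lexicon.
#'
#' @param texts Character vector of raw texts, or a list of token
#'   vectors (already tokenized).
#' @param lex A [lexicon()].
#' @return Numeric vector of fractions, `NA` where a text has no tokens.
#' @export
indicator_fractions <- function(texts, lex) {
  stopifnot(is_lexicon(lex))
  toks <- if (is.list(texts)) texts else tokenize_all(texts)
  n_tok <- lengths(toks)
  out <- rep(NA_real_, length(toks))
  keep <- n_tok > 0L
  if (!any(keep)) return(out)
  flat <- unlist(toks[keep], use.names = FALSE)
  idx <- rep.int(seq_len(sum(keep)), n_tok[keep])
  hits <- match_tokens(flat, lex)
  out[keep] <- as.numeric(rowsum(as.numeric(hits), idx)) / n_tok[keep]
  out
}

#' Percent increase of a category between two corpora
#'
#' Dictionary-validation statistic: by how many percent the mean
#' per-text indicator fraction of `corpus_a` exceeds that of `corpus_b`
#' (e.g. sentiment-annotated positive tweets vs a control sample).
#'
#' @param corpus_a,corpus_b Character vectors of raw texts (or lists of
#'   token vectors).
#' @param lex A [lexicon()].
#' @return `100 * (mean_a / mean_b - 1)`; texts with no tokens are
#'   excluded from the means.
#' @export
validate_percent_increase <- function(corpus_a, corpus_b, lex) {
  if (length(corpus_a) == 0L || length(corpus_b) == 0L)
    stop("both corpora must be non-empty")
  m_a <- mean(indicator_fractions(corpus_a, lex), na.rm = TRUE)
  m_b <- mean(indicator_fractions(corpus_b, lex), na.rm = TRUE)
  if (!is.finite(m_b) || m_b <= 0)
    stop("undefined baseline: corpus_b has mean indicator 0 for '",
         lex$name, "'")
  100 * (m_a / m_b - 1)
}

# ---- LIWC .dic dialect -------------------------------------------------

#' Read a LIWC-dialect `.dic` dictionary file
#'
#' Parses the `%`-delimited dialect: a header block between two lines
#' containing only `%`, with one `id<TAB>name` pair per line, followed by
#' word lines `word<TAB>id[<TAB>id...]`. Words ending in `*` become stem
#' entries.
#'
#' @param path Path to the `.dic` file.
#' @return Named list of [lexicon()] objects, one per header category.
#' @export
read_liwc_dic <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  pct <- which(trimws(lines) == "%")
  if (length(pct) < 2L)
    stop("malformed .dic header in '", path,
         "': expected two '%' delimiter lines")
  hdr <- lines[(pct[1L] + 1L):(pct[2L] - 1L)]
  hdr <- hdr[nzchar(trimws(hdr))]
  if (length(hdr) == 0L) stop("empty .dic category header in '", path, "'")
  parts <- strsplit(trimws(hdr), "[\t ]+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("malformed .dic header line ", pct[1L] + bad[1L], ": '",
         hdr[bad[1L]], "'")
  ids <- vapply(parts, `[[`, "", 1L)
  names_ <- vapply(parts, `[[`, "", 2L)
  if (anyDuplicated(ids))
    stop("duplicate category id in .dic header: ",
         ids[duplicated(ids)][1L])
  words <- stats::setNames(vector("list", length(ids)), ids)
  body_start <- pct[2L] + 1L
  if (body_start <= length(lines)) {
    for (i in body_start:length(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln)) next
      fields <- strsplit(ln, "[\t ]+")[[1L]]
      w <- fields[1L]
      cat_ids <- fields[-1L]
      if (length(cat_ids) == 0L)
        stop(".dic word line ", i, " ('", w, "') lists no category id")
      unknown <- setdiff(cat_ids, ids)
      if (length(unknown))
        stop(".dic word line ", i, " ('", w,
             "') references unknown category id ", unknown[1L])
      for (ci in cat_ids) words[[ci]] <- c(words[[ci]], w)
    }
  }
  empty <- ids[lengths(words) == 0L]
  if (length(empty))
    stop("empty .dic category: ", paste(names_[ids %in% empty],
                                        collapse = ", "))
  out <- lapply(seq_along(ids), function(k)
    lexicon(names_[k], words[[k]], source = paste0("dic:", basename(path))))
  stats::setNames(out, names_)
}

#' Write lexicons to a LIWC-dialect `.dic` file
#'
#' Inverse of [read_liwc_dic()]: re-reading the written file recovers
#' the same entry sets.
#'
#' @param lexicons List of [lexicon()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_liwc_dic <- function(lexicons, path) {
  stopifnot(all(vapply(lexicons, is_lexicon, logical(1))))
  ids <- as.character(seq_along(lexicons))
  hdr <- paste(ids, vapply(lexicons, `[[`, "", "name"), sep = "\t")
  word_map <- list()
  for (k in seq_along(lexicons)) {
    for (w in lexicon_entries(lexicons[[k]]))
      word_map[[w]] <- c(word_map[[w]], ids[k])
  }
  body <- vapply(names(word_map), function(w)
    paste(c(w, word_map[[w]]), collapse = "\t"), "")
  writeLines(c("%", hdr, "%", body), path, useBytes = TRUE)
  invisible(path)
}

#' Read or write lexicons as plain JSON
#'
#' The plain format is a JSON object mapping category name to an array
#' of entries (trailing `*` marks stems).
#'
#' @param path File path.
#' @return `read_lexicon_json()`: named list of [lexicon()] objects.
#' @export
read_lexicon_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(obj) || is.null(names(obj)))
    stop("plain lexicon JSON must be an object mapping name -> word list")
  out <- lapply(names(obj), function(nm)
    lexicon(nm, as.character(obj[[nm]]),
            source = paste0("json:", basename(path))))
  stats::setNames(out, names(obj))
}

#' @rdname read_lexicon_json
#' @param lexicons Named list of [lexicon()] objects.
#' @export
write_lexicon_json <- function(lexicons, path) {
  obj <- lapply(lexicons, lexicon_entries)
  names(obj) <- vapply(lexicons, `[[`, "", "name")
  jsonlite::write_json(obj, path, pretty = TRUE)
  invisible(path)
}
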