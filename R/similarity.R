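#' Length-weighted Levenshtein name similarity
#'
#' Base similarity is `1 - levenshtein(a, b) / max(|a|, |b|)`, multiplied by
#' a length-difference weight `(min(|a|,|b|) / max(|a|,|b|))^length_exponent`
#' so that a short string embedded in a much longer one does not score as a
#' near match. Identical non-empty strings score 1; if either string is empty
#' or missing the score is 0. Symmetric in its arguments.
#'
#' @param a,b character vectors, recycled to a common length.
#' @param length_exponent exponent of the length-ratio weight; 0 disables
#'   length weighting.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
name_similarity <- function(a, b, length_exponent = 0.5) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  la <- nchar(a); lb <- nchar(b)
  out <- numeric(n)
  ok <- !is.na(a) & !is.na(b) & la > 0 & lb > 0
  if (any(ok)) {
    d <- mapply(function(x, y) adist(x, y)[1, 1], a[ok], b[ok],
                USE.NAMES = FALSE)
    mx <- pmax(la[ok], lb[ok]); mn <- pmin(la[ok], lb[ok])
    out[ok] <- pmax(0, 1 - d / mx) * (mn / mx)^length_exponent
  }
  out
}

# similarity of one string against many (row of an adist matrix); used on
# blocked candidate sets where it is much cheaper than pairwise mapply
similarity_to_many <- function(a, bs, length_exponent = 0.5) {
  if (length(bs) == 0) return(numeric(0))
  la <- nchar(a); lb <- nchar(bs)
  ok <- !is.na(bs) & lb > 0
  out <- numeric(length(bs))
  if (is.na(a) || la == 0) return(out)
  if (any(ok)) {
    d <- as.numeric(adist(a, bs[ok]))
    mx <- pmax(la, lb[ok]); mn <- pmin(la, lb[ok])
    out[ok] <- pmax(0, 1 - d / mx) * (mn / mx)^length_exponent
  }
  out
}

#' American Soundex phonetic key
#'
#' Standard 4-character Soundex code (initial letter plus three digits),
#' used for blocking candidate comparisons in deduplication and linkage.
#'
#' @param x character vector of single tokens.
#' @return character vector of Soundex codes.
#' @export
soundex <- function(x) {
  vapply(toupper(x), function(s) {
    s <- gsub("[^A-Z]", "", s)
    if (!nzchar(s)) return("0000")
    ch <- strsplit(s, "")[[1]]
    codes <- c(B = "1", F = "1", P = "1", V = "1",
               C = "2", G = "2", J = "2", K = "2", Q = "2", S = "2",
               X = "2", Z = "2", D = "3", T = "3", L = "4",
               M = "5", N = "5", R = "6")
    dig <- codes[ch]
    dig[is.na(dig)] <- ifelse(ch[is.na(dig)] %in% c("H", "W"), "-", "0")
    # collapse runs of the same digit (H/W transparent, vowels break runs)
    out <- character(0)
    prev <- dig[1]
    for (i in seq_along(dig)[-1]) {
      if (dig[i] == "-") next
      if (dig[i] != "0" && dig[i] != prev) out <- c(out, dig[i])
      prev <- dig[i]
    }
    out <- out[out != "0"]
    substr(paste0(ch[1], paste(out, collapse = ""), "000"), 1, 4)
  }, character(1), USE.NAMES = FALSE)
}

# blocking keys for a full name: Soundex of the first and of the last token
block_keys <- function(name) {
  toks <- strsplit(ifelse(is.na(name), "", name), " ", fixed = TRUE)
  first <- vapply(toks, function(t) if (length(t)) t[1] else "", character(1))
  last <- vapply(toks, function(t) if (length(t)) t[length(t)] else "",
                 character(1))
  tibble(key1 = soundex(first), key2 = soundex(last))
}
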