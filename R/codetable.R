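#' Fixed-length character-to-nucleotide code tables
#'
#' A code table is an ordered bijection between characters and fixed-length
#' nucleotide codewords of `word_length` bases, together with an ordered
#' free pool of unassigned codewords used to extend the table with characters
#' encountered after construction. Codewords are enumerated lexicographically
#' under the base order A < C < G < T, so the same character list always
#' yields the same table. The last free-pool codeword is reserved as the
#' padding codeword (it stays in the pool but is never handed out by
#' [extend_table()]); the associated padding character fills the final,
#' partially used record of a document.
#'
#' @name code-tables
NULL

# Reserved padding character (open-box symbol); never a payload character.
PAD_CHAR <- "␣"

#' Minimum codeword length for a character set
#'
#' Smallest `n >= 1` with `4^n >= K`: the shortest fixed codeword length
#' whose capacity `4^n` covers `K` characters.
#'
#' @param K Number of characters (positive integer).
#' @return Codeword length in nucleotides.
#' @examples
#' min_word_length(16)    # 2
#' min_word_length(7445)  # 7
#' @export
min_word_length <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K < 1) {
    stop("K must be a positive integer", call. = FALSE)
  }
  n <- 1L
  while (4^n < K) n <- n + 1L
  n
}

#' Capacity of a codeword length
#'
#' @param n Codeword length in nucleotides (>= 1).
#' @return `4^n`, the number of distinct codewords.
#' @examples
#' table_capacity(7)  # 16384
#' @export
table_capacity <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  as.integer(4^n)
}

# All 4^n codewords in lexicographic order under A < C < G < T.
enumerate_codewords <- function(n) {
  words <- DNA_BASES
  if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      words <- as.vector(t(outer(words, DNA_BASES, paste0)))
    }
  }
  words
}

#' Build a code table
#'
#' Assigns codewords, in lexicographic enumeration order, to `characters` in
#' their given order; the remaining codewords form the free pool in the same
#' order. Deterministic: the same input always produces a byte-identical
#' persisted table.
#'
#' @param characters Character vector of distinct single characters.
#' @param n Codeword length; defaults to [min_word_length()] of the input
#'   (at least 1).
#' @return An object of class `code_table`.
#' @examples
#' tab <- code_table(c("甲", "乙"), n = 1)
#' @export
code_table <- function(characters = character(), n = NULL) {
  characters <- as.character(characters)
  if (anyNA(characters)) stop("characters must not contain NA", call. = FALSE)
  if (length(characters) && any(nchar(characters) != 1L)) {
    stop("each table entry must be a single character", call. = FALSE)
  }
  if (anyDuplicated(characters)) {
    stop("duplicate characters in table input", call. = FALSE)
  }
  if (PAD_CHAR %in% characters) {
    stop(sprintf("the padding character '%s' is reserved", PAD_CHAR),
         call. = FALSE)
  }
  if (is.null(n)) n <- min_word_length(max(1L, length(characters)))
  n <- as.integer(n)
  M <- table_capacity(n)
  K <- length(characters)
  if (K > M) {
    stop(sprintf("capacity exceeded: %d characters but 4^%d = %d codewords",
                 K, n, M), call. = FALSE)
  }
  words <- enumerate_codewords(n)
  tab <- structure(
    list(
      word_length = n,
      chars = characters,
      codewords = words[seq_len(K)],
      free_pool = if (K < M) words[seq.int(K + 1L, M)] else character(),
      extension_key = data.frame(char = character(), codeword = character(),
                                 stringsAsFactors = FALSE)
    ),
    class = "code_table"
  )
  tab$pad <- pad_codeword(tab)
  tab
}

#' @export
print.code_table <- function(x, ...) {
  cat(sprintf(paste0("<code_table> word length %d nt, %d entries, ",
                     "%d free codewords, %d extensions\n"),
              x$word_length, length(x$chars), length(x$free_pool),
              nrow(x$extension_key)))
  invisible(x)
}

#' @export
length.code_table <- function(x) length(x$chars)

# The reserved padding codeword: the last free-pool codeword whose
# repetition is itself constraint-compliant (no run over 3 across a w+w
# junction, GC of the word within [0.4, 0.6]), so that a padded final chunk
# does not enter the shift search carrying an unbreakable homopolymer. When
# no pool codeword qualifies (tiny tables), falls back to the plain last
# codeword. Tables at full capacity have no pool and cannot pad.
pad_codeword <- function(table) {
  if (!is.null(table$pad)) return(table$pad)
  pool <- table$free_pool
  if (!length(pool)) return(NA_character_)
  for (w in rev(pool)) {
    twice <- paste0(w, w)
    if (max_homopolymer(twice) <= 3L) {
      gc <- gc_content(w)
      if (gc >= 0.4 && gc <= 0.6) return(w)
    }
  }
  pool[length(pool)]
}

#' Extend a table with a new character
#'
#' Binds `ch` to the first free-pool codeword, removes that codeword from
#' the pool, and appends the pair to the extension key (the "decryption key"
#' shipped alongside encoded documents so a stock table can decode them).
#' Extending with an already-mapped character is a warning no-op. The
#' reserved padding codeword (last in the pool) is never allocated.
#'
#' @param table A [code_table()].
#' @param ch A single character.
#' @return The updated table, invisibly carrying the assigned codeword in
#'   attribute `"codeword"`.
#' @export
extend_table <- function(table, ch) {
  stopifnot(inherits(table, "code_table"), is.character(ch), nchar(ch) == 1L)
  hit <- match(ch, table$chars)
  if (!is.na(hit)) {
    warning(sprintf("character '%s' already mapped to %s; table unchanged",
                    ch, table$codewords[hit]), call. = FALSE)
    attr(table, "codeword") <- table$codewords[hit]
    return(table)
  }
  pad <- pad_codeword(table)
  candidates <- setdiff(table$free_pool, pad)
  if (!length(candidates)) {
    stop("code table capacity exhausted: no free codewords beyond the pad",
         call. = FALSE)
  }
  cw <- candidates[1L]
  table$free_pool <- table$free_pool[table$free_pool != cw]
  table$chars <- c(table$chars, ch)
  table$codewords <- c(table$codewords, cw)
  table$extension_key <- rbind(
    table$extension_key,
    data.frame(char = ch, codeword = cw, stringsAsFactors = FALSE)
  )
  attr(table, "codeword") <- cw
  table
}

#' Encode characters as nucleotides
#'
#' Concatenates the codeword of each character of `text`. With
#' `auto_extend = TRUE`, characters missing from the table are first bound
#' to free-pool codewords via [extend_table()]; the grown table is returned
#' in attribute `"table"` so the caller can persist the extension key.
#'
#' @param table A [code_table()].
#' @param text String to encode.
#' @param auto_extend Extend the table for unknown characters?
#' @return Nucleotide string of length `nchar(text) * word_length`, with the
#'   (possibly extended) table in attribute `"table"`.
#' @export
chars_to_nt <- function(table, text, auto_extend = FALSE) {
  stopifnot(inherits(table, "code_table"), is.character(text),
            length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  idx <- match(chars, table$chars)
  if (anyNA(idx)) {
    missing_chars <- unique(chars[is.na(idx)])
    if (!auto_extend) {
      stop(sprintf("characters not in code table: %s",
                   paste(missing_chars, collapse = " ")), call. = FALSE)
    }
    for (ch in missing_chars) table <- extend_table(table, ch)
    idx <- match(chars, table$chars)
  }
  # PAD encodes via the reserved codeword, resolved outside the entries map.
  out <- table$codewords[idx]
  if (anyNA(idx)) {
    stop("internal error: unresolved characters after extension",
         call. = FALSE)
  }
  res <- paste(out, collapse = "")
  attr(res, "table") <- table
  res
}

#' Decode nucleotides back to characters
#'
#' @param table A [code_table()] (including any extensions used at encode
#'   time).
#' @param seq Nucleotide string; its length must be a multiple of the
#'   table's word length.
#' @param keep_pad Keep padding characters in the output? (Framing strips
#'   them itself.)
#' @return The decoded character string.
#' @export
nt_to_chars <- function(table, seq, keep_pad = TRUE) {
  stopifnot(inherits(table, "code_table"))
  assert_dna(seq, allow_empty = TRUE)
  n <- table$word_length
  L <- nchar(seq)
  if (L %% n != 0L) {
    stop(sprintf("sequence length %d is not a multiple of word length %d",
                 L, n), call. = FALSE)
  }
  if (L == 0L) return("")
  starts <- seq.int(1L, L, by = n)
  words <- substring(seq, starts, starts + n - 1L)
  idx <- match(words, table$codewords)
  pad <- pad_codeword(table)
  is_pad <- !is.na(pad) & words == pad
  if (any(is.na(idx) & !is_pad)) {
    bad <- which(is.na(idx) & !is_pad)[1L]
    stop(sprintf("unknown codeword '%s' at nt offset %d",
                 words[bad], starts[bad] - 1L), call. = FALSE)
  }
  chars <- ifelse(is_pad, PAD_CHAR, table$chars[idx])
  if (!keep_pad) chars <- chars[chars != PAD_CHAR]
  paste(chars, collapse = "")
}

#' Persist and restore code tables
#'
#' Tables are stored as UTF-8 TSV with a `char<TAB>codeword` header, one
#' entry per row in table order; the extension key uses the same dialect in
#' its own file. `load_table(save_table(t))` reproduces `t` exactly,
#' including free-pool order (recomputed from the lexicographic enumeration)
#' and the extension key.
#'
#' @param table A [code_table()].
#' @param path File path for the entries TSV.
#' @param key_path Optional path for the extension-key TSV (written only
#'   when extensions exist or `key_path` is given explicitly).
#' @return `save_table()`: `path`, invisibly. `load_table()`: the restored
#'   `code_table`.
#' @export
save_table <- function(table, path, key_path = NULL) {
  stopifnot(inherits(table, "code_table"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("char\tcodeword", con)
  if (length(table$chars)) {
    writeLines(paste(table$chars, table$codewords, sep = "\t"), con)
  }
  if (!is.null(key_path)) {
    save_extension_key(table$extension_key, key_path)
  }
  invisible(path)
}

#' @rdname save_table
#' @export
load_table <- function(path, key_path = NULL) {
  rows <- read_tsv_pairs(path)
  n <- if (nrow(rows)) unique(nchar(rows$codeword)) else 1L
  if (length(n) != 1L) {
    stop(sprintf("parse error in %s: codewords of differing lengths", path),
         call. = FALSE)
  }
  if (nrow(rows) && grepl("[^ACGT]", paste(rows$codeword, collapse = ""))) {
    bad <- which(grepl("[^ACGT]", rows$codeword))[1L]
    stop(sprintf("parse error in %s line %d: non-ACGT codeword", path,
                 bad + 1L), call. = FALSE)
  }
  if (anyDuplicated(rows$char)) {
    stop(sprintf("parse error in %s line %d: duplicate character", path,
                 anyDuplicated(rows$char) + 1L), call. = FALSE)
  }
  if (anyDuplicated(rows$codeword)) {
    stop(sprintf("parse error in %s line %d: duplicate codeword", path,
                 anyDuplicated(rows$codeword) + 1L), call. = FALSE)
  }
  key <- if (!is.null(key_path)) load_extension_key(key_path) else
    data.frame(char = character(), codeword = character(),
               stringsAsFactors = FALSE)
  rebuild_table(rows, n, key)
}

# Reconstruct a code_table from its persisted rows: the free pool is the
# lexicographic enumeration minus assigned codewords (head-of-pool
# allocation preserves enumeration order, so this is exact).
rebuild_table <- function(rows, n, key) {
  words <- enumerate_codewords(n)
  assigned <- match(rows$codeword, words)
  if (anyNA(assigned)) {
    stop("parse error: codeword of wrong length for table", call. = FALSE)
  }
  pool <- words[!(words %in% rows$codeword)]
  tab <- structure(
    list(word_length = as.integer(n), chars = rows$char,
         codewords = rows$codeword, free_pool = pool, extension_key = key),
    class = "code_table"
  )
  tab$pad <- pad_codeword(tab)
  tab
}

save_extension_key <- function(key, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("char\tcodeword", con)
  if (nrow(key)) writeLines(paste(key$char, key$codeword, sep = "\t"), con)
  invisible(path)
}

load_extension_key <- function(path) {
  read_tsv_pairs(path)
}

read_tsv_pairs <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines) || !identical(lines[1L], "char\tcodeword")) {
    stop(sprintf("parse error in %s line 1: expected 'char\\tcodeword' header",
                 path), call. = FALSE)
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(data.frame(char = character(), codeword = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("parse error in %s line %d: expected 2 tab-separated fields",
                 path, bad[1L] + 1L), call. = FALSE)
  }
  data.frame(char = vapply(parts, `[[`, character(1), 1L),
             codeword = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}
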