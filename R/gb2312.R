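#' The default GB2312 code table
#'
#' Enumerates the GB2312 character set in code-point order (symbol rows 1-9,
#' Hanzi rows 16-87, cells 1-94, decoded with `iconv`) — exactly 7,445
#' graphic characters — and builds the default 7-nt code table over it. With
#' `K = 7445` and `n = 7` the capacity is `4^7 = 16384`, leaving 8,939
#' unassigned codewords as extension space for characters outside GB2312.
#' The table is rebuilt deterministically at call time (and memoised for the
#' session), so no table file needs to be distributed.
#'
#' @param n Codeword length; default the minimum for the character count.
#' @return A [code_table()] over the GB2312 characters.
#' @examples
#' \donttest{
#' tab <- gb2312_table()
#' length(tab)           # 7445
#' tab$word_length       # 7
#' }
#' @export
gb2312_table <- function(n = NULL) {
  chars <- gb2312_characters()
  if (is.null(n)) n <- min_word_length(length(chars))
  key <- sprintf("table_n%d", n)
  cached <- .dnashift_cache[[key]]
  if (!is.null(cached)) return(cached)
  tab <- code_table(chars, n = n)
  .dnashift_cache[[key]] <- tab
  tab
}

#' @rdname gb2312_table
#' @export
gb2312_characters <- function() {
  cached <- .dnashift_cache[["chars"]]
  if (!is.null(cached)) return(cached)
  rows <- c(1:9, 16:87)
  grid <- expand.grid(col = 1:94, row = rows)
  bytes <- vapply(seq_len(nrow(grid)), function(k) {
    rawToChar(as.raw(c(0xA0 + grid$row[k], 0xA0 + grid$col[k])))
  }, character(1))
  chars <- iconv(bytes, "GB2312", "UTF-8")
  chars <- chars[!is.na(chars) & nchar(chars) == 1L]
  if (anyDuplicated(chars)) chars <- unique(chars)
  .dnashift_cache[["chars"]] <- chars
  chars
}

.dnashift_cache <- new.env(parent = emptyenv())
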