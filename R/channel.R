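#' Seeded synthetic text
#'
#' Samples `n_chars` characters uniformly (with replacement) from a code
#' table's character set — the padding character excluded — for reproducible
#' end-to-end fixtures. The caller's RNG stream is left untouched.
#'
#' @param n_chars Number of characters (>= 0).
#' @param table A non-empty [code_table()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A string of `n_chars` encodable characters.
#' @export
random_text <- function(n_chars, table = gb2312_table(), seed = NULL) {
  stopifnot(inherits(table, "code_table"))
  if (!is.numeric(n_chars) || length(n_chars) != 1L || is.na(n_chars) ||
      n_chars < 0) {
    stop("n_chars must be a nonnegative integer", call. = FALSE)
  }
  if (!length(table$chars)) stop("code table is empty", call. = FALSE)
  pool <- setdiff(table$chars, PAD_CHAR)
  with_seed(seed, paste(sample(pool, n_chars, replace = TRUE),
                        collapse = ""))
}

#' Substitution-error channel
#'
#' Replaces exactly `n_errors` bases of `seq`, at distinct positions, each
#' by a different uniformly chosen base, so the Hamming distance between
#' input and output equals `n_errors`. With `byte_group_distinct = TRUE`
#' the positions fall in distinct 4-nt groups, the regime in which an RS
#' code with `2 * n_errors` parity bytes is guaranteed to correct the
#' record. Insertions and deletions are deliberately not modelled.
#'
#' @param seq DNA string.
#' @param n_errors Number of substitutions, `<= nchar(seq)` (and `<=` the
#'   number of 4-nt groups when group-distinct).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param byte_group_distinct Place each error in a different 4-nt group?
#' @return The corrupted sequence, same length.
#' @export
corrupt <- function(seq, n_errors, seed = NULL,
                    byte_group_distinct = FALSE) {
  assert_dna(seq)
  L <- nchar(seq)
  n_errors <- as.integer(n_errors)
  if (n_errors < 0L || n_errors > L) {
    stop(sprintf("n_errors %d impossible for a %d-nt sequence",
                 n_errors, L), call. = FALSE)
  }
  if (n_errors == 0L) return(seq)
  with_seed(seed, {
    if (byte_group_distinct) {
      n_groups <- L %/% 4L
      if (n_errors > n_groups) {
        stop(sprintf("n_errors %d exceeds the %d complete 4-nt groups",
                     n_errors, n_groups), call. = FALSE)
      }
      groups <- sample(n_groups, n_errors)
      pos <- (groups - 1L) * 4L + sample(4L, n_errors, replace = TRUE)
    } else {
      pos <- sample(L, n_errors)
    }
    v <- nt_ints(seq)
    v[pos] <- (v[pos] + sample(3L, n_errors, replace = TRUE)) %% 4L
    ints_nt(v)
  })
}
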