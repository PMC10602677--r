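#' Record layouts
#'
#' One storable record is laid out as five nucleotide segments:
#' `index | data | mod | iterate | RS parity`. The index is a base-4
#' address; `data` holds `data_nt / word_length` character codewords; the
#' `mod` and `iterate` fields store the shift parameters found for the
#' record (zero-valued for untouched records); the parity segment holds
#' `rs_nt / 4` Reed-Solomon parity bytes computed over the packed bytes of
#' all preceding segments, so the shift parameters themselves are protected.
#'
#' Two presets mirror published configurations:
#' \describe{
#'   \item{`short128`}{index 8, data 105 (15 characters at 7 nt), mod 3,
#'     iterate 4, parity 8 nt (2 bytes, 1 correctable byte error); 128 nt
#'     total.}
#'   \item{`plasmid744`}{index 5, data 658 (94 characters), mod 4,
#'     iterate 5, parity 72 nt (18 bytes, 9 correctable byte errors);
#'     744 nt total.}
#' }
#'
#' @param index_nt,data_nt,mod_nt,iterate_nt,rs_nt Segment lengths in nt.
#' @param name Optional preset name carried into FASTA headers.
#' @param word_length Code-table word length the layout must divide into.
#' @return An object of class `record_layout`.
#' @examples
#' record_layout("plasmid744")$total_nt  # 744
#' @export
record_layout <- function(name = NULL, index_nt = NULL, data_nt = NULL,
                          mod_nt = NULL, iterate_nt = NULL, rs_nt = NULL,
                          word_length = 7L) {
  presets <- list(
    short128 = c(8L, 105L, 3L, 4L, 8L),
    plasmid744 = c(5L, 658L, 4L, 5L, 72L)
  )
  if (!is.null(name) && is.character(name)) {
    if (!name %in% names(presets)) {
      stop(sprintf("unknown layout preset '%s' (have: %s)", name,
                   paste(names(presets), collapse = ", ")), call. = FALSE)
    }
    p <- presets[[name]]
    index_nt <- p[1L]; data_nt <- p[2L]; mod_nt <- p[3L]
    iterate_nt <- p[4L]; rs_nt <- p[5L]
  } else if (is.numeric(name)) {
    stop("pass segment lengths by name (index_nt = ...)", call. = FALSE)
  }
  segs <- c(index_nt = index_nt, data_nt = data_nt, mod_nt = mod_nt,
            iterate_nt = iterate_nt, rs_nt = rs_nt)
  if (any(vapply(segs, is.null, logical(1))) || length(segs) != 5L) {
    stop("either a preset name or all five segment lengths are required",
         call. = FALSE)
  }
  segs <- vapply(segs, as.integer, integer(1))
  if (any(segs < 0L)) stop("segment lengths must be nonnegative",
                           call. = FALSE)
  if (segs[["data_nt"]] %% word_length != 0L) {
    stop(sprintf("data_nt %d is not a multiple of word length %d",
                 segs[["data_nt"]], word_length), call. = FALSE)
  }
  body <- sum(segs[c("index_nt", "data_nt", "mod_nt", "iterate_nt")])
  if (body %% 4L != 0L || segs[["rs_nt"]] %% 4L != 0L) {
    stop("index+data+mod+iterate and rs segments must pack into whole bytes",
         call. = FALSE)
  }
  if (body %/% 4L + segs[["rs_nt"]] %/% 4L > 255L) {
    stop("layout exceeds the 255-byte RS block", call. = FALSE)
  }
  structure(
    c(as.list(segs),
      list(total_nt = sum(segs) ,
           chars_per_record = segs[["data_nt"]] %/% word_length,
           word_length = as.integer(word_length),
           name = if (is.character(name)) name else "custom")),
    class = "record_layout"
  )
}

#' @export
print.record_layout <- function(x, ...) {
  cat(sprintf(paste0("<record_layout '%s'> index %d | data %d | mod %d | ",
                     "iterate %d | rs %d = %d nt (%d chars/record)\n"),
              x$name, x$index_nt, x$data_nt, x$mod_nt, x$iterate_nt,
              x$rs_nt, x$total_nt, x$chars_per_record))
  invisible(x)
}

#' Base-4 integer fields
#'
#' Nonnegative integers are stored big-endian in base 4 with digit map
#' A=0, C=1, G=2, T=3, zero-padded to the field width.
#'
#' @param v Nonnegative integer, `v < 4^width_nt`.
#' @param width_nt Field width in nt.
#' @return `int_to_nt()`: a nucleotide string; `nt_to_int()`: an integer.
#' @examples
#' int_to_nt(1, 5)     # "AAAAC"
#' nt_to_int("AAAAC")  # 1
#' @export
int_to_nt <- function(v, width_nt) {
  stopifnot(is.numeric(v), length(v) == 1L, v >= 0, width_nt >= 0)
  v <- as.numeric(v)
  if (v >= 4^width_nt) {
    stop(sprintf("value %.0f overflows a %d-nt field (max %.0f)",
                 v, width_nt, 4^width_nt - 1), call. = FALSE)
  }
  if (width_nt == 0L) return("")
  digits <- integer(width_nt)
  for (k in seq.int(width_nt, 1L)) {
    digits[k] <- v %% 4
    v <- v %/% 4
  }
  ints_nt(as.integer(digits))
}

#' @rdname int_to_nt
#' @param seq Nucleotide field string.
#' @export
nt_to_int <- function(seq) {
  assert_dna(seq, allow_empty = TRUE)
  if (!nzchar(seq)) return(0L)
  v <- sum(nt_ints(seq) * 4^(rev(seq_len(nchar(seq))) - 1L))
  if (v < .Machine$integer.max) as.integer(v) else v
}

#' Split text into record-sized chunks
#'
#' Chunks `text` into pieces of `chars_per_record` characters; the final
#' chunk is padded to full length with the reserved padding character,
#' which [decode_document()] strips.
#'
#' @param text Input string (may be empty: zero chunks).
#' @param chars_per_record Characters per record (>= 1).
#' @return Character vector of equal-length chunks.
#' @examples
#' length(chunk_text(strrep("x", 747), 94))  # 8
#' @export
chunk_text <- function(text, chars_per_record) {
  stopifnot(is.character(text), length(text) == 1L, chars_per_record >= 1)
  n <- nchar(text)
  if (n == 0L) return(character())
  k <- as.integer(chars_per_record)
  starts <- seq.int(1L, n, by = k)
  chunks <- substring(text, starts, pmin(starts + k - 1L, n))
  short <- nchar(chunks[length(chunks)])
  if (short < k) {
    chunks[length(chunks)] <- paste0(chunks[length(chunks)],
                                     strrep(PAD_CHAR, k - short))
  }
  chunks
}

#' Assemble one framed record
#'
#' Builds `index | data` from the base-4 index and the chunk's codewords,
#' runs the shift parameter search on that segment until it satisfies the
#' constraint policy, appends the `mod` and `iterate` fields (zero for the
#' sentinel), and finally appends RS parity computed over the packed bytes
#' of everything before it.
#'
#' @param chunk Character chunk of exactly `layout$chars_per_record`
#'   characters (padding included).
#' @param index_value Record address, `< 4^index_nt`.
#' @param layout A [record_layout()].
#' @param table A [code_table()] resolving every chunk character.
#' @param policy A [constraint_policy()].
#' @param mod_max Search bound; defaults to the layout's mod-field capacity.
#' @return An object of class `encoded_record` with fields `index_value`,
#'   `params`, `sequence`, `payload_chars`.
#' @export
assemble_record <- function(chunk, index_value, layout, table,
                            policy = constraint_policy(), mod_max = NULL) {
  stopifnot(inherits(layout, "record_layout"), inherits(table, "code_table"))
  if (nchar(chunk) != layout$chars_per_record) {
    stop(sprintf("chunk has %d characters; layout stores %d per record",
                 nchar(chunk), layout$chars_per_record), call. = FALSE)
  }
  if (is.null(mod_max)) mod_max <- as.integer(4^layout$mod_nt - 1)
  idx_nt <- int_to_nt(index_value, layout$index_nt)
  data_nt <- encode_chunk_nt(table, chunk)
  body <- paste0(idx_nt, data_nt)
  found <- tryCatch(
    encode_search(body, policy, mod_max = mod_max),
    error = function(e) {
      stop(sprintf("record %d: %s", index_value, conditionMessage(e)),
           call. = FALSE)
    }
  )
  params <- found$params
  if (params$mod >= 4^layout$mod_nt || params$iterate >= 4^layout$iterate_nt) {
    stop(sprintf("record %d: shift params (mod=%d, iterate=%d) overflow %d/%d-nt fields",
                 index_value, params$mod, params$iterate,
                 layout$mod_nt, layout$iterate_nt), call. = FALSE)
  }
  pre_parity <- paste0(found$seq,
                       int_to_nt(params$mod, layout$mod_nt),
                       int_to_nt(params$iterate, layout$iterate_nt))
  parity <- rs_encode(nt_to_bytes(pre_parity), layout$rs_nt %/% 4L)
  record_seq <- paste0(pre_parity, bytes_to_nt(parity))
  structure(
    list(index_value = as.integer(index_value), params = params,
         sequence = record_seq,
         payload_chars = layout$chars_per_record, layout_name = layout$name),
    class = "encoded_record"
  )
}

# Encode one chunk via the table; PAD resolves to the reserved codeword.
encode_chunk_nt <- function(table, chunk) {
  chars <- strsplit(chunk, "", fixed = TRUE)[[1L]]
  is_pad <- chars == PAD_CHAR
  if (any(is_pad)) {
    pad <- pad_codeword(table)
    if (is.na(pad)) {
      stop("table has no free codeword to use as padding", call. = FALSE)
    }
    out <- character(length(chars))
    if (any(!is_pad)) {
      out[!is_pad] <- vapply(chars[!is_pad], function(ch) {
        i <- match(ch, table$chars)
        if (is.na(i)) stop(sprintf("character '%s' not in code table", ch),
                           call. = FALSE)
        table$codewords[i]
      }, character(1))
    }
    out[is_pad] <- pad
    paste(out, collapse = "")
  } else {
    as.character(chars_to_nt(table, chunk))
  }
}

#' @export
print.encoded_record <- function(x, ...) {
  cat(sprintf("<encoded_record> index %d, %d nt, %s\n", x$index_value,
              nchar(x$sequence),
              if (x$params$sentinel) "no shift" else
                sprintf("shift mod=%d iterate=%d", x$params$mod,
                        x$params$iterate)))
  invisible(x)
}

#' Disassemble one record
#'
#' RS-corrects the record, reads the `mod`/`iterate` fields, reverses the
#' shift transform on `index | data`, and decodes index and characters
#' (padding retained; [decode_document()] strips it).
#'
#' @param sequence Record nucleotide string of `layout$total_nt` nt.
#' @param layout A [record_layout()].
#' @param table The [code_table()] used at encode time (with extensions).
#' @return List with `index_value`, `chars`, `params`, `corrections`.
#' @export
disassemble_record <- function(sequence, layout, table) {
  stopifnot(inherits(layout, "record_layout"), inherits(table, "code_table"))
  assert_dna(sequence)
  if (nchar(sequence) != layout$total_nt) {
    stop(sprintf("record has %d nt; layout expects %d", nchar(sequence),
                 layout$total_nt), call. = FALSE)
  }
  nsym <- layout$rs_nt %/% 4L
  decoded <- rs_decode(nt_to_bytes(sequence), nsym)
  body <- bytes_to_nt(decoded$message)
  o <- 0L
  idx_field <- substr(body, o + 1L, o + layout$index_nt)
  o <- o + layout$index_nt
  data_field <- substr(body, o + 1L, o + layout$data_nt)
  o <- o + layout$data_nt
  mod_v <- nt_to_int(substr(body, o + 1L, o + layout$mod_nt))
  o <- o + layout$mod_nt
  it_v <- nt_to_int(substr(body, o + 1L, o + layout$iterate_nt))
  params <- if (mod_v == 0L && it_v == 0L) {
    shift_params(sentinel = TRUE)
  } else {
    shift_params(mod_v, it_v)
  }
  restored <- decode_shift(paste0(idx_field, data_field), params,
                           mod_max = max(63L, mod_v))
  idx_restored <- substr(restored, 1L, layout$index_nt)
  data_restored <- substr(restored, layout$index_nt + 1L, nchar(restored))
  list(index_value = nt_to_int(idx_restored),
       chars = nt_to_chars(table, data_restored, keep_pad = TRUE),
       params = params, corrections = decoded$corrections)
}

#' Encode a whole document
#'
#' Chunks `text`, assembles one record per chunk with consecutive index
#' values from 0, and returns the records with the (possibly extended)
#' table and its extension key.
#'
#' @param text Document string.
#' @param layout A [record_layout()].
#' @param table A [code_table()]; defaults to the GB2312 table.
#' @param policy A [constraint_policy()].
#' @param auto_extend Extend the table for characters it lacks?
#' @return List of class `encoded_document`: `records` (list of
#'   [assemble_record()] results), `table`, `extension_key`, `char_count`,
#'   `layout`.
#' @export
encode_document <- function(text, layout, table = gb2312_table(),
                            policy = constraint_policy(),
                            auto_extend = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl(PAD_CHAR, text, fixed = TRUE)) {
    stop(sprintf("text contains the reserved padding character '%s'",
                 PAD_CHAR), call. = FALSE)
  }
  if (auto_extend) {
    chars <- unique(strsplit(text, "", fixed = TRUE)[[1L]])
    missing_chars <- chars[is.na(match(chars, table$chars))]
    for (ch in missing_chars) table <- extend_table(table, ch)
  }
  chunks <- chunk_text(text, layout$chars_per_record)
  if (length(chunks) > 4^layout$index_nt) {
    stop(sprintf("document needs %d records but the %d-nt index addresses %.0f",
                 length(chunks), layout$index_nt, 4^layout$index_nt),
         call. = FALSE)
  }
  records <- vector("list", length(chunks))
  for (k in seq_along(chunks)) {
    records[[k]] <- assemble_record(chunks[k], k - 1L, layout, table, policy)
  }
  structure(
    list(records = records, table = table,
         extension_key = table$extension_key,
         char_count = nchar(text), layout = layout),
    class = "encoded_document"
  )
}

#' @export
print.encoded_document <- function(x, ...) {
  cat(sprintf("<encoded_document> %d characters in %d records of %d nt (%s)\n",
              x$char_count, length(x$records), x$layout$total_nt,
              x$layout$name))
  invisible(x)
}

#' Decode a document from its records
#'
#' Records may arrive in any order: they are disassembled, sorted by index
#' value ascending, concatenated, and trailing padding is stripped. Missing
#' or duplicate indices are an error naming the offending addresses.
#'
#' @param records List of record sequences (strings or `encoded_record`s).
#' @param layout A [record_layout()].
#' @param table The encode-time [code_table()], or a stock table plus
#'   `extension_key` to replay extensions.
#' @param extension_key Optional extension-key data frame (`char`,
#'   `codeword`) to graft onto `table` before decoding.
#' @return The decoded document string.
#' @export
decode_document <- function(records, layout, table = gb2312_table(),
                            extension_key = NULL) {
  stopifnot(is.list(records) || is.character(records))
  if (!length(records)) return("")
  if (!is.null(extension_key) && nrow(extension_key)) {
    table <- graft_extension_key(table, extension_key)
  }
  seqs <- vapply(records, function(r) {
    if (inherits(r, "encoded_record")) r$sequence else as.character(r)
  }, character(1))
  parts <- lapply(seqs, disassemble_record, layout = layout, table = table)
  idx <- vapply(parts, `[[`, integer(1), "index_value")
  if (anyDuplicated(idx)) {
    stop(sprintf("duplicate record indices: %s",
                 paste(unique(idx[duplicated(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  expected <- seq.int(0L, max(idx))
  gaps <- setdiff(expected, idx)
  if (length(gaps)) {
    stop(sprintf("missing record indices: %s",
                 paste(gaps, collapse = ", ")), call. = FALSE)
  }
  ord <- order(idx)
  text <- paste(vapply(parts[ord], `[[`, character(1), "chars"),
                collapse = "")
  sub(paste0(PAD_CHAR, "+$"), "", text)
}

# Re-apply a persisted extension key to a stock table, verifying that each
# pair lands on the codeword recorded at encode time.
graft_extension_key <- function(table, key) {
  for (k in seq_len(nrow(key))) {
    table <- extend_table(table, key$char[k])
    got <- attr(table, "codeword")
    if (!identical(got, key$codeword[k])) {
      stop(sprintf("extension key mismatch for '%s': expected %s, got %s",
                   key$char[k], key$codeword[k], got), call. = FALSE)
    }
  }
  table
}

#' Storage-density metrics
#'
#' Characters are costed at 24 bits each (the UTF-8 width of CJK
#' characters, the comparison basis for Chinese text).
#' \describe{
#'   \item{`density_total`}{stored bits over all synthesized bases,
#'     `char_count * 24 / (n_records * total_nt)`, rounded to 2 decimals.}
#'   \item{`density_payload`}{stored bits over payload bases only,
#'     `char_count * 24 / (n_records * data_nt)`, truncated to 2 decimals.}
#'   \item{`invalid_ratio`}{percentage of bases carrying no payload,
#'     `100 * (total_nt - data_nt) / total_nt`, rounded to 2 decimals.}
#' }
#'
#' @param records Nonempty list of records (or an `encoded_document`).
#' @param char_count Number of stored characters.
#' @param layout A [record_layout()].
#' @return Named list `density_total`, `density_payload`, `invalid_ratio`.
#' @export
storage_metrics <- function(records, char_count = NULL, layout = NULL) {
  if (inherits(records, "encoded_document")) {
    char_count <- records$char_count
    layout <- records$layout
    records <- records$records
  }
  if (!length(records)) stop("no records", call. = FALSE)
  stopifnot(!is.null(char_count), inherits(layout, "record_layout"))
  n <- length(records)
  bits <- char_count * 24
  list(
    density_total = round(bits / (n * layout$total_nt), 2),
    density_payload = trunc(100 * bits / (n * layout$data_nt)) / 100,
    invalid_ratio = round(100 * (layout$total_nt - layout$data_nt) /
                            layout$total_nt, 2)
  )
}
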