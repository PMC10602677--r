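#' FASTA import/export of encoded records
#'
#' Records are exchanged as FASTA with 60-column wrapping and headers of
#' the form `rec<index> mod=<m> iterate=<t> layout=<name>`. The header
#' fields are a human-readable convenience; the in-band index, mod and
#' iterate segments of each sequence remain authoritative on decode.
#'
#' @param doc An `encoded_document` (or list of `encoded_record`s).
#' @param path Output FASTA path.
#' @return `write_records_fasta()`: `path`, invisibly;
#'   `read_records_fasta()`: character vector of record sequences, named by
#'   header line.
#' @export
write_records_fasta <- function(doc, path) {
  records <- if (inherits(doc, "encoded_document")) doc$records else doc
  layout_name <- if (inherits(doc, "encoded_document")) doc$layout$name
    else "custom"
  seqs <- vapply(records, function(r) r$sequence, character(1))
  names(seqs) <- vapply(records, function(r) {
    sprintf("rec%d mod=%d iterate=%d layout=%s", r$index_value,
            r$params$mod, r$params$iterate,
            if (inherits(r, "encoded_record") && !is.null(r$layout_name))
              r$layout_name else layout_name)
  }, character(1))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 60L)
  invisible(path)
}

#' @rdname write_records_fasta
#' @export
read_records_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}
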