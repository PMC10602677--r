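test_that("layout presets reproduce the published segment arithmetic", {
  p <- record_layout("plasmid744")
  expect_identical(p$total_nt, 744L)
  expect_identical(p$chars_per_record, 94L)
  s <- record_layout("short128")
  expect_identical(s$total_nt, 128L)
  expect_identical(s$chars_per_record, 15L)
  expect_error(record_layout("nope"), "unknown layout")
  # custom layouts must pack into whole bytes and divide the word length
  expect_error(record_layout(index_nt = 5, data_nt = 100, mod_nt = 3,
                             iterate_nt = 4, rs_nt = 8), "multiple")
  expect_error(record_layout(index_nt = 6, data_nt = 105, mod_nt = 3,
                             iterate_nt = 4, rs_nt = 8), "whole bytes")
})

test_that("base-4 integer fields are big-endian with A=0..T=3", {
  expect_identical(int_to_nt(0, 5), "AAAAA")
  expect_identical(int_to_nt(1, 5), "AAAAC")
  expect_identical(int_to_nt(4^5 - 1, 5), "TTTTT")
  expect_identical(nt_to_int("AAAAC"), 1L)
  set.seed(71)
  for (k in 1:30) {
    w <- sample(1:8, 1)
    v <- sample(0:(4^w - 1), 1)
    expect_identical(nt_to_int(int_to_nt(v, w)), as.integer(v))
  }
  expect_error(int_to_nt(4^3, 3), "overflow")
})

test_that("chunking pads the final record and counts match the layouts", {
  expect_identical(length(chunk_text(strrep("x", 747), 94)), 8L)
  expect_identical(length(chunk_text(strrep("x", 6821), 15)), 455L)
  one <- chunk_text(strrep("x", 15), 15)
  expect_identical(length(one), 1L)
  expect_false(grepl("␣", one))
  padded <- chunk_text(strrep("x", 16), 15)
  expect_identical(nchar(padded[2]), 15L)
  expect_identical(substr(padded[2], 2, 15), strrep("␣", 14))
  expect_identical(chunk_text("", 15), character())
})

test_that("assembled records have the layout length and compliant bodies", {
  tab <- gb2312_table()
  pol <- constraint_policy()
  for (name in c("short128", "plasmid744")) {
    lay <- record_layout(name)
    chunk <- chunk_text(random_text(lay$chars_per_record, tab, seed = 83),
                        lay$chars_per_record)[1]
    rec <- assemble_record(chunk, 5, lay, tab, pol)
    expect_identical(nchar(rec$sequence), lay$total_nt)
    body <- substr(rec$sequence, 1, lay$index_nt + lay$data_nt)
    expect_true(check_constraints(body, pol)$passes)
  }
})

test_that("disassembly inverts assembly, including shift params", {
  tab <- gb2312_table()
  lay <- record_layout("short128")
  set.seed(91)
  for (k in 1:10) {
    txt <- random_text(lay$chars_per_record, tab)
    rec <- assemble_record(txt, k, lay, tab)
    d <- disassemble_record(rec$sequence, lay, tab)
    expect_identical(d$index_value, k)
    expect_identical(d$chars, txt)
    expect_identical(d$params$mod, rec$params$mod)
    expect_identical(d$params$iterate, rec$params$iterate)
    expect_identical(d$corrections, 0L)
  }
})

test_that("records survive substitutions within the parity budget", {
  tab <- gb2312_table()
  lay <- record_layout("plasmid744")
  txt <- random_text(lay$chars_per_record, tab, seed = 103)
  rec <- assemble_record(txt, 3, lay, tab)
  set.seed(104)
  for (k in 1:10) {
    bad <- corrupt(rec$sequence, 9, byte_group_distinct = TRUE)
    d <- disassemble_record(bad, lay, tab)
    expect_identical(d$chars, txt)
    expect_identical(d$index_value, 3L)
  }
  # a corrupted mod field is repaired before the reverse shift runs
  o <- lay$index_nt + lay$data_nt  # 0-based offset of the mod field
  hit <- paste0(substr(rec$sequence, 1, o),
                chartr("ACGT", "CTAG", substr(rec$sequence, o + 1, o + 1)),
                substr(rec$sequence, o + 2, lay$total_nt))
  d2 <- disassemble_record(hit, lay, tab)
  expect_identical(d2$chars, txt)
  expect_gte(d2$corrections, 1L)
})

test_that("documents round-trip under record shuffling", {
  tab <- gb2312_table()
  lay <- record_layout("short128")
  txt <- random_text(100, tab, seed = 113)
  doc <- encode_document(txt, lay, tab)
  expect_identical(length(doc$records), 7L)
  expect_identical(decode_document(doc$records, lay, tab), txt)
  set.seed(114)
  for (k in 1:5) {
    expect_identical(decode_document(sample(doc$records), lay, tab), txt)
  }
})

test_that("missing and duplicate indices are reported by address", {
  tab <- gb2312_table()
  lay <- record_layout("short128")
  txt <- random_text(60, tab, seed = 123)
  doc <- encode_document(txt, lay, tab)
  expect_error(decode_document(doc$records[-2], lay, tab),
               "missing record indices: 1")
  expect_error(decode_document(c(doc$records, doc$records[1]), lay, tab),
               "duplicate record indices: 0")
})

test_that("documents with out-of-table characters travel via the key", {
  tab <- code_table(strsplit("abcdefgh", "")[[1]], n = 3)
  lay <- record_layout(index_nt = 4, data_nt = 12, mod_nt = 4,
                       iterate_nt = 4, rs_nt = 8, word_length = 3)
  txt <- "abcdXYab"
  doc <- encode_document(txt, lay, tab, auto_extend = TRUE)
  expect_identical(doc$extension_key$char, c("X", "Y"))
  # decode with the stock table plus the persisted key
  stock <- code_table(strsplit("abcdefgh", "")[[1]], n = 3)
  out <- decode_document(doc$records, lay, stock,
                         extension_key = doc$extension_key)
  expect_identical(out, txt)
})

test_that("density metrics reproduce the published arithmetic", {
  tab <- gb2312_table()
  lay <- record_layout("plasmid744")
  txt <- random_text(747, tab, seed = 131)
  doc <- encode_document(txt, lay, tab)
  m <- storage_metrics(doc)
  expect_identical(length(doc$records), 8L)
  expect_identical(m$density_total, 3.01)
  expect_identical(m$invalid_ratio, 11.56)
  # payload density for the short-record configuration
  lay2 <- record_layout("short128")
  m2 <- storage_metrics(rep(list(NULL), 455), char_count = 6821,
                        layout = lay2)
  expect_identical(m2$density_payload, 3.42)
})

test_that("FASTA export and import preserve the records", {
  tab <- gb2312_table()
  lay <- record_layout("short128")
  txt <- random_text(45, tab, seed = 141)
  doc <- encode_document(txt, lay, tab)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_records_fasta(doc, fa)
  lines <- readLines(fa)
  expect_match(lines[1], "^>rec0 mod=\\d+ iterate=\\d+ layout=short128$")
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_records_fasta(fa)
  expect_identical(unname(back),
                   vapply(doc$records, function(r) r$sequence, character(1)))
  expect_identical(decode_document(as.list(back), lay, tab), txt)
})
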