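test_that("minimum word length is the smallest n with 4^n >= K", {
  cases <- list(list(K = 16, n = 2), list(K = 7445, n = 7),
                list(K = 4, n = 1), list(K = 1, n = 1),
                list(K = 5, n = 2), list(K = 16384, n = 7),
                list(K = 16385, n = 8))
  for (cs in cases) {
    expect_identical(min_word_length(cs$K), as.integer(cs$n))
    expect_gte(4^min_word_length(cs$K), cs$K)
  }
  expect_error(min_word_length(0), "positive")
  expect_error(min_word_length(-3), "positive")
})

test_that("capacity is 4^n", {
  expect_identical(table_capacity(7), 16384L)
  expect_identical(table_capacity(1), 4L)
  expect_identical(table_capacity(2), 16L)
})

test_that("tables assign codewords lexicographically under A < C < G < T", {
  tab <- code_table(c("甲", "乙"), n = 1)
  expect_identical(tab$codewords, c("A", "C"))
  expect_identical(tab$free_pool, c("G", "T"))

  tab2 <- small_table()
  expect_identical(tab2$codewords[1:5], c("AA", "AC", "AG", "AT", "CA"))
  expect_identical(length(tab2$free_pool), 0L)

  empty <- code_table(character(), n = 1)
  expect_identical(length(empty), 0L)
  expect_identical(empty$free_pool, c("A", "C", "G", "T"))
})

test_that("table construction rejects bad input", {
  expect_error(code_table(c("a", "a"), n = 1), "duplicate")
  expect_error(code_table(strsplit("abcde", "")[[1]], n = 1), "capacity")
  expect_error(code_table("␣", n = 1), "reserved")
})

test_that("extension allocates from the head of the free pool", {
  tab <- code_table(c("a", "b"), n = 2)
  expect_identical(tab$free_pool[1:2], c("AG", "AT"))
  tab <- extend_table(tab, "〇")
  expect_identical(attr(tab, "codeword"), "AG")
  expect_identical(tab$extension_key$char, "〇")
  expect_identical(tab$extension_key$codeword, "AG")
  expect_false("AG" %in% tab$free_pool)

  # idempotence: extending an existing character warns and returns its word
  expect_warning(tab2 <- extend_table(tab, "a"), "already mapped")
  expect_identical(attr(tab2, "codeword"), "AA")
  expect_identical(length(tab2), length(tab))
})

test_that("extension fails when only the pad codeword remains", {
  tab <- code_table(c("a", "b", "c"), n = 1)  # pool = "T" only
  expect_error(extend_table(tab, "d"), "exhausted")
})

test_that("capacity conservation holds through arbitrary extensions", {
  set.seed(101)
  tab <- code_table(c("a", "b", "c"), n = 2)
  pool_chars <- strsplit("uvwxyz0123456789", "")[[1]]
  for (ch in sample(pool_chars, 10)) {
    tab <- extend_table(tab, ch)
    expect_identical(length(tab$chars) + length(tab$free_pool),
                     table_capacity(tab$word_length))
    expect_identical(anyDuplicated(c(tab$codewords, tab$free_pool)), 0L)
  }
})

test_that("character <-> nucleotide conversion round-trips", {
  tab <- small_table()
  for (txt in c("abc", "ponm", "a", paste(rep("pag", 30), collapse = ""))) {
    nt <- chars_to_nt(tab, txt)
    expect_identical(nchar(nt), nchar(txt) * tab$word_length)
    expect_identical(nt_to_chars(tab, as.character(nt)), txt)
  }
  # paper-scale arithmetic: 7-nt words
  big <- code_table(strsplit("abcdefghij", "")[[1]], n = 7)
  expect_identical(nchar(chars_to_nt(big, strrep("a", 15))), 105L)
  expect_identical(nchar(chars_to_nt(big, strrep("ab", 47))), 658L)
})

test_that("unknown characters and codewords are reported with context", {
  tab <- small_table()
  expect_error(chars_to_nt(tab, "abz"), "z")
  expect_error(nt_to_chars(tab, "AAA"), "not a multiple")
  tab1 <- code_table(c("a", "b"), n = 1)
  expect_error(nt_to_chars(tab1, "AG"), "offset 1")
})

test_that("auto-extension during encoding grows the key", {
  tab <- code_table(c("a", "b"), n = 2)
  nt <- chars_to_nt(tab, "abz", auto_extend = TRUE)
  grown <- attr(nt, "table")
  expect_identical(grown$extension_key$char, "z")
  expect_identical(nt_to_chars(grown, as.character(nt)), "abz")
})

test_that("persisted tables reload identically, including pool order and key", {
  tab <- code_table(strsplit("abcdefgh", "")[[1]], n = 2)
  tab <- extend_table(tab, "x")
  tab <- extend_table(tab, "y")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  key <- withr::local_tempfile(fileext = ".tsv")
  save_table(tab, tsv, key_path = key)
  back <- load_table(tsv, key_path = key)
  expect_identical(back$chars, tab$chars)
  expect_identical(back$codewords, tab$codewords)
  expect_identical(back$free_pool, tab$free_pool)
  expect_identical(back$extension_key, tab$extension_key)
  expect_identical(back$word_length, tab$word_length)

  # byte-identical persistence for identical inputs
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  save_table(code_table(strsplit("abcdefgh", "")[[1]], n = 2), tsv2)
  tsv3 <- withr::local_tempfile(fileext = ".tsv")
  save_table(code_table(strsplit("abcdefgh", "")[[1]], n = 2), tsv3)
  expect_identical(readBin(tsv2, "raw", file.size(tsv2)),
                   readBin(tsv3, "raw", file.size(tsv3)))
})

test_that("malformed table files raise parse errors with line numbers", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("char\tcodeword", "a\tAA", "b\tAA"), p)
  expect_error(load_table(p), "duplicate codeword")
  writeLines(c("char\tcodeword", "a\tAA", "b\tACG"), p)
  expect_error(load_table(p), "differing lengths")
  writeLines(c("char\tcodeword", "a\tAA", "b"), p)
  expect_error(load_table(p), "line 3")
  writeLines(c("wrong header"), p)
  expect_error(load_table(p), "line 1")
  writeLines(c("char\tcodeword", "a\tAX"), p)
  expect_error(load_table(p), "non-ACGT")
})

test_that("the pad codeword is drawn from the pool tail and repetition-safe", {
  tab <- gb2312_table()
  pad <- dnashift:::pad_codeword(tab)
  expect_true(pad %in% tab$free_pool)
  expect_lte(max_homopolymer(strrep(pad, 3)), 3L)
  gc <- gc_content(pad)
  expect_gte(gc, 0.4); expect_lte(gc, 0.6)
  # nothing later in the pool qualifies
  later <- tab$free_pool[seq.int(match(pad, tab$free_pool) + 1L,
                                 length(tab$free_pool))]
  ok_later <- vapply(later, function(w) {
    max_homopolymer(strrep(w, 2)) <= 3 &&
      gc_content(w) >= 0.4 && gc_content(w) <= 0.6
  }, logical(1))
  expect_false(any(ok_later))
})
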