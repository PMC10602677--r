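# Independent oracles and small fixtures, written without touching package
# internals so that each check has two genuinely separate routes.

# A tiny 16-character table (n = 2) over ASCII letters for fast unit tests.
small_table <- function() {
  code_table(strsplit("abcdefghijklmnop", "")[[1L]], n = 2)
}

# Brute-force shift-search oracle: explicitly materialises every cumulative
# prefix of the canonical schedule with its own string-level shift, and
# returns the first compliant state.
oracle_shift_search <- function(seq, gc_min = 0.40, gc_max = 0.60,
                                max_run = 3, mod_max = 63) {
  fwd <- c(A = "C", C = "T", T = "G", G = "A")
  shift_once <- function(s, i) {
    ch <- strsplit(s, "")[[1L]]
    pos <- seq(1L, length(ch), by = i)
    ch[pos] <- fwd[ch[pos]]
    paste(ch, collapse = "")
  }
  ok <- function(s) {
    ch <- strsplit(s, "")[[1L]]
    gc <- mean(ch %in% c("G", "C"))
    gc >= gc_min && gc <= gc_max && max(rle(ch)$lengths) <= max_run
  }
  if (ok(seq)) return(list(mod = 0L, iterate = 0L, seq = seq))
  cur <- seq
  for (m in 3:mod_max) {
    for (it in 2:(4 * m + 2)) {
      i <- it %% m
      if (i == 0 || i == 1) next
      cur <- shift_once(cur, i)
      if (ok(cur)) return(list(mod = m, iterate = it, seq = cur))
    }
  }
  NULL
}

# Independent GF(256) syndrome check: rebuilds the 0x11D log/antilog tables
# from scratch and evaluates the codeword polynomial at the generator roots.
# A valid systematic RS codeword must have all-zero syndromes.
oracle_rs_syndromes <- function(codeword, nsym) {
  exp_t <- integer(256L)
  x <- 1L
  for (i in 0:254) {
    exp_t[i + 1L] <- x
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwAnd(bitwXor(x, 0x11DL), 0xFFL)
  }
  log_t <- integer(256L)
  log_t[exp_t[1:255] + 1L] <- 0:254
  mul <- function(a, b) {
    if (a == 0L || b == 0L) return(0L)
    exp_t[(log_t[a + 1L] + log_t[b + 1L]) %% 255L + 1L]
  }
  vapply(0:(nsym - 1L), function(j) {
    root <- exp_t[j %% 255L + 1L]
    acc <- 0L
    for (c in codeword) acc <- bitwXor(mul(acc, root), c)
    acc
  }, integer(1))
}

random_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
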