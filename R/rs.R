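#' Reed-Solomon error correction over GF(256)
#'
#' Systematic RS in the conventional byte-oriented dialect: GF(2^8) with
#' primitive polynomial 0x11D, generator element 2, first consecutive root
#' index 0. A code with `parity_bytes` parity symbols corrects up to
#' `parity_bytes / 2` byte errors per codeword (minimum Hamming distance
#' `parity_bytes + 1`); codewords are limited to 255 bytes. Nucleotides map
#' to bytes 4-at-a-time (2 bits per base, A=00, C=01, G=10, T=11,
#' big-endian), so one substituted base corrupts at most one byte.
#'
#' @name reed-solomon
NULL

# GF(256) log/antilog tables for primitive polynomial 0x11D, built once.
.gf <- new.env(parent = emptyenv())

gf_tables <- function() {
  if (is.null(.gf$exp)) {
    exp_t <- integer(512L)
    log_t <- integer(256L)
    x <- 1L
    for (i in 0:254) {
      exp_t[i + 1L] <- x
      log_t[x + 1L] <- i
      x <- bitwShiftL(x, 1L)
      if (x >= 256L) x <- bitwAnd(bitwXor(x, 0x11DL), 0xFFL)
    }
    # duplicate the 255-periodic table so unreduced exponents still index
    exp_t[256:510] <- exp_t[1:255]
    exp_t[511:512] <- exp_t[1:2]
    .gf$exp <- exp_t
    .gf$log <- log_t
  }
  .gf
}

gf_mul <- function(a, b) {
  if (a == 0L || b == 0L) return(0L)
  g <- gf_tables()
  g$exp[((g$log[a + 1L] + g$log[b + 1L]) %% 255L) + 1L]
}

gf_div <- function(a, b) {
  if (b == 0L) stop("GF(256) division by zero", call. = FALSE)
  if (a == 0L) return(0L)
  g <- gf_tables()
  g$exp[((g$log[a + 1L] - g$log[b + 1L] + 255L) %% 255L) + 1L]
}

gf_pow <- function(a, p) {
  g <- gf_tables()
  if (a == 0L) return(if (p == 0L) 1L else 0L)
  g$exp[((g$log[a + 1L] * p) %% 255L + 255L) %% 255L + 1L]
}

gf_inverse <- function(a) gf_div(1L, a)

# Polynomials are integer vectors with the highest-degree coefficient first.
gf_poly_scale <- function(p, x) {
  vapply(p, gf_mul, integer(1), b = x)
}

gf_poly_add <- function(p, q) {
  n <- max(length(p), length(q))
  r <- integer(n)
  r[(n - length(p) + 1L):n] <- p
  r[(n - length(q) + 1L):n] <- bitwXor(r[(n - length(q) + 1L):n], q)
  r
}

gf_poly_mul <- function(p, q) {
  r <- integer(length(p) + length(q) - 1L)
  for (j in seq_along(q)) {
    if (q[j] == 0L) next
    for (i in seq_along(p)) {
      if (p[i] == 0L) next
      k <- i + j - 1L
      r[k] <- bitwXor(r[k], gf_mul(p[i], q[j]))
    }
  }
  r
}

gf_poly_eval <- function(p, x) {
  y <- p[1L]
  for (i in seq_along(p)[-1L]) {
    y <- bitwXor(gf_mul(y, x), p[i])
  }
  y
}

rs_generator_poly <- function(nsym) {
  g <- 1L
  for (i in seq_len(nsym) - 1L) {
    g <- gf_poly_mul(g, c(1L, gf_pow(2L, i)))
  }
  g
}

#' RS parity generation
#'
#' Computes `parity_bytes` parity symbols for `message` (integers 0-255);
#' the systematic codeword is `c(message, parity)`.
#'
#' @param message Integer vector of bytes (0-255).
#' @param parity_bytes Even positive parity length; message + parity must
#'   fit in a 255-byte GF(256) block.
#' @return Integer vector of `parity_bytes` parity bytes.
#' @export
rs_encode <- function(message, parity_bytes) {
  message <- check_bytes(message)
  parity_bytes <- as.integer(parity_bytes)
  stopifnot(parity_bytes >= 0L)
  if (length(message) + parity_bytes > 255L) {
    stop(sprintf("RS block overflow: %d message + %d parity bytes > 255",
                 length(message), parity_bytes), call. = FALSE)
  }
  if (parity_bytes == 0L) return(integer())
  gen <- rs_generator_poly(parity_bytes)
  # synthetic division of message * x^parity_bytes by the generator
  buf <- c(message, integer(parity_bytes))
  for (i in seq_along(message)) {
    coef <- buf[i]
    if (coef != 0L) {
      for (j in seq_along(gen)[-1L]) {
        buf[i + j - 1L] <- bitwXor(buf[i + j - 1L], gf_mul(gen[j], coef))
      }
    }
  }
  buf[seq.int(length(message) + 1L, length(buf))]
}

#' RS decoding with error correction
#'
#' Corrects up to `parity_bytes / 2` byte errors anywhere in the codeword
#' (message or parity). Uncorrectable codewords raise an `rs_decode_error`
#' condition — decoding never silently returns corrupted data.
#'
#' @param codeword Integer byte vector `c(message, parity)`.
#' @param parity_bytes Parity length used at encode time.
#' @return List with `message` (integer bytes) and `corrections` (number of
#'   byte positions repaired).
#' @export
rs_decode <- function(codeword, parity_bytes) {
  codeword <- check_bytes(codeword)
  parity_bytes <- as.integer(parity_bytes)
  n <- length(codeword)
  stopifnot(parity_bytes >= 0L, n > parity_bytes, n <= 255L)
  msg_len <- n - parity_bytes
  if (parity_bytes == 0L) {
    return(list(message = codeword, corrections = 0L))
  }
  synd <- vapply(seq_len(parity_bytes) - 1L, function(i) {
    gf_poly_eval(codeword, gf_pow(2L, i))
  }, integer(1))
  if (all(synd == 0L)) {
    return(list(message = codeword[seq_len(msg_len)], corrections = 0L))
  }
  err_loc <- rs_error_locator(synd, parity_bytes)
  n_err <- length(err_loc) - 1L
  if (2L * n_err > parity_bytes) {
    rs_fail("too many errors for the parity budget")
  }
  err_pos <- rs_find_errors(err_loc, n)
  if (length(err_pos) != n_err) {
    rs_fail("error locator roots do not match its degree")
  }
  corrected <- rs_correct_errata(codeword, synd, err_pos)
  # re-verify: a miscorrection must not escape as success
  synd2 <- vapply(seq_len(parity_bytes) - 1L, function(i) {
    gf_poly_eval(corrected, gf_pow(2L, i))
  }, integer(1))
  if (any(synd2 != 0L)) {
    rs_fail("residual syndromes after correction")
  }
  list(message = corrected[seq_len(msg_len)], corrections = n_err)
}

rs_fail <- function(msg) {
  stop(structure(
    class = c("rs_decode_error", "error", "condition"),
    list(message = paste0("RS decode failure: ", msg), call = NULL)
  ))
}

# Berlekamp-Massey: error locator polynomial from the syndromes.
rs_error_locator <- function(synd, nsym) {
  err_loc <- 1L
  old_loc <- 1L
  for (i in seq_len(nsym)) {
    old_loc <- c(old_loc, 0L)
    delta <- synd[i]
    if (length(err_loc) > 1L) {
      for (j in seq_len(length(err_loc) - 1L)) {
        delta <- bitwXor(delta,
                         gf_mul(err_loc[length(err_loc) - j], synd[i - j]))
      }
    }
    if (delta != 0L) {
      if (length(old_loc) > length(err_loc)) {
        new_loc <- gf_poly_scale(old_loc, delta)
        old_loc <- gf_poly_scale(err_loc, gf_inverse(delta))
        err_loc <- new_loc
      }
      err_loc <- gf_poly_add(err_loc, gf_poly_scale(old_loc, delta))
    }
  }
  while (length(err_loc) > 1L && err_loc[1L] == 0L) err_loc <- err_loc[-1L]
  err_loc
}

# Chien search: 0-based positions (from the codeword start) of the errors.
# The locator is evaluated in ascending-coefficient order so that a root at
# the generator power i marks coefficient position n-1-i.
rs_find_errors <- function(err_loc, n) {
  err_loc <- rev(err_loc)
  pos <- integer()
  for (i in seq_len(n) - 1L) {
    if (gf_poly_eval(err_loc, gf_pow(2L, i)) == 0L) {
      pos <- c(pos, n - 1L - i)
    }
  }
  pos
}

# Forney algorithm: error magnitudes at known positions.
rs_correct_errata <- function(codeword, synd, err_pos) {
  n <- length(codeword)
  coef_pos <- n - 1L - err_pos
  # errata locator from the known positions
  loc <- 1L
  for (p in coef_pos) {
    loc <- gf_poly_mul(loc, c(gf_pow(2L, p), 1L))
  }
  # error evaluator: S(x) * Lambda(x), truncated to the e+1 lowest-order
  # terms (e = number of errors); higher terms vanish for consistent input
  synd_poly <- rev(synd)
  eval_poly <- gf_poly_mul(synd_poly, loc)
  keep <- length(coef_pos) + 1L
  eval_poly <- eval_poly[seq.int(length(eval_poly) - keep + 1L,
                                 length(eval_poly))]
  X <- vapply(coef_pos, function(p) gf_pow(2L, p), integer(1))
  E <- integer(n)
  for (i in seq_along(X)) {
    Xi <- X[i]
    Xi_inv <- gf_inverse(Xi)
    loc_prime <- 1L
    for (j in seq_along(X)) {
      if (j != i) {
        loc_prime <- gf_mul(loc_prime,
                            bitwXor(1L, gf_mul(Xi_inv, X[j])))
      }
    }
    if (loc_prime == 0L) rs_fail("errata locator derivative is zero")
    # Forney, fcr = 0 convention: e_i = Omega(Xi^-1) / prod_{j!=i}(1 + Xj/Xi)
    y <- gf_poly_eval(eval_poly, Xi_inv)
    E[err_pos[i] + 1L] <- gf_div(y, loc_prime)
  }
  bitwXor(codeword, E)
}

check_bytes <- function(x) {
  x <- as.integer(x)
  if (anyNA(x) || any(x < 0L | x > 255L)) {
    stop("bytes must be integers in 0..255", call. = FALSE)
  }
  x
}

#' Pack nucleotides into bytes (and back)
#'
#' Four bases become one byte, big-endian, with A=00, C=01, G=10, T=11; the
#' sequence length must be a multiple of 4. `bytes_to_nt()` is the exact
#' inverse.
#'
#' @param seq DNA string with `nchar(seq) %% 4 == 0`.
#' @return Integer vector of bytes.
#' @examples
#' nt_to_bytes("AAAA")  # 0
#' nt_to_bytes("TTTT")  # 255
#' @export
nt_to_bytes <- function(seq) {
  assert_dna(seq, allow_empty = TRUE)
  L <- nchar(seq)
  if (L %% 4L != 0L) {
    stop(sprintf("sequence length %d is not a multiple of 4", L),
         call. = FALSE)
  }
  if (L == 0L) return(integer())
  v <- nt_ints(seq)
  m <- matrix(v, nrow = 4L)
  as.integer(m[1L, ] * 64L + m[2L, ] * 16L + m[3L, ] * 4L + m[4L, ])
}

#' @rdname nt_to_bytes
#' @param bytes Integer vector of bytes (0-255).
#' @export
bytes_to_nt <- function(bytes) {
  bytes <- check_bytes(bytes)
  if (!length(bytes)) return("")
  d1 <- bytes %/% 64L
  d2 <- (bytes %/% 16L) %% 4L
  d3 <- (bytes %/% 4L) %% 4L
  d4 <- bytes %% 4L
  ints_nt(as.vector(rbind(d1, d2, d3, d4)))
}
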