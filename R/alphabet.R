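#' @keywords internal
"_PACKAGE"

# Canonical base order used for codeword enumeration and base-4 digits.
DNA_BASES <- c("A", "C", "G", "T")

# Forward shift permutation on base indices (A=0, C=1, G=2, T=3):
# A -> C -> T -> G -> A, a single 4-cycle, so four applications are the
# identity. The reverse permutation is the decode map A->G, G->T, T->C, C->A.
.SHIFT_FWD <- c(1L, 3L, 0L, 2L)
.SHIFT_REV <- c(2L, 0L, 3L, 1L)

# String <-> integer-vector conversions. All sequence-mutating internals work
# on integer vectors in 0..3; strings are the user-facing representation.
nt_ints <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  v <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_BASES) - 1L
  if (anyNA(v)) {
    bad <- which(is.na(v))[1L]
    stop(sprintf("invalid nucleotide at position %d (alphabet is A/C/G/T)", bad),
         call. = FALSE)
  }
  v
}

ints_nt <- function(v) {
  paste(DNA_BASES[v + 1L], collapse = "")
}

assert_dna <- function(seq, allow_empty = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  if (!allow_empty && !nzchar(seq)) {
    stop("sequence must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGT]", seq)) {
    stop("sequence contains characters outside the A/C/G/T alphabet",
         call. = FALSE)
  }
  invisible(seq)
}

# Run a block with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}
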