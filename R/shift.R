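#' DNA shift transform
#'
#' The shift codec coerces a sequence into biological constraints by a
#' deterministic search over cumulative base-substitution passes. One pass is
#' parameterised by a pair `(mod, iterate)`: the residue
#' `i = iterate %% mod` selects the 0-based positions `0, i, 2i, ...` and
#' each selected base is advanced one step around the 4-cycle
#' A -> C -> T -> G -> A. Passes are applied cumulatively in a canonical
#' schedule (`mod = 3, 4, ...`; for each `mod`, `iterate = 2 .. 4*mod + 2`,
#' skipping inadmissible values) until the running sequence satisfies the
#' constraint policy. Because every step is a permutation of the sequence
#' space, the search is exactly invertible given the final `(mod, iterate)`.
#'
#' @name shift-transform
NULL

#' Single-base shift and its inverse
#'
#' Forward substitution A->C, C->T, T->G, G->A; `unshift_base()` applies the
#' decode map A->G, G->T, T->C, C->A. Four forward applications return the
#' input.
#'
#' @param b A single base, one of "A", "C", "G", "T".
#' @return The substituted base.
#' @examples
#' shift_base("A")    # "C"
#' unshift_base("C")  # "A"
#' @export
shift_base <- function(b) {
  assert_dna(b)
  if (nchar(b) != 1L) stop("shift_base expects a single base", call. = FALSE)
  DNA_BASES[.SHIFT_FWD[nt_ints(b) + 1L] + 1L]
}

#' @rdname shift_base
#' @export
unshift_base <- function(b) {
  assert_dna(b)
  if (nchar(b) != 1L) stop("unshift_base expects a single base", call. = FALSE)
  DNA_BASES[.SHIFT_REV[nt_ints(b) + 1L] + 1L]
}

#' Residue of a shift step
#'
#' @param iterate Integer >= 2.
#' @param mod Integer >= 3.
#' @return `iterate %% mod`.
#' @export
shift_residue <- function(iterate, mod) {
  stopifnot(mod >= 3, iterate >= 2)
  as.integer(iterate %% mod)
}

#' Admissibility of a (mod, iterate) pair
#'
#' A step is admissible unless `iterate` is a multiple of `mod` or a multiple
#' of `mod` plus one — i.e. unless the residue is 0 or 1, which would select
#' every position (or degenerate to step 1) and cannot break runs.
#'
#' @inheritParams shift_residue
#' @return Logical.
#' @examples
#' admissible(6, 3)  # FALSE (multiple of mod)
#' admissible(5, 3)  # TRUE  (residue 2)
#' @export
admissible <- function(iterate, mod) {
  !(shift_residue(iterate, mod) %in% c(0L, 1L))
}

#' Positions touched by one pass
#'
#' 0-based positions `{i*j : j = 0, 1, ...}` strictly below the sequence
#' length; position 0 (the first base) is always included.
#'
#' @param i Step size (residue), >= 2.
#' @param L Sequence length, >= 1.
#' @return Integer vector of 0-based positions.
#' @examples
#' pass_positions(2, 7)  # 0 2 4 6
#' @export
pass_positions <- function(i, L) {
  stopifnot(i >= 2, L >= 1)
  seq.int(0L, as.integer(L) - 1L, by = as.integer(i))
}

# One pass on an integer-vector sequence; direction +1 forward, -1 reverse.
apply_pass_ints <- function(v, mod, iterate, direction = 1L) {
  i <- shift_residue(iterate, mod)
  idx <- pass_positions(i, length(v)) + 1L
  perm <- if (direction > 0L) .SHIFT_FWD else .SHIFT_REV
  v[idx] <- perm[v[idx] + 1L]
  v
}

#' Apply or reverse one shift pass
#'
#' Substitutes the base at every position selected by
#' `pass_positions(iterate %% mod, nchar(seq))`, leaving all others
#' untouched. `reverse_pass()` is its exact inverse.
#'
#' @param seq DNA string.
#' @param mod,iterate An admissible step (see [admissible()]).
#' @return The transformed sequence, same length.
#' @export
apply_pass <- function(seq, mod, iterate) {
  assert_dna(seq)
  if (!admissible(iterate, mod)) {
    stop(sprintf("inadmissible shift step (mod=%d, iterate=%d)", mod, iterate),
         call. = FALSE)
  }
  ints_nt(apply_pass_ints(nt_ints(seq), mod, iterate, 1L))
}

#' @rdname apply_pass
#' @export
reverse_pass <- function(seq, mod, iterate) {
  assert_dna(seq)
  if (!admissible(iterate, mod)) {
    stop(sprintf("inadmissible shift step (mod=%d, iterate=%d)", mod, iterate),
         call. = FALSE)
  }
  ints_nt(apply_pass_ints(nt_ints(seq), mod, iterate, -1L))
}

#' Canonical shift schedule
#'
#' For each `mod` from `mod_start` upward, `iterate` runs over
#' `2, 3, ..., 4*mod + 2`, emitting only admissible pairs. The encoder walks
#' this list cumulatively; the decoder replays it backwards.
#'
#' @param mod_start First modulus (default 3).
#' @param mod_max Last modulus included.
#' @return Data frame with columns `mod` and `iterate`.
#' @examples
#' subset(shift_schedule(mod_max = 3), mod == 3)$iterate  # 2 5 8 11 14
#' @export
shift_schedule <- function(mod_start = 3L, mod_max = 63L) {
  stopifnot(mod_max >= mod_start, mod_start >= 3)
  steps <- lapply(seq.int(mod_start, mod_max), function(m) {
    it <- seq.int(2L, 4L * m + 2L)
    it <- it[!(it %% m) %in% c(0L, 1L)]
    data.frame(mod = m, iterate = it)
  })
  do.call(rbind, steps)
}

#' Shift parameters
#'
#' The `(mod, iterate)` pair identifying the last cumulative schedule step an
#' encoder applied; `shift_params()` with no arguments (or `sentinel = TRUE`)
#' denotes "no transform applied" and is stored as zero-valued fields in a
#' framed record.
#'
#' @param mod,iterate The final schedule step; ignored when `sentinel`.
#' @param sentinel Logical; identity transform marker.
#' @return An object of class `shift_params`.
#' @export
shift_params <- function(mod = NULL, iterate = NULL, sentinel = is.null(mod)) {
  if (sentinel) {
    return(structure(list(mod = 0L, iterate = 0L, sentinel = TRUE),
                     class = "shift_params"))
  }
  mod <- as.integer(mod); iterate <- as.integer(iterate)
  if (mod < 3L || iterate < 2L || iterate > 4L * mod + 2L ||
      !admissible(iterate, mod)) {
    stop(sprintf("invalid shift params (mod=%d, iterate=%d)", mod, iterate),
         call. = FALSE)
  }
  structure(list(mod = mod, iterate = iterate, sentinel = FALSE),
            class = "shift_params")
}

#' @export
print.shift_params <- function(x, ...) {
  if (x$sentinel) cat("<shift_params> identity (no transform)\n")
  else cat(sprintf("<shift_params> mod=%d iterate=%d (i=%d)\n",
                   x$mod, x$iterate, x$iterate %% x$mod))
  invisible(x)
}

#' Search for a constraint-satisfying shift transform
#'
#' If `seq` already satisfies `policy`, returns the sentinel parameters and
#' the sequence unchanged. Otherwise applies schedule steps cumulatively —
#' each pass transforms the output of the previous one — and stops at the
#' first step whose running result satisfies the policy.
#'
#' @param seq DNA string.
#' @param policy A [constraint_policy()].
#' @param mod_max Largest modulus to try before giving up.
#' @return List with elements `params` ([shift_params()]) and `seq` (the
#'   compliant sequence).
#' @export
encode_search <- function(seq, policy = constraint_policy(), mod_max = 63L) {
  assert_dna(seq)
  v <- nt_ints(seq)
  if (check_ints(v, policy)) {
    return(list(params = shift_params(sentinel = TRUE), seq = seq))
  }
  best_gc <- NA_real_; best_run <- NA_integer_
  for (m in seq.int(3L, mod_max)) {
    for (it in seq.int(2L, 4L * m + 2L)) {
      r <- it %% m
      if (r == 0L || r == 1L) next
      v <- apply_pass_ints(v, m, it, 1L)
      if (check_ints(v, policy)) {
        return(list(params = shift_params(m, it), seq = ints_nt(v)))
      }
      gc <- mean(v == 1L | v == 2L)
      run <- max(rle(v)$lengths)
      if (is.na(best_gc) || abs(gc - 0.5) + max(0L, run - policy$max_run) <
            abs(best_gc - 0.5) + max(0L, best_run - policy$max_run)) {
        best_gc <- gc; best_run <- run
      }
    }
  }
  stop(sprintf(paste0("shift schedule exhausted at mod_max=%d without a ",
                      "compliant sequence (best GC %.3f, best max run %d)"),
               mod_max, best_gc, best_run), call. = FALSE)
}

#' Invert a shift transform
#'
#' Replays the canonical schedule from `params` back to the first step
#' `(3, 2)` inclusive, applying the reverse substitution at each admissible
#' step — the exact inverse of the cumulative forward walk. Sentinel
#' parameters return the input unchanged.
#'
#' @param seq DNA string produced by [encode_search()].
#' @param params The [shift_params()] returned alongside it.
#' @param mod_max Must cover `params$mod`.
#' @return The original, pre-transform sequence.
#' @export
decode_shift <- function(seq, params, mod_max = 63L) {
  assert_dna(seq)
  stopifnot(inherits(params, "shift_params"))
  if (params$sentinel) return(seq)
  if (params$mod > mod_max) {
    stop("params outside schedule: mod exceeds mod_max", call. = FALSE)
  }
  v <- nt_ints(seq)
  for (m in seq.int(params$mod, 3L)) {
    it_top <- if (m == params$mod) params$iterate else 4L * m + 2L
    if (it_top < 2L) next
    for (it in seq.int(it_top, 2L)) {
      r <- it %% m
      if (r == 0L || r == 1L) next
      v <- apply_pass_ints(v, m, it, -1L)
    }
  }
  ints_nt(v)
}
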