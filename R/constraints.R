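#' Biological constraint policy
#'
#' Bundle of the synthesis/sequencing constraints enforced on stored DNA:
#' GC content within `[gc_min, gc_max]` (inclusive at both ends) and no
#' homopolymer run longer than `max_run` bases. The defaults — GC between
#' 40% and 60% and runs of at most three identical bases — are the standard
#' oligo-design bounds this codec targets.
#'
#' @param gc_min,gc_max GC-content bounds as fractions in `[0, 1]`.
#' @param max_run Maximum tolerated homopolymer run length (bases).
#' @return An object of class `constraint_policy`.
#' @examples
#' constraint_policy()
#' constraint_policy(max_run = 4)
#' @export
constraint_policy <- function(gc_min = 0.40, gc_max = 0.60, max_run = 3L) {
  stopifnot(is.numeric(gc_min), is.numeric(gc_max), gc_min >= 0,
            gc_max <= 1, gc_min <= gc_max, max_run >= 1)
  structure(
    list(gc_min = gc_min, gc_max = gc_max, max_run = as.integer(max_run)),
    class = "constraint_policy"
  )
}

#' @export
print.constraint_policy <- function(x, ...) {
  cat(sprintf("<constraint_policy> GC in [%g%%, %g%%], max homopolymer run %d\n",
              100 * x$gc_min, 100 * x$gc_max, x$max_run))
  invisible(x)
}

#' GC content of a DNA sequence
#'
#' @param seq A non-empty string over A/C/G/T.
#' @return Fraction of bases that are G or C.
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(seq) {
  assert_dna(seq)
  v <- nt_ints(seq)
  mean(v == 1L | v == 2L)  # C = 1, G = 2
}

#' Longest homopolymer run
#'
#' @param seq A non-empty string over A/C/G/T.
#' @return Length of the longest run of one repeated base.
#' @examples
#' max_homopolymer("AAAGAA")  # 3
#' @export
max_homopolymer <- function(seq) {
  assert_dna(seq)
  max(rle(strsplit(seq, "", fixed = TRUE)[[1L]])$lengths)
}

# Fast internal check on an integer-vector sequence; used inside the shift
# parameter search where the string round trip would dominate runtime.
check_ints <- function(v, policy) {
  gc <- mean(v == 1L | v == 2L)
  if (gc < policy$gc_min || gc > policy$gc_max) return(FALSE)
  max(rle(v)$lengths) <= policy$max_run
}

#' Check a sequence against a constraint policy
#'
#' Both GC bounds are inclusive: a sequence at exactly 40% or 60% GC passes
#' the default policy.
#'
#' @param seq A non-empty string over A/C/G/T.
#' @param policy A [constraint_policy()].
#' @return A list of class `constraint_report` with elements `gc`, `max_run`,
#'   `passes`, and `reasons` (character vector, empty when passing).
#' @examples
#' check_constraints("ACGTACGT")
#' @export
check_constraints <- function(seq, policy = constraint_policy()) {
  gc <- gc_content(seq)
  run <- max_homopolymer(seq)
  reasons <- character()
  if (gc < policy$gc_min || gc > policy$gc_max) {
    reasons <- c(reasons, sprintf("GC content %.4f outside [%g, %g]",
                                  gc, policy$gc_min, policy$gc_max))
  }
  if (run > policy$max_run) {
    reasons <- c(reasons, sprintf("homopolymer run %d exceeds %d",
                                  run, policy$max_run))
  }
  structure(
    list(gc = gc, max_run = run, passes = length(reasons) == 0L,
         reasons = reasons),
    class = "constraint_report"
  )
}

#' @export
print.constraint_report <- function(x, ...) {
  cat(sprintf("<constraint_report> GC %.2f%%, max run %d: %s\n",
              100 * x$gc, x$max_run, if (x$passes) "PASS" else "FAIL"))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Per-sequence constraint report table
#'
#' Vectorised [check_constraints()] for a set of sequences, returned as a
#' data frame suitable for TSV export (the `validate` CLI output).
#'
#' @param seqs Character vector of DNA sequences (names become the `id`
#'   column when present).
#' @param policy A [constraint_policy()].
#' @return A data frame with columns `id`, `gc`, `max_run`, `pass`.
#' @export
constraint_table <- function(seqs, policy = constraint_policy()) {
  reports <- lapply(seqs, check_constraints, policy = policy)
  data.frame(
    id = if (is.null(names(seqs))) seq_along(seqs) else names(seqs),
    gc = vapply(reports, `[[`, numeric(1), "gc"),
    max_run = vapply(reports, `[[`, integer(1), "max_run"),
    pass = vapply(reports, `[[`, logical(1), "passes"),
    stringsAsFactors = FALSE
  )
}
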