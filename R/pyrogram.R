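#' Pyro-signal objects
#'
#' A pyro-signal is the vector of chemiluminescent peak heights produced by a
#' pyrosequencing run, one peak per dispensed nucleotide. `pyro_signal()` wraps
#' a numeric height vector together with the dispensation order that produced
#' it, so that downstream code can check that signals and dictionaries refer to
#' the same order. The object behaves as a plain numeric vector in arithmetic.
#'
#' Theoretical signals are integer-valued (incorporation counts) but are stored
#' as reals so that standardized and noisy signals share one representation.
#'
#' @param heights Numeric vector of non-negative peak heights, one per
#'   dispensation.
#' @param dispensations Dispensation order string over `A`, `C`, `G`, `T`;
#'   its length must equal `length(heights)`.
#' @param standardized Logical; `TRUE` once heights are expressed in
#'   single-incorporation units (see [fuph_standardize()]).
#' @param well_id Optional well label.
#' @return A numeric vector of class `pyro_signal` with attributes
#'   `dispensations`, `standardized` and `well_id`.
#' @seealso [simulate_pyrogram()], [fuph_standardize()]
#' @export
#' @examples
#' pyro_signal(c(0, 2, 1), "CTG")
pyro_signal <- function(heights, dispensations, standardized = FALSE,
                        well_id = NULL) {
  heights <- as.numeric(heights)
  check_dispensations(dispensations)
  if (length(heights) != nchar(dispensations)) {
    abort("`heights` must have one entry per dispensation.")
  }
  if (any(is.na(heights)) || any(heights < 0)) {
    abort("peak heights must be non-negative and non-missing.")
  }
  structure(heights,
    dispensations = dispensations,
    standardized = isTRUE(standardized),
    well_id = well_id,
    class = c("pyro_signal", "numeric")
  )
}

#' @export
print.pyro_signal <- function(x, ...) {
  cat(sprintf(
    "<pyro_signal> %d dispensations (%s)%s%s\n",
    length(x), attr(x, "dispensations"),
    if (isTRUE(attr(x, "standardized"))) ", standardized" else "",
    if (!is.null(attr(x, "well_id"))) paste0(", well ", attr(x, "well_id")) else ""
  ))
  print(stats::setNames(as.numeric(x), strsplit(attr(x, "dispensations"), "")[[1]]))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble pyro_signal
#' @export
as_tibble.pyro_signal <- function(x, ...) {
  tibble(
    dispensation = seq_along(x),
    base = strsplit(attr(x, "dispensations"), "")[[1]],
    height = as.numeric(x)
  )
}

check_nuc_seq <- function(seq, arg = "sequence") {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq) || nchar(seq) == 0) {
    abort(sprintf("`%s` must be a single non-empty string.", arg))
  }
  if (grepl("[^ACGT]", seq)) {
    abort(sprintf("`%s` may only contain A, C, G and T (got \"%s\").", arg, seq))
  }
  invisible(seq)
}

check_dispensations <- function(order) {
  check_nuc_seq(order, arg = "dispensations")
}

#' Simulate a theoretical pyrogram
#'
#' Runs the standard pyrosequencing incorporation model: a read pointer starts
#' at the first base of `sequence`; for each dispensed nucleotide in turn, the
#' peak height equals the length of the homopolymer run of that base at the
#' pointer (0 on mismatch) and the pointer advances past the incorporated run.
#' Dispensations beyond the end of the template yield zero peaks.
#'
#' @param sequence Template sequence (5'→3' as read by the sequencing primer),
#'   a string over `A`, `C`, `G`, `T`.
#' @param dispensations Dispensation order string.
#' @return A [pyro_signal()] of integer-valued heights whose sum is the number
#'   of template bases consumed (at most `nchar(sequence)`).
#' @export
#' @examples
#' simulate_pyrogram("TTCCCTCCCA", "CTGCATGACTCGAT")
simulate_pyrogram <- function(sequence, dispensations) {
  check_nuc_seq(sequence)
  check_dispensations(dispensations)
  s <- strsplit(sequence, "")[[1]]
  d <- strsplit(dispensations, "")[[1]]
  heights <- numeric(length(d))
  pos <- 1L
  n <- length(s)
  for (j in seq_along(d)) {
    run <- 0L
    while (pos + run <= n && s[pos + run] == d[j]) run <- run + 1L
    heights[j] <- run
    pos <- pos + run
  }
  pyro_signal(heights, dispensations)
}

#' Number of template bases consumed by a dispensation order
#'
#' The sum of the theoretical peak heights of [simulate_pyrogram()]; equals
#' `nchar(sequence)` exactly when the order sequences the template to its end.
#' Used by the order designer as its coverage feasibility check.
#'
#' @inheritParams simulate_pyrogram
#' @return Integer count of consumed bases.
#' @export
#' @examples
#' consumed_length("TTCCCTCCCA", "CTGCATGACTCGAT") # 10: fully sequenced
#' consumed_length("A", "C") # 0
consumed_length <- function(sequence, dispensations) {
  as.integer(sum(simulate_pyrogram(sequence, dispensations)))
}

#' Reverse complement of a nucleotide sequence
#'
#' Watson–Crick complement, reversed. Used to convert sequences read from the
#' opposite strand (reverse-orientation assays) into the sense actually read
#' by the sequencing primer.
#'
#' @param sequence A string over `A`, `C`, `G`, `T`.
#' @return The reverse-complemented string.
#' @export
#' @examples
#' reverse_complement("TTCCCTCCCA")
reverse_complement <- function(sequence) {
  check_nuc_seq(sequence)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Standardize a pyro-signal by its first unitary peak height
#'
#' Divides every peak height by the height of a peak known to correspond to a
#' single nucleotide incorporation (the FUPH), putting the signal on the
#' incorporation-count scale of the theoretical dictionary. Theoretical
#' pyrograms already have FUPH 1.
#'
#' @param signal A [pyro_signal()] (or plain numeric vector with a
#'   `dispensations` attribute).
#' @param fuph Positive first unitary peak height.
#' @return The standardized [pyro_signal()] (`standardized` flag set).
#' @export
#' @examples
#' fuph_standardize(pyro_signal(c(2, 4), "AC"), fuph = 2)
fuph_standardize <- function(signal, fuph) {
  if (!is.numeric(fuph) || length(fuph) != 1 || is.na(fuph) || fuph <= 0) {
    abort("`fuph` must be a single positive number.")
  }
  pyro_signal(as.numeric(signal) / fuph,
    dispensations = attr(signal, "dispensations"),
    standardized = TRUE,
    well_id = attr(signal, "well_id")
  )
}
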