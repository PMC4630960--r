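#' Pairwise correlation between dictionary atoms
#'
#' Pearson correlations between all standardized uniplex atom signals of a
#' dictionary. A well-chosen dispensation order keeps the off-diagonal
#' entries well below 1, avoiding collinearity between the predictors of the
#' sparse decomposition. Zero-variance atoms are given correlation 0.
#'
#' @param dictionary A [build_dictionary()] result with at least two atoms.
#' @return A symmetric K x K correlation matrix named by `atom_id`.
#' @export
atom_correlation_matrix <- function(dictionary) {
  m <- atom_matrix(dictionary)
  if (ncol(m) < 2) abort("need at least two atoms.")
  safe_cor(m)
}

max_offdiag <- function(cm) {
  diag(cm) <- -Inf
  max(cm)
}

# Incremental beam-search state: per-UNS read pointers plus the partial atom
# signal matrix, extended one dispensation at a time.
extend_candidate <- function(cand, base, reads) {
  n_uns <- length(reads)
  row <- numeric(n_uns)
  ptr <- cand$ptr
  for (k in seq_len(n_uns)) {
    s <- reads[[k]]
    run <- 0L
    while (ptr[k] + run <= length(s) && s[ptr[k] + run] == base) run <- run + 1L
    row[k] <- run
    ptr[k] <- ptr[k] + run
  }
  list(
    order = c(cand$order, base),
    ptr = ptr,
    sig = rbind(cand$sig, row)
  )
}

candidate_score <- function(cand, need) {
  uncovered <- sum(pmax(0L, need - (cand$ptr - 1L)))
  corr <- if (nrow(cand$sig) >= 2) max_offdiag(safe_cor(cand$sig)) else 1
  c(uncovered = uncovered, corr = corr)
}

#' Select a dispensation order for a panel
#'
#' Breadth-first beam search for a nucleotide dispensation order that reads
#' every allele UNS of the panel at least up to its variant position (so that
#' every allele is distinguishable; set `coverage = "full"` to demand
#' consumption of every UNS to its last base) while minimizing the maximum
#' pairwise Pearson correlation between the theoretical atom signals it
#' induces. Candidate orders are extended one dispensation at a time;
#' consecutive identical dispensations are never generated (a repeated
#' nucleotide cannot incorporate after an exhausted run). Partial candidates
#' are ranked by remaining uncovered bases, then partial atom correlation,
#' and the `beam_width` best are kept at each length. Among all feasible
#' candidates the winner minimizes, lexicographically: maximum atom
#' correlation, order length, then the order string itself (so results are
#' deterministic).
#'
#' @param panel An [snp_panel()]; its current dispensation order, if any, is
#'   ignored by the search.
#' @param max_length Longest order considered.
#' @param beam_width Number of partial candidates retained per length. On
#'   panels small enough for exhaustive search, a beam at least as wide as
#'   the candidate space reproduces the exhaustive optimum.
#' @param coverage Feasibility criterion: `"variant"` (default) requires the
#'   read to reach each allele's variant base; `"full"` requires complete
#'   consumption of every UNS.
#' @param seed Accepted for interface stability; the default search is fully
#'   deterministic and does not consume randomness.
#' @return A list of class `order_search` with `order` (the selected string),
#'   `score` (its maximum pairwise atom correlation), `length`, `n_feasible`
#'   and a `report` from [validate_dispensation_order()].
#' @export
#' @examples
#' toy <- snp_panel(tibble::tibble(
#'   snp_id = "s1", allele_ref = "C", allele_alt = "G",
#'   uns_ref = "AC", uns_alt = "AG", orientation = "forward",
#'   as_read = TRUE, ploidy = 2
#' ))
#' select_dispensation_order(toy, max_length = 4, beam_width = 64)$order
select_dispensation_order <- function(panel, max_length = 20, beam_width = 50,
                                      coverage = c("variant", "full"),
                                      seed = NULL) {
  coverage <- match.arg(coverage)
  uns <- uns_as_read(panel)
  reads <- lapply(strsplit(uns$read_seq, ""), identity)
  need <- if (coverage == "full") nchar(uns$read_seq) else uns$variant_pos
  bases <- c("A", "C", "G", "T")

  beam <- list(list(order = character(0), ptr = rep(1L, length(reads)), sig = NULL))
  feasible <- list()

  for (step in seq_len(max_length)) {
    nxt <- list()
    for (cand in beam) {
      last <- if (length(cand$order)) cand$order[length(cand$order)] else ""
      for (b in setdiff(bases, last)) {
        nxt[[length(nxt) + 1L]] <- extend_candidate(cand, b, reads)
      }
    }
    scores <- t(vapply(nxt, candidate_score, numeric(2), need = need))
    ord_str <- vapply(nxt, function(c) paste(c$order, collapse = ""), "")
    keep <- order(scores[, "uncovered"], scores[, "corr"], ord_str)
    beam <- nxt[keep[seq_len(min(beam_width, length(nxt)))]]

    done <- which(scores[, "uncovered"] == 0)
    for (i in done) {
      feasible[[length(feasible) + 1L]] <- list(
        order = ord_str[i], score = scores[i, "corr"], length = step
      )
    }
  }

  if (length(feasible) == 0) {
    cov <- beam[[1]]$ptr - 1L
    missing <- uns$snp_id[cov < need]
    abort(paste0(
      "no feasible order of length <= ", max_length,
      " covers every UNS; uncovered SNPs in the best candidate: ",
      paste(unique(missing), collapse = ", ")
    ))
  }

  sc <- vapply(feasible, `[[`, numeric(1), "score")
  len <- vapply(feasible, `[[`, numeric(1), "length")
  os <- vapply(feasible, `[[`, "", "order")
  best <- order(sc, len, os)[1]

  structure(
    list(
      order = os[best],
      score = sc[best],
      length = len[best],
      n_feasible = length(feasible),
      report = validate_dispensation_order(panel, os[best])
    ),
    class = "order_search"
  )
}

#' @export
print.order_search <- function(x, ...) {
  cat(sprintf(
    "<order_search> %s (length %d), max atom correlation %.4f, %d feasible candidates\n",
    x$order, x$length, x$score, x$n_feasible
  ))
  invisible(x)
}

#' Validate a dispensation order against a panel
#'
#' Checks, per allele UNS, how far the order reads into the template and
#' whether it reaches the variant base (the condition for the allele to be
#' distinguishable at all); summarizes the collinearity of the induced atom
#' dictionary; computes the ambiguity index over all genotype combinations;
#' and flags whether every combination yields a unique multiplex signal.
#' Full consumption of every UNS is reported too, but an order can be
#' perfectly usable without it.
#'
#' @param panel An [snp_panel()].
#' @param dispensations Dispensation order string to validate.
#' @return A list of class `order_validation` with elements `coverage`
#'   (tibble: snp_id, allele, read_seq, length, consumed, variant_pos,
#'   variant_read, fully_consumed), `all_covered` (every variant read),
#'   `all_fully_consumed`, `atom_correlation_max`, `ambiguity` (max
#'   combination correlation) and `unique_combinations`.
#' @export
validate_dispensation_order <- function(panel, dispensations) {
  check_dispensations(dispensations)
  p <- panel
  dispensation_order(p) <- dispensations
  uns <- uns_as_read(p)
  coverage <- uns |>
    mutate(
      length = nchar(.data$read_seq),
      consumed = purrr::map_int(.data$read_seq, consumed_length, dispensations = dispensations),
      variant_read = .data$consumed >= .data$variant_pos,
      fully_consumed = .data$consumed == .data$length
    ) |>
    select(
      "snp_id", "allele", "read_seq", "length", "consumed",
      "variant_pos", "variant_read", "fully_consumed"
    )

  dict <- build_dictionary(p)
  amb <- ambiguity_index(p, dict)
  sigs <- vapply(amb$combinations$signal, paste, "", collapse = ",")
  structure(
    list(
      coverage = coverage,
      all_covered = all(coverage$variant_read),
      all_fully_consumed = all(coverage$fully_consumed),
      atom_correlation_max = max_offdiag(atom_correlation_matrix(dict)),
      ambiguity = amb$max_correlation,
      unique_combinations = !anyDuplicated(sigs)
    ),
    class = "order_validation"
  )
}

#' @export
print.order_validation <- function(x, ...) {
  cat(sprintf(
    "<order_validation> variants read %d/%d, fully consumed %d/%d, max atom correlation %.4f, ambiguity %.4f, unique combinations: %s\n",
    sum(x$coverage$variant_read), nrow(x$coverage),
    sum(x$coverage$fully_consumed), nrow(x$coverage),
    x$atom_correlation_max, x$ambiguity, x$unique_combinations
  ))
  invisible(x)
}
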