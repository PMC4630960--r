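#' Build the standardized learning dictionary for a panel
#'
#' The dictionary is the set of standardized uniplex "atom" pyro-signals that
#' a multiplex signal is decomposed against: one theoretical atom per SNP
#' allele, obtained by simulating the allele's as-read UNS under the panel's
#' dispensation order (theoretical signals have first unitary peak height 1 by
#' construction), optionally followed by experimental uniplex signals which
#' are FUPH-standardized before inclusion. Experimental atoms supplement the
#' theoretical ones; they never replace them.
#'
#' Theoretical atoms that are identical to an earlier atom are kept but
#' flagged in the `duplicate_of` column, and the count of distinct theoretical
#' signals is stored in `$n_distinct_theoretical` (identical atoms arise when
#' a dispensation order stops short of the variant position of some UNS).
#'
#' @param panel An [snp_panel()] with its dispensation order set.
#' @param experimental_signals Optional tibble of uniplex measurements with
#'   columns `snp_id`, `allele`, `fuph` and `signal` (a list column of
#'   numeric height vectors of the panel's signal length).
#' @return A `pyro_dictionary`: a list with elements `atoms` (tibble with
#'   columns `atom_id`, `snp_id`, `allele`, `role`, `source`, `duplicate_of`
#'   and the list column `signal`), `dispensations`, `panel_name` and
#'   `n_distinct_theoretical`.
#' @seealso [atom_matrix()], [genotype_signal()], [decompose_pyrosignal()]
#' @export
#' @examples
#' dict <- build_dictionary(quadruplex_panel())
#' dict$n_distinct_theoretical
build_dictionary <- function(panel, experimental_signals = NULL) {
  order <- dispensation_order(panel)
  if (is.null(order)) abort("panel has no dispensation order; set one first.")
  m <- nchar(order)

  atoms <- uns_as_read(panel) |>
    mutate(
      source = "theoretical",
      atom_id = paste(.data$snp_id, .data$allele, "theoretical", sep = "_"),
      signal = purrr::map(.data$read_seq, function(s) {
        as.numeric(simulate_pyrogram(s, order))
      })
    ) |>
    select("atom_id", "snp_id", "allele", "role", "source", "signal")

  if (!is.null(experimental_signals)) {
    exp_tbl <- as_tibble(experimental_signals)
    needed <- c("snp_id", "allele", "fuph", "signal")
    if (!all(needed %in% names(exp_tbl))) {
      abort("`experimental_signals` needs columns snp_id, allele, fuph, signal.")
    }
    bad_len <- which(purrr::map_int(exp_tbl$signal, length) != m)
    if (length(bad_len) > 0) {
      abort(sprintf(
        "experimental signal %d has %d heights; the panel order has %d dispensations.",
        bad_len[1], length(exp_tbl$signal[[bad_len[1]]]), m
      ))
    }
    key <- paste(atoms$snp_id, atoms$allele)
    exp_key <- paste(exp_tbl$snp_id, exp_tbl$allele)
    if (!all(exp_key %in% key)) {
      abort("experimental signals refer to snp/allele pairs absent from the panel.")
    }
    exp_atoms <- exp_tbl |>
      mutate(
        role = atoms$role[match(exp_key, key)],
        source = "experimental",
        signal = purrr::map2(.data$signal, .data$fuph, function(s, f) {
          as.numeric(fuph_standardize(pyro_signal(s, order), f))
        })
      ) |>
      group_by(.data$snp_id, .data$allele) |>
      mutate(atom_id = paste(.data$snp_id, .data$allele, "experimental",
        row_number(),
        sep = "_"
      )) |>
      ungroup() |>
      select("atom_id", "snp_id", "allele", "role", "source", "signal")
    atoms <- bind_rows(atoms, exp_atoms)
  }

  sig_key <- purrr::map_chr(atoms$signal, paste, collapse = ",")
  first_idx <- match(sig_key, sig_key)
  atoms$duplicate_of <- ifelse(first_idx < seq_along(sig_key),
    atoms$atom_id[first_idx], NA_character_
  )

  theo <- atoms$source == "theoretical"
  structure(
    list(
      atoms = atoms,
      dispensations = order,
      panel_name = attr(panel, "panel_name"),
      n_distinct_theoretical = length(unique(sig_key[theo]))
    ),
    class = "pyro_dictionary"
  )
}

#' @export
print.pyro_dictionary <- function(x, ...) {
  cat(sprintf(
    "<pyro_dictionary> \"%s\": %d atoms (%d theoretical, %d distinct theoretical signals) over order %s\n",
    x$panel_name, nrow(x$atoms), sum(x$atoms$source == "theoretical"),
    x$n_distinct_theoretical, x$dispensations
  ))
  print(x$atoms)
  invisible(x)
}

#' Dictionary as a dispensations-by-atoms matrix
#'
#' @param dictionary A [build_dictionary()] result.
#' @return An m x K numeric matrix; columns are named by `atom_id`.
#' @export
atom_matrix <- function(dictionary) {
  stopifnot(inherits(dictionary, "pyro_dictionary"))
  m <- do.call(cbind, dictionary$atoms$signal)
  dimnames(m) <- list(NULL, dictionary$atoms$atom_id)
  m
}

genotype_states <- function(ploidy) {
  if (ploidy == 1) c("hemi_ref", "hemi_alt") else c("hom_ref", "het", "hom_alt")
}

#' Theoretical pyro-signal of one genotype
#'
#' Homozygous (and hemizygous) genotypes produce that allele's atom at full
#' height. A heterozygote carries one template copy of each allele, so its
#' signal is the superposition of both homozygote atoms at half height —
#' the heterozygote correction applied throughout the package:
#' `0.5 * (atom_ref + atom_alt)`.
#'
#' Only theoretical atoms enter genotype composition.
#'
#' @param dictionary A [build_dictionary()] result.
#' @param snp_id SNP identifier present in the dictionary.
#' @param state One of `"hom_ref"`, `"het"`, `"hom_alt"` (diploid) or
#'   `"hemi_ref"`, `"hemi_alt"` (haploid).
#' @return A standardized [pyro_signal()].
#' @export
genotype_signal <- function(dictionary, snp_id, state) {
  stopifnot(inherits(dictionary, "pyro_dictionary"))
  atoms <- dictionary$atoms
  sel <- atoms$snp_id == snp_id & atoms$source == "theoretical"
  if (!any(sel)) abort(sprintf("SNP \"%s\" is not in the dictionary.", snp_id))
  ref <- atoms$signal[sel & atoms$role == "ref"][[1]]
  alt <- atoms$signal[sel & atoms$role == "alt"][[1]]
  h <- switch(state,
    hom_ref = ,
    hemi_ref = ref,
    hom_alt = ,
    hemi_alt = alt,
    het = 0.5 * (ref + alt),
    abort(sprintf("unknown genotype state \"%s\".", state))
  )
  pyro_signal(h, dictionary$dispensations, standardized = TRUE)
}

#' Enumerate all theoretical multiplex combination signals
#'
#' Forms the Cartesian product of per-SNP genotype states (three states for
#' diploid SNPs, two for haploid ones) and, for each combination, sums the
#' per-SNP [genotype_signal()]s with equal weight. These are the noiseless
#' multiplex signals an assay can produce under equal per-SNP amplification.
#'
#' @inheritParams build_dictionary
#' @param dictionary Optional pre-built dictionary (built from `panel` when
#'   omitted).
#' @param force_diploid If `TRUE`, haploid SNPs are enumerated with the three
#'   diploid states as well. This is the convention used for order-design
#'   ambiguity scoring (see the package vignette); genotype calling and
#'   simulation always respect true ploidy.
#' @return A tibble with one row per combination: `combo_id`, a `genotype`
#'   list column of named per-SNP states, and a `signal` list column.
#' @export
enumerate_combination_signals <- function(panel, dictionary = NULL,
                                          force_diploid = FALSE) {
  dictionary <- dictionary %||% build_dictionary(panel)
  states <- lapply(panel$ploidy, function(p) {
    genotype_states(if (force_diploid) 2L else p)
  })
  names(states) <- panel$snp_id
  grid <- expand.grid(states, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)

  per_snp_state_signals <- lapply(panel$snp_id, function(id) {
    sigs <- lapply(unique(unlist(states)), function(st) {
      ok <- tryCatch(genotype_signal(dictionary, id, st), error = function(e) NULL)
      if (is.null(ok)) NULL else as.numeric(ok)
    })
    stats::setNames(sigs, unique(unlist(states)))
  })
  names(per_snp_state_signals) <- panel$snp_id

  signals <- lapply(seq_len(nrow(grid)), function(i) {
    tot <- numeric(nchar(dictionary$dispensations))
    for (id in panel$snp_id) {
      tot <- tot + per_snp_state_signals[[id]][[grid[i, id]]]
    }
    tot
  })
  tibble(
    combo_id = seq_len(nrow(grid)),
    genotype = lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, , drop = FALSE])),
    signal = signals
  )
}

# Pearson correlation matrix with zero-variance columns given correlation 0
# (and excluded from any argmax by construction).
safe_cor <- function(m) {
  sds <- apply(m, 2, stats::sd)
  out <- matrix(0, ncol(m), ncol(m), dimnames = list(colnames(m), colnames(m)))
  ok <- !is.na(sds) & sds > 0
  if (sum(ok) >= 2) out[ok, ok] <- stats::cor(m[, ok, drop = FALSE])
  diag(out) <- 1
  out
}

#' Ambiguity index of a panel under its dispensation order
#'
#' The maximum pairwise Pearson correlation over all distinct theoretical
#' multiplex combination signals of [enumerate_combination_signals()]. Values
#' close to 1 mean two genotype combinations produce nearly collinear
#' multiplex signals and are hard to tell apart; a value of exactly 1 means
#' two combinations are indistinguishable. Correlation with a zero-variance
#' signal is defined as 0 and cannot attain the maximum.
#'
#' @inheritParams enumerate_combination_signals
#' @return A list with `max_correlation`, `pair` (the two achieving
#'   combination ids), `n_combinations` and the `combinations` tibble.
#' @export
#' @examples
#' ambiguity_index(quadruplex_panel(), force_diploid = TRUE)$max_correlation
ambiguity_index <- function(panel, dictionary = NULL, force_diploid = FALSE) {
  combos <- enumerate_combination_signals(panel, dictionary, force_diploid)
  if (nrow(combos) < 2) abort("ambiguity index needs at least two combinations.")
  m <- do.call(cbind, combos$signal)
  colnames(m) <- combos$combo_id
  cm <- safe_cor(m)
  diag(cm) <- -Inf
  imax <- which(cm == max(cm), arr.ind = TRUE)[1, ]
  list(
    max_correlation = max(cm),
    pair = combos$combo_id[imax],
    n_combinations = nrow(combos),
    combinations = combos
  )
}
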