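#' Well-by-dispensation signal tables
#'
#' A signal table holds the peak heights of a plate of wells run under one
#' dispensation order, one well per row. On disk the dialect is plain CSV:
#' the first line is the dispensation order string itself, every following
#' line is `well_id,h1,...,hm` with exactly one height per dispensation.
#'
#' @param heights Numeric matrix (wells x dispensations) or data frame of
#'   heights.
#' @param dispensations Dispensation order string; its length must match the
#'   number of height columns.
#' @param well_ids Character vector of well labels (defaults to `W1`, `W2`,
#'   ...).
#' @return A tibble of class `signal_table` with a `well_id` column, one
#'   `h<i>` column per dispensation, and a `dispensations` attribute.
#' @export
signal_table <- function(heights, dispensations, well_ids = NULL) {
  check_dispensations(dispensations)
  heights <- as.matrix(heights)
  m <- nchar(dispensations)
  if (ncol(heights) != m) {
    abort(sprintf(
      "heights have %d columns but the order has %d dispensations.",
      ncol(heights), m
    ))
  }
  if (any(heights < 0) || any(is.na(heights))) {
    abort("heights must be non-negative and non-missing.")
  }
  well_ids <- well_ids %||% rownames(heights) %||% paste0("W", seq_len(nrow(heights)))
  out <- as_tibble(as.data.frame(heights), .name_repair = "minimal")
  names(out) <- paste0("h", seq_len(m))
  out <- bind_cols(tibble(well_id = as.character(well_ids)), out)
  structure(out,
    dispensations = dispensations,
    class = c("signal_table", class(out))
  )
}

# Heights of a signal table as a numeric matrix with well_id rownames.
signal_heights <- function(signals, dispensations = NULL) {
  disp <- attr(signals, "dispensations")
  if (!is.null(dispensations) && !is.null(disp) && disp != dispensations) {
    abort(sprintf(
      "signal table order (%s) does not match the panel order (%s).",
      disp, dispensations
    ))
  }
  h <- as.matrix(signals[, setdiff(names(signals), "well_id"), drop = FALSE])
  storage.mode(h) <- "double"
  rownames(h) <- signals$well_id
  m <- nchar(dispensations %||% disp)
  if (!is.null(m) && ncol(h) != m) {
    abort(sprintf(
      "signal table has %d heights per well; the order has %d dispensations.",
      ncol(h), m
    ))
  }
  h
}

#' Read or write a signal table
#'
#' See [signal_table()] for the CSV dialect. Heights are written with six
#' significant digits, so `read_signal_table(write_signal_table(x, p))`
#' round-trips up to that precision.
#'
#' @param path File path.
#' @return `read_signal_table()` returns a [signal_table()];
#'   `write_signal_table()` returns `path` invisibly.
#' @export
read_signal_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) abort("signal file needs a header line and at least one well.")
  dispensations <- trimws(lines[1])
  if (grepl("[^ACGT]", dispensations)) {
    abort(sprintf(
      "line 1: header must be a dispensation order over A/C/G/T (got \"%s\").",
      dispensations
    ))
  }
  m <- nchar(dispensations)
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  well_ids <- character(length(rows))
  heights <- matrix(NA_real_, length(rows), m)
  for (i in seq_along(rows)) {
    r <- trimws(rows[[i]])
    if (length(r) != m + 1) {
      abort(sprintf(
        "line %d: expected well_id plus %d heights, found %d fields.",
        i + 1, m, length(r)
      ))
    }
    h <- suppressWarnings(as.numeric(r[-1]))
    if (any(is.na(h))) {
      abort(sprintf("line %d: heights must be numeric.", i + 1))
    }
    if (any(h < 0)) {
      abort(sprintf("line %d: heights must be non-negative.", i + 1))
    }
    well_ids[i] <- r[1]
    heights[i, ] <- h
  }
  signal_table(heights, dispensations, well_ids = well_ids)
}

#' @rdname read_signal_table
#' @param signals A [signal_table()].
#' @export
write_signal_table <- function(signals, path) {
  h <- signal_heights(signals)
  lines <- c(
    attr(signals, "dispensations"),
    vapply(seq_len(nrow(h)), function(i) {
      paste(c(rownames(h)[i], formatC(h[i, ], digits = 6, format = "g")),
        collapse = ","
      )
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

normalize_genotype <- function(g) {
  if (is.na(g)) {
    return(NA_character_)
  }
  paste(sort(strsplit(g, "/")[[1]]), collapse = "/")
}

#' Genotype concordance between calls and truth
#'
#' Compares called genotypes against a reference table over the shared
#' (well, SNP) pairs. Genotypes are compared as unordered allele sets, so
#' `"G/T"` and `"T/G"` agree. No-calls count as discordant and are listed.
#'
#' @param calls Tibble with `well_id`, `snp_id` and a `genotype` column
#'   (e.g. from [genotype_wells()]).
#' @param truth Reference tibble of the same shape (a `patient_id` column is
#'   accepted in place of `well_id`).
#' @return A list of class `concordance_report` with `n_compared`,
#'   `n_concordant`, `percent`, `per_snp` (tibble) and `discordant` (tibble
#'   of well, snp, truth, call).
#' @export
concordance <- function(calls, truth) {
  fix <- function(x) {
    if (!"well_id" %in% names(x) && "patient_id" %in% names(x)) {
      x <- rename(x, well_id = "patient_id")
    }
    if (!all(c("well_id", "snp_id", "genotype") %in% names(x))) {
      abort("need columns well_id (or patient_id), snp_id and genotype.")
    }
    x[, c("well_id", "snp_id", "genotype")]
  }
  calls <- fix(calls)
  truth <- fix(truth)
  joined <- inner_join(calls, truth,
    by = c("well_id", "snp_id"), suffix = c("_call", "_truth")
  )
  if (nrow(joined) == 0) abort("calls and truth share no (well, SNP) pairs.")
  joined <- joined |>
    mutate(
      g_call = vapply(.data$genotype_call, normalize_genotype, ""),
      g_truth = vapply(.data$genotype_truth, normalize_genotype, ""),
      concordant = !is.na(.data$g_call) & .data$g_call == .data$g_truth
    )
  per_snp <- joined |>
    group_by(.data$snp_id) |>
    summarise(
      n_compared = n(),
      n_concordant = sum(.data$concordant),
      percent = 100 * sum(.data$concordant) / n(),
      .groups = "drop"
    )
  structure(
    list(
      n_compared = nrow(joined),
      n_concordant = sum(joined$concordant),
      percent = 100 * sum(joined$concordant) / nrow(joined),
      per_snp = per_snp,
      discordant = joined |>
        filter(!.data$concordant) |>
        select("well_id", "snp_id",
          truth = "genotype_truth", call = "genotype_call"
        )
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "<concordance_report> %d/%d concordant (%.1f%%)\n",
    x$n_concordant, x$n_compared, x$percent
  ))
  if (nrow(x$discordant) > 0) {
    cat("discordant calls:\n")
    print(x$discordant)
  }
  invisible(x)
}
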