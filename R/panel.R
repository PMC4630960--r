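#' SNP panel objects
#'
#' A panel groups the bi-allelic SNPs of one multiplex pyrosequencing assay
#' together with the nucleotide dispensation order the assay is run under.
#' Each SNP carries the two 10-nt unique nucleotide sequences (UNS) expected
#' downstream of its sequencing primer — one per allele — plus assay
#' orientation, ploidy and population parameters.
#'
#' The `as_read` column records the strand convention of the stored UNS pair:
#' `TRUE` means the string is the sequence as read by the sequencing primer
#' and is simulated directly; `FALSE` means it is stored in reporting
#' (genomic) sense and is reverse-complemented before pyrogram simulation.
#' Allele labels always refer to the stored (reporting-sense) strings, so
#' genotypes are reported in the same letters regardless of orientation.
#'
#' @param snps A data frame with columns `snp_id`, `chromosome`,
#'   `allele_ref`, `allele_alt`, `uns_ref`, `uns_alt`, `orientation`
#'   (`"forward"`/`"reverse"`), `as_read` (logical), `ploidy` (1 or 2),
#'   `maf` (frequency of `allele_alt`, in (0, 0.5] for a minor allele) and
#'   `allelic_or`. An optional `group` column labels the assay.
#' @param dispensation_order Dispensation order string for the assay, or
#'   `NULL` for a panel not yet assigned an order.
#' @param name Panel label.
#' @return A tibble of class `snp_panel` with attributes
#'   `dispensation_order` and `panel_name`.
#' @seealso [quadruplex_panel()], [quintuplex_panel()], [read_panel()]
#' @export
snp_panel <- function(snps, dispensation_order = NULL, name = "panel") {
  required <- c(
    "snp_id", "allele_ref", "allele_alt", "uns_ref", "uns_alt",
    "orientation", "as_read", "ploidy"
  )
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    abort(paste0("panel is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  snps <- as_tibble(snps)
  if (anyDuplicated(snps$snp_id)) abort("each SNP may appear only once in a panel.")
  if (nrow(snps) < 1) abort("a panel needs at least one SNP.")
  for (i in seq_len(nrow(snps))) {
    check_nuc_seq(snps$uns_ref[i], "uns_ref")
    check_nuc_seq(snps$uns_alt[i], "uns_alt")
    if (nchar(snps$uns_ref[i]) != nchar(snps$uns_alt[i])) {
      abort(sprintf("%s: allele UNS must have equal length.", snps$snp_id[i]))
    }
    diffs <- which(strsplit(snps$uns_ref[i], "")[[1]] != strsplit(snps$uns_alt[i], "")[[1]])
    if (length(diffs) != 1) {
      abort(sprintf(
        "%s: the two allele UNS must differ at exactly one position (found %d).",
        snps$snp_id[i], length(diffs)
      ))
    }
    ref_base <- substr(snps$uns_ref[i], diffs, diffs)
    alt_base <- substr(snps$uns_alt[i], diffs, diffs)
    if (ref_base != snps$allele_ref[i] || alt_base != snps$allele_alt[i]) {
      abort(sprintf(
        "%s: allele labels (%s/%s) do not match the variant bases of the UNS pair (%s/%s).",
        snps$snp_id[i], snps$allele_ref[i], snps$allele_alt[i], ref_base, alt_base
      ))
    }
  }
  if (!all(snps$ploidy %in% c(1L, 2L))) abort("`ploidy` must be 1 or 2.")
  if (!all(snps$orientation %in% c("forward", "reverse"))) {
    abort('`orientation` must be "forward" or "reverse".')
  }
  if (!is.null(dispensation_order)) check_dispensations(dispensation_order)
  structure(snps,
    dispensation_order = dispensation_order,
    panel_name = name,
    class = c("snp_panel", class(snps))
  )
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf(
    "<snp_panel> \"%s\": %d SNPs, dispensation order %s\n",
    attr(x, "panel_name"), nrow(x),
    if (is.null(attr(x, "dispensation_order"))) "(unset)" else attr(x, "dispensation_order")
  ))
  NextMethod()
}

#' Dispensation order of a panel
#'
#' @param panel An [snp_panel()].
#' @return The panel's dispensation order string (or `NULL` if unset).
#' @export
dispensation_order <- function(panel) {
  attr(panel, "dispensation_order")
}

#' @rdname dispensation_order
#' @param value New dispensation order string.
#' @export
`dispensation_order<-` <- function(panel, value) {
  check_dispensations(value)
  attr(panel, "dispensation_order") <- value
  panel
}

# One row per SNP allele with the template sequence actually read by the
# sequencing primer (reverse-complemented when as_read = FALSE) and the
# 1-based position of the variant base on that read.
uns_as_read <- function(panel) {
  long <- tidyr::pivot_longer(
    as_tibble(panel)[, c("snp_id", "as_read", "ploidy", "allele_ref", "allele_alt", "uns_ref", "uns_alt")],
    cols = c("uns_ref", "uns_alt"),
    names_to = "role", names_prefix = "uns_", values_to = "uns"
  ) |>
    mutate(
      allele = ifelse(.data$role == "ref", .data$allele_ref, .data$allele_alt),
      read_seq = ifelse(.data$as_read, .data$uns,
        purrr::map_chr(.data$uns, reverse_complement)
      )
    ) |>
    select("snp_id", "ploidy", "role", "allele", "uns", "read_seq")
  long |>
    group_by(.data$snp_id) |>
    mutate(variant_pos = which(
      strsplit(.data$read_seq[1], "")[[1]] != strsplit(.data$read_seq[2], "")[[1]]
    )[1]) |>
    ungroup()
}

#' Built-in prostate-cancer SNP panels
#'
#' Nine prostate-cancer risk SNPs split over two multiplex pyrosequencing
#' assays: a quadruplex (rs1016343, rs10993994, rs16901979 and the X-linked
#' rs5945619) run under dispensation order `CTGCATGACTCGAT`, and a quintuplex
#' (rs10896449, rs1859962, rs4242382, rs4430796, rs6983267) run under
#' `AGATCGCTACGACTG`. Per SNP the fixture carries the two allele UNS, assay
#' orientation, ploidy (1 for the X-linked SNP, genotyped hemizygously in the
#' all-male cohort), the alt-allele frequency used by [sample_cohort()] and
#' the allelic odds ratio.
#'
#' `pca_snp_panel()` returns the full nine-SNP table without an order;
#' `quadruplex_panel()` and `quintuplex_panel()` return ready-to-use
#' [snp_panel()] objects.
#'
#' @return A tibble ([pca_snp_panel()]) or an [snp_panel()].
#' @export
pca_snp_panel <- function() {
  path <- system.file("extdata", "pca_snp_panel.tsv", package = "pyromux")
  as_tibble(read.delim(path, colClasses = c(chromosome = "character")))
}

#' @rdname pca_snp_panel
#' @export
quadruplex_panel <- function() {
  snps <- pca_snp_panel()
  snp_panel(snps[snps$group == "quadruplex", ],
    dispensation_order = "CTGCATGACTCGAT", name = "quadruplex"
  )
}

#' @rdname pca_snp_panel
#' @export
quintuplex_panel <- function() {
  snps <- pca_snp_panel()
  snp_panel(snps[snps$group == "quintuplex", ],
    dispensation_order = "AGATCGCTACGACTG", name = "quintuplex"
  )
}

#' Read or write a panel definition file
#'
#' Panels are stored as tab-separated text with one row per SNP and the
#' columns documented in [snp_panel()].
#'
#' @param path File path.
#' @inheritParams snp_panel
#' @return `read_panel()` returns an [snp_panel()]; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path, dispensation_order = NULL, name = NULL) {
  tab <- read.delim(path, colClasses = if ("chromosome" %in% names(read.delim(path, nrows = 1))) c(chromosome = "character") else NA)
  snp_panel(tab,
    dispensation_order = dispensation_order,
    name = name %||% sub("\\.[^.]*$", "", basename(path))
  )
}

#' @rdname read_panel
#' @param panel An [snp_panel()] or compatible data frame.
#' @export
write_panel <- function(panel, path) {
  write.table(as.data.frame(panel), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
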