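#' Turnaround-time and reagent-cost model
#'
#' Per-step durations (minutes) and per-patient reagent costs (US$) of the
#' uniplex and multiplex genotyping workflows for a nine-SNP panel run as
#' nine uniplex reactions versus one quadruplex plus one quintuplex assay.
#' Defaults are the published figures for the built-in panel; all fields can
#' be overridden for other assays.
#'
#' @param pcr_min PCR duration per run.
#' @param pyro_uniplex_min,pyro_multiplex_min Pyrosequencing duration per
#'   uniplex / multiplex run (a multiplex run dispenses more nucleotides and
#'   takes slightly longer).
#' @param buffy_min,extraction_min,quantification_min Shared sample
#'   preparation steps, identical for both workflows and reported separately
#'   from the headline totals.
#' @param cost_extraction,cost_pcr_uniplex,cost_pyro_uniplex,cost_pcr_multiplex,cost_pyro_multiplex
#'   Per-patient reagent costs.
#' @param currency Currency label.
#' @return A list of class `cost_tat_model`.
#' @export
cost_tat_model <- function(pcr_min = 165,
                           pyro_uniplex_min = 60,
                           pyro_multiplex_min = 70,
                           buffy_min = 30,
                           extraction_min = 30,
                           quantification_min = 20,
                           cost_extraction = 16.5,
                           cost_pcr_uniplex = 71.0,
                           cost_pyro_uniplex = 141.5,
                           cost_pcr_multiplex = 16.0,
                           cost_pyro_multiplex = 31.5,
                           currency = "US$") {
  model <- list(
    pcr_min = pcr_min,
    pyro_uniplex_min = pyro_uniplex_min,
    pyro_multiplex_min = pyro_multiplex_min,
    buffy_min = buffy_min,
    extraction_min = extraction_min,
    quantification_min = quantification_min,
    cost_extraction = cost_extraction,
    cost_pcr_uniplex = cost_pcr_uniplex,
    cost_pyro_uniplex = cost_pyro_uniplex,
    cost_pcr_multiplex = cost_pcr_multiplex,
    cost_pyro_multiplex = cost_pyro_multiplex,
    currency = currency
  )
  if (any(vapply(model[-length(model)], function(v) v < 0, logical(1)))) {
    abort("durations and costs must be non-negative.")
  }
  structure(model, class = "cost_tat_model")
}

#' Compare turnaround time of uniplex versus multiplex workflows
#'
#' Headline totals are `(pcr + pyro) * number of runs` for each workflow;
#' shared sample preparation (buffy coat, extraction, quantification) is
#' identical for both and reported separately, not added to the totals.
#'
#' @param model A [cost_tat_model()].
#' @param n_uniplex,n_multiplex Number of uniplex / multiplex runs needed to
#'   cover the panel (9 and 2 for the built-in nine-SNP panel).
#' @return A one-row tibble with `uniplex_min`, `multiplex_min`,
#'   `shared_prep_min` and `reduction_pct`.
#' @export
#' @examples
#' tat_compare() # 2025 vs 470 min
tat_compare <- function(model = cost_tat_model(), n_uniplex = 9, n_multiplex = 2) {
  stopifnot(n_uniplex >= 1, n_multiplex >= 1)
  uni <- (model$pcr_min + model$pyro_uniplex_min) * n_uniplex
  multi <- (model$pcr_min + model$pyro_multiplex_min) * n_multiplex
  tibble(
    uniplex_min = uni,
    multiplex_min = multi,
    shared_prep_min = model$buffy_min + model$extraction_min + model$quantification_min,
    reduction_pct = 100 * (1 - multi / uni)
  )
}

#' Compare per-patient reagent costs of uniplex versus multiplex workflows
#'
#' Each total is extraction + PCR + pyrosequencing reagents for one patient
#' across the whole panel (extraction is counted once per patient in both
#' workflows).
#'
#' @param model A [cost_tat_model()].
#' @return A one-row tibble with `uniplex_total`, `multiplex_total`,
#'   `reduction_pct` and `currency`.
#' @export
#' @examples
#' cost_compare() # ~229 vs ~64 US$/patient
cost_compare <- function(model = cost_tat_model()) {
  uni <- model$cost_extraction + model$cost_pcr_uniplex + model$cost_pyro_uniplex
  multi <- model$cost_extraction + model$cost_pcr_multiplex + model$cost_pyro_multiplex
  tibble(
    uniplex_total = uni,
    multiplex_total = multi,
    reduction_pct = 100 * (1 - multi / uni),
    currency = model$currency
  )
}

#' Waste-material model and comparison
#'
#' Consumables used to genotype a full 96-well plate of patients with the
#' nine-SNP panel: nine uniplex runs versus one quadruplex plus one
#' quintuplex run. Defaults are the published counts for the built-in panel.
#'
#' @param pcr_plates,pcr_tips,pyro_plates,pyro_tips,reagent_bottles
#'   Length-2 numeric vectors `c(uniplex, multiplex)`.
#' @return `waste_model()` returns a named list of class `waste_model`;
#'   `waste_compare()` returns a tibble with one row per item and columns
#'   `item`, `uniplex`, `multiplex`, `reduction_pct`.
#' @export
#' @examples
#' waste_compare()
waste_model <- function(pcr_plates = c(9, 2),
                        pcr_tips = c(936, 222),
                        pyro_plates = c(9, 2),
                        pyro_tips = c(918, 211),
                        reagent_bottles = c(18, 4)) {
  items <- list(
    pcr_plates = pcr_plates, pcr_tips = pcr_tips,
    pyro_plates = pyro_plates, pyro_tips = pyro_tips,
    reagent_bottles = reagent_bottles
  )
  for (nm in names(items)) {
    if (length(items[[nm]]) != 2 || any(items[[nm]] < 0)) {
      abort(sprintf("`%s` must be two non-negative counts c(uniplex, multiplex).", nm))
    }
  }
  structure(items, class = "waste_model")
}

#' @rdname waste_model
#' @param model A `waste_model()`.
#' @export
waste_compare <- function(model = waste_model()) {
  tibble(
    item = names(model),
    uniplex = unname(vapply(unclass(model), `[`, numeric(1), 1)),
    multiplex = unname(vapply(unclass(model), `[`, numeric(1), 2)),
  ) |>
    mutate(reduction_pct = ifelse(.data$uniplex > 0,
      100 * (1 - .data$multiplex / .data$uniplex), 0
    ))
}
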