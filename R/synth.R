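#' Noise model for synthetic pyro-signals
#'
#' Describes how a simulated well departs from the clean theoretical
#' superposition: peaks are scaled by `fuph_scale` (emulating the arbitrary
#' light-intensity units of a given sequencer — different instruments report
#' different absolute scales), shifted by a constant `background`, and
#' perturbed by Gaussian noise with an affine standard deviation
#' `sd_base + sd_prop * height` before truncation at zero.
#'
#' @param sd_base Additive noise floor (in scaled height units).
#' @param sd_prop Proportional noise coefficient.
#' @param background Constant added to every peak.
#' @param fuph_scale First-unitary-peak height of the simulated instrument;
#'   irrelevant to genotype calls, which are scale invariant.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sd_base = 0.03, sd_prop = 0.02, background = 0,
                        fuph_scale = 7) {
  stopifnot(sd_base >= 0, sd_prop >= 0, background >= 0, fuph_scale > 0)
  structure(
    list(
      sd_base = sd_base, sd_prop = sd_prop,
      background = background, fuph_scale = fuph_scale
    ),
    class = "noise_model"
  )
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Sample a synthetic cohort under Hardy-Weinberg equilibrium
#'
#' Draws per-patient genotypes for every SNP of a panel. Diploid SNPs are
#' sampled under Hardy-Weinberg equilibrium with alt-allele frequency `maf`;
#' haploid (hemizygous) SNPs are Bernoulli draws of the alt allele.
#'
#' @param panel An [snp_panel()] with a populated `maf` column.
#' @param n Number of patients.
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @return A tibble with `patient_id`, `snp_id`, `state` and the
#'   corresponding `genotype` string.
#' @export
sample_cohort <- function(panel, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!"maf" %in% names(panel) || any(is.na(panel$maf))) {
    abort("panel must carry a `maf` value for every SNP.")
  }
  with_optional_seed(seed, {
    purrr::map(seq_len(nrow(panel)), function(i) {
      p <- panel$maf[i]
      if (panel$ploidy[i] == 1) {
        alt <- stats::rbinom(n, 1, p)
        state <- c("hemi_ref", "hemi_alt")[alt + 1]
      } else {
        n_alt <- stats::rbinom(n, 2, p)
        state <- c("hom_ref", "het", "hom_alt")[n_alt + 1]
      }
      tibble(
        patient_id = paste0("P", seq_len(n)),
        snp_id = panel$snp_id[i],
        state = state,
        genotype = vapply(
          state, state_to_genotype, "",
          ref = panel$allele_ref[i], alt = panel$allele_alt[i]
        )
      )
    }) |> bind_rows()
  })
}

#' The ten-patient validation cohort
#'
#' Genotypes of the ten blood-donor patients used to validate the built-in
#' quadruplex and quintuplex assays, across all nine panel SNPs. The X-linked
#' rs5945619 is hemizygous (single allele) for every patient in this all-male
#' prostate-cancer cohort.
#'
#' @return A tibble with `patient_id`, `snp_id`, `genotype` (as reported) and
#'   the canonical `state`.
#' @export
validation_cohort <- function() {
  path <- system.file("extdata", "validation_cohort.tsv", package = "pyromux")
  wide <- as_tibble(read.delim(path, check.names = FALSE))
  long <- tidyr::pivot_longer(wide, -"patient_id",
    names_to = "snp_id", values_to = "genotype"
  )
  panel <- pca_snp_panel()
  idx <- match(long$snp_id, panel$snp_id)
  long |>
    mutate(state = purrr::pmap_chr(
      list(.data$genotype, panel$allele_ref[idx], panel$allele_alt[idx], panel$ploidy[idx]),
      genotype_to_state
    ))
}

#' Simulate a multiplex pyrosequencing well
#'
#' Builds the noiseless multiplex signal as the per-SNP-weighted sum of
#' genotype signals (heterozygotes at half height), scales it by the noise
#' model's `fuph_scale`, adds background and Gaussian peak noise, and clips
#' at zero. With zero noise, unit efficiencies and `fuph_scale = 1` the
#' result equals the corresponding theoretical combination signal exactly.
#'
#' @param genotypes Named character vector (or tibble with `snp_id` and
#'   `state`) giving one genotype state per panel SNP.
#' @param panel An [snp_panel()] with a dispensation order.
#' @param efficiency Named per-SNP amplification weights (default 1 for every
#'   SNP), emulating PCR primer imbalance.
#' @param noise A [noise_model()].
#' @param seed Optional integer seed.
#' @param well_id Optional well label.
#' @param dictionary Optional pre-built dictionary (avoids rebuilding in
#'   loops).
#' @return A [pyro_signal()].
#' @export
simulate_multiplex_well <- function(genotypes, panel, efficiency = NULL,
                                    noise = noise_model(), seed = NULL,
                                    well_id = NULL, dictionary = NULL) {
  dict <- dictionary %||% build_dictionary(panel)
  if (is.data.frame(genotypes)) {
    genotypes <- stats::setNames(genotypes$state, genotypes$snp_id)
  }
  if (!all(panel$snp_id %in% names(genotypes))) {
    abort("`genotypes` must cover every SNP of the panel.")
  }
  eff <- rep(1, nrow(panel))
  names(eff) <- panel$snp_id
  if (!is.null(efficiency)) {
    if (is.null(names(efficiency))) abort("`efficiency` must be named by snp_id.")
    stopifnot(all(efficiency > 0))
    eff[names(efficiency)] <- efficiency
  }
  clean <- numeric(nchar(dict$dispensations))
  for (id in panel$snp_id) {
    clean <- clean + eff[[id]] * as.numeric(genotype_signal(dict, id, genotypes[[id]]))
  }
  mu <- noise$fuph_scale * clean + noise$background
  heights <- with_optional_seed(seed, {
    sds <- noise$sd_base + noise$sd_prop * mu
    pmax(0, mu + stats::rnorm(length(mu), 0, sds))
  })
  pyro_signal(heights, dict$dispensations, well_id = well_id)
}

#' Simulate a uniplex pyrosequencing well
#'
#' Single-SNP special case of [simulate_multiplex_well()], used to emulate
#' the experimental uniplex runs from which measured dictionary atoms are
#' built.
#'
#' @param snp_id SNP to sequence.
#' @param state Genotype state of the template.
#' @inheritParams simulate_multiplex_well
#' @return A [pyro_signal()].
#' @export
simulate_uniplex_well <- function(snp_id, state, panel, noise = noise_model(),
                                  seed = NULL, well_id = NULL,
                                  dictionary = NULL) {
  dict <- dictionary %||% build_dictionary(panel)
  mu <- noise$fuph_scale * as.numeric(genotype_signal(dict, snp_id, state)) +
    noise$background
  heights <- with_optional_seed(seed, {
    sds <- noise$sd_base + noise$sd_prop * mu
    pmax(0, mu + stats::rnorm(length(mu), 0, sds))
  })
  pyro_signal(heights, dict$dispensations, well_id = well_id)
}

#' Simulate multiplex signals for a whole cohort
#'
#' One multiplex well per patient, with the patient id as well id, plus the
#' matching truth table for concordance evaluation.
#'
#' @param cohort A tibble with `patient_id`, `snp_id` and `state` (from
#'   [sample_cohort()] or [validation_cohort()]); SNPs outside the panel are
#'   ignored.
#' @inheritParams simulate_multiplex_well
#' @return A list with `signals` (a [signal_table()]) and `truth` (tibble
#'   with `well_id`, `snp_id`, `genotype`).
#' @export
simulate_cohort_signals <- function(cohort, panel, efficiency = NULL,
                                    noise = noise_model(), seed = NULL) {
  cohort <- cohort[cohort$snp_id %in% panel$snp_id, ]
  if (nrow(cohort) == 0) abort("cohort has no SNPs overlapping the panel.")
  dict <- build_dictionary(panel)
  patients <- unique(cohort$patient_id)
  heights <- with_optional_seed(seed, {
    t(vapply(patients, function(p) {
      g <- cohort[cohort$patient_id == p, ]
      as.numeric(simulate_multiplex_well(g, panel,
        efficiency = efficiency,
        noise = noise, dictionary = dict, well_id = p
      ))
    }, numeric(nchar(dict$dispensations))))
  })
  truth <- cohort |>
    mutate(
      well_id = .data$patient_id,
      genotype = if ("genotype" %in% names(cohort)) {
        .data$genotype
      } else {
        idx <- match(.data$snp_id, panel$snp_id)
        purrr::map2_chr(
          .data$state, idx,
          function(s, i) state_to_genotype(s, panel$allele_ref[i], panel$allele_alt[i])
        )
      }
    ) |>
    select("well_id", "snp_id", "genotype")
  list(
    signals = signal_table(heights, dict$dispensations, well_ids = patients),
    truth = truth
  )
}
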