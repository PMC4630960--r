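#' Decoder configuration
#'
#' Tuning parameters for [decompose_pyrosignal()] and [call_genotypes()].
#'
#' The decomposition solves a non-negativity-constrained least-squares
#' problem; `lambda` adds an L1 penalty on the coefficients
#' (`0.5 * ||y - Dx||^2 + lambda * sum(x)`, `x >= 0`). The default
#' `lambda = 0` is plain non-negative least squares, which is already sparse
#' in practice. With `lambda = "auto"` the smallest value on a grid is chosen
#' at which every retained atom contributes more than `min_rel_contribution`
#' percent of the coefficient mass.
#'
#' Genotypes are called from the alt-allele coefficient fraction
#' `f = w_alt / (w_ref + w_alt)`: `f <= hom_fraction_max` is homozygous
#' reference, `f >= 1 - hom_fraction_max` homozygous alternate, and
#' `het_fraction_lo <= f <= het_fraction_hi` heterozygous (diploid SNPs
#' only); anything else is a no-call. The windows follow common
#' pyrosequencing allele-quantification practice.
#'
#' @param lambda Non-negative L1 penalty, or `"auto"`.
#' @param hom_fraction_max Largest alt fraction still called homozygous
#'   reference (mirrored for homozygous alternate).
#' @param het_fraction_lo,het_fraction_hi Heterozygote window.
#' @param min_rel_contribution Minimum per-SNP relative contribution (%)
#'   before a `low_contribution` flag is raised; also the retention threshold
#'   of the `"auto"` penalty.
#' @param min_confidence_r Wells whose confidence index falls below this get
#'   every call flagged `low_confidence`.
#' @param contribution How per-SNP absolute contribution is measured:
#'   `"coefficient"` sums the allele coefficients (the default);
#'   `"light"` weights each coefficient by its atom's total light
#'   (sum of peak heights).
#' @return A list of class `decoder_config`.
#' @export
decoder_config <- function(lambda = 0,
                           hom_fraction_max = 0.2,
                           het_fraction_lo = 0.3,
                           het_fraction_hi = 0.7,
                           min_rel_contribution = 1,
                           min_confidence_r = 0.95,
                           contribution = c("coefficient", "light")) {
  if (!identical(lambda, "auto") &&
    (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)) {
    abort("`lambda` must be a single non-negative number or \"auto\".")
  }
  if (!(hom_fraction_max >= 0 && hom_fraction_max < het_fraction_lo &&
    het_fraction_lo < het_fraction_hi && het_fraction_hi <= 1)) {
    abort("need 0 <= hom_fraction_max < het_fraction_lo < het_fraction_hi <= 1.")
  }
  structure(
    list(
      lambda = lambda,
      hom_fraction_max = hom_fraction_max,
      het_fraction_lo = het_fraction_lo,
      het_fraction_hi = het_fraction_hi,
      min_rel_contribution = min_rel_contribution,
      min_confidence_r = min_confidence_r,
      contribution = match.arg(contribution)
    ),
    class = "decoder_config"
  )
}

solve_nnls_l1 <- function(A, y, lambda) {
  if (lambda == 0) {
    pracma::lsqnonneg(A, y)$x
  } else {
    fit <- glmnet::glmnet(A, y,
      alpha = 1, lambda = lambda / nrow(A),
      lower.limits = 0, intercept = FALSE, standardize = FALSE
    )
    as.numeric(fit$beta[, 1])
  }
}

#' Decompose a multiplex pyro-signal over a dictionary
#'
#' Fits the observed peak-height vector as a sparse non-negative combination
#' of the dictionary atoms (see [decoder_config()] for the penalty). The
#' confidence index R is the Pearson correlation between the observed signal
#' and its fitted reconstruction; values near 1 indicate that the sparse
#' model explains the multiplex signal almost perfectly.
#'
#' Observed signals need not be FUPH-standardized: the coefficients absorb
#' the overall scale and genotype calls depend only on coefficient ratios.
#' If a `fuph` is supplied the coefficients are reported in FUPH units.
#'
#' @param observed A [pyro_signal()] or numeric vector whose length matches
#'   the dictionary's dispensation order.
#' @param dictionary A [build_dictionary()] result.
#' @param config A [decoder_config()].
#' @param fuph Optional first unitary peak height used to rescale the
#'   observed signal before fitting.
#' @return A list of class `pyro_decomposition` with `coefficients` (named
#'   by atom), `fitted`, `observed`, `residual_norm`, `confidence_r`,
#'   `lambda` (the value actually used), `atoms`, `config` and `well_id`.
#'   Use [tidy()] / [glance()] for tabular views.
#' @export
decompose_pyrosignal <- function(observed, dictionary, config = decoder_config(),
                                 fuph = NULL) {
  stopifnot(inherits(dictionary, "pyro_dictionary"))
  y <- as.numeric(observed)
  A <- atom_matrix(dictionary)
  if (length(y) != nrow(A)) {
    abort(sprintf(
      "observed signal has %d heights but the dictionary order has %d dispensations.",
      length(y), nrow(A)
    ))
  }
  if (all(y == 0)) abort("observed signal is all zero; nothing to decompose.")
  if (any(y < 0) || any(is.na(y))) abort("observed heights must be non-negative.")
  if (!is.null(fuph)) y <- as.numeric(fuph_standardize(pyro_signal(y, dictionary$dispensations), fuph))

  lambda_used <- config$lambda
  if (identical(config$lambda, "auto")) {
    path <- glmnet::glmnet(A, y,
      alpha = 1, lower.limits = 0,
      intercept = FALSE, standardize = FALSE, nlambda = 30
    )
    grid <- sort(unique(c(0, as.numeric(path$lambda) * nrow(A))))
    lambda_used <- grid[length(grid)]
    for (l in grid) {
      x <- solve_nnls_l1(A, y, l)
      share <- if (sum(x) > 0) 100 * x / sum(x) else x
      if (all(share[x > 0] > config$min_rel_contribution)) {
        lambda_used <- l
        break
      }
    }
  }
  x <- solve_nnls_l1(A, y, lambda_used)
  names(x) <- colnames(A)
  fitted <- as.numeric(A %*% x)
  structure(
    list(
      coefficients = x,
      fitted = pyro_signal(fitted, dictionary$dispensations,
        standardized = TRUE
      ),
      observed = y,
      residual_norm = sqrt(sum((y - fitted)^2)),
      confidence_r = if (stats::sd(y) > 0 && stats::sd(fitted) > 0) {
        stats::cor(y, fitted)
      } else {
        0
      },
      lambda = lambda_used,
      atoms = dictionary$atoms,
      dispensations = dictionary$dispensations,
      config = config,
      well_id = attr(observed, "well_id")
    ),
    class = "pyro_decomposition"
  )
}

#' @export
print.pyro_decomposition <- function(x, ...) {
  cat(sprintf(
    "<pyro_decomposition>%s R = %.4f, %d/%d atoms retained (lambda = %g)\n",
    if (!is.null(x$well_id)) paste0(" well ", x$well_id, ",") else "",
    x$confidence_r, sum(x$coefficients > 0), length(x$coefficients), x$lambda
  ))
  print(tidy(x))
  invisible(x)
}

#' @rdname decompose_pyrosignal
#' @param x A `pyro_decomposition`.
#' @param ... Unused.
#' @method tidy pyro_decomposition
#' @export
tidy.pyro_decomposition <- function(x, ...) {
  x$atoms |>
    select("atom_id", "snp_id", "allele", "role", "source") |>
    mutate(coefficient = unname(x$coefficients))
}

#' @rdname decompose_pyrosignal
#' @method glance pyro_decomposition
#' @export
glance.pyro_decomposition <- function(x, ...) {
  tibble(
    well_id = x$well_id %||% NA_character_,
    confidence_r = x$confidence_r,
    residual_norm = x$residual_norm,
    lambda = x$lambda,
    n_atoms = length(x$coefficients),
    n_retained = sum(x$coefficients > 0)
  )
}

#' Call per-SNP genotypes from a decomposition
#'
#' Per SNP, coefficients are summed by allele over all of that SNP's atoms
#' (theoretical plus experimental) into allele weights `w_ref` and `w_alt`,
#' and the alt fraction `f = w_alt / (w_ref + w_alt)` is thresholded into a
#' genotype (see [decoder_config()]). Haploid SNPs are called hemizygous by
#' majority allele with the same homozygote threshold. Per-SNP absolute
#' contributions are `w_ref + w_alt` (or light-weighted, per the config) and
#' relative contributions are their percentages of the well total.
#'
#' @param decomposition A [decompose_pyrosignal()] result.
#' @param panel The [snp_panel()] the dictionary was built from.
#' @param config A [decoder_config()]; defaults to the one used for the
#'   decomposition.
#' @return A tibble with one row per SNP: `well_id`, `snp_id`, `call` (a
#'   genotype state or `"no_call"`), `genotype` (e.g. `"C/T"`, or a single
#'   letter for hemizygous calls; `NA` for no-calls), `allele_fraction_alt`,
#'   `contribution_abs`, `contribution_rel`, `confidence_r` and `flags`
#'   (comma-separated; empty when clean).
#' @export
call_genotypes <- function(decomposition, panel, config = NULL) {
  stopifnot(inherits(decomposition, "pyro_decomposition"))
  config <- config %||% decomposition$config
  atoms <- decomposition$atoms
  if (!all(panel$snp_id %in% atoms$snp_id)) {
    abort("panel contains SNPs absent from the decomposition's dictionary.")
  }
  coef_w <- decomposition$coefficients
  if (config$contribution == "light") {
    coef_w <- coef_w * vapply(atoms$signal, sum, numeric(1))
  }

  per_snp <- purrr::map(seq_len(nrow(panel)), function(i) {
    id <- panel$snp_id[i]
    sel <- atoms$snp_id == id
    w_ref <- sum(coef_w[sel & atoms$role == "ref"])
    w_alt <- sum(coef_w[sel & atoms$role == "alt"])
    total <- w_ref + w_alt
    f <- if (total > 0) w_alt / total else NA_real_
    flags <- character(0)
    state <- if (is.na(f)) {
      flags <- c(flags, "low_contribution")
      "no_call"
    } else if (panel$ploidy[i] == 1) {
      if (f <= config$hom_fraction_max) {
        "hemi_ref"
      } else if (f >= 1 - config$hom_fraction_max) {
        "hemi_alt"
      } else {
        flags <- c(flags, "ambiguous_fraction")
        "no_call"
      }
    } else if (f <= config$hom_fraction_max) {
      "hom_ref"
    } else if (f >= 1 - config$hom_fraction_max) {
      "hom_alt"
    } else if (f >= config$het_fraction_lo && f <= config$het_fraction_hi) {
      "het"
    } else {
      flags <- c(flags, "ambiguous_fraction")
      "no_call"
    }
    tibble(
      snp_id = id,
      call = state,
      genotype = state_to_genotype(state, panel$allele_ref[i], panel$allele_alt[i]),
      allele_fraction_alt = f,
      contribution_abs = total,
      flags = list(flags)
    )
  }) |> bind_rows()

  grand <- sum(per_snp$contribution_abs)
  per_snp |>
    mutate(
      contribution_rel = if (grand > 0) 100 * .data$contribution_abs / grand else NA_real_,
      flags = purrr::map2(.data$flags, .data$contribution_rel, function(fl, rel) {
        if (!is.na(rel) && rel < config$min_rel_contribution) c(fl, "low_contribution") else fl
      }),
      flags = purrr::map_chr(.data$flags, function(fl) {
        if (decomposition$confidence_r < config$min_confidence_r) {
          fl <- c(fl, "low_confidence")
        }
        paste(unique(fl), collapse = ",")
      }),
      confidence_r = decomposition$confidence_r,
      well_id = decomposition$well_id %||% NA_character_
    ) |>
    select(
      "well_id", "snp_id", "call", "genotype", "allele_fraction_alt",
      "contribution_abs", "contribution_rel", "confidence_r", "flags"
    )
}

state_to_genotype <- function(state, ref, alt) {
  switch(state,
    hom_ref = paste(ref, ref, sep = "/"),
    hom_alt = paste(alt, alt, sep = "/"),
    het = paste(ref, alt, sep = "/"),
    hemi_ref = ref,
    hemi_alt = alt,
    no_call = NA_character_,
    abort(sprintf("unknown state \"%s\".", state))
  )
}

genotype_to_state <- function(genotype, ref, alt, ploidy) {
  alleles <- strsplit(genotype, "/")[[1]]
  if (ploidy == 1) {
    if (length(alleles) != 1) abort(sprintf("haploid genotype \"%s\" must be a single allele.", genotype))
    if (alleles == ref) {
      return("hemi_ref")
    }
    if (alleles == alt) {
      return("hemi_alt")
    }
    abort(sprintf("allele \"%s\" is neither %s nor %s.", alleles, ref, alt))
  }
  if (length(alleles) != 2 || !all(alleles %in% c(ref, alt))) {
    abort(sprintf("genotype \"%s\" is not composed of alleles %s/%s.", genotype, ref, alt))
  }
  n_alt <- sum(alleles == alt)
  c("hom_ref", "het", "hom_alt")[n_alt + 1]
}

#' Decode and genotype a table of multiplex wells
#'
#' Convenience pipeline: builds the panel dictionary once, decomposes each
#' well of a signal table and calls genotypes, returning one tidy table.
#'
#' @param signals A [signal_table()] (or any data frame with a `well_id`
#'   column followed by one numeric column per dispensation, carrying a
#'   `dispensations` attribute matching the panel order).
#' @inheritParams call_genotypes
#' @param config A [decoder_config()].
#' @param experimental_signals Passed on to [build_dictionary()].
#' @return A tibble of per-well, per-SNP genotype calls (see
#'   [call_genotypes()]).
#' @export
genotype_wells <- function(signals, panel, config = decoder_config(),
                           experimental_signals = NULL) {
  dict <- build_dictionary(panel, experimental_signals)
  hmat <- signal_heights(signals, dict$dispensations)
  purrr::map(seq_len(nrow(hmat)), function(i) {
    obs <- pyro_signal(hmat[i, ], dict$dispensations, well_id = rownames(hmat)[i])
    call_genotypes(decompose_pyrosignal(obs, dict, config), panel, config)
  }) |> bind_rows()
}

#' Mean relative signal contribution per SNP
#'
#' Averages, across wells, each SNP's percentage share of the global
#' multiplex signal. Used to judge amplification balance and drive primer
#' concentration adjustment.
#'
#' @param calls A tibble of [call_genotypes()] rows covering one or more
#'   wells.
#' @return A tibble with `snp_id`, `mean_contribution_rel` and `n_wells`.
#' @export
relative_contribution_summary <- function(calls) {
  if (nrow(calls) == 0) abort("no calls supplied.")
  calls |>
    group_by(.data$snp_id) |>
    summarise(
      mean_contribution_rel = mean(.data$contribution_rel, na.rm = TRUE),
      n_wells = dplyr::n_distinct(.data$well_id),
      .groups = "drop"
    )
}

#' Suggest PCR primer concentration adjustments
#'
#' Rescales each SNP's primer concentration in inverse proportion to its
#' observed share of the multiplex signal: over-represented SNPs are
#' decreased, under-represented ones increased
#' (`new = current * target / observed`). Optionally snaps the result to a
#' concentration grid.
#'
#' @param shares Tibble with `snp_id` and a share column
#'   (`mean_contribution_rel` from [relative_contribution_summary()], or
#'   `share`), in percent.
#' @param current_conc Named numeric vector of current concentrations, names
#'   matching `snp_id`.
#' @param target_share Named or unnamed target shares in percent; defaults
#'   to a balanced assay (100 / number of SNPs for every SNP).
#' @param conc_grid Optional vector of allowed concentrations; suggestions
#'   are rounded to the nearest grid point.
#' @return A tibble with `snp_id`, `observed_share`, `target_share`,
#'   `current_conc`, `adjusted_conc` and `flagged` (TRUE when the observed
#'   share was zero and no adjustment is possible).
#' @export
suggest_primer_adjustment <- function(shares, current_conc, target_share = NULL,
                                      conc_grid = NULL) {
  share_col <- intersect(c("mean_contribution_rel", "share"), names(shares))[1]
  if (is.na(share_col)) abort("`shares` needs a mean_contribution_rel or share column.")
  ids <- shares$snp_id
  if (!all(ids %in% names(current_conc))) {
    abort("`current_conc` must be named by every snp_id in `shares`.")
  }
  obs <- shares[[share_col]]
  tgt <- if (is.null(target_share)) {
    rep(100 / length(ids), length(ids))
  } else if (!is.null(names(target_share))) {
    unname(target_share[ids])
  } else {
    rep_len(target_share, length(ids))
  }
  cur <- unname(current_conc[ids])
  adj <- ifelse(obs > 0, cur * tgt / obs, cur)
  if (!is.null(conc_grid)) {
    adj <- vapply(adj, function(a) conc_grid[which.min(abs(conc_grid - a))], numeric(1))
  }
  tibble(
    snp_id = ids,
    observed_share = obs,
    target_share = tgt,
    current_conc = cur,
    adjusted_conc = adj,
    flagged = obs <= 0
  )
}
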