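test_that("a pure atom decomposes onto itself with confidence 1", {
  d4 <- build_dictionary(quadruplex_panel())
  A <- atom_matrix(d4)
  for (k in c(1, 4, 8)) {
    obs <- pyro_signal(A[, k], d4$dispensations)
    dec <- decompose_pyrosignal(obs, d4)
    expect_equal(unname(dec$coefficients[k]), 1, tolerance = 1e-6)
    expect_equal(unname(dec$coefficients[-k]), rep(0, 7), tolerance = 1e-6)
    expect_equal(dec$confidence_r, 1, tolerance = 1e-9)
  }
})

test_that("a het construction recovers 0.5/0.5 coefficients at lambda = 0", {
  d4 <- build_dictionary(quadruplex_panel())
  A <- atom_matrix(d4)
  obs <- pyro_signal(0.5 * A[, 1] + 0.5 * A[, 2], d4$dispensations)
  dec <- decompose_pyrosignal(obs, d4)
  expect_equal(unname(dec$coefficients[1:2]), c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(sum(dec$coefficients[-(1:2)]), 0, tolerance = 1e-8)
  expect_equal(dec$confidence_r, 1, tolerance = 1e-12)
})

test_that("a noiseless multiplex well lights up exactly the generating atoms", {
  # first validation patient, quadruplex: C/C, T/T, C/C and hemizygous T
  q4 <- quadruplex_panel()
  d4 <- build_dictionary(q4)
  states <- c(
    rs1016343 = "hom_ref", rs10993994 = "hom_alt",
    rs16901979 = "hom_alt", rs5945619 = "hemi_alt"
  )
  obs <- simulate_multiplex_well(states, q4,
    noise = noise_model(sd_base = 0, sd_prop = 0, fuph_scale = 1),
    dictionary = d4
  )
  dec <- decompose_pyrosignal(obs, d4)
  active <- names(dec$coefficients)[dec$coefficients > 1e-8]
  expect_setequal(active, c(
    "rs1016343_C_theoretical", "rs10993994_T_theoretical",
    "rs16901979_C_theoretical", "rs5945619_T_theoretical"
  ))
  calls <- call_genotypes(dec, q4)
  expect_equal(
    calls$genotype[match(names(states), calls$snp_id)],
    c("C/C", "T/T", "C/C", "T")
  )
})

test_that("decoding is scale invariant", {
  q5 <- quintuplex_panel()
  d5 <- build_dictionary(q5)
  set.seed(5)
  states <- c(
    rs10896449 = "het", rs1859962 = "hom_ref", rs4242382 = "hom_alt",
    rs4430796 = "het", rs6983267 = "hom_ref"
  )
  obs <- simulate_multiplex_well(states, q5, noise = noise_model(), seed = 99, dictionary = d5)
  base <- decompose_pyrosignal(obs, d5)
  base_calls <- call_genotypes(base, q5)
  for (c_scale in c(0.1, 3, 42)) {
    scaled <- decompose_pyrosignal(
      pyro_signal(c_scale * as.numeric(obs), d5$dispensations), d5
    )
    expect_equal(scaled$coefficients, c_scale * base$coefficients, tolerance = 1e-6)
    expect_equal(scaled$confidence_r, base$confidence_r, tolerance = 1e-9)
    sc_calls <- call_genotypes(scaled, q5)
    expect_equal(sc_calls$call, base_calls$call)
    expect_equal(sc_calls$allele_fraction_alt, base_calls$allele_fraction_alt,
      tolerance = 1e-6
    )
    expect_equal(sc_calls$contribution_rel, base_calls$contribution_rel,
      tolerance = 1e-6
    )
  }
})

test_that("confidence R is exactly 1 inside the dictionary cone", {
  d5 <- build_dictionary(quintuplex_panel())
  A <- atom_matrix(d5)
  set.seed(8)
  for (i in 1:10) {
    w <- stats::runif(ncol(A)) * stats::rbinom(ncol(A), 1, 0.5)
    if (sum(w) == 0) w[1] <- 1
    dec <- decompose_pyrosignal(pyro_signal(A %*% w, d5$dispensations), d5)
    expect_equal(dec$confidence_r, 1, tolerance = 1e-9)
  }
})

test_that("allele-fraction thresholds drive the genotype call", {
  q4 <- quadruplex_panel()
  d4 <- build_dictionary(q4)
  A <- atom_matrix(d4)
  mk <- function(w) {
    decompose_pyrosignal(pyro_signal(A %*% w, d4$dispensations), d4)
  }
  # rs1016343 atoms are columns 1 (C, ref) and 2 (T, alt)
  w <- rep(0, 8)
  w[1] <- 1
  w[5] <- 1
  w[7] <- 1 # keep other SNPs defined
  calls <- call_genotypes(mk(w), q4)
  expect_equal(calls$call[calls$snp_id == "rs1016343"], "hom_ref")
  expect_equal(calls$allele_fraction_alt[calls$snp_id == "rs1016343"], 0)

  w[1] <- 0.5
  w[2] <- 0.5
  calls <- call_genotypes(mk(w), q4)
  expect_equal(calls$call[calls$snp_id == "rs1016343"], "het")
  expect_equal(calls$allele_fraction_alt[calls$snp_id == "rs1016343"], 0.5)

  w[1] <- 0
  w[2] <- 1
  calls <- call_genotypes(mk(w), q4)
  expect_equal(calls$call[calls$snp_id == "rs1016343"], "hom_alt")

  # an ambiguous fraction in (hom_fraction_max, het_fraction_lo) is a no-call
  w[1] <- 0.75
  w[2] <- 0.25
  calls <- call_genotypes(mk(w), q4)
  expect_equal(calls$call[calls$snp_id == "rs1016343"], "no_call")
  expect_match(calls$flags[calls$snp_id == "rs1016343"], "ambiguous_fraction")

  # absent SNP: zero weights on both alleles
  w2 <- rep(0, 8)
  w2[1] <- 1
  w2[5] <- 1
  w2[7] <- 1
  calls <- call_genotypes(mk(w2), q4)
  expect_equal(calls$call[calls$snp_id == "rs10993994"], "no_call")
  expect_match(calls$flags[calls$snp_id == "rs10993994"], "low_contribution")
})

test_that("relative contributions sum to 100% and average correctly", {
  q4 <- quadruplex_panel()
  coh <- sample_cohort(q4, 6, seed = 21)
  sim <- simulate_cohort_signals(coh, q4, seed = 22)
  calls <- genotype_wells(sim$signals, q4)
  sums <- calls |>
    dplyr::group_by(well_id) |>
    dplyr::summarise(total = sum(contribution_rel))
  expect_equal(sums$total, rep(100, 6), tolerance = 1e-9)
  summ <- relative_contribution_summary(calls)
  expect_equal(nrow(summ), 4)
  expect_equal(sum(summ$mean_contribution_rel), 100, tolerance = 1e-9)
  one_well <- relative_contribution_summary(calls[calls$well_id == "P1", ])
  expect_equal(
    one_well$mean_contribution_rel,
    calls$contribution_rel[calls$well_id == "P1"][match(one_well$snp_id, calls$snp_id[calls$well_id == "P1"])]
  )
})

test_that("balanced efficiencies give near-equal mean shares in a 4-plex", {
  q4 <- quadruplex_panel()
  coh <- sample_cohort(q4, 100, seed = 31)
  sim <- simulate_cohort_signals(coh, q4, seed = 32)
  calls <- genotype_wells(sim$signals, q4)
  summ <- relative_contribution_summary(calls)
  # equal per-SNP weights: shares are proportional to mean atom total light,
  # which differs somewhat between SNPs, but all stay within a broad band of 25%
  expect_true(all(abs(summ$mean_contribution_rel - 25) < 12))
  # and the noiseless equal-weight well has shares proportional to total light
  d4 <- build_dictionary(q4)
  states <- stats::setNames(
    ifelse(q4$ploidy == 1, "hemi_ref", "hom_ref"), q4$snp_id
  )
  obs <- simulate_multiplex_well(states, q4,
    noise = noise_model(sd_base = 0, sd_prop = 0, fuph_scale = 1),
    dictionary = d4
  )
  calls0 <- call_genotypes(decompose_pyrosignal(obs, d4), q4)
  light <- vapply(q4$snp_id, function(id) {
    sum(as.numeric(genotype_signal(d4, id, if (q4$ploidy[q4$snp_id == id] == 1) "hemi_ref" else "hom_ref")))
  }, numeric(1))
  # coefficient-based contributions are equal per SNP (weight 1 each)
  expect_equal(calls0$contribution_rel, rep(25, 4), tolerance = 1e-6)
  cfg <- decoder_config(contribution = "light")
  calls_light <- call_genotypes(decompose_pyrosignal(obs, d4, cfg), q4, cfg)
  expect_equal(
    calls_light$contribution_rel[match(q4$snp_id, calls_light$snp_id)],
    unname(100 * light / sum(light)),
    tolerance = 1e-6
  )
})

test_that("primer adjustment rescales toward the target share", {
  expect_equal(
    suggest_primer_adjustment(
      tibble::tibble(snp_id = "a", share = 50),
      c(a = 0.1), target_share = 25
    )$adjusted_conc, 0.05
  )
  expect_equal(
    suggest_primer_adjustment(
      tibble::tibble(snp_id = "a", share = 12.5),
      c(a = 0.1), target_share = 25
    )$adjusted_conc, 0.2
  )
  # published pre-adjustment quadruplex shares: the over-represented X SNP
  # is decreased, matching the reported 0.1 -> 0.05 direction
  shares <- tibble::tibble(
    snp_id = c("rs1016343", "rs10993994", "rs16901979", "rs5945619"),
    share = c(15.9, 27.4, 21.4, 35.3)
  )
  conc <- stats::setNames(rep(0.1, 4), shares$snp_id)
  adj <- suggest_primer_adjustment(shares, conc)
  expect_lt(adj$adjusted_conc[adj$snp_id == "rs5945619"], 0.1)
  expect_gt(adj$adjusted_conc[adj$snp_id == "rs1016343"], 0.1)
  # zero observed share is flagged, not divided by
  z <- suggest_primer_adjustment(
    tibble::tibble(snp_id = "a", share = 0), c(a = 0.1)
  )
  expect_true(z$flagged)
  expect_equal(z$adjusted_conc, 0.1)
})

test_that("auto penalty keeps every retained atom above the share floor", {
  q4 <- quadruplex_panel()
  d4 <- build_dictionary(q4)
  states <- c(
    rs1016343 = "het", rs10993994 = "hom_ref",
    rs16901979 = "hom_ref", rs5945619 = "hemi_ref"
  )
  obs <- simulate_multiplex_well(states, q4, noise = noise_model(), seed = 77, dictionary = d4)
  cfg <- decoder_config(lambda = "auto", min_rel_contribution = 1)
  dec <- decompose_pyrosignal(obs, d4, cfg)
  share <- 100 * dec$coefficients / sum(dec$coefficients)
  expect_true(all(share[dec$coefficients > 0] > 1))
  calls <- call_genotypes(dec, q4, cfg)
  expect_equal(calls$call[calls$snp_id == "rs1016343"], "het")
})

test_that("degenerate and mismatched inputs are rejected", {
  d4 <- build_dictionary(quadruplex_panel())
  expect_error(
    decompose_pyrosignal(rep(0, 14), d4),
    "all zero"
  )
  expect_error(
    decompose_pyrosignal(rep(1, 10), d4),
    "dispensations"
  )
})

test_that("plotting helpers return ggplot objects", {
  q4 <- quadruplex_panel()
  d4 <- build_dictionary(q4)
  obs <- simulate_multiplex_well(
    c(
      rs1016343 = "het", rs10993994 = "hom_ref",
      rs16901979 = "hom_ref", rs5945619 = "hemi_ref"
    ),
    q4,
    noise = noise_model(), seed = 3, dictionary = d4
  )
  expect_s3_class(plot_pyrogram(obs), "ggplot")
  dec <- decompose_pyrosignal(obs, d4)
  expect_s3_class(ggplot2::autoplot(dec), "ggplot")
  expect_s3_class(tidy(dec), "tbl_df")
  expect_equal(nrow(glance(dec)), 1)
})
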