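test_that("cohort sampling follows Hardy-Weinberg with the panel allele frequencies", {
  p0 <- toy_panel(order = "ACG")
  p0$maf <- 0
  all_ref <- sample_cohort(p0, 50, seed = 1)
  expect_true(all(all_ref$state == "hom_ref"))

  p5 <- toy_panel(order = "ACG")
  p5$maf <- 0.5
  coh <- sample_cohort(p5, 4000, seed = 2)
  het_freq <- mean(coh$state == "het")
  expect_lt(abs(het_freq - 0.5), 3 * sqrt(0.25 / 4000))

  # built-in panel at n = 1000: observed alt-allele frequency within 3
  # binomial standard errors of the panel frequency
  panel <- pca_snp_panel()
  full <- snp_panel(panel[panel$group == "quadruplex", ], "CTGCATGACTCGAT")
  coh <- sample_cohort(full, 1000, seed = 3)
  for (id in full$snp_id) {
    maf <- full$maf[full$snp_id == id]
    states <- coh$state[coh$snp_id == id]
    ploidy <- full$ploidy[full$snp_id == id]
    n_chrom <- 1000 * ploidy
    n_alt <- sum((states == "het") + 2 * (states == "hom_alt") + (states == "hemi_alt"))
    se <- sqrt(maf * (1 - maf) / n_chrom)
    expect_lt(abs(n_alt / n_chrom - maf), 3 * se)
  }
})

test_that("simulation is deterministic under a seed and varies across seeds", {
  q4 <- quadruplex_panel()
  coh <- validation_cohort()
  a <- simulate_cohort_signals(coh, q4, seed = 10)
  b <- simulate_cohort_signals(coh, q4, seed = 10)
  c <- simulate_cohort_signals(coh, q4, seed = 11)
  expect_equal(a$signals, b$signals)
  expect_false(isTRUE(all.equal(a$signals, c$signals)))
})

test_that("zero noise, unit efficiency and unit scale reproduce the theoretical signal", {
  q5 <- quintuplex_panel()
  d5 <- build_dictionary(q5)
  combos <- enumerate_combination_signals(q5, d5)
  quiet <- noise_model(sd_base = 0, sd_prop = 0, fuph_scale = 1)
  for (i in c(1, 57, 243)) {
    g <- combos$genotype[[i]]
    sim <- simulate_multiplex_well(g, q5, noise = quiet, dictionary = d5)
    expect_equal(as.numeric(sim), combos$signal[[i]])
  }
})

test_that("doubling one SNP's efficiency doubles its contribution ratio", {
  q4 <- quadruplex_panel()
  d4 <- build_dictionary(q4)
  states <- stats::setNames(
    ifelse(q4$ploidy == 1, "hemi_ref", "hom_ref"), q4$snp_id
  )
  quiet <- noise_model(sd_base = 0, sd_prop = 0, fuph_scale = 1)
  base <- call_genotypes(decompose_pyrosignal(
    simulate_multiplex_well(states, q4, noise = quiet, dictionary = d4), d4
  ), q4)
  boosted <- call_genotypes(decompose_pyrosignal(
    simulate_multiplex_well(states, q4,
      efficiency = c(rs1016343 = 2),
      noise = quiet, dictionary = d4
    ), d4
  ), q4)
  ratio <- function(calls) {
    calls$contribution_abs[calls$snp_id == "rs1016343"] /
      calls$contribution_abs[calls$snp_id == "rs10993994"]
  }
  expect_equal(ratio(boosted), 2 * ratio(base), tolerance = 1e-6)
})

test_that("simulated wells are unbiased before clipping", {
  q4 <- quadruplex_panel()
  d4 <- build_dictionary(q4)
  states <- c(
    rs1016343 = "het", rs10993994 = "hom_ref",
    rs16901979 = "hom_alt", rs5945619 = "hemi_ref"
  )
  nm <- noise_model()
  mu <- nm$fuph_scale * as.numeric(Reduce(
    `+`,
    lapply(names(states), function(id) genotype_signal(d4, id, states[[id]]))
  ))
  sims <- withr::with_seed(123, {
    replicate(1000, as.numeric(
      simulate_multiplex_well(states, q4, noise = nm, dictionary = d4)
    ))
  })
  sds <- nm$sd_base + nm$sd_prop * mu
  se <- sds / sqrt(1000)
  # positive peaks: clipping is negligible at these signal-to-noise ratios,
  # so the empirical mean sits within Monte-Carlo error of the clean signal
  pos <- mu > 0
  expect_true(all(abs(rowMeans(sims)[pos] - mu[pos]) < 4 * se[pos]))
  # zero peaks are biased upward only by truncation of the noise floor,
  # E[max(0, N(0, sd_base))] = sd_base / sqrt(2 * pi) ~ 0.012
  if (any(!pos)) {
    expect_true(all(rowMeans(sims)[!pos] < nm$sd_base))
  }
})

test_that("uniplex wells reproduce atoms and augment the dictionary usefully", {
  q4 <- quadruplex_panel()
  d4 <- build_dictionary(q4)
  quiet <- noise_model(sd_base = 0, sd_prop = 0, fuph_scale = 3)
  hom <- simulate_uniplex_well("rs1016343", "hom_ref", q4,
    noise = quiet,
    dictionary = d4
  )
  expect_equal(as.numeric(hom), 3 * as.numeric(genotype_signal(d4, "rs1016343", "hom_ref")))
  het <- simulate_uniplex_well("rs1016343", "het", q4, noise = quiet, dictionary = d4)
  expect_equal(
    as.numeric(het),
    1.5 * (as.numeric(genotype_signal(d4, "rs1016343", "hom_ref")) +
      as.numeric(genotype_signal(d4, "rs1016343", "hom_alt")))
  )

  # a noisy FUPH-standardized experimental hom atom appended to the dictionary
  # must not break noiseless identifiability of all 54 combinations
  noisy <- simulate_uniplex_well("rs1016343", "hom_ref", q4,
    noise = noise_model(), seed = 41, dictionary = d4
  )
  exp_sig <- tibble::tibble(
    snp_id = "rs1016343", allele = "C", fuph = 7,
    signal = list(as.numeric(noisy))
  )
  d4x <- build_dictionary(q4, exp_sig)
  combos <- enumerate_combination_signals(q4, d4)
  ok <- 0
  for (i in seq_len(nrow(combos))) {
    dec <- decompose_pyrosignal(
      pyro_signal(combos$signal[[i]], d4$dispensations), d4x
    )
    calls <- call_genotypes(dec, q4)
    truth <- combos$genotype[[i]]
    if (all(calls$call[match(names(truth), calls$snp_id)] == truth)) ok <- ok + 1
  }
  expect_equal(ok, nrow(combos))
})

test_that("decoder concordance degrades monotonically with noise", {
  q4 <- quadruplex_panel()
  coh <- sample_cohort(q4, 15, seed = 61)
  grid <- c(0, 0.3, 1.2, 4)
  conc <- vapply(seq_along(grid), function(i) {
    nm <- noise_model(sd_base = grid[i], sd_prop = 0.02)
    sim <- simulate_cohort_signals(coh, q4, noise = nm, seed = 62 + i)
    calls <- genotype_wells(sim$signals, q4)
    concordance(calls, sim$truth)$percent
  }, numeric(1))
  expect_equal(conc[1], 100)
  # allow small Monte-Carlo wobble but require an overall downward trend
  expect_true(all(diff(conc) <= 5))
  expect_lt(conc[length(conc)], conc[1])
})

test_that("the validation cohort fixture is consistent with the panel", {
  coh <- validation_cohort()
  expect_equal(nrow(coh), 90)
  expect_equal(length(unique(coh$patient_id)), 10)
  expect_equal(length(unique(coh$snp_id)), 9)
  # X-linked SNP is hemizygous for every patient
  x <- coh[coh$snp_id == "rs5945619", ]
  expect_true(all(x$state %in% c("hemi_ref", "hemi_alt")))
  expect_true(all(!grepl("/", x$genotype)))
})
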