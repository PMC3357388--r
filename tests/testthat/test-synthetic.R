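test_that("generator config validates its invariants", {
  expect_error(generator_config(class_proportions = c(I = 0.5, II = 0.1,
                                                      III = 0.1, IV = 0.1,
                                                      V = 0.1, VI = 0.05,
                                                      NC = 0.1)),
               "sum to 1")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
  expect_error(generator_config(timepoints = c(1, 25)), "timepoints")
  expect_error(generator_config(hormone = list(noise_frac = -0.1)), "noise_frac")
  expect_error(generator_config(tolerance = list(times = c(0, 10, 10))),
               "strictly increasing")
})

test_that("noiseless waveform values are exact and truth is class-consistent", {
  cfg <- generator_config(n_genes = 1, noise_sd = 0,
                          class_proportions = c(I = 1, II = 0, III = 0,
                                                IV = 0, V = 0, VI = 0, NC = 0))
  sim <- generate_transcriptome(cfg, seed = 2)
  tr <- sim$truth
  expect_identical(tr$class, "I")
  sel <- sim$samples$condition == "control"
  expected <- tr$mesor_control +
    tr$amplitude_control * cos(2 * pi * (sim$samples$zt[sel] - tr$acrophase_control) / 24)
  expect_equal(unname(sim$expression[1, sel]), expected, tolerance = 1e-12)

  # all-NC world: flat rows plus noise, zero rhythmic truth
  cfg2 <- generator_config(n_genes = 50,
                           class_proportions = c(I = 0, II = 0, III = 0,
                                                 IV = 0, V = 0, VI = 0, NC = 1))
  sim2 <- generate_transcriptome(cfg2, seed = 2)
  expect_true(all(sim2$truth$class == "NC"))
  expect_true(all(sim2$truth$amplitude_control == 0))

  # class semantics: III rhythmic in condition 1 only, VI in condition 2 only
  sim3 <- fixture_sim()
  t3 <- sim3$truth
  expect_true(all(t3$amplitude_control[t3$class == "III"] > 0))
  expect_true(all(t3$amplitude_TSR[t3$class == "III"] == 0))
  expect_true(all(t3$amplitude_control[t3$class == "VI"] == 0))
  expect_true(all(t3$amplitude_TSR[t3$class == "VI"] > 0))
  expect_true(all(abs(t3$mesor_TSR - t3$mesor_control)[t3$class %in% c("I", "II", "III", "VI", "NC")] == 0))
})

test_that("seeding is deterministic and truth is stable under n_genes changes", {
  cfg <- generator_config(n_genes = 60)
  a <- generate_transcriptome(cfg, seed = 9)
  b <- generate_transcriptome(cfg, seed = 9)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth, b$truth)

  c_ <- generate_transcriptome(cfg, seed = 10)
  expect_false(identical(a$expression, c_$expression))

  # per-gene streams: the first 60 genes of a larger run are unchanged
  big <- generate_transcriptome(generator_config(n_genes = 120), seed = 9)
  expect_identical(big$truth[1:60, ], a$truth)
})

test_that("rhythm caller rejection matches alpha on the all-NC world", {
  cfg <- generator_config(n_genes = 3000,
                          class_proportions = c(I = 0, II = 0, III = 0,
                                                IV = 0, V = 0, VI = 0, NC = 1))
  sim <- generate_transcriptome(cfg, seed = 4)
  r <- detect_rhythms(sim$expression, sim$samples, "control")
  expect_lt(abs(mean(r$p_value < 0.05) - 0.05), 0.013)
})

test_that("planted gene sets honour the odds parameter", {
  sim <- fixture_sim()
  sets_inf <- generate_gene_sets(
    sim$truth, list(S = list(class = "III", odds = Inf, size = 25)), seed = 1)
  expect_equal(sum(sim$truth$class[match(sets_inf$S, sim$truth$gene)] == "III"), 25)

  # odds = 1: expected overlap = size * class prevalence (binomial check)
  prev <- mean(sim$truth$class == "III")
  overlaps <- vapply(1:300, function(i) {
    s <- generate_gene_sets(sim$truth,
                            list(S = list(class = "III", odds = 1, size = 40)),
                            seed = i)
    sum(sim$truth$class[match(s$S, sim$truth$gene)] == "III")
  }, numeric(1))
  expected <- 40 * prev
  se <- sqrt(40 * prev * (1 - prev) / 300)
  expect_lt(abs(mean(overlaps) - expected), 4 * se)

  expect_length(generate_gene_sets(sim$truth, list(), seed = 1), 0)
  expect_error(generate_gene_sets(
    sim$truth, list(S = list(class = "III", odds = 1, size = 10000)), seed = 1),
    "exceeds")
  expect_error(generate_gene_sets(
    sim$truth, list(S = list(class = "XX", odds = 1, size = 5)), seed = 1),
    "absent")
})

test_that("hormone profiles realise the configured acrophases", {
  cfg <- generator_config(hormone = list(noise_frac = 0))
  h <- generate_hormone_profile(cfg, seed = 1)
  ctrl <- h[h$condition == "control", ]
  # noiseless: argmax on a dense reconstruction is the configured peak
  expect_equal(profile_peak_phase(h, "control"), 12, tolerance = 1e-6)
  expect_equal(profile_peak_phase(h, "TSR"), 6, tolerance = 1e-6)
  expect_equal(length(unique(h$zt)), 8)

  # conditions differ only in acrophase: same value sets, shifted
  expect_equal(sort(unique(round(ctrl$value, 9))),
               sort(unique(round(h$value[h$condition == "TSR"], 9))))

  h2 <- generate_hormone_profile(cfg, seed = 1)
  expect_identical(h, h2)
})

test_that("tolerance tests reproduce the pulse family", {
  cfg <- generator_config(tolerance = list(noise_sd = 0, pulse = c(control = 0, TSR = 0)))
  flat <- generate_tolerance_test(cfg, seed = 1)
  expect_true(all(flat$glucose == 70))

  cfg2 <- generator_config(tolerance = list(noise_sd = 0))
  tt <- generate_tolerance_test(cfg2, seed = 1)
  auc_c <- with(tt[tt$condition == "control" & tt$replicate == 1, ],
                tolerance_auc(minutes, glucose))
  auc_t <- with(tt[tt$condition == "TSR" & tt$replicate == 1, ],
                tolerance_auc(minutes, glucose))
  expect_gt(auc_c$baseline_corrected_auc, auc_t$baseline_corrected_auc)
  expect_identical(generate_tolerance_test(cfg2, seed = 3),
                   generate_tolerance_test(cfg2, seed = 3))
})
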