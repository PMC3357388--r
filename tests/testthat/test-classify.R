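test_that("Welch baseline test matches the formula oracle and handles degeneracy", {
  x <- c(8.1, 8.3, 7.9, 8.0)
  same <- baseline_change_test(x, x)
  expect_equal(same$baseline_lfc, 0)
  expect_equal(same$p_value, 1)

  # exact separation with zero within-condition variance
  sep <- baseline_change_test(rep(5, 6), rep(6, 6))
  expect_equal(sep$baseline_lfc, 1)
  expect_equal(sep$p_value, 0)
  expect_true(sep$degenerate)

  set.seed(31)
  for (i in 1:20) {
    x1 <- rnorm(sample(3:10, 1), mean = 8, sd = runif(1, 0.1, 1))
    x2 <- rnorm(sample(3:10, 1), mean = 8.4, sd = runif(1, 0.1, 1))
    got <- baseline_change_test(x1, x2)
    o <- welch_oracle(x1, x2)
    expect_equal(got$baseline_lfc, o$lfc, tolerance = 1e-12)
    expect_equal(got$t_stat, o$t, tolerance = 1e-9)
    expect_equal(got$df, o$df, tolerance = 1e-9)
    expect_equal(got$p_value, o$p, tolerance = 1e-9)
  }
  expect_error(baseline_change_test(1, c(1, 2)), ">= 2 samples")
})

test_that("rule order and thresholds drive the class assignment", {
  mk_rhythm <- function(rhythmic, acrophase) {
    data.frame(gene = c("gA", "gB", "gC"), condition = "x",
               mesor = 8, amplitude = ifelse(rhythmic, 1, 0),
               acrophase = acrophase, F_stat = 1,
               p_value = ifelse(rhythmic, 0.001, 0.9),
               q_value = ifelse(rhythmic, 0.01, 0.9),
               rhythmic = rhythmic, stringsAsFactors = FALSE)
  }
  base <- data.frame(gene = c("gA", "gB", "gC"), baseline_lfc = 0,
                     baseline_p = 1, stringsAsFactors = FALSE)
  cfg <- analysis_config()

  # phase 13 -> 14 conserved (I); 13 -> 19 shifted (II); rhythmic -> flat (III)
  r1 <- mk_rhythm(c(TRUE, TRUE, TRUE), c(13, 13, 13))
  r2 <- mk_rhythm(c(TRUE, TRUE, FALSE), c(14, 19, NA))
  cl <- classify_genes(r1, r2, base, cfg)
  expect_identical(cl$class_label, c("I", "II", "III"))
  expect_equal(cl$delta_phase, c(1, 6, NA))

  # rhythmic only in condition 2 -> VI
  cl2 <- classify_genes(mk_rhythm(c(FALSE, FALSE, FALSE), NA), r2, base, cfg)
  expect_identical(cl2$class_label[1:2], c("VI", "VI"))
  expect_identical(cl2$class_label[3], "NC")

  expect_error(classify_genes(r1[c(2, 1, 3), ], r2, base, cfg),
               "universes")
})

test_that("classes partition the universe and swap symmetry holds", {
  fx <- fixture_analysis()
  cl <- fx$classes
  expect_equal(nrow(cl), nrow(fx$sim$truth))
  expect_true(all(cl$class_label %in% c("I", "II", "III", "IV", "V", "VI", "NC")))
  expect_equal(sum(table(cl$class_label)), nrow(cl))

  # swapping the conditions maps III<->VI, IV<->V, fixes I/II/NC and
  # negates delta_phase and baseline_lfc
  base_sw <- baseline_change_table(fx$sim$expression, fx$sim$samples,
                                   "TSR", "control")
  cl_sw <- classify_genes(fx$r2, fx$r1, base_sw, fx$cfg)
  map <- c(I = "I", II = "II", III = "VI", IV = "V", V = "IV", VI = "III",
           NC = "NC")
  expect_identical(cl_sw$class_label, unname(map[cl$class_label]))
  expect_equal(cl_sw$baseline_lfc, -cl$baseline_lfc, tolerance = 1e-12)
  both <- cl$class_label %in% c("I", "II") & abs(cl$delta_phase) < 12
  expect_equal(cl_sw$delta_phase[both], -cl$delta_phase[both], tolerance = 1e-9)
})

test_that("noiseless synthetic data is classified in full agreement with truth", {
  sim <- generate_transcriptome(
    generator_config(n_genes = 300, noise_sd = 0), seed = 11)
  cfg <- analysis_config()
  r1 <- detect_rhythms(sim$expression, sim$samples, "control", cfg)
  r2 <- detect_rhythms(sim$expression, sim$samples, "TSR", cfg)
  base <- baseline_change_table(sim$expression, sim$samples, "control", "TSR")
  cl <- classify_genes(r1, r2, base, cfg)
  expect_identical(cl$class_label, sim$truth$class)
})

test_that("peak-time histogram bins to the nearest center with earlier-bin ties", {
  rt <- data.frame(gene = paste0("g", 1:3), condition = "c",
                   acrophase = c(0.5, 1.2, 13.4),
                   rhythmic = TRUE)
  h <- peak_time_histogram(rt)
  expect_equal(h$count, c(2, 0, 1, 0))

  # acrophase 4 is equidistant from centers 1 and 7 -> earlier bin
  rt2 <- data.frame(gene = "g", condition = "c", acrophase = 4, rhythmic = TRUE)
  expect_equal(peak_time_histogram(rt2)$count, c(1, 0, 0, 0))

  # empty rhythmic subset -> zero counts
  rt3 <- rt; rt3$rhythmic <- FALSE
  expect_equal(sum(peak_time_histogram(rt3)$count), 0)

  # conservation on the fixture
  fx <- fixture_analysis()
  h1 <- peak_time_histogram(fx$r1)
  expect_equal(sum(h1$count), sum(fx$r1$rhythmic & !is.na(fx$r1$acrophase)))
})

test_that("gene-set filtering preserves order and rejects unknown sets", {
  fx <- fixture_analysis()
  cl <- fx$classes
  all_set <- list(ALL = cl$gene, NONE = c("zzz1", "zzz2"),
                  S1 = cl$gene[1:50], S2 = cl$gene[30:80])
  expect_identical(filter_by_gene_sets(cl, all_set, "ALL"), cl)
  expect_equal(nrow(filter_by_gene_sets(cl, all_set, "NONE")), 0)
  un <- filter_by_gene_sets(cl, all_set, c("S1", "S2"))
  expect_equal(nrow(un), 80)
  expect_false(anyDuplicated(un$gene) > 0)
  expect_error(filter_by_gene_sets(cl, all_set, "MISSING"), "unknown set")
})
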