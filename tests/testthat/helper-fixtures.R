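# Small in-code fixtures shared across test files.

fixture_sample_table <- function(zts = c(1, 7, 13, 19), reps = 3,
                                 conditions = c("control", "TSR")) {
  df <- expand.grid(replicate = seq_len(reps), zt = zts,
                    condition = conditions,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$sample_id <- sprintf("%s_ZT%g_r%d", df$condition, df$zt, df$replicate)
  df[, c("sample_id", "condition", "zt", "replicate")]
}

# deterministic small synthetic dataset reused by several files
fixture_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_transcriptome(generator_config(n_genes = 400), seed = 42)
    }
    cache
  }
})

fixture_analysis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- fixture_sim()
      cfg <- analysis_config()
      r1 <- detect_rhythms(sim$expression, sim$samples, "control", cfg)
      r2 <- detect_rhythms(sim$expression, sim$samples, "TSR", cfg)
      base <- baseline_change_table(sim$expression, sim$samples, "control", "TSR")
      cache <<- list(sim = sim, cfg = cfg, r1 = r1, r2 = r2, base = base,
                     classes = classify_genes(r1, r2, base, cfg))
    }
    cache
  }
})
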