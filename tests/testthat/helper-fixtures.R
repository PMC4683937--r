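# Fixture builders shared by the suite. Everything is generated in code; no
# stored data files.

test_panel <- function() default_panel()

# A noiseless run: one wild-type control plus one sample per copy pair given
# as list(c(hba1, hba2), ...). Deterministic (no RNG touched).
noiseless_run <- function(pairs, panel = test_panel(), scale = 1) {
  genes <- c(panel$reference_gene, panel$target_genes)
  specs <- c(
    list(sim_sample_spec("control", noise_sd = 0)),
    lapply(seq_along(pairs), function(i) {
      copies <- c(panel$reference_copies, pairs[[i]][1L], pairs[[i]][2L])
      names(copies) <- genes
      sim_sample_spec(sprintf("s%02d", i), copies, scale = scale, noise_sd = 0)
    })
  )
  curves <- lapply(specs, simulate_curve, panel = panel)
  melt_run(curves, control_sample_id = "control", run_id = "noiseless")
}

# All 17 copy-pair/count rows of the bundled validation cohort.
cohort_pairs <- function() {
  tbl <- table2_cohort()
  lapply(seq_len(nrow(tbl)), function(i) c(tbl$hba1[i], tbl$hba2[i]))
}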