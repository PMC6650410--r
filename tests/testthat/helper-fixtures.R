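# Shared small fixtures built in code.

# tiny two-sample profile pair sharing one peptide within tolerance
tiny_profiles <- function(mass2 = 2000.05) {
  list(
    A = peptide_profile("a1", 2000.00, 20.0, 100),
    B = peptide_profile("b1", mass2, 20.3, 120)
  )
}

# a small fully-observed matched matrix built directly
toy_matrix <- function(values, sample_ids = paste0("s", seq_len(ncol(values)))) {
  matched_matrix(
    data.frame(master_id = seq_len(nrow(values)),
               mass_da = 1000 + seq_len(nrow(values)),
               migration_min = 20 + seq_len(nrow(values)) / 10),
    values, sample_ids = sample_ids)
}

# small pipeline run: generate -> normalize -> match
run_small_pipeline <- function(config) {
  sim <- generate_cohort(config)
  prof <- lapply(sim$profiles, normalize_profile, reference = sim$reference)
  m <- match_profiles(prof, reference = sim$reference)
  list(sim = sim, matrix = m, truth_map = map_to_truth(m, sim$truth))
}
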