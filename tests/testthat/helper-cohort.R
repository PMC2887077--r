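# Shared fixture builders. Desk-scale cohorts use 2000 probes so the whole
# suite stays fast; the generator itself defaults to the full array size.

studyConfig <- function(rng_seed, n_probes = 2000,
                        n_signature_probes = min(150L, n_probes %/% 5), ...) {
  simConfig(n_probes = n_probes, n_signature_probes = n_signature_probes,
            seed_counts = c(9, 5), rng_seed = rng_seed, ...)
}

scoreFixture <- function() {
  read.csv(system.file("extdata", "synthetic_histology_scores_47.csv",
                       package = "hepaStage"), stringsAsFactors = FALSE)
}

histologyTable <- function(cohort) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  data.frame(subject_id = cd$sample_id,
             inflammation_grade = cd$inflammation_grade,
             fibrosis_stage = cd$fibrosis_stage)
}

# random small expression matrix with dimnames
randomMatrix <- function(p, n, sd = 1, mean = 7) {
  matrix(rnorm(p * n, mean, sd), p, n,
         dimnames = list(sprintf("p%03d", seq_len(p)),
                         sprintf("s%03d", seq_len(n))))
}
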