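# hepaStage

Molecular staging of liver disease in biliary atresia from bulk
gene-expression profiles.

Biliary atresia obstructs the extrahepatic bile ducts of infants and
progresses to cirrhosis; biopsies taken at portoenterostomy show portal
inflammation and fibrosis in varying mixtures. `hepaStage` implements a
staging workflow for such cohorts: biopsies whose ordinal histology scores
(0–3 inflammation grade, 0–3 fibrosis stage) differ by at least 2 define
*seed groups* with a predominant phenotype; a differential-expression
signature between the seed groups is derived from the log2 expression
matrix (per-gene median normalization → fold-change filter `> 2`, strict →
Welch's t-test → Benjamini–Hochberg FDR, retaining `q < 0.05`); the
remaining "mixed" biopsies are then assigned to molecular inflammation or
fibrosis by a nearest shrunken centroid (PAM-style) classifier under
ten-times ten-fold stratified cross-validation with a ≥ 6-of-10
majority-vote rule; finally the molecular groups are tested against
clinical covariates and transplant-free survival (Fisher exact, Wilcoxon,
Kruskal–Wallis, Gaussian-kernel age densities, Kaplan–Meier + log-rank,
conditional-exact odds ratios, logistic regression).

The classifier shrinks standardized centroid contrasts

    d_ik = (xbar_ik − xbar_i) / (m_k (s_i + s_0)),   m_k = sqrt(1/n_k + 1/n)

by soft threshold Δ and assigns a sample x to the class minimizing
`Σ_i (x_i − xbar'_ik)² / (s_i + s_0)² − 2 log π_k`.

A synthetic-cohort generator (`simulateCohort()`) reproduces the cohort
structure this analysis assumes — two latent molecular groups, 150 planted
probes with > 2-fold effects, ordinal histology concordant with the latent
group, a group age shift, and group-dependent hazard of transplant/death
with 24-month censoring — so the entire pipeline is testable without
microarray data. See the vignette in `vignettes/molecular-staging.Rmd` for
the model, parameter and design notes.

## Worked example

```r
library(hepaStage)

cohort <- simulateCohort(simConfig(n_probes = 2000, seed_counts = c(9, 5),
                                   rng_seed = 1))
scores <- data.frame(subject_id = colnames(cohort),
                     inflammation_grade = SummarizedExperiment::colData(cohort)$inflammation_grade,
                     fibrosis_stage = SummarizedExperiment::colData(cohort)$fibrosis_stage)
groups <- assignHistologyGroups(scores, threshold = 2)
histologyCounts(groups)
#> n_inflammation     n_fibrosis        n_mixed
#>              9              5             33

sig <- deriveSignature(cohort,
                       inflammation = groups$subject_id[groups$label == "inflammation"],
                       fibrosis = groups$subject_id[groups$label == "fibrosis"])
sig
#> SignatureResult
#>   filter trail: 2000 probes -> 148 after fold-change (> 2) -> 148 after FDR (q < 0.05)
#>   direction: up_in_fibrosis = 49, up_in_inflammation = 99

probes <- signatureProbes(sig)
xn <- perGeneMedianNormalize(cohort)[probes, ]
seedIds  <- groups$subject_id[groups$label != "mixed"]
mixedIds <- groups$subject_id[groups$label == "mixed"]
votes <- repeatedCVClassify(xn[, seedIds],
                            factor(groups$label[groups$label != "mixed"],
                                   levels = c("inflammation", "fibrosis")),
                            external = xn[, mixedIds], seed = 1)
votes
#> VoteTable: 47 samples ( 14 train, 33 external ), 10 repetitions, >= 6 votes to assign
#>               role
#> assignment     external train
#>   fibrosis           23     5
#>   inflammation       10     9

cd <- SummarizedExperiment::colData(cohort)
mol <- assignments(votes)
lr <- logrankTest(cd$followup_months, cd$event, mol[colnames(cohort)])
sprintf("log-rank chi2 = %.2f, p = %.3f", lr$chi2, lr$p)
#> "log-rank chi2 = 11.12, p = 0.001"
```

Of the 47 biopsies, 14 are histology-predominant (9 inflammation, 5
fibrosis) and seed the signature; the signature recovers 148 of the 2,000
probes as differential; all 33 mixed biopsies receive a ≥ 6-of-10 majority
vote; and the molecular fibrosis group shows significantly lower
transplant-free survival, as the generating hazard ratio of 3 implies.

The same stages run end to end from files via `runPipeline()` with a YAML
configuration (see `?pipelineConfig`), or from a shell through the thin
wrapper `inst/scripts/stagepipe.R` (`simulate`, `classify-histology`,
`run-all`).

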