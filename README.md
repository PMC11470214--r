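# vioscales

Violence-situation typology and reproducibility of functional-impairment
scales.

Forensic physicians who examine individuals exposed to violence certify
functional impairment (in France: days of *total incapacity to work*, TIW)
and rate subjective elements — pain, fear, perceived life threat — on
7-level Likert scales (0–6).  `vioscales` implements the analysis needed to
evaluate such scales under real-life conditions, where a classic
test–retest design is impossible:

1. **Typology.** Consultations are clustered into violence-situation
   profiles from mixed binary/numeric features, using Gower dissimilarity
   and partitioning around medoids (PAM); the number of profiles is chosen
   by consensus resampling with a multimetric rule (PAC, mean within-cluster
   consensus, Jaccard stability, consensus silhouette).
2. **Concordance.** Patients are randomly matched within profiles — between
   physician pairs (interrater) or within one physician (intrarater) — and
   agreement of the scale scores is measured by the tie-corrected Kendall
   coefficient of concordance

   W = 12·S / (m²(n³−n) − m·ΣTⱼ),  S = Σᵢ (Rᵢ − m(n+1)/2)²,

   with mid-ranks per rater and tie terms Tⱼ = Σ(t³−t), repeated over many
   random matchings.
3. **Characterization.** Scales are described by median (IQR) per profile,
   compared between physicians with the Kruskal–Wallis test and
   Conover–Iman post hoc comparisons (Bonferroni-adjusted), and regressed
   univariately against TIW.

Records of this kind are private, so the package ships a synthetic-cohort
generator (`generate_cohort()`) reproducing the structure the analysis
assumes — five latent situation profiles with published mixing proportions
and per-profile feature frequencies, per-physician rater bias, ordinal
scales from rounded latent Gaussians, a linear TIW link, typo-bearing
certificate free text, and MCAR missingness — plus a lexicon miner
(`extract_features()`) that recovers symptom flags from the text.

## Worked example

```r
library(vioscales)

cfg <- cohort_config(n_patients = 1000)   # defaults encode the study tables
coh <- generate_cohort(cfg, seed = 42)
d   <- gower_dissimilarity(coh)

cc <- consensus_clustering(d, k_range = 2:7, n_resamples = 30,
                           subsample_frac = 0.8, seed = 43)
print(cc)
#> Consensus clustering over k = {2, 3, 4, 5, 6, 7}: selected k = 4
#>   30 resamples of 80% of n = 1000
#>  k   pac mean_consensus jaccard silhouette
#>  2 0.327          0.908   0.850      0.882
#>  3 0.403          0.801   0.679      0.729
#>  4 0.188          0.870   0.791      0.842
#>  5 0.191          0.850   0.761      0.818
#>  6 0.233          0.763   0.632      0.680
#>  7 0.188          0.790   0.675      0.720
```

At this desk scale the two closest planted profiles (low- and high-impact
single-assailant assaults) merge and k = 4 wins narrowly over 5; at full
study scale (n = 4180, 50 resamples of 20%) the same procedure selects
k = 5 with PAC dipping sharply there — that run is what the acceptance
script reproduces.

```r
ap  <- assign_profiles(coh, d, k = cc$selected_k, seed = 44)
res <- concordance_analysis(coh, ap$labels, "fear_assault", type = "inter",
                            contexts = list(c("D01", "D02")), R = 50, seed = 45)
subset(as.data.frame(res), profile == "pooled")
#>          scale context profile    W_mean    W_p2.5   W_p97.5 n_pairs  R
#> 5 fear_assault D01:D02  pooled 0.5277133 0.4194556 0.6173537     102 50
```

Pooled across profiles, the two physicians' fear-at-assault ratings agree
at W ≈ 0.53 (0.42–0.62 across matching repetitions) — "mild" concordance:
0.5 is the expected value for unrelated patients, and values rise only as
far as profile membership explains the scores.

```r
ols_univariate(coh, "pain_assault")
#> pain_assault: beta = 0.643 (0.584 to 0.702), n = 1000
```

Each point of pain during the assault is associated with ~0.64 extra days
of TIW in this simulated cohort (the generator plants 0.68 directly plus
correlated fear/life-threat effects).

The end-to-end pipeline — simulate → certificates → mining → eligibility →
typology → statistics → concordance, with one master seed and a written
report — is `run_pipeline()` / `write_report()`, also available as a thin
command-line wrapper in `inst/scripts/vioscales-pipeline.R`.

## Documentation

The methods vignette (`vignettes/vioscales-methods.Rmd`) documents the
generative model, the dissimilarity/clustering/selection choices, the
matching designs, the tie-corrected statistics, numerical edge cases, and
what passing tests do and do not establish about real data.
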