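# junctionMH

Quantifying how germline-encoded microhomology biases trimming and ligation
in V(D)J recombination.

## The problem

When a V and a J gene end are joined during V(D)J recombination, short
stretches of sequence shared between the two ends — microhomology (MH) —
can pair across the break and appear only once in the junction. For a
junction without N-insertions, this means several distinct annotations
(delV, delJ, MH) can explain the same observed sequence, yet conventional
annotation software attributes shared nucleotides to a single gene and
considers only the MH = 0 explanations. `junctionMH` is for immune
repertoire analysts and recombination-mechanism researchers who want to

* enumerate **every** trimming/ligation annotation consistent with an
  observed zero-N-insertion junction,
* estimate how strongly microhomology biases trimming and ligation,
* test those effects, and
* see how MH parameterization re-ranks per-sequence annotations.

## The model

Scenario choice is a **two-step conditional logit on the base-10 odds
scale**. A scenario `s = (delVJ, MH)` in the choice set `C` of a gene pair
and productivity class gets

    P(s | C; β) = 10^η(s) / Σ_{s'∈C} 10^η(s'),
    η(s) = β_trim · f_trim(s) + β_lig · f_lig(s)

with trimming-step features (per-gene trimming motif one-hots, 5'/3' AT/GC
base counts, and `mh_trim` = average MH available to the trimmed pair) and
the ligation-step feature `mh_lig` = MH used in the joint. The joint
factors exactly into a trimming marginal and a ligation conditional
because productivity conditioning restricts the choice set before
normalization. Each coefficient `b` is a log10 odds increment:
`oddsPercent(b) = 100·(10^b − 1)` percent per feature unit.

Because the true annotation of each sequence is latent, fitting uses EM:
the E-step assigns posterior responsibilities over each sequence's
annotation set, the M-step is a weighted conditional-logit fit over full
choice sets. Bootstrap Wald tests (sequence-level resampling, Bonferroni
correction) assess individual coefficients; a likelihood-ratio test with
2 df assesses the MH pair jointly against the nested no-MH model.

## Worked example

```r
library(junctionMH)

## the toy pair shares "AG", so one junction has six annotations
v <- germlineGene("toyV", "V", "CACAG")   # extended CACAGCT
j <- germlineGene("toyJ", "J", "AGGTA")   # extended CTAGGTA
ax <- enumerateAnnotations("CACAGGTA", v, j)
annotationPosteriors(ax, mhParameters(c(mh_lig = log10(2))))$annotations
#>   del_v del_j mh junction   productivity       prob
#> 1     0     0  2 CACAGGTA non-productive 0.36363636
#> 2     0     1  1 CACAGGTA non-productive 0.18181818
#> 3     0     2  0 CACAGGTA non-productive 0.09090909
#> 4     1     0  1 CACAGGTA non-productive 0.18181818
#> 5     1     1  0 CACAGGTA non-productive 0.09090909
#> 6     2     0  0 CACAGGTA non-productive 0.09090909
```

With a ligation coefficient of log10(2), every microhomologous nucleotide
doubles a scenario's odds, so the 2-MH annotation is top-ranked at
P = 4/11 ≈ 0.364 while each MH-free attribution of the shared "AG" gets
1/11.

```r
## fit the model on a synthetic repertoire with known truth
pair <- generateGenePair(seed = 1)                      # plants a shared "AGG"
rep  <- sampleRepertoire(pair$v, pair$j, mhRegime("mh_both"),  # truth .45/.13
                         n = 2000, seed = 2)
data <- prepareRepertoireData(rep, list(synthV = pair$v, synthJ = pair$j))
(fit <- fitEM(data))
#> MHFitResult: 24 EM iteration(s), converged; logLik = -5890.217
#>   MH coefficients: mh_trim = 0.427, mh_lig = 0.1612

se <- bootstrapSE(data, fit, B = 50, seed = 3)
waldTests(coef(fit)[c("mh_trim", "mh_lig")],
          se[c("mh_trim", "mh_lig")], nParams = length(se))
#>   parameter  estimate         se statistic      p_value significant
#> 1   mh_trim 0.4269831 0.06864882  6.219817 4.977346e-10        TRUE
#> 2    mh_lig 0.1612124 0.02859373  5.638031 1.720054e-08        TRUE

fit0 <- fitEM(data, includeMHTrim = FALSE, includeMHLig = FALSE)
lrtTest(fit, fit0)
#> $LR: 96.05843   $df: 2   $p: 1.384132e-21
```

The planted effects (0.45 trimming, 0.13 ligation, log10-odds) are
recovered within two bootstrap standard errors, both Wald tests reject at
the Bonferroni threshold, and the likelihood-ratio test strongly rejects
the no-MH model. `compareModels()` / `pairFlipCorrelation()` then
summarize how the MH terms change top-ranked annotations.

See `vignettes/microhomology-model.Rmd` for the modeling conventions
(P-nucleotides, deletion indexing, productivity), feature definitions,
and numerical details.

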