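# CoCoDiff

Complex-centric differential co-expression analysis with
transcription-factor influence inference, for two-condition expression
studies (e.g. normal vs. tumour cohorts) overlaid on a protein-protein
interaction (PPI) network.

Individual-gene differential expression misses coordinated changes in the
machinery cells actually run on: protein complexes. CoCoDiff asks a
complex-level question instead — which complexes lose or gain internal
co-expression between two conditions, and which transcription factors
(TFs) drive those changes?

## The method

Starting from a PPI network *H = (V, E)* with per-edge reliability scores
(iterated Czekanowski–Dice scoring, low-scoring edges discarded) and one
expression matrix per condition:

1. **Conditional networks.** Every edge *(p, q)* is weighted by the
   Pearson correlation ρ(p, q) of its genes in that condition, passed
   through the variance-emphasizing transform
   *z = ½·log((1+ρ)/(1−ρ))* (base-10 by default, so ρ = 0.99 ↦ 1.149).
2. **Complex extraction.** Markov clustering (inflation 2.3) of the
   co-expression-weighted network; clusters with ≥ 4 members become
   complexes. Each complex *S* gets a co-expression score *C(S)*, the
   average transformed pairwise correlation of its members.
3. **Matching.** Complexes from the two conditions are paired when their
   composition overlaps (Jaccard ≥ 0.67) and their co-expression differs
   (ΔC = |C(S) − C(T)| ≥ 0.10), one-to-one. Matched pairs split into M′
   (higher in the first condition) and M″ (lower), with KS and
   random-complex null statistics for the distribution-level comparisons.
4. **TF influence.** A TF regulates a complex only if it physically
   interacts with a member; its regulation score *R(S, F)* is the mean
   correlation with those members. The log-linear model
   *ΔC(S,T) = Π_f ΔR(S,T,F_f)^γ_f* is solved for the influence
   coefficients γ by SVD least squares; |γ| ranks TFs, signs separate
   cooperative from counteractive TFs, and permutation of the ΔC vector
   gives per-TF p-values.

A synthetic-study generator plants complexes, co-expression shifts and TF
influence coefficients with known ground truth, so every stage is
testable without external downloads.

## Worked example

The two-complex, two-TF demonstration system: complexes *A* and *B* change
co-expression by 0.50 and 0.60 while two TFs change their regulation by
(5, 10) and (6, 20):

```r
library(CoCoDiff)
model <- assembleModel(c(0.50, 0.60), rbind(c(5, 10), c(6, 20)))
model$logDR
#        TF1     TF2
# [1,] 0.69897 1.00000
# [2,] 0.77815 1.30103
fit <- solveInfluence(model)
round(fit$gamma, 3)
#    TF1    TF2
# -1.294  0.603
round(normalizeInfluence(fit$gamma), 3)
#    TF1    TF2
# -1.000  0.466   # scaled by the largest |gamma|; signs preserved
```

The first TF is roughly twice as influential as the second and the
opposite signs mean the two act counteractively: the second TF doubles
its regulation yet co-expression barely moves, because the first
counteracts it.

A full synthetic run:

```r
study <- generateRecoveryStudy(seed = 7)          # 8 planted complexes, 3 TFs
cnA <- conditionNetwork(study$net, study$exprA)
cnB <- conditionNetwork(study$net, study$exprB)
SA  <- extractComplexes(cnA, study$exprA)
SB  <- extractComplexes(cnB, study$exprB)
matched <- matchComplexes(SA, SB)                 # tJ = 0.67, delta = 0.10
res <- tfInfluence(matched, SA, SB, study$tfs, study$net,
                   study$exprA, study$exprB, nPerm = 200, seed = 7)
influenceTable(res)
#    tf       gamma   normGamma nComplexes     pValue
#   TF1  1.99281484  1.00000000          8 0.01492537
#   TF2 -1.03732028 -0.52053018          8 0.06965174
#   TF3  0.04422262  0.02219103          8 0.92039801
```

The planted coefficients were γ = (+2, −1, 0): the two active TFs are
recovered with the right magnitudes and signs and the inert TF sits near
zero with an unremarkable permutation p-value.

There is also a thin command-line front end
(`inst/scripts/cocodiff`, subcommands `simulate`, `score-net`,
`condition`, `extract`, `match`, `influence`) over the same functions.

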