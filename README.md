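# urateh2

Rare-variant heritability of serum urate by carrier-grouped variance
decomposition.

## The problem

Common variants found by GWAS explain only a small fraction of the 30–70%
heritability of serum urate — the "missing heritability" problem. One
candidate reservoir is rare, strongly functional coding variants of
*SLC22A12*, the gene encoding the renal urate transporter URAT1:
loss-of-function alleles impair urate reabsorption and lower serum urate.
This package implements, as a tested and reusable pipeline, the analysis
that quantifies how much trait variance such variants explain in a
sex-stratified cohort: participant filtering, functional classification of
transporter variants from oocyte uptake-assay statistics, covariate
adjustment, a carrier-collapsing burden test, and a carrier-grouped
variance decomposition. It is aimed at statistical geneticists and
epidemiologists who want to apply or probe this estimator without access
to the original (access-controlled) biobank data — a seeded synthetic
cohort generator reproduces the study conditions end to end.

## The estimator

With U = G + E, Cov(G, E) = 0, adjusted urate defined as the residual of a
sex-stratified OLS fit of urate on age, BMI, eGFR, and HbA1c, and
participants collapsed into carriers (n2, mean m2) of any qualifying
functional variant versus wild-type homozygotes (n1, m1), the gene's
additive variance is the between-group component of the law of total
variance,

    V(A_gene) = [ n1 (m1 − m)² + n2 (m2 − m)² ] / (n1 + n2),   m = grand mean,

and its heritability share is h²_gene = 100 · V(A_gene) / V(U). All
decomposition variances use divisor n, under which
V(U_adjusted) = pooled within-group variance + V(A_gene) holds exactly.
The carrier/wild-type contrast is tested with Welch's two-sample t-test
from group summaries (the equal-weight burden test). Variants qualify via
a Welch test of oocyte urate uptake against wild type (reduced uptake,
p < 0.01) or a loss-of-function annotation (stop gain, validated splice
disruption). eGFR is CKD-EPI 2009 × 0.908 (Japanese coefficient).

## Worked example

```r
library(urateh2)

co  <- simulate_cohort(sim_config(seed = 2))   # 631 men, 647 women, ~6% carriers
men <- co$participants[co$participants$sex == "male", ]
fit <- urate_h2(urate ~ age + bmi + egfr + hba1c, data = men,
                carrier = co$carrier[men$id])
summary(fit)
```

```
Carrier-grouped urate heritability

Covariate adjustment:
         term estimate       se      t         p
1 (Intercept)  6.61278 0.737863  8.962 3.638e-18
2         age  0.02728 0.004750  5.744 1.442e-08
3         bmi  0.06857 0.017093  4.012 6.759e-05
4        egfr -0.03313 0.003742 -8.851 8.815e-18
5       hba1c -0.19535 0.077474 -2.521 1.194e-02

Carrier-group statistics (adjusted urate)
  wild type: n = 589, mean = 0.126, SD = 1.248
  carriers : n = 42, mean = -1.767, SD = 1.123
  grand mean = 0.0000

Variance decomposition of serum urate
  component variance portion_pct
       V(U)     2.13       100.0
 V(E_known)     0.37        17.4
  V(A_gene)     0.22        10.5
Burden test (carriers vs wild type): t = 10.47, df = 48.5, p = 4.82e-14
```

Reading the output: the 42 simulated carriers sit ~1.9 mg/dl below the
wild-type mean after covariate adjustment; that contrast places
0.22 (mg/dl)² of between-group variance in the gene, 10.5% of the total
trait variance — close to this cohort's realized ground truth
(`co$true$male$h2_true`), which the generator returns for recovery checks.

Applied to the *published* carrier-group summaries instead of simulated
data, the same functions give the headline estimates of the original
analysis:

```r
st <- group_stats_from_summary(596, 0.12, 1.25, 38, -1.92, 0.87)  # men
round(additive_variance(st), 2)        # 0.23 (mg/dl)^2
round(heritability_share(0.23, 1.73), 1)  # 13.3 (%)
burden_test(st)$p.value                # ~6e-18
```

`run_pipeline(pipeline_config(...), out_dir)` wires all stages (simulate
or read TSV/VCF inputs → filter → classify → adjust → decompose) behind
one validated config and writes report tables, a JSON summary, and a log;
`inst/scripts/urate-pipeline.R` is a thin command-line wrapper. See the
vignette (`vignettes/urate-heritability.Rmd`) for the model, assumptions,
and design choices.

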