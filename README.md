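# cidnet

Supervised transcription-factor network analysis and prognostic signature
discovery for probe-level expression cohorts.

## The problem

Bulk tumor expression cohorts carry two kinds of signal about a regulator:
which genes its expression *tracks* (its putative transcriptional network)
and which of those genes *matter clinically* (association with histology and
survival). `cidnet` implements a supervised pipeline that couples the two,
built around a breast-carcinoma study design of 181 infiltrating ductal
carcinomas split into an ER(+) cohort of 90 (called `90A`), an ER(−) cohort
of 91 (`91A`) and their union (`181A`):

1. **Association.** For a driver TF with expression `x` and each candidate
   target `y`, two statistics are computed. The **CID** (coefficient of
   intrinsic dependence) cuts `x` into `K` near-equal rank bins and measures

   `S = Σ_k (n_k/n) · (1/n) Σ_i [F_k(y_i) − F(y_i)]²`,

   the weighted squared distance between each bin's empirical distribution
   function `F_k` of `y` and the pooled EDF `F`, normalised by the
   maximal-separation configuration so that CID = `S/S_max ∈ [0,1]`. It is a
   rank statistic: invariant to monotone transforms, sensitive to nonlinear
   and non-monotone dose-response. Its significance comes from a permutation
   null. The **GPCC** (Galton–Pearson correlation coefficient) is the usual
   Pearson `r` with the t-reference p-value. An edge is called when *either*
   adjusted p-value passes the threshold — the **CIDUGPCC union rule** — and
   each called edge gets an up/down regulatory mode.
2. **Clinical relevance.** Per-probe one-way ANOVA screens against
   histology (grade, nuclear pleomorphism, mitotic count, …) give gene
   pools; intersecting the pools that contain the TF itself gives its
   clinically significant cluster. Called networks are profiled against 13
   pathway gene sets.
3. **Prognostic typing.** Every probe is split at its 90th expression
   percentile in each cohort and log-rank tested (Kaplan–Meier). A probe is
   **type 1** if prognostic in all three cohorts, **type 2** in `91A` and
   `181A` only, **type 3** in `90A` and `181A` only, **type 4** in `181A`
   only. Intersecting with a called network gives **feature types I–IV**.
4. **Signatures.** The consensus poor-prognosis signature is the overlap of
   a TF's feature-type-II pools in `91A` and `181A`; the antagonistic
   favorable signature is the shared feature-type-IV targets on which two
   TFs act with opposite modes. Samples are scored by mode-aligned mean
   z-score; subcohorts are the top score decile; evaluation is
   Kaplan–Meier/log-rank plus univariate and multivariate Cox proportional
   hazards.

A synthetic cohort generator (`simulate_cohort`) reproduces this study
design with planted linear / threshold / quadratic edges, an antagonistic
second TF, histology linked to the driver TF and survival tied to a planted
15-probe signature module, so every stage can be validated against known
truth. Two packaged tables ship the study's printed 16-probe poor-prognosis
pool and 8-TF antagonistic signature.

## Worked example

```r
library(cidnet)

dat <- simulate_cohort(sim_config(), seed = 1)   # 2000 probes x 181 samples
cohorts <- define_cohorts(dat$clinical)
net <- tf_network(dat$expr, dat$truth$tf_a, cohorts[["181A"]], "181A", seed = 1)
print(net)
#> tf_network: TF 1 (TFA), cohort 181A (181 samples)
#>   1999 probes scanned, 40 called (39/1 up/down)  [K=5, B=4999, BH q<=0.05]

run <- run_pipeline(seed = 1)                     # the whole pipeline
print(run)
#> pipeline_run (seed 1 )
#>   samples: 181 | network called 91A/181A: 39/40 | cluster: 21
#>   typed probes (181A significant): 110 | consensus: 12 probes | antagonistic: 0 probes
#>   held-out evaluation log-rank p = 2.866e-18 (high_poor)
```

The network fit scans every probe against the driver TF and calls 40 edges
(exactly the 40 the generator planted for this TF at this seed); the
pipeline then types all probes across the three cohorts, intersects
feature type II of the `91A` and `181A` networks into a consensus
signature (12 probes here, all from the planted 15-probe module), and
evaluates its top score decile on a *fresh* cohort drawn from the same
generative truth — the log-rank p above is held-out evidence, not
resubstitution. The antagonistic route returns an empty signature on this
truth because the default generator plants no favorable type-IV module;
that path is exercised by the packaged 8-TF table and the unit tests.
(Counts and the held-out p are exactly what these commands print at
seed 1; other seeds vary.)

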