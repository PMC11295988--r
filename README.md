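# oddballcrp

Free-recall dynamics around emotional and perceptual oddballs: lag-CRP and
item-anchored CRP estimation, behavioural recall measures, within-subject
inference, plus a paradigm generator and a generative recall simulator so the
whole pipeline runs end-to-end on synthetic data.

## Who this is for

Researchers analysing free-recall experiments in oddball (Von Restorff)
list-learning paradigms: word lists containing one deviant item — emotionally
aversive content (*emotional oddball*) or a deviant font (*perceptual
oddball*) — followed by free recall, where the question is not just *whether*
the oddball is better recalled but *how recall flows around it*.

## The statistics at the core

**Lag-CRP.** For signed lag *k*, the conditional response probability is

```
CRP(k) = (# transitions of lag k) / (# opportunities for a lag-k transition)
```

where, at each scored transition from the item studied at position *i*, every
not-yet-recalled position *j* contributes an opportunity at lag *j − i*
(window ±5 by default). Transitions touching intrusions or repetitions are
excluded and never bridged. Healthy free recall shows *forward contiguity*:
CRP peaks at small positive lags.

**Anchored CRP.** The same ratio restricted to transitions whose *source* is
a designated item — the list's oddball, or a control item matched to the
oddball's study position in another list — with lag measured from that
anchor (lag 0 is the anchor itself and carries no ratio). The central test is
a 2×2 within-subject RM-ANOVA on mean forward anchored CRP with factors
salience type (emotional/perceptual) × novelty (oddball/control), with
FDR-corrected paired-*t* post-hocs (Cohen's *dz*) and partial eta squared.

**Design and power.** The paradigm generator reproduces the encoding design
(40 lists of 14 nouns; oddballs at positions 7–12 excluding 10; input-matched
controls ≥3 positions away; SOAs of 1–6 s balanced 4 lists per SOA per type),
and the power module computes minimal paired-*t* sample sizes from the
noncentral *t* distribution.

## Worked example

```r
library(oddballcrp)

design  <- generate_design(seed = 1)                       # 40 x 14 design
dataset <- simulate_experiment(design, sim_params(n_subjects = 70, seed = 1))

cells <- anchored_cell_means(dataset, "forward")           # per-subject cells
rm_anova_2x2(cells, mean_crp, subject_id, oddball_type, anchor_role)
```

```
2x2 within-subject RM-ANOVA (n = 68 subjects, 2 dropped)
# A tibble: 3 × 8
  effect ss_effect ss_error df_effect df_error statistic p.value partial_eta_sq
1 A        0.00948    0.484         1       67     1.31   0.256         0.0192
2 B        0.00173    0.608         1       67     0.190  0.664         0.00283
3 A:B      0.0400     0.885         1       67     3.03   0.0866        0.0432
```

Factor A is salience type, B is novelty; the A:B row is the novelty ×
salience interaction on forward transitions from the anchors. The group cell
means behind it show the selective emotional pattern the simulator's
forward-binding boost (`b_E = 2`) produces — transitions out of emotional
oddballs are enhanced relative to their matched controls, while perceptual
oddballs are not:

```
  oddball_type anchor_role mean_crp
1 emotional    control        0.179
2 emotional    oddball        0.196
3 perceptual   control        0.191
4 perceptual   oddball        0.161
```

Recall also improves with presentation rate (mean % of the 14 items recalled
per list, by SOA):

```
  soa_s   pct
1     1  23.8
2     2  26.0
3     3  30.7
4     4  37.2
5     6  51.7
```

And the planning computation for a paired design at the previously reported
retrograde-amnesia effect size:

```r
required_n_paired_t(dz = 1.69, power = 0.95, alpha = 0.05)
#> [1] 7
```

Other entry points: `lag_crp()`, `anchored_crp()`, `total_recall_by_soa()`,
`item_recall_proportion()`, `peri_oddball_recall()`, `output_position()`,
`probability_first_recall()`, `forwardflow_amnesia_correlation()`,
`paired_t()`, `fdr_adjust()`, `pearson_corr()`, the plot helpers
(`plot_crp()`, `plot_anchored_cells()`, `plot_recall_by_soa()`,
`plot_pfr()`), and `run_pipeline()`, which writes the full CSV/report bundle.
A thin command-line front end with `design` / `simulate` / `analyze` /
`power` / `report` subcommands ships in `inst/cli/oddballcrp`.

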