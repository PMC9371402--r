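# tolcat

Headless engine for an adaptive, computerized **Tower of London (TOL)**
planning test, with the item-response-theory (IRT) machinery used to
calibrate it. It is aimed at computational psychometricians and
neuropsychology researchers who need a fully scriptable, testable version
of the instrument: no UI, no server — puzzle mathematics, adaptive
administration, scoring, calibration, and simulation.

## What is inside

* **Puzzle model** — exact enumeration of TOL board state spaces, legal
  moves, and minimal-move solving by breadth-first search. The three-disc
  board (peg capacities 3, 2, 1; 36 states) supports difficulty levels up
  to 8 moves; the four-disc board (3, 2, 2; 192 states) reaches 10. The
  Tower of Hanoi (minimal solution `2^n - 1`) is included as a search
  oracle.
* **Item bank** — deterministic, seeded generation of 2 familiarization +
  4 assessment + 10×3 testing items, every level verified by the solver;
  schema-versioned JSON serialization with re-validation on load; the
  published 25-item 2PL calibration, item-fit table and model-comparison
  summary ship as plain-CSV fixtures (`packaged_calibration()`).
* **Adaptive engine** — three phases (familiarization with feedback,
  assessment fixing the entry level, adaptive testing). A level passes on
  2-of-3 successes; failing demotes, passing promotes; two consecutive
  failed levels stop the test. Items are scored from millisecond
  grab/drop/done event streams against move limits (tightened
  `adjusted` scheme 1,3,4,5,7,8,10,11,12,14 or `legacy` 2×minimal) and
  time limits, with `wrong_layout` / `time_exceeded` / `moves_exceeded`
  flags.
* **IRT calibration** — Rasch / 2PL / 3PL by marginal maximum likelihood
  (EM with Gauss-Hermite quadrature over a standard-normal ability prior):

  `P(correct | θ) = c + (1 − c) / (1 + exp(−a(θ − b)))`

  with EAP ability estimates, item/test information functions
  (`a²P(1−P)` for the 2PL), rest-score-conditioned chi-square item fit,
  AIC/BIC, and likelihood-ratio model comparison.
* **Simulation** — Bernoulli (ICC-driven) respondents, a noisy-optimal
  puzzle-playing agent, seeded cohort simulation, and parameter-recovery
  studies.

## Worked example

```r
library(tolcat)

bank <- generate_bank(seed = 1)
bank
#> <tol_item_bank> seed 1, scheme adjusted
#>  familiarization: 2, assessment: 4 (levels 2,4,6,8), testing: 30
#>      variant
#> level D3 D4
#>    1   1  2
#>    ...
#>    9   0  3
#>    10  0  3

# one simulated examinee of above-average planning ability
rec <- run_session(
  bernoulli_cat_responder(default_item_params(bank), theta = 0.8, seed = 7),
  session_config(bank), "demo")
rec
#> <tol_session demo> start level 7, final score 10 (ceiling_passed)
#>  levels administered: 7 8 9 10
```

The examinee solved all four assessment items, so testing starts at level
7; passing 7 through 10 ends the session at the ceiling with final score
10 (the highest passed level). A cohort pipeline, ending in a calibrated
2PL:

```r
cohort <- simulate_cat_cohort(bank, n = 50, seed = 42)
M <- complete_matrix(cohort$sessions, bank)
M
#> <tol_response_matrix> 50 respondents x 30 items
#> status
#> administered      granted  not_reached
#>          494          631          375

fit <- fit_irt(exclude_easy_items(M)$matrix, "2pl", se = FALSE)
fit
#> <tol_irt_fit 2PL> 21 items, N = 50
#>  log-lik -303.48 (k = 42), AIC 690.96, BIC 771.27; 29 EM iterations
#>  flagged items: Item_4_2, Item_4_3, Item_6_3, ...
```

Most responses were never administered: the adaptive procedure *grants*
items below the examinee's band and scores unreached items 0, which is how
the published analysis completed its matrix. At N = 50 many items are
Heywood-flagged (extreme estimates) — expected at this sample size; the
package flags rather than hides them.

There is also a command-line surface:

```sh
Rscript -e 'tolcat::tolcat_cli()' generate-bank --out bank.json --seed 1
Rscript -e 'tolcat::tolcat_cli()' run-session --bank bank.json --agent noisy-optimal --seed 7 --out_json s.json
Rscript -e 'tolcat::tolcat_cli()' simulate-cohort --bank bank.json --n 214 --seed 42 --out cohort/
Rscript -e 'tolcat::tolcat_cli()' compare-models --matrix cohort/response_matrix.csv --out cmp.csv
Rscript -e 'tolcat::tolcat_cli()' info-curve --params table2 --out curve.csv
```

## Further reading

The methods vignette (`vignettes/tolcat-methods.Rmd`) documents the model
and every consequential design decision: board geometries, move/time
limits, the session completion rule, EM settings and Heywood flagging, the
rest-conditioned item-fit statistic, and what the synthetic-data tests do
and do not establish.
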