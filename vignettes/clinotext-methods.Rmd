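---
title: "Mining performance status and progression-free survival from clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining performance status and progression-free survival from clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinotext)
```

## The problem

Two of the most important endpoints in observational oncology research —
the ECOG/WHO performance status (PS) at treatment initiation and
progression-free survival (PFS) — are rarely stored as structured data.
They live in free-text outpatient notes, admission summaries, and small
remarks, written tersely and inconsistently. Collecting them manually is
accurate but extremely labor intensive; `clinotext` implements a
transparent, rule-based alternative: every extraction is produced by a
regular expression a clinical researcher can read, audit, and extend.

The pipeline has two arms sharing infrastructure:

* **PS arm**: aggressive text normalization, a single compact pattern
  matching a PS keyword followed by one or two digits, and a temporal rule
  matching the extracted values to the treatment initiation date.
* **PFS arm**: sentence-preserving normalization, custom sentence
  segmentation, rule-based labelling of sentences as before (BP), around
  (PP), or after (AP) progression, and a resolution step that turns each
  patient's chronological label sequence into a progression or censoring
  date.

## Text normalization

PS values appear in many surface forms: `WHO 1`, `who:1`, `ECOG 1-2`,
`P.S. 1`. Rather than enumerating formats, `normalize_for_ps()` lowercases
the text and deletes all whitespace and all punctuation except `.` and `,`
(which delimit sentences and clauses). Everything above collapses onto
`who1` / `ecog12`-like forms that one pattern covers. Two consequences are
deliberate:

* Hyphens are punctuation, so a range `WHO 1-2` becomes `who12`. The
  extractor therefore reads two adjacent digits as a clinician's range
  (first digit = score, second = secondary score), never as a score of 12;
  a second digit more than 2 apart from the first is not a plausible range
  and is left unconsumed.
* The normalization is faithful to the method's known misses. `WHO O`
  (letter O for the number 0) becomes `whoo` and does not match; `PS is 2`
  becomes `psis2` and does not match the strict pattern. These failure
  modes cause *misses, never false values*, which is the right failure
  direction for a screening tool. An optional relaxed pattern
  (`ps$allow_intervening`) accepts a short non-digit gap and recovers the
  `psis2` family; it ships off by default because silent recovery changes
  the method's error profile.

For the PFS arm the text must stay sentence-shaped.
`normalize_for_pfs()` lowercases, expands abbreviations (including drug
shorthands such as `osi` → `osimertinib` and period-bearing forms such as
`mg.` whose periods would fool the sentence splitter), and removes only
articles (`de`/`het` in Dutch, `the` in English). General stop-word lists
are not used: they contain words equivalent to *no* and *maybe*, and
deleting a negation flips the meaning of a progression sentence. The
abbreviation map is applied in one pass, longest form first, so produced
text is never re-expanded.

## Sentence segmentation

Clinical notes often lack terminal punctuation; authors separate
statements with new lines and runs of spaces. Built-in sentence tokenizers
assume prose, so `split_sentences()` defines boundaries directly:

1. `.`, `?`, `!` followed by whitespace or end of text — a period between
   digits (`1.5`) is never a boundary;
2. any newline;
3. a run of three or more spaces (two spaces are common after manual
   edits and do not split; the threshold is configurable).

These rules are this package's concrete definition of the segmentation
step; they are deterministic, order-preserving, and token-conserving
(tested as a property).

## Rule discovery and the rule engine

Expert knowledge alone does not enumerate how progression is actually
written. `ngram_counts()` and `kwic()` (keyword-in-context) exist to mine
the corpus for candidate phrasings before encoding them. Phase rules are
`(rule_id, phase, pattern, priority)` rows; the engine evaluates them in
descending priority, breaking ties by lexicographically lower `rule_id`
(deterministic and visible in the output). Negation-aware BP rules (e.g.
*geen progressie*) must outrank bare keyword PP rules; the engine performs
no implicit negation scoping — all semantics live in the patterns, where
they can be audited. A built-in rule assigns AP to any sentence starting a
post-progression drug, since a new anticancer line implies progression has
occurred.

The shipped English and Dutch lexicons are starter sets, deliberately
small. Real deployments must extend them against their own corpus via the
n-gram workflow.

## Temporal resolution

**Baseline PS.** The PS closest to treatment initiation within 30 days
before (inclusive of the initiation day) is matched; only if that window
is empty is the earliest PS up to 14 days after allowed. Same-day ties
prefer structured over mined values, then the lower score. The matcher is
verified against an exhaustive brute-force search over all offsets in
−60…+60 days.

**Progression call.** Each patient's dated BP/PP/AP labels are resolved
as follows: the earliest PP is the candidate event; it stands unless a BP
occurs within the confirmation window (default 30 days) after it without
any PP/AP re-assertion before that BP. A retracted candidate is dropped
and the next PP after the contradicting BP is evaluated the same way; if
every PP is retracted but an AP follows the last retraction, the first
such AP is the event (`ap_only` — the event happened at or before it).
Only-BP timelines censor at the last BP date. Contradictions that never
re-assert, and empty timelines, return `unresolved` and are routed to the
manual-review list: the tool's job is to say *when it does not know*.
This resolution procedure is this package's formalization of reading the
chronological overview; the retraction-then-reassertion branch is our own
design choice, kept because it preserves a useful monotonicity — deleting
a BP observation can never move a progression date later (tested as a
property).

**Scan alignment.** Progression is documented at the visit a few days
after the scan that shows it, so a called event date snaps back to the
latest CT/MRI date within 14 days before it (configurable).

**Months.** PFS is reported in months using 30.44 days/month (365.25/12).

**Death.** A deaths table is optional; when supplied, a death date is a
progression event per the PFS definition. The default is no deaths table:
inferring death from silence in the notes invites incorrect assumptions,
and such patients surface as `no_followup` for manual collection.

## Evaluation layer

* **PS**: confusion matrix over patients scored by both arms; class-wise
  precision/recall/F1 on the 0–100 scale; weighted F1 = support-weighted
  mean of class F1. A class never predicted gets precision 0 (with a
  warning) so the weighted total stays defined.
* **PFS**: Kaplan–Meier product-limit curves per arm via the `survival`
  package with log–log confidence bands; the median CI is the band
  inversion at 0.5 (Brookmeyer–Crowley style). The method had to be
  chosen here: log–log is the common default for survival data and is
  range-respecting. An all-censored arm reports an undefined median, not
  an error.
* **C-index**: Harrell's C with the reference arm as outcome and the
  text-mined time as predictor, computed in-package by full pair
  enumeration. Comparability is decided on the reference arm only (the
  earlier reference time must be an event; equal reference times are not
  orderable); text-mined ties count 0.5. Censoring in the text-mined arm
  does not affect comparability — those times enter at their recorded
  value. This convention is stated prominently because no single C-index
  variant is canonical under censoring in both arms.
* **Discrepancy flags**: per-patient ratio of text-mined to reference
  PFS; ratios above 3 or below 1/3 (or with a zero reference time) are
  flagged and sorted by |log ratio| for root-cause review.
* **Cohort flow**: every patient lands in exactly one of
  resolved / unresolved / no-follow-up / unmatched per arm; the counts
  must partition the cohort and the function enforces it.

## The synthetic cohort generator

Because real EMR text cannot ship with a package, `generate_cohort()` +
`render_notes()` produce cohorts with *known ground truth*, and that
ground truth — not any hand-labelled fixture — is the oracle for the
end-to-end tests.

What it emulates, and the defaults chosen once as realistic study
conditions:

* baseline PS distributed with mass on 0–2 (weights 90:163:51:22 on PS
  0–3), the shape of an advanced-NSCLC cohort fit for targeted therapy;
* PFS exponential with median 8 months (Weibull available);
* follow-up visits every 42 ± 10 days — routine oncology cadence — with
  one pre-treatment visit and a baseline visit on the initiation day;
* a CT scan 2–7 days before the visit at which progression is discussed;
* censoring as an *independent* exponential time whose rate is calibrated
  so the marginal censoring probability equals `censoring_prob`
  (`λ_C = λ_T · p/(1−p)`). Drawing a censor time uniformly before the
  event would be informative censoring and would bias the Kaplan–Meier
  estimate; independence keeps the KM coverage property testable. An
  administrative cutoff is available and off (`Inf`) by default, so
  `censoring_prob = 0` means every patient has an event.

Noise modes reproduce documented failure modes, each with its own rate:
`WHO O` misspellings of PS 0, intervening words (`PS is 2`), vague
progression language outside the rule lexicon (growth-of-a-lesion
phrasing, which delays detection to the next AP evidence or routes the
patient to review), drug shorthand (`osi`, absorbed by the abbreviation
map), and missing PS mentions. Corruption decisions use common random
numbers — per-mention uniforms are drawn unconditionally and compared to
the rate — so the corpus at rate 0.2 corrupts a subset of the mentions
corrupted at 0.5 under the same seed, making "degradation is monotone in
the noise rate" a well-posed, testable statement.

Two time scales coexist in the ground truth: the *latent* event time
drawn from the PFS distribution, and the *reference* (chart-detectable)
time — the scan date before the progression visit, or the last visit for
censored patients. The reference tables are what a perfect manual curator
reading the chart would produce, and are the comparison arm for
end-to-end recovery (a noise-free run reproduces them exactly: weighted
F1 = 100%, C = 1, identical KM medians). Distribution-recovery checks use
the latent times (`truth_tables(truth, time = "latent")`), because the
visit grid adds a forward shift of about half a visit interval that is a
property of chart abstraction, not of the estimator under test.

What the generator does **not** emulate: real clinical language variety,
multi-topic notes, copy-paste artifacts, spelling errors beyond the
specific `WHO O` mode, PDF-only documentation, and multi-line treatment
histories. Passing the synthetic suite therefore demonstrates the
mechanics are correct, not that the starter lexicons suffice on real
text.

## Numerical and degenerate-input choices

* Notes dated exactly on the initiation day stay in the PFS input
  (progression cannot be called before day 0; baseline visits are often
  same-day).
* Rows with unparseable dates, out-of-range dates (default 1990–2100), or
  invalid PS values are rejected into a side report, never dropped
  silently; ambiguous day/month literals under `dialect = "auto"` are
  flagged.
* A patient whose notes all precede initiation is retained with zero
  notes and reported as `no_followup`.
* Empty treatment tables abort the PFS run; unresolved calls have no
  survival representation and must be excluded or resolved by the caller.
* `km_estimate()` requires at least one record; `concordance_index()`
  returns `NA` with a warning below two comparable pairs.

## Problem sizes in the test suite

The package's own checks run cohorts of 300 patients for end-to-end
recovery and noise degradation, 50 replicates of 300 for the KM-median
coverage property, and 5000 draws for the distribution sanity check —
sizes at which Monte-Carlo error is small relative to the tested margins
while the suite stays fast.

## Known limitations

Rule-based extraction cannot recognize what is not encoded: vague or
sparse descriptions delay or prevent detection, and the correct response
is the manual-review route, not a guess. The shipped lexicons are
illustrative starter sets; real deployments must grow them. The approach
is complementary to manual curation — it removes the bulk of the work and
says explicitly where a human is still needed.
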