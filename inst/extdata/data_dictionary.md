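# Participant CSV data dictionary

One row per participant; missing values are empty cells. Synthetic cohorts
written by `write_trial()` follow this layout exactly; `read_trial()`
validates the header and every Likert cell against it.

| Column | Type | Units / codes | Description |
|---|---|---|---|
| id | string | — | opaque participant identifier |
| age | numeric | years | age at enrolment (synthetic cohorts: 45–74) |
| female | integer | 0/1 | female sex indicator |
| education | string | primary, secondary, technical_bachelor | highest educational attainment; ordinal 1–3 in regressions |
| married | integer | 0/1 | married indicator |
| employed | integer | 0/1 | employed indicator |
| bmi_baseline | numeric | kg/m2 | baseline body-mass index |
| bmi_change | numeric | kg/m2 | 90-day change (follow-up minus baseline) |
| weight_baseline | numeric | kg | baseline weight |
| weight_change | numeric | kg | 90-day change |
| sbp_baseline | numeric | mmHg | baseline systolic blood pressure |
| sbp_change | numeric | mmHg | 90-day change |
| dbp_baseline | numeric | mmHg | baseline diastolic blood pressure |
| dbp_change | numeric | mmHg | 90-day change |
| hba1c_baseline | numeric | % | baseline glycated haemoglobin |
| hba1c_change | numeric | % | 90-day change |
| diabetes_duration | integer | years | optional covariate |
| comorbidity_count | integer | count | optional covariate |
| medication_regimen | string | oral_mono, oral_dual, oral_plus | optional covariate |
| csuq_01 … csuq_16 | integer | 1–7 Likert | CSUQ item responses; empty = missing. Items 1–6 system quality, 7–12 information quality, 13–15 interface quality, 16 overall satisfaction |

Synthetic cohorts additionally carry two in-memory attributes (not written
to CSV): `latents` — the generator's internal trace (`M` latent interface
quality used for items 13–15 and the outcome equation, `S`/`I`/`O` dimension
latents, `eps_m`/`eps_y` structural noise draws) — and `config`, the
`generator_config` that produced them.
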