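# File schemas

All tabular files are CSV: UTF-8, snake_case headers, "." decimal separator,
empty string for missing values.

## children.csv (one row per measured child)

| column | type | notes |
|---|---|---|
| country | string | country code |
| region | string | label from the region roster |
| round_id | string | survey round identifier, unique within country |
| interview_year | int | calendar year of measurement |
| interview_month | int | 1-12 |
| age_months | int | 0-59 |
| whz | float | weight-for-height z-score; optional if indicators present |
| wasting_any / wasting_mod_sev / wasting_severe | 0/1 | WHZ < -1 / < -2 / < -3 |
| asset_class | string | none / some / all (of five listed assets) |
| maternal_education_years | int | |
| piped_water, flush_toilet, facility_birth, anc4, fully_vaccinated, teen_birth, parity_4plus, female, rural | 0/1 | household/maternal/child controls |
| design_weight | float > 0 | within-survey design weight |
| diarrhea, fever_only, low_maternal_bmi, min_diet_diversity | 0/1 | mechanism outcomes; min_diet_diversity missing outside ages 6-35 months |

## macro.csv (one row per country-year)

`country, year`, plus either levels `gni_pc, gdp_pc` (strictly positive,
preferred) or precomputed `gni_growth, gdp_growth` (percent per annum).
Annual growth is simple percent change of per-capita levels.

## countries.csv (one row per country)

`country, region, pop_u5` (under-5 population, > 0), plus optional planted
baseline prevalence columns in synthetic data.

## projection input (one row per country)

`country, grouping, prev_2019` (percent), `pop_u5`, and either `shock`
(percent) or both `g2020` and `g_decade_mean` (percent).

## fit output (tidy, one row per coefficient)

`term, estimate, se_clustered, ci_lo, ci_hi, block`, with a companion
`*_meta.txt` echoing sample size, cluster count, dropped columns and
per-column missingness.
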