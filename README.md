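# adamatrix

Machine-readable data-use conditions for biomedical resources: an R
implementation of the **Automatable Discovery and Access Matrix (ADA-M)
v1.0** information model, with a typed Profile document model, two
serialization dialects, the seven-rule Profile validator, and a formulaic
decision engine for screening discovery queries and adjudicating access
requests.

## The problem

Datasets, biospecimen collections and other biomedical resources are shared
under heterogeneous conditions — consents, laws, access policies, transfer
agreements. Without a common information model these conditions live in
free-text documents that Data Access Committees (DACs), Research Ethics
Committees and end users must re-read and re-interpret at every request.
ADA-M structures them as a metadata **Profile**: one **Header** (13 items, 3
required) plus one or more **Main Bodies**, each Main Body holding 42
concepts in three sections:

* **Permissions** (26 hierarchically arranged concepts, mostly
  consent-derived). Each takes one value from
  `Unrestricted | Limited | Unrestricted[Obligatory] | Limited[Obligatory] | Forbidden`;
  the last three options are unavailable for the three use-scope concepts
  (use within countries/locations, use by organizations, use by categories
  of person) whose use must unavoidably occur in some manner. A `Limited`
  value is ideally elaborated with a condition list such as
  `"Use permitted for research on diseases A, B[Obligatory], and C"` —
  meaning the use *must* relate to disease B and *may* also cover A and/or C.
* **Terms** (11 concepts, legal/contractual), phrased as negated statements
  ("There are no requirements regarding collaboration") with values
  `True` (no condition) / `Untrue` (a condition applies).
* **Meta-Conditions** (5 concepts), notably the required **Mode of sharing**
  (`Discovery`, `Access`, `Discovery and Access`) and the interpretation
  rule (`Meet all` / `Meet any`) that becomes mandatory once two or more
  entries carry `[Obligatory]` markers.

A request is adjudicated per eligible body: `PERMIT` when some body passes
every formulaic check, `DENY` when every eligible body fails one, and
`REFER` — route to a human — whenever the decisive input is non-formulaic
(prose free text, a `Limited` value without a machine-readable list, an
acknowledged unspecified restriction).

## Worked example

```r
library(adamatrix)

p <- adam_profile(header = list(
  profile_id         = "CANCER-RES-0001",
  profile_version    = "2026-09-19/1.0",
  resource_reference = "doi:10.5072/synthetic-cancer-cohort"))
p <- set_entry(p, 1, "mode_of_sharing", "Discovery and Access")
p <- set_entry(p, 1, "research_disease_specific", "Limited",
               free_text = "Use permitted for research on diseases cancer, and melanoma")
p <- set_entry(p, 1, "profit_use", "Forbidden")

validate_profile(p)
#> <adam_validation> valid (no findings)

cancer_req <- adam_request("Access",
  declared_uses = list(research_disease_specific = "cancer"))
adjudicate(p, cancer_req)
#> <adam_decision> PERMIT (via body 1) | mode: Access | 1 eligible body/bodies

diabetes_req <- adam_request("Access",
  declared_uses = list(research_disease_specific = "diabetes"))
adjudicate(p, diabetes_req)
#> <adam_decision> DENY  | mode: Access | 1 eligible body/bodies
```

`PERMIT` here means every entry of the body passed: the declared disease
falls inside the permitted list and the forbidden profit use is not
requested; the diabetes request is denied because its declared use falls
outside the `Limited` list. Results are tidyverse-friendly: `tidy()` returns
the per-concept verdict (or validation finding) tibble, `glance()` the
one-row summary, `autoplot()` a ggplot view.

Profiles serialize to two equivalent dialects — pretty-printed JSON
(`profile_to_json()`) and a flat `key=value` text format
(`profile_to_keyvalue()`, e.g.
`body.0.permissions.research_disease_specific.value=Limited`) — with
byte-stable output and exact round-trip identity. `generate_profile()` /
`generate_request()` synthesize seeded, validator-passing corpora for
testing, and `screen_profiles()` prescreens a collection of Profiles for a
discovery query.

## Command line

A thin wrapper over the same functions is installed at
`inst/cli/adam`:

```
adam validate profile.adam.json            # exit 0 valid / 1 findings / 2 malformed
adam convert --to kv profile.adam.json     # JSON <-> key-value
adam decide --profile p.adam.json --request r.req.json   # exit 0 PERMIT / 1 DENY / 3 REFER
adam query --profiles dir/ --request r.req.json
adam generate --n 10 --seed 1 --out dir/
```

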