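---
title: "Data-use Profiles, validation and formulaic access decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-use Profiles, validation and formulaic access decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adamatrix)
```

## The information model

`adamatrix` implements the ADA-M v1.0 model for machine-readable data-use
conditions. A **Profile** is one Header plus one or more Main Bodies; each
body states one combination of use criteria through three sections —
Permissions (what uses are allowed, forbidden or obligated), Terms
(contractual conditions expressed as negated statements), and
Meta-Conditions (over-arching settings, notably the Mode of sharing that
says whether the body governs discovery, access, or both). Multiple bodies
are *alternatives*: a request is permitted if any eligible body permits it.
The model's premise is a clean split between what a computer can evaluate
formulaically (enumerated values, parseable condition lists) and what must
stay with a human — the package never guesses at prose.

The concept taxonomy is data, not code: `default_registry()` loads a
versioned JSON document (`inst/extdata/adam_registry_v1.0.json`) with 13
Header items (3 required), 26 Permissions, 11 Terms and 5 Meta-Conditions
concepts, and `load_registry()` accepts a replacement taxonomy with the same
invariants. The model fixes the *cardinalities* and the anchor concepts (the
three restricted use-scope concepts, the recontact Terms concept with its
two free-text slots, Mode of sharing, the interpretation rule, the
"no other restrictions" concept); the remaining concept ids in the shipped
registry are our own names, grounded in the model's category descriptions
(laws, access policies, transfer and access agreements, consent scope, and
disease-, method-, user- and purpose-scoped research use). An adopter bound
to an official taxonomy can swap the registry document without code
changes. Which three Header items are required is likewise our choice:
profile identifier, creation date/version, and the reference to the
governed resource — the minimum for a Profile to be citable and resolvable.

## The `[Obligatory]` list micro-grammar

Free text accompanying a `Limited` permission ideally takes the shape
`"Use permitted for research on diseases A, B[Obligatory], and C"`.
`parse_condition_list()` accepts exactly that shape: comma-separated items,
an optional final "and", an optional prose preamble whose last token is the
first item, and a case-insensitive `[Obligatory]` suffix per item
(canonicalized on output by `render_condition_list()`). The grammar is
deliberately conservative, because a false parse silently changes a
decision while a refused parse merely routes to a human:

* comma-free multi-word text is prose;
* any sentence punctuation (`.;:`) makes the whole text prose — so the
  two-sentence permitted/prohibited pattern is prose too, since a
  prohibited-list would need negation semantics the model does not define;
* items after the first must stay short (at most three words);
* a parse failure returns `NULL`, never an error, and the text is kept
  verbatim.

One consequence: a *single*-item list can only be written bare (`"A"` or
`"A[Obligatory]"`); `render_condition_list()` therefore drops the preamble
for one-item lists so that parse and render stay exact mutual inverses —
a property the suite checks over seeded random lists.

## Validation

`validate_profile()` evaluates seven completion rules (R1–R7,
`validation_rules()`), reporting every violation with a location path and
never short-circuiting: required Header items non-empty (R1); every body
asserts at least one Permissions-or-Terms value (R2); every body sets Mode
of sharing (R3); the interpretation rule is present once a body carries two
or more `[Obligatory]` markers, counted over entry values, parsed list
items, and the recontact concept's "must occur" slot (R4); the three
restricted use-scope concepts carry only `Unrestricted`/`Limited` (R5); no
free text under a concept with no main value (R6); every value belongs to
its concept's permitted list (R7). One boundary needed a decision: R7
checks membership in the concept *type's* vocabulary (the five permission
tokens, `True`/`Untrue`, each Meta concept's own list), while the narrower
domain of the restricted trio is enforced by R5 alone — otherwise a single
`Forbidden` on a restricted concept would be double-reported, and the
generator's per-rule mutations (`mutate_invalid()`) could not be flagged by
exactly one rule each, which is how the rule set is audited.

## The decision engine and the REFER boundary

`adjudicate()` evaluates a request against every mode-eligible body:

* `Unrestricted` passes; `Forbidden` fails exactly when the request
  declares a use under the concept (and passes vacuously otherwise);
  `Limited` passes when the declared uses fall inside the parsed permitted
  list. Label matching is exact after trimming and case-folding — no
  synonym or ontology expansion; REFER is the escape hatch.
* Obligations — `[Obligatory]` entry values (the use must be engaged) and
  `[Obligatory]` list items (that item must be declared) — are pooled per
  body and resolved under the body's interpretation rule: `Meet all`
  (default when the rule is absent, which validation only allows below two
  obligations, where the two rules coincide) requires every obligation,
  `Meet any` at least one. An unmet pool fails the concepts holding the
  unmet obligations: an obligated use that the request omits is
  formulaically incompatible, not a judgement call.
* Terms: `True` passes; `Untrue` in access mode requires the requester to
  have accepted the concept; in discovery mode it is merely informative and
  passes.
* REFER arises only from non-formulaic input: prose free text on a
  permission that would otherwise pass (a possible conditionality a human
  must read), a `Limited` value with no machine-readable list, an entry
  with free text but no value, or a Meta acknowledgement that unspecified
  restrictions exist. A failing entry stays FAIL even when prose is
  present: extra conditions cannot weaken an already-decisive denial.
  Concepts absent from a body impose no constraint.

Across bodies: `PERMIT` if some eligible body is all-PASS, `DENY` if every
eligible body (vacuously: none) has a failure, `REFER` otherwise.
`screen_profiles()` applies this to a collection with a discovery request
and keeps `PERMIT`/`REFER` — the prescreen that spares DACs ineligible
requests. Vulnerable-group considerations have no trigger attribute in the
model; where they exist they will surface as prose, and hence as REFER.

Two engine properties are tested rather than assumed: exhaustive agreement
with an independently coded brute-force oracle on a small registry
(every declared-use subset over a 3-label vocabulary, both modes, both
accepted-terms subsets — 4,096 requests), and monotonicity over 1,000
seeded relaxation pairs. The relaxation set is deliberately the provable
one: `Forbidden → Limited`, obligation-free `Limited → Unrestricted`,
appending a non-obligatory list item, enlarging the accepted terms.
Removing an `[Obligatory]` marker is *not* monotone under `Meet any` —
deleting the one satisfied obligation can flip a permit — so it is not
treated as a relaxation.

## Serialization

Two equivalent dialects, both UTF-8, both canonicalized to registry order
so equal Profiles serialize byte-identically and unset fields are omitted
entirely: a pretty-printed JSON document (`adamVersion`, `header`,
`bodies[]`, entries keyed by concept id with `value`/`freeText`/
`freeText2`), and a flat key-value text with dotted, zero-based paths
(`body.0.permissions.<id>.value=Limited`), `\n` line ends and
backslash-escaped newlines in values. Errors carry the line number
(key-value) or JSON path; duplicate keys are rejected; unknown concept ids
are an error in strict mode and dropped with a warning otherwise. The body
count of a key-value document is the largest body index plus one — an
entirely empty trailing body is not representable, which is harmless since
such a body is invalid anyway (R2/R3). Enum tokens serialize exactly as
canonically printed (`Unrestricted[Obligatory]`, `Untrue`, ...).

## The synthetic generator

`generate_profile()` defines the study conditions for all property suites:
one or two bodies; one to four Permissions entries per body with
`Limited` probability 0.35, `Forbidden` 0.10 and an `[Obligatory]` upgrade
probability of 0.25 (entry and per-item); up to two Terms entries split
evenly between `True`/`Untrue`; condition lists drawn from the disease
tokens A–F of the worked examples; optional Header items filled with
probability 0.25. These rates are chosen so that a 200-profile census
exercises all five permission values and both term values while keeping
most profiles formulaic; with `strictness = FALSE` the generator also
emits prose free text and acknowledged-unspecified restrictions, i.e.
REFER-grade profiles. A single integer seed drives one stream
(`withr::with_seed`), the global RNG state is untouched, and every
generated Profile is asserted valid before it is returned.

`generate_request()` constructs PERMIT-by-construction or
DENY-by-construction requests and *verifies* the intent by adjudication
before returning, raising `adam_intent_unsatisfiable` when the Profile
admits no such request (nothing can be denied against an all-`Unrestricted`
profile). Incompatible requests are found by searching a small candidate
set (undeclared-label poisoning of `Limited`/`Forbidden` concepts, empty
declarations against obligations, unaccepted terms) — a search, not a
proof, so the generator fails loudly rather than returning a request of
unknown intent.

What the generator does not emulate: real consent language (labels are
tokens, not ontology terms), deep Permissions hierarchies, conflicting
multi-authority profiles, or adversarial free text. Passing suites
therefore demonstrate the mechanics of the model on well-formed input, not
robustness to messy real-world curation.

## Problem sizes and degenerate inputs

The shipped suites use: a 500-profile corpus for validation and round-trip
identity; 25 profiles per rule for mutation detection; 4,096
request-profile pairs for oracle agreement; 1,000 relaxation pairs for
monotonicity; 200 pairs per intent for the request contracts. Degenerate
inputs are pinned by tests: empty registries count as zero per section;
an empty condition list cannot be rendered; a profile must hold at least
one body; requests against a mode no body covers are denied (nothing can
permit them); screening an empty collection yields an empty tibble.

## Known limitations

* The shipped registry's non-anchor concept names are placeholders, not an
  official taxonomy; interoperating deployments should agree on a registry
  document.
* The condition-list grammar reads permitted lists only; prohibited lists
  and cross-references ("resulting data must be made public") remain prose
  and hence REFER.
* Decisions assume the Profile is trustworthy metadata; the package neither
  verifies a requester's declarations nor audits the underlying governance
  documents.
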