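test_that("default registry reproduces the v1.0 section structure", {
  reg <- default_registry()
  counts <- section_counts(reg)
  expect_equal(counts$n[counts$section == "HEADER"], 13L)
  expect_equal(counts$n[counts$section == "PERMISSIONS"], 26L)
  expect_equal(counts$n[counts$section == "TERMS"], 11L)
  expect_equal(counts$n[counts$section == "META"], 5L)
  expect_equal(sum(counts$n[counts$section != "HEADER"]), 42L)
  expect_equal(sum(reg$section == "HEADER" & reg$requirement == "REQUIRED"), 3L)
  main <- reg[reg$section != "HEADER", ]
  expect_identical(main$concept_id[main$requirement == "REQUIRED"],
                   "mode_of_sharing")
  expect_identical(main$concept_id[main$requirement == "CONDITIONAL"],
                   "interpretation_rule")
})

test_that("permission value domains split 23 extended / 3 restricted", {
  reg <- default_registry()
  perm <- reg[reg$section == "PERMISSIONS", ]
  dom_len <- vapply(perm$value_domain, length, 1L)
  expect_equal(sum(dom_len == 5L), 23L)
  expect_equal(sum(dom_len == 2L), 3L)
  restricted <- perm$concept_id[!perm$supports_forbidden_obligatory]
  expect_setequal(restricted, c("use_within_countries", "use_by_organizations",
                                "use_by_person_categories"))
  # restricted concepts can be neither Forbidden nor made Obligatory
  for (id in restricted) {
    dom <- perm$value_domain[perm$concept_id == id][[1]]
    expect_setequal(dom, c("Unrestricted", "Limited"))
  }
})

test_that("registry hierarchy is a one-level forest, checked by traversal", {
  reg <- default_registry()
  with_parent <- reg$concept_id[!is.na(reg$parent_id)]
  parents <- reg$parent_id[!is.na(reg$parent_id)]
  expect_true(all(parents %in% reg$concept_id[reg$section == "PERMISSIONS"]))
  # walking upward from any concept terminates after at most one step
  for (id in with_parent) {
    parent <- reg$parent_id[reg$concept_id == id]
    expect_true(is.na(reg$parent_id[reg$concept_id == parent]))
  }
})

test_that("loading the shipped document round-trips to the default registry", {
  path <- system.file("extdata", "adam_registry_v1.0.json",
                      package = "adamatrix")
  expect_identical(load_registry(path), default_registry())
})

test_that("invariant violations are rejected with named errors", {
  reg <- default_registry()
  # unknown parent
  broken <- tibble::as_tibble(reg)
  broken$parent_id[broken$concept_id == "clinical_care"] <- "not_a_concept"
  expect_error(adam_registry(broken, version_tag = "broken/1"),
               class = "adam_registry_invariant")
  # wrong cardinality under the default version tag
  short <- tibble::as_tibble(reg)[reg$concept_id != "data_linkage", ]
  expect_error(adam_registry(short, version_tag = registry_version(reg)),
               class = "adam_registry_invariant")
  # same document under a custom tag is structurally fine
  expect_s3_class(adam_registry(short, version_tag = "custom/25perm"),
                  "adam_registry")
  # malformed document file
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", tmp)
  expect_error(load_registry(tmp), class = "adam_malformed_registry")
})

test_that("section_counts recounts arbitrary registries", {
  empty <- adam_registry(tibble::tibble(concept_id = character(),
                                        section = character()),
                         version_tag = "empty/0")
  expect_equal(section_counts(empty)$n, rep(0L, 4))
  reg <- default_registry()
  dropped <- adam_registry(
    tibble::as_tibble(reg)[reg$concept_id != "no_fee_terms", ],
    version_tag = "custom/10terms")
  sc <- section_counts(dropped)
  expect_equal(sc$n[sc$section == "TERMS"], 10L)
})
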