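test_that("json serialization omits unset fields and is byte-deterministic", {
  p <- minimal_profile()
  j <- profile_to_json(p)
  expect_false(grepl("\"terms\"", j))
  expect_false(grepl("\"freeText\"", j))
  expect_false(grepl("null", j, fixed = TRUE))
  expect_identical(j, profile_to_json(p))
  expect_identical(profile_from_json(j), p)
})

test_that("unknown concept ids follow the strictness flag", {
  j <- sub("research_use", "reasearch_use", profile_to_json(minimal_profile()))
  expect_error(profile_from_json(j), class = "adam_unknown_concept")
  expect_warning(p <- profile_from_json(j, strict = FALSE), "Dropping")
  expect_length(p$bodies[[1]]$permissions, 0L)
})

test_that("multi-body documents round-trip with body count intact", {
  p <- minimal_profile()
  p <- add_body(p)
  p <- set_entry(p, 2, "mode_of_sharing", "Access")
  p <- set_entry(p, 2, "no_collaboration_terms", "Untrue")
  expect_equal(n_bodies(profile_from_json(profile_to_json(p))), 2L)
  expect_equal(n_bodies(profile_from_keyvalue(profile_to_keyvalue(p))), 2L)
})

test_that("the key-value dialect writes dotted zero-based paths", {
  p <- disease_profile()
  kv <- profile_to_keyvalue(p)
  expect_match(kv, "body\\.0\\.permissions\\.research_disease_specific\\.value=Limited")
  expect_match(kv, "body\\.0\\.meta\\.mode_of_sharing\\.value=Discovery and Access")
  expect_match(kv, "header\\.profile_id=P-0002")
  expect_identical(profile_from_keyvalue(kv), p)
})

test_that("key-value errors carry line numbers", {
  p <- minimal_profile()
  kv <- profile_to_keyvalue(p)
  dup <- paste0(kv, "header.profile_id=OTHER\n")
  err <- expect_error(profile_from_keyvalue(dup), class = "adam_duplicate_key")
  expect_match(conditionMessage(err), "line 6")
  expect_error(profile_from_keyvalue("header.profile_id\n"),
               class = "adam_malformed_document")
  expect_error(profile_from_keyvalue("body.0.permits.consent.value=Limited\n"),
               class = "adam_malformed_document")
  expect_error(profile_from_keyvalue(sub("research_use", "zz", kv)),
               class = "adam_unknown_concept")
})

test_that("values with newlines and backslashes survive both formats", {
  p <- minimal_profile()
  p <- set_entry(p, 1, "consent", "Unrestricted",
                 free_text = "line one\nline two \\ backslash=equals")
  expect_identical(profile_from_keyvalue(profile_to_keyvalue(p)), p)
  expect_identical(profile_from_json(profile_to_json(p)), p)
})

test_that("generated profiles round-trip and agree across both formats", {
  for (seed in 1:40) {
    p <- generate_profile(generator_params(seed = seed,
                                           strictness = seed %% 2 == 0))
    via_json <- profile_from_json(profile_to_json(p))
    via_kv <- profile_from_keyvalue(profile_to_keyvalue(p))
    expect_identical(via_json, p)
    expect_identical(via_kv, p)
    expect_identical(via_json, via_kv)
  }
})

test_that("file readers infer the dialect from the extension", {
  p <- disease_profile()
  dir <- withr::local_tempdir()
  fj <- file.path(dir, "p.adam.json")
  fk <- file.path(dir, "p.adam.kv")
  write_profile(p, fj)
  write_profile(p, fk)
  expect_identical(read_profile(fj), p)
  expect_identical(read_profile(fk), p)
})
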