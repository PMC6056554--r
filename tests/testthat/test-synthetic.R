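test_that("generation is fully reproducible from the seed", {
  a <- generate_profile(generator_params(seed = 42))
  b <- generate_profile(generator_params(seed = 42))
  expect_identical(profile_to_json(a), profile_to_json(b))
  expect_false(identical(profile_to_json(a),
                         profile_to_json(generate_profile(generator_params(seed = 43)))))
})

test_that("the generator does not disturb the global RNG stream", {
  set.seed(99)
  x1 <- stats::runif(3)
  set.seed(99)
  invisible(generate_profile(generator_params(seed = 1)))
  x2 <- stats::runif(3)
  expect_identical(x1, x2)
})

test_that("zero obligatory probability forces obligation-free bodies", {
  for (seed in 1:30) {
    p <- generate_profile(generator_params(seed = seed, p_obligatory = 0))
    for (b in p$bodies) expect_equal(count_obligatory(b), 0L)
  }
})

test_that("a default-parameter corpus covers all values and passes validation", {
  values_seen <- character(0)
  term_seen <- character(0)
  for (seed in 1:200) {
    p <- generate_profile(generator_params(seed = seed))
    expect_true(validate_profile(p)$valid)
    for (b in p$bodies) {
      values_seen <- union(values_seen,
                           unlist(lapply(b$permissions, `[[`, "value")))
      term_seen <- union(term_seen, unlist(lapply(b$terms, `[[`, "value")))
    }
  }
  expect_setequal(intersect(values_seen, adam_values()$permissions),
                  adam_values()$permissions)
  expect_setequal(term_seen, c("True", "Untrue"))
})

test_that("request intents honour their contract or fail loudly", {
  # nothing to violate in an all-Unrestricted profile
  expect_error(generate_request(minimal_profile(), "INCOMPATIBLE", seed = 1),
               class = "adam_intent_unsatisfiable")
  # the worked list: a compatible request must declare the obligated disease
  p <- disease_profile()
  rq <- generate_request(p, "COMPATIBLE", seed = 5)
  expect_true("b" %in% rq$declared_uses$research_disease_specific)
  expect_equal(adjudicate(p, rq)$overall, "PERMIT")
  rq2 <- generate_request(p, "INCOMPATIBLE", seed = 5)
  expect_equal(adjudicate(p, rq2)$overall, "DENY")
})

test_that("each rule mutation is flagged by that rule alone", {
  for (rule in validation_rules()$rule_id) {
    flagged <- 0L
    for (seed in 1:12) {
      p <- generate_profile(generator_params(seed = seed + 300L))
      m <- tryCatch(mutate_invalid(p, rule, seed = seed),
                    adam_mutation_inapplicable = function(e) NULL)
      if (is.null(m)) next
      found <- unique(tidy(validate_profile(m))$rule_id)
      expect_identical(found, rule)
      flagged <- flagged + 1L
    }
    expect_gt(flagged, 0L)
  }
})

test_that("mutations are inapplicable only when the profile truly blocks them", {
  expect_error(mutate_invalid(minimal_profile(), "R9"),
               class = "adam_unknown_rule")
  # a profile with a single plain permission cannot cheaply reach R4
  expect_error(mutate_invalid(minimal_profile(), "R4", seed = 1),
               class = "adam_mutation_inapplicable")
})

test_that("generator parameters are checked", {
  expect_error(generator_params(p_limited = 1.5),
               class = "adam_malformed_document")
  expect_error(generator_params(vocab = character()),
               class = "adam_malformed_document")
})
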