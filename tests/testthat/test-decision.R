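test_that("permission evaluation follows the value truth table", {
  limited <- list(value = "Limited", free_text = disease_list_text)
  expect_equal(evaluate_permission(limited, "B")$verdict, "PASS")
  expect_equal(evaluate_permission(limited, c("A", "C"))$verdict, "FAIL")
  expect_equal(evaluate_permission(limited, c("B", "C"))$verdict, "PASS")
  expect_equal(evaluate_permission(limited, "X")$verdict, "FAIL")
  expect_equal(evaluate_permission(list(value = "Unrestricted"), "anything")$verdict,
               "PASS")
  forb <- list(value = "Forbidden")
  expect_equal(evaluate_permission(forb, character())$verdict, "PASS")
  expect_equal(evaluate_permission(forb, "x")$verdict, "FAIL")
  # non-formulaic entries are REFER, never guessed
  expect_equal(evaluate_permission(list(value = "Limited"), "x")$verdict,
               "REFER")
  prose <- list(value = "Limited", free_text = "Ask the data access committee")
  expect_equal(evaluate_permission(prose, "x")$verdict, "REFER")
  # matching is normalized: trimmed and case-folded
  expect_equal(evaluate_permission(limited, " b ")$verdict, "PASS")
})

test_that("terms evaluation distinguishes discovery from access", {
  t_true <- list(value = "True")
  t_untrue <- list(value = "Untrue")
  expect_equal(evaluate_terms(t_true, character(), "Access",
                              "no_collaboration_terms")$verdict, "PASS")
  expect_equal(evaluate_terms(t_untrue, character(), "Access",
                              "no_collaboration_terms")$verdict, "FAIL")
  expect_equal(evaluate_terms(t_untrue, "no_collaboration_terms", "Access",
                              "no_collaboration_terms")$verdict, "PASS")
  expect_equal(evaluate_terms(t_untrue, character(), "Discovery",
                              "no_collaboration_terms")$verdict, "PASS")
})

test_that("the worked disease scenario adjudicates as glossed", {
  p <- disease_profile()
  permit <- adjudicate(p, adam_request("Access", list(
    research_disease_specific = "B")))
  expect_equal(permit$overall, "PERMIT")
  expect_equal(permit$selected_body, 1L)
  deny <- adjudicate(p, adam_request("Access", list(
    research_disease_specific = c("A", "C"))))
  expect_equal(deny$overall, "DENY")
})

test_that("bodies combine as alternatives and modes gate eligibility", {
  p <- disease_profile(mode = "Access")
  # a second body with laxer criteria rescues the request
  p2 <- add_body(p)
  p2 <- set_entry(p2, 2, "mode_of_sharing", "Access")
  p2 <- set_entry(p2, 2, "research_disease_specific", "Unrestricted")
  req <- adam_request("Access", list(research_disease_specific = "X"))
  expect_equal(adjudicate(p, req)$overall, "DENY")
  d2 <- adjudicate(p2, req)
  expect_equal(d2$overall, "PERMIT")
  expect_equal(d2$selected_body, 2L)
  # no mode-eligible body: nothing can permit
  expect_equal(adjudicate(p, adam_request("Discovery", list()))$overall,
               "DENY")
})

test_that("pooled obligations respect the interpretation rule", {
  base <- minimal_profile()
  base <- set_entry(base, 1, "consent", "Unrestricted[Obligatory]")
  base <- set_entry(base, 1, "research_disease_specific", "Limited",
                    free_text = disease_list_text)
  all_rule <- set_entry(base, 1, "interpretation_rule", "Meet all")
  any_rule <- set_entry(base, 1, "interpretation_rule", "Meet any")
  one_met <- adam_request("Access", list(consent = "secondary-use"))
  both_met <- adam_request("Access", list(consent = "secondary-use",
                                          research_disease_specific = "B"))
  expect_equal(adjudicate(all_rule, one_met)$overall, "DENY")
  expect_equal(adjudicate(any_rule, one_met)$overall, "PERMIT")
  expect_equal(adjudicate(all_rule, both_met)$overall, "PERMIT")
  none_met <- adam_request("Access", list())
  expect_equal(adjudicate(any_rule, none_met)$overall, "DENY")
})

test_that("non-formulaic profiles REFER instead of deciding", {
  p <- minimal_profile()
  p <- set_entry(p, 1, "data_linkage", "Limited",
                 free_text = "Linkage subject to committee approval")
  d <- adjudicate(p, adam_request("Access", list()))
  expect_equal(d$overall, "REFER")
  expect_true("REFER" %in% tidy(d)$verdict)
  # an acknowledged unspecified restriction is likewise REFER-grade
  q <- set_entry(minimal_profile(), 1, "no_other_restrictions", "Untrue")
  expect_equal(adjudicate(q, adam_request("Access", list()))$overall, "REFER")
})

test_that("adjudication refuses invalid profiles", {
  p <- minimal_profile()
  p$bodies[[1]]$meta[["mode_of_sharing"]] <- NULL
  expect_error(adjudicate(p, adam_request("Access", list())),
               class = "adam_invalid_profile")
  expect_error(adam_request("Sometimes"), class = "adam_malformed_document")
  expect_error(adam_request("Access", list(no_such = "x")),
               class = "adam_unknown_concept")
})

test_that("screening keeps PERMIT and REFER profiles only", {
  permitting <- minimal_profile()
  forbidding <- set_entry(minimal_profile(), 1, "research_use", "Forbidden")
  refer <- set_entry(minimal_profile(), 1, "data_linkage", "Limited",
                     free_text = "Subject to committee approval")
  req <- adam_request("Discovery", list(research_use = "gwas"))
  hits <- screen_profiles(list(a = permitting, b = forbidding, c = refer), req)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$profile, c("a", "c"))
  expect_setequal(hits$overall, c("PERMIT", "REFER"))
  expect_equal(nrow(screen_profiles(list(), req)), 0L)
  # access-only profiles never surface in discovery screening
  acc <- disease_profile(mode = "Access")
  expect_equal(nrow(screen_profiles(list(acc), req)), 0L)
  expect_error(screen_profiles(list(permitting),
                               adam_request("Access", list())),
               class = "adam_malformed_document")
})

test_that("adjudication agrees with the brute-force oracle on a tiny registry", {
  reg <- tiny_registry()
  vocab <- c("a", "b", "c")
  profiles <- list()
  p <- tiny_profile_base(reg)
  p <- set_entry(p, 1, "use_a", "Limited", free_text = "a, b[Obligatory]",
                 registry = reg)
  p <- set_entry(p, 1, "use_b", "Forbidden", registry = reg)
  p <- set_entry(p, 1, "no_collab", "Untrue", registry = reg)
  profiles$mixed <- p
  q <- tiny_profile_base(reg)
  q <- set_entry(q, 1, "use_a", "Unrestricted[Obligatory]", registry = reg)
  q <- set_entry(q, 1, "use_b", "Limited[Obligatory]", free_text = "a, c",
                 registry = reg)
  q <- set_entry(q, 1, "interpretation_rule", "Meet any", registry = reg)
  profiles$obligatory <- q
  r <- tiny_profile_base(reg, mode = "Discovery")
  r <- set_entry(r, 1, "use_countries", "Limited", free_text = "a",
                 registry = reg)
  r <- add_body(r)
  r <- set_entry(r, 2, "mode_of_sharing", "Access", registry = reg)
  r <- set_entry(r, 2, "use_a", "Limited",
                 free_text = "Subject to review by the committee",
                 registry = reg)
  profiles$two_body <- r
  requests <- oracle_requests(c("use_a", "use_b"), vocab, "no_collab", reg)
  for (p in profiles) {
    got <- vapply(requests, function(rq)
      adjudicate(p, rq, reg)$overall, "")
    want <- vapply(requests, function(rq) oracle_decide(p, rq, reg), "")
    expect_identical(got, want)
  }
})

test_that("relaxing a profile or request never flips PERMIT to DENY", {
  flips <- 0L
  n <- 0L
  for (seed in 1:150) {
    p <- generate_profile(generator_params(seed = seed))
    rq <- generate_request(p, "RANDOM", seed = seed + 10000L)
    before <- adjudicate(p, rq)$overall
    relaxed <- relax_pair(p, rq, seed = seed + 20000L)
    if (is.null(relaxed)) next
    n <- n + 1L
    after <- adjudicate(relaxed$profile, relaxed$request)$overall
    if (before == "PERMIT" && after == "DENY") flips <- flips + 1L
  }
  expect_gt(n, 50L)
  expect_equal(flips, 0L)
})

test_that("decisions are pure and adding a body never flips PERMIT to DENY", {
  for (seed in 1:40) {
    p <- generate_profile(generator_params(seed = seed))
    rq <- generate_request(p, "RANDOM", seed = seed + 500L)
    d1 <- adjudicate(p, rq)
    expect_identical(d1, adjudicate(p, rq))
    p2 <- add_body(p)
    p2 <- set_entry(p2, n_bodies(p2), "mode_of_sharing", "Discovery and Access")
    p2 <- set_entry(p2, n_bodies(p2), "research_use", "Forbidden")
    d2 <- adjudicate(p2, rq)
    expect_false(d1$overall == "PERMIT" && d2$overall == "DENY")
  }
})
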