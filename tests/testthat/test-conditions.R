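test_that("the worked three-disease list parses with one obligatory item", {
  items <- parse_condition_list(disease_list_text)
  expect_equal(items$label, c("A", "B", "C"))
  expect_equal(items$obligatory, c(FALSE, TRUE, FALSE))
})

test_that("plain lists, single items and casing variants parse", {
  expect_equal(parse_condition_list("A"),
               tibble::tibble(label = "A", obligatory = FALSE))
  items <- parse_condition_list("Use permitted for research on diseases A, B, and C")
  expect_equal(items$obligatory, rep(FALSE, 3))
  expect_identical(parse_condition_list(render_condition_list(items)), items)
  # suffix matching is case-insensitive
  items <- parse_condition_list("a, b[obligatory], and c")
  expect_true(items$obligatory[2])
  # canonical casing on render
  expect_match(render_condition_list(items), "b[Obligatory]", fixed = TRUE)
})

test_that("prose free text yields a no-parse signal, not an error", {
  expect_null(parse_condition_list("Results must be made public"))
  expect_null(parse_condition_list(
    "Use permitted for research on diseases A, B, and C. Use prohibited for research on diseases X, Y, and Z"))
  expect_null(parse_condition_list("As agreed, the data may be reused subject to review, per policy"))
  expect_null(parse_condition_list(""))
})

test_that("parse and render are mutual inverses on generated lists", {
  withr::with_seed(7, {
    for (i in 1:100) {
      n <- sample(1:6, 1)
      items <- tibble::tibble(
        label = paste0(sample(LETTERS, n), sample(0:9, n, replace = TRUE)),
        obligatory = stats::runif(n) < 0.4)
      text <- render_condition_list(
        items, preamble = sample(c("", "Use permitted for diseases"), 1))
      expect_identical(parse_condition_list(text), items)
    }
  })
})

test_that("rendering an empty list is an error", {
  expect_error(render_condition_list(tibble::tibble(label = character(),
                                                    obligatory = logical())),
               class = "adam_empty_list")
  expect_error(render_condition_list(tibble::tibble(label = "a b",
                                                    obligatory = FALSE)),
               class = "adam_malformed_document")
})

test_that("count_obligatory sums entry markers, list items and the recontact slot", {
  p <- minimal_profile()
  expect_equal(count_obligatory(p$bodies[[1]]), 0L)
  p1 <- set_entry(p, 1, "research_disease_specific", "Limited",
                  free_text = disease_list_text)
  expect_equal(count_obligatory(p1$bodies[[1]]), 1L)
  p2 <- set_entry(p1, 1, "consent", "Unrestricted[Obligatory]")
  expect_equal(count_obligatory(p2$bodies[[1]]), 2L)
  # additive over disjoint entries
  p3 <- set_entry(p2, 1, "data_linkage", "Limited",
                  free_text = "X[Obligatory], Y[Obligatory]")
  expect_equal(count_obligatory(p3$bodies[[1]]), 4L)
  # the "must occur" recontact slot counts once when non-empty
  p4 <- set_entry(p3, 1, "no_recontact_terms", "Untrue",
                  free_text_2 = "Recontact must occur for incidental findings")
  expect_equal(count_obligatory(p4$bodies[[1]]), 5L)
})
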