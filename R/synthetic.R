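# Seeded generator of Profiles and access requests. Every other module is
# testable against generated input with no external data: the generator only
# emits validator-passing Profiles, and request generation is
# intent-constrained (COMPATIBLE requests adjudicate to PERMIT, INCOMPATIBLE
# to DENY) with a loud failure when a Profile admits no such request. A
# single integer seed drives one reproducible stream; the global RNG state is
# left untouched.

#' Generator parameters
#'
#' @param seed Integer seed driving the whole generation stream.
#' @param n_bodies Candidate Main-Body counts to draw from.
#' @param p_limited Probability that a Permissions entry is `Limited` (versus
#'   `Unrestricted`), before any `[Obligatory]` upgrade.
#' @param p_forbidden Probability that an extended-vocabulary Permissions
#'   entry is `Forbidden`.
#' @param p_obligatory Probability of the `[Obligatory]` upgrade on an entry
#'   value, and per condition-list item, where supported.
#' @param vocab Label pool for condition lists and declared uses; defaults to
#'   the disease tokens A–F of the worked examples.
#' @param strictness If `TRUE` (default) every generated entry is formulaic
#'   (machine-evaluable); if `FALSE`, prose free text and
#'   acknowledged-unspecified restrictions may appear, producing REFER-grade
#'   Profiles.
#' @return A `generator_params` list.
#' @export
generator_params <- function(seed = 1L, n_bodies = 1:2, p_limited = 0.35,
                             p_forbidden = 0.10, p_obligatory = 0.25,
                             vocab = c("A", "B", "C", "D", "E", "F"),
                             strictness = TRUE) {
  probs <- c(p_limited = p_limited, p_forbidden = p_forbidden,
             p_obligatory = p_obligatory)
  if (any(probs < 0 | probs > 1)) {
    abort("Generator probabilities must lie in [0, 1].",
          class = "adam_malformed_document")
  }
  if (!length(vocab)) {
    abort("Generator vocab must be non-empty.",
          class = "adam_malformed_document")
  }
  structure(list(seed = as.integer(seed), n_bodies = n_bodies,
                 p_limited = p_limited, p_forbidden = p_forbidden,
                 p_obligatory = p_obligatory, vocab = as.character(vocab),
                 strictness = isTRUE(strictness)),
            class = "generator_params")
}

.sample1 <- function(x) x[[sample.int(length(x), 1L)]]

.gen_condition_text <- function(params) {
  n <- sample.int(min(4L, length(params$vocab)), 1L)
  labels <- sample(params$vocab, n)
  items <- tibble(label = labels,
                  obligatory = stats::runif(n) < params$p_obligatory)
  render_condition_list(items,
                        preamble = "Use permitted for research on diseases")
}

#' Generate a validator-passing Profile
#'
#' Draws a Profile under the study conditions encoded in
#' [generator_params()]: one Header with the three required items (plus
#' optional items at random), one or more Main Bodies each with a Mode of
#' sharing, one to four Permissions entries, up to two Terms entries, and the
#' interpretation rule whenever two or more `[Obligatory]` markers arise. The
#' same seed always yields the identical Profile, and every generated Profile
#' passes [validate_profile()].
#'
#' @param params A [generator_params()] object.
#' @param registry Registry to generate against.
#' @return An `adam_profile`.
#' @examples
#' p <- generate_profile(generator_params(seed = 42))
#' validate_profile(p)$valid
#' @export
generate_profile <- function(params = generator_params(),
                             registry = default_registry()) {
  .with_seed(params$seed, {
    header_req <- registry$concept_id[registry$section == "HEADER" &
                                        registry$requirement == "REQUIRED"]
    header_opt <- registry$concept_id[registry$section == "HEADER" &
                                        registry$requirement != "REQUIRED"]
    p <- adam_profile(bodies = list(adam_body()))
    for (id in header_req) {
      p <- set_header(p, id, sprintf("%s-%05d", id, sample.int(99999L, 1L)),
                      registry)
    }
    for (id in header_opt) {
      if (stats::runif(1) < 0.25) {
        p <- set_header(p, id, paste0("synthetic ", gsub("_", " ", id)),
                        registry)
      }
    }
    n_b <- .sample1(params$n_bodies)
    while (n_bodies(p) < n_b) p <- add_body(p)
    perm <- registry[registry$section == "PERMISSIONS", ]
    term_ids <- .section_ids(registry, "TERMS")
    recontact <- registry$concept_id[registry$section == "TERMS" &
                                       registry$free_text_slots == 2L]
    for (k in seq_len(n_b)) {
      mode <- .sample1(.mode_values)
      p <- set_entry(p, k, "mode_of_sharing", mode, registry = registry)
      ids <- sample(perm$concept_id, sample.int(min(4L, nrow(perm)), 1L))
      for (id in ids) {
        cdef <- .concept(registry, id)
        extended <- cdef$supports_forbidden_obligatory
        u <- stats::runif(1)
        value <- if (extended && u < params$p_forbidden) "Forbidden"
        else if (u < params$p_forbidden + params$p_limited) "Limited"
        else "Unrestricted"
        if (extended && value != "Forbidden" &&
            stats::runif(1) < params$p_obligatory) {
          value <- paste0(value, "[Obligatory]")
        }
        free_text <- NULL
        if (.is_limited_value(value)) {
          free_text <- if (!params$strictness && stats::runif(1) < 0.3) {
            "Use subject to conditions described in the access policy"
          } else {
            .gen_condition_text(params)
          }
        } else if (!params$strictness && stats::runif(1) < 0.15) {
          free_text <- "Resulting data must be made publicly available"
        }
        p <- set_entry(p, k, id, value, free_text = free_text,
                       registry = registry)
      }
      n_t <- sample.int(3L, 1L) - 1L
      if (n_t > 0L) {
        for (id in sample(term_ids, n_t)) {
          value <- .sample1(.term_values)
          ft <- if (value == "Untrue" && stats::runif(1) < 0.5) {
            "See the provider's governance policy for details"
          } else NULL
          ft2 <- if (value == "Untrue" && id %in% recontact &&
                     stats::runif(1) < 0.25) {
            "Recontact must occur for incidental findings"
          } else NULL
          p <- set_entry(p, k, id, value, free_text = ft, free_text_2 = ft2,
                         registry = registry)
        }
      }
      if (!params$strictness && stats::runif(1) < 0.1) {
        p <- set_entry(p, k, "no_other_restrictions", "Untrue",
                       registry = registry)
      }
      if (count_obligatory(p$bodies[[k]], registry) >= 2L) {
        p <- set_entry(p, k, "interpretation_rule", .sample1(.rule_values),
                       registry = registry)
      }
    }
    stopifnot(validate_profile(p, registry)$valid)
    p
  })
}

# Modes for which at least one body is eligible.
.covered_modes <- function(profile) {
  covered <- character(0)
  for (m in c("Discovery", "Access")) {
    if (any(map_lgl(profile$bodies, .mode_covers, mode = m))) {
      covered <- c(covered, m)
    }
  }
  covered
}

# A request designed to make body `k` pass in mode `mode`.
.compatible_candidate <- function(profile, k, mode, params) {
  b <- profile$bodies[[k]]
  declared <- list()
  for (id in names(b$permissions)) {
    e <- b$permissions[[id]]
    v <- e$value
    if (is.null(v) || v == "Forbidden") next
    items <- if (!is.null(e[["free_text"]])) parse_condition_list(e[["free_text"]])
    if (.is_limited_value(v)) {
      if (is.null(items)) return(NULL)  # REFER-grade entry: cannot PERMIT
      labs <- items$label[items$obligatory]
      if (v == "Limited[Obligatory]" && !length(labs)) {
        labs <- items$label[[1]]
      }
      if (length(labs)) declared[[id]] <- labs
    } else {
      if (!is.null(e[["free_text"]])) return(NULL)  # prose on Unrestricted: REFER
      if (v == "Unrestricted[Obligatory]") {
        declared[[id]] <- .sample1(params$vocab)
      } else if (stats::runif(1) < 0.5) {
        declared[[id]] <- .sample1(params$vocab)
      }
    }
  }
  no_other <- b$meta[["no_other_restrictions"]]
  if (!is.null(no_other$value) && no_other$value == "Untrue") return(NULL)
  accepted <- names(keep(b$terms, function(e) identical(e$value, "Untrue")))
  list(mode = mode, declared_uses = declared, accepted_terms = accepted)
}

# Candidate requests designed to make every eligible body fail.
.incompatible_candidates <- function(profile, mode, params) {
  poison <- "zz-undeclared-use"
  eligible <- which(map_lgl(profile$bodies, .mode_covers, mode = mode))
  cands <- list(list(mode = mode, declared_uses = list(),
                     accepted_terms = character()))
  poison_ids <- character(0)
  for (k in eligible) {
    b <- profile$bodies[[k]]
    for (id in names(b$permissions)) {
      v <- b$permissions[[id]]$value
      if (is.null(v)) next
      if (v == "Forbidden" || .is_limited_value(v)) {
        poison_ids <- union(poison_ids, id)
      }
    }
  }
  if (length(poison_ids)) {
    declared <- stats::setNames(as.list(rep(poison, length(poison_ids))),
                                poison_ids)
    cands[[length(cands) + 1L]] <-
      list(mode = mode, declared_uses = declared,
           accepted_terms = character())
    # single-concept variants, in case the full poison set trips a REFER
    for (id in poison_ids) {
      cands[[length(cands) + 1L]] <-
        list(mode = mode, declared_uses = stats::setNames(list(poison), id),
             accepted_terms = character())
    }
  }
  cands
}

#' Generate an access request with a stated intent
#'
#' Builds a request whose adjudication against `profile` is known:
#' `"COMPATIBLE"` requests PERMIT, `"INCOMPATIBLE"` requests DENY, and
#' `"RANDOM"` requests are unconstrained draws. When the Profile admits no
#' request of the requested intent (an all-`Unrestricted` Profile cannot be
#' denied; a Profile whose every body is REFER-grade cannot be cleanly
#' permitted) an error of class `adam_intent_unsatisfiable` is raised.
#'
#' @param profile A validator-passing `adam_profile`.
#' @param intent `"COMPATIBLE"`, `"INCOMPATIBLE"` or `"RANDOM"`.
#' @param seed Integer seed.
#' @param params [generator_params()] supplying the label vocabulary.
#' @param registry Registry the Profile is interpreted against.
#' @return An [adam_request()].
#' @export
generate_request <- function(profile, intent = c("COMPATIBLE", "INCOMPATIBLE",
                                                 "RANDOM"),
                             seed = 1L, params = generator_params(seed),
                             registry = default_registry()) {
  intent <- match.arg(intent)
  .with_seed(seed, {
    modes <- .covered_modes(profile)
    if (intent == "RANDOM") {
      mode <- .sample1(c("Discovery", "Access"))
      perm_ids <- .section_ids(registry, "PERMISSIONS")
      n <- sample.int(4L, 1L) - 1L
      declared <- list()
      for (id in if (n) sample(perm_ids, n) else character()) {
        declared[[id]] <- sample(params$vocab,
                                 sample.int(min(3L, length(params$vocab)), 1L))
      }
      term_ids <- .section_ids(registry, "TERMS")
      accepted <- term_ids[stats::runif(length(term_ids)) < 0.3]
      return(adam_request(mode, declared, accepted, registry))
    }
    if (intent == "COMPATIBLE") {
      for (k in sample(seq_along(profile$bodies))) {
        both <- c("Access", "Discovery")
        body_modes <- both[map_lgl(both, function(m)
          .mode_covers(profile$bodies[[k]], m))]
        for (mode in body_modes) {
          cand <- .compatible_candidate(profile, k, mode, params)
          if (is.null(cand)) next
          req <- adam_request(cand$mode, cand$declared_uses,
                              cand$accepted_terms, registry)
          if (adjudicate(profile, req, registry)$overall == "PERMIT") {
            return(req)
          }
        }
      }
      abort("Profile admits no COMPATIBLE (PERMIT) request.",
            class = "adam_intent_unsatisfiable")
    }
    # INCOMPATIBLE: a mode no body covers is denied outright; otherwise
    # search the candidate violations
    for (mode in c("Access", "Discovery")) {
      if (!mode %in% modes) {
        return(adam_request(mode, list(), character(), registry))
      }
    }
    for (mode in sample(c("Access", "Discovery"))) {
      for (cand in .incompatible_candidates(profile, mode, params)) {
        req <- adam_request(cand$mode, cand$declared_uses,
                            cand$accepted_terms, registry)
        if (adjudicate(profile, req, registry)$overall == "DENY") return(req)
      }
    }
    abort("Profile admits no INCOMPATIBLE (DENY) request.",
          class = "adam_intent_unsatisfiable")
  })
}

#' Minimally mutate a valid Profile to violate one validation rule
#'
#' Produces a Profile whose [validate_profile()] report flags exactly the
#' requested rule: e.g. `R3` removes a Mode of sharing, `R6` adds free text
#' under a concept with no main value. When the Profile offers no cheap way
#' to violate the rule (e.g. `R4` on a Profile that cannot reach two
#' obligations) an error of class `adam_mutation_inapplicable` is raised.
#'
#' @param profile A validator-passing `adam_profile`.
#' @param rule_id One of `"R1"` to `"R7"`.
#' @param seed Integer seed for the random choices within the mutation.
#' @param registry Registry the Profile is interpreted against.
#' @return The mutated `adam_profile`.
#' @export
mutate_invalid <- function(profile, rule_id, seed = 1L,
                           registry = default_registry()) {
  if (!rule_id %in% names(.rule_summaries)) {
    abort(paste0("Unknown validation rule `", rule_id, "`."),
          class = "adam_unknown_rule")
  }
  inapplicable <- function(msg) abort(msg,
                                      class = "adam_mutation_inapplicable")
  .with_seed(seed, {
    switch(rule_id,
      R1 = {
        req <- registry$concept_id[registry$section == "HEADER" &
                                     registry$requirement == "REQUIRED"]
        present <- intersect(req, names(profile$header))
        if (!length(present)) inapplicable("No required header value to blank.")
        profile$header[[.sample1(present)]] <- ""
        profile
      },
      R2 = {
        k <- .sample1(seq_along(profile$bodies))
        profile$bodies[[k]]$permissions <- list()
        profile$bodies[[k]]$terms <- list()
        profile
      },
      R3 = {
        k <- .sample1(seq_along(profile$bodies))
        profile$bodies[[k]]$meta[["mode_of_sharing"]] <- NULL
        profile
      },
      R4 = {
        counts <- map_int(profile$bodies, count_obligatory,
                          registry = registry)
        k <- which(counts >= 2L)[1]
        if (!is.na(k)) {
          profile$bodies[[k]]$meta[["interpretation_rule"]] <- NULL
          return(profile)
        }
        # upgrade list items of an existing Limited entry to reach two
        for (k in seq_along(profile$bodies)) {
          b <- profile$bodies[[k]]
          for (id in names(b$permissions)) {
            e <- b$permissions[[id]]
            if (is.null(e[["free_text"]])) next
            items <- parse_condition_list(e[["free_text"]])
            if (is.null(items)) next
            need <- 2L - counts[[k]]
            if (nrow(items) - sum(items$obligatory) >= need) {
              idx <- which(!items$obligatory)[seq_len(need)]
              items$obligatory[idx] <- TRUE
              profile$bodies[[k]]$permissions[[id]]$free_text <-
                render_condition_list(
                  items, preamble = "Use permitted for research on diseases")
              profile$bodies[[k]]$meta[["interpretation_rule"]] <- NULL
              return(profile)
            }
          }
        }
        inapplicable("Profile cannot cheaply reach two [Obligatory] markers.")
      },
      R5 = {
        restricted <- registry$concept_id[
          registry$section == "PERMISSIONS" &
            !registry$supports_forbidden_obligatory]
        if (!length(restricted)) inapplicable("Registry has no restricted concept.")
        id <- .sample1(restricted)
        k <- .sample1(seq_along(profile$bodies))
        e <- profile$bodies[[k]]$permissions[[id]] %||% list()
        e$value <- "Forbidden"
        profile$bodies[[k]]$permissions[[id]] <-
          .new_entry(e$value, e[["free_text"]], NULL)
        .canonicalize(profile, registry)
      },
      R6 = {
        k <- .sample1(seq_along(profile$bodies))
        unused <- setdiff(.section_ids(registry, "PERMISSIONS"),
                          names(profile$bodies[[k]]$permissions))
        if (!length(unused)) inapplicable("Every Permissions concept is set.")
        id <- .sample1(unused)
        profile$bodies[[k]]$permissions[[id]] <-
          .new_entry(free_text = "Additional details pending review")
        .canonicalize(profile, registry)
      },
      R7 = {
        restricted <- registry$concept_id[
          registry$section == "PERMISSIONS" &
            !registry$supports_forbidden_obligatory]
        hits <- list()
        for (k in seq_along(profile$bodies)) {
          b <- profile$bodies[[k]]
          for (slot in unname(.body_sections)) {
            for (id in names(b[[slot]])) {
              if (id %in% restricted) next  # that would be R5's finding
              if (!is.null(b[[slot]][[id]]$value)) {
                hits[[length(hits) + 1L]] <- list(k = k, slot = slot, id = id)
              }
            }
          }
        }
        if (!length(hits)) inapplicable("No entry with a main value to corrupt.")
        h <- .sample1(hits)
        profile$bodies[[h$k]][[h$slot]][[h$id]]$value <- "Sometimes"
        profile
      })
  })
}
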