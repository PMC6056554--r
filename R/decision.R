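# Formulaic adjudication of discovery/access requests against Profiles.
#
# The engine only decides what can be decided mechanically: straightforward
# Permissions and Terms values, parseable [Obligatory] condition lists, and
# the body-level interpretation rule over pooled obligations. Anything
# non-formulaic — prose free text (possible conditionalities), a Limited
# value with no machine-readable list, an acknowledged unspecified
# restriction — yields REFER, routing the request to a human (the DAC).
# Multiple Main Bodies are alternative sets of criteria: any body that
# cleanly permits is enough to PERMIT.

#' Construct an access request
#'
#' A requester's declaration: the mode of the interaction (discovery of a
#' resource versus actually seeking access), the uses they assert per
#' Permissions concept (e.g. diseases studied, requester category, country),
#' and the Terms concepts whose conditions they agree to comply with. Labels
#' are normalized (trimmed, case-folded) for matching.
#'
#' @param mode `"Discovery"` or `"Access"` (case-insensitive).
#' @param declared_uses Named list: Permissions concept id to character vector
#'   of asserted use labels.
#' @param accepted_terms Character vector of Terms concept ids.
#' @param registry Registry to check concept ids against.
#' @return An `adam_request`.
#' @examples
#' adam_request("Access",
#'              declared_uses = list(research_disease_specific = "B"),
#'              accepted_terms = "no_collaboration_terms")
#' @export
adam_request <- function(mode, declared_uses = list(),
                         accepted_terms = character(),
                         registry = default_registry()) {
  m <- c(discovery = "Discovery", access = "Access")[tolower(mode)]
  if (is.na(m)) {
    abort(paste0("Request mode must be Discovery or Access, got `", mode, "`."),
          class = "adam_malformed_document")
  }
  declared_uses <- as.list(declared_uses)
  for (id in names(declared_uses)) {
    cdef <- .concept(registry, id)
    if (is.null(cdef) || cdef$section != "PERMISSIONS") {
      abort(paste0("Unknown PERMISSIONS concept `", id, "` in declared_uses."),
            class = "adam_unknown_concept")
    }
    declared_uses[[id]] <- unique(.normalize_label(declared_uses[[id]]))
  }
  accepted_terms <- as.character(accepted_terms)
  for (id in accepted_terms) {
    cdef <- .concept(registry, id)
    if (is.null(cdef) || cdef$section != "TERMS") {
      abort(paste0("Unknown TERMS concept `", id, "` in accepted_terms."),
            class = "adam_unknown_concept")
    }
  }
  structure(list(mode = unname(m), declared_uses = declared_uses,
                 accepted_terms = sort(unique(accepted_terms))),
            class = "adam_request")
}

#' @export
print.adam_request <- function(x, ...) {
  cat("<adam_request> mode:", x$mode, "|", length(x$declared_uses),
      "declared use concept(s),", length(x$accepted_terms),
      "accepted term(s)\n")
  invisible(x)
}

.verdict_row <- function(concept_id, verdict, rationale) {
  tibble(concept_id = concept_id, verdict = verdict, rationale = rationale)
}

# Core permission evaluation without obligation resolution. Returns the base
# verdict plus this entry's obligations (to be pooled at body level).
.eval_permission <- function(entry, requested, concept_id) {
  requested <- unique(.normalize_label(requested))
  value <- entry$value
  obligations <- tibble(concept_id = character(), kind = character(),
                        label = character(), satisfied = logical())
  prose <- FALSE
  items <- NULL
  if (!is.null(entry[["free_text"]]) && nzchar(trimws(entry[["free_text"]]))) {
    items <- parse_condition_list(entry[["free_text"]])
    prose <- is.null(items)
  }
  if (is.null(value)) {
    return(list(verdict = "REFER", obligations = obligations,
                rationale = "Entry has no main value."))
  }
  if (value == "Forbidden") {
    if (length(requested)) {
      return(list(verdict = "FAIL", obligations = obligations,
                  rationale = "Use is Forbidden but the request declares it."))
    }
    return(list(verdict = "PASS", obligations = obligations,
                rationale = "Forbidden use not requested."))
  }
  limited <- .is_limited_value(value)
  if (limited && is.null(entry[["free_text"]])) {
    return(list(verdict = "REFER", obligations = obligations,
                rationale = paste("Limited without a machine-readable list of",
                                  "permitted items.")))
  }
  if (prose && limited) {
    # possible conditionality; a human must read it before any verdict
    return(list(verdict = "REFER", obligations = obligations,
                rationale = "Free text is prose, not a condition list."))
  }
  verdict <- "PASS"
  rationale <- "Unrestricted."
  if (limited) {
    permitted <- .normalize_label(items$label)
    outside <- setdiff(requested, permitted)
    if (length(outside)) {
      verdict <- "FAIL"
      rationale <- paste0("Requested use(s) outside the permitted list: ",
                          paste(outside, collapse = ", "), ".")
    } else {
      rationale <- "Requested uses fall within the permitted list."
    }
    obl_items <- items[items$obligatory, , drop = FALSE]
    if (nrow(obl_items)) {
      obligations <- bind_rows(obligations, tibble(
        concept_id = concept_id, kind = "item",
        label = .normalize_label(obl_items$label),
        satisfied = .normalize_label(obl_items$label) %in% requested))
    }
  }
  if (.is_obligatory_value(value)) {
    satisfied <- length(requested) > 0L && verdict != "FAIL"
    obligations <- bind_rows(obligations, tibble(
      concept_id = concept_id, kind = "entry", label = NA_character_,
      satisfied = satisfied))
  }
  if (verdict == "PASS" && !limited && prose) {
    verdict <- "REFER"
    rationale <- "Free text is prose (possible conditionality)."
  }
  list(verdict = verdict, obligations = obligations, rationale = rationale)
}

# Apply the interpretation rule to a pool of obligations.
.obligations_met <- function(obligations, rule) {
  if (nrow(obligations) == 0L) return(TRUE)
  if (identical(rule, "Meet any")) any(obligations$satisfied)
  else all(obligations$satisfied)
}

#' Evaluate one Permission entry against requested uses
#'
#' Formulaic semantics: `Unrestricted` passes; `Forbidden` fails exactly when
#' the request declares a use under the concept; `Limited` passes when every
#' requested use falls within the permitted condition list, and is REFER when
#' the entry has no parseable list (prose or missing free text). Obligations
#' — an `[Obligatory]` main value or `[Obligatory]` list items — must be met
#' under the supplied interpretation rule (`"Meet all"` requires every
#' obligation of this entry, `"Meet any"` at least one).
#'
#' @param entry An entry list with `value` and optional `free_text` (as
#'   stored in an [adam_body()]), e.g.
#'   `list(value = "Limited", free_text = "A, B[Obligatory], and C")`.
#' @param requested Character vector of use labels the requester declares for
#'   this concept.
#' @param rule Interpretation rule context, `"Meet all"` (default) or
#'   `"Meet any"`.
#' @param concept_id Concept id used in the verdict row.
#' @return A one-row tibble: `concept_id`, `verdict` (`PASS`/`FAIL`/`REFER`),
#'   `rationale`.
#' @examples
#' entry <- list(value = "Limited",
#'               free_text = "Use permitted for research on diseases A, B[Obligatory], and C")
#' evaluate_permission(entry, "B")        # PASS
#' evaluate_permission(entry, c("A", "C"))  # FAIL: obligation unmet
#' @export
evaluate_permission <- function(entry, requested = character(),
                                rule = "Meet all",
                                concept_id = "permission") {
  res <- .eval_permission(entry, requested, concept_id)
  verdict <- res$verdict
  rationale <- res$rationale
  if (verdict == "PASS" && !.obligations_met(res$obligations, rule)) {
    verdict <- "FAIL"
    rationale <- "Obligatory use not declared by the request."
  }
  .verdict_row(concept_id, verdict, rationale)
}

#' Evaluate one Terms entry against accepted terms
#'
#' Terms are negated statements ("There are no requirements regarding ...").
#' `True` means no condition applies, so it always passes. `Untrue` means a
#' condition applies: when actually seeking access the requester must have
#' accepted the concept, otherwise the entry fails; in a discovery context
#' the condition is merely useful to know about, so it passes with an
#' informational rationale.
#'
#' @param entry An entry list with `value` (`"True"`/`"Untrue"`).
#' @param accepted Character vector of Terms concept ids the requester agrees
#'   to comply with.
#' @param mode `"Discovery"` or `"Access"`.
#' @param concept_id Concept id used in the verdict row.
#' @return A one-row verdict tibble as in [evaluate_permission()].
#' @export
evaluate_terms <- function(entry, accepted = character(), mode = "Access",
                           concept_id = "term") {
  value <- entry$value
  if (is.null(value)) {
    return(.verdict_row(concept_id, "REFER", "Entry has no main value."))
  }
  if (value == "True") {
    return(.verdict_row(concept_id, "PASS", "No condition applies."))
  }
  if (identical(mode, "Discovery")) {
    return(.verdict_row(concept_id, "PASS",
                        paste("A condition applies; useful to know about in",
                              "a discovery context.")))
  }
  if (concept_id %in% accepted) {
    .verdict_row(concept_id, "PASS",
                 "Condition applies and the requester accepts it.")
  } else {
    .verdict_row(concept_id, "FAIL",
                 "Condition applies and the requester has not accepted it.")
  }
}

# Does a body's Mode of sharing cover the request mode?
.mode_covers <- function(body, mode) {
  e <- body$meta[["mode_of_sharing"]]
  v <- e$value
  if (is.null(v)) return(FALSE)
  v == "Discovery and Access" || v == mode
}

.eval_body <- function(body, request, registry) {
  verdicts <- list()
  pool <- list()
  for (id in names(body$permissions)) {
    res <- .eval_permission(body$permissions[[id]],
                            request$declared_uses[[id]] %||% character(), id)
    verdicts[[length(verdicts) + 1L]] <-
      mutate(.verdict_row(id, res$verdict, res$rationale),
             section = "permissions", .before = 1)
    pool[[length(pool) + 1L]] <- res$obligations
  }
  for (id in names(body$terms)) {
    row <- evaluate_terms(body$terms[[id]], request$accepted_terms,
                          request$mode, id)
    verdicts[[length(verdicts) + 1L]] <- mutate(row, section = "terms",
                                                .before = 1)
  }
  for (id in names(body$meta)) {
    e <- body$meta[[id]]
    if (is.null(e$value)) next
    row <- if (id == "no_other_restrictions" && e$value == "Untrue") {
      .verdict_row(id, "REFER",
                   "Other unspecified restrictions are in force.")
    } else {
      .verdict_row(id, "PASS", "Meta-condition noted.")
    }
    verdicts[[length(verdicts) + 1L]] <- mutate(row, section = "meta",
                                                .before = 1)
  }
  vt <- bind_rows(verdicts)
  obligations <- bind_rows(c(list(tibble(concept_id = character(),
                                         kind = character(),
                                         label = character(),
                                         satisfied = logical())), pool))
  rule <- body$meta[["interpretation_rule"]]$value %||% "Meet all"
  if (!.obligations_met(obligations, rule)) {
    unmet <- unique(obligations$concept_id[!obligations$satisfied])
    for (id in unmet) {
      i <- which(vt$section == "permissions" & vt$concept_id == id)
      vt$verdict[i] <- "FAIL"
      vt$rationale[i] <- paste0("Obligatory use not declared by the request (",
                                rule, ").")
    }
  }
  vt
}

.body_outcome <- function(verdicts) {
  if (any(verdicts$verdict == "FAIL")) "FAIL"
  else if (any(verdicts$verdict == "REFER")) "REFER"
  else "PASS"
}

#' Adjudicate an access request against a Profile
#'
#' Selects the Main Bodies whose Mode of sharing covers the request mode,
#' evaluates every entry of each ([evaluate_permission()],
#' [evaluate_terms()]), applies each body's interpretation rule to its pooled
#' obligations, and combines bodies as alternative criteria sets: PERMIT when
#' some eligible body passes every check, DENY when every eligible body fails
#' at least one check (including the case of no eligible body), REFER
#' otherwise — i.e. when no body cleanly permits or denies and a human must
#' look.
#'
#' @param profile An `adam_profile`; must pass [validate_profile()], else an
#'   error of class `adam_invalid_profile` is raised.
#' @param request An [adam_request()].
#' @param registry Registry the Profile is interpreted against.
#' @return An `adam_decision`: list with `overall`
#'   (`"PERMIT"`/`"DENY"`/`"REFER"`), `selected_body` (1-based index of the
#'   first permitting body, or `NA`), `eligible` (indices of mode-eligible
#'   bodies) and `verdicts` (tibble: `body`, `section`, `concept_id`,
#'   `verdict`, `rationale`). Use [tidy()]/[glance()] to extract tables.
#' @export
adjudicate <- function(profile, request, registry = default_registry()) {
  report <- validate_profile(profile, registry)
  if (!report$valid) {
    abort(paste0("Profile fails validation (",
                 paste(unique(report$findings$rule_id), collapse = ", "),
                 "); adjudication requires a valid Profile."),
          class = "adam_invalid_profile", report = report)
  }
  if (!inherits(request, "adam_request")) {
    abort("`request` must be an adam_request.",
          class = "adam_malformed_document")
  }
  eligible <- which(map_lgl(profile$bodies, .mode_covers, mode = request$mode))
  verdicts <- list()
  outcomes <- character(0)
  for (k in eligible) {
    vt <- .eval_body(profile$bodies[[k]], request, registry)
    verdicts[[length(verdicts) + 1L]] <- mutate(vt, body = k, .before = 1)
    outcomes[[as.character(k)]] <- .body_outcome(vt)
  }
  overall <- if (any(outcomes == "PASS")) "PERMIT"
  else if (length(outcomes) == 0L || all(outcomes == "FAIL")) "DENY"
  else "REFER"
  selected <- if (overall == "PERMIT") {
    eligible[which(outcomes == "PASS")[1]]
  } else NA_integer_
  vt <- if (length(verdicts)) bind_rows(verdicts) else
    tibble(body = integer(), section = character(), concept_id = character(),
           verdict = character(), rationale = character())
  structure(list(overall = overall, selected_body = selected,
                 eligible = eligible, mode = request$mode, verdicts = vt),
            class = "adam_decision")
}

#' @export
print.adam_decision <- function(x, ...) {
  cat("<adam_decision>", x$overall,
      if (!is.na(x$selected_body)) paste0("(via body ", x$selected_body, ")")
      else "",
      "| mode:", x$mode, "|", length(x$eligible), "eligible body/bodies\n")
  invisible(x)
}

#' @rdname adjudicate
#' @param x An `adam_decision`.
#' @param ... Unused.
#' @export
tidy.adam_decision <- function(x, ...) x$verdicts

#' @rdname adjudicate
#' @export
glance.adam_decision <- function(x, ...) {
  tibble(overall = x$overall, mode = x$mode,
         n_eligible = length(x$eligible), selected_body = x$selected_body)
}

#' Screen a collection of Profiles with a discovery request
#'
#' Prescreening for resource discovery: adjudicates the request against every
#' Profile and keeps only those whose decision is PERMIT or REFER — filtering
#' out resources a requester could never be granted, before any human is
#' involved.
#'
#' @param profiles A (preferably named) list of `adam_profile` objects.
#' @param request An [adam_request()] with mode `"Discovery"`.
#' @param registry Registry the Profiles are interpreted against.
#' @return A tibble with columns `profile` (name or index), `overall`, and
#'   `decision` (list column of `adam_decision` objects), one row per
#'   retained Profile.
#' @export
screen_profiles <- function(profiles, request, registry = default_registry()) {
  if (!identical(request$mode, "Discovery")) {
    abort("screen_profiles() requires a Discovery-mode request.",
          class = "adam_malformed_document")
  }
  ids <- names(profiles) %||% as.character(seq_along(profiles))
  ids[!nzchar(ids)] <- as.character(which(!nzchar(ids)))
  rows <- list()
  for (i in seq_along(profiles)) {
    d <- adjudicate(profiles[[i]], request, registry)
    if (d$overall %in% c("PERMIT", "REFER")) {
      rows[[length(rows) + 1L]] <-
        tibble(profile = ids[[i]], overall = d$overall, decision = list(d))
    }
  }
  if (!length(rows)) {
    return(tibble(profile = character(), overall = character(),
                  decision = list()))
  }
  bind_rows(rows)
}

# ---- request document dialect ----------------------------------------------

#' Serialize an access request to JSON
#'
#' @param request An [adam_request()].
#' @return A JSON string with fields `mode`, `declaredUses`, `acceptedTerms`.
#' @export
request_to_json <- function(request) {
  doc <- list(mode = request$mode,
              declaredUses = map(request$declared_uses, as.list),
              acceptedTerms = as.list(request$accepted_terms))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE))
}

#' Parse an access request from JSON
#'
#' @param text JSON text as produced by [request_to_json()].
#' @param registry Registry to check concept ids against.
#' @return An `adam_request`.
#' @export
request_from_json <- function(text, registry = default_registry()) {
  doc <- tryCatch(jsonlite::parse_json(text, simplifyVector = FALSE),
                  error = function(e)
                    .stop_malformed(paste0("invalid JSON: ",
                                           conditionMessage(e)), "$"))
  if (!is.list(doc) || is.null(doc$mode)) {
    .stop_malformed("request document needs a `mode`", "$.mode")
  }
  adam_request(doc$mode,
               declared_uses = map(doc$declaredUses %||% list(),
                                   function(x) as.character(unlist(x))),
               accepted_terms = as.character(unlist(doc$acceptedTerms %||%
                                                      list())),
               registry = registry)
}

#' Read an access request document from a file
#' @param path Path to a `.req.json` document.
#' @inheritParams request_from_json
#' @return An `adam_request`.
#' @export
read_request <- function(path, registry = default_registry()) {
  request_from_json(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                          collapse = "\n"), registry)
}
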