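# The seven-rule Profile validator. Rules are table-driven: each rule has an
# id, a one-line summary, and a check function returning a findings tibble,
# so an adopter can swap wording without touching the evaluation machinery.
# All rules are always evaluated (no short-circuit) and every violation is
# reported with a location path.

.finding <- function(rule_id, location, message) {
  tibble(rule_id = rule_id, location = location, message = message)
}

.no_findings <- tibble(rule_id = character(), location = character(),
                       message = character())

.rule_summaries <- c(
  R1 = "All required Header items are present with non-empty values.",
  R2 = paste("Each Main Body asserts at least one condition of use: one",
             "Permissions or Terms concept must carry a main value."),
  R3 = paste("Each Main Body sets Mode of sharing, the single required",
             "Main-Body concept."),
  R4 = paste("When two or more entries across the Permissions and Terms",
             "sections of a body are marked [Obligatory], the interpretation",
             "rule for multiple obligatory permissions must be filled in."),
  R5 = paste("Use-within-countries/locations, use-by-organizations and",
             "use-by-categories-of-person can only be Unrestricted or",
             "Limited: such use must unavoidably occur in some manner, so it",
             "cannot logically be Forbidden or made Obligatory."),
  R6 = paste("A completed free-text field is anomalous under a concept for",
             "which no main value has been entered."),
  R7 = "Every entered value must belong to its concept's list of permitted values."
)

#' The validator's rule table
#'
#' @return A tibble with columns `rule_id` (`"R1"` to `"R7"`) and `summary`.
#' @export
validation_rules <- function() {
  tibble(rule_id = names(.rule_summaries), summary = unname(.rule_summaries))
}

#' Explain a validation rule
#'
#' @param rule_id One of `"R1"` to `"R7"`.
#' @return The rule's human-readable summary text.
#' @export
explain_rule <- function(rule_id) {
  if (length(rule_id) != 1L || !rule_id %in% names(.rule_summaries)) {
    abort(paste0("Unknown validation rule `", paste(rule_id, collapse = ","),
                 "`; rules are R1..R7."),
          class = "adam_unknown_rule")
  }
  unname(.rule_summaries[[rule_id]])
}

.loc_entry <- function(k, slot, id) paste0("body[", k - 1L, "].", slot, ".", id)

# Each check takes (profile, registry) and returns a findings tibble.
.rule_checks <- list(
  R1 = function(profile, registry) {
    req <- registry$concept_id[registry$section == "HEADER" &
                                 registry$requirement == "REQUIRED"]
    out <- list()
    for (id in req) {
      v <- profile$header[[id]]
      if (is.null(v) || !nzchar(trimws(v))) {
        out[[length(out) + 1L]] <- .finding(
          "R1", paste0("header.", id),
          paste0("Required Header item `", id, "` is missing or empty."))
      }
    }
    bind_rows(c(list(.no_findings), out))
  },
  R2 = function(profile, registry) {
    out <- list()
    for (k in seq_along(profile$bodies)) {
      b <- profile$bodies[[k]]
      has_main <- any(map_lgl(c(b$permissions, b$terms),
                              function(e) !is.null(e$value)))
      if (!has_main) {
        out[[length(out) + 1L]] <- .finding(
          "R2", paste0("body[", k - 1L, "]"),
          "Body asserts no condition of use: no Permissions or Terms main value.")
      }
    }
    bind_rows(c(list(.no_findings), out))
  },
  R3 = function(profile, registry) {
    req <- registry$concept_id[registry$section != "HEADER" &
                                 registry$requirement == "REQUIRED"]
    out <- list()
    for (k in seq_along(profile$bodies)) {
      b <- profile$bodies[[k]]
      for (id in req) {
        slot <- .body_sections[[registry$section[registry$concept_id == id]]]
        e <- b[[slot]][[id]]
        if (is.null(e) || is.null(e$value)) {
          out[[length(out) + 1L]] <- .finding(
            "R3", .loc_entry(k, slot, id),
            paste0("Required concept `", id, "` is not set in this body."))
        }
      }
    }
    bind_rows(c(list(.no_findings), out))
  },
  R4 = function(profile, registry) {
    cond <- registry$concept_id[registry$section != "HEADER" &
                                  registry$requirement == "CONDITIONAL"]
    if (!length(cond)) return(.no_findings)
    out <- list()
    for (k in seq_along(profile$bodies)) {
      b <- profile$bodies[[k]]
      n_obl <- count_obligatory(b, registry)
      for (id in cond) {
        slot <- .body_sections[[registry$section[registry$concept_id == id]]]
        e <- b[[slot]][[id]]
        if (n_obl >= 2L && (is.null(e) || is.null(e$value))) {
          out[[length(out) + 1L]] <- .finding(
            "R4", .loc_entry(k, slot, id),
            paste0("Body carries ", n_obl, " [Obligatory] markers but the ",
                   "interpretation rule is not filled in."))
        }
      }
    }
    bind_rows(c(list(.no_findings), out))
  },
  R5 = function(profile, registry) {
    restricted <- registry$concept_id[registry$section == "PERMISSIONS" &
                                        !registry$supports_forbidden_obligatory]
    out <- list()
    for (k in seq_along(profile$bodies)) {
      perms <- profile$bodies[[k]]$permissions
      for (id in intersect(names(perms), restricted)) {
        v <- perms[[id]]$value
        if (!is.null(v) && !v %in% c("Unrestricted", "Limited")) {
          out[[length(out) + 1L]] <- .finding(
            "R5", .loc_entry(k, "permissions", id),
            paste0("`", id, "` cannot be `", v,
                   "`: this use must unavoidably occur in some manner."))
        }
      }
    }
    bind_rows(c(list(.no_findings), out))
  },
  R6 = function(profile, registry) {
    out <- list()
    for (k in seq_along(profile$bodies)) {
      b <- profile$bodies[[k]]
      for (slot in unname(.body_sections)) {
        for (id in names(b[[slot]])) {
          e <- b[[slot]][[id]]
          has_text <- (!is.null(e[["free_text"]]) && nzchar(trimws(e[["free_text"]]))) ||
            (!is.null(e[["free_text_2"]]) && nzchar(trimws(e[["free_text_2"]])))
          if (is.null(e$value) && has_text) {
            out[[length(out) + 1L]] <- .finding(
              "R6", .loc_entry(k, slot, id),
              paste0("Free text present under `", id,
                     "` but no main value has been entered."))
          }
        }
      }
    }
    bind_rows(c(list(.no_findings), out))
  },
  R7 = function(profile, registry) {
    # membership in the concept type's vocabulary; the restricted trio's
    # narrower domain is rule R5's business
    out <- list()
    for (k in seq_along(profile$bodies)) {
      b <- profile$bodies[[k]]
      for (sec in names(.body_sections)) {
        slot <- .body_sections[[sec]]
        for (id in names(b[[slot]])) {
          v <- b[[slot]][[id]]$value
          if (is.null(v)) next
          vocab <- switch(sec,
                          PERMISSIONS = .perm_values,
                          TERMS = .term_values,
                          META = {
                            cdef <- .concept(registry, id)
                            if (is.null(cdef)) character() else
                              cdef$value_domain[[1]]
                          })
          if (!v %in% vocab) {
            out[[length(out) + 1L]] <- .finding(
              "R7", .loc_entry(k, slot, id),
              paste0("Value `", v, "` is not a permitted value for `",
                     id, "`."))
          }
        }
      }
    }
    bind_rows(c(list(.no_findings), out))
  }
)

#' Validate a Profile against the seven completion rules
#'
#' Evaluates every rule (R1–R7, see [validation_rules()]) and reports every
#' violation; a Profile is valid exactly when no finding is produced. The
#' check is pure: the same Profile and registry always give the same report.
#'
#' @param profile An `adam_profile`.
#' @param registry The registry the Profile is interpreted against.
#' @return An `adam_validation` object: a list with `valid` (logical) and
#'   `findings` (tibble of `rule_id`, `location`, `message`). Use [tidy()] to
#'   extract the findings tibble.
#' @examples
#' p <- adam_profile(header = list(profile_id = "P-1",
#'                                 profile_version = "2026-01-01",
#'                                 resource_reference = "doi:10.0000/x"))
#' p <- set_entry(p, 1, "mode_of_sharing", "Discovery")
#' p <- set_entry(p, 1, "research_use", "Unrestricted")
#' validate_profile(p)$valid
#' @export
validate_profile <- function(profile, registry = default_registry()) {
  findings <- bind_rows(map(.rule_checks,
                            function(chk) chk(profile, registry)))
  structure(list(valid = nrow(findings) == 0L, findings = findings),
            class = "adam_validation")
}

#' @export
print.adam_validation <- function(x, ...) {
  if (x$valid) {
    cat("<adam_validation> valid (no findings)\n")
  } else {
    cat("<adam_validation>", nrow(x$findings), "finding(s):\n")
    print(x$findings, ...)
  }
  invisible(x)
}

#' @rdname validate_profile
#' @param x An `adam_validation` object.
#' @param ... Unused.
#' @export
tidy.adam_validation <- function(x, ...) x$findings

#' @rdname validate_profile
#' @export
glance.adam_validation <- function(x, ...) {
  tibble(valid = x$valid, n_findings = nrow(x$findings))
}
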