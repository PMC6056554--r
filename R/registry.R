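# The concept registry: the taxonomy of Header items and Main-Body concepts
# (Permissions, Terms, Meta-Conditions) that every Profile is interpreted
# against. A registry is a tibble of concept definitions, one row per concept,
# carrying a version tag attribute. The shipped v1.0 default is data, not
# code, so an adopter can swap in another taxonomy without code changes.

.registry_cols <- c("concept_id", "section", "label", "parent_id",
                    "value_domain", "supports_forbidden_obligatory",
                    "free_text_slots", "requirement")

.default_version_tag <- "adam-registry/1.0"

.registry_cache <- new.env(parent = emptyenv())

#' Construct a concept registry from a concept table
#'
#' Builds an `adam_registry` (a tibble subclass) from a data frame with one
#' row per concept. Only `concept_id` and `section` are mandatory columns;
#' the rest are filled with section-appropriate defaults: Permissions concepts
#' get the five-value vocabulary and one free-text slot, Terms concepts the
#' `True`/`Untrue` vocabulary and one free-text slot, Header items an empty
#' value domain (their value is free text). Structural invariants (unique ids,
#' one-level Permissions hierarchy, free-text slot limits) are always checked;
#' the full v1.0 cardinality invariants are additionally enforced when
#' `version_tag` is the shipped default tag.
#'
#' @param concepts A data frame with columns `concept_id` and `section`
#'   (one of `"HEADER"`, `"PERMISSIONS"`, `"TERMS"`, `"META"`), and optionally
#'   `label`, `parent_id`, `value_domain` (list column of character vectors),
#'   `supports_forbidden_obligatory`, `free_text_slots`, `requirement`
#'   (`"REQUIRED"`, `"OPTIONAL"` or `"CONDITIONAL"`).
#' @param version_tag Version string identifying the taxonomy.
#' @return An `adam_registry` tibble with all columns filled in.
#' @examples
#' tiny <- adam_registry(tibble::tibble(
#'   concept_id = c("profile_id", "research_use", "mode_of_sharing"),
#'   section    = c("HEADER", "PERMISSIONS", "META"),
#'   requirement = c("REQUIRED", "OPTIONAL", "REQUIRED"),
#'   value_domain = list(character(), NULL, c("Discovery", "Access"))
#' ), version_tag = "example/0.1")
#' section_counts(tiny)
#' @export
adam_registry <- function(concepts, version_tag = "custom") {
  tbl <- as_tibble(concepts)
  if (!all(c("concept_id", "section") %in% names(tbl))) {
    abort("`concepts` needs at least columns `concept_id` and `section`.",
          class = "adam_malformed_registry")
  }
  n <- nrow(tbl)
  if (!"label" %in% names(tbl)) tbl$label <- tbl$concept_id
  tbl$label <- ifelse(is.na(tbl$label), tbl$concept_id, tbl$label)
  if (!"parent_id" %in% names(tbl)) tbl$parent_id <- NA_character_
  if (!"free_text_slots" %in% names(tbl)) tbl$free_text_slots <- NA_integer_
  tbl$free_text_slots <- as.integer(ifelse(
    is.na(tbl$free_text_slots),
    ifelse(tbl$section %in% c("PERMISSIONS", "TERMS"), 1L, 0L),
    tbl$free_text_slots))
  if (!"value_domain" %in% names(tbl)) tbl$value_domain <- vector("list", n)
  tbl$value_domain <- map(seq_len(n), function(i) {
    dom <- tbl$value_domain[[i]]
    if (!is.null(dom) && !(length(dom) == 1L && is.na(dom))) {
      return(as.character(dom))
    }
    switch(tbl$section[[i]],
           PERMISSIONS = .perm_values,
           TERMS = .term_values,
           META = abort(
             paste0("META concept `", tbl$concept_id[[i]],
                    "` needs an explicit value_domain."),
             class = "adam_malformed_registry"),
           character())
  })
  if (!"supports_forbidden_obligatory" %in% names(tbl)) {
    tbl$supports_forbidden_obligatory <- NA
  }
  tbl$supports_forbidden_obligatory <- ifelse(
    is.na(tbl$supports_forbidden_obligatory),
    tbl$section == "PERMISSIONS" &
      map_lgl(tbl$value_domain, function(d) "Forbidden" %in% d),
    tbl$supports_forbidden_obligatory)
  if (!"requirement" %in% names(tbl)) tbl$requirement <- "OPTIONAL"
  tbl$requirement <- ifelse(is.na(tbl$requirement), "OPTIONAL", tbl$requirement)
  tbl <- tbl[, .registry_cols]
  reg <- structure(tbl, version_tag = version_tag,
                   class = c("adam_registry", class(tbl)))
  .check_registry(reg)
  reg
}

#' @export
print.adam_registry <- function(x, ...) {
  cat("<adam_registry> version:", registry_version(x), "\n")
  NextMethod()
}

#' Version tag of a registry
#' @param registry An `adam_registry`.
#' @return The registry's version string.
#' @export
registry_version <- function(registry) attr(registry, "version_tag")

# Structural invariants (all registries) plus the printed v1.0 cardinalities
# when the registry claims the default version tag.
.check_registry <- function(reg) {
  fail <- function(msg) abort(paste0("Registry invariant violated: ", msg),
                              class = "adam_registry_invariant")
  if (anyDuplicated(reg$concept_id)) {
    fail(paste0("duplicate concept_id `",
                reg$concept_id[duplicated(reg$concept_id)][1], "`"))
  }
  if (!all(reg$section %in% .sections)) {
    fail("section must be one of HEADER, PERMISSIONS, TERMS, META")
  }
  if (!all(reg$requirement %in% c("REQUIRED", "OPTIONAL", "CONDITIONAL"))) {
    fail("requirement must be REQUIRED, OPTIONAL or CONDITIONAL")
  }
  parents <- reg$parent_id[!is.na(reg$parent_id)]
  if (length(parents)) {
    perm_ids <- reg$concept_id[reg$section == "PERMISSIONS"]
    with_parent <- reg$concept_id[!is.na(reg$parent_id)]
    if (!all(reg$section[!is.na(reg$parent_id)] == "PERMISSIONS") ||
        !all(parents %in% perm_ids)) {
      fail("parent_id must name an existing PERMISSIONS concept")
    }
    # one-level forest: a parent may not itself have a parent (this also
    # rejects self-parents and any cycle)
    if (any(parents %in% with_parent)) {
      fail("hierarchy deeper than one level (a parent has a parent)")
    }
  }
  if (any(reg$free_text_slots < 0L | reg$free_text_slots > 2L)) {
    fail("free_text_slots must be 0, 1 or 2")
  }
  if (any(reg$free_text_slots == 2L & reg$section != "TERMS")) {
    fail("only a TERMS concept may have two free-text slots")
  }
  if (registry_version(reg) == .default_version_tag) {
    counts <- table(factor(reg$section, levels = .sections))
    want <- c(HEADER = 13L, PERMISSIONS = 26L, TERMS = 11L, META = 5L)
    for (s in names(want)) {
      if (counts[[s]] != want[[s]]) {
        fail(sprintf("default registry must have %d %s concepts, found %d",
                     want[[s]], s, counts[[s]]))
      }
    }
    if (sum(reg$section == "HEADER" & reg$requirement == "REQUIRED") != 3L) {
      fail("default registry must have exactly 3 REQUIRED HEADER items")
    }
    main <- reg[reg$section != "HEADER", ]
    req <- main$concept_id[main$requirement == "REQUIRED"]
    if (!identical(req, "mode_of_sharing")) {
      fail("Mode of sharing must be the single REQUIRED Main-Body concept")
    }
    cond <- main$concept_id[main$requirement == "CONDITIONAL"]
    if (!identical(cond, "interpretation_rule")) {
      fail("the interpretation rule must be the single CONDITIONAL concept")
    }
    perm <- reg[reg$section == "PERMISSIONS", ]
    restricted <- sort(perm$concept_id[!perm$supports_forbidden_obligatory])
    if (!identical(restricted, sort(c("use_within_countries",
                                      "use_by_organizations",
                                      "use_by_person_categories")))) {
      fail("exactly the three use-scope concepts must be restricted")
    }
    dom_len <- map_int(perm$value_domain, length)
    if (sum(dom_len == 5L) != 23L || sum(dom_len == 2L) != 3L) {
      fail("23 PERMISSIONS concepts need the 5-value list, 3 the 2-value list")
    }
    if (sum(reg$free_text_slots == 2L) != 1L ||
        reg$concept_id[reg$free_text_slots == 2L] != "no_recontact_terms") {
      fail("only the recontact Terms concept may have two free-text slots")
    }
  }
  invisible(reg)
}

#' The shipped ADA-M v1.0 default registry
#'
#' Loads (and caches) the default concept taxonomy: 13 Header items (3
#' required), 26 hierarchically arranged Permissions concepts (23 with the
#' extended five-value option list; use-within-countries/locations,
#' use-by-organizations and use-by-categories-of-person are restricted to
#' `Unrestricted`/`Limited`), 11 Terms concepts (the recontact concept with
#' two free-text slots), and 5 Meta-Conditions concepts of which only Mode of
#' sharing is required and the interpretation rule is conditional.
#'
#' @return An `adam_registry` tibble of 55 concept definitions.
#' @examples
#' reg <- default_registry()
#' section_counts(reg)
#' @export
default_registry <- function() {
  if (is.null(.registry_cache$default)) {
    path <- system.file("extdata", "adam_registry_v1.0.json",
                        package = "adamatrix", mustWork = TRUE)
    .registry_cache$default <- load_registry(path)
  }
  .registry_cache$default
}

#' Load a registry from a configuration document
#'
#' Reads a registry JSON document (the format shipped at
#' `inst/extdata/adam_registry_v1.0.json`: a `version_tag` and an array of
#' concept records with the fields of [adam_registry()]'s concept table) and
#' checks all registry invariants.
#'
#' @param path Path to a registry JSON document.
#' @return An `adam_registry`.
#' @seealso [default_registry()], [adam_registry()]
#' @export
load_registry <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) abort(paste0("Malformed registry document: ",
                                     conditionMessage(e)),
                              class = "adam_malformed_registry")
  )
  if (!is.list(doc) || is.null(doc$concepts) || is.null(doc$version_tag)) {
    abort("Malformed registry document: needs `version_tag` and `concepts`.",
          class = "adam_malformed_registry")
  }
  rows <- map(doc$concepts, function(cp) {
    for (f in c("concept_id", "section")) {
      if (is.null(cp[[f]])) {
        abort(paste0("Malformed registry document: concept missing `", f, "`."),
              class = "adam_malformed_registry")
      }
    }
    tibble(concept_id = cp$concept_id,
           section = cp$section,
           label = cp$label %||% cp$concept_id,
           parent_id = cp$parent_id %||% NA_character_,
           value_domain = list(as.character(unlist(cp$value_domain))),
           supports_forbidden_obligatory =
             cp$supports_forbidden_obligatory %||% NA,
           free_text_slots = as.integer(cp$free_text_slots %||% NA_integer_),
           requirement = cp$requirement %||% "OPTIONAL")
  })
  adam_registry(bind_rows(rows), version_tag = doc$version_tag)
}

#' Count concepts per registry section
#'
#' @param registry An `adam_registry` (or any data frame with a `section`
#'   column).
#' @return A tibble with columns `section` and `n`, one row per section in
#'   canonical order (`HEADER`, `PERMISSIONS`, `TERMS`, `META`), including
#'   zero counts.
#' @examples
#' section_counts(default_registry())
#' @export
section_counts <- function(registry) {
  tab <- table(factor(registry$section, levels = .sections))
  tibble(section = .sections, n = as.integer(tab))
}

# Row lookup; NULL when absent.
.concept <- function(registry, concept_id) {
  i <- match(concept_id, registry$concept_id)
  if (is.na(i)) return(NULL)
  registry[i, ]
}

.section_ids <- function(registry, section) {
  registry$concept_id[registry$section == section]
}
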