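# The Profile document model. A Profile is one Header plus one or more Main
# Bodies, each body holding Permissions, Terms and Meta-Conditions entries
# keyed by concept id. Entries are stored in canonical registry order so that
# structurally equal Profiles are `identical()` and serialization is
# byte-stable.

#' Construct a Main Body
#'
#' A Main Body holds at most one entry per concept across its three
#' sub-sections. Each entry is a list with a `value` (a token from the
#' concept's value domain) and optional `free_text` (and, for the recontact
#' Terms concept only, `free_text_2`).
#'
#' @param permissions,terms,meta Named lists of entries keyed by concept id.
#' @return An `adam_body`.
#' @seealso [set_entry()] for the checked way to populate a body.
#' @export
adam_body <- function(permissions = list(), terms = list(), meta = list()) {
  structure(list(permissions = permissions, terms = terms, meta = meta),
            class = "adam_body")
}

#' Construct an ADA-M Profile
#'
#' @param header Named list (or named character vector) of Header values keyed
#'   by Header concept id.
#' @param bodies List of [adam_body()] objects; a Profile carries one or more
#'   Main Bodies, entered sequentially under the single Header.
#' @return An `adam_profile`.
#' @examples
#' p <- adam_profile(header = list(profile_id = "P-1",
#'                                 profile_version = "2026-01-01/1.0",
#'                                 resource_reference = "doi:10.0000/demo"))
#' p <- set_entry(p, 1, "mode_of_sharing", "Discovery and Access")
#' @export
adam_profile <- function(header = list(), bodies = list(adam_body())) {
  header <- as.list(header)
  if (length(header) && is.null(names(header))) {
    abort("`header` must be named by Header concept id.",
          class = "adam_malformed_document")
  }
  if (!length(bodies)) {
    abort("A Profile must contain at least one Main Body.",
          class = "adam_malformed_document")
  }
  bodies <- map(bodies, function(b) {
    if (!inherits(b, "adam_body")) abort("`bodies` must be adam_body objects.",
                                         class = "adam_malformed_document")
    b
  })
  structure(list(header = header, bodies = bodies), class = "adam_profile")
}

#' @export
print.adam_profile <- function(x, ...) {
  cat("<adam_profile>", length(x$bodies),
      if (length(x$bodies) == 1L) "body," else "bodies,",
      length(x$header), "header value(s)\n")
  for (i in seq_along(x$bodies)) {
    b <- x$bodies[[i]]
    cat(sprintf("  body %d: %d permission(s), %d term(s), %d meta\n",
                i, length(b$permissions), length(b$terms), length(b$meta)))
  }
  invisible(x)
}

#' Number of Main Bodies in a Profile
#' @param profile An `adam_profile`.
#' @return Integer count of bodies.
#' @export
n_bodies <- function(profile) length(profile$bodies)

# Build a canonical entry list, dropping NULL slots, fixed field order.
.new_entry <- function(value = NULL, free_text = NULL, free_text_2 = NULL) {
  compact(list(value = value, free_text = free_text,
               free_text_2 = free_text_2))
}

# Reorder header values and body entries into registry order; unknown ids (if
# tolerated upstream) sort last in input order.
.canonicalize <- function(profile, registry) {
  ord <- function(ids, universe) {
    ids[order(match(ids, universe), na.last = TRUE)]
  }
  hids <- .section_ids(registry, "HEADER")
  profile$header <- profile$header[ord(names(profile$header), hids)]
  profile$bodies <- map(profile$bodies, function(b) {
    for (sec in names(.body_sections)) {
      slot <- .body_sections[[sec]]
      ids <- .section_ids(registry, sec)
      b[[slot]] <- b[[slot]][ord(names(b[[slot]]), ids)]
    }
    b
  })
  profile
}

#' Set a Header value
#'
#' @param profile An `adam_profile`.
#' @param concept_id A Header concept id from the registry.
#' @param value Character value; `NULL` removes the entry.
#' @param registry Registry to check ids against.
#' @return The updated `adam_profile`.
#' @export
set_header <- function(profile, concept_id, value,
                       registry = default_registry()) {
  cdef <- .concept(registry, concept_id)
  if (is.null(cdef) || cdef$section != "HEADER") {
    abort(paste0("Unknown HEADER concept `", concept_id, "`."),
          class = "adam_unknown_concept")
  }
  profile$header[[concept_id]] <- if (is.null(value)) NULL
                                  else as.character(value)
  .canonicalize(profile, registry)
}

#' Upsert a Main-Body entry
#'
#' Sets (or, with `value = NULL`, removes) the entry for one concept in one
#' Main Body, fail-fast: the concept must exist in the registry and the value
#' must belong to that concept's own value domain, so e.g. `Forbidden` on
#' use-by-organizations is rejected here as well as by the validator. Setting
#' a concept twice replaces the earlier entry (one entry per concept per
#' body).
#'
#' @param profile An `adam_profile`.
#' @param body_index 1-based Main Body index.
#' @param concept_id A Permissions, Terms or Meta concept id.
#' @param value A token from the concept's value domain, or `NULL` to remove
#'   the entry.
#' @param free_text Optional accompanying free text.
#' @param free_text_2 Optional second free-text slot (recontact Terms concept
#'   only; the "must occur" slot).
#' @param registry Registry the Profile is interpreted against.
#' @return The updated `adam_profile`.
#' @examples
#' p <- adam_profile()
#' p <- set_entry(p, 1, "research_disease_specific", "Limited",
#'                free_text = "Use permitted for research on diseases A, B[Obligatory], and C")
#' @export
set_entry <- function(profile, body_index, concept_id, value,
                      free_text = NULL, free_text_2 = NULL,
                      registry = default_registry()) {
  if (body_index < 1L || body_index > length(profile$bodies)) {
    abort(paste0("Body index ", body_index, " out of range (profile has ",
                 length(profile$bodies), " bodies)."),
          class = "adam_index_out_of_range")
  }
  cdef <- .concept(registry, concept_id)
  if (is.null(cdef) || cdef$section == "HEADER") {
    abort(paste0("Unknown Main-Body concept `", concept_id, "`."),
          class = "adam_unknown_concept")
  }
  slot <- .body_sections[[cdef$section]]
  if (is.null(value)) {
    profile$bodies[[body_index]][[slot]][[concept_id]] <- NULL
    return(.canonicalize(profile, registry))
  }
  domain <- cdef$value_domain[[1]]
  if (!value %in% domain) {
    abort(paste0("Value `", value, "` is not in the value domain of `",
                 concept_id, "` (", paste(domain, collapse = ", "), ")."),
          class = "adam_value_not_in_domain")
  }
  if (!is.null(free_text_2) && cdef$free_text_slots < 2L) {
    abort(paste0("Concept `", concept_id, "` has no second free-text slot."),
          class = "adam_value_not_in_domain")
  }
  if (!is.null(free_text) && cdef$free_text_slots < 1L) {
    abort(paste0("Concept `", concept_id, "` has no free-text slot."),
          class = "adam_value_not_in_domain")
  }
  profile$bodies[[body_index]][[slot]][[concept_id]] <-
    .new_entry(value, free_text, free_text_2)
  .canonicalize(profile, registry)
}

#' Append a Main Body to a Profile
#'
#' Additional bodies express alternative combinations of use criteria (e.g.
#' different conditions for discovery versus access); they are entered
#' sequentially under the one Header.
#'
#' @param profile An `adam_profile`.
#' @param body An [adam_body()]; empty by default.
#' @return The updated `adam_profile`.
#' @export
add_body <- function(profile, body = adam_body()) {
  profile$bodies <- c(profile$bodies, list(body))
  profile
}

#' Condition items of a Main-Body entry
#'
#' Convenience accessor: parses the entry's free text under the
#' `[Obligatory]` list grammar.
#'
#' @param profile An `adam_profile`.
#' @param body_index 1-based body index.
#' @param concept_id Permissions concept id.
#' @return A tibble of condition items, or `NULL` when the entry is absent,
#'   has no free text, or its free text is prose.
#' @export
condition_items <- function(profile, body_index, concept_id) {
  entry <- profile$bodies[[body_index]]$permissions[[concept_id]]
  if (is.null(entry) || is.null(entry[["free_text"]])) return(NULL)
  parse_condition_list(entry[["free_text"]])
}

#' Flatten a Profile's entries to a tibble
#'
#' One row per Header value and Main-Body entry; the long, tabular view of a
#' Profile used by the key-value writer and the plotting helpers.
#'
#' @param x An `adam_profile`.
#' @param ... Unused.
#' @return A tibble with columns `body` (0-based index; `NA` for Header
#'   rows), `section`, `concept_id`, `field` (`"value"`, `"freeText"`,
#'   `"freeText2"`) and `text`.
#' @export
tidy.adam_profile <- function(x, ...) {
  rows <- list()
  for (id in names(x$header)) {
    rows[[length(rows) + 1L]] <-
      tibble(body = NA_integer_, section = "header", concept_id = id,
             field = "value", text = as.character(x$header[[id]]))
  }
  for (k in seq_along(x$bodies)) {
    b <- x$bodies[[k]]
    for (slot in unname(.body_sections)) {
      for (id in names(b[[slot]])) {
        entry <- b[[slot]][[id]]
        fields <- c(value = "value", free_text = "freeText",
                    free_text_2 = "freeText2")
        for (f in names(fields)) {
          if (!is.null(entry[[f]])) {
            rows[[length(rows) + 1L]] <-
              tibble(body = k - 1L, section = slot, concept_id = id,
                     field = fields[[f]], text = as.character(entry[[f]]))
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(tibble(body = integer(), section = character(),
                  concept_id = character(), field = character(),
                  text = character()))
  }
  bind_rows(rows)
}
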