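# Bit-stable readers/writers for the two standard Profile document formats:
# a JSON dialect and a flat key-value pair text dialect. Both impose
# canonical registry order on entries, so serialization is deterministic and
# the two formats are mutually convertible without loss.
#
# Key-value dialect (documented here normatively so other implementations can
# interoperate):
#   header.<concept_id>=<text>
#   body.<k>.<section>.<concept_id>.value=<token>      # k is 0-based
#   body.<k>.<section>.<concept_id>.freeText=<text>
#   body.<k>.<section>.<concept_id>.freeText2=<text>   # recontact slot only
# with <section> one of permissions|terms|meta, UTF-8, "\n" line ends, and
# backslash escapes in values: "\\" backslash, "\n" newline, "\r" carriage
# return. One pair per line; duplicate keys are an error. The number of
# bodies is the largest k seen plus one.

.entry_fields <- c(value = "value", free_text = "freeText",
                   free_text_2 = "freeText2")

#' Serialize a Profile to the JSON dialect
#'
#' Writes the canonical JSON document: a top-level `adamVersion`, the Header
#' values, and the ordered array of Main Bodies, each body holding
#' `permissions`/`terms`/`meta` objects keyed by concept id. Unset optional
#' fields are omitted entirely (fields without values are left blank and not
#' reported), keys follow registry order, and two calls on the same Profile
#' produce byte-identical text.
#'
#' @param profile An `adam_profile`.
#' @param registry Registry providing canonical concept order.
#' @return A single character string of pretty-printed JSON.
#' @seealso [profile_from_json()], [profile_to_keyvalue()]
#' @export
profile_to_json <- function(profile, registry = default_registry()) {
  profile <- .canonicalize(profile, registry)
  body_doc <- function(b) {
    out <- list()
    for (slot in unname(.body_sections)) {
      entries <- b[[slot]]
      if (!length(entries)) next
      out[[slot]] <- map(entries, function(e) {
        doc <- list()
        for (f in names(.entry_fields)) {
          if (!is.null(e[[f]])) doc[[.entry_fields[[f]]]] <- e[[f]]
        }
        doc
      })
    }
    out
  }
  doc <- list(adamVersion = "1.0")
  if (length(profile$header)) doc$header <- profile$header
  doc$bodies <- map(profile$bodies, body_doc)
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                                null = "null"))
}

# Decode one entry object at `path`, checking field names.
.entry_from_doc <- function(doc, path) {
  if (!is.list(doc)) .stop_malformed("entry must be an object", path)
  extra <- setdiff(names(doc), unname(.entry_fields))
  if (length(extra)) {
    .stop_malformed(paste0("unknown entry field `", extra[1], "`"), path)
  }
  .new_entry(value = doc$value, free_text = doc[["freeText"]],
             free_text_2 = doc[["freeText2"]])
}

#' Parse a Profile from the JSON dialect
#'
#' @param text A JSON document string (as produced by [profile_to_json()]).
#' @param registry Registry used to resolve concept ids and canonical order.
#' @param strict If `TRUE` (default), an unknown concept id is an error of
#'   class `adam_unknown_concept`; if `FALSE`, unknown entries are dropped
#'   with a warning.
#' @return An `adam_profile`.
#' @export
profile_from_json <- function(text, registry = default_registry(),
                              strict = TRUE) {
  doc <- tryCatch(jsonlite::parse_json(text, simplifyVector = FALSE),
                  error = function(e)
                    .stop_malformed(paste0("invalid JSON: ",
                                           conditionMessage(e)), "$"))
  if (!is.list(doc) || is.null(doc$bodies) || !length(doc$bodies)) {
    .stop_malformed("document must contain a non-empty `bodies` array",
                    "$.bodies")
  }
  known <- function(id, section, path) {
    cdef <- .concept(registry, id)
    ok <- !is.null(cdef) && cdef$section == section
    if (!ok) {
      if (strict) {
        abort(paste0("Unknown ", section, " concept `", id, "` at ", path, "."),
              class = "adam_unknown_concept")
      }
      warn(paste0("Dropping unknown concept `", id, "` at ", path, "."))
    }
    ok
  }
  header <- list()
  for (id in names(doc$header)) {
    if (known(id, "HEADER", paste0("$.header.", id))) {
      header[[id]] <- as.character(doc$header[[id]])
    }
  }
  bodies <- imap(doc$bodies, function(bdoc, k) {
    b <- adam_body()
    for (sec in names(.body_sections)) {
      slot <- .body_sections[[sec]]
      for (id in names(bdoc[[slot]])) {
        path <- paste0("$.bodies[", k - 1L, "].", slot, ".", id)
        if (known(id, sec, path)) {
          b[[slot]][[id]] <- .entry_from_doc(bdoc[[slot]][[id]], path)
        }
      }
    }
    b
  })
  .canonicalize(adam_profile(header = header, bodies = bodies), registry)
}

.kv_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

.kv_unescape <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
    buf <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      ch <- chars[[j]]
      if (ch == "\\" && j < length(chars)) {
        nxt <- chars[[j + 1L]]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        buf <- c(buf, ch)
        j <- j + 1L
      }
    }
    out[[i]] <- paste(buf, collapse = "")
  }
  out
}

#' Serialize a Profile to the key-value dialect
#'
#' One `key=value` pair per line, dotted-path keys, 0-based body indices,
#' canonical registry order (see the dialect description in this file's
#' documentation). The inverse of [profile_from_keyvalue()].
#'
#' @inheritParams profile_to_json
#' @return A single character string (lines joined with `"\n"`, trailing
#'   newline).
#' @export
profile_to_keyvalue <- function(profile, registry = default_registry()) {
  long <- tidy(.canonicalize(profile, registry))
  keys <- ifelse(is.na(long$body),
                 paste0("header.", long$concept_id),
                 paste0("body.", long$body, ".", long$section, ".",
                        long$concept_id, ".", long$field))
  paste0(paste0(keys, "=", .kv_escape(long$text), collapse = "\n"), "\n")
}

#' Parse a Profile from the key-value dialect
#'
#' Errors carry the offending line number: lines without `=` or with
#' unparseable keys raise `adam_malformed_document`; a repeated key raises
#' `adam_duplicate_key`.
#'
#' @param text Key-value document string.
#' @inheritParams profile_from_json
#' @return An `adam_profile`.
#' @export
profile_from_keyvalue <- function(text, registry = default_registry(),
                                  strict = TRUE) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  header <- list()
  body_entries <- list()  # key -> list(body, slot, id, field, value)
  seen <- character(0)
  max_body <- -1L
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    loc <- paste0("line ", line_no[[i]])
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 1L) .stop_malformed("missing `=`", loc)
    key <- substr(ln, 1L, eq - 1L)
    val <- .kv_unescape(substr(ln, eq + 1L, nchar(ln)))
    if (key %in% seen) {
      abort(paste0("Duplicate key `", key, "` at ", loc, "."),
            class = "adam_duplicate_key")
    }
    seen <- c(seen, key)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2L && parts[[1]] == "header") {
      header[[parts[[2]]]] <- val
    } else if (length(parts) == 5L && parts[[1]] == "body") {
      k <- suppressWarnings(as.integer(parts[[2]]))
      if (is.na(k) || k < 0L) .stop_malformed("bad body index", loc)
      slot <- parts[[3]]
      if (!slot %in% unname(.body_sections)) {
        .stop_malformed(paste0("unknown section `", slot, "`"), loc)
      }
      field <- names(.entry_fields)[match(parts[[5]], .entry_fields)]
      if (is.na(field)) {
        .stop_malformed(paste0("unknown field `", parts[[5]], "`"), loc)
      }
      max_body <- max(max_body, k)
      rows[[length(rows) + 1L]] <-
        list(body = k, slot = slot, id = parts[[4]], field = field,
             value = val, loc = loc)
    } else {
      .stop_malformed(paste0("unparseable key `", key, "`"), loc)
    }
  }
  if (max_body < 0L) .stop_malformed("document contains no body entries", "")
  bodies <- map(seq_len(max_body + 1L), function(i) adam_body())
  for (r in rows) {
    bodies[[r$body + 1L]][[r$slot]][[r$id]][[r$field]] <- r$value
  }
  # check ids against the registry and normalize entry field order
  sec_of <- c(permissions = "PERMISSIONS", terms = "TERMS", meta = "META")
  for (k in seq_along(bodies)) {
    for (slot in unname(.body_sections)) {
      ids <- names(bodies[[k]][[slot]])
      for (id in ids) {
        cdef <- .concept(registry, id)
        if (is.null(cdef) || cdef$section != sec_of[[slot]]) {
          if (strict) {
            abort(paste0("Unknown ", sec_of[[slot]], " concept `", id, "`."),
                  class = "adam_unknown_concept")
          }
          warn(paste0("Dropping unknown concept `", id, "`."))
          bodies[[k]][[slot]][[id]] <- NULL
          next
        }
        e <- bodies[[k]][[slot]][[id]]
        bodies[[k]][[slot]][[id]] <-
          .new_entry(e$value, e[["free_text"]], e[["free_text_2"]])
      }
    }
  }
  hids <- .section_ids(registry, "HEADER")
  unknown_h <- setdiff(names(header), hids)
  if (length(unknown_h)) {
    if (strict) {
      abort(paste0("Unknown HEADER concept `", unknown_h[1], "`."),
            class = "adam_unknown_concept")
    }
    warn(paste0("Dropping unknown header concept(s): ",
                paste(unknown_h, collapse = ", "), "."))
    header <- header[setdiff(names(header), unknown_h)]
  }
  .canonicalize(adam_profile(header = header, bodies = bodies), registry)
}

# ---- file-level helpers -----------------------------------------------------

.guess_format <- function(path) {
  if (grepl("\\.kv$", path)) "kv" else "json"
}

#' Read a Profile document from a file
#'
#' @param path Path to a `.adam.json` or `.adam.kv` document (format inferred
#'   from the extension unless given).
#' @param format `"json"`, `"kv"`, or `NULL` to infer from the extension.
#' @inheritParams profile_from_json
#' @return An `adam_profile`.
#' @export
read_profile <- function(path, format = NULL, registry = default_registry(),
                         strict = TRUE) {
  format <- format %||% .guess_format(path)
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  switch(format,
         json = profile_from_json(text, registry, strict),
         kv = profile_from_keyvalue(text, registry, strict),
         .stop_malformed(paste0("unknown format `", format, "`"), path))
}

#' Write a Profile document to a file
#'
#' @param profile An `adam_profile`.
#' @param path Output path.
#' @inheritParams read_profile
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, format = NULL,
                          registry = default_registry()) {
  format <- format %||% .guess_format(path)
  text <- switch(format,
                 json = profile_to_json(profile, registry),
                 kv = profile_to_keyvalue(profile, registry),
                 .stop_malformed(paste0("unknown format `", format, "`"),
                                 path))
  writeLines(text, path, sep = if (format == "json") "\n" else "",
             useBytes = TRUE)
  invisible(path)
}
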