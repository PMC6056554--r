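# The "[Obligatory]" condition-list micro-grammar.
#
# Free text accompanying a Limited permission ideally takes the shape of a
# short list, e.g. "Use permitted for research on diseases A, B[Obligatory],
# and C". Items suffixed "[Obligatory]" are uses that must occur, not merely
# may. The grammar is deliberately conservative: anything that does not look
# like such a list is treated as prose, kept verbatim, and handled by the
# decision engine as REFER-grade (to be read by a human).

.oblig_suffix_re <- "\\s*\\[\\s*[Oo][Bb][Ll][Ii][Gg][Aa][Tt][Oo][Rr][Yy]\\s*\\]\\s*$"

.strip_obligatory <- function(x) {
  has <- grepl(.oblig_suffix_re, x)
  list(label = trimws(sub(.oblig_suffix_re, "", x)), obligatory = has)
}

#' Parse an `[Obligatory]`-annotated condition list
#'
#' Attempts to parse free text as a comma-separated list of permitted items,
#' splitting on commas and a final "and", and stripping a per-item
#' `[Obligatory]` suffix (matched case-insensitively). A leading prose
#' preamble on the first item ("Use permitted for research on diseases A")
#' is discarded, keeping its final token as the item label. Text that is not
#' list-shaped — multi-sentence prose, comma-free multi-word text, or
#' segments longer than three words — yields `NULL` rather than an error, so
#' prose free text can be retained verbatim and routed to a human.
#'
#' @param text A single character string.
#' @return A tibble with columns `label` (character) and `obligatory`
#'   (logical), in input order; or `NULL` when `text` is not list-shaped.
#' @examples
#' parse_condition_list("Use permitted for research on diseases A, B[Obligatory], and C")
#' parse_condition_list("Results must be made public")  # prose: NULL
#' @export
parse_condition_list <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) return(NULL)
  txt <- trimws(text)
  txt <- sub("\\.$", "", txt)
  if (!nzchar(txt)) return(NULL)
  # multi-sentence or clause-separated text is prose
  if (grepl("[.;:]", txt)) return(NULL)
  segs <- trimws(strsplit(txt, ",", fixed = TRUE)[[1]])
  if (any(!nzchar(segs))) return(NULL)
  n <- length(segs)
  if (n == 1L) {
    p <- .strip_obligatory(segs)
    if (!nzchar(p$label) || grepl("\\s", p$label)) return(NULL)
    return(tibble(label = p$label, obligatory = p$obligatory))
  }
  segs[n] <- sub("^[Aa][Nn][Dd]\\s+", "", segs[n])
  parsed <- .strip_obligatory(segs)
  labels <- parsed$label
  # first segment may carry a preamble; its item is the final token
  first_tokens <- strsplit(labels[1], "\\s+")[[1]]
  labels[1] <- first_tokens[length(first_tokens)]
  if (any(!nzchar(labels))) return(NULL)
  # later items must stay short to count as list items, not prose
  n_words <- lengths(strsplit(labels[-1], "\\s+"))
  if (length(n_words) && any(n_words > 3L)) return(NULL)
  if (any(grepl("\\[|\\]", labels))) return(NULL)
  tibble(label = labels, obligatory = parsed$obligatory)
}

#' Render a condition list to canonical text
#'
#' The inverse of [parse_condition_list()]: items are joined with `", "`, each
#' obligatory item suffixed with the canonical `[Obligatory]` marker, after an
#' optional preamble. `parse_condition_list(render_condition_list(items))`
#' recovers `items` exactly.
#'
#' @param items A data frame with columns `label` and `obligatory`, as
#'   returned by [parse_condition_list()]. Labels must be non-empty single
#'   tokens (no whitespace, commas or brackets).
#' @param preamble Optional prose prefix (e.g. `"Use permitted for research
#'   on diseases"`); emitted only for lists of two or more items, since a
#'   prefixed single item would read as prose on re-parse.
#' @return A single character string.
#' @examples
#' render_condition_list(tibble::tibble(label = c("A", "B"),
#'                                      obligatory = c(FALSE, TRUE)))
#' @export
render_condition_list <- function(items, preamble = "") {
  items <- as_tibble(items)
  if (nrow(items) == 0L) {
    abort("Cannot render an empty condition list.", class = "adam_empty_list")
  }
  bad <- !nzchar(items$label) | grepl("[,\\s\\[\\]]", items$label, perl = TRUE)
  if (any(bad)) {
    abort(paste0("Condition-item labels must be single tokens without ",
                 "commas or brackets; offending label: `",
                 items$label[bad][1], "`."),
          class = "adam_malformed_document")
  }
  rendered <- paste0(items$label, ifelse(items$obligatory, "[Obligatory]", ""))
  body <- paste(rendered, collapse = ", ")
  # a preamble on a one-item list could not be told apart from prose on
  # re-parse, so it is only emitted for lists of two or more items
  if (nzchar(preamble) && nrow(items) > 1L) paste(trimws(preamble), body)
  else body
}

#' Count obligatory markers in a Main Body
#'
#' Counts, across the Permissions and Terms sections of one Main Body:
#' entries whose main value carries the `[Obligatory]` marker
#' (`Unrestricted[Obligatory]`, `Limited[Obligatory]`); condition items
#' flagged `[Obligatory]` inside parseable permission free text; and the
#' recontact Terms concept's "must occur" second free-text slot when
#' non-empty. The conditional interpretation-rule Meta concept becomes
#' mandatory when this count reaches two.
#'
#' @param body An `adam_body` (see [adam_body()]).
#' @param registry The registry the body is interpreted against.
#' @return An integer count.
#' @export
count_obligatory <- function(body, registry = default_registry()) {
  n <- 0L
  for (entry in body$permissions) {
    if (!is.null(entry$value) && .is_obligatory_value(entry$value)) {
      n <- n + 1L
    }
    if (!is.null(entry[["free_text"]])) {
      items <- parse_condition_list(entry[["free_text"]])
      if (!is.null(items)) n <- n + sum(items$obligatory)
    }
  }
  recontact <- registry$concept_id[registry$section == "TERMS" &
                                     registry$free_text_slots == 2L]
  for (id in names(body$terms)) {
    entry <- body$terms[[id]]
    if (id %in% recontact && !is.null(entry[["free_text_2"]]) &&
        nzchar(trimws(entry[["free_text_2"]]))) {
      n <- n + 1L
    }
  }
  n
}
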