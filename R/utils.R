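# Canonical value vocabularies. Permission values come in a 5-token list for
# most concepts and a 2-token list for the three use-scope concepts that can
# never logically be forbidden or obligated.
.perm_values <- c("Unrestricted", "Limited", "Unrestricted[Obligatory]",
                  "Limited[Obligatory]", "Forbidden")
.term_values <- c("True", "Untrue")
.mode_values <- c("Discovery", "Access", "Discovery and Access")
.rule_values <- c("Meet all", "Meet any")

.sections <- c("HEADER", "PERMISSIONS", "TERMS", "META")
.body_sections <- c(PERMISSIONS = "permissions", TERMS = "terms", META = "meta")

#' Canonical value vocabularies of the ADA-M model
#'
#' The fixed token lists used throughout the model: the five-value Permissions
#' vocabulary (`"Unrestricted"`, `"Limited"`, `"Unrestricted[Obligatory]"`,
#' `"Limited[Obligatory]"`, `"Forbidden"`), the two-value Terms vocabulary
#' (`"True"`, `"Untrue"`), the Mode-of-sharing list and the
#' interpretation-rule list.
#'
#' @return A named list of character vectors with elements `permissions`,
#'   `terms`, `mode_of_sharing` and `interpretation_rule`.
#' @examples
#' adam_values()$permissions
#' @export
adam_values <- function() {
  list(permissions = .perm_values, terms = .term_values,
       mode_of_sharing = .mode_values, interpretation_rule = .rule_values)
}

# Does a value carry an entry-level [Obligatory] marker?
.is_obligatory_value <- function(value) {
  value %in% c("Unrestricted[Obligatory]", "Limited[Obligatory]")
}

.is_limited_value <- function(value) {
  value %in% c("Limited", "Limited[Obligatory]")
}

# Case-folded, trimmed label normalization used for request matching.
.normalize_label <- function(x) tolower(trimws(x))

.stop_malformed <- function(message, location = NULL) {
  abort(message, class = "adam_malformed_document", location = location)
}

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring any
# pre-existing global .Random.seed afterwards.
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
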