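# Fixture builders shared across the suite. Everything is constructed in
# code; no external data.

`%||%` <- function(x, y) if (is.null(x)) y else x

minimal_profile <- function() {
  p <- adam_profile(header = list(
    profile_id = "P-0001",
    profile_version = "2026-01-01/1.0",
    resource_reference = "doi:10.5072/synthetic-minimal"))
  p <- set_entry(p, 1, "mode_of_sharing", "Discovery and Access")
  set_entry(p, 1, "research_use", "Unrestricted")
}

disease_list_text <- "Use permitted for research on diseases A, B[Obligatory], and C"

# One Limited permission with the worked three-disease list.
disease_profile <- function(mode = "Discovery and Access") {
  p <- adam_profile(header = list(
    profile_id = "P-0002",
    profile_version = "2026-01-01/1.0",
    resource_reference = "doi:10.5072/synthetic-diseases"))
  p <- set_entry(p, 1, "mode_of_sharing", mode)
  set_entry(p, 1, "research_disease_specific", "Limited",
            free_text = disease_list_text)
}

# A small registry for exhaustive oracle runs: two extended Permissions
# concepts, one restricted, one Terms concept, and the two structural Meta
# concepts.
tiny_registry <- function() {
  adam_registry(tibble::tibble(
    concept_id = c("p_hdr", "use_a", "use_b", "use_countries",
                   "no_collab", "mode_of_sharing", "interpretation_rule"),
    section = c("HEADER", "PERMISSIONS", "PERMISSIONS", "PERMISSIONS",
                "TERMS", "META", "META"),
    requirement = c("REQUIRED", "OPTIONAL", "OPTIONAL", "OPTIONAL",
                    "OPTIONAL", "REQUIRED", "CONDITIONAL"),
    value_domain = list(character(), NULL, NULL,
                        c("Unrestricted", "Limited"), NULL,
                        c("Discovery", "Access", "Discovery and Access"),
                        c("Meet all", "Meet any"))
  ), version_tag = "tiny/1.0")
}

tiny_profile_base <- function(reg, mode = "Discovery and Access") {
  p <- adam_profile(header = list(p_hdr = "T-1"))
  set_entry(p, 1, "mode_of_sharing", mode, registry = reg)
}

# All subsets of a label vector, as a list (power set).
power_set <- function(labels) {
  out <- list(character(0))
  for (l in labels) out <- c(out, lapply(out, function(s) c(s, l)))
  out
}
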