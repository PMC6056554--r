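# Independent brute-force decision oracle. It re-derives the decision from
# the semantic truth table directly on the raw Profile lists, with its own
# tiny list parser, sharing no code path with adjudicate().

# Parses only canonical "X, Y[Obligatory], Z" lists (with optional preamble
# and final "and"); anything else is prose (NULL).
oracle_parse_list <- function(text) {
  if (is.null(text)) return(NULL)
  txt <- sub("\\.$", "", trimws(text))
  if (!nzchar(txt) || grepl("[.;:]", txt)) return(NULL)
  parts <- trimws(strsplit(txt, ",", fixed = TRUE)[[1]])
  if (!length(parts) || any(!nzchar(parts))) return(NULL)
  parts[length(parts)] <- sub("^[Aa][Nn][Dd]\\s+", "", parts[length(parts)])
  obl <- grepl("\\[[Oo]bligatory\\]\\s*$", parts)
  labs <- trimws(sub("\\s*\\[[Oo]bligatory\\]\\s*$", "", parts))
  if (length(parts) == 1L && grepl("\\s", labs[1])) return(NULL)
  toks <- strsplit(labs[1], "\\s+")[[1]]
  labs[1] <- toks[length(toks)]
  if (length(labs) > 1L &&
      any(lengths(strsplit(labs[-1], "\\s+")) > 3L)) return(NULL)
  if (any(!nzchar(labs)) || any(grepl("\\[|\\]", labs))) return(NULL)
  data.frame(label = labs, obligatory = obl)
}

# Decision by direct enumeration of the truth table per entry.
oracle_decide <- function(profile, request, registry) {
  mode <- request$mode
  norm <- function(x) tolower(trimws(x))
  body_states <- character(0)
  for (b in profile$bodies) {
    mv <- b$meta[["mode_of_sharing"]]$value
    if (is.null(mv) || !(mv == "Discovery and Access" || mv == mode)) next
    fail <- FALSE
    refer <- FALSE
    obl_sat <- logical(0)
    for (id in names(b$permissions)) {
      e <- b$permissions[[id]]
      v <- e$value
      req <- norm(request$declared_uses[[id]] %||% character(0))
      txt <- e$free_text
      items <- if (!is.null(txt)) oracle_parse_list(txt)
      prose <- !is.null(txt) && is.null(items)
      if (is.null(v)) { refer <- TRUE; next }
      if (v == "Forbidden") {
        if (length(req) > 0L) fail <- TRUE
        next
      }
      limited <- v %in% c("Limited", "Limited[Obligatory]")
      if (limited && (is.null(txt) || prose)) { refer <- TRUE; next }
      allowed <- if (limited) all(req %in% norm(items$label)) else TRUE
      if (!allowed) fail <- TRUE
      if (limited) {
        for (lab in norm(items$label[items$obligatory])) {
          obl_sat <- c(obl_sat, lab %in% req)
        }
      }
      if (v %in% c("Unrestricted[Obligatory]", "Limited[Obligatory]")) {
        obl_sat <- c(obl_sat, length(req) > 0L && allowed)
      }
      if (!limited && prose && allowed) refer <- TRUE
    }
    for (id in names(b$terms)) {
      v <- b$terms[[id]]$value
      if (is.null(v)) { refer <- TRUE; next }
      if (v == "Untrue" && mode == "Access" &&
          !(id %in% request$accepted_terms)) fail <- TRUE
    }
    nor <- b$meta[["no_other_restrictions"]]$value
    if (!is.null(nor) && nor == "Untrue") refer <- TRUE
    rule <- b$meta[["interpretation_rule"]]$value
    if (is.null(rule)) rule <- "Meet all"
    if (length(obl_sat)) {
      ok <- if (rule == "Meet any") any(obl_sat) else all(obl_sat)
      if (!ok) fail <- TRUE
    }
    body_states <- c(body_states,
                     if (fail) "FAIL" else if (refer) "REFER" else "PASS")
  }
  if (any(body_states == "PASS")) "PERMIT"
  else if (length(body_states) == 0L || all(body_states == "FAIL")) "DENY"
  else "REFER"
}

# Every request over the given declared-use concepts and label vocabulary:
# both modes, every per-concept label subset, every accepted-terms subset.
oracle_requests <- function(concept_ids, vocab, term_ids, registry) {
  subsets <- power_set(vocab)
  term_subsets <- power_set(term_ids)
  idx <- expand.grid(rep(list(seq_along(subsets)), length(concept_ids)))
  out <- list()
  for (mode in c("Discovery", "Access")) {
    for (r in seq_len(nrow(idx))) {
      declared <- list()
      for (j in seq_along(concept_ids)) {
        s <- subsets[[idx[r, j]]]
        if (length(s)) declared[[concept_ids[j]]] <- s
      }
      for (ts in term_subsets) {
        out[[length(out) + 1L]] <-
          adam_request(mode, declared, ts, registry)
      }
    }
  }
  out
}

# One provably monotone relaxation of (profile, request): Forbidden ->
# Limited(full list), obligation-free Limited -> Unrestricted, a non-
# obligatory item appended to a list, or one more accepted Terms concept.
# Returns NULL when nothing is applicable.
relax_pair <- function(profile, request, seed,
                       registry = default_registry()) {
  cands <- list()
  for (k in seq_along(profile$bodies)) {
    perms <- profile$bodies[[k]]$permissions
    for (id in names(perms)) {
      v <- perms[[id]]$value
      if (is.null(v)) next
      if (v == "Forbidden") {
        cands[[length(cands) + 1L]] <- list(op = "f2l", k = k, id = id)
      } else if (v == "Limited") {
        items <- parse_condition_list(perms[[id]]$free_text %||% "")
        if (!is.null(items)) {
          if (!any(items$obligatory)) {
            cands[[length(cands) + 1L]] <- list(op = "l2u", k = k, id = id)
          }
          cands[[length(cands) + 1L]] <-
            list(op = "superset", k = k, id = id, items = items)
        }
      } else if (v == "Limited[Obligatory]") {
        items <- parse_condition_list(perms[[id]]$free_text %||% "")
        if (!is.null(items)) {
          cands[[length(cands) + 1L]] <-
            list(op = "superset", k = k, id = id, items = items)
        }
      }
    }
  }
  term_ids <- registry$concept_id[registry$section == "TERMS"]
  free_terms <- setdiff(term_ids, request$accepted_terms)
  if (length(free_terms)) {
    cands[[length(cands) + 1L]] <- list(op = "accept", id = free_terms)
  }
  if (!length(cands)) return(NULL)
  withr::with_seed(seed, {
    c0 <- cands[[sample.int(length(cands), 1L)]]
    if (c0$op == "accept") {
      request <- adam_request(request$mode, request$declared_uses,
                              c(request$accepted_terms,
                                c0$id[sample.int(length(c0$id), 1L)]),
                              registry)
    } else if (c0$op == "f2l") {
      profile <- set_entry(profile, c0$k, c0$id, "Limited",
                           free_text = render_condition_list(
                             tibble::tibble(label = c("A", "B", "C"),
                                            obligatory = FALSE)),
                           registry = registry)
    } else if (c0$op == "l2u") {
      profile <- set_entry(profile, c0$k, c0$id, "Unrestricted",
                           registry = registry)
    } else {
      items <- rbind(c0$items,
                     data.frame(label = "z9", obligatory = FALSE))
      value <- profile$bodies[[c0$k]]$permissions[[c0$id]]$value
      profile <- set_entry(profile, c0$k, c0$id, value,
                           free_text = render_condition_list(items),
                           registry = registry)
    }
    list(profile = profile, request = request)
  })
}
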