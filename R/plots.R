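# ggplot2 views of the result objects: findings per rule for a validation
# report, a per-concept verdict matrix for a decision.

#' Plot a validation report
#'
#' Bar chart of findings per rule; an empty (all-zero) chart means a valid
#' Profile.
#'
#' @param object An `adam_validation` from [validate_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adam_validation <- function(object, ...) {
  counts <- tibble(rule_id = names(.rule_summaries)) |>
    left_join(count(object$findings, .data$rule_id), by = "rule_id") |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$rule_id, y = .data$n)) +
    ggplot2::geom_col(fill = "#b2182b") +
    ggplot2::labs(x = "validation rule", y = "findings",
                  title = if (object$valid) "Valid profile (no findings)"
                  else "Validation findings per rule") +
    ggplot2::theme_minimal()
}

#' Plot an adjudication decision
#'
#' Tile matrix of per-concept verdicts across the mode-eligible Main Bodies.
#'
#' @param object An `adam_decision` from [adjudicate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adam_decision <- function(object, ...) {
  vt <- object$verdicts
  if (!nrow(vt)) {
    vt <- tibble(body = 0L, section = "none", concept_id = "(no eligible body)",
                 verdict = "FAIL", rationale = "")
  }
  vt <- mutate(vt, body = factor(paste("body", .data$body)),
               verdict = factor(.data$verdict,
                                levels = c("PASS", "REFER", "FAIL")))
  ggplot2::ggplot(vt, ggplot2::aes(x = .data$body, y = .data$concept_id,
                                   fill = .data$verdict)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(PASS = "#1a9850", REFER = "#fdae61",
                                          FAIL = "#d73027"),
                               drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Decision:", object$overall,
                                "(mode:", object$mode, ")")) +
    ggplot2::theme_minimal()
}
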