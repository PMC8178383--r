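#' Thresholds for promising-MQTL selection
#'
#' The three Loeffler-style criteria gate which meta-QTL are promising for
#' marker-assisted selection: many contributing QTL, a small support
#' interval and a high mean effect. A fourth, physical criterion restricts
#' candidate-gene analysis to compact genomic regions.
#'
#' @param min_n_qtl minimum member-QTL count (inclusive, default 5).
#' @param max_ci maximum CI width in cM (inclusive); `NULL` (default)
#'   means "the mean MQTL CI width of the current run", computed when the
#'   filter is applied. The reference study's realized value was 4.9 cM.
#' @param min_mean_pve minimum mean PVE of the member QTL (inclusive,
#'   default 0.10).
#' @param max_span_bp physical distance threshold between flanking markers
#'   (strict `<`, default 5,000,000 bp).
#' @return a `selection_config` list.
#' @export
selection_config <- function(min_n_qtl = 5, max_ci = NULL,
                             min_mean_pve = 0.10, max_span_bp = 5e6) {
  thresholds <- c(min_n_qtl = min_n_qtl,
                  max_ci = max_ci %||% NA_real_,
                  min_mean_pve = min_mean_pve, max_span_bp = max_span_bp)
  if (any(thresholds <= 0, na.rm = TRUE))
    abort("all selection thresholds must be > 0")
  structure(list(min_n_qtl = min_n_qtl, max_ci = max_ci,
                 min_mean_pve = min_mean_pve, max_span_bp = max_span_bp),
            class = "selection_config")
}

#' Select promising meta-QTL (Loeffler-style criteria)
#'
#' Keeps MQTL with `n_qtl >= min_n_qtl`, CI width `<= max_ci` and
#' `mean_pve >= min_mean_pve` (all inclusive). Every comparison is
#' recorded in the audit table attached as attribute `"audit"`
#' (accessible via [selection_audit()]); an MQTL without a `mean_pve`
#' fails that criterion with reason `"pve unavailable"`.
#'
#' @param mqtls MQTL tibble with `mqtl_id`, `n_qtl`, `ci_left`/`ci_right`
#'   (or a precomputed `ci_width`), `mean_pve`.
#' @param config a [selection_config()].
#' @return the selected rows, with attribute `"audit"`: one row per input
#'   MQTL with per-criterion pass/fail and the thresholds applied.
#' @export
loffler_select <- function(mqtls, config = selection_config()) {
  ci_width <- if ("ci_width" %in% names(mqtls)) mqtls$ci_width
              else mqtls$ci_right - mqtls$ci_left
  max_ci <- config$max_ci %||% mean(ci_width)
  pve_ok <- !is.na(mqtls$mean_pve) & mqtls$mean_pve >= config$min_mean_pve
  audit <- tibble::tibble(
    mqtl_id = mqtls$mqtl_id,
    n_qtl = mqtls$n_qtl, pass_n_qtl = mqtls$n_qtl >= config$min_n_qtl,
    ci_width = ci_width, pass_ci = ci_width <= max_ci,
    mean_pve = mqtls$mean_pve, pass_pve = pve_ok,
    reason_pve = ifelse(is.na(mqtls$mean_pve), "pve unavailable", ""),
    selected = .data$pass_n_qtl & .data$pass_ci & .data$pass_pve)
  attr(audit, "thresholds") <- list(min_n_qtl = config$min_n_qtl,
                                    max_ci = max_ci,
                                    min_mean_pve = config$min_mean_pve)
  out <- mqtls[audit$selected, , drop = FALSE]
  attr(out, "audit") <- audit
  out
}

#' Physical-distance filter for candidate-gene analysis
#'
#' Keeps MQTL whose flanking markers are less than `max_span_bp` apart
#' (strictly). MQTL with an undefined span are excluded, with the reason
#' recorded in the audit.
#'
#' @inheritParams loffler_select
#' @return the retained rows, with attribute `"audit"`.
#' @export
physical_filter <- function(mqtls, config = selection_config()) {
  span <- if ("span_bp" %in% names(mqtls)) mqtls$span_bp
          else mqtls$span_mb * 1e6
  keep <- !is.na(span) & span < config$max_span_bp
  audit <- tibble::tibble(
    mqtl_id = mqtls$mqtl_id, span_bp = span, pass_span = keep,
    reason = ifelse(is.na(span), "span undefined",
                    ifelse(keep, "", "span >= threshold")))
  out <- mqtls[keep, , drop = FALSE]
  attr(out, "audit") <- audit
  out
}

#' @rdname loffler_select
#' @param x result of [loffler_select()] or [physical_filter()].
#' @export
selection_audit <- function(x) attr(x, "audit")
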