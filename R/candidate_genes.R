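#' Gene models overlapping a physical interval
#'
#' Any-overlap on closed bp intervals: a gene partially inside the
#' interval counts. Transposable-element-flagged genes are removed when
#' `exclude_te` is set.
#'
#' @param genes tibble from [read_gff3()].
#' @param chromosome chromosome label; an unknown chromosome yields an
#'   empty result with a warning.
#' @param start_bp,end_bp interval bounds (bp, `start_bp <= end_bp`).
#' @param exclude_te drop TE-flagged genes (default TRUE).
#' @return the overlapping gene rows.
#' @export
genes_in_interval <- function(genes, chromosome, start_bp, end_bp,
                              exclude_te = TRUE) {
  if (start_bp > end_bp) abort("start_bp must be <= end_bp")
  if (!chromosome %in% genes$chromosome) {
    warn(paste0("no gene models on chromosome ", chromosome))
    return(genes[0, , drop = FALSE])
  }
  hit <- genes$chromosome == chromosome &
    genes$start <= end_bp & genes$end >= start_bp
  if (exclude_te) hit <- hit & !genes$is_te
  genes[hit, , drop = FALSE]
}

#' Genes upregulated under stress relative to control
#'
#' For each (stress, control) condition pair, a gene is reported when
#' `tpm_stress / max(tpm_control, epsilon) >= min_fold` and
#' `tpm_stress > 0`. The reported fold change is capped at `fold_cap`
#' (relevant when the control is zero). Expression is summarized per
#' condition as the maximum tpm over tissues/stages, i.e. a gene counts
#' as stress-upregulated if any tissue shows the induction.
#'
#' @param expr expression tibble ([read_expression_matrix()]).
#' @param gene_ids genes to screen; genes absent from `expr` are skipped
#'   and counted in a coverage warning.
#' @param pairs tibble or data.frame with columns `stress`, `control`
#'   naming conditions present in `expr`.
#' @param min_fold fold-change threshold (default 2).
#' @param epsilon floor for the control tpm (default 0.01).
#' @param fold_cap reported fold changes are capped here (default 1000).
#' @return tibble `gene_id`, `stress`, `control`, `fold` (the largest
#'   passing per-tissue fold for that gene and pair).
#' @export
upregulated_genes <- function(expr, gene_ids, pairs, min_fold = 2,
                              epsilon = 0.01, fold_cap = 1000) {
  pairs <- tibble::as_tibble(pairs)
  missing_cond <- setdiff(unique(c(pairs$stress, pairs$control)),
                          unique(expr$condition))
  if (length(missing_cond))
    abort(paste0("condition(s) absent from expression data: ",
                 paste(missing_cond, collapse = ", ")))
  absent <- setdiff(gene_ids, unique(expr$gene_id))
  if (length(absent))
    warn(paste0(length(absent), " of ", length(gene_ids),
                " gene(s) absent from expression data"))
  sub <- filter(expr, .data$gene_id %in% .env$gene_ids)
  purrr::pmap_dfr(pairs, function(stress, control) {
    s <- filter(sub, .data$condition == .env$stress)
    ctl <- filter(sub, .data$condition == .env$control)
    joined <- inner_join(s, ctl, by = c("gene_id", "tissue", "stage"),
                         suffix = c("_stress", "_control")) |>
      mutate(fold = pmin(.data$tpm_stress /
                           pmax(.data$tpm_control, .env$epsilon),
                         .env$fold_cap)) |>
      filter(.data$tpm_stress > 0, .data$fold >= .env$min_fold) |>
      group_by(.data$gene_id) |>
      summarise(fold = max(.data$fold), .groups = "drop")
    tibble::tibble(gene_id = joined$gene_id, stress = stress,
                   control = control, fold = joined$fold)
  })
}

#' Genes expressed in a tissue/stage above a tpm threshold
#'
#' The threshold is strict (`tpm > min_tpm`), matching the reference
#' screens: > 1 tpm for general tissue expression, > 2 tpm for high grain
#' expression.
#'
#' @inheritParams upregulated_genes
#' @param tissue tissue to screen (e.g. `"grain"`, `"spike"`).
#' @param stage developmental stage; `NULL` means any stage.
#' @param min_tpm strict lower threshold (default 1).
#' @return tibble `gene_id`, `tissue`, `stage`, `tpm` of passing records.
#' @export
tissue_expressed <- function(expr, gene_ids, tissue, stage = NULL,
                             min_tpm = 1) {
  if (min_tpm < 0) abort("min_tpm must be >= 0")
  out <- expr |>
    filter(.data$gene_id %in% .env$gene_ids, .data$tissue == .env$tissue)
  if (!is.null(stage)) out <- filter(out, .data$stage == .env$stage)
  filter(out, .data$tpm > .env$min_tpm) |>
    select("gene_id", "tissue", "stage", "tpm")
}

#' Candidate-gene report per selected meta-QTL
#'
#' For each MQTL the gene models overlapping its flanking-marker physical
#' interval are extracted (TE excluded), then screened for stress
#' upregulation and tissue expression.
#'
#' @param mqtls selected MQTL tibble carrying `mqtl_id`, `chromosome`,
#'   `left_bp`, `right_bp`.
#' @param genes tibble from [read_gff3()].
#' @param expr expression tibble, or `NULL` to skip expression screens.
#' @param pairs stress/control condition pairs (see
#'   [upregulated_genes()]); `NULL` to skip.
#' @param tissues character vector of tissues for the `> min_tpm` screen.
#' @param min_fold,min_tpm thresholds for the two screens.
#' @return tibble, one row per MQTL: `mqtl_id`, `n_genes`, `genes`
#'   (list-column of gene ids), `n_upregulated`, `upregulated`
#'   (list-column), `tissue_expressed` (list-column). Attribute
#'   `"grand_total"` holds the total TE-excluded gene count.
#' @export
build_report <- function(mqtls, genes, expr = NULL, pairs = NULL,
                         tissues = character(), min_fold = 2, min_tpm = 1) {
  rows <- purrr::pmap(
    list(mqtls$mqtl_id, mqtls$chromosome, mqtls$left_bp, mqtls$right_bp),
    function(id, chr, bp1, bp2) {
      if (is.na(bp1) || is.na(bp2)) {
        g <- genes[0, , drop = FALSE]
      } else {
        g <- genes_in_interval(genes, chr, min(bp1, bp2), max(bp1, bp2),
                               exclude_te = TRUE)
      }
      up <- if (!is.null(expr) && !is.null(pairs) && nrow(g)) {
        suppressWarnings(
          upregulated_genes(expr, g$gene_id, pairs, min_fold = min_fold))
      } else tibble::tibble(gene_id = character(), stress = character(),
                            control = character(), fold = double())
      te <- if (!is.null(expr) && length(tissues) && nrow(g)) {
        bind_rows(purrr::map(tissues, ~tissue_expressed(
          expr, g$gene_id, .x, min_tpm = min_tpm)))
      } else tibble::tibble(gene_id = character(), tissue = character(),
                            stage = character(), tpm = double())
      tibble::tibble(mqtl_id = id, n_genes = nrow(g),
                     genes = list(g$gene_id),
                     n_upregulated = length(unique(up$gene_id)),
                     upregulated = list(up), tissue_expressed = list(te))
    })
  out <- bind_rows(rows)
  attr(out, "grand_total") <- sum(out$n_genes)
  out
}
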