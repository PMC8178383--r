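#' Summary statistics of a meta-analysis run
#'
#' Computes the bookkeeping the reference study reports: classification
#' counts (which must partition the projected set), per-chromosome QTL and
#' MQTL counts, CI statistics (mean/min/max, cM) for the original,
#' projected and meta-QTL intervals, and the two reduction percentages:
#' `reduction_pct_loci = 100 * (n_projected - n_mqtl) / n_projected` and
#' `reduction_pct_ci = 100 * (1 - mean CI_mqtl / mean CI_original)`.
#'
#' Displayed cM means are rounded to one decimal and reductions to whole
#' percent (the source's precision); the returned object keeps full
#' precision.
#'
#' @param projected projected-QTL tibble (with `ci95`, optionally
#'   `ci_original`).
#' @param mqtls MQTL tibble (with `ci_left`, `ci_right` or `ci_width`,
#'   `n_qtl`, `chromosome`).
#' @param assignments classification tibble (`qtl_id`, `status`).
#' @return object of class `mqtl_run_summary`.
#' @export
summarize_run <- function(projected, mqtls, assignments) {
  if (!nrow(projected)) abort("no projected QTL to summarize")
  tab <- table(factor(assignments$status,
                      levels = c("grouped", "single", "unassigned")))
  n_proj <- nrow(projected)
  if (sum(tab) != n_proj)
    abort("classification counts do not partition the projected QTL set")
  ci_width <- if ("ci_width" %in% names(mqtls)) mqtls$ci_width
              else mqtls$ci_right - mqtls$ci_left
  ci_stats <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(mean = NA_real_, min = NA_real_,
                             max = NA_real_))
    c(mean = mean(x), min = min(x), max = max(x))
  }
  chrom_col <- if ("chromosome_cons" %in% names(projected))
    "chromosome_cons" else "chromosome"
  per_chromosome <- full_join(
    count(projected, chromosome = .data[[chrom_col]], name = "n_qtl"),
    count(mqtls, .data$chromosome, name = "n_mqtl"),
    by = "chromosome") |>
    mutate(across(c("n_qtl", "n_mqtl"), ~tidyr::replace_na(.x, 0L))) |>
    arrange(.data$chromosome)
  orig <- ci_stats(projected$ci_original)
  mq <- ci_stats(ci_width)
  structure(list(
    n_projected = n_proj,
    n_grouped = as.integer(tab[["grouped"]]),
    n_single = as.integer(tab[["single"]]),
    n_unassigned = as.integer(tab[["unassigned"]]),
    n_mqtl = nrow(mqtls),
    per_chromosome = per_chromosome,
    ci_stats_original = orig,
    ci_stats_projected = ci_stats(projected$ci95),
    ci_stats_mqtl = mq,
    reduction_pct_loci = 100 * (n_proj - nrow(mqtls)) / n_proj,
    reduction_pct_ci = if (is.na(orig[["mean"]]) || is.na(mq[["mean"]]))
      NA_real_ else 100 * (1 - mq[["mean"]] / orig[["mean"]])),
    class = "mqtl_run_summary")
}

#' @export
print.mqtl_run_summary <- function(x, ...) {
  cat("Meta-QTL run summary\n")
  cat(sprintf("  projected QTL: %d (grouped %d, single %d, unassigned %d)\n",
              x$n_projected, x$n_grouped, x$n_single, x$n_unassigned))
  cat(sprintf("  MQTL: %d  |  locus reduction: %d%%\n",
              x$n_mqtl, round(x$reduction_pct_loci)))
  fmt <- function(s) if (is.na(s[["mean"]])) "n/a" else
    sprintf("mean %.1f (%.1f-%.1f) cM", s[["mean"]], s[["min"]], s[["max"]])
  cat("  CI original: ", fmt(x$ci_stats_original), "\n")
  cat("  CI projected:", fmt(x$ci_stats_projected), "\n")
  cat("  CI MQTL:     ", fmt(x$ci_stats_mqtl), "\n")
  if (!is.na(x$reduction_pct_ci))
    cat(sprintf("  CI reduction: %d%%\n", round(x$reduction_pct_ci)))
  invisible(x)
}

#' @method glance mqtl_run_summary
#' @export
glance.mqtl_run_summary <- function(x, ...) {
  tibble::tibble(n_projected = x$n_projected, n_mqtl = x$n_mqtl,
                 n_grouped = x$n_grouped, n_single = x$n_single,
                 n_unassigned = x$n_unassigned,
                 mean_ci_mqtl = x$ci_stats_mqtl[["mean"]],
                 reduction_pct_loci = x$reduction_pct_loci,
                 reduction_pct_ci = x$reduction_pct_ci)
}

#' Write the publication-style output tables
#'
#' Emits `mqtl_table.tsv` (MQTL catalogue schema), `selected.tsv`,
#' `genes.tsv` and `summary.json` into `out_dir`. Output is byte-stable
#' for identical inputs (fixed column order, full-precision JSON).
#'
#' @param summary an `mqtl_run_summary`.
#' @param mqtls MQTL tibble.
#' @param selected selected-MQTL tibble (may be empty).
#' @param reports candidate-gene report ([build_report()]) or `NULL`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
emit_tables <- function(summary, mqtls, selected = NULL, reports = NULL,
                        out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flatten_members <- function(x) {
    if ("members" %in% names(x))
      x$members <- purrr::map_chr(x$members, paste, collapse = ";")
    x
  }
  paths <- character()
  p <- file.path(out_dir, "mqtl_table.tsv")
  readr::write_tsv(flatten_members(mqtls), p)
  paths <- c(paths, p)
  p <- file.path(out_dir, "selected.tsv")
  sel <- selected %||% mqtls[0, , drop = FALSE]
  readr::write_tsv(flatten_members(sel), p)
  paths <- c(paths, p)
  if (!is.null(reports)) {
    p <- file.path(out_dir, "genes.tsv")
    readr::write_tsv(select(reports, "mqtl_id", "n_genes",
                            "n_upregulated"), p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "summary.json")
  js <- summary
  class(js) <- NULL
  js$per_chromosome <- as.data.frame(js$per_chromosome)
  jsonlite::write_json(js, p, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  paths <- c(paths, p)
  invisible(paths)
}

#' Run the full meta-QTL pipeline
#'
#' Chains projection, per-chromosome meta-analysis, promising-MQTL
#' selection, the physical filter and (when an annotation is supplied)
#' candidate-gene screening, then summarizes. With `out_dir` set, the
#' publication-style tables and `summary.json` are written; re-running
#' with identical inputs reproduces them byte for byte.
#'
#' @param qtl study-QTL tibble ([read_qtl_table()] schema).
#' @param study_maps study-map tibble (`study_id`, `marker`, `cm`).
#' @param consensus_map consensus-map tibble.
#' @param genes,expr optional annotation and expression tibbles.
#' @param pairs optional stress/control condition pairs for the
#'   upregulation screen.
#' @param selection a [selection_config()].
#' @param kmax,restarts,seed,tol,id_prefix passed to
#'   [run_meta_analysis()].
#' @param out_dir optional output directory for [emit_tables()].
#' @param verbose log per-stage counts via `message()`.
#' @return object of class `metaqtl_pipeline`: list with `projection`,
#'   `meta`, `selected`, `gene_report`, `summary`.
#' @export
run_pipeline <- function(qtl, study_maps, consensus_map, genes = NULL,
                         expr = NULL, pairs = NULL,
                         selection = selection_config(),
                         kmax = 10, restarts = 10, seed = 42, tol = 1e-8,
                         id_prefix = "durumMQTL", out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("projection: %d QTL in", nrow(qtl))
  proj <- project_qtl(qtl, study_maps, consensus_map)
  say("projection: %d projected, %d rejected",
      nrow(proj$projected), nrow(proj$rejected))
  meta <- run_meta_analysis(proj$projected, consensus_map, kmax = kmax,
                            restarts = restarts, seed = seed, tol = tol,
                            id_prefix = id_prefix)
  say("meta-analysis: %d MQTL", nrow(meta$mqtl))
  sel <- loffler_select(meta$mqtl, selection)
  say("selection: %d of %d MQTL pass the promising-MQTL criteria",
      nrow(sel), nrow(meta$mqtl))
  sel <- physical_filter(sel, selection)
  say("physical filter: %d MQTL retained", nrow(sel))
  gene_report <- NULL
  if (!is.null(genes) && nrow(sel)) {
    gene_report <- build_report(sel, genes, expr = expr, pairs = pairs)
    say("candidate genes: %d total in %d MQTL",
        attr(gene_report, "grand_total"), nrow(gene_report))
  }
  summ <- summarize_run(proj$projected, meta$mqtl, meta$assignments)
  if (!is.null(out_dir))
    emit_tables(summ, meta$mqtl, sel, gene_report, out_dir)
  structure(list(projection = proj, meta = meta, selected = sel,
                 gene_report = gene_report, summary = summ),
            class = "metaqtl_pipeline")
}

#' @export
print.metaqtl_pipeline <- function(x, ...) {
  print(x$summary)
  cat("  selected MQTL:", nrow(x$selected), "\n")
  if (!is.null(x$gene_report))
    cat("  candidate genes:", attr(x$gene_report, "grand_total"), "\n")
  invisible(x)
}
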