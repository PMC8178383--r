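#' Derive meta-QTL from a chosen mixture fit
#'
#' Each projected QTL is assigned to its argmax-responsibility component.
#' Components with at least two members become meta-QTL: the MQTL peak is
#' the inverse-variance weighted mean of the member peaks, its 95% CI width
#' is `3.92 * sqrt(1 / sum_i 1/s_i^2)` (the pooled standard error of the
#' peak, so never wider than any member CI), and the flanking markers are
#' the consensus markers nearest outside the CI bounds (the terminal marker
#' when the CI runs past the end of the map), carried with their physical
#' positions. Single-member components are returned as candidates for
#' "single QTL" status, not as MQTL.
#'
#' @param fit chosen `mqtl_mixture` for one chromosome.
#' @param qtls projected QTL of the same chromosome, in the order used for
#'   the fit (needs `qtl_id`, `peak_cons`, `sd`, `trait`, and optionally
#'   `pve`).
#' @param consensus_map tibble from [read_consensus_map()].
#' @param chromosome chromosome label for the output.
#' @return list with `mqtl` (tibble: `component`, `chromosome`, `peak`,
#'   `ci95`, `ci_left`, `ci_right`, `n_qtl`, `traits`, `members`,
#'   `mean_pve`, `left_marker`, `left_bp`, `right_marker`, `right_bp`,
#'   `span_bp`), `assignment` (component index per QTL) and `singles`
#'   (qtl_ids of lone-member components).
#' @export
derive_mqtl <- function(fit, qtls, consensus_map, chromosome = NULL) {
  stopifnot(nrow(qtls) == fit$n)
  chromosome <- chromosome %||% qtls$chromosome_cons[1] %||% qtls$chromosome[1]
  comp <- max.col(fit$responsibilities, ties.method = "first")
  cmap <- consensus_map[consensus_map$chromosome == chromosome, , drop = FALSE]
  cmap <- cmap[order(cmap$cm), , drop = FALSE]

  groups <- split(seq_len(fit$n), comp)
  rows <- purrr::map(groups, function(idx) {
    if (length(idx) < 2) return(NULL)
    x <- qtls$peak_cons[idx]
    s <- qtls$sd[idx]
    w <- 1 / s^2
    peak <- sum(w * x) / sum(w)
    ci95 <- 3.92 * sqrt(1 / sum(w))
    ci_l <- peak - ci95 / 2
    ci_r <- peak + ci95 / 2
    fl <- flank_marker(cmap, ci_l, side = "left")
    fr <- flank_marker(cmap, ci_r, side = "right")
    pve <- if ("pve" %in% names(qtls)) qtls$pve[idx] else NA_real_
    tibble::tibble(
      component = comp[idx[1]], chromosome = chromosome,
      peak = peak, ci95 = ci95, ci_left = ci_l, ci_right = ci_r,
      n_qtl = length(idx),
      traits = paste(sort(unique(qtls$trait[idx])), collapse = ", "),
      members = list(qtls$qtl_id[idx]),
      mean_pve = if (all(is.na(pve))) NA_real_ else mean(pve, na.rm = TRUE),
      left_marker = fl$marker, left_bp = fl$bp,
      right_marker = fr$marker, right_bp = fr$bp,
      span_bp = abs(fr$bp - fl$bp))
  })
  mqtl <- bind_rows(rows)
  if (nrow(mqtl)) mqtl <- arrange(mqtl, .data$peak)
  singles <- qtls$qtl_id[comp %in% as.integer(
    names(groups)[lengths(groups) == 1])]
  list(mqtl = mqtl, assignment = comp, singles = singles)
}

# nearest consensus marker outside a CI bound; terminal marker fallback
flank_marker <- function(cmap, bound, side) {
  if (!nrow(cmap))
    return(list(marker = NA_character_, bp = NA_real_))
  idx <- if (side == "left") {
    cand <- which(cmap$cm <= bound)
    if (length(cand)) max(cand) else 1L
  } else {
    cand <- which(cmap$cm >= bound)
    if (length(cand)) min(cand) else nrow(cmap)
  }
  list(marker = cmap$marker[idx], bp = cmap$bp[idx])
}

#' Classify projected QTL against the derived meta-QTL
#'
#' Statuses follow the reference study's bookkeeping:
#' * `grouped` — member of exactly one MQTL, its peak lies inside that
#'   MQTL's CI and its own CI overlaps no other MQTL;
#' * `unassigned` — its CI overlaps two or more MQTL CIs, or it belongs to
#'   a multi-member component but its peak falls outside every MQTL CI, or
#'   it is a lone-member QTL whose CI overlaps an MQTL;
#' * `single` — lone-member component whose CI overlaps no MQTL.
#'
#' Interval overlap is closed on both ends (touching endpoints count).
#'
#' @param qtls projected QTL of one chromosome (with `qtl_id`,
#'   `peak_cons`, `ci_left`, `ci_right`).
#' @param mqtls the `mqtl` tibble from [derive_mqtl()].
#' @param assignment component index per QTL (from [derive_mqtl()]);
#'   `NULL` treats every QTL as a lone-member candidate.
#' @return tibble `qtl_id`, `status`, `mqtl_id` (NA unless grouped).
#' @export
classify_qtl <- function(qtls, mqtls, assignment = NULL) {
  n <- nrow(qtls)
  if (!nrow(mqtls)) {
    return(tibble::tibble(qtl_id = qtls$qtl_id,
                          status = "single", mqtl_id = NA_character_))
  }
  has_id <- "mqtl_id" %in% names(mqtls)
  member_of <- rep(NA_integer_, n)
  if (!is.null(assignment)) {
    for (j in seq_len(nrow(mqtls))) {
      member_of[assignment == mqtls$component[j]] <- j
    }
  }
  status <- character(n)
  mqtl_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ov <- which(qtls$ci_left[i] <= mqtls$ci_right &
                qtls$ci_right[i] >= mqtls$ci_left)
    j <- member_of[i]
    if (length(ov) >= 2) {
      status[i] <- "unassigned"
    } else if (!is.na(j)) {
      peak_inside <- qtls$peak_cons[i] >= mqtls$ci_left[j] &&
        qtls$peak_cons[i] <= mqtls$ci_right[j]
      other_ov <- setdiff(ov, j)
      status[i] <- if (peak_inside && !length(other_ov)) "grouped"
                   else "unassigned"
      if (status[i] == "grouped")
        mqtl_id[i] <- if (has_id) mqtls$mqtl_id[j] else as.character(j)
    } else {
      status[i] <- if (length(ov)) "unassigned" else "single"
    }
  }
  tibble::tibble(qtl_id = qtls$qtl_id, status = status, mqtl_id = mqtl_id)
}

#' Per-chromosome meta-analysis of projected QTL
#'
#' Chromosomes are processed independently: the heteroscedastic Gaussian
#' mixture is fitted for `k = 1 .. min(n, kmax)`, the number of meta-QTL
#' is chosen by criterion vote ([select_best_k()]), meta-QTL are derived
#' and member QTL classified. MQTL identifiers are assigned per
#' chromosome in order of peak position as `<prefix><chromosome>.<index>`.
#' A chromosome carrying a single projected QTL is not fitted; its QTL is
#' a "single" by construction.
#'
#' @param projected projected QTL tibble ([project_qtl()]'s `projected`
#'   element, or anything with `qtl_id`, `chromosome_cons` (or
#'   `chromosome`), `peak_cons`, `sd`, `ci_left`, `ci_right`, `trait`,
#'   `pve`).
#' @param consensus_map tibble from [read_consensus_map()].
#' @param kmax maximum number of components per chromosome (default 10).
#' @param restarts,seed,tol passed to [fit_mixture()].
#' @param id_prefix prefix for MQTL identifiers (default `"durumMQTL"`).
#' @return object of class `meta_analysis`: list with `mqtl` (tibble over
#'   all chromosomes, with `mqtl_id`), `assignments` (tibble `qtl_id`,
#'   `status`, `mqtl_id`) and `fits` (per-chromosome list of all
#'   `mqtl_mixture` fits plus the chosen `k`).
#' @export
run_meta_analysis <- function(projected, consensus_map, kmax = 10,
                              restarts = 10, seed = 42, tol = 1e-8,
                              id_prefix = "durumMQTL") {
  if (!nrow(projected)) abort("no projected QTL supplied")
  chrom_col <- if ("chromosome_cons" %in% names(projected))
    "chromosome_cons" else "chromosome"
  projected <- arrange(projected, .data[[chrom_col]], .data$peak_cons)
  chroms <- unique(projected[[chrom_col]])

  all_mqtl <- list(); all_assign <- list(); fits <- list()
  for (chr in chroms) {
    sub <- projected[projected[[chrom_col]] == chr, , drop = FALSE]
    n <- nrow(sub)
    if (n == 1) {
      all_assign[[chr]] <- tibble::tibble(
        qtl_id = sub$qtl_id, status = "single", mqtl_id = NA_character_)
      next
    }
    kk <- seq_len(min(n, kmax))
    chr_fits <- purrr::map(kk, ~fit_mixture(
      sub$peak_cons, sub$sd, k = .x, restarts = restarts,
      seed = seed + .x, tol = tol))
    best <- select_best_k(chr_fits)
    der <- derive_mqtl(best, sub, consensus_map, chromosome = chr)
    mq <- der$mqtl
    if (nrow(mq)) {
      mq$mqtl_id <- paste0(id_prefix, chr, ".", seq_len(nrow(mq)))
      mq <- relocate(mq, "mqtl_id")
    }
    all_assign[[chr]] <- classify_qtl(sub, mq, der$assignment)
    all_mqtl[[chr]] <- mq
    fits[[chr]] <- list(fits = chr_fits, chosen_k = best$k, chosen = best)
  }
  structure(list(mqtl = bind_rows(all_mqtl),
                 assignments = bind_rows(all_assign),
                 fits = fits,
                 projected = projected),
            class = "meta_analysis")
}

#' @export
print.meta_analysis <- function(x, ...) {
  cat("Meta-QTL analysis\n")
  cat("  projected QTL:", nrow(x$projected), "\n")
  cat("  MQTL:         ", nrow(x$mqtl), "on",
      length(unique(x$mqtl$chromosome)), "chromosome(s)\n")
  tab <- table(x$assignments$status)
  cat("  classification:",
      paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy meta_analysis
#' @export
tidy.meta_analysis <- function(x, ...) x$mqtl

#' @method glance meta_analysis
#' @export
glance.meta_analysis <- function(x, ...) {
  tab <- table(factor(x$assignments$status,
                      levels = c("grouped", "single", "unassigned")))
  tibble::tibble(n_projected = nrow(x$projected),
                 n_mqtl = nrow(x$mqtl),
                 n_grouped = as.integer(tab[["grouped"]]),
                 n_single = as.integer(tab[["single"]]),
                 n_unassigned = as.integer(tab[["unassigned"]]))
}

#' Per-chromosome model-selection report
#'
#' @param x `meta_analysis` object.
#' @return tibble of criterion values for every chromosome and candidate
#'   `k`, with the chosen `k` flagged.
#' @export
model_selection_report <- function(x) {
  purrr::imap_dfr(x$fits, function(f, chr) {
    purrr::map_dfr(f$fits, glance) |>
      mutate(chromosome = chr, chosen = .data$k == f$chosen_k,
             .before = 1)
  })
}
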