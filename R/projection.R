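#' Population-type constants for the empirical 95% CI formula
#'
#' The 95% confidence interval of a QTL peak is estimated empirically as
#' `k / (N * R2)` where `N` is the mapping population size, `R2` the
#' proportion of phenotypic variance explained and `k` a constant that
#' depends on the population type: 163 for recombinant inbred lines (RIL),
#' 287 for doubled haploids (DH) and 530 for F2 and backcross (BC)
#' populations. Backcross inbred lines (BIL) default to the BC constant;
#' "BP" (biparental populations of unstated structure) default to the RIL
#' constant. Both defaults are overridable here.
#'
#' @param ... named overrides, e.g. `guo_constants(BP = 287)`.
#' @return named numeric vector of constants per population type.
#' @export
guo_constants <- function(...) {
  k <- c(RIL = 163, DH = 287, F2 = 530, BC = 530, BIL = 530, BP = 163)
  user <- c(...)
  bad <- setdiff(names(user), names(k))
  if (length(bad))
    abort(paste0("unknown population type(s): ", paste(bad, collapse = ", "),
                 "; accepted: ", paste(names(k), collapse = ", ")))
  k[names(user)] <- user
  k
}

#' Empirical 95% confidence-interval width for a QTL peak
#'
#' @param pop_type population type (`RIL`, `DH`, `F2`, `BC`, `BIL`, `BP`);
#'   vectorized.
#' @param pop_size mapping population size `N >= 2`.
#' @param pve proportion of phenotypic variance explained, in (0, 1].
#' @param constants constants per population type, see [guo_constants()].
#' @return CI width in cM: `k / (N * R2)`.
#' @export
#' @examples
#' guo_ci95("RIL", 100, 0.10)  # 16.3 cM
guo_ci95 <- function(pop_type, pop_size, pve, constants = guo_constants()) {
  n <- max(length(pop_type), length(pop_size), length(pve))
  pop_type <- rep_len(pop_type, n)
  pop_size <- rep_len(pop_size, n)
  pve <- rep_len(pve, n)
  unknown <- setdiff(unique(pop_type[!is.na(pop_type)]), names(constants))
  if (length(unknown))
    abort(paste0("unknown population type(s): ",
                 paste(unknown, collapse = ", "), "; accepted: ",
                 paste(names(constants), collapse = ", ")))
  if (any(pve <= 0, na.rm = TRUE))
    abort("pve must be > 0 (CI width is undefined at pve = 0)")
  if (any(pve > 1, na.rm = TRUE)) abort("pve must be <= 1")
  if (any(pop_size < 2, na.rm = TRUE)) abort("pop_size must be >= 2")
  unname(constants[pop_type]) / (pop_size * pve)
}

#' Homothetic transfer of a position between two maps
#'
#' Affine map fixing the two flanking markers:
#' `c_L + (peak - a_L) * (c_R - c_L) / (a_R - a_L)`, where `a` are study-map
#' and `c` consensus-map positions. All arguments are vectorized.
#'
#' @param peak_cm peak position on the study map, within `[left_study,
#'   right_study]`.
#' @param left_study,right_study flanking-marker positions on the study map
#'   (`left_study < right_study`).
#' @param left_cons,right_cons the same markers' positions on the consensus
#'   map.
#' @return peak position on the consensus map (cM).
#' @export
#' @examples
#' project_position(15, 10, 20, 100, 120)  # 110
project_position <- function(peak_cm, left_study, right_study,
                             left_cons, right_cons) {
  if (any(right_study <= left_study, na.rm = TRUE))
    abort("zero-length or inverted study flanking interval")
  out_of_range <- peak_cm < left_study | peak_cm > right_study
  if (any(out_of_range, na.rm = TRUE))
    abort("peak outside the flanking interval on the study map")
  left_cons + (peak_cm - left_study) *
    (right_cons - left_cons) / (right_study - left_study)
}

#' Project study QTL onto the consensus map
#'
#' Each QTL is transferred by homothetic scaling between its two flanking
#' markers, which must be present (on the same chromosome) both on the
#' study map and on the consensus map — QTL whose flanking markers are
#' absent from the consensus map are rejected, mirroring the projection
#' filter of the reference study. The 95% CI on the consensus map comes
#' from the empirical population formula ([guo_ci95()]) when `pop_size`
#' and `pve` are available, otherwise from the consensus-map distance
#' between the projected flanking markers; the peak standard deviation is
#' `ci95 / 3.92` (a two-sided normal 95% interval).
#'
#' @param qtl tibble from [read_qtl_table()].
#' @param study_maps tibble of study-map positions with columns `study_id`,
#'   `marker`, `cm` (optionally `chromosome`).
#' @param consensus_map tibble from [read_consensus_map()].
#' @param constants see [guo_constants()].
#' @param low_conf_frac flanking intervals spanning more than this fraction
#'   of the consensus chromosome are flagged `low_confidence` (projection
#'   still performed).
#' @return object of class `qtl_projection`: a list with `projected` (a
#'   tibble adding `peak_cons`, `ci95`, `sd`, `ci_left`, `ci_right`,
#'   `ci_left_clamped`, `ci_right_clamped`, `low_confidence`) and
#'   `rejected` (tibble `qtl_id`, `reason`).
#' @export
project_qtl <- function(qtl, study_maps, consensus_map,
                        constants = guo_constants(),
                        low_conf_frac = 1 / 3) {
  smap_key <- paste(study_maps$study_id, study_maps$marker)
  s_cm <- setNames(study_maps$cm, smap_key)
  c_cm <- setNames(consensus_map$cm, consensus_map$marker)
  c_chr <- setNames(consensus_map$chromosome, consensus_map$marker)
  chr_len <- consensus_map |>
    group_by(.data$chromosome) |>
    summarise(len = max(.data$cm), .groups = "drop")
  chr_len <- setNames(chr_len$len, chr_len$chromosome)

  rows <- purrr::pmap(qtl, function(...) {
    q <- list(...)
    reject <- function(reason) list(status = "rejected", reason = reason)
    sl <- unname(s_cm[paste(q$study_id, q$left_marker)])
    sr <- unname(s_cm[paste(q$study_id, q$right_marker)])
    if (is.na(sl) || is.na(sr))
      return(reject("flanking markers absent from study map"))
    if (!(q$left_marker %in% names(c_cm)) ||
        !(q$right_marker %in% names(c_cm)))
      return(reject("flanking markers absent from consensus map"))
    chrs <- c(c_chr[[q$left_marker]], c_chr[[q$right_marker]])
    if (chrs[1] != chrs[2])
      return(reject("flanking markers on different consensus chromosomes"))
    if (sl > sr) {  # orient by study-map order
      tmp <- sl; sl <- sr; sr <- tmp
      lm <- q$right_marker; rm_ <- q$left_marker
    } else {
      lm <- q$left_marker; rm_ <- q$right_marker
    }
    if (sr == sl) return(reject("zero-length study flanking interval"))
    if (q$peak_cm < sl || q$peak_cm > sr)
      return(reject("peak outside the flanking interval"))
    cl <- c_cm[[lm]]; cr <- c_cm[[rm_]]
    peak_cons <- project_position(q$peak_cm, sl, sr, cl, cr)
    has_pop <- !is.null(q$pop_size) && !is.na(q$pop_size) &&
      !is.null(q$pve) && !is.na(q$pve) &&
      !is.null(q$pop_type) && !is.na(q$pop_type)
    ci95 <- if (has_pop) {
      guo_ci95(q$pop_type, q$pop_size, q$pve, constants)
    } else {
      abs(cr - cl)
    }
    if (!is.finite(ci95) || ci95 <= 0)
      return(reject("non-positive confidence interval"))
    len <- chr_len[[chrs[1]]]
    list(status = "ok", chromosome_cons = chrs[1], peak_cons = peak_cons,
         ci95 = ci95, sd = ci95 / 3.92,
         ci_left = peak_cons - ci95 / 2, ci_right = peak_cons + ci95 / 2,
         ci_left_clamped = max(0, peak_cons - ci95 / 2),
         ci_right_clamped = min(len, peak_cons + ci95 / 2),
         low_confidence = abs(cr - cl) > low_conf_frac * len)
  })

  ok <- purrr::map_chr(rows, "status") == "ok"
  rejected <- tibble::tibble(
    qtl_id = qtl$qtl_id[!ok],
    reason = purrr::map_chr(rows[!ok], "reason"))
  projected <- bind_cols(
    qtl[ok, ],
    purrr::map_dfr(rows[ok], ~tibble::as_tibble(.x[-1])))
  structure(list(projected = projected, rejected = rejected),
            class = "qtl_projection")
}

#' @export
print.qtl_projection <- function(x, ...) {
  cat("QTL projection onto consensus map\n")
  cat("  projected:", nrow(x$projected), "QTL\n")
  cat("  rejected: ", nrow(x$rejected), "QTL\n")
  if (nrow(x$rejected)) {
    tab <- table(x$rejected$reason)
    for (r in names(tab)) cat("    -", tab[[r]], r, "\n")
  }
  invisible(x)
}

#' @method tidy qtl_projection
#' @export
tidy.qtl_projection <- function(x, ...) x$projected

#' @method glance qtl_projection
#' @export
glance.qtl_projection <- function(x, ...) {
  tibble::tibble(n_projected = nrow(x$projected),
                 n_rejected = nrow(x$rejected),
                 mean_ci95 = mean(x$projected$ci95),
                 n_low_confidence = sum(x$projected$low_confidence))
}
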