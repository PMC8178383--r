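#' Configuration for the synthetic meta-QTL scenario
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' QTL observed in independent studies scatter around a set of true
#' cluster positions with per-QTL noise implied by the empirical CI
#' formula (`sd = guo_ci95(type, N, R2) / 3.92`), study maps are locally
#' affine distortions of the consensus map (so two-anchor projection is
#' exact by construction), and gene annotations carry planted
#' transposable-element flags and stress-responsive expression.
#'
#' The default scenario echoes the scale of the reference study: three
#' chromosomes with three well-separated QTL clusters each, 8–12 QTL per
#' cluster (so roughly 24–36 QTL per chromosome, within the study's 11–40
#' per-chromosome range), population sizes 85–249 drawn mostly from RIL
#' populations, PVE between 0.05 and 0.40, and a marker density (200 per
#' chromosome, roughly 0.8 cM spacing) coarse relative to a real consensus
#' map but fine enough that flanking-marker intervals stay local.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param chromosomes tibble `name`, `len_cm`, `len_bp`, `n_markers`.
#' @param clusters tibble `chromosome`, `pos_cm`, `n_qtl` (`NA` draws
#'   from `n_qtl_range`).
#' @param n_qtl_range inclusive range for per-cluster QTL counts.
#' @param pop_profiles tibble `pop_type`, `weight`, `size_min`,
#'   `size_max` describing the population spectrum.
#' @param pve_range inclusive PVE range, within (0, 1).
#' @param trait_pool trait codes sampled per QTL.
#' @param n_studies number of synthetic studies the QTL are spread over.
#' @param absent_marker_frac fraction of QTL given a flanking marker
#'   absent from the consensus map (exercises projection rejection).
#' @param map_distortion per-interval scale range for study maps.
#' @param noise_scale multiplier on the positional noise (0 = peaks sit
#'   exactly on their cluster positions).
#' @param n_genes genes per chromosome.
#' @param te_fraction fraction of genes flagged as transposable elements.
#' @param gene_width_bp gene model width.
#' @param conditions tibble `stress`, `control` condition pairs.
#' @param tissues,stages levels used for expression records.
#' @param responsive_frac fraction of non-TE genes planted as
#'   stress-responsive.
#' @param responsive_fold planted stress/control fold change.
#' @return a `sim_config` list.
#' @export
sim_config <- function(
    seed = 42,
    chromosomes = tibble::tibble(name = c("1A", "2B", "3B"), len_cm = 160,
                                 len_bp = 600e6, n_markers = 200),
    clusters = NULL,
    n_qtl_range = c(8, 12),
    pop_profiles = tibble::tibble(
      pop_type = c("RIL", "DH", "BC", "BIL"),
      weight = c(0.70, 0.15, 0.10, 0.05),
      size_min = c(85, 85, 126, 171),
      size_max = c(249, 185, 134, 171)),
    pve_range = c(0.05, 0.40),
    trait_pool = c("GPC", "YPC", "FHB", "RRT", "NDVI", "LR"),
    n_studies = 6,
    absent_marker_frac = 0,
    map_distortion = c(0.7, 1.3),
    noise_scale = 1,
    n_genes = 150,
    te_fraction = 0.2,
    gene_width_bp = 3000,
    conditions = tibble::tibble(stress = "drought", control = "control"),
    tissues = c("root", "leaf", "spike", "grain"),
    stages = c("seedling", "vegetative", "reproductive"),
    responsive_frac = 0.1,
    responsive_fold = 4) {
  if (is.null(clusters)) {
    # three clusters at 20/50/80% of each chromosome's genetic length
    clusters <- purrr::map2_dfr(chromosomes$name, chromosomes$len_cm,
                                ~tibble::tibble(chromosome = .x,
                                                pos_cm = .y * c(0.2, 0.5,
                                                                0.8),
                                                n_qtl = NA_integer_))
  }
  len <- setNames(chromosomes$len_cm, chromosomes$name)
  if (any(clusters$pos_cm < 0 | clusters$pos_cm > len[clusters$chromosome]))
    abort("cluster positions must lie within their chromosome")
  if (te_fraction < 0 || te_fraction > 1)
    abort("te_fraction must be in [0, 1]")
  if (pve_range[1] <= 0 || pve_range[2] > 1)
    abort("pve_range must lie within (0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

# evaluate expr under a derived seed, restoring the caller's RNG
with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}

#' Generate a synthetic consensus map
#'
#' Markers are evenly spaced with jitter along each chromosome, anchored
#' at both chromosome ends; physical positions are strictly increasing
#' and monotone with the genetic positions. Deterministic under the
#' config seed.
#'
#' @param cfg a [sim_config()].
#' @return consensus-map tibble (`marker`, `chromosome`, `cm`, `bp`).
#' @export
gen_consensus_map <- function(cfg) {
  with_sim_seed(cfg$seed + 1L, {
    purrr::pmap_dfr(cfg$chromosomes, function(name, len_cm, len_bp,
                                              n_markers) {
      stopifnot(n_markers >= 2)
      cm <- seq(0, len_cm, length.out = n_markers)
      if (n_markers > 2) {
        jit <- runif(n_markers - 2, -0.3, 0.3) * len_cm / n_markers
        cm[2:(n_markers - 1)] <- sort(cm[2:(n_markers - 1)] + jit)
      }
      # bp increments proportional to cM with jittered local rate
      inc <- diff(cm) * runif(n_markers - 1, 0.5, 1.5)
      bp <- c(1, 1 + round(cumsum(inc) / sum(inc) * (len_bp - 1)))
      bp <- cummax(bp + seq_len(n_markers) - 1)  # strictly increasing
      tibble::tibble(marker = sprintf("%s_M%03d", name, seq_len(n_markers)),
                     chromosome = name, cm = cm, bp = bp)
    })
  })
}

#' Generate synthetic study QTL with planted ground truth
#'
#' Each cluster contributes `n_qtl` QTL whose observed consensus peaks are
#' the true cluster position plus `Normal(0, s^2)` noise, `s` implied by
#' the empirical CI for the drawn population; peaks are then expressed in
#' the coordinates of a per-study map that distorts every consensus
#' interval by a random scale in `map_distortion` (piecewise affine, so
#' homothetic projection recovers the consensus position exactly). A
#' fraction of QTL can be given a flanking marker missing from the
#' consensus map to exercise the projection filter.
#'
#' @param cfg a [sim_config()].
#' @param consensus_map optional precomputed [gen_consensus_map()] result.
#' @return list with `qtl` (study-QTL tibble readable by the projection
#'   stage), `study_maps` (`study_id`, `marker`, `chromosome`, `cm`) and
#'   `truth` (`qtl_id`, `chromosome`, `cluster`, `true_pos`, `sd`,
#'   `planted_reject`).
#' @export
gen_study_qtl <- function(cfg, consensus_map = gen_consensus_map(cfg)) {
  with_sim_seed(cfg$seed + 2L, {
    studies <- sprintf("S%02d", seq_len(cfg$n_studies))
    # distorted study maps: every study re-scales each consensus interval
    study_maps <- tidyr::expand_grid(study_id = studies,
                                     chromosome = cfg$chromosomes$name) |>
      purrr::pmap_dfr(function(study_id, chromosome) {
        cmap <- consensus_map[consensus_map$chromosome == chromosome, ]
        sc <- runif(nrow(cmap) - 1, cfg$map_distortion[1],
                    cfg$map_distortion[2])
        tibble::tibble(study_id = study_id, marker = cmap$marker,
                       chromosome = chromosome,
                       cm = c(0, cumsum(diff(cmap$cm) * sc)),
                       cons_cm = cmap$cm)
      })

    qtl <- list(); truth <- list(); qid <- 0L
    for (ci in seq_len(nrow(cfg$clusters))) {
      chr <- cfg$clusters$chromosome[ci]
      pos <- cfg$clusters$pos_cm[ci]
      nq <- cfg$clusters$n_qtl[ci]
      if (is.na(nq))
        nq <- cfg$n_qtl_range[1] +
          sample.int(cfg$n_qtl_range[2] - cfg$n_qtl_range[1] + 1L, 1) - 1L
      cmap <- consensus_map[consensus_map$chromosome == chr, ]
      len_cm <- cfg$chromosomes$len_cm[cfg$chromosomes$name == chr]
      for (j in seq_len(nq)) {
        qid <- qid + 1L
        prof <- cfg$pop_profiles[sample(nrow(cfg$pop_profiles), 1,
                                        prob = cfg$pop_profiles$weight), ]
        n_pop <- prof$size_min +
          sample.int(prof$size_max - prof$size_min + 1L, 1) - 1L
        pve <- runif(1, cfg$pve_range[1], cfg$pve_range[2])
        sdq <- guo_ci95(prof$pop_type, n_pop, pve) / 3.92
        obs <- pos + cfg$noise_scale * rnorm(1, 0, sdq)
        obs <- min(max(obs, 0), len_cm)
        below <- max(which(cmap$cm <= obs), 1)
        if (below == nrow(cmap)) below <- nrow(cmap) - 1L
        lm <- cmap$marker[below]; rm_ <- cmap$marker[below + 1L]
        study <- sample(studies, 1)
        smap <- study_maps[study_maps$study_id == study &
                             study_maps$chromosome == chr, ]
        peak_study <- stats::approx(smap$cons_cm, smap$cm, xout = obs)$y
        qtl[[qid]] <- tibble::tibble(
          qtl_id = sprintf("Q%04d", qid), study_id = study,
          trait = sample(cfg$trait_pool, 1), chromosome = chr,
          peak_cm = peak_study, ci_original = NA_real_,
          left_marker = lm, right_marker = rm_,
          lod = round(runif(1, 2.5, 12), 1), pve = pve,
          pop_size = n_pop, pop_type = prof$pop_type)
        truth[[qid]] <- tibble::tibble(
          qtl_id = sprintf("Q%04d", qid), chromosome = chr,
          cluster = ci, true_pos = pos, sd = sdq, planted_reject = FALSE)
      }
    }
    qtl <- bind_rows(qtl); truth <- bind_rows(truth)

    if (cfg$absent_marker_frac > 0) {
      n_rej <- round(cfg$absent_marker_frac * nrow(qtl))
      rej <- sample(nrow(qtl), n_rej)
      ghosts <- purrr::map_dfr(rej, function(i) {
        smap <- study_maps[study_maps$study_id == qtl$study_id[i] &
                             study_maps$chromosome == qtl$chromosome[i], ]
        old <- smap[smap$marker == qtl$right_marker[i], ]
        tibble::tibble(study_id = old$study_id,
                       marker = paste0(old$marker, "_ghost"),
                       chromosome = old$chromosome, cm = old$cm,
                       cons_cm = old$cons_cm)
      })
      qtl$right_marker[rej] <- paste0(qtl$right_marker[rej], "_ghost")
      truth$planted_reject[rej] <- TRUE
      study_maps <- bind_rows(study_maps, ghosts)
    }
    list(qtl = qtl,
         study_maps = select(study_maps, -"cons_cm"),
         truth = truth)
  })
}

#' Generate a synthetic genome annotation and expression records
#'
#' Genes are placed uniformly along each chromosome's physical axis; a
#' configured fraction are flagged transposable elements. Control-level
#' expression is drawn per gene/tissue/stage (log-normal); planted
#' "responsive" genes express the configured stress/control fold change
#' in every tissue, all others fluctuate by a factor in (0.7, 1.4) that
#' can never reach the default 2-fold screen.
#'
#' @param cfg a [sim_config()].
#' @return list with `genes` (same schema as [read_gff3()]),
#'   `expression` (long tibble) and `gene_truth` (`gene_id`, `is_te`,
#'   `responsive`, `fold`).
#' @export
gen_genome_annotation <- function(cfg) {
  with_sim_seed(cfg$seed + 3L, {
    genes <- purrr::pmap_dfr(cfg$chromosomes, function(name, len_cm, len_bp,
                                                       n_markers) {
      start <- sort(sample.int(len_bp - cfg$gene_width_bp, cfg$n_genes))
      tibble::tibble(gene_id = sprintf("%s_G%04d", name,
                                       seq_len(cfg$n_genes)),
                     chromosome = name, start = start,
                     end = start + cfg$gene_width_bp - 1,
                     is_te = runif(cfg$n_genes) < cfg$te_fraction,
                     description = "synthetic gene model")
    })
    genes$description[genes$is_te] <- "transposable element (synthetic)"

    non_te <- which(!genes$is_te)
    n_resp <- round(cfg$responsive_frac * length(non_te))
    resp_idx <- sort(sample(non_te, n_resp))
    responsive <- seq_len(nrow(genes)) %in% resp_idx

    grid <- tidyr::expand_grid(gene_id = genes$gene_id,
                               tissue = cfg$tissues, stage = cfg$stages)
    conds <- unique(c(cfg$conditions$control, cfg$conditions$stress))
    ctl_names <- unique(cfg$conditions$control)
    expr <- purrr::map_dfr(conds, function(cond) {
      base <- grid
      base$condition <- cond
      base
    })
    # control tpm per (gene, tissue, stage), shared across control columns
    ctl_tpm <- setNames(
      round(stats::rlnorm(nrow(grid), meanlog = 0.3, sdlog = 1), 3),
      paste(grid$gene_id, grid$tissue, grid$stage))
    key <- paste(expr$gene_id, expr$tissue, expr$stage)
    is_stress <- !(expr$condition %in% ctl_names)
    fold <- ifelse(expr$gene_id %in% genes$gene_id[responsive],
                   cfg$responsive_fold,
                   round(runif(nrow(expr), 0.7, 1.4), 3))
    expr$tpm <- ifelse(is_stress, round(ctl_tpm[key] * fold, 3),
                       ctl_tpm[key])
    expr <- select(expr, "gene_id", "condition", "tissue", "stage", "tpm")

    list(genes = genes,
         expression = expr,
         gene_truth = tibble::tibble(gene_id = genes$gene_id,
                                     chromosome = genes$chromosome,
                                     start = genes$start, end = genes$end,
                                     is_te = genes$is_te,
                                     responsive = responsive,
                                     fold = ifelse(responsive,
                                                   cfg$responsive_fold, NA)))
  })
}

#' Generate the full synthetic input bundle
#'
#' @param cfg a [sim_config()].
#' @return list: `consensus_map`, `qtl`, `study_maps`, `truth`, `genes`,
#'   `expression`, `gene_truth`.
#' @export
simulate_metaqtl_study <- function(cfg = sim_config()) {
  cmap <- gen_consensus_map(cfg)
  sq <- gen_study_qtl(cfg, cmap)
  ann <- gen_genome_annotation(cfg)
  c(list(consensus_map = cmap), sq, ann)
}

#' Write gene models as a GFF3 file
#'
#' @param genes tibble with `gene_id`, `chromosome`, `start`, `end`,
#'   `is_te`, `description`.
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tmetaqtl\t%s\t%d\t%d\t.\t+\t.\tID=%s;description=%s",
                     genes$chromosome,
                     ifelse(genes$is_te, "transposable_element_gene", "gene"),
                     as.integer(genes$start), as.integer(genes$end),
                     genes$gene_id, genes$description))
  writeLines(lines, path)
  invisible(path)
}
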