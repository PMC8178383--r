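projected_stub <- function(peaks, sds, chromosome = "1A",
                           traits = "GPC", pves = 0.2) {
  n <- length(peaks)
  tibble::tibble(
    qtl_id = sprintf("q%d", seq_len(n)), trait = rep_len(traits, n),
    chromosome_cons = chromosome, peak_cons = peaks, sd = sds,
    ci95 = 3.92 * sds, ci_left = peaks - 1.96 * sds,
    ci_right = peaks + 1.96 * sds, pve = rep_len(pves, n))
}

test_that("MQTL peak and CI pool member evidence", {
  q <- projected_stub(c(14, 16), c(2, 2))
  f <- fit_mixture(q$peak_cons, q$sd, k = 1)
  d <- derive_mqtl(f, q, tiny_consensus_map())
  expect_equal(nrow(d$mqtl), 1)
  expect_equal(d$mqtl$peak, 15)
  expect_equal(d$mqtl$ci95, 3.92 * sqrt(2), tolerance = 1e-9)
  expect_equal(d$mqtl$n_qtl, 2L)
  expect_equal(d$mqtl$mean_pve, 0.2)
  expect_length(d$singles, 0)
})

test_that("the pooled MQTL CI is never wider than any member CI", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    q <- projected_stub(runif(n, 40, 60), runif(n, 0.5, 5))
    f <- fit_mixture(q$peak_cons, q$sd, k = 1)
    d <- derive_mqtl(f, q, tiny_consensus_map())
    expect_true(d$mqtl$ci95 <= min(q$ci95) + 1e-12)
  }
})

test_that("single-member components become 'single' candidates, not MQTL", {
  q <- projected_stub(c(10, 11, 150), c(1, 1, 1))
  f <- fit_mixture(q$peak_cons, q$sd, k = 2, seed = 1)
  d <- derive_mqtl(f, q, tiny_consensus_map())
  expect_equal(nrow(d$mqtl), 1)
  expect_equal(d$singles, "q3")
})

test_that("flanking markers are the nearest outside the CI, with bp", {
  # map 1A markers at 0, 50, 100, 120, 160
  q <- projected_stub(c(74, 76), c(2, 2))
  f <- fit_mixture(q$peak_cons, q$sd, k = 1)
  d <- derive_mqtl(f, q, tiny_consensus_map())
  expect_equal(d$mqtl$left_marker, "m2")    # 50 <= ci_left
  expect_equal(d$mqtl$right_marker, "m3")   # 100 >= ci_right
  expect_equal(d$mqtl$span_bp, 400e6 - 150e6)

  # CI running past the terminal marker uses the terminal marker
  q2 <- projected_stub(c(0.4, 0.6), c(1, 1))
  f2 <- fit_mixture(q2$peak_cons, q2$sd, k = 1)
  d2 <- derive_mqtl(f2, q2, tiny_consensus_map())
  expect_equal(d2$mqtl$left_marker, "m1")
})

test_that("traits aggregate as the union over members", {
  q <- projected_stub(c(14, 15, 16), c(2, 2, 2),
                      traits = c("GPC", "FHB", "GPC"))
  f <- fit_mixture(q$peak_cons, q$sd, k = 1)
  d <- derive_mqtl(f, q, tiny_consensus_map())
  expect_equal(d$mqtl$traits, "FHB, GPC")
})

test_that("classification follows the grouped/single/unassigned rules", {
  mq <- tibble::tibble(mqtl_id = c("M1", "M2"), component = c(1L, 2L),
                       ci_left = c(10, 30), ci_right = c(20, 40))
  qtls <- tibble::tibble(
    qtl_id = c("inside", "bridging", "lonely", "outlier"),
    peak_cons = c(15, 22, 90, 25),
    ci_left = c(14, 12, 85, 24), ci_right = c(16, 32, 95, 26))
  # inside: member of M1; bridging: member of M1 but CI spans both MQTL;
  # lonely: own component far away; outlier: member of M2, peak outside it
  assignment <- c(1L, 1L, 3L, 2L)
  cls <- classify_qtl(qtls, mq, assignment)
  expect_equal(cls$status, c("grouped", "unassigned", "single", "unassigned"))
  expect_equal(cls$mqtl_id, c("M1", NA, NA, NA))
})

test_that("touching CI endpoints count as overlap", {
  mq <- tibble::tibble(mqtl_id = "M1", component = 1L,
                       ci_left = 10, ci_right = 20)
  q <- tibble::tibble(qtl_id = "t", peak_cons = 25,
                      ci_left = 20, ci_right = 30)
  cls <- classify_qtl(q, mq, assignment = NULL)
  expect_equal(cls$status, "unassigned")  # overlap, but not a member
})

test_that("per-chromosome analysis names MQTL by peak order", {
  set.seed(17)
  peaks <- c(rnorm(6, 30, 0.5), rnorm(6, 120, 0.5))
  q <- projected_stub(peaks, rep(1, 12))
  res <- run_meta_analysis(q, tiny_consensus_map(), kmax = 5,
                           restarts = 4, seed = 9)
  expect_equal(res$mqtl$mqtl_id, c("durumMQTL1A.1", "durumMQTL1A.2"))
  expect_lt(res$mqtl$peak[1], res$mqtl$peak[2])
  expect_equal(sort(unique(res$assignments$status)), "grouped")
  expect_equal(glance(res)$n_projected, 12)
})

test_that("a chromosome with a single QTL yields a single, no fit", {
  q <- dplyr::bind_rows(projected_stub(c(30, 31), c(1, 1)),
                        projected_stub(70, 1, chromosome = "2B"))
  q$qtl_id <- sprintf("q%d", 1:3)
  res <- run_meta_analysis(q, tiny_consensus_map(), restarts = 3)
  expect_equal(res$assignments$status[res$assignments$qtl_id == "q3"],
               "single")
  expect_false("2B" %in% res$mqtl$chromosome)
  expect_null(res$fits[["2B"]])
})

test_that("planted clusters are recovered on a synthetic chromosome", {
  cfg <- sim_config(seed = 123,
                    chromosomes = tibble::tibble(name = "2B", len_cm = 160,
                                                 len_bp = 600e6,
                                                 n_markers = 200))
  sim <- simulate_metaqtl_study(cfg)
  proj <- project_qtl(sim$qtl, sim$study_maps, sim$consensus_map)
  res <- run_meta_analysis(proj$projected, sim$consensus_map,
                           restarts = 5, seed = 1)
  expect_equal(nrow(res$mqtl), 3)
  truth_pos <- sort(unique(sim$truth$true_pos))
  expect_true(all(abs(sort(res$mqtl$peak) - truth_pos) < 1.5))
})

test_that("the model-selection report flags the chosen k per chromosome", {
  q <- projected_stub(c(rnorm(5, 20, 0.3), rnorm(5, 100, 0.3)), rep(1, 10))
  res <- run_meta_analysis(q, tiny_consensus_map(), kmax = 4, restarts = 3)
  rep_ <- model_selection_report(res)
  expect_equal(nrow(rep_), 4)
  expect_equal(rep_$k[rep_$chosen], 2)
})
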