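# Small in-code fixtures shared across test files.

# a two-chromosome consensus map with bp anchors
tiny_consensus_map <- function() {
  tibble::tibble(
    marker = c("m1", "m2", "m3", "m4", "m5", "n1", "n2", "n3"),
    chromosome = c(rep("1A", 5), rep("2B", 3)),
    cm = c(0, 50, 100, 120, 160, 0, 80, 160),
    bp = c(1e6, 150e6, 400e6, 470e6, 590e6, 1e6, 300e6, 600e6))
}

# study map matching tiny_consensus_map with a x2 stretch on 1A m2..m3
tiny_study_map <- function(study_id = "S1") {
  tibble::tibble(
    study_id = study_id,
    marker = c("m1", "m2", "m3", "m4", "m5", "n1", "n2", "n3"),
    chromosome = c(rep("1A", 5), rep("2B", 3)),
    cm = c(0, 10, 20, 40, 60, 0, 40, 80))
}

make_qtl <- function(qtl_id = "q1", study_id = "S1", trait = "GPC",
                     chromosome = "1A", peak_cm = 15, ci_original = NA_real_,
                     left_marker = "m2", right_marker = "m3", lod = 3.5,
                     pve = 0.10, pop_size = 100, pop_type = "RIL") {
  tibble::tibble(qtl_id = qtl_id, study_id = study_id, trait = trait,
                 chromosome = chromosome, peak_cm = peak_cm,
                 ci_original = ci_original, left_marker = left_marker,
                 right_marker = right_marker, lod = lod, pve = pve,
                 pop_size = pop_size, pop_type = pop_type)
}

write_tsv_tmp <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path)
  path
}

# a synthetic expression table with explicit values
tiny_expression <- function() {
  tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), each = 4),
    condition = rep(c("control", "drought"), 6),
    tissue = rep(c("grain", "grain", "spike", "spike"), 3),
    stage = "reproductive",
    tpm = c(1, 4, 2.5, 2.5,    # g1: 4x up in grain under drought
            0, 3, 1.2, 1.2,    # g2: zero control in grain
            2, 2, 0.5, 0.5))   # g3: flat
}
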