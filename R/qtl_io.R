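#' Column mapping for QTL tables
#'
#' A schema maps the canonical column names used throughout the package to
#' the column names found in an input file. Only entries whose file column
#' differs from the canonical name need to be given.
#'
#' Canonical columns: `qtl_id`, `study_id`, `trait`, `chromosome`,
#' `peak_cm`, `ci_original`, `left_marker`, `right_marker`, `lod`, `pve`,
#' `pop_size`, `pop_type`. Required: `qtl_id`, `study_id`, `trait`,
#' `chromosome`, `peak_cm`, `left_marker`, `right_marker`; the rest are
#' optional and filled with `NA` when absent.
#'
#' @param ... named character entries, e.g. `pve = "R2"`.
#' @return A named character vector (canonical -> file column).
#' @export
#' @examples
#' qtl_schema(pve = "R2", pop_size = "N")
qtl_schema <- function(...) {
  canonical <- c("qtl_id", "study_id", "trait", "chromosome", "peak_cm",
                 "ci_original", "left_marker", "right_marker", "lod", "pve",
                 "pop_size", "pop_type")
  user <- c(...)
  if (length(user) && (is.null(names(user)) || any(names(user) == "")))
    abort("schema entries must be named, e.g. qtl_schema(pve = \"R2\")")
  bad <- setdiff(names(user), canonical)
  if (length(bad))
    abort(paste0("unknown canonical column(s): ", paste(bad, collapse = ", ")))
  out <- setNames(canonical, canonical)
  out[names(user)] <- user
  out
}

REQUIRED_QTL_COLS <- c("qtl_id", "study_id", "trait", "chromosome",
                       "peak_cm", "left_marker", "right_marker")

POP_TYPES <- c("RIL", "DH", "F2", "BC", "BIL", "BP")

#' Read a per-study QTL table
#'
#' Reads a TSV/CSV of published QTL (one row per QTL as reported on its
#' original study map) and validates each row against the domain
#' invariants: `0 < pve <= 1`, `pop_size >= 2`, distinct flanking markers,
#' known population type. Rows violating an invariant are dropped from the
#' returned tibble and reported, with their row numbers, in the
#' `"rejected"` attribute (and a warning).
#'
#' @param path path to a TSV or CSV file (may be gzip-compressed).
#' @param schema column mapping from [qtl_schema()].
#' @param trait_dict trait dictionary tibble with columns `trait`,
#'   `category` (default the packaged vocabulary, [trait_dictionary()]).
#'   Unknown trait codes are kept with `trait_category = NA` and a warning.
#' @return A tibble of validated QTL with canonical columns plus
#'   `trait_category`; attribute `"rejected"` holds a tibble
#'   (`row`, `qtl_id`, `reason`) of dropped rows.
#' @export
read_qtl_table <- function(path, schema = qtl_schema(),
                           trait_dict = trait_dictionary()) {
  raw <- read_delim_auto(path)
  missing <- setdiff(unname(schema[REQUIRED_QTL_COLS]), names(raw))
  if (length(missing))
    abort(paste0("QTL table ", path, " lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  df <- tibble::tibble(.rows = nrow(raw))
  for (canon in names(schema)) {
    col <- schema[[canon]]
    df[[canon]] <- if (col %in% names(raw)) raw[[col]] else NA
  }
  for (col in c("peak_cm", "ci_original", "lod", "pve")) {
    df[[col]] <- parse_numeric_col(df[[col]], col)
  }
  df$pop_size <- parse_numeric_col(df$pop_size, "pop_size")
  df$chromosome <- normalize_chromosome(df$chromosome)
  validate_qtl_rows(df, trait_dict)
}

# numeric coercion with a row-indexed parse error
parse_numeric_col <- function(x, name) {
  if (is.numeric(x) || all(is.na(x))) return(as.numeric(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    abort(paste0("non-numeric ", name, " in row(s) ",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) ", ..." else ""))
  out
}

validate_qtl_rows <- function(df, trait_dict) {
  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- msg
  }
  flag(!is.na(df$pve) & (df$pve <= 0 | df$pve > 1), "pve outside (0, 1]")
  flag(!is.na(df$pop_size) & df$pop_size < 2, "pop_size < 2")
  flag(df$left_marker == df$right_marker, "identical flanking markers")
  flag(!is.na(df$pop_type) & !(df$pop_type %in% POP_TYPES),
       paste0("pop_type not one of ", paste(POP_TYPES, collapse = "/")))
  flag(!is.na(df$peak_cm) & df$peak_cm < 0, "negative peak_cm")
  bad <- which(!is.na(reason))
  rejected <- tibble::tibble(row = bad, qtl_id = df$qtl_id[bad],
                             reason = reason[bad])
  if (length(bad)) {
    warn(paste0(length(bad), " QTL row(s) rejected: ",
                paste(paste0("row ", bad, " (", reason[bad], ")"),
                      collapse = "; ")))
    df <- df[-bad, ]
  }
  df <- left_join(df, select(trait_dict, "trait", trait_category = "category"),
                  by = "trait")
  unknown <- unique(df$trait[is.na(df$trait_category)])
  if (length(unknown))
    warn(paste0("unknown trait code(s) kept with NA category: ",
                paste(unknown, collapse = ", ")))
  attr(df, "rejected") <- rejected
  df
}

#' Read a consensus genetic map
#'
#' @param path TSV with columns `marker`, `chromosome`, `cm` and optional
#'   `bp` (gzip allowed).
#' @return A tibble sorted by (chromosome, cm). Duplicate marker names are
#'   an error; unsorted input is sorted silently.
#' @export
read_consensus_map <- function(path) {
  df <- read_delim_auto(path)
  need <- setdiff(c("marker", "chromosome", "cm"), names(df))
  if (length(need))
    abort(paste0("consensus map lacks column(s): ",
                 paste(need, collapse = ", ")))
  if (!"bp" %in% names(df)) df$bp <- NA_real_
  df$cm <- parse_numeric_col(df$cm, "cm")
  df$bp <- parse_numeric_col(df$bp, "bp")
  df$chromosome <- normalize_chromosome(df$chromosome)
  dup <- unique(df$marker[duplicated(df$marker)])
  if (length(dup))
    abort(paste0("duplicate marker name(s) in map: ",
                 paste(head(dup, 5), collapse = ", ")))
  if (any(df$cm < 0, na.rm = TRUE)) abort("negative cM position in map")
  if (any(!is.na(df$bp) & df$bp < 1)) abort("bp positions must be >= 1")
  arrange(df, .data$chromosome, .data$cm) |>
    select("marker", "chromosome", "cm", "bp")
}

#' @rdname read_qtl_table
#' @param x tibble to write.
#' @export
write_qtl_table <- function(x, path) {
  readr::write_tsv(select(x, -any_of("trait_category")), path)
  invisible(path)
}

#' @rdname read_consensus_map
#' @param x map tibble to write.
#' @export
write_consensus_map <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Normalize chromosome labels to the "1A".."7B" scheme
#'
#' Accepts aliases such as `"chr1A"`, `"Chr_2B"` or lower case letters.
#' Labels that do not match any alias are returned unchanged (the
#' chromosome set is configurable downstream, not enforced here).
#'
#' @param x character vector of chromosome labels.
#' @export
normalize_chromosome <- function(x) {
  x <- as.character(x)
  y <- stringr::str_replace(x, stringr::regex("^chr[._-]?", ignore_case = TRUE), "")
  y <- toupper(trimws(y))
  ifelse(y %in% DURUM_CHROMOSOMES, y, x)
}

#' Read gene models from a GFF3 file
#'
#' Gene features (`type == "gene"` and variants such as
#' `"transposable_element_gene"`) are returned one per row. A gene is
#' flagged as a transposable element when its feature type or description
#' matches any of `te_keywords` (case-insensitive).
#'
#' @param path GFF3 file (gzip allowed).
#' @param te_keywords character vector of keywords marking transposable
#'   elements.
#' @return tibble with `gene_id`, `chromosome`, `start`, `end`, `is_te`,
#'   `description` (GFF3 1-based inclusive coordinates).
#' @export
read_gff3 <- function(path,
                      te_keywords = c("transposable", "transposon",
                                      "retrotransposon", "retroelement")) {
  empty <- tibble::tibble(gene_id = character(), chromosome = character(),
                          start = double(), end = double(),
                          is_te = logical(), description = character())
  body_lines <- grep("^\\s*(#|$)", readLines(path, warn = FALSE),
                     invert = TRUE, value = TRUE)
  if (!length(body_lines)) return(empty)
  nfield <- lengths(strsplit(body_lines, "\t", fixed = TRUE))
  if (any(nfield != 9))
    abort(paste0("malformed GFF3 line (expected 9 tab-separated fields) ",
                 "at data line ", which(nfield != 9)[1], " of ", path))
  gff <- tryCatch(
    ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE),
    error = function(e) abort(paste0("malformed GFF3 file ", path, ": ",
                                     conditionMessage(e))))
  genes <- gff[grepl("gene", gff$type, ignore.case = TRUE), , drop = FALSE]
  if (!nrow(genes)) {
    return(tibble::tibble(gene_id = character(), chromosome = character(),
                          start = double(), end = double(),
                          is_te = logical(), description = character()))
  }
  if (any(genes$start > genes$end))
    abort("GFF3 gene feature with start > end")
  attr_field <- function(attrs, key) {
    m <- stringr::str_match(attrs, paste0("(?:^|;)\\s*", key, "=([^;]*)"))
    m[, 2]
  }
  ids <- attr_field(genes$attributes, "ID")
  ids[is.na(ids)] <- attr_field(genes$attributes, "Name")[is.na(ids)]
  if (anyNA(ids)) abort("GFF3 gene feature without an ID attribute")
  desc <- attr_field(genes$attributes, "description")
  desc[is.na(desc)] <- ""
  pat <- paste(te_keywords, collapse = "|")
  is_te <- stringr::str_detect(tolower(paste(genes$type, desc)),
                               stringr::regex(pat, ignore_case = TRUE))
  tibble::tibble(gene_id = ids,
                 chromosome = normalize_chromosome(genes$seqid),
                 start = as.numeric(genes$start),
                 end = as.numeric(genes$end),
                 is_te = is_te,
                 description = desc)
}

#' Read a long-format expression matrix
#'
#' @param path TSV with columns `gene_id`, `condition`, `tissue`, `stage`,
#'   `tpm` (gzip allowed).
#' @return tibble of expression records; negative tpm and duplicated
#'   (gene_id, condition, tissue, stage) keys are errors.
#' @export
read_expression_matrix <- function(path) {
  df <- read_delim_auto(path)
  need <- setdiff(c("gene_id", "condition", "tissue", "stage", "tpm"),
                  names(df))
  if (length(need))
    abort(paste0("expression matrix lacks column(s): ",
                 paste(need, collapse = ", ")))
  df$tpm <- parse_numeric_col(df$tpm, "tpm")
  if (any(df$tpm < 0, na.rm = TRUE)) {
    bad <- which(df$tpm < 0)
    abort(paste0("negative tpm in row(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  key <- paste(df$gene_id, df$condition, df$tissue, df$stage, sep = "|")
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    abort(paste0("duplicated expression key(s): ",
                 paste(head(dup, 3), collapse = "; ")))
  tibble::as_tibble(df[c("gene_id", "condition", "tissue", "stage", "tpm")])
}

# readr-based reader: TSV by default, falls back to comma when the header
# has no tab; transparently handles gz.
read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}
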