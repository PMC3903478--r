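#' Published comparative panel of aromatic amino acid ammonia-lyases
#'
#' The printed reference comparison of ionizable-residue composition, acid
#' excess and homotetramer salt-bridge content across the family, including
#' the alkalophilic thermotolerant R. xylanophilus PAL.  These are published
#' values shipped as reference data, not quantities this package computes:
#' the RxPAL and PlPAL rows were evaluated on undeposited homology models
#' (285 and 220 bridges), so they are reproducible only with those models in
#' hand.  The composition columns are 1-decimal percentages of chain length;
#' `acid_excess` is `(#Asp + #Glu) - (#Lys + #Arg)` per chain; `pct_in_sb`
#' counts each residue of the tetramer once however many bridges it joins.
#'
#' @return A tibble with one row per enzyme: `taxon`, `enzyme`,
#'   `chain_length`, `cys_per_chain`, `pct_asp`, `pct_glu`, `pct_lys`,
#'   `pct_arg`, `acid_excess`, `n_salt_bridges`, `pct_in_sb`, `structure`
#'   (PDB code or `"homology model"`), `source` (`"published"`).
#' @export
published_lyase_panel <- function() {
  tibble::tribble(
    ~taxon, ~enzyme, ~chain_length, ~cys_per_chain,
    ~pct_asp, ~pct_glu, ~pct_lys, ~pct_arg,
    ~acid_excess, ~n_salt_bridges, ~pct_in_sb, ~structure,
    "Rubrobacter xylanophilus",  "PAL", 540L, 9L, 4.8, 8.5, 2.0, 8.3,
      16L, 285L, 23.1, "homology model",
    "Photorhabdus luminescens",  "PAL", 532L, 7L, 4.5, 6.2, 5.1, 3.9,
      9L, 220L, 16.0, "homology model",
    "Pseudomonas putida",        "HAL", 509L, 7L, 5.1, 5.7, 3.5, 5.3,
      10L, 128L, 11.4, "1GKM",
    "Petroselinum crispum",      "PAL", 716L, 9L, 3.8, 7.7, 5.6, 5.6,
      12L, 148L, 9.1, "1W27",
    "Rhodosporidium toruloides", "PAL", 716L, 4L, 4.2, 5.7, 4.0, 4.9,
      7L, 137L, 8.0, "1Y2M",
    "Rhodobacter sphaeroides",   "TAL", 523L, 8L, 5.5, 4.2, 1.0, 8.8,
      0L, 98L, 8.2, "2O7E",
    "Anabaena variabilis",       "PAL", 567L, 6L, 5.5, 3.4, 3.2, 4.4,
      7L, 74L, 5.9, "3CZO",
    "Nostoc punctiforme",        "PAL", 569L, 7L, 5.6, 3.9, 3.1, 4.4,
      11L, 68L, 5.3, "2NYF"
  ) %>%
    mutate(source = "published")
}

#' Run the profiling pipeline over a panel of inputs
#'
#' Orchestrates the whole pipeline for each panel entry: sequence
#' composition and family classification, and — when a structure is given —
#' biological-assembly expansion, salt-bridge and disulfide detection and
#' the surface-charge proxy.  Entries are processed independently; a failing
#' entry yields a row with its `error` recorded and the remaining columns
#' `NA`.
#'
#' @param panel A data frame with columns `label`, `sequence_file`
#'   (FASTA; optional when `structure_file` is given, in which case chain
#'   sequences are extracted from the structure), and optionally
#'   `structure_file`, `assembly` (label, default `"1"` when transforms
#'   exist), `use_asymmetric_unit` (logical).  Alternatively the path of a
#'   JSON file holding an array of such entries.
#' @param anchors Anchor set for [classify_family()]; `NULL` skips
#'   classification.
#' @param saltbridge_cutoff,ss_cutoff,include_his,include_termini Detection
#'   criteria, see [find_salt_bridges()] and [find_disulfide_candidates()].
#' @param compute_surface Compute the SASA-based surface-charge proxy
#'   (the slowest step) — default `TRUE`.
#' @param sphere_points,probe,exposure_threshold Surface-descriptor
#'   parameters, see [compute_sasa()] and [surface_charge_summary()].
#' @param strict Abort (after processing every entry) if any entry failed.
#' @return A tibble of descriptor rows in panel order; numeric columns exact
#'   (round only for reporting), plus `provenance` and `error` columns.
#' @export
run_panel <- function(panel, anchors = NULL,
                      saltbridge_cutoff = 3.2, ss_cutoff = 6.0,
                      include_his = FALSE, include_termini = FALSE,
                      compute_surface = TRUE, sphere_points = 960,
                      probe = 1.4, exposure_threshold = 5,
                      strict = FALSE) {
  if (is.character(panel) && length(panel) == 1) {
    panel <- jsonlite::fromJSON(panel)
    if (length(panel) == 0) panel <- data.frame(label = character())
  }
  panel <- as_tibble(panel)
  if (!nrow(panel)) return(empty_descriptor_rows())
  stopifnot("label" %in% names(panel))
  for (col in c("sequence_file", "structure_file", "assembly")) {
    if (!col %in% names(panel)) panel[[col]] <- NA_character_
  }
  if (!"use_asymmetric_unit" %in% names(panel)) {
    panel$use_asymmetric_unit <- FALSE
  }
  rows <- purrr::pmap(
    list(panel$label, panel$sequence_file, panel$structure_file,
         panel$assembly, panel$use_asymmetric_unit),
    function(label, seq_file, struct_file, assembly, use_asu) {
      tryCatch(
        descriptor_row(label, seq_file, struct_file, assembly, use_asu,
                       anchors, saltbridge_cutoff, ss_cutoff, include_his,
                       include_termini, compute_surface, sphere_points,
                       probe, exposure_threshold),
        error = function(e) error_row(label, conditionMessage(e)))
    })
  out <- bind_rows(rows)
  if (strict && any(!is.na(out$error))) {
    abort(paste0("panel entries failed: ",
                 paste(out$label[!is.na(out$error)], collapse = ", ")),
          class = "lyaseprofile_panel_error", rows = out)
  }
  out
}

error_row <- function(label, msg) {
  tibble(label = label, family = NA_character_,
         selectivity_pair = NA_character_, chain_length = NA_integer_,
         cys_per_chain = NA_integer_, pct_asp = NA_real_,
         pct_glu = NA_real_, pct_lys = NA_real_, pct_arg = NA_real_,
         acid_excess = NA_integer_, n_chains = NA_integer_,
         total_residues = NA_integer_, n_salt_bridges = NA_integer_,
         pct_in_sb = NA_real_, n_inter_chain = NA_integer_,
         n_disulfides = NA_integer_, n_inter_subunit_ss = NA_integer_,
         surface_charge_balance = NA_real_,
         provenance = list(list()), error = msg)
}

empty_descriptor_rows <- function() {
  tibble(label = character(), family = character(),
         selectivity_pair = character(), chain_length = integer(),
         cys_per_chain = integer(), pct_asp = numeric(),
         pct_glu = numeric(), pct_lys = numeric(), pct_arg = numeric(),
         acid_excess = integer(), n_chains = integer(),
         total_residues = integer(), n_salt_bridges = integer(),
         pct_in_sb = numeric(), n_inter_chain = integer(),
         n_disulfides = integer(), n_inter_subunit_ss = integer(),
         surface_charge_balance = numeric(),
         provenance = list(), error = character())
}

descriptor_row <- function(label, seq_file, struct_file, assembly, use_asu,
                           anchors, saltbridge_cutoff, ss_cutoff,
                           include_his, include_termini, compute_surface,
                           sphere_points, probe, exposure_threshold) {
  model <- NULL
  seqs <- NULL
  checksums <- character()
  if (!is.na(struct_file) && nzchar(struct_file)) {
    model <- read_structure(struct_file)
    checksums <- c(checksums, unname(tools::md5sum(struct_file)))
    if (!isTRUE(use_asu)) {
      lab <- if (is.na(assembly) || !nzchar(assembly)) "1" else assembly
      model <- apply_assembly(model, lab)
    }
  }
  if (!is.na(seq_file) && nzchar(seq_file)) {
    seqs <- read_fasta(seq_file)[1, ]
    checksums <- c(checksums, unname(tools::md5sum(seq_file)))
  } else if (!is.null(model)) {
    seqs <- extract_sequences(model)[1, ]
  }
  if (is.null(seqs)) {
    abort(paste0("panel entry '", label,
                 "' has neither sequence nor structure"))
  }
  comp <- composition(seqs)
  fam <- if (!is.null(anchors)) classify_family(seqs, anchors) else
    tibble(family = NA_character_, selectivity_pair = NA_character_)

  if (!is.null(model)) {
    br <- bridge_report(model, saltbridge_cutoff, ss_cutoff, include_his,
                        include_termini)
    surf <- if (compute_surface) {
      surface_charge_summary(
        model, compute_sasa(model, probe, sphere_points),
        exposure_threshold)
    } else tibble(surface_charge_balance = NA_real_)
  } else {
    br <- NULL
    surf <- tibble(surface_charge_balance = NA_real_)
  }
  cfg <- list(saltbridge_cutoff = saltbridge_cutoff, ss_cutoff = ss_cutoff,
              include_his = include_his, include_termini = include_termini,
              sphere_points = sphere_points, probe = probe,
              exposure_threshold = exposure_threshold,
              assembly = if (is.null(model)) NA_character_ else
                attr(model, "assembly_label"),
              surface_descriptor = "exposure-weighted proxy")
  tibble(
    label = label,
    family = fam$family,
    selectivity_pair = fam$selectivity_pair,
    chain_length = comp$chain_length,
    cys_per_chain = comp$cys_count,
    pct_asp = comp$pct_asp, pct_glu = comp$pct_glu,
    pct_lys = comp$pct_lys, pct_arg = comp$pct_arg,
    acid_excess = comp$acid_excess,
    n_chains = if (is.null(br)) NA_integer_ else br$n_chains,
    total_residues = if (is.null(br)) NA_integer_ else br$total_residues,
    n_salt_bridges = if (is.null(br)) NA_integer_ else br$n_salt_bridges,
    pct_in_sb = if (is.null(br)) NA_real_ else br$pct_in_sb,
    n_inter_chain = if (is.null(br)) NA_integer_ else br$n_inter_chain,
    n_disulfides = if (is.null(br)) NA_integer_ else br$n_disulfides,
    n_inter_subunit_ss = if (is.null(br)) NA_integer_ else
      br$n_inter_subunit_ss,
    surface_charge_balance = surf$surface_charge_balance,
    provenance = list(list(config = cfg, config_hash = rlang::hash(cfg),
                           inputs = checksums,
                           tool_version = as.character(
                             utils::packageVersion("lyaseprofile")))),
    error = NA_character_
  )
}

#' Stable descending sort of descriptor rows
#'
#' Orders a report by one numeric column, largest first, ties keeping panel
#' order — the ranking used to compare salt-bridge content across the
#' family.
#'
#' @param rows Descriptor tibble (any data frame).
#' @param key Name of a numeric column.
#' @return The rows reordered.
#' @export
rank_rows <- function(rows, key) {
  if (!key %in% names(rows)) {
    abort(paste0("unknown column '", key, "'; available: ",
                 paste(names(rows), collapse = ", ")))
  }
  if (!is.numeric(rows[[key]])) {
    abort(paste0("column '", key, "' is not numeric"))
  }
  rows[order(-xtfrm(rows[[key]])), ]
}

#' Render a descriptor report as TSV text
#'
#' Human-comparable report: percentages to 1 decimal, the surface-charge
#' proxy to 3 decimals with its proxy flag in the header; full-precision
#' values belong in the JSON output ([jsonlite::write_json()] of the rows).
#'
#' @param rows Descriptor tibble from [run_panel()].
#' @return A single TSV string.
#' @export
format_report_tsv <- function(rows) {
  r <- rows
  for (col in c("pct_asp", "pct_glu", "pct_lys", "pct_arg", "pct_in_sb")) {
    if (col %in% names(r)) r[[col]] <- sprintf("%.1f", r[[col]])
  }
  if ("surface_charge_balance" %in% names(r)) {
    r$surface_charge_balance <- ifelse(
      is.na(rows$surface_charge_balance), "NA",
      sprintf("%.3f", rows$surface_charge_balance))
    names(r)[names(r) == "surface_charge_balance"] <-
      "surface_charge_balance_proxy"
  }
  r <- r[setdiff(names(r), c("provenance"))]
  r[] <- lapply(r, function(x) ifelse(is.na(x), "NA", as.character(x)))
  lines <- paste(names(r), collapse = "\t")
  if (nrow(r)) {
    lines <- c(lines, apply(r, 1, paste, collapse = "\t"))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
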