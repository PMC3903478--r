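#' Read a protein structure into a tidy atom table
#'
#' Parses a PDB or mmCIF document into a `structure_model`: a tibble with one
#' row per atom and columns `chain`, `resno`, `ins`, `resname`, `aa`, `atom`,
#' `element`, `alt`, `occ`, `hydrogen`, `x`, `y`, `z`.  Waters and
#' non-amino-acid heteroatoms are dropped, alternate locations are reduced to
#' the highest-occupancy conformer (ties broken by alphabetical alt-loc id),
#' hydrogens are retained but flagged so distance-based analyses can ignore
#' them, and non-standard residue names are kept with `aa = "X"`
#' (selenomethionine maps to `"M"`).  Only the first model of a multi-model
#' file is read.
#'
#' Biological-assembly transforms found in the document (PDB `REMARK 350`,
#' mmCIF `pdbx_struct_assembly_gen`/`pdbx_struct_oper_list`) are attached as
#' the `"assemblies"` attribute for [apply_assembly()].
#'
#' @param x Path to a PDB/mmCIF file, or the document text itself (anything
#'   containing a newline is treated as text).
#' @param format `"pdb"`, `"cif"`, or `NULL` to guess from the file name and
#'   content.
#' @param structure_id Identifier stored with the model; defaults to the file
#'   base name.
#' @return A `structure_model` tibble of atoms.
#' @export
#' @examples
#' pdb <- generate_structure(synthetic_structure_spec(
#'   n_chains = 1, residues_per_chain = 5, seed = 1))
#' mod <- read_structure(pdb$pdb_text, structure_id = "toy")
#' dplyr::count(mod, chain)
read_structure <- function(x, format = NULL, structure_id = NULL) {
  stopifnot(is.character(x), length(x) == 1)
  is_text <- grepl("\n", x, fixed = TRUE)
  path <- x
  if (is_text) {
    path <- tempfile(fileext = ".struct")
    writeLines(sub("\n$", "", x), path)
    on.exit(unlink(path))
  } else if (!file.exists(x)) {
    abort(paste0("structure file not found: ", x))
  }
  lines <- readLines(path, warn = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.(cif|mmcif)$", x, ignore.case = TRUE) ||
                  any(startsWith(lines, "data_"))) "cif" else "pdb"
  }
  if (is.null(structure_id)) {
    structure_id <- if (is_text) "structure" else
      sub("\\.[^.]*$", "", basename(x))
  }

  raw <- if (format == "cif") {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  } else {
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, rm.insert = FALSE,
                                     multi = FALSE, verbose = FALSE))
  }
  atoms <- tidy_bio3d_atoms(raw$atom)
  assemblies <- if (format == "cif") cif_assemblies(lines) else
    pdb_assemblies(raw)
  new_structure_model(atoms, structure_id = structure_id,
                      assemblies = assemblies)
}

# Convert a bio3d atom data.frame to the tidy atom table, applying the
# polymer / water / alt-loc rules.
tidy_bio3d_atoms <- function(at) {
  if (is.null(at) || nrow(at) == 0) {
    abort("malformed input: document contains no ATOM/HETATM records")
  }
  at$ins <- ifelse(is.na(at$insert), "", at$insert)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$o <- ifelse(is.na(at$o), 1, at$o)
  at$chain <- ifelse(is.na(at$chain), "A", at$chain)

  known_aa <- at$resid %in% names(AA_321)
  keep <- (at$type == "ATOM" & !(at$resid %in% WATER_NAMES)) |
    (at$type == "HETATM" & known_aa)
  if (!any(keep)) {
    bad <- at[1, ]
    abort(paste0(
      "malformed input: no polymer atom records found ",
      "(first record: ", bad$type, " ", bad$resid, " ",
      bad$chain, " ", bad$resno, ")"
    ))
  }
  at <- at[keep, ]

  element <- at$elesy
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    guess <- sub("^[0-9]*", "", at$elety[missing_el])
    element[missing_el] <- toupper(substr(guess, 1, 1))
  }
  hyd <- toupper(element) %in% c("H", "D")

  atoms <- tibble(
    chain = at$chain,
    resno = as.integer(at$resno),
    ins = at$ins,
    resname = at$resid,
    aa = unname(AA_321[at$resid]) %|NA|% "X",
    atom = at$elety,
    element = toupper(element),
    alt = at$alt,
    occ = pmin(pmax(at$o, 0), 1),
    hydrogen = hyd,
    x = at$x, y = at$y, z = at$z
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("malformed input: non-finite atom coordinates")
  }
  # alt-loc reduction: highest occupancy wins, ties alphabetical
  atoms <- atoms %>%
    group_by(.data$chain, .data$resno, .data$ins, .data$resname, .data$atom) %>%
    arrange(desc(.data$occ), .data$alt, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  # atoms now ordered by (chain, resno, ins) — deterministic
  atoms
}

`%|NA|%` <- function(x, y) {
  x[is.na(x)] <- y
  x
}

#' Construct a structure_model from a tidy atom table
#'
#' @param atoms Tibble with the atom columns produced by [read_structure()].
#' @param structure_id Identifier.
#' @param assemblies Named list of biological-assembly definitions, each a
#'   `list(chains = , ops = )` where `ops` is a list of 3x4 rotation +
#'   translation matrices.
#' @param assembly_applied,assembly_label Assembly provenance flags.
#' @return A `structure_model` tibble.
#' @export
new_structure_model <- function(atoms, structure_id = "structure",
                                assemblies = list(),
                                assembly_applied = FALSE,
                                assembly_label = "") {
  atoms <- as_tibble(atoms)
  needed <- c("chain", "resno", "ins", "resname", "aa", "atom", "element",
              "occ", "hydrogen", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing)) {
    abort(paste0("atom table lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (!"alt" %in% names(atoms)) atoms$alt <- ""
  structure(
    atoms,
    structure_id = structure_id,
    assemblies = assemblies,
    assembly_applied = assembly_applied,
    assembly_label = assembly_label,
    class = c("structure_model", class(tibble())))
}

#' @export
print.structure_model <- function(x, ...) {
  res <- residue_table(x)
  cat("<structure_model> ", attr(x, "structure_id") %||% "?",
      ": ", length(unique(x$chain)), " chain(s), ",
      nrow(res), " residues, ", nrow(x), " atoms",
      if (isTRUE(attr(x, "assembly_applied")))
        paste0(" [assembly ", attr(x, "assembly_label"), "]") else "",
      "\n", sep = "")
  NextMethod()
}

# One row per residue, in atom-table order.
residue_table <- function(model) {
  distinct(as_tibble(model)[c("chain", "resno", "ins", "resname", "aa")])
}

# ---- biological assemblies ---------------------------------------------

pdb_assemblies <- function(raw) {
  bm <- raw$remark$biomat
  if (is.null(bm)) return(list())
  out <- list()
  for (i in seq_along(bm$num)) {
    out[[as.character(bm$num[i])]] <- list(
      chains = bm$chain[[i]],
      ops = unname(bm$mat[[i]])
    )
  }
  out
}

# Minimal reader for the two mmCIF categories describing assemblies.  Handles
# the plain loop_/key-value forms used by wwPDB entries; quoted multi-line
# values are not needed for these categories.
cif_category <- function(lines, category) {
  pref <- paste0("_", category, ".")
  idx <- grep(pref, lines, fixed = TRUE)
  if (!length(idx)) return(NULL)
  first <- idx[1]
  in_loop <- any(trimws(lines[max(1, first - 1)]) == "loop_")
  if (in_loop) {
    fields <- character()
    i <- first
    while (i <= length(lines) && startsWith(trimws(lines[i]), pref)) {
      fields <- c(fields, sub(paste0("^\\s*", pref), "", trimws(lines[i])))
      i <- i + 1
    }
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || ln == "#" || startsWith(ln, "_") ||
          startsWith(ln, "loop_") || startsWith(ln, "data_")) break
      rows[[length(rows) + 1]] <- scan(text = ln, what = character(),
                                       quiet = TRUE)
      i <- i + 1
    }
    if (!length(rows)) return(NULL)
    m <- do.call(rbind, rows)
    colnames(m) <- fields
    as.data.frame(m, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    vals <- list()
    for (i in idx) {
      parts <- scan(text = trimws(lines[i]), what = character(), quiet = TRUE)
      key <- sub(pref, "", parts[1], fixed = TRUE)
      vals[[key]] <- if (length(parts) > 1) paste(parts[-1], collapse = " ")
        else trimws(lines[i + 1])
    }
    as.data.frame(vals, stringsAsFactors = FALSE, check.names = FALSE)
  }
}

expand_oper_expression <- function(expr) {
  expr <- gsub("[()']", "", expr)
  parts <- unlist(strsplit(expr, ","))
  out <- character()
  for (p in parts) {
    p <- trimws(p)
    if (grepl("-", p)) {
      ab <- as.integer(unlist(strsplit(p, "-")))
      out <- c(out, as.character(seq(ab[1], ab[2])))
    } else out <- c(out, p)
  }
  out
}

cif_assemblies <- function(lines) {
  gen <- cif_category(lines, "pdbx_struct_assembly_gen")
  ops <- cif_category(lines, "pdbx_struct_oper_list")
  if (is.null(gen) || is.null(ops)) return(list())
  mats <- list()
  for (k in seq_len(nrow(ops))) {
    m <- matrix(0, 3, 4)
    for (i in 1:3) {
      for (j in 1:3) {
        m[i, j] <- as.numeric(ops[[paste0("matrix[", i, "][", j, "]")]][k])
      }
      m[i, 4] <- as.numeric(ops[[paste0("vector[", i, "]")]][k])
    }
    mats[[ops$id[k]]] <- m
  }
  out <- list()
  for (k in seq_len(nrow(gen))) {
    ids <- expand_oper_expression(gen$oper_expression[k])
    out[[gen$assembly_id[k]]] <- list(
      chains = unlist(strsplit(gsub("\\s", "", gen$asym_id_list[k]), ",")),
      ops = unname(mats[ids])
    )
  }
  out
}

#' Expand a structure to one of its biological assemblies
#'
#' Applies the rotation + translation operators recorded for
#' `assembly_label`, producing symmetry copies of the covered chains.  When
#' the assembly has more than one operator, copied chains are renamed
#' deterministically as original id + operator index (`"A"` under operators
#' 1..4 becomes `"A1".."A4"`); an identity-only assembly returns the input
#' coordinates unchanged apart from the provenance flags.  These lyases are
#' functional homotetramers, and the salt-bridge statistics of the pipeline
#' are defined on the assembly, not the crystal asymmetric unit.
#'
#' @param model A `structure_model`.
#' @param assembly_label Assembly identifier as given in the file (usually
#'   `"1"`).
#' @return A `structure_model` with `assembly_applied = TRUE`.
#' @export
apply_assembly <- function(model, assembly_label = "1") {
  assemblies <- attr(model, "assemblies") %||% list()
  if (!length(assemblies)) {
    abort(paste0(
      "no assembly transforms present in this structure; ",
      "rerun with use_asymmetric_unit = TRUE to analyse the deposited ",
      "coordinates as-is"))
  }
  assembly_label <- as.character(assembly_label)
  if (!assembly_label %in% names(assemblies)) {
    abort(paste0("unknown assembly label '", assembly_label,
                 "'; available: ",
                 paste(names(assemblies), collapse = ", ")))
  }
  asm <- assemblies[[assembly_label]]
  chains <- asm$chains
  atoms <- as_tibble(model)
  sel <- if (is.null(chains)) rep(TRUE, nrow(atoms)) else
    atoms$chain %in% chains
  base <- atoms[sel, ]
  n_ops <- length(asm$ops)
  copies <- vector("list", n_ops)
  for (k in seq_len(n_ops)) {
    m <- asm$ops[[k]]
    xyz <- t(m[, 1:3] %*% t(as.matrix(base[c("x", "y", "z")])) + m[, 4])
    cp <- base
    cp$x <- xyz[, 1]; cp$y <- xyz[, 2]; cp$z <- xyz[, 3]
    if (n_ops > 1) cp$chain <- paste0(cp$chain, k)
    copies[[k]] <- cp
  }
  new_structure_model(
    bind_rows(copies),
    structure_id = attr(model, "structure_id"),
    assemblies = assemblies,
    assembly_applied = TRUE,
    assembly_label = assembly_label)
}

#' Extract per-chain sequences from a structure
#'
#' @param model A `structure_model`.
#' @return Tibble with one row per chain: `source_id`, `chain`, `sequence`
#'   (one-letter codes, non-standard residues as `"X"`), and `offset`, the
#'   author residue number of the first residue (numbering is taken verbatim
#'   from the file).
#' @export
extract_sequences <- function(model) {
  res <- residue_table(model)
  if (!nrow(res)) abort("empty structure model")
  res %>%
    group_by(.data$chain) %>%
    summarise(
      source_id = attr(model, "structure_id") %||% "structure",
      sequence = paste(.data$aa, collapse = ""),
      offset = .data$resno[1],
      .groups = "drop"
    ) %>%
    select("source_id", "chain", "sequence", "offset")
}

# ---- FASTA --------------------------------------------------------------

#' Read and write FASTA sequence tables
#'
#' `read_fasta()` parses a FASTA file (or text) into a tibble of sequences;
#' `write_fasta()` renders such a tibble back to 60-column-wrapped FASTA.
#' Sequences must use the 20 canonical one-letter codes plus `X`; anything
#' else is a parse error naming the offending record.
#'
#' @param x Path to a FASTA file, or FASTA text (anything containing a
#'   newline).
#' @return `read_fasta()`: tibble with `source_id`, `chain` (`NA`),
#'   `sequence`, `offset` (1).
#' @export
read_fasta <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  path <- x
  if (grepl("\n", x, fixed = TRUE)) {
    path <- tempfile(fileext = ".fasta")
    writeLines(sub("\n$", "", x), path)
    on.exit(unlink(path))
  } else if (!file.exists(x)) {
    abort(paste0("FASTA file not found: ", x))
  }
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) abort("FASTA parse error: no records")
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) {
      abort(paste0("FASTA parse error: empty record '", ids[i], "'"))
    }
    bad <- setdiff(strsplit(seqs[i], "")[[1]], c(AA_ONE, "X"))
    if (length(bad)) {
      abort(paste0("FASTA parse error: illegal character(s) ",
                   paste(unique(bad), collapse = ""),
                   " in record '", ids[i], "'"))
    }
  }
  tibble(source_id = ids, chain = NA_character_,
         sequence = unname(seqs), offset = 1L)
}

#' @rdname read_fasta
#' @param seqs Tibble with `source_id` and `sequence` columns (as returned by
#'   [read_fasta()] or [extract_sequences()]).
#' @param path Optional output file; when `NULL` the FASTA text is returned.
#' @export
write_fasta <- function(seqs, path = NULL) {
  stopifnot(all(c("source_id", "sequence") %in% names(seqs)))
  ids <- seqs$source_id
  if ("chain" %in% names(seqs) && any(!is.na(seqs$chain))) {
    ids <- ifelse(is.na(seqs$chain), ids,
                  paste0(ids, "_", seqs$chain))
  }
  set <- Biostrings::BStringSet(setNames(seqs$sequence, ids))
  out <- path %||% tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(set, out, width = 60)
  if (is.null(path)) {
    txt <- paste0(paste(readLines(out), collapse = "\n"), "\n")
    unlink(out)
    txt
  } else invisible(path)
}
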