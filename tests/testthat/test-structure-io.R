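test_that("a hand-written two-chain PDB parses to the expected counts", {
  mod <- read_structure(fixture_two_chain_pdb(), structure_id = "fix")
  expect_s3_class(mod, "structure_model")
  expect_equal(length(unique(mod$chain)), 2)
  res <- dplyr::distinct(tibble::as_tibble(mod)[c("chain", "resno")])
  expect_equal(nrow(res), 6)
  expect_equal(nrow(mod), 24)
})

test_that("documents without polymer atoms are rejected with a named record", {
  waters <- paste0(
    pdb_atom_line(1, "O", "HOH", "A", 101, 1, 2, 3, record = "HETATM"), "\n",
    pdb_atom_line(2, "O", "HOH", "A", 102, 4, 5, 6, record = "HETATM"), "\n",
    "END\n")
  expect_error(read_structure(waters), "no polymer.*HETATM HOH",
               ignore.case = TRUE)
})

test_that("alt-loc groups keep only the highest-occupancy conformer", {
  txt <- paste0(
    pdb_atom_line(1, "CA", "ASP", "A", 1, 0, 0, 0), "\n",
    pdb_atom_line(2, "OD1", "ASP", "A", 1, 1, 0, 0, occ = 0.6, alt = "A"), "\n",
    pdb_atom_line(3, "OD1", "ASP", "A", 1, 1.1, 0, 0, occ = 0.4, alt = "B"),
    "\nEND\n")
  mod <- read_structure(txt)
  od1 <- mod[mod$atom == "OD1", ]
  expect_equal(nrow(od1), 1)
  expect_equal(od1$alt, "A")
  expect_equal(od1$x, 1)

  # tie broken alphabetically
  txt2 <- paste0(
    pdb_atom_line(1, "OD1", "ASP", "A", 1, 1, 0, 0, occ = 0.5, alt = "B"), "\n",
    pdb_atom_line(2, "OD1", "ASP", "A", 1, 2, 0, 0, occ = 0.5, alt = "A"),
    "\nEND\n")
  expect_equal(read_structure(txt2)$alt, "A")
})

test_that("hydrogens are retained but flagged and waters are stripped", {
  txt <- paste0(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0), "\n",
    pdb_atom_line(2, "H", "ALA", "A", 1, 0, 1, 0, element = "H"), "\n",
    pdb_atom_line(3, "O", "HOH", "A", 90, 9, 9, 9, record = "HETATM"),
    "\nEND\n")
  mod <- read_structure(txt)
  expect_equal(nrow(mod), 2)
  expect_equal(mod$hydrogen, c(FALSE, TRUE))
  expect_false(any(mod$resname == "HOH"))
})

test_that("four-operator assembly expansion multiplies counts and renames", {
  mod <- read_structure(fixture_assembly_pdb(), structure_id = "asm")
  expect_false(attr(mod, "assembly_applied"))
  tet <- apply_assembly(mod, "1")
  expect_true(attr(tet, "assembly_applied"))
  expect_equal(nrow(tet), 4 * nrow(mod))
  expect_setequal(unique(tet$chain), c("A1", "A2", "A3", "A4"))
  res_n <- nrow(dplyr::distinct(tibble::as_tibble(tet)[c("chain", "resno")]))
  expect_equal(res_n, 4 * 2)
  # chain ids unique after renaming
  expect_equal(anyDuplicated(unique(tet$chain)), 0)
})

test_that("identity-only assembly changes nothing but the provenance flags", {
  mod <- read_structure(fixture_assembly_pdb(ops = list(rot_z(0))))
  out <- apply_assembly(mod, "1")
  expect_true(attr(out, "assembly_applied"))
  expect_equal(out$x, mod$x)
  expect_equal(out$chain, mod$chain)
})

test_that("assembly errors name available labels or advise the fallback", {
  mod <- read_structure(fixture_assembly_pdb())
  expect_error(apply_assembly(mod, "9"), "available: 1")
  bare <- read_structure(fixture_two_chain_pdb())
  expect_error(apply_assembly(bare, "1"), "use_asymmetric_unit")
})

test_that("mmCIF atoms and assembly operators are read", {
  cif <- paste(c(
    "data_FIX", "#", "loop_",
    "_pdbx_struct_assembly_gen.assembly_id",
    "_pdbx_struct_assembly_gen.oper_expression",
    "_pdbx_struct_assembly_gen.asym_id_list",
    "1 '(1-2)' A", "#", "loop_",
    "_pdbx_struct_oper_list.id",
    "_pdbx_struct_oper_list.matrix[1][1]",
    "_pdbx_struct_oper_list.matrix[1][2]",
    "_pdbx_struct_oper_list.matrix[1][3]",
    "_pdbx_struct_oper_list.vector[1]",
    "_pdbx_struct_oper_list.matrix[2][1]",
    "_pdbx_struct_oper_list.matrix[2][2]",
    "_pdbx_struct_oper_list.matrix[2][3]",
    "_pdbx_struct_oper_list.vector[2]",
    "_pdbx_struct_oper_list.matrix[3][1]",
    "_pdbx_struct_oper_list.matrix[3][2]",
    "_pdbx_struct_oper_list.matrix[3][3]",
    "_pdbx_struct_oper_list.vector[3]",
    "1 1 0 0 0 0 1 0 0 0 0 1 0",
    "2 1 0 0 25 0 1 0 0 0 0 1 0", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ASP A 1 1 ? 1.0 2.0 3.0 1.00 0.00 ? 1 ASP A N 1",
    "ATOM 2 C CA . ASP A 1 1 ? 2.0 2.0 3.0 1.00 0.00 ? 1 ASP A CA 1",
    "#"), collapse = "\n")
  mod <- read_structure(cif, format = "cif")
  expect_equal(nrow(mod), 2)
  expect_equal(mod$resname, c("ASP", "ASP"))
  dimer <- apply_assembly(mod, "1")
  expect_equal(nrow(dimer), 4)
  expect_setequal(unique(dimer$chain), c("A1", "A2"))
  expect_equal(sort(dimer$x), sort(c(1, 2, 26, 27)))
})

test_that("sequences extract with author numbering and MSE mapped to M", {
  txt <- paste0(
    pdb_atom_line(1, "CA", "ASP", "A", 5, 0, 0, 0), "\n",
    pdb_atom_line(2, "CA", "GLU", "A", 6, 4, 0, 0), "\n",
    pdb_atom_line(3, "CA", "LYS", "A", 7, 8, 0, 0), "\n",
    pdb_atom_line(4, "CA", "MSE", "A", 8, 12, 0, 0, record = "HETATM"), "\n",
    pdb_atom_line(5, "CA", "XYZ", "A", 9, 16, 0, 0),
    "\nEND\n")
  seqs <- extract_sequences(read_structure(txt))
  expect_equal(seqs$sequence, "DEKMX")
  expect_equal(seqs$offset, 5)
})

test_that("a homotetramer yields four identical chain sequences", {
  gen <- generate_structure(synthetic_structure_spec(
    n_chains = 4, residues_per_chain = 12, n_salt_bridges = 0, n_decoys = 0,
    n_disulfides = 0, seed = 3))
  # same filler draw per chain is not guaranteed; use assembly expansion
  mono <- read_structure(fixture_assembly_pdb())
  tet <- apply_assembly(mono, "1")
  seqs <- extract_sequences(tet)
  expect_equal(nrow(seqs), 4)
  expect_equal(length(unique(seqs$sequence)), 1)
})

test_that("FASTA reading, wrapping and round-trips behave", {
  expect_equal(read_fasta(">a\nDEK\n")$sequence, "DEK")
  set.seed(42)
  seqs <- tibble::tibble(
    source_id = c("s1", "s2", "s3"), chain = NA_character_,
    sequence = c(random_aa_string(150), random_aa_string(61),
                 random_aa_string(7)),
    offset = 1L)
  txt <- write_fasta(seqs)
  expect_true(max(nchar(strsplit(txt, "\n")[[1]])) <= 61)
  back <- read_fasta(txt)
  expect_equal(back$source_id, seqs$source_id)
  expect_equal(back$sequence, seqs$sequence)
})

test_that("FASTA records with illegal characters fail naming the record", {
  expect_error(read_fasta(">a\nDE9K\n"), "9.*record 'a'")
  expect_error(read_fasta(">empty\n\n>b\nDEK\n"), "empty")
})

test_that("read-only analyses never mutate coordinates", {
  gen <- generate_structure(synthetic_structure_spec(seed = 5))
  before <- model_checksum(gen$model)
  invisible(find_salt_bridges(gen$model))
  invisible(find_disulfide_candidates(gen$model))
  invisible(compute_sasa(gen$model, n_points = 60))
  invisible(extract_sequences(gen$model))
  expect_identical(model_checksum(gen$model), before)
})
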