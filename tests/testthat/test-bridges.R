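test_that("planted tetramer ion pairs are recovered exactly", {
  gen <- generate_structure(synthetic_structure_spec(
    n_chains = 4, residues_per_chain = 60, n_salt_bridges = 12,
    n_inter_chain_bridges = 3, n_disulfides = 2, seed = 7))
  pairs <- find_salt_bridges(gen$model)
  expect_equal(nrow(pairs), 12)
  expect_equal(sum(pairs$inter_chain), 3)
  truth_keys <- sort(paste(
    gen$truth$planted_ion_pairs$acid_chain,
    gen$truth$planted_ion_pairs$acid_resno, "",
    gen$truth$planted_ion_pairs$basic_chain,
    gen$truth$planted_ion_pairs$basic_resno, ""))
  expect_equal(ion_pair_keys(pairs), truth_keys)
  ss <- find_disulfide_candidates(gen$model)
  expect_equal(nrow(ss), 2)
  expect_equal(sum(ss$inter_subunit), 1)
})

test_that("the ion-pair cutoff is inclusive and the disulfide cutoff strict", {
  m <- toy_model(
    list(chain = "A", resno = 1, resname = "ASP", atom = "OD1",
         element = "O", x = 0, y = 0, z = 0),
    list(chain = "A", resno = 2, resname = "LYS", atom = "NZ",
         element = "N", x = 3.2, y = 0, z = 0))
  expect_equal(nrow(find_salt_bridges(m)), 1)
  m2 <- toy_model(
    list(chain = "A", resno = 1, resname = "ASP", atom = "OD1",
         element = "O", x = 0, y = 0, z = 0),
    list(chain = "A", resno = 2, resname = "LYS", atom = "NZ",
         element = "N", x = 3.2000001, y = 0, z = 0))
  expect_equal(nrow(find_salt_bridges(m2)), 0)

  ss_at <- function(d) toy_model(
    list(chain = "A", resno = 1, resname = "CYS", atom = "SG",
         element = "S", x = 0, y = 0, z = 0),
    list(chain = "B", resno = 9, resname = "CYS", atom = "SG",
         element = "S", x = d, y = 0, z = 0))
  expect_equal(nrow(find_disulfide_candidates(ss_at(6.0))), 0)
  hit <- find_disulfide_candidates(ss_at(5.99))
  expect_equal(nrow(hit), 1)
  expect_true(hit$inter_subunit)
  expect_false(hit$fallback_atoms)
})

test_that("residue pairs count once however many atomic contacts they make", {
  m <- toy_model(
    list(chain = "A", resno = 1, resname = "ASP", atom = "OD1",
         element = "O", x = 0, y = 0, z = 0),
    list(chain = "A", resno = 1, resname = "ASP", atom = "OD2",
         element = "O", x = 0.5, y = 0, z = 0),
    list(chain = "A", resno = 2, resname = "ARG", atom = "NH1",
         element = "N", x = 2.5, y = 0, z = 0),
    list(chain = "A", resno = 2, resname = "ARG", atom = "NH2",
         element = "N", x = 3.0, y = 0, z = 0))
  pairs <- find_salt_bridges(m)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$min_distance, 2.0)
})

test_that("charged-residue-free models give empty results, not errors", {
  poly_ala <- toy_model(
    list(chain = "A", resno = 1, resname = "ALA", atom = "CA",
         element = "C", x = 0, y = 0, z = 0),
    list(chain = "A", resno = 2, resname = "ALA", atom = "CA",
         element = "C", x = 3, y = 0, z = 0))
  expect_equal(nrow(find_salt_bridges(poly_ala)), 0)
  expect_equal(nrow(find_disulfide_candidates(poly_ala)), 0)
  st <- ion_pair_stats(find_salt_bridges(poly_ala), poly_ala)
  expect_equal(st$n_pairs, 0)
  expect_equal(st$fraction_in_sb, 0)
})

test_that("count-once statistics match direct enumeration", {
  # 3 pairs sharing one acidic residue in a 100-residue model
  shared <- c(
    res_atoms("A", 1, "GLU", list(list("OE1", "O", 0, 0, 0))),
    res_atoms("A", 10, "LYS", list(list("NZ", "N", 2.8, 0, 0))),
    res_atoms("A", 20, "LYS", list(list("NZ", "N", -2.8, 0, 0))),
    res_atoms("A", 30, "ARG", list(list("NH1", "N", 0, 2.8, 0))))
  filler <- unlist(lapply(31:126, function(i)
    res_atoms("A", i, "ALA", list(list("CA", "C", 50 + 5 * i, 0, 0)))),
    recursive = FALSE)
  m <- do.call(toy_model, c(shared, filler))
  pairs <- find_salt_bridges(m)
  expect_equal(nrow(pairs), 3)
  st <- ion_pair_stats(pairs, m)
  expect_equal(st$n_unique_residues, 4)
  expect_equal(st$total_residues, 100)
  expect_equal(st$fraction_in_sb, 4.0)
})

test_that("ion_pair_stats rejects pairs from a different model", {
  gen <- generate_structure(synthetic_structure_spec(seed = 2))
  pairs <- find_salt_bridges(gen$model)
  other <- toy_model(list(chain = "Q", resno = 1, resname = "ALA",
                          atom = "CA", element = "C", x = 0, y = 0, z = 0))
  expect_error(ion_pair_stats(pairs, other), "consistency")
})

test_that("grid detection equals brute force on random synthetic instances", {
  for (seed in 1:12) {
    spec <- synthetic_structure_spec(
      n_chains = sample(1:4, 1), residues_per_chain = sample(c(40, 60), 1),
      n_salt_bridges = sample(0:8, 1),
      n_inter_chain_bridges = 0, n_decoys = sample(0:4, 1),
      n_disulfides = sample(0:3, 1), n_inter_chain_disulfides = 0,
      seed = seed)
    spec$n_inter_chain_bridges <- if (spec$n_chains > 1)
      min(2, spec$n_salt_bridges) else 0
    gen <- generate_structure(spec)
    expect_equal(ion_pair_keys(find_salt_bridges(gen$model)),
                 brute_force_ion_pairs(gen$model),
                 info = paste("seed", seed))
    expect_equal(disulfide_keys(find_disulfide_candidates(gen$model)),
                 brute_force_disulfides(gen$model),
                 info = paste("seed", seed))
  }
})

test_that("pair sets are monotone in the cutoff", {
  gen <- generate_structure(synthetic_structure_spec(seed = 9))
  cuts <- c(2.5, 3.0, 3.2, 3.6, 4.2)
  sets <- lapply(cuts, function(cc)
    ion_pair_keys(find_salt_bridges(gen$model, cutoff = cc)))
  for (i in seq_len(length(cuts) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]),
                info = paste(cuts[i], "vs", cuts[i + 1]))
  }
})

test_that("statistics are invariant to chain relabeling and atom order", {
  gen <- generate_structure(synthetic_structure_spec(seed = 4))
  atoms <- tibble::as_tibble(gen$model)
  relabeled <- atoms
  relabeled$chain <- chartr("ABCD", "WXYZ", relabeled$chain)
  set.seed(1)
  relabeled <- relabeled[sample(nrow(relabeled)), ]
  m2 <- new_structure_model(relabeled, structure_id = "perm")
  s1 <- ion_pair_stats(find_salt_bridges(gen$model), gen$model)
  s2 <- ion_pair_stats(find_salt_bridges(m2), m2)
  expect_equal(s1$n_pairs, s2$n_pairs)
  expect_equal(s1$n_unique_residues, s2$n_unique_residues)
  expect_equal(s1$fraction_in_sb, s2$fraction_in_sb)
  expect_equal(nrow(find_disulfide_candidates(gen$model)),
               nrow(find_disulfide_candidates(m2)))
})

test_that("single-chain models never report inter-chain pairs", {
  gen <- generate_structure(synthetic_structure_spec(
    n_chains = 1, residues_per_chain = 40, n_salt_bridges = 5,
    n_inter_chain_bridges = 0, n_disulfides = 1,
    n_inter_chain_disulfides = 0, seed = 21))
  pairs <- find_salt_bridges(gen$model)
  expect_equal(nrow(pairs), 5)
  expect_equal(sum(pairs$inter_chain), 0)
  st <- ion_pair_stats(pairs, gen$model)
  expect_equal(st$n_inter_chain, 0)
})

test_that("bridge_report bundles statistics with provenance", {
  gen <- generate_structure(synthetic_structure_spec(seed = 7))
  br <- bridge_report(gen$model)
  expect_equal(br$n_salt_bridges, 12)
  expect_equal(br$n_disulfides, 2)
  expect_equal(br$n_inter_subunit_ss, 1)
  expect_equal(br$n_chains, 4)
  cfg <- br$config[[1]]
  expect_equal(cfg$saltbridge_cutoff, 3.2)
  expect_equal(cfg$ss_cutoff, 6.0)
  expect_false(cfg$include_his)
})

test_that("the include_his flag widens the basic set", {
  m <- toy_model(
    list(chain = "A", resno = 1, resname = "GLU", atom = "OE1",
         element = "O", x = 0, y = 0, z = 0),
    list(chain = "A", resno = 2, resname = "HIS", atom = "NE2",
         element = "N", x = 3.0, y = 0, z = 0))
  expect_equal(nrow(find_salt_bridges(m)), 0)
  expect_equal(nrow(find_salt_bridges(m, include_his = TRUE)), 1)
})
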