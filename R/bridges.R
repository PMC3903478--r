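# Side-chain atoms defining the ion-pair criterion.  Histidine nitrogens are
# excluded by default: the comparison tabulates Lys/Arg only among basics,
# and the flag exists for sensitivity analysis.
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
HIS_ATOMS <- c("ND1", "NE2")

# Grid-accelerated cross-pair search: all (i, j) with distance(a_i, b_j)
# within `cutoff` (inclusive).  Identical in result to the O(n^2) scan; the
# test suite asserts exact set equality against brute force.
grid_cross_pairs <- function(a, b, cutoff) {
  if (!nrow(a) || !nrow(b)) {
    return(tibble(i = integer(), j = integer(), d = numeric()))
  }
  cell <- cutoff
  key <- function(m) {
    paste(floor(m$x / cell), floor(m$y / cell), floor(m$z / cell))
  }
  cb <- floor(cbind(b$x, b$y, b$z) / cell)
  bkey <- paste(cb[, 1], cb[, 2], cb[, 3])
  bindex <- split(seq_len(nrow(b)), bkey)
  ca <- floor(cbind(a$x, a$y, a$z) / cell)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out_i <- integer(); out_j <- integer(); out_d <- numeric()
  for (i in seq_len(nrow(a))) {
    nb_keys <- paste(ca[i, 1] + off[, 1], ca[i, 2] + off[, 2],
                     ca[i, 3] + off[, 3])
    cand <- unlist(bindex[nb_keys], use.names = FALSE)
    if (!length(cand)) next
    d <- sqrt((b$x[cand] - a$x[i])^2 + (b$y[cand] - a$y[i])^2 +
                (b$z[cand] - a$z[i])^2)
    hit <- d <= cutoff
    if (any(hit)) {
      out_i <- c(out_i, rep.int(i, sum(hit)))
      out_j <- c(out_j, cand[hit])
      out_d <- c(out_d, d[hit])
    }
  }
  tibble(i = out_i, j = out_j, d = out_d)
}

charged_atom_tables <- function(atoms, include_his = FALSE,
                                include_termini = FALSE) {
  heavy <- atoms[!atoms$hydrogen, ]
  pick <- function(sets) {
    keep <- rep(FALSE, nrow(heavy))
    for (rn in names(sets)) {
      keep <- keep | (heavy$resname == rn & heavy$atom %in% sets[[rn]])
    }
    heavy[keep, ]
  }
  acid <- pick(ACIDIC_ATOMS)
  basic_sets <- BASIC_ATOMS
  if (include_his) basic_sets$HIS <- HIS_ATOMS
  basic <- pick(basic_sets)
  if (include_termini) {
    acid <- bind_rows(acid, heavy[heavy$atom == "OXT", ])
    first_res <- heavy %>%
      group_by(.data$chain) %>%
      filter(.data$resno == min(.data$resno)) %>%
      ungroup()
    basic <- bind_rows(basic, first_res[first_res$atom == "N", ])
  }
  list(acid = acid, basic = basic)
}

#' Detect salt bridges under the side-chain oxygen-nitrogen criterion
#'
#' An ion pair is an acidic residue (Asp/Glu) and a basic residue (Lys/Arg;
#' His optionally) with any side-chain carboxylate-oxygen to amine/guanidinium
#' -nitrogen distance within `cutoff` (inclusive; default 3.2 Angstrom).  The
#' unit reported is the residue pair: however many atomic O-N contacts two
#' residues make, they contribute one pair.  Hydrogens are ignored.
#' Detection uses a spatial grid but is result-identical to an all-pairs
#' scan.
#'
#' @param model A `structure_model` (apply the biological assembly first if
#'   the statistics are meant per functional oligomer).
#' @param cutoff Inclusive distance cutoff in Angstrom (default 3.2).
#' @param include_his Also treat His ND1/NE2 as basic nitrogens.
#' @param include_termini Also include terminal carboxylate (OXT) oxygens and
#'   each chain's first backbone N.
#' @return Tibble with one row per ion pair, ordered by acidic then basic
#'   residue: `acid_chain`, `acid_resno`, `acid_ins`, `acid_resname`,
#'   `basic_chain`, `basic_resno`, `basic_ins`, `basic_resname`,
#'   `min_distance`, `inter_chain`.
#' @export
find_salt_bridges <- function(model, cutoff = 3.2, include_his = FALSE,
                              include_termini = FALSE) {
  stopifnot(cutoff > 0)
  atoms <- as_tibble(model)
  ab <- charged_atom_tables(atoms, include_his, include_termini)
  hits <- grid_cross_pairs(ab$acid, ab$basic, cutoff)
  if (!nrow(hits)) return(empty_ion_pairs())
  acid <- ab$acid[hits$i, c("chain", "resno", "ins", "resname")]
  basic <- ab$basic[hits$j, c("chain", "resno", "ins", "resname")]
  names(acid) <- paste0("acid_", names(acid))
  names(basic) <- paste0("basic_", names(basic))
  pairs <- bind_cols(acid, basic)
  pairs$d <- hits$d
  pairs <- pairs %>%
    filter(!(.data$acid_chain == .data$basic_chain &
               .data$acid_resno == .data$basic_resno &
               .data$acid_ins == .data$basic_ins)) %>%
    group_by(across(c("acid_chain", "acid_resno", "acid_ins",
                      "acid_resname", "basic_chain", "basic_resno",
                      "basic_ins", "basic_resname"))) %>%
    summarise(min_distance = min(.data$d), .groups = "drop") %>%
    mutate(inter_chain = .data$acid_chain != .data$basic_chain) %>%
    arrange(.data$acid_chain, .data$acid_resno, .data$acid_ins,
            .data$basic_chain, .data$basic_resno, .data$basic_ins)
  pairs
}

empty_ion_pairs <- function() {
  tibble(acid_chain = character(), acid_resno = integer(),
         acid_ins = character(), acid_resname = character(),
         basic_chain = character(), basic_resno = integer(),
         basic_ins = character(), basic_resname = character(),
         min_distance = numeric(), inter_chain = logical())
}

#' Aggregate ion pairs into the comparative salt-bridge statistics
#'
#' Yields the two structure-derived descriptors of the thermotolerance
#' comparison: the salt-bridge count and the percentage of all residues of
#' the assembly participating in at least one bridge, each participating
#' residue counted once no matter how many bridges it joins.
#'
#' @param pairs Ion-pair tibble from [find_salt_bridges()].
#' @param model The same `structure_model` the pairs were detected on.
#' @return One-row tibble: `n_pairs`, `n_unique_residues`, `total_residues`,
#'   `fraction_in_sb` (percent), `n_inter_chain`.
#' @export
ion_pair_stats <- function(pairs, model) {
  res <- residue_table(model)
  res_key <- paste(res$chain, res$resno, res$ins)
  keys <- c(paste(pairs$acid_chain, pairs$acid_resno, pairs$acid_ins),
            paste(pairs$basic_chain, pairs$basic_resno, pairs$basic_ins))
  if (nrow(pairs) && !all(keys %in% res_key)) {
    abort("consistency error: ion pair references residues absent from model")
  }
  uniq <- unique(keys)
  tibble(
    n_pairs = nrow(pairs),
    n_unique_residues = length(uniq),
    total_residues = nrow(res),
    fraction_in_sb = 100 * length(uniq) / nrow(res),
    n_inter_chain = sum(pairs$inter_chain)
  )
}

#' Detect disulfide-bond candidates between cysteines
#'
#' All cysteine pairs whose sulfur-sulfur (SG-SG) distance is strictly below
#' `cutoff` (default 6 Angstrom) are reported as candidate disulfide
#' bridges, classified as intra- or inter-subunit by chain identity.  When a
#' cysteine lacks its SG atom the beta carbon is used and the pair flagged.
#'
#' @param model A `structure_model`.
#' @param cutoff Strict (<) distance cutoff in Angstrom, default 6.
#' @return Tibble, one row per unordered pair (first residue lowest by
#'   chain/number): `chain_a`, `resno_a`, `ins_a`, `chain_b`, `resno_b`,
#'   `ins_b`, `distance`, `inter_subunit`, `fallback_atoms`.
#' @export
find_disulfide_candidates <- function(model, cutoff = 6.0) {
  stopifnot(cutoff > 0)
  atoms <- as_tibble(model)
  cys <- atoms[!atoms$hydrogen & atoms$resname == "CYS", ]
  if (!nrow(cys)) return(empty_disulfides())
  cys$.prio <- match(cys$atom, c("SG", "CB"))  # SG preferred, CB fallback
  anchor <- cys %>%
    filter(!is.na(.data$.prio)) %>%
    group_by(.data$chain, .data$resno, .data$ins) %>%
    arrange(.data$.prio, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("chain", "resno", "ins", "atom", "x", "y", "z")
  if (nrow(anchor) < 2) return(empty_disulfides())
  hits <- grid_cross_pairs(anchor, anchor, cutoff)
  hits <- hits[hits$i < hits$j & hits$d < cutoff, ]
  if (!nrow(hits)) return(empty_disulfides())
  a <- anchor[hits$i, ]; b <- anchor[hits$j, ]
  swap <- (b$chain < a$chain) | (b$chain == a$chain & b$resno < a$resno)
  a2 <- a; a <- ifelse_rows(swap, b, a); b <- ifelse_rows(swap, a2, b)
  tibble(
    chain_a = a$chain, resno_a = a$resno, ins_a = a$ins,
    chain_b = b$chain, resno_b = b$resno, ins_b = b$ins,
    distance = hits$d,
    inter_subunit = a$chain != b$chain,
    fallback_atoms = a$atom != "SG" | b$atom != "SG"
  ) %>%
    arrange(.data$chain_a, .data$resno_a, .data$chain_b, .data$resno_b)
}

ifelse_rows <- function(test, yes, no) {
  out <- no
  out[test, ] <- yes[test, ]
  out
}

empty_disulfides <- function() {
  tibble(chain_a = character(), resno_a = integer(), ins_a = character(),
         chain_b = character(), resno_b = integer(), ins_b = character(),
         distance = numeric(), inter_subunit = logical(),
         fallback_atoms = logical())
}

#' Structure-level bridge report
#'
#' Bundles the salt-bridge statistics, disulfide-candidate count and
#' per-chain cysteine counts for one (assembled) structure, with the
#' configuration recorded for provenance.
#'
#' @inheritParams find_salt_bridges
#' @param saltbridge_cutoff,ss_cutoff Distance criteria in Angstrom
#'   (inclusive 3.2 for ion pairs, strict 6 for disulfides).
#' @return One-row tibble: `structure_id`, `n_chains`, `total_residues`,
#'   `cys_per_chain` (list-column of named counts), `n_salt_bridges`,
#'   `n_unique_in_sb`, `pct_in_sb`, `n_inter_chain`, `n_disulfides`,
#'   `n_inter_subunit_ss`, `config` (list-column).
#' @export
bridge_report <- function(model, saltbridge_cutoff = 3.2, ss_cutoff = 6.0,
                          include_his = FALSE, include_termini = FALSE) {
  pairs <- find_salt_bridges(model, saltbridge_cutoff, include_his,
                             include_termini)
  stats <- ion_pair_stats(pairs, model)
  ss <- find_disulfide_candidates(model, ss_cutoff)
  res <- residue_table(model)
  cys <- res %>%
    group_by(.data$chain) %>%
    summarise(n_cys = sum(.data$resname == "CYS"), .groups = "drop")
  tibble(
    structure_id = attr(model, "structure_id") %||% "structure",
    n_chains = length(unique(res$chain)),
    total_residues = stats$total_residues,
    cys_per_chain = list(setNames(cys$n_cys, cys$chain)),
    n_salt_bridges = stats$n_pairs,
    n_unique_in_sb = stats$n_unique_residues,
    pct_in_sb = stats$fraction_in_sb,
    n_inter_chain = stats$n_inter_chain,
    n_disulfides = nrow(ss),
    n_inter_subunit_ss = sum(ss$inter_subunit),
    config = list(list(saltbridge_cutoff = saltbridge_cutoff,
                       ss_cutoff = ss_cutoff,
                       include_his = include_his,
                       include_termini = include_termini,
                       assembly_applied = isTRUE(attr(model,
                                                      "assembly_applied")),
                       assembly_label = attr(model, "assembly_label") %||% ""))
  )
}
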