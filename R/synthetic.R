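#' Specification for a synthetic multimeric test structure
#'
#' Defines a toy multimer with a known, certified number of planted ion
#' pairs, decoy near-miss pairs and disulfide candidates.  Residues sit on a
#' 12-Angstrom lattice (chains stacked in y, residues along x) so that the
#' only side-chain contacts inside any detection criterion are the planted
#' ones; a brute-force self-check certifies this before the structure is
#' returned.  Planted and decoy distance ranges must keep a clear margin of
#' at least 0.05 Angstrom around the 3.2 Angstrom ion-pair cutoff.
#'
#' @param n_chains Number of chains (default 4, the functional oligomer of
#'   the lyase family).
#' @param residues_per_chain Residues per chain (default 60).
#' @param n_salt_bridges Planted acidic-basic pairs inside the cutoff.
#' @param n_inter_chain_bridges How many of those straddle two chains.
#' @param n_decoys Acidic-basic pairs planted just outside the cutoff.
#' @param n_disulfides Planted Cys-Cys pairs inside the 6 Angstrom
#'   criterion.
#' @param n_inter_chain_disulfides How many disulfides straddle two chains.
#' @param bridge_distance_range O-N distance interval for planted pairs,
#'   within (0, 3.15].
#' @param decoy_distance_range O-N interval for decoys, within [3.25, Inf).
#' @param ss_distance_range SG-SG interval for planted disulfides (< 5.95).
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @return A `synthetic_structure_spec` list.
#' @export
synthetic_structure_spec <- function(n_chains = 4, residues_per_chain = 60,
                                     n_salt_bridges = 12,
                                     n_inter_chain_bridges =
                                       if (n_chains > 1)
                                         min(3L, n_salt_bridges) else 0L,
                                     n_decoys = 4,
                                     n_disulfides = 2,
                                     n_inter_chain_disulfides =
                                       if (n_chains > 1)
                                         min(1L, n_disulfides) else 0L,
                                     bridge_distance_range = c(2.8, 3.1),
                                     decoy_distance_range = c(3.4, 4.0),
                                     ss_distance_range = c(2.0, 2.1),
                                     seed = 1) {
  spec <- list(n_chains = n_chains, residues_per_chain = residues_per_chain,
               n_salt_bridges = n_salt_bridges,
               n_inter_chain_bridges = n_inter_chain_bridges,
               n_decoys = n_decoys, n_disulfides = n_disulfides,
               n_inter_chain_disulfides = n_inter_chain_disulfides,
               bridge_distance_range = bridge_distance_range,
               decoy_distance_range = decoy_distance_range,
               ss_distance_range = ss_distance_range, seed = seed)
  if (n_chains < 1 || residues_per_chain < 3) {
    abort("unsatisfiable spec: need at least 1 chain of 3 residues")
  }
  if (n_inter_chain_bridges > n_salt_bridges) {
    abort("unsatisfiable spec: more inter-chain bridges than bridges")
  }
  if (n_inter_chain_disulfides > n_disulfides) {
    abort("unsatisfiable spec: more inter-chain disulfides than disulfides")
  }
  if ((n_inter_chain_bridges > 0 || n_inter_chain_disulfides > 0) &&
      n_chains < 2) {
    abort("unsatisfiable spec: inter-chain features need at least 2 chains")
  }
  if (bridge_distance_range[2] > 3.15 || bridge_distance_range[1] <= 0) {
    abort("unsatisfiable spec: bridge distances must lie in (0, 3.15]")
  }
  if (decoy_distance_range[1] < 3.25) {
    abort("unsatisfiable spec: decoy distances must be >= 3.25")
  }
  if (ss_distance_range[2] >= 5.95 || ss_distance_range[1] <= 0) {
    abort("unsatisfiable spec: disulfide distances must lie in (0, 5.95)")
  }
  n_sites <- n_salt_bridges + n_decoys + n_disulfides
  # every feature takes its own 3-column lattice block (separation margin)
  if (3 * n_sites - 1 > residues_per_chain) {
    abort(paste0("unsatisfiable spec: ", n_sites, " planted features need ",
                 3 * n_sites - 1, " residues per chain, have ",
                 residues_per_chain))
  }
  structure(spec, class = "synthetic_structure_spec")
}

FILLER_RES <- c("ALA", "GLY", "SER", "LEU", "VAL", "THR", "PHE")

#' Generate a synthetic structure with certified planted features
#'
#' Builds the toy multimer described by `spec`: minimal backbone (N, CA, C,
#' O) per residue plus the named side-chain atoms the detection criteria
#' reference (OD1/OE1, NZ/NH1, SG).  Ion pairs, decoys and disulfides are
#' planted at seeded distances inside their configured ranges, each in its
#' own lattice region, then a brute-force all-pairs scan certifies that the
#' planted features are the only ones inside the criteria.
#'
#' @param spec A [synthetic_structure_spec()].
#' @return A list: `model` (a `structure_model`), `truth` (list with
#'   `planted_ion_pairs`, `decoys`, `planted_disulfides` tibbles), `pdb_text`
#'   (the structure as PDB format text) and `spec`.
#' @export
#' @examples
#' gen <- generate_structure(synthetic_structure_spec(seed = 7))
#' nrow(gen$truth$planted_ion_pairs)
generate_structure <- function(spec) {
  stopifnot(inherits(spec, "synthetic_structure_spec"))
  for (attempt in 1:5) {
    gen <- build_synthetic_structure(spec, attempt)
    if (certify_synthetic(gen)) return(gen)
  }
  abort("generator failed certification after 5 attempts")  # nocov
}

build_synthetic_structure <- function(spec, attempt = 1) {
  set.seed(as.integer((as.numeric(spec$seed) * 131071 + attempt) %%
                        2147483647))
  S <- 12
  nc <- spec$n_chains
  nr <- spec$residues_per_chain
  chains <- LETTERS[seq_len(min(nc, 26))]
  if (nc > 26) chains <- c(chains, paste0("Z", seq_len(nc - 26)))

  resname <- matrix(sample(FILLER_RES, nc * nr, replace = TRUE), nc, nr)
  extra <- list()  # per (chain,res) extra side-chain atoms

  n_sites <- spec$n_salt_bridges + spec$n_decoys + spec$n_disulfides
  # one globally unique lattice block of 3 columns per feature, so features
  # can never share residues and stay >= 2 lattice cells apart
  site_cols <- 1L + 3L * (seq_len(n_sites) - 1L)
  site_chain <- 1L + ((seq_len(n_sites) - 1L) %% nc)

  rand_unit <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  runif1 <- function(rng) stats::runif(1, rng[1], rng[2])
  pos <- function(ci, ri) c((ri - 1) * S, (ci - 1) * S, 0)

  ion <- list(); decoy <- list(); ss <- list()
  si <- 0
  add_pair <- function(kind, k_inter, n_inter) {
    si <<- si + 1
    ci <- site_chain[si]; r <- site_cols[si]
    inter <- k_inter >= 1 && k_inter <= n_inter
    if (inter && ci >= nc) ci <- max(1L, nc - 1L)  # partner chain must exist
    cj <- if (inter) ci + 1L else ci
    rj <- if (inter) r else r + 1L
    m <- (pos(ci, r) + pos(cj, rj)) / 2
    u <- rand_unit()
    list(ci = ci, ri = r, cj = cj, rj = rj, m = m, u = u, inter = inter)
  }

  for (k in seq_len(spec$n_salt_bridges)) {
    p <- add_pair("ion", k, spec$n_inter_chain_bridges)
    d <- runif1(spec$bridge_distance_range)
    acid_res <- if (p$inter) "GLU" else "ASP"
    base_res <- if (p$inter) "ARG" else "LYS"
    acid_atom <- if (p$inter) "OE1" else "OD1"
    base_atom <- if (p$inter) "NH1" else "NZ"
    resname[p$ci, p$ri] <- acid_res
    resname[p$cj, p$rj] <- base_res
    extra[[paste(p$ci, p$ri)]] <- tibble(atom = acid_atom, element = "O",
                                         x = p$m[1] - d / 2 * p$u[1],
                                         y = p$m[2] - d / 2 * p$u[2],
                                         z = p$m[3] - d / 2 * p$u[3])
    extra[[paste(p$cj, p$rj)]] <- tibble(atom = base_atom, element = "N",
                                         x = p$m[1] + d / 2 * p$u[1],
                                         y = p$m[2] + d / 2 * p$u[2],
                                         z = p$m[3] + d / 2 * p$u[3])
    ion[[k]] <- tibble(acid_chain = chains[p$ci], acid_resno = p$ri,
                       acid_resname = acid_res,
                       basic_chain = chains[p$cj], basic_resno = p$rj,
                       basic_resname = base_res,
                       distance = d, inter_chain = p$inter)
  }
  for (k in seq_len(spec$n_decoys)) {
    p <- add_pair("decoy", 0, 0)
    d <- runif1(spec$decoy_distance_range)
    resname[p$ci, p$ri] <- "ASP"
    resname[p$cj, p$rj] <- "LYS"
    extra[[paste(p$ci, p$ri)]] <- tibble(atom = "OD1", element = "O",
                                         x = p$m[1] - d / 2 * p$u[1],
                                         y = p$m[2] - d / 2 * p$u[2],
                                         z = p$m[3] - d / 2 * p$u[3])
    extra[[paste(p$cj, p$rj)]] <- tibble(atom = "NZ", element = "N",
                                         x = p$m[1] + d / 2 * p$u[1],
                                         y = p$m[2] + d / 2 * p$u[2],
                                         z = p$m[3] + d / 2 * p$u[3])
    decoy[[k]] <- tibble(acid_chain = chains[p$ci], acid_resno = p$ri,
                         basic_chain = chains[p$cj], basic_resno = p$rj,
                         distance = d)
  }
  for (k in seq_len(spec$n_disulfides)) {
    p <- add_pair("ss", k, spec$n_inter_chain_disulfides)
    d <- runif1(spec$ss_distance_range)
    resname[p$ci, p$ri] <- "CYS"
    resname[p$cj, p$rj] <- "CYS"
    extra[[paste(p$ci, p$ri)]] <- tibble(atom = "SG", element = "S",
                                         x = p$m[1] - d / 2 * p$u[1],
                                         y = p$m[2] - d / 2 * p$u[2],
                                         z = p$m[3] - d / 2 * p$u[3])
    extra[[paste(p$cj, p$rj)]] <- tibble(atom = "SG", element = "S",
                                         x = p$m[1] + d / 2 * p$u[1],
                                         y = p$m[2] + d / 2 * p$u[2],
                                         z = p$m[3] + d / 2 * p$u[3])
    ss[[k]] <- tibble(chain_a = chains[p$ci], resno_a = p$ri,
                      chain_b = chains[p$cj], resno_b = p$rj,
                      distance = d, inter_subunit = p$inter)
  }

  rows <- vector("list", nc * nr)
  idx <- 0
  for (ci in seq_len(nc)) {
    for (ri in seq_len(nr)) {
      o <- pos(ci, ri)
      rn <- resname[ci, ri]
      at <- tibble(
        atom = c("N", "CA", "C", "O"),
        element = c("N", "C", "C", "O"),
        x = o[1] + c(-1.2, 0, 1.2, 1.8),
        y = o[2] + c(0, 0, 0, 0),
        z = o[3] + c(0, 0, 0, 1.0))
      if (rn != "GLY") {
        at <- bind_rows(at, tibble(atom = "CB", element = "C",
                                   x = o[1], y = o[2], z = o[3] + 1.6))
      }
      ex <- extra[[paste(ci, ri)]]
      if (!is.null(ex)) at <- bind_rows(at, ex)
      at$chain <- chains[ci]; at$resno <- ri; at$resname <- rn
      idx <- idx + 1
      rows[[idx]] <- at
    }
  }
  atoms <- bind_rows(rows)
  atoms <- tibble(
    chain = atoms$chain, resno = as.integer(atoms$resno), ins = "",
    resname = atoms$resname,
    aa = unname(AA_321[atoms$resname]),
    atom = atoms$atom, element = atoms$element, alt = "",
    occ = 1, hydrogen = FALSE,
    x = atoms$x, y = atoms$y, z = atoms$z)
  model <- new_structure_model(atoms, structure_id =
                                 paste0("synthetic_seed", spec$seed))
  truth <- list(
    planted_ion_pairs = if (length(ion)) bind_rows(ion) else
      tibble(acid_chain = character(), acid_resno = integer(),
             acid_resname = character(), basic_chain = character(),
             basic_resno = integer(), basic_resname = character(),
             distance = numeric(), inter_chain = logical()),
    decoys = if (length(decoy)) bind_rows(decoy) else
      tibble(acid_chain = character(), acid_resno = integer(),
             basic_chain = character(), basic_resno = integer(),
             distance = numeric()),
    planted_disulfides = if (length(ss)) bind_rows(ss) else
      tibble(chain_a = character(), resno_a = integer(),
             chain_b = character(), resno_b = integer(),
             distance = numeric(), inter_subunit = logical())
  )
  list(model = model, truth = truth,
       pdb_text = write_pdb_text(atoms), spec = spec)
}

# Brute-force certification that planted features are the only ones inside
# the criteria (independent of the grid-based detectors).
certify_synthetic <- function(gen) {
  atoms <- as_tibble(gen$model)
  pair_key <- function(c1, r1, c2, r2) paste(c1, r1, c2, r2)
  acid <- atoms[atoms$atom %in% c("OD1", "OD2", "OE1", "OE2"), ]
  basic <- atoms[atoms$atom %in% c("NZ", "NE", "NH1", "NH2"), ]
  found <- character()
  if (nrow(acid) && nrow(basic)) {
    for (i in seq_len(nrow(acid))) {
      d <- sqrt((basic$x - acid$x[i])^2 + (basic$y - acid$y[i])^2 +
                  (basic$z - acid$z[i])^2)
      hit <- which(d <= 3.2)
      if (length(hit)) {
        found <- c(found, pair_key(acid$chain[i], acid$resno[i],
                                   basic$chain[hit], basic$resno[hit]))
      }
    }
  }
  tp <- gen$truth$planted_ion_pairs
  want <- pair_key(tp$acid_chain, tp$acid_resno, tp$basic_chain,
                   tp$basic_resno)
  ok_ion <- setequal(unique(found), want)

  sg <- atoms[atoms$atom == "SG", ]
  found_ss <- character()
  if (nrow(sg) > 1) {
    for (i in seq_len(nrow(sg) - 1)) {
      js <- (i + 1):nrow(sg)
      d <- sqrt((sg$x[js] - sg$x[i])^2 + (sg$y[js] - sg$y[i])^2 +
                  (sg$z[js] - sg$z[i])^2)
      hit <- js[d < 6]
      if (length(hit)) {
        found_ss <- c(found_ss, pair_key(sg$chain[i], sg$resno[i],
                                         sg$chain[hit], sg$resno[hit]))
      }
    }
  }
  ts <- gen$truth$planted_disulfides
  want_ss <- pair_key(ts$chain_a, ts$resno_a, ts$chain_b, ts$resno_b)
  ok_ion && setequal(unique(found_ss), want_ss)
}

# Render the tidy atom table as fixed-width PDB ATOM records.
write_pdb_text <- function(atoms) {
  name4 <- ifelse(nchar(atoms$atom) < 4, paste0(" ", atoms$atom),
                  atoms$atom)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), name4, "", atoms$resname,
    substr(atoms$chain, 1, 1), atoms$resno, "",
    atoms$x, atoms$y, atoms$z, atoms$occ %||% 1, 0, atoms$element)
  paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
}

#' Generate a sequence with controlled composition and planted motifs
#'
#' Builds a random protein sequence whose residue counts match
#' `composition_target` (within one count per targeted letter), then plants
#' the requested motifs at their exact positions by swapping residues, and
#' rejection-samples the remainder until each planted motif string occurs
#' nowhere else in the sequence.
#'
#' @param length Sequence length in residues.
#' @param composition_target Named numeric vector of target frequencies
#'   (fractions summing to at most 1), e.g. `c(D = 0.2)`; unspecified mass
#'   is spread over the remaining canonical residues.
#' @param plants A data frame (or list coercible to one) with columns
#'   `motif` and `position` (1-based start).  Plants must not overlap.
#' @param seed Integer seed.
#' @return A list: `sequence` (one-row tibble `source_id`, `chain`,
#'   `sequence`, `offset`), `truth` (tibble of planted motifs).
#' @export
#' @examples
#' gen <- generate_sequence(60, plants = data.frame(motif = "ASG",
#'                                                  position = 20), seed = 2)
#' substr(gen$sequence$sequence, 20, 22)
generate_sequence <- function(length, composition_target = NULL,
                              plants = NULL, seed = 1) {
  stopifnot(length >= 1)
  if (!is.null(plants)) {
    plants <- as_tibble(as.data.frame(plants))
    stopifnot(all(c("motif", "position") %in% names(plants)))
    plants$motif <- toupper(plants$motif)
    plants$position <- as.integer(plants$position)
    ends <- plants$position + nchar(plants$motif) - 1L
    if (any(plants$position < 1) || any(ends > length)) {
      abort("plants do not fit inside the sequence length")
    }
    if (nrow(plants) > 1) {
      o <- order(plants$position)
      p <- plants[o, ]
      if (any(p$position[-1] <= (p$position + nchar(p$motif) - 1L)
              [-nrow(p)])) {
        abort("overlapping plants")
      }
    }
  } else {
    plants <- tibble(motif = character(), position = integer())
  }

  target <- rep(0, 20)
  names(target) <- AA_ONE
  if (!is.null(composition_target)) {
    stopifnot(all(names(composition_target) %in% AA_ONE))
    target[names(composition_target)] <- composition_target
  }
  fixed_n <- round_half_away(target * length)
  rest <- length - sum(fixed_n)
  if (rest < 0) abort("composition_target frequencies exceed 1")
  free_letters <- setdiff(AA_ONE, names(composition_target))
  if (!length(free_letters)) free_letters <- AA_ONE
  pool <- c(rep(names(fixed_n), fixed_n),
            free_letters[1 + (seq_len(rest) - 1) %% length(free_letters)])

  planted_pos <- unlist(purrr::map2(plants$position, nchar(plants$motif),
                                    function(p, w) seq(p, p + w - 1L)))
  planted_chr <- unlist(strsplit(plants$motif, ""))

  set.seed(as.integer((as.numeric(seed) * 524287) %% 2147483647))
  for (try in 1:100) {
    s <- sample(pool, length)
    # impose plants by swapping with positions holding the needed letter
    for (k in seq_along(planted_pos)) {
      p <- planted_pos[k]; L <- planted_chr[k]
      if (s[p] == L) next
      cand <- setdiff(which(s == L), planted_pos)
      if (length(cand)) {
        q <- cand[1]
        s[q] <- s[p]
        s[p] <- L
      } else {
        s[p] <- L  # letter absent from pool: replace (count drifts by 1)
      }
    }
    seq_str <- paste(s, collapse = "")
    clean <- TRUE
    for (k in seq_len(nrow(plants))) {
      occ <- gregexpr(plants$motif[k], seq_str, fixed = TRUE)[[1]]
      occ <- occ[occ > 0]
      if (!setequal(occ, plants$position[k])) {
        # also accept occurrences that are themselves other plant sites
        if (!all(occ %in% plants$position)) {
          clean <- FALSE
          break
        }
      }
    }
    if (clean) {
      return(list(
        sequence = tibble(source_id = paste0("synthetic_seq_seed", seed),
                          chain = NA_character_, sequence = seq_str,
                          offset = 1L),
        truth = plants))
    }
  }
  abort("could not place plants without accidental motif copies")
}
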