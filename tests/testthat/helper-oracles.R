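# Independent oracles: deliberately naive implementations, sharing no code
# with the package internals they check.

# All-pairs O(n^2) ion-pair scan over the atom table.
brute_force_ion_pairs <- function(model, cutoff = 3.2, include_his = FALSE) {
  atoms <- as.data.frame(model)
  atoms <- atoms[!atoms$hydrogen, ]
  acid_names <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  basic_names <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
  if (include_his) basic_names$HIS <- c("ND1", "NE2")
  is_in <- function(df, sets) {
    keep <- rep(FALSE, nrow(df))
    for (rn in names(sets)) {
      keep <- keep | (df$resname == rn & df$atom %in% sets[[rn]])
    }
    df[keep, ]
  }
  acid <- is_in(atoms, acid_names)
  basic <- is_in(atoms, basic_names)
  keys <- character()
  if (nrow(acid) && nrow(basic)) {
    for (i in seq_len(nrow(acid))) {
      d <- sqrt((basic$x - acid$x[i])^2 + (basic$y - acid$y[i])^2 +
                  (basic$z - acid$z[i])^2)
      hit <- which(d <= cutoff)
      if (length(hit)) {
        keys <- c(keys, paste(acid$chain[i], acid$resno[i], acid$ins[i],
                              basic$chain[hit], basic$resno[hit],
                              basic$ins[hit]))
      }
    }
  }
  sort(unique(keys))
}

brute_force_disulfides <- function(model, cutoff = 6.0) {
  atoms <- as.data.frame(model)
  sg <- atoms[!atoms$hydrogen & atoms$resname == "CYS" & atoms$atom == "SG", ]
  keys <- character()
  if (nrow(sg) > 1) {
    for (i in seq_len(nrow(sg) - 1)) {
      for (j in (i + 1):nrow(sg)) {
        d <- sqrt(sum((unlist(sg[i, c("x", "y", "z")]) -
                         unlist(sg[j, c("x", "y", "z")]))^2))
        if (d < cutoff) {
          a <- sg[i, ]; b <- sg[j, ]
          if (b$chain < a$chain || (b$chain == a$chain && b$resno < a$resno)) {
            tmp <- a; a <- b; b <- tmp
          }
          keys <- c(keys, paste(a$chain, a$resno, b$chain, b$resno))
        }
      }
    }
  }
  sort(unique(keys))
}

ion_pair_keys <- function(pairs) {
  sort(paste(pairs$acid_chain, pairs$acid_resno, pairs$acid_ins,
             pairs$basic_chain, pairs$basic_resno, pairs$basic_ins))
}

disulfide_keys <- function(ss) {
  sort(paste(ss$chain_a, ss$resno_a, ss$chain_b, ss$resno_b))
}

# Independent affine-gap global alignment score (Gotoh three-state DP).
# Gap of length L costs open + L * extend, end gaps penalized.
nw_affine_score <- function(q, r, mat, open = 10, extend = 0.5) {
  qs <- strsplit(q, "")[[1]]
  rs <- strsplit(r, "")[[1]]
  n <- length(qs); m <- length(rs)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in reference (consume query)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in query (consume reference)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - extend * (i - 1)
  for (j in 2:(m + 1)) Iy[1, j] <- -open - extend * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[qs[i - 1], rs[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend,
                      Iy[i - 1, j] - open - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend,
                      Ix[i, j - 1] - open - extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# Exact accessible area of sphere 1 (radius R1) partially covered by sphere 2
# (radius R2) at centre distance d: full area minus the spherical cap.
two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  if (d + R1 <= R2) return(0)
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# Minimal hand-written PDB fixtures ---------------------------------------

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, element = substr(name, 1, 1),
                          alt = " ", record = "ATOM") {
  name4 <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, alt, resname, chain, resno, x, y, z,
          occ, 0, element)
}

# Two chains x three residues, four atoms each (N, CA, C, O) = 24 atoms.
fixture_two_chain_pdb <- function() {
  res <- c("ASP", "GLU", "LYS")
  lines <- character(); serial <- 0
  for (ch in c("A", "B")) {
    for (ri in 1:3) {
      base <- c((ri - 1) * 10, if (ch == "A") 0 else 30, 0)
      for (at in list(c("N", -1.2, 0, 0), c("CA", 0, 0, 0),
                      c("C", 1.2, 0, 0), c("O", 1.8, 0, 1))) {
        serial <- serial + 1
        lines <- c(lines, pdb_atom_line(
          serial, at[1], res[ri], ch, ri,
          base[1] + as.numeric(at[2]), base[2] + as.numeric(at[3]),
          base[3] + as.numeric(at[4])))
      }
    }
  }
  paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
}

remark350_block <- function(ops, chains = "A", biomol = 1) {
  lines <- c(sprintf("REMARK 350 BIOMOLECULE: %d", biomol),
             paste0("REMARK 350 APPLY THE FOLLOWING TO CHAINS: ",
                    paste(chains, collapse = ", ")))
  for (k in seq_along(ops)) {
    m <- ops[[k]]
    for (i in 1:3) {
      lines <- c(lines, sprintf(
        "REMARK 350   BIOMT%d %3d %9.6f %9.6f %9.6f %14.5f",
        i, k, m[i, 1], m[i, 2], m[i, 3], m[i, 4]))
    }
  }
  lines
}

rot_z <- function(deg, shift = c(0, 0, 0)) {
  th <- deg * pi / 180
  cbind(matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3),
        shift)
}

# A one-chain, two-residue monomer carrying a 4-operator assembly.
fixture_assembly_pdb <- function(ops = list(rot_z(0), rot_z(90, c(20, 0, 0)),
                                            rot_z(180, c(0, 20, 0)),
                                            rot_z(270, c(20, 20, 0)))) {
  lines <- remark350_block(ops)
  serial <- 0
  for (ri in 1:2) {
    for (at in list(c("N", -1.2, 0, 0), c("CA", 0, 0, 0),
                    c("C", 1.2, 0, 0))) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line(
        serial, at[1], "ALA", "A", ri,
        (ri - 1) * 5 + as.numeric(at[2]), as.numeric(at[3]),
        as.numeric(at[4])))
    }
  }
  paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
}

model_checksum <- function(model) {
  atoms <- as.data.frame(model)
  sum(atoms$x * 1.7 + atoms$y * 2.3 + atoms$z * 3.1) + nrow(atoms)
}

# Tiny bespoke model builder for targeted geometric cases.
toy_model <- function(..., structure_id = "toy") {
  rows <- list(...)
  at <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chain = r$chain, resno = r$resno, resname = r$resname,
               atom = r$atom, element = r$element,
               x = r$x, y = r$y, z = r$z, stringsAsFactors = FALSE)
  }))
  aa_map <- c(ALA = "A", ASP = "D", GLU = "E", LYS = "K", ARG = "R",
              CYS = "C", GLY = "G", SER = "S")
  new_structure_model(tibble::tibble(
    chain = at$chain, resno = as.integer(at$resno), ins = "",
    resname = at$resname,
    aa = ifelse(is.na(aa_map[at$resname]), "X", aa_map[at$resname]),
    atom = at$atom, element = at$element, alt = "", occ = 1,
    hydrogen = FALSE, x = at$x, y = at$y, z = at$z),
    structure_id = structure_id)
}

res_atoms <- function(chain, resno, resname, atoms) {
  lapply(atoms, function(a) {
    list(chain = chain, resno = resno, resname = resname,
         atom = a[[1]], element = a[[2]],
         x = a[[3]], y = a[[4]], z = a[[5]])
  })
}

random_aa_string <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
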