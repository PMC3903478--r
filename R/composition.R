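#' Per-chain residue composition, cysteine count and acid excess
#'
#' Computes the sequence-derived descriptors used to compare alkalophilic and
#' thermotolerant ammonia-lyases: chain length, per-residue counts and
#' percentages, cysteine count, and the acid excess
#' `(#Asp + #Glu) - (#Lys + #Arg)`.  A positive acid excess marks a
#' net-acidic chain, the compositional signature associated with activity at
#' strongly basic pH.  `X` placeholders for non-standard residues count
#' toward chain length but never toward the charged-residue statistics.
#'
#' @param seqs A sequence tibble (columns `source_id`, `chain`, `sequence`),
#'   as returned by [read_fasta()] or [extract_sequences()], or a character
#'   vector of sequences.
#' @return A tibble with one row per sequence: `source_id`, `chain`,
#'   `chain_length`, `cys_count`, `pct_asp`, `pct_glu`, `pct_lys`, `pct_arg`,
#'   `acid_excess`, and a `counts` list-column holding the full named count
#'   vector.  Percentages are exact; round only for reporting.
#' @export
#' @examples
#' composition("DDEEKR")
composition <- function(seqs) {
  if (is.character(seqs)) {
    seqs <- tibble(source_id = paste0("seq", seq_along(seqs)),
                   chain = NA_character_, sequence = seqs)
  }
  stopifnot(all(c("source_id", "sequence") %in% names(seqs)))
  if (!"chain" %in% names(seqs)) seqs$chain <- NA_character_
  rows <- purrr::pmap(
    list(seqs$source_id, seqs$chain, seqs$sequence),
    function(id, ch, s) {
      if (!nzchar(s)) abort(paste0("empty sequence for '", id, "'"))
      letters1 <- strsplit(s, "")[[1]]
      bad <- setdiff(letters1, c(AA_ONE, "X"))
      if (length(bad)) {
        abort(paste0("non-canonical residue code(s) ",
                     paste(unique(bad), collapse = ""), " in '", id, "'"))
      }
      counts <- table(factor(letters1, levels = c(AA_ONE, "X")))
      counts <- setNames(as.integer(counts), names(counts))
      len <- length(letters1)
      tibble(
        source_id = id, chain = ch,
        chain_length = len,
        cys_count = counts[["C"]],
        pct_asp = 100 * counts[["D"]] / len,
        pct_glu = 100 * counts[["E"]] / len,
        pct_lys = 100 * counts[["K"]] / len,
        pct_arg = 100 * counts[["R"]] / len,
        acid_excess = counts[["D"]] + counts[["E"]] -
          counts[["K"]] - counts[["R"]],
        counts = list(counts)
      )
    })
  bind_rows(rows)
}

#' Reconstruct acid excess from printed composition percentages
#'
#' Published comparison tables report Asp/Glu/Lys/Arg content as rounded
#' percentages of chain length; this utility inverts that rounding to recover
#' the integer acid excess `(#Asp + #Glu) - (#Lys + #Arg)`:
#' `round(length * (asp + glu - lys - arg) / 100)`, with exact halves rounded
#' away from zero.
#'
#' @param length Chain length in residues.
#' @param asp_pct,glu_pct,lys_pct,arg_pct Percent content of the four
#'   residue types (as printed, typically 1 decimal).
#' @return Integer acid excess (vectorised).
#' @export
#' @examples
#' acid_excess_from_percentages(509, 5.1, 5.7, 3.5, 5.3) # 10
acid_excess_from_percentages <- function(length, asp_pct, glu_pct,
                                         lys_pct, arg_pct) {
  stopifnot(all(length > 0),
            all(c(asp_pct, glu_pct, lys_pct, arg_pct) >= 0))
  as.integer(round_half_away(
    length * (asp_pct + glu_pct - lys_pct - arg_pct) / 100))
}
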