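#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pairwise alignment into one row per alignment column
#'
#' @param x An `alignment_result` from [global_align()].
#' @param ... Unused.
#' @return Tibble with `column`, `query_pos`, `ref_pos` (`NA` opposite a
#'   gap), `query_char`, `ref_char`, `match`.
#' @method tidy alignment_result
#' @export
tidy.alignment_result <- function(x, ...) {
  qc <- strsplit(x$aligned_query, "")[[1]]
  rc <- strsplit(x$aligned_reference, "")[[1]]
  qpos <- cumsum(qc != "-"); qpos[qc == "-"] <- NA
  rpos <- cumsum(rc != "-"); rpos[rc == "-"] <- NA
  tibble(column = seq_along(qc), query_pos = as.integer(qpos),
         ref_pos = as.integer(rpos), query_char = qc, ref_char = rc,
         match = qc == rc & qc != "-")
}

#' @rdname tidy.alignment_result
#' @method glance alignment_result
#' @export
glance.alignment_result <- function(x, ...) {
  tibble(score = x$score, percent_identity = x$percent_identity,
         alignment_length = nchar(x$aligned_query))
}

#' Tidy per-residue solvent accessibility
#'
#' @param x A `sasa_result` from [compute_sasa()].
#' @param ... Unused.
#' @return `tidy()`: the per-residue area tibble.  `glance()`: a one-row
#'   summary (`n_atoms`, `total_area`, `probe`, `n_points`).
#' @method tidy sasa_result
#' @export
tidy.sasa_result <- function(x, ...) x$per_residue

#' @rdname tidy.sasa_result
#' @method glance sasa_result
#' @export
glance.sasa_result <- function(x, ...) {
  tibble(n_atoms = nrow(x$per_atom), total_area = sum(x$per_atom$area),
         probe = x$probe, n_points = x$n_points)
}

#' Per-residue accessibility profile plot
#'
#' @param object A `sasa_result`.
#' @param ... Unused.
#' @return A ggplot: residue SASA along each chain.
#' @method autoplot sasa_result
#' @export
autoplot.sasa_result <- function(object, ...) {
  pr <- object$per_residue
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$resno, y = .data$area)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~chain) +
    ggplot2::labs(x = "residue number",
                  y = expression("SASA (" * ring(A)^2 * ")"))
}

#' Ionizable-residue composition plot
#'
#' Bar chart of the Asp/Glu/Lys/Arg percentages per sequence, the
#' compositional signature separating acid-rich alkalophilic chains from
#' their neutral relatives.
#'
#' @param profile Composition tibble from [composition()] (or any data frame
#'   with `source_id` and the four `pct_*` columns).
#' @return A ggplot.
#' @export
plot_composition <- function(profile) {
  long <- tidyr::pivot_longer(
    profile[c("source_id", "pct_asp", "pct_glu", "pct_lys", "pct_arg")],
    cols = -"source_id", names_to = "residue", values_to = "pct")
  long$residue <- factor(toupper(sub("pct_", "", long$residue)),
                         levels = c("ASP", "GLU", "LYS", "ARG"))
  long$charge <- ifelse(long$residue %in% c("ASP", "GLU"),
                        "acidic", "basic")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$residue, y = .data$pct,
                                     fill = .data$charge)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~source_id) +
    ggplot2::labs(x = NULL, y = "% of chain")
}

#' Ion-pair distance distribution plot
#'
#' @param pairs Ion-pair tibble from [find_salt_bridges()].
#' @param binwidth Histogram bin width in Angstrom.
#' @return A ggplot of minimum O-N distances, intra vs inter chain.
#' @export
plot_ion_pairs <- function(pairs, binwidth = 0.05) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$min_distance,
                                      fill = .data$inter_chain)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = expression("minimum O-N distance (" * ring(A) * ")"),
                  y = "ion pairs", fill = "inter-chain")
}
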