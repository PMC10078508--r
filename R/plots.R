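# ggplot2 views of the three result types mitogenome papers figure:
# RSCU bars per synonymous family, the amino-acid usage bar chart, and the
# per-gene Pi / Ka/Ks divergence panel.

#' RSCU bar chart grouped by amino acid
#'
#' @param usage a `codon_usage` object from [count_codons()].
#' @return a ggplot object.
#' @export
plot_rscu <- function(usage) {
  stopifnot(inherits(usage, "codon_usage"))
  df <- as_tibble(usage) |> filter(!is.na(.data$rscu))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$rscu,
                                   fill = .data$aa)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_grid(~aa, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "RSCU",
                  title = "Relative synonymous codon usage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Amino-acid usage bar chart
#'
#' @param usage a `codon_usage` object.
#' @return a ggplot object.
#' @export
plot_amino_acids <- function(usage) {
  aa <- amino_acid_usage(usage)
  ggplot2::ggplot(aa, ggplot2::aes(x = stats::reorder(.data$aa, -.data$pct),
                                   y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "amino acid", y = "% of codons",
                  title = "Amino-acid composition of the PCGs") +
    ggplot2::theme_minimal()
}

#' Per-gene divergence panel (Pi and Ka/Ks)
#'
#' @param panel the tibble returned by [gene_panel()].
#' @return a ggplot object with one facet per statistic.
#' @export
plot_divergence <- function(panel) {
  df <- panel |>
    select("gene", Pi = "pi", `Ka/Ks` = "omega") |>
    tidyr::pivot_longer(-"gene", names_to = "stat", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$value)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::facet_wrap(~stat, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Nucleotide diversity and Ka/Ks per PCG") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
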