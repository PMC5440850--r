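#' Plot a vote vector
#'
#' Displacement profile of a voting task: raw votes and, optionally, the
#' window-sum convolved votes used for scoring.
#'
#' @param votes an `mv_votes` object from [cast_votes()].
#' @param n_conv if not `NULL`, overlay the convolved votes at this radius.
#' @return A ggplot object.
#' @export
plot_votes <- function(votes, n_conv = 10L) {
  stopifnot(inherits(votes, "mv_votes"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_votes() requires ggplot2")
  phi <- votes$phi0 + seq_along(votes$V) - 1
  df <- tibble::tibble(phi = phi, votes = votes$V, what = "raw")
  if (!is.null(n_conv)) {
    vc <- convolve_votes(votes, n_conv)
    df <- rbind(df, tibble::tibble(phi = phi, votes = vc$V,
                                   what = sprintf("convolved (n=%d)", n_conv)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = phi, y = votes,
                                   colour = what)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "displacement (contig - read position)", y = "votes",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the mapping-quality distribution of an alignment run
#'
#' @param alignments an `mv_alignments` tibble.
#' @return A ggplot object.
#' @export
plot_mapq <- function(alignments) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_mapq() requires ggplot2")
  ggplot2::ggplot(alignments[alignments$mapped, ],
                  ggplot2::aes(x = mapq)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "mapping quality", y = "reads") +
    ggplot2::theme_minimal()
}
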