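#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers and plots for cascade results
#'
#' `tidy()` returns the assignment table, `glance()` a one-row summary
#' (inputs, assigned, orphans, assignment rate), and `autoplot()` the
#' per-round assignment counts.
#'
#' @param x A `cascade_result` from [run_cascade()].
#' @param ... Unused.
#' @name cascade_result-tidiers
NULL

#' @rdname cascade_result-tidiers
#' @export
tidy.cascade_result <- function(x, ...) x$assignments

#' @rdname cascade_result-tidiers
#' @export
glance.cascade_result <- function(x, ...) {
  n_in <- nrow(x$assignments) + nrow(x$orphans)
  tibble(n_input = n_in, n_assigned = nrow(x$assignments),
         n_orphan = nrow(x$orphans),
         assignment_rate = if (n_in > 0) nrow(x$assignments) / n_in else NA_real_)
}

#' @rdname cascade_result-tidiers
#' @param object A `cascade_result`.
#' @export
autoplot.cascade_result <- function(object, ...) {
  counts <- object$round_counts
  counts$round <- factor(counts$round, levels = counts$round)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$round, y = .data$n_assigned)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_assigned), vjust = -0.4) +
    ggplot2::labs(x = "cascade round", y = "queries assigned",
                  title = "Homology assignment by round") +
    ggplot2::theme_minimal()
}

#' Tidiers and plots for consensus records
#'
#' `tidy()` returns one row per member with its orientation/frame,
#' `glance()` a one-row summary including the regional gap percentages, and
#' `autoplot()` a bar chart of gap percentage per consensus region.
#'
#' @param x A `consensus_record` from [build_consensus()].
#' @param ... Unused.
#' @name consensus_record-tidiers
NULL

#' @rdname consensus_record-tidiers
#' @export
tidy.consensus_record <- function(x, ...) {
  mutate(x$members, consensus = x$name)
}

#' @rdname consensus_record-tidiers
#' @export
glance.consensus_record <- function(x, ...) {
  tibble(name = x$name, n_members = nrow(x$members),
         is_one_to_one = x$is_one_to_one,
         length = nchar(x$aligned_seq), ref_len = x$ref_len,
         gap_pct_5prime = x$gap_pct[[1]], gap_pct_middle = x$gap_pct[[2]],
         gap_pct_3prime = x$gap_pct[[3]], discordant = x$discordant)
}

#' @rdname consensus_record-tidiers
#' @param object A `consensus_record`.
#' @export
autoplot.consensus_record <- function(object, ...) {
  df <- tibble(region = factor(c("5'", "middle", "3'"),
                               levels = c("5'", "middle", "3'")),
               gap_pct = as.numeric(object$gap_pct))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$gap_pct)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "gap %",
                  title = paste0("Gap regions of consensus ", object$name)) +
    ggplot2::theme_minimal()
}

#' Tidiers and plots for supermatrices
#'
#' `tidy()` returns one row per partition with its width and gap content,
#' `glance()` a one-row summary of the matrix, and `autoplot()` the sorted
#' per-column gap-score distribution (the curve the maximum-drop trimming
#' rule cuts), with the cut threshold marked when the matrix has been
#' trimmed with `max_drop`.
#'
#' @param x A `supermatrix` from [concatenate_genes()].
#' @param ... Unused.
#' @name supermatrix-tidiers
NULL

#' @rdname supermatrix-tidiers
#' @export
tidy.supermatrix <- function(x, ...) {
  scores <- .gap_scores(x)
  x$partitions |>
    mutate(width = .data$end - .data$start + 1L,
           mean_gap_score = map2_dbl(.data$start, .data$end, function(s, e) {
             mean(scores[s:e])
           }))
}

#' @rdname supermatrix-tidiers
#' @export
glance.supermatrix <- function(x, ...) {
  scores <- .gap_scores(x)
  tibble(n_taxa = length(x$seqs), n_columns = nchar(x$seqs[[1]]),
         n_genes = nrow(x$partitions),
         pct_gap = 100 * (1 - mean(scores)),
         n_complete_columns = sum(scores == 1))
}

#' @rdname supermatrix-tidiers
#' @param object A `supermatrix`.
#' @export
autoplot.supermatrix <- function(object, ...) {
  scores <- sort(.gap_scores(object), decreasing = TRUE)
  df <- tibble(rank = seq_along(scores), gap_score = scores)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$gap_score)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "column rank", y = "gap score (fraction non-gap)",
                  title = "Sorted column gap scores") +
    ggplot2::theme_minimal()
  if (!is.null(object$trim_threshold) && !is.na(object$trim_threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = object$trim_threshold,
                                 linetype = "dashed")
  }
  p
}

#' Plot per-feature coverage of a reference-guided assembly
#'
#' @param assembly The list returned by [reference_guided_assembly()] (with
#'   a non-`NULL` coverage element).
#' @return A ggplot.
#' @export
plot_mt_coverage <- function(assembly) {
  cov <- assembly$coverage
  if (is.null(cov)) abort("assembly has no coverage table (no features given)")
  cov$gene_name <- factor(cov$gene_name, levels = cov$gene_name)
  ggplot2::ggplot(cov, ggplot2::aes(x = .data$gene_name,
                                    y = .data$covered_frac,
                                    fill = .data$feature_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of positions covered",
                  title = "Mitochondrial feature coverage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
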