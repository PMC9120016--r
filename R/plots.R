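# ggplot2 autoplot methods for the main result types.

#' Plot an rmsf flexibility profile
#'
#' @param object a `fold_flexprofile`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fold_flexprofile
#' @export
autoplot.fold_flexprofile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$position <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$rmsf_nm,
                                   colour = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "rmsf (nm)",
                  title = "Flexibility profile") +
    ggplot2::theme_minimal()
}

#' Scree plot of a PCA result
#'
#' @param object a `fold_pca`.
#' @param n_modes leading modes to show (default 10).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fold_pca
#' @export
autoplot.fold_pca <- function(object, n_modes = 10L, ...) {
  df <- tidy(object, n_modes = n_modes)
  ggplot2::ggplot(df, ggplot2::aes(.data$mode, .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::labs(x = "principal component", y = "variance fraction",
                  title = "Mode spectrum") +
    ggplot2::theme_minimal()
}

#' Plot the nMI distribution and retained edges of a coupling network
#'
#' @param object a `fold_network`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fold_network
#' @export
autoplot.fold_network <- function(object, ...) {
  df <- object$all_pairs
  ggplot2::ggplot(df, ggplot2::aes(.data$nmi)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$nmi_threshold,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$significance_cut,
                        linetype = "dotted") +
    ggplot2::labs(x = "corrected nMI", y = "pairs",
                  title = "Coupling strength distribution") +
    ggplot2::theme_minimal()
}

#' Plot a frustration profile
#'
#' @param object a `fold_frustration`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fold_frustration
#' @export
autoplot.fold_frustration <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$contact <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$contact, .data$index,
                                   colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(0.78, -1), linetype = "dashed") +
    ggplot2::labs(y = "frustration index",
                  title = "Contact frustration") +
    ggplot2::theme_minimal()
}

#' Plot ranked scaled coevolution scores
#'
#' @param object a `fold_coevolution`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fold_coevolution
#' @export
autoplot.fold_coevolution <- function(object, ...) {
  df <- object$pairs
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$s_s,
                                   colour = .data$tier)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(object$top_tier,
                                       object$mapped_tier),
                        linetype = "dashed") +
    ggplot2::labs(x = "pair rank", y = "scaled score S_s",
                  title = "Coevolution scores") +
    ggplot2::theme_minimal()
}

#' Plot an Evolutionary Trace profile
#'
#' @param object a `fold_et`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fold_et
#' @export
autoplot.fold_et <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$position, .data$rvet)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "rvET (1 = fully conserved)",
                  title = "Evolutionary Trace profile") +
    ggplot2::theme_minimal()
}

#' Scatter plot of paired tip distances for a tree comparison
#'
#' @param object a `fold_treecomp`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fold_treecomp
#' @export
autoplot.fold_treecomp <- function(object, ...) {
  ggplot2::ggplot(object$distances, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "tip distance, tree A", y = "tip distance, tree B",
                  title = sprintf("Tree similarity r = %.2f", object$r)) +
    ggplot2::theme_minimal()
}
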