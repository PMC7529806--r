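# TF-RE-TG triplet assembly and subnetwork extraction.

#' Assemble the TF-RE-TG triplet network
#'
#' A triplet (TF m, RE k, gene l) exists when the gene model has a
#' nonzero `beta` for RE k, a nonzero `gamma` for TF m, and the TF has
#' a motif on the RE (`B[k, m] > 0`). The gene-level TF -> TG edge list
#' is the projection of the triplets with REs collapsed.
#'
#' @param fits A `vpeca_expression_fit`.
#' @param B RE x TF motif strength matrix.
#' @param classes RE classification tibble from [classify_res()]
#'   (optional; class/P_sel/omega columns are filled from it).
#' @param nonzero_tol Numerical zero.
#' @return A `vpeca_network`: list with `triplets` and `edges` tibbles.
#' @export
assemble_triplets <- function(fits, B, classes = NULL, nonzero_tol = 1e-8) {
  trip <- purrr::imap_dfr(fits$fits, function(f, g) {
    if (f$empty) return(NULL)
    res <- names(f$beta)[abs(f$beta) > nonzero_tol]
    tfs <- names(f$gamma)[abs(f$gamma) > nonzero_tol]
    if (length(res) == 0 || length(tfs) == 0) return(NULL)
    purrr::map_dfr(res, function(k) {
      m <- tfs[B[k, tfs] > 0]
      if (length(m) == 0) return(NULL)
      tibble::tibble(TF = m, RE_id = k, TG = g,
                     beta = unname(f$beta[k]),
                     gamma = unname(f$gamma[m]),
                     alpha = unname(f$alpha[k]))
    })
  })
  if (nrow(trip) == 0) {
    trip <- tibble::tibble(TF = character(), RE_id = character(),
                           TG = character(), beta = numeric(),
                           gamma = numeric(), alpha = numeric())
  }
  if (!is.null(classes)) {
    trip <- trip |>
      dplyr::left_join(classes, by = c(RE_id = "re_id")) |>
      dplyr::rename(P_selected = "P_sel") |>
      dplyr::mutate(class = dplyr::coalesce(.data$class, "inactive"),
                    P_selected = dplyr::coalesce(.data$P_selected, 0),
                    omega_flag = dplyr::coalesce(.data$omega_flag, FALSE))
  } else {
    trip <- trip |>
      dplyr::mutate(P_selected = NA_real_, class = NA_character_,
                    omega_flag = NA)
  }
  edges <- trip |>
    dplyr::distinct(.data$TF, .data$TG) |>
    dplyr::arrange(.data$TF, .data$TG)
  structure(list(triplets = trip, edges = edges), class = "vpeca_network")
}

#' @export
print.vpeca_network <- function(x, ...) {
  cat("vPECA network:", nrow(x$triplets), "TF-RE-TG triplets,",
      nrow(x$edges), "TF-TG edges\n")
  invisible(x)
}

#' @export
tidy.vpeca_network <- function(x, ...) x$triplets

#' @export
glance.vpeca_network <- function(x, ...) {
  tibble::tibble(n_triplets = nrow(x$triplets), n_edges = nrow(x$edges),
                 n_tf = length(unique(x$triplets$TF)),
                 n_tg = length(unique(x$triplets$TG)),
                 n_re = length(unique(x$triplets$RE_id)))
}

#' Downstream subnetwork of a transcription factor
#'
#' Takes the closure of edges out of the root to the requested order
#' (1st or 2nd downstream neighbours); optional differential-evidence
#' flags then prune target genes and supporting REs. The root is always
#' retained.
#'
#' @param net A `vpeca_network`.
#' @param root_tf Root TF gene id.
#' @param order 1 or 2: neighbourhood order downstream of the root.
#' @param gene_flags Optional named logical vector: genes to keep.
#' @param re_flags Optional named logical vector: REs to keep.
#' @return A `vpeca_network` restricted to the subnetwork.
#' @export
tf_subnetwork <- function(net, root_tf, order = 2, gene_flags = NULL,
                          re_flags = NULL) {
  trip <- net$triplets
  if (!root_tf %in% trip$TF) stop("root TF '", root_tf, "' not in network")
  frontier <- root_tf
  keep_rows <- rep(FALSE, nrow(trip))
  for (step in seq_len(order)) {
    rows <- trip$TF %in% frontier
    keep_rows <- keep_rows | rows
    frontier <- setdiff(unique(trip$TG[rows]), root_tf)
  }
  sub <- trip[keep_rows, , drop = FALSE]
  if (!is.null(gene_flags)) {
    ok <- function(g) g == root_tf |
      (g %in% names(gene_flags) & gene_flags[g])
    sub <- sub[vapply(sub$TG, ok, logical(1)) &
                 vapply(sub$TF, ok, logical(1)), , drop = FALSE]
  }
  if (!is.null(re_flags)) {
    sub <- sub[sub$RE_id %in% names(re_flags)[re_flags], , drop = FALSE]
  }
  edges <- sub |> dplyr::distinct(.data$TF, .data$TG)
  structure(list(triplets = sub, edges = edges, root = root_tf),
            class = "vpeca_network")
}

#' TF enrichment in a subnetwork
#'
#' Scores each TF by its occurrence count in the subnetwork divided by
#' its genome-wide background occurrence (the maximum occurrence among
#' all motifs mapped to the TF). TFs with zero background are excluded
#' with a warning; ties rank by TF id.
#'
#' @param net A `vpeca_network` (typically a subnetwork).
#' @param background Named vector of per-TF background counts.
#' @param top_n Number of top TFs to return.
#' @return A tibble `TF`, `n_subnetwork`, `n_background`, `score`,
#'   ranked by decreasing score.
#' @export
tf_enrichment_in_subnetwork <- function(net, background, top_n = 25) {
  occ <- net$triplets |> dplyr::count(.data$TF, name = "n_subnetwork")
  zero_bg <- setdiff(occ$TF, names(background)[background > 0])
  if (length(zero_bg) > 0) {
    warning("TF(s) with zero/absent background excluded: ",
            paste(zero_bg, collapse = ", "))
    occ <- occ[!occ$TF %in% zero_bg, , drop = FALSE]
  }
  occ |>
    dplyr::mutate(n_background = unname(background[.data$TF]),
                  score = .data$n_subnetwork / .data$n_background) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$TF) |>
    utils::head(top_n)
}

#' Per-target RE-count summary under a root TF
#'
#' For each target gene regulated by the root TF, counts the distinct
#' REs supporting the regulation; reports the histogram and the mean
#' (rounded to 2 decimals, the conventional report precision).
#'
#' @param net A `vpeca_network`.
#' @param root_tf Root TF gene id.
#' @return A list with `per_tg` (tibble `TG`, `n_re`), `mean_re`
#'   (2-dp rounded) and `histogram` (tibble `n_re`, `n_tg`).
#' @export
degree_summary <- function(net, root_tf) {
  sub <- net$triplets[net$triplets$TF == root_tf, , drop = FALSE]
  per_tg <- sub |>
    dplyr::distinct(.data$TG, .data$RE_id) |>
    dplyr::count(.data$TG, name = "n_re")
  hist <- per_tg |> dplyr::count(.data$n_re, name = "n_tg")
  list(per_tg = per_tg,
       mean_re = if (nrow(per_tg) > 0) round(mean(per_tg$n_re), 2) else NaN,
       histogram = hist)
}

#' Log-log RE-degree distribution plot
#'
#' Displays the number of REs per target gene against the number of
#' such genes on log-log axes; an approximately linear decay is the
#' power-law pattern reported for active-RE counts.
#'
#' @param net A `vpeca_network`.
#' @param root_tf Root TF gene id.
#' @return A ggplot.
#' @export
plot_degree_distribution <- function(net, root_tf) {
  h <- degree_summary(net, root_tf)$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$n_re, y = .data$n_tg)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "REs per target gene", y = "Target genes",
                  title = paste("RE-degree distribution under", root_tf))
}
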