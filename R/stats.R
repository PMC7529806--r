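# Supporting statistics: hypergeometric enrichment, ME score, dynamic
# TF selection, and the simplified linear-model differential analysis.

#' Hypergeometric enrichment (upper tail)
#'
#' `p = P(X >= x)` for `X ~ Hypergeometric(M, K, N)`: drawing `N` query
#' items from a universe of `M` containing `K` gold items. The fold is
#' the observed overlap over its expectation `K * N / M`.
#'
#' @param x Overlap count.
#' @param M Universe size.
#' @param K Gold-set size within the universe.
#' @param N Query-set size.
#' @return A list with `p` and `fold`.
#' @export
hypergeom_enrichment <- function(x, M, K, N) {
  if (K > M || N > M) stop("K and N must not exceed M")
  if (x > min(K, N) || x < 0) stop("impossible overlap count")
  p <- stats::phyper(x - 1, m = K, n = M - K, k = N, lower.tail = FALSE)
  list(p = p, fold = x / (K * N / M))
}

#' Motif-enrichment (ME) score
#'
#' `ME = sqrt(-log10(p) * fold_change)`; a motif with p = 1 scores 0.
#'
#' @param p Enrichment p-value in (0, 1].
#' @param fold_change Non-negative fold change.
#' @param floor p-values of 0 are clamped here with a warning.
#' @return The ME score.
#' @export
me_score <- function(p, fold_change, floor = 1e-300) {
  if (any(fold_change < 0)) stop("fold change must be >= 0")
  if (any(p > 1 | p < 0)) stop("p outside [0, 1]")
  if (any(p == 0)) {
    warning("p-value(s) of 0 clamped to ", floor)
    p <- pmax(p, floor)
  }
  sqrt(-log10(p) * fold_change)
}

expression_level <- function(fpkm) {
  cut(fpkm, breaks = c(-Inf, 6, 12, 30, 120, Inf),
      labels = c("I", "II", "III", "IV", "V"), right = TRUE)
}

#' Select expressed, motif-enriched, dynamic TFs
#'
#' The long list keeps TFs whose maximal per-time mean expression is at
#' least `min_fpkm` and maximal ME score at least `min_me`. The short
#' list keeps long-list TFs that are dynamic: their expression level
#' (bins at 6/12/30/120) or ME level (7 equal-width bins over the
#' observed ME range) changes across the time points.
#'
#' @param tf_expr TF x time matrix of mean FPKM.
#' @param me TF x time matrix of ME scores.
#' @param min_fpkm,min_me Long-list thresholds.
#' @param me_breaks Optional custom ME bin breakpoints; default 7
#'   equal-width bins over \[0, max(me)\].
#' @return A list with `long_list` and `short_list` (TF id vectors) and
#'   a per-TF `detail` tibble.
#' @export
dynamic_tf_filter <- function(tf_expr, me, min_fpkm = 12, min_me = 2,
                              me_breaks = NULL) {
  stopifnot(identical(dim(tf_expr), dim(me)),
            identical(rownames(tf_expr), rownames(me)))
  if (is.null(me_breaks)) {
    me_breaks <- seq(0, max(me, na.rm = TRUE), length.out = 8)
    me_breaks[1] <- -Inf
    me_breaks[8] <- Inf
  }
  passes <- apply(tf_expr, 1, max) >= min_fpkm & apply(me, 1, max) >= min_me
  dynamic <- vapply(seq_len(nrow(tf_expr)), function(i) {
    e_lvl <- expression_level(tf_expr[i, ])
    m_lvl <- cut(me[i, ], breaks = me_breaks, labels = FALSE)
    length(unique(e_lvl)) > 1 || length(unique(m_lvl)) > 1
  }, logical(1))
  detail <- tibble::tibble(
    TF = rownames(tf_expr),
    max_fpkm = apply(tf_expr, 1, max),
    max_me = apply(me, 1, max),
    long_list = passes,
    dynamic = dynamic,
    short_list = passes & dynamic
  )
  list(long_list = detail$TF[detail$long_list],
       short_list = detail$TF[detail$short_list],
       detail = detail)
}

build_design_matrix <- function(design) {
  dd <- design |>
    dplyr::mutate(time = factor(.data$time, ordered = FALSE)) |>
    dplyr::mutate(time = droplevels(.data$time))
  terms <- c("population", "time", "individual")
  terms <- terms[vapply(terms, function(v)
    length(unique(dd[[v]])) > 1, logical(1))]
  # the individual blocking term is only estimable when individuals are
  # observed repeatedly (it saturates a one-sample-per-individual design)
  if ("individual" %in% terms && max(table(dd$individual)) < 2) {
    terms <- setdiff(terms, "individual")
  }
  if (length(terms) == 0) stop("design has no varying terms")
  X <- stats::model.matrix(stats::reformulate(terms), data = dd)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop_cols <- q$pivot[(q$rank + 1):ncol(X)]
    warning("dropping ", length(drop_cols), " aliased design column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
  }
  X
}

#' Simplified linear-model differential analysis
#'
#' Per-entity ordinary least squares on `~ population + time +
#' individual` (individual is nested in population, so aliased dummy
#' columns are dropped with a warning), a t-test on the requested
#' contrast, and BH adjustment across entities. Time contrasts are
#' flagged at `q < fdr`; the population contrast is conventionally
#' flagged at raw `p < 0.05` (pass `flag_on = "p"`).
#'
#' @param values Entity x sample matrix (single entities may be passed
#'   as a vector).
#' @param design Sample design tibble aligned to the columns.
#' @param contrast Either `"population"` or `"time:<a>-<b>"` (e.g.
#'   `"time:6h-0h"` for the 6h-minus-0h effect).
#' @param fdr Flag threshold.
#' @param flag_on `"q"` (default) or `"p"`.
#' @return A tibble: `id`, `estimate`, `t`, `p`, `q`, `flag`.
#' @export
differential <- function(values, design, contrast, fdr = 0.05,
                         flag_on = c("q", "p")) {
  flag_on <- match.arg(flag_on)
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  stopifnot(ncol(values) == nrow(design))
  X <- build_design_matrix(design)
  cn <- colnames(X)
  cvec <- stats::setNames(rep(0, ncol(X)), cn)
  if (identical(contrast, "population")) {
    pop_col <- grep("^population", cn, value = TRUE)
    if (length(pop_col) != 1) stop("no single population column in design matrix")
    cvec[pop_col] <- 1
  } else if (startsWith(contrast, "time:")) {
    parts <- strsplit(sub("^time:", "", contrast), "-", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("time contrast must be 'time:a-b'")
    for (i in 1:2) {
      lev <- parts[i]
      col <- paste0("time", lev)
      sgn <- if (i == 1) 1 else -1
      if (col %in% cn) {
        cvec[col] <- cvec[col] + sgn
      } else if (lev != levels(design$time)[1]) {
        stop("unknown time level in contrast: ", lev)
      } # reference level contributes 0
    }
  } else {
    stop("contrast must be 'population' or 'time:a-b'")
  }
  qrX <- qr(X)
  coefs <- t(qr.coef(qrX, t(values)))
  fitted <- coefs %*% t(X)
  res <- values - fitted
  df <- ncol(values) - qrX$rank
  s2 <- rowSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  var_c <- drop(t(cvec) %*% XtXinv %*% cvec)
  est <- drop(coefs %*% cvec)
  se <- sqrt(s2 * var_c)
  tstat <- ifelse(se > 0, est / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p[se == 0] <- 1
  adj <- bh_fdr(p, level = fdr)
  tibble::tibble(
    id = rownames(values) %||% as.character(seq_len(nrow(values))),
    estimate = est, t = tstat, p = p, q = adj$q,
    flag = if (flag_on == "q") adj$q < fdr else p < fdr
  )
}
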