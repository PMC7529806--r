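# Accessibility model: per (RE, time), openness regressed on the
# population indicator for selected REs; t-test on the population term.

#' Fit the accessibility model
#'
#' For each selected RE (`S = 1`) and each time point, openness is
#' regressed on the population indicator `delta` by least squares:
#' `O = eta + omega * delta + e`. `omega` measures the adaptive-vs-
#' wildtype accessibility shift at that time and is tested against zero
#' with a two-sided t-test on `n - 2` degrees of freedom. For
#' unselected REs the model reduces to a within-time mean
#' (`omega = 0`, p = 1). A population absent at a time point leaves
#' `omega` undefined (`NA`) there.
#'
#' @param openness RE x sample openness matrix.
#' @param design Sample design tibble aligned to the columns.
#' @param S Named 0/1 vector of selection calls (names = RE ids); RE
#'   rows without a name in `S` are treated as unselected.
#' @param p_cutoff Flag threshold on the omega p-value.
#' @return A `vpeca_accessibility_fit`: list with `fit` (tibble of
#'   `re_id`, `time`, `eta`, `omega`, `p`, `omega_flag`) and `sigma2`
#'   (per-RE pooled residual variance).
#' @export
fit_accessibility <- function(openness, design, S, p_cutoff = 0.05) {
  stopifnot(ncol(openness) == nrow(design))
  re_ids <- rownames(openness)
  if (is.null(re_ids)) stop("openness matrix must have RE row names")
  s_vec <- rep(0L, length(re_ids))
  names(s_vec) <- re_ids
  common <- intersect(re_ids, names(S))
  s_vec[common] <- as.integer(S[common])

  times <- levels(design$time)
  rss <- numeric(length(re_ids))
  nres <- 0L
  pieces <- vector("list", length(times))
  for (ti in seq_along(times)) {
    idx <- which(design$time == times[ti])
    if (length(idx) == 0) next
    O <- openness[, idx, drop = FALSE]
    d <- design$delta[idx]
    n <- length(idx)
    eta <- rowMeans(O)
    omega <- rep(0, length(re_ids))
    p <- rep(1, length(re_ids))
    sel <- s_vec == 1L
    both_pops <- length(unique(d)) == 2
    if (any(sel) && both_pops && n >= 3) {
      dc <- d - mean(d)
      sxx <- sum(dc^2)
      Osel <- O[sel, , drop = FALSE]
      slope <- drop(Osel %*% dc) / sxx
      icpt <- rowMeans(Osel) - slope * mean(d)
      fitted <- outer(icpt, rep(1, n)) + outer(slope, d)
      res <- Osel - fitted
      s2 <- rowSums(res^2) / (n - 2)
      se <- sqrt(s2 / sxx)
      tstat <- ifelse(se > 0, slope / se, Inf * sign(slope))
      pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
      pv[se == 0 & slope == 0] <- 1
      eta[sel] <- icpt
      omega[sel] <- slope
      p[sel] <- pv
      rss[sel] <- rss[sel] + rowSums(res^2)
      # unselected REs: residuals about the within-time mean
      res0 <- O[!sel, , drop = FALSE] - rowMeans(O[!sel, , drop = FALSE])
      rss[!sel] <- rss[!sel] + rowSums(res0^2)
    } else {
      if (any(sel) && !both_pops) {
        omega[sel] <- NA_real_
        p[sel] <- NA_real_
      }
      res0 <- O - rowMeans(O)
      rss <- rss + rowSums(res0^2)
    }
    pieces[[ti]] <- tibble::tibble(
      re_id = re_ids, time = times[ti],
      S = unname(s_vec), eta = unname(eta), omega = unname(omega),
      p = unname(p),
      omega_flag = unname(!is.na(p) & p < p_cutoff & s_vec == 1L)
    )
    nres <- nres + n
  }
  df_resid <- nres - 2 * length(times)  # 2 params per time at most
  out <- list(
    fit = dplyr::bind_rows(pieces) |>
      dplyr::mutate(time = factor(.data$time, levels = times, ordered = TRUE)) |>
      dplyr::arrange(.data$re_id, .data$time),
    sigma2 = stats::setNames(rss / max(df_resid, 1), re_ids),
    p_cutoff = p_cutoff
  )
  class(out) <- "vpeca_accessibility_fit"
  out
}

#' @export
print.vpeca_accessibility_fit <- function(x, ...) {
  cat("vPECA accessibility fit:", length(unique(x$fit$re_id)), "REs x",
      length(unique(x$fit$time)), "time points;",
      sum(x$fit$omega_flag), "(RE, time) cells with population-shifted",
      "openness (p <", x$p_cutoff, ")\n")
  invisible(x)
}

#' @export
tidy.vpeca_accessibility_fit <- function(x, ...) x$fit

#' @export
glance.vpeca_accessibility_fit <- function(x, ...) {
  tibble::tibble(
    n_re = length(unique(x$fit$re_id)),
    n_time = length(unique(x$fit$time)),
    n_flagged = sum(x$fit$omega_flag)
  )
}
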