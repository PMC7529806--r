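# Selection-status inference: iterate least-squares on the logit scale
# against the LD-weighted score aggregates, then threshold.

sigmoid <- function(x) 1 / (1 + exp(-x))

feature_matrix <- function(features) {
  cbind(intercept = 1,
        fst = features$agg_fst, ihs = features$agg_ihs,
        xpehh = features$agg_xpehh, pbs = features$agg_pbs,
        ddaf = features$agg_ddaf)
}

ols_mu <- function(X, z) {
  fit <- tryCatch(qr.solve(crossprod(X), crossprod(X, z)),
                  error = function(e) NULL)
  if (is.null(fit) || qr(X)$rank < ncol(X)) {
    warning("rank-deficient selection design; ridge fallback (1e-8)")
    fit <- solve(crossprod(X) + diag(1e-8, ncol(X)), crossprod(X, z))
  }
  drop(fit)
}

#' Infer the selection status of regulatory elements
#'
#' Iterates the two-step scheme: (a) clip the current selection
#' probabilities away from 0/1 and regress their logit on the
#' LD-weighted per-RE score aggregates by ordinary least squares to get
#' the coefficient vector `mu`; (b) set the probabilities to the
#' sigmoid of the fitted linear predictor; repeat until `mu` stops
#' changing. Probabilities are initialised at
#' `p0 = 1 - mean(composite p-value)`. After convergence an RE is
#' called selected when its probability strictly exceeds the threshold.
#' REs with no SNPs get probability 0 and never enter the regression.
#'
#' @param features Output of [aggregate_re_features()].
#' @param threshold Call threshold on `P(S = 1)` (strict `>`).
#' @param tol Convergence tolerance on `max(abs(delta mu))`.
#' @param max_iter Iteration cap; non-convergence returns the best fit
#'   with `converged = FALSE`.
#' @param clip Probability clipping bound before the logit.
#' @return A `vpeca_selection_fit`: list with `fit` (tibble of `re_id`,
#'   `P_sel`, `S`), `mu`, `n_iter`, `converged`.
#' @export
estimate_selection_status <- function(features, threshold = 0.95,
                                      tol = 1e-6, max_iter = 100,
                                      clip = 1e-6) {
  use <- features$n_snps > 0
  if (sum(use) < 2) stop("need at least 2 REs with SNPs")
  X <- feature_matrix(features[use, ])
  P <- pmin(pmax(features$p0[use], clip), 1 - clip)
  mu <- rep(0, ncol(X))
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    Pc <- pmin(pmax(P, clip), 1 - clip)
    mu_new <- ols_mu(X, log(Pc / (1 - Pc)))
    P <- sigmoid(drop(X %*% mu_new))
    if (max(abs(mu_new - mu)) < tol) {
      mu <- mu_new
      converged <- TRUE
      break
    }
    mu <- mu_new
  }
  if (!converged) warning("selection-status loop did not converge in ",
                          max_iter, " iterations")
  P_all <- numeric(nrow(features))
  P_all[use] <- P
  out <- list(
    fit = tibble::tibble(
      re_id = features$re_id,
      n_snps = features$n_snps,
      P_sel = P_all,
      S = as.integer(P_all > threshold)
    ),
    mu = stats::setNames(mu, colnames(X)),
    n_iter = iter,
    converged = converged,
    threshold = threshold
  )
  class(out) <- "vpeca_selection_fit"
  out
}

#' @export
print.vpeca_selection_fit <- function(x, ...) {
  cat("vPECA selection-status fit:", nrow(x$fit), "REs,",
      sum(x$fit$S), "selected (P >", x$threshold, "),",
      x$n_iter, "iterations",
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.vpeca_selection_fit <- function(x, ...) x$fit

#' @export
glance.vpeca_selection_fit <- function(x, ...) {
  tibble::tibble(n_re = nrow(x$fit), n_selected = sum(x$fit$S),
                 n_iter = x$n_iter, converged = x$converged)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of inferred selection probabilities
#'
#' @param object A `vpeca_selection_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vpeca_selection_fit <- function(object, ...) {
  ggplot2::ggplot(object$fit, ggplot2::aes(x = .data$P_sel)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "P(S = 1 | X, Y)", y = "REs",
                  title = "Inferred RE selection probabilities")
}
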