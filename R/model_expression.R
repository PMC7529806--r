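# Expression model: cross-context priors, the motif-weighted TF
# feature, and the three-stage LASSO + quasi-Newton estimation of
# (beta, gamma, alpha) per target gene.

#' Cross-context correlation priors
#'
#' Across a panel of cellular contexts (>= 3), computes the Pearson
#' correlation between each RE's openness and each gene's expression
#' (`beta0`) and between each TF's and each gene's expression
#' (`gamma0`). Constant rows get prior 0 and are flagged.
#'
#' @param panel_expression Gene x context matrix.
#' @param panel_openness RE x context matrix.
#' @param tf_ids TF identifiers (rows of `panel_expression`).
#' @return A list with `beta0` (RE x gene), `gamma0` (TF x gene) and
#'   `constant` (character vector of flagged constant rows).
#' @export
compute_priors <- function(panel_expression, panel_openness, tf_ids) {
  if (ncol(panel_expression) < 3 || ncol(panel_openness) < 3) {
    stop("need at least 3 shared contexts to compute priors")
  }
  if (ncol(panel_expression) != ncol(panel_openness)) {
    stop("expression and openness panels must share contexts")
  }
  missing_tf <- setdiff(tf_ids, rownames(panel_expression))
  if (length(missing_tf) > 0) {
    stop("TF(s) absent from panel expression: ",
         paste(utils::head(missing_tf, 5), collapse = ", "))
  }
  const_o <- apply(panel_openness, 1, stats::sd) == 0
  const_e <- apply(panel_expression, 1, stats::sd) == 0
  safe_cor <- function(a, b) {
    r <- suppressWarnings(stats::cor(t(a), t(b)))
    r[is.na(r)] <- 0
    r
  }
  beta0 <- safe_cor(panel_openness, panel_expression)
  gamma0 <- safe_cor(panel_expression[tf_ids, , drop = FALSE], panel_expression)
  list(beta0 = beta0, gamma0 = gamma0,
       constant = c(rownames(panel_openness)[const_o],
                    rownames(panel_expression)[const_e]))
}

#' Motif-weighted TF activity feature of an RE
#'
#' The combined binding input of an RE: `sum_m gamma_m * B[k, m] *
#' TF[m, sample]` over the TFs with a motif on the RE.
#'
#' @param B RE x TF motif strength matrix.
#' @param tf_expr TF x sample expression matrix.
#' @param gamma Named coefficient vector over (a subset of) TFs.
#' @param re RE id (row of `B`).
#' @return Per-sample feature vector.
#' @export
tf_feature <- function(B, tf_expr, gamma, re) {
  tfs <- intersect(names(gamma), colnames(B))
  tfs <- tfs[B[re, tfs] > 0]
  if (length(tfs) == 0) return(rep(0, ncol(tf_expr)))
  drop((gamma[tfs] * B[re, tfs]) %*% tf_expr[tfs, , drop = FALSE])
}

#' Deterministic cross-validation folds stratified by condition
#'
#' Fold assignment is reproducible from the seed and stratified by
#' (population, time) so that every fold spans all conditions.
#'
#' @param design Sample design tibble.
#' @param nfolds Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per sample.
#' @export
make_folds <- function(design, nfolds = 5, seed = 1) {
  foldid <- integer(nrow(design))
  groups <- split(seq_len(nrow(design)),
                  paste(design$population, design$time, sep = "."))
  withr::with_seed(seed, {
    for (idx in groups) {
      foldid[idx] <- (sample(seq_along(idx)) - 1L) %% nfolds + 1L
    }
  })
  foldid
}

# L1-penalized least squares with lambda chosen by CV (lambda.1se, the
# parsimonious standard choice). Handles the single-predictor case that
# glmnet refuses, via the univariate soft-threshold path.
lasso_cv <- function(x, y, foldid, standardize = TRUE, ...) {
  keep <- apply(x, 2, stats::sd) > 0
  coefs <- stats::setNames(rep(0, ncol(x)), colnames(x))
  if (!any(keep)) return(list(a0 = mean(y), beta = coefs, lambda = Inf))
  xk <- x[, keep, drop = FALSE]
  if (ncol(xk) == 1) {
    fit <- lasso_cv_uni(drop(xk), y, foldid, standardize = standardize)
    coefs[which(keep)] <- fit$beta
    return(list(a0 = fit$a0, beta = coefs, lambda = fit$lambda))
  }
  cv <- glmnet::cv.glmnet(xk, y, foldid = foldid, standardize = standardize,
                          ...)
  cf <- stats::coef(cv, s = "lambda.1se")
  coefs[rownames(cf)[-1]] <- cf[-1, 1]
  list(a0 = cf[1, 1], beta = coefs, lambda = cv$lambda.1se)
}

# Univariate lasso in the glmnet parameterization:
# (1/2n)||y - a0 - x b||^2 + lambda |b|  =>  b = S(cov_xy, lambda) / var_x
# on centered data (standardized internally like glmnet).
lasso_cv_uni <- function(x, y, foldid, standardize = TRUE) {
  n <- length(y)
  sx <- if (standardize) sqrt(mean((x - mean(x))^2)) else 1
  xs <- (x - mean(x)) / sx
  lam_max <- abs(mean(xs * (y - mean(y))))
  lambdas <- lam_max * exp(seq(0, log(1e-4), length.out = 50))
  soft <- function(z, l) sign(z) * pmax(abs(z) - l, 0)
  cv_err <- cv_se <- numeric(length(lambdas))
  for (li in seq_along(lambdas)) {
    errs <- vapply(sort(unique(foldid)), function(f) {
      tr <- foldid != f
      xm <- mean(xs[tr]); ym <- mean(y[tr])
      vx <- mean((xs[tr] - xm)^2)
      cxy <- mean((xs[tr] - xm) * (y[tr] - ym))
      b <- if (vx > 0) soft(cxy, lambdas[li]) / vx else 0
      mean((y[!tr] - ym - b * (xs[!tr] - xm))^2)
    }, numeric(1))
    cv_err[li] <- mean(errs)
    cv_se[li] <- stats::sd(errs) / sqrt(length(errs))
  }
  i_min <- which.min(cv_err)
  i_1se <- which(cv_err <= cv_err[i_min] + cv_se[i_min])[1]
  vx <- mean((xs - mean(xs))^2)
  cxy <- mean((xs - mean(xs)) * (y - mean(y)))
  b <- sign(cxy) * max(abs(cxy) - lambdas[i_1se], 0) / vx
  b_orig <- b / sx
  list(a0 = mean(y) - b_orig * mean(x), beta = b_orig, lambda = lambdas[i_1se])
}

# Step-3 objective and gradient. Parameters are packed as
# theta = c(b0, beta[K], gamma[M], alpha[free]) where alpha is free only
# where S = 1. `prior_scale` multiplies the prior-reward + ridge block.
step3_objective <- function(theta, tg, O, Bk, TFm, dS, alpha_free,
                            beta0, gamma0, prior_scale = 1) {
  K <- nrow(O); M <- nrow(TFm)
  b0 <- theta[1]
  beta <- theta[2:(K + 1)]
  gamma <- theta[(K + 2):(K + M + 1)]
  alpha <- rep(0, K)
  if (any(alpha_free)) {
    alpha[alpha_free] <- theta[(K + M + 2):length(theta)]
  }
  G <- Bk %*% (gamma * TFm)              # K x n
  Z <- O + alpha * dS                    # dS is K x n (delta * S_k rows)
  r <- tg - b0 - colSums(beta * Z * G)
  0.5 * sum(r^2) +
    prior_scale * (-sum(beta0 * beta) - sum(gamma0 * gamma) +
                     0.5 * sum(beta^2) + 0.5 * sum(gamma^2))
}

step3_gradient <- function(theta, tg, O, Bk, TFm, dS, alpha_free,
                           beta0, gamma0, prior_scale = 1) {
  K <- nrow(O); M <- nrow(TFm)
  b0 <- theta[1]
  beta <- theta[2:(K + 1)]
  gamma <- theta[(K + 2):(K + M + 1)]
  alpha <- rep(0, K)
  if (any(alpha_free)) {
    alpha[alpha_free] <- theta[(K + M + 2):length(theta)]
  }
  G <- Bk %*% (gamma * TFm)
  Z <- O + alpha * dS
  r <- tg - b0 - colSums(beta * Z * G)
  g_b0 <- -sum(r)
  g_beta <- -drop((Z * G) %*% r) + prior_scale * (beta - beta0)
  W <- beta * Z                          # K x n
  g_gamma <- -drop(((t(Bk) %*% W) * TFm) %*% r) + prior_scale * (gamma - gamma0)
  g_alpha <- -(beta * drop((dS * G) %*% r))[alpha_free]
  c(g_b0, g_beta, g_gamma, g_alpha)
}

#' Fit the expression model for one target gene
#'
#' Three stages. Stage 1: LASSO of the target gene's expression on the
#' per-RE products (openness x prior-weighted TF feature) over the
#' candidate set `I_l`, penalty chosen by stratified 5-fold CV; REs
#' with nonzero coefficients survive. Stage 2: with those coefficients
#' fixed, LASSO in the TF coefficients over the TFs with motifs on the
#' surviving REs. Stage 3: on the survivors, quasi-Newton (BFGS)
#' minimisation of the squared error plus the prior reward
#' `-beta0'beta - gamma0'gamma` and ridge `(||beta||^2 + ||gamma||^2)/2`,
#' with the selection-activity shifts `alpha` free only where `S = 1`.
#'
#' @param tg Target-gene expression vector over samples.
#' @param re_ids Candidate RE ids (`I_l`).
#' @param openness RE x sample openness matrix.
#' @param B RE x TF motif strength matrix.
#' @param tf_expr TF x sample expression matrix.
#' @param S Named 0/1 selection calls.
#' @param delta Per-sample 0/1 population indicator.
#' @param beta0,gamma0 Named prior vectors (cross-context correlations)
#'   for this gene; missing names default to 0.
#' @param foldid CV fold assignment from [make_folds()].
#' @param prior_scale Scalar on the prior-reward + ridge block.
#' @param nonzero_tol Coefficients below this in absolute value count
#'   as zero.
#' @return A `vpeca_gene_fit` list: `b0`, `beta`, `gamma`, `alpha`
#'   (named, survivors only), `sigma2`, `Z` (RE x sample plug-in
#'   activity for surviving REs), `converged`, `empty`.
#' @export
fit_expression_gene <- function(tg, re_ids, openness, B, tf_expr, S, delta,
                                beta0 = NULL, gamma0 = NULL, foldid,
                                prior_scale = 1, nonzero_tol = 1e-8) {
  re_ids <- intersect(re_ids, rownames(openness))
  if (length(re_ids) == 0) stop("no candidate REs with openness rows")
  n <- length(tg)
  tfs_all <- colnames(B)
  g0 <- stats::setNames(rep(0, length(tfs_all)), tfs_all)
  if (!is.null(gamma0)) g0[intersect(names(gamma0), tfs_all)] <-
      gamma0[intersect(names(gamma0), tfs_all)]
  b0p <- stats::setNames(rep(0, length(re_ids)), re_ids)
  if (!is.null(beta0)) b0p[intersect(names(beta0), re_ids)] <-
      beta0[intersect(names(beta0), re_ids)]

  empty_fit <- function() {
    structure(list(b0 = mean(tg), beta = numeric(0), gamma = numeric(0),
                   alpha = numeric(0), sigma2 = stats::var(tg),
                   Z = NULL, converged = TRUE, empty = TRUE),
              class = "vpeca_gene_fit")
  }

  # Stage 1: RE selection
  X1 <- t(vapply(re_ids, function(k) {
    openness[k, ] * tf_feature(B, tf_expr, g0, k)
  }, numeric(n)))
  l1 <- lasso_cv(t(X1), tg, foldid)
  beta1 <- l1$beta[abs(l1$beta) > nonzero_tol]
  if (length(beta1) == 0) return(empty_fit())
  K1 <- names(beta1)

  # Stage 2: TF selection among TFs with motifs on surviving REs
  M1 <- tfs_all[colSums(B[K1, , drop = FALSE] > 0) > 0]
  if (length(M1) == 0) return(empty_fit())
  U <- vapply(M1, function(m) {
    colSums(beta1 * openness[K1, , drop = FALSE] *
              (B[K1, m] %o% tf_expr[m, ]))
  }, numeric(n))
  l2 <- lasso_cv(U, tg, foldid)
  gamma2 <- l2$beta[abs(l2$beta) > nonzero_tol]
  if (length(gamma2) == 0) return(empty_fit())
  M2 <- names(gamma2)

  # Stage 3: joint quasi-Newton refinement on survivors
  s_k <- stats::setNames(rep(0L, length(K1)), K1)
  common <- intersect(K1, names(S))
  s_k[common] <- as.integer(S[common])
  dS <- outer(s_k, delta)                 # K1 x n
  alpha_free <- s_k == 1L
  Bk <- B[K1, M2, drop = FALSE]
  TFm <- tf_expr[M2, , drop = FALSE]
  O1 <- openness[K1, , drop = FALSE]
  theta0 <- c(l2$a0, beta1, gamma2, rep(0, sum(alpha_free)))
  args <- list(tg = tg, O = O1, Bk = Bk, TFm = TFm, dS = dS,
               alpha_free = alpha_free, beta0 = b0p[K1],
               gamma0 = g0[M2], prior_scale = prior_scale)
  opt <- tryCatch(
    stats::optim(theta0,
                 fn = function(th) do.call(step3_objective, c(list(th), args)),
                 gr = function(th) do.call(step3_gradient, c(list(th), args)),
                 method = "BFGS", control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(opt)) {
    warning("step-3 optimiser failed; falling back to stage-1/2 solution")
    theta <- theta0
    converged <- FALSE
  } else {
    theta <- opt$par
    converged <- opt$convergence == 0
  }
  K <- length(K1); M <- length(M2)
  beta <- stats::setNames(theta[2:(K + 1)], K1)
  gamma <- stats::setNames(theta[(K + 2):(K + M + 1)], M2)
  alpha <- stats::setNames(rep(0, K), K1)
  if (any(alpha_free)) alpha[alpha_free] <- theta[(K + M + 2):length(theta)]
  Z <- O1 + alpha * dS
  G <- Bk %*% (gamma * TFm)
  r <- tg - theta[1] - colSums(beta * Z * G)
  structure(list(b0 = theta[1], beta = beta, gamma = gamma, alpha = alpha,
                 sigma2 = sum(r^2) / max(n - length(theta), 1),
                 Z = Z, converged = converged, empty = FALSE),
            class = "vpeca_gene_fit")
}

#' Fit the expression model for every mapped gene
#'
#' @param expression Gene x sample expression matrix (target genes).
#' @param map Candidate map tibble (`gene_id`, `re_id`) from
#'   [candidate_map()].
#' @param openness,B,tf_expr,S,delta,prior_scale,nonzero_tol See
#'   [fit_expression_gene()].
#' @param priors Optional output of [compute_priors()].
#' @param design Sample design (for fold stratification).
#' @param folds,seed CV folds and seed for their assignment.
#' @return A `vpeca_expression_fit`: list of per-gene fits plus a tidy
#'   coefficient table.
#' @export
fit_expression <- function(expression, map, openness, B, tf_expr, S, delta,
                           design, priors = NULL, folds = 5, seed = 1,
                           prior_scale = 1, nonzero_tol = 1e-8) {
  foldid <- make_folds(design, nfolds = folds, seed = seed)
  genes <- intersect(unique(map$gene_id), rownames(expression))
  fits <- purrr::map(genes, function(g) {
    b0p <- if (!is.null(priors) && g %in% colnames(priors$beta0))
      priors$beta0[, g] else NULL
    g0p <- if (!is.null(priors) && g %in% colnames(priors$gamma0))
      priors$gamma0[, g] else NULL
    fit_expression_gene(
      tg = expression[g, ],
      re_ids = map$re_id[map$gene_id == g],
      openness = openness, B = B, tf_expr = tf_expr, S = S, delta = delta,
      beta0 = b0p, gamma0 = g0p, foldid = foldid,
      prior_scale = prior_scale, nonzero_tol = nonzero_tol)
  })
  names(fits) <- genes
  out <- list(fits = fits, genes = genes, nonzero_tol = nonzero_tol,
              seed = seed)
  class(out) <- "vpeca_expression_fit"
  out
}

#' @export
print.vpeca_expression_fit <- function(x, ...) {
  modeled <- sum(!vapply(x$fits, function(f) f$empty, logical(1)))
  cat("vPECA expression fit:", length(x$fits), "genes,", modeled,
      "with a non-empty RE model\n")
  invisible(x)
}

#' @export
tidy.vpeca_expression_fit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, g) {
    if (f$empty) return(NULL)
    tibble::tibble(gene_id = g, re_id = names(f$beta),
                   beta = unname(f$beta), alpha = unname(f$alpha[names(f$beta)]))
  })
}

#' @export
glance.vpeca_expression_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$fits),
    n_modeled = sum(!vapply(x$fits, function(f) f$empty, logical(1))),
    n_re_effects = sum(vapply(x$fits, function(f) length(f$beta), integer(1)))
  )
}

#' Classify REs as active (ARE) / active selected (ASRE)
#'
#' An RE is an ARE when its regression effect `beta` is nonzero in at
#' least one gene model; an ASRE additionally has selection probability
#' strictly above the threshold and a nonzero selection-activity shift
#' `alpha`. The omega flag marks REs whose population accessibility
#' shift passed the t-test at some time point.
#'
#' @param expression_fits A `vpeca_expression_fit`.
#' @param selection A `vpeca_selection_fit`.
#' @param accessibility A `vpeca_accessibility_fit` (optional; omega
#'   flags are FALSE without it).
#' @param nonzero_tol Numerical zero for beta/alpha.
#' @return A tibble: `re_id`, `class` (ARE/ASRE/inactive), `P_sel`,
#'   `omega_flag`.
#' @export
classify_res <- function(expression_fits, selection, accessibility = NULL,
                         nonzero_tol = 1e-8) {
  sel <- selection$fit
  eff <- purrr::imap_dfr(expression_fits$fits, function(f, g) {
    if (f$empty || length(f$beta) == 0) return(NULL)
    tibble::tibble(re_id = names(f$beta), beta = unname(f$beta),
                   alpha = unname(f$alpha[names(f$beta)]))
  })
  by_re <- if (nrow(eff) > 0) {
    eff |>
      dplyr::group_by(.data$re_id) |>
      dplyr::summarise(
        any_beta = any(abs(.data$beta) > nonzero_tol),
        any_alpha = any(abs(.data$alpha) > nonzero_tol),
        .groups = "drop")
  } else {
    tibble::tibble(re_id = character(), any_beta = logical(),
                   any_alpha = logical())
  }
  omega <- if (!is.null(accessibility)) {
    accessibility$fit |>
      dplyr::group_by(.data$re_id) |>
      dplyr::summarise(omega_flag = any(.data$omega_flag), .groups = "drop")
  } else {
    tibble::tibble(re_id = character(), omega_flag = logical())
  }
  sel |>
    dplyr::left_join(by_re, by = "re_id") |>
    dplyr::left_join(omega, by = "re_id") |>
    dplyr::mutate(
      any_beta = dplyr::coalesce(.data$any_beta, FALSE),
      any_alpha = dplyr::coalesce(.data$any_alpha, FALSE),
      omega_flag = dplyr::coalesce(.data$omega_flag, FALSE),
      class = dplyr::case_when(
        any_beta & .data$P_sel > selection$threshold & any_alpha ~ "ASRE",
        any_beta ~ "ARE",
        TRUE ~ "inactive")
    ) |>
    dplyr::select("re_id", "class", "P_sel", "omega_flag")
}
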