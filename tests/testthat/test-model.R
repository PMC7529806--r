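test_that("selection-status loop matches a naive reference implementation", {
  # two-group synthetic: high-score REs start near p0 = 0.99, low near 0.01
  set.seed(5)
  n <- 60
  hi <- rep(c(TRUE, FALSE), each = n / 2)
  feats <- tibble::tibble(
    re_id = paste0("r", 1:n), n_snps = 1L,
    agg_fst = ifelse(hi, rnorm(n, 0.5, 0.05), rnorm(n, 0.05, 0.02)),
    agg_ihs = ifelse(hi, rnorm(n, 0.5, 0.05), rnorm(n, 0.05, 0.02)),
    agg_xpehh = ifelse(hi, rnorm(n, 0.5, 0.05), rnorm(n, 0.05, 0.02)),
    agg_pbs = ifelse(hi, rnorm(n, 0.5, 0.05), rnorm(n, 0.05, 0.02)),
    agg_ddaf = ifelse(hi, rnorm(n, 0.05, 0.02), 0),
    p0 = ifelse(hi, 0.99, 0.01))
  fit <- estimate_selection_status(feats, tol = 1e-10)

  # naive reference loop: lm() + plogis, no vectorized shortcuts
  X <- cbind(1, feats$agg_fst, feats$agg_ihs, feats$agg_xpehh,
             feats$agg_pbs, feats$agg_ddaf)
  P <- pmin(pmax(feats$p0, 1e-6), 1 - 1e-6)
  mu <- rep(0, 6)
  for (it in 1:200) {
    Pc <- pmin(pmax(P, 1e-6), 1 - 1e-6)
    mu_new <- unname(coef(lm(log(Pc / (1 - Pc)) ~ X - 1)))
    P <- plogis(drop(X %*% mu_new))
    if (max(abs(mu_new - mu)) < 1e-10) { mu <- mu_new; break }
    mu <- mu_new
  }
  expect_true(fit$converged)
  expect_equal(unname(fit$mu), mu, tolerance = 1e-8)
  expect_equal(fit$fit$P_sel, plogis(drop(X %*% mu)), tolerance = 1e-8)
  # converged probabilities separate the groups; calls land on the high group
  expect_true(all(fit$fit$P_sel[hi] > 0.95))
  expect_true(all(fit$fit$P_sel[!hi] < 0.05))
  expect_equal(fit$fit$S, as.integer(hi))
})

test_that("selection calls are strict at the threshold and order-invariant", {
  set.seed(6)
  feats <- tibble::tibble(
    re_id = paste0("r", 1:30), n_snps = rep(c(1L, 0L), 15),
    agg_fst = runif(30), agg_ihs = runif(30), agg_xpehh = runif(30),
    agg_pbs = runif(30), agg_ddaf = runif(30, -0.2, 0.2),
    p0 = ifelse(rep(c(TRUE, FALSE), 15), runif(30, 0.3, 0.99), 0))
  fit <- suppressWarnings(estimate_selection_status(feats))
  # the call is S = 1 iff P strictly exceeds the threshold
  expect_identical(fit$fit$S, as.integer(fit$fit$P_sel > 0.95))
  # REs with no SNPs never enter: probability 0, call 0
  expect_true(all(fit$fit$P_sel[feats$n_snps == 0] == 0))
  # output invariant to RE ordering
  perm <- sample(30)
  fit2 <- suppressWarnings(estimate_selection_status(feats[perm, ]))
  expect_equal(fit2$fit$re_id, feats$re_id[perm])
  expect_equal(fit2$fit$P_sel[order(perm)], fit$fit$P_sel, tolerance = 1e-10)
  # degenerate: all p0 at zero -> clip floor everywhere, no calls
  flat <- feats |> dplyr::mutate(p0 = 0, n_snps = 1L)
  fit3 <- estimate_selection_status(flat)
  expect_true(all(fit3$fit$S == 0))
})

test_that("accessibility fit matches normal equations and reduces for S = 0", {
  d <- toy_design(n_rep = 5, times = "0h")   # 10 samples, one time
  set.seed(7)
  eta <- 2; omega <- 1; sig <- 0.1
  O <- matrix(eta + omega * d$delta + rnorm(10, 0, sig), 1,
              dimnames = list("r1", d$sample_id))
  fit <- fit_accessibility(O, d, c(r1 = 1L))
  # hand-coded normal-equations oracle for the per-time regression
  X <- cbind(1, d$delta)
  ab <- solve(t(X) %*% X, t(X) %*% O[1, ])
  expect_equal(fit$fit$eta[1], unname(ab[1, 1]), tolerance = 1e-10)
  expect_equal(fit$fit$omega[1], unname(ab[2, 1]), tolerance = 1e-10)
  r <- O[1, ] - X %*% ab
  se <- sqrt(sum(r^2) / 8 / sum((d$delta - mean(d$delta))^2))
  t_or <- ab[2, 1] / se
  expect_equal(fit$fit$p[1], unname(2 * pt(-abs(t_or), 8)), tolerance = 1e-10)
  expect_true(fit$fit$omega_flag[1])

  # noiseless: exact recovery
  On <- matrix(2 + 1 * d$delta, 1, dimnames = list("r1", d$sample_id))
  fn <- fit_accessibility(On, d, c(r1 = 1L))
  expect_equal(fn$fit$eta[1], 2)
  expect_equal(fn$fit$omega[1], 1)
  expect_lt(fn$fit$p[1], 1e-12)

  # S = 0 reduction: omega 0, eta the within-time mean, p = 1
  f0 <- fit_accessibility(O, d, c(r1 = 0L))
  expect_equal(f0$fit$omega[1], 0)
  expect_equal(f0$fit$eta[1], unname(mean(O[1, ])))
  expect_equal(f0$fit$p[1], 1)
  expect_false(f0$fit$omega_flag[1])
})

test_that("accessibility detection rate at omega = 10 sigma is near 1", {
  d <- toy_design(n_rep = 5, times = "0h")
  set.seed(8)
  reps <- 200
  O <- matrix(2 + rep(d$delta, each = reps) + rnorm(10 * reps, 0, 0.1),
              reps, dimnames = list(paste0("r", 1:reps), d$sample_id))
  fit <- fit_accessibility(O, d, setNames(rep(1L, reps), rownames(O)))
  expect_gte(mean(fit$fit$p < 0.05), 0.8)
})

test_that("priors: perfect, null and constant rows", {
  set.seed(9)
  ctx <- 200
  o <- matrix(rlnorm(3 * ctx), 3, ctx,
              dimnames = list(paste0("r", 1:3), paste0("c", 1:ctx)))
  e <- rbind(g1 = o[1, ],               # identical to RE 1's openness
             g2 = rlnorm(ctx),          # independent noise
             tfA = rlnorm(ctx),
             flat = rep(1, ctx))        # constant row
  pr <- compute_priors(e, o, tf_ids = "tfA")
  expect_equal(pr$beta0["r1", "g1"], 1)
  expect_lt(abs(pr$beta0["r2", "g2"]), 0.25)   # null correlation at 200 contexts
  expect_equal(unname(pr$beta0[, "flat"]), rep(0, 3))
  expect_true("flat" %in% pr$constant)
  expect_equal(dim(pr$gamma0), c(1L, 4L))
  expect_error(compute_priors(e[, 1:2], o[, 1:2], "tfA"), "3 shared contexts")
})

test_that("TF feature equals the direct triple loop", {
  B <- matrix(0, 2, 2, dimnames = list(c("r1", "r2"), c("m1", "m2")))
  B["r1", "m1"] <- 2; B["r1", "m2"] <- 1.5; B["r2", "m2"] <- 0.5
  tf <- matrix(0, 2, 2, dimnames = list(c("m1", "m2"), c("s1", "s2")))
  tf["m1", ] <- c(3, 5); tf["m2", ] <- c(4, 6)
  # single TF: gamma * B * TF = 1 * 2 * (3, 5)
  expect_equal(unname(tf_feature(B, tf, c(m1 = 1), "r1")), c(6, 10))
  # m1 has no motif on r2; only m2 contributes: 0.5 * 0.5 * (4, 6)
  expect_equal(unname(tf_feature(B, tf, c(m1 = 1, m2 = 0.5), "r2")),
               c(1, 1.5))
  expect_equal(unname(tf_feature(B, tf, c(m2 = 1), "r1")), 1.5 * c(4, 6))
  expect_equal(tf_feature(B, tf, numeric(0), "r1"), c(0, 0))
  set.seed(10)
  Br <- matrix(runif(12, 0, 2), 3, 4,
               dimnames = list(paste0("r", 1:3), paste0("m", 1:4)))
  tfr <- matrix(runif(20), 4, 5, dimnames = list(paste0("m", 1:4), NULL))
  g <- setNames(runif(4), paste0("m", 1:4))
  want <- sapply(1:5, function(s)
    sum(sapply(paste0("m", 1:4), function(m) g[m] * Br["r2", m] * tfr[m, s])))
  expect_equal(tf_feature(Br, tfr, g, "r2"), want)
})

test_that("lasso solver agrees with the soft-threshold closed form and a QP oracle", {
  set.seed(11)
  n <- 60
  # exactly orthonormal in the glmnet metric AND orthogonal to the
  # intercept: X'X/n = I, colMeans(X) = 0
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n, 4))))[, -1] * sqrt(n)
  colnames(X) <- paste0("x", 1:4)
  beta_true <- c(2, -1, 0, 0)
  y <- drop(X %*% beta_true) + rnorm(n, 0, 0.3)
  foldid <- rep_len(1:5, n)
  got <- vpeca:::lasso_cv(X, y, foldid, standardize = FALSE, thresh = 1e-14)
  lam <- got$lambda
  # closed form on (near-)orthonormal columns: S(x_j'y/n, lambda) / (x_j'x_j/n)
  yc <- y - mean(y)
  closed <- vapply(1:4, function(j) {
    z <- sum(X[, j] * yc) / n
    sign(z) * max(abs(z) - lam, 0) / (sum(X[, j]^2) / n)
  }, numeric(1))
  expect_equal(unname(got$beta), closed, tolerance = 1e-6)

  # split-variable QP oracle at the same lambda (independent solver)
  qp_lasso <- function(X, y, lam) {
    n <- nrow(X); p <- ncol(X)
    obj <- function(th) {
      b <- th[1:p] - th[(p + 1):(2 * p)]
      sum((y - mean(y) - X %*% b)^2) / (2 * n) + lam * sum(th)
    }
    gr <- function(th) {
      b <- th[1:p] - th[(p + 1):(2 * p)]
      g <- -t(X) %*% (y - mean(y) - X %*% b) / n
      c(g + lam, -g + lam)
    }
    o <- optim(rep(0, 2 * p), obj, gr, method = "L-BFGS-B",
               lower = 0,
               control = list(maxit = 20000, factr = 10, pgtol = 1e-12))
    o$par[1:p] - o$par[(p + 1):(2 * p)]
  }
  expect_lt(max(abs(unname(got$beta) - qp_lasso(X, y, lam))), 1e-4)

  # correlated 6-predictor instance vs the QP oracle
  set.seed(12)
  X6 <- matrix(rnorm(n * 6), n, 6) %*% chol(0.5 + 0.5 * diag(6))
  X6 <- scale(X6) * sqrt(n / (n - 1))
  colnames(X6) <- paste0("x", 1:6)
  y6 <- drop(X6 %*% c(1.5, -1, 0.5, 0, 0, 0)) + rnorm(n, 0, 0.5)
  g6 <- vpeca:::lasso_cv(X6, y6, foldid, standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(unname(g6$beta) - qp_lasso(X6, y6, g6$lambda))), 1e-4)

  # single-predictor path agrees with glmnet-parameterized closed form
  x1 <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x1"))
  y1 <- drop(2 * x1) + rnorm(n, 0, 0.3)
  u <- vpeca:::lasso_cv(x1, y1, foldid)
  z <- mean((x1 - mean(x1)) * (y1 - mean(y1))) / sd(drop(x1)) / sqrt((n - 1) / n)
  expect_equal(sign(unname(u$beta)), sign(z))
})

test_that("penalty limit: lambda -> infinity zeroes the model", {
  set.seed(13)
  d <- toy_design(n_rep = 5)
  # pure-noise target: CV picks the null model, gene reported empty
  n <- nrow(d)
  B <- matrix(1, 2, 2, dimnames = list(c("r1", "r2"), c("m1", "m2")))
  open <- matrix(rlnorm(2 * n), 2, dimnames = list(c("r1", "r2"), d$sample_id))
  tfx <- matrix(rlnorm(2 * n, 1), 2, dimnames = list(c("m1", "m2"), d$sample_id))
  tg <- rnorm(n)
  fit <- fit_expression_gene(tg, c("r1", "r2"), open, B, tfx,
                             S = c(r1 = 0L, r2 = 0L), delta = d$delta,
                             foldid = make_folds(d, 5, 1))
  # with a pure-noise response the 1-SE rule returns the empty model
  expect_true(fit$empty || length(fit$beta) <= 2)
})

test_that("step-3 gradient matches central finite differences", {
  set.seed(14)
  K <- 3; M <- 2; n <- 20
  args <- list(
    tg = rnorm(n, 10), O = matrix(rlnorm(K * n), K),
    Bk = matrix(runif(K * M, 0.5, 2), K),
    TFm = matrix(rlnorm(M * n, 1), M),
    dS = matrix(rep(rep(0:1, each = n / 2), K), K, n, byrow = TRUE) *
      c(1, 0, 1),                      # S = 1 for REs 1 and 3
    alpha_free = c(TRUE, FALSE, TRUE),
    beta0 = runif(K, -0.5, 0.5), gamma0 = runif(M, -0.5, 0.5),
    prior_scale = 1)
  npar <- 1 + K + M + 2
  for (rep in 1:10) {
    th <- rnorm(npar, 0, 0.7)
    g_an <- do.call(vpeca:::step3_gradient, c(list(th), args))
    g_fd <- vapply(seq_len(npar), function(j) {
      h <- 1e-6 * max(1, abs(th[j]))
      tp <- th; tp[j] <- th[j] + h
      tm <- th; tm[j] <- th[j] - h
      (do.call(vpeca:::step3_objective, c(list(tp), args)) -
         do.call(vpeca:::step3_objective, c(list(tm), args))) / (2 * h)
    }, numeric(1))
    expect_equal(g_an, g_fd, tolerance = 1e-5)
  }
})

test_that("with no priors/ridge and S = 0, step 3 solves the normal equations", {
  set.seed(15)
  d <- toy_design(n_rep = 5)
  n <- nrow(d)
  res_ids <- c("r1", "r2")
  B <- matrix(c(2, 1, 0, 1.5), 2, 2,
              dimnames = list(res_ids, c("m1", "m2")))
  open <- matrix(rlnorm(2 * n, 0.5), 2, dimnames = list(res_ids, d$sample_id))
  tfx <- matrix(rlnorm(2 * n, 1.5, 0.2), 2,
                dimnames = list(c("m1", "m2"), d$sample_id))
  gam <- c(m1 = 0.8, m2 = 0.6)
  feat <- rbind(r1 = open[1, ] * tf_feature(B, tfx, gam, "r1"),
                r2 = open[2, ] * tf_feature(B, tfx, gam, "r2"))
  tg <- 5 + 1.2 * feat["r1", ] - 0.7 * feat["r2", ] + rnorm(n, 0, 0.3)
  fit <- fit_expression_gene(tg, res_ids, open, B, tfx,
                             S = c(r1 = 0L, r2 = 0L), delta = d$delta,
                             gamma0 = gam, foldid = make_folds(d, 5, 2),
                             prior_scale = 0)
  skip_if(fit$empty, "lasso stage dropped both REs on this draw")
  # at the joint optimum with gamma fixed at its fitted value, (b0, beta)
  # must satisfy the normal equations of the induced linear model
  G1 <- drop(B[, names(fit$gamma), drop = FALSE] %*%
               (fit$gamma * tfx[names(fit$gamma), , drop = FALSE]))
  Xl <- cbind(1, t(open[names(fit$beta), , drop = FALSE] *
                     G1[names(fit$beta), , drop = FALSE]))
  ols <- drop(solve(t(Xl) %*% Xl, t(Xl) %*% tg))
  expect_equal(unname(c(fit$b0, fit$beta)), unname(ols), tolerance = 1e-4)
  expect_true(all(fit$alpha == 0))   # alpha fixed at 0 where S = 0
})

test_that("RE classification applies the ARE/ASRE rules", {
  sel <- fake_selection_fit(c("r1", "r2", "r3", "r4"),
                            c(0.99, 0.80, 0.99, 0.10))
  fits <- fake_expression_fit(list(
    g1 = fake_gene_fit(beta = c(r1 = 1.2, r2 = 0.8),
                       gamma = c(m1 = 0.5),
                       alpha = c(r1 = 0.5, r2 = 0)),
    g2 = fake_gene_fit(beta = c(r3 = 0), gamma = c(m1 = 0.2),
                       alpha = c(r3 = 0))))
  got <- classify_res(fits, sel)
  cls <- setNames(got$class, got$re_id)
  expect_equal(unname(cls["r1"]), "ASRE")   # P > .95, alpha != 0, beta != 0
  expect_equal(unname(cls["r2"]), "ARE")    # beta != 0 but P = 0.80
  expect_equal(unname(cls["r3"]), "inactive")  # beta numerically zero
  expect_equal(unname(cls["r4"]), "inactive")
  # ASRE implies ARE conditions: idempotent reclassification, subset rule
  expect_true(all(got$class[got$class == "ASRE"] != "inactive"))
  got2 <- classify_res(fits, sel)
  expect_identical(got, got2)
})
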