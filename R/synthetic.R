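# Synthetic-study generator: a toy genome plus matrices drawn from the
# model's own generative equations, with full ground truth, so every
# stage of the inference chain is testable without external data.

#' Default synthetic-study configuration
#'
#' The canonical parameter-recovery setting: 200 REs (100 promoters +
#' 100 distal, 20% carrying shifted selection scores), 100 target
#' genes, 50 TFs, 400 SNPs, two populations x 5 time points x 5
#' individuals (50 samples), RE effects `|beta| in [0.5, 1.5]`
#' (random sign), TF effects `|gamma| in [0.5, 1]` (positive), activity
#' shift `alpha = 1`, accessibility shift `omega = 2 * sigma_o`, and a
#' 200-context cross-tissue panel for the correlation priors.
#'
#' @return A named list of generator settings.
#' @export
default_recovery_config <- function() {
  list(
    n_re = 200, n_genes = 100, n_tf = 50, n_snp = 400,
    frac_selected = 0.2, n_rep = 5,
    times = c("0h", "6h", "1d", "3d", "5d"),
    chrom = "chr1", genome_len = 1e7,
    flank = 1e6, promoter_len = 2000,
    loop_coverage = 0.5,
    n_tf_per_re = 5,
    n_support_re = 3, n_support_tf = 3,
    beta_range = c(0.5, 1.5), gamma_range = c(0.5, 1.0),
    alpha_star = 1,
    sigma_o = 0.4, omega_star = 0.8,   # omega = 2 * sigma_o
    sigma_l = 5,
    mu_star = c(intercept = -5, fst = 6, ihs = 6, xpehh = 6, pbs = 6, ddaf = 2),
    sel_score_shift = 6, sel_score_shape = 4, sel_score_scale = 0.5,
    ld_range = c(10, 20),
    ddaf_sel = c(0.3, 0.7), ddaf_null_sd = 0.1,
    cp_logit_sd = 0.5,
    b_range = c(1, 2),
    n_ctx = 200, panel_sdlog_open = 0.5, panel_sdlog_tf = 0.25,
    min_abs_prior = 0.2
  )
}

validate_config <- function(config) {
  n_sel <- ceiling(config$frac_selected * config$n_re)
  if (n_sel > config$n_re) stop("more selected REs than REs")
  if (config$n_re < config$n_genes) stop("need at least one RE per gene (promoters)")
  if (config$n_snp < config$n_re) {
    stop("default generator places >= 1 SNP per RE; need n_snp >= n_re")
  }
  invisible(config)
}

#' Simulate a full synthetic study
#'
#' Draws a toy genome (genes, loops, candidate REs, motif hits), per-SNP
#' selection scores (shifted for the designated selected REs), the
#' selection status `S` from the logistic model on the LD-weighted
#' aggregates, openness from the accessibility model
#' (`O = eta + omega * delta * S + noise`), plug-in RE activity
#' (`Z = O + alpha * delta * S`), target-gene expression from the
#' regression model with sparse RE and TF supports, and a cross-context
#' panel for the priors. Composite per-SNP p-values are drawn calibrated
#' to the RE's true selection probability (the model's own premise that
#' `1 - mean(c_p)` approximates `P(S = 1)`).
#'
#' @param config Settings from [default_recovery_config()] (modifiable).
#' @param seed Integer seed; output is reproducible from (config, seed).
#' @return A list with the emitted study (`design`, `expression`,
#'   `tf_expr`, `openness`, `snps`, `genes`, `res`, `loops`, `B`,
#'   `map`, `panel`) and the `truth` (mu, P, S, eta, omega, alpha,
#'   per-gene beta/gamma supports, sigmas).
#' @export
simulate_study <- function(config = default_recovery_config(), seed = 1) {
  validate_config(config)
  withr::with_seed(seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cf) {
  # --- design ---------------------------------------------------------
  inds <- c(paste0("A", seq_len(cf$n_rep)), paste0("W", seq_len(cf$n_rep)))
  design <- tidyr::expand_grid(individual = inds, time = cf$times) |>
    dplyr::mutate(
      population = ifelse(startsWith(.data$individual, "A"),
                          "adaptive", "wildtype"),
      sample_id = paste(.data$individual, .data$time, sep = "_")
    ) |>
    dplyr::select("sample_id", "individual", "time", "population") |>
    as_sample_design(time_levels = cf$times)
  n <- nrow(design)
  delta <- design$delta

  # --- toy genome -----------------------------------------------------
  gene_ids <- sprintf("G%03d", seq_len(cf$n_genes))
  tf_ids <- sprintf("TF%02d", seq_len(cf$n_tf))
  genes <- tibble::tibble(
    gene_id = gene_ids, chrom = cf$chrom,
    tss = round(seq(5e5, cf$genome_len - 5e5, length.out = cf$n_genes)),
    strand = rep(c("+", "-"), length.out = cf$n_genes)
  )
  looped <- sample(cf$n_genes, round(cf$loop_coverage * cf$n_genes))
  loops <- tibble::tibble(
    chrom = cf$chrom,
    span_start = pmax(0, genes$tss[looped] -
                        round(stats::runif(length(looped), 2e5, 8e5))),
    span_end = pmin(cf$genome_len, genes$tss[looped] +
                      round(stats::runif(length(looped), 2e5, 8e5)))
  ) |>
    dplyr::mutate(start1 = .data$span_start, end1 = .data$span_start + 5000,
                  start2 = .data$span_end - 5000, end2 = .data$span_end)

  n_distal <- cf$n_re - cf$n_genes
  grid <- seq(1e4, cf$genome_len - 1e4, length.out = n_distal)
  width <- round(stats::runif(n_distal, 500, 2000))
  distal <- tibble::tibble(
    chrom = cf$chrom,
    start = round(grid + stats::runif(n_distal, -2000, 2000)),
    end = NA_integer_
  )
  distal$end <- distal$start + width
  # mark files whose intersection reproduces exactly these distal REs
  h3k27ac <- distal |> dplyr::mutate(end = .data$end + 300)
  h3k4me1 <- distal |> dplyr::mutate(start = .data$start - 300)
  res <- build_candidate_res(h3k27ac, h3k4me1, genes,
                             promoter_len = cf$promoter_len)
  re_ids <- res$re_id
  boundaries <- regulatory_boundaries(genes, loops, flank = cf$flank)
  map <- candidate_map(res, genes, boundaries)

  # --- motif hits -----------------------------------------------------
  B <- matrix(0, cf$n_re, cf$n_tf, dimnames = list(re_ids, tf_ids))
  for (k in seq_len(cf$n_re)) {
    m <- sample(cf$n_tf, cf$n_tf_per_re)
    B[k, m] <- stats::runif(cf$n_tf_per_re, cf$b_range[1], cf$b_range[2])
  }

  # --- SNPs and selection status --------------------------------------
  n_sel <- ceiling(cf$frac_selected * cf$n_re)
  shifted <- sample(re_ids, n_sel)
  re_of_snp <- c(seq_len(cf$n_re),
                 sample(cf$n_re, cf$n_snp - cf$n_re, replace = TRUE))
  pos <- round(res$start[re_of_snp] +
                 stats::runif(cf$n_snp) * (res$end[re_of_snp] - res$start[re_of_snp] - 1))
  is_shifted <- re_ids[re_of_snp] %in% shifted
  score_draw <- function(shifted_snp) {
    ifelse(shifted_snp,
           cf$sel_score_shift +
             stats::rgamma(cf$n_snp, cf$sel_score_shape, scale = cf$sel_score_scale),
           -log10(stats::runif(cf$n_snp)))
  }
  ddaf <- ifelse(
    is_shifted,
    cf$ddaf_sel[1] + (cf$ddaf_sel[2] - cf$ddaf_sel[1]) * stats::rbeta(cf$n_snp, 2, 2),
    pmin(pmax(stats::rnorm(cf$n_snp, 0, cf$ddaf_null_sd), -1), 1))
  snps <- tibble::tibble(
    snp_id = sprintf("snp%04d", seq_len(cf$n_snp)),
    chrom = cf$chrom, pos = pos,
    fst_mlogp = score_draw(is_shifted), ihs_mlogp = score_draw(is_shifted),
    xpehh_mlogp = score_draw(is_shifted), pbs_mlogp = score_draw(is_shifted),
    ddaf = ddaf,
    ld_score = stats::runif(cf$n_snp, cf$ld_range[1], cf$ld_range[2])
  ) |>
    dplyr::mutate(w = ld_weights(.data$ld_score), c_p = NA_real_)

  feats <- aggregate_re_features(snps, res)
  L <- drop(feature_matrix(feats) %*% cf$mu_star)
  P_true <- sigmoid(L)
  P_true[feats$n_snps == 0] <- 0
  S_true <- stats::rbinom(cf$n_re, 1, P_true)
  names(S_true) <- re_ids
  # composite p-values calibrated to the true selection probability:
  # 1 - c_p is a logit-scale perturbation of P(S = 1), the model's own
  # premise that p0 = 1 - mean(c_p) approximates the selection
  # probability. The perturbation is drawn per RE — SNPs in one RE share
  # the local sweep, so their composite evidence is correlated.
  eps_re <- stats::rnorm(cf$n_re, 0, cf$cp_logit_sd)
  snps$c_p <- 1 - sigmoid(L[re_of_snp] + eps_re[re_of_snp])
  adj <- bh_fdr(snps$c_p, 0.05)
  snps$selected <- adj$reject

  # --- openness -------------------------------------------------------
  base_eta <- stats::runif(cf$n_re, 1.5, 3.5)
  eta <- outer(base_eta, rep(1, length(cf$times))) *
    matrix(stats::runif(cf$n_re * length(cf$times), 0.6, 1.4),
           cf$n_re)
  dimnames(eta) <- list(re_ids, cf$times)
  omega <- matrix(0, cf$n_re, length(cf$times), dimnames = dimnames(eta))
  omega[S_true == 1, ] <- cf$omega_star
  t_idx <- match(as.character(design$time), cf$times)
  openness <- eta[, t_idx] + (omega[, t_idx] * (S_true == 1)) *
    matrix(delta, cf$n_re, n, byrow = TRUE) +
    matrix(stats::rnorm(cf$n_re * n, 0, cf$sigma_o), cf$n_re)
  openness <- pmax(openness, 0)
  colnames(openness) <- design$sample_id

  # --- TF expression --------------------------------------------------
  base_tf <- stats::rlnorm(cf$n_tf, log(10), 0.4)
  # TF expression varies much less than chromatin over the time course
  # (expression lags accessibility), so openness carries the linking signal
  tfac <- matrix(exp(stats::rnorm(cf$n_tf * length(cf$times), 0, 0.1)),
                 cf$n_tf, dimnames = list(tf_ids, cf$times))
  tf_expr <- (base_tf * tfac[, t_idx]) *
    matrix(exp(stats::rnorm(cf$n_tf * n, 0, 0.05)), cf$n_tf)
  dimnames(tf_expr) <- list(tf_ids, design$sample_id)

  # --- activity and target-gene expression ----------------------------
  alpha_true <- stats::setNames(ifelse(S_true == 1, cf$alpha_star, 0), re_ids)
  Z_true <- openness + (alpha_true * (S_true == 1)) %o% delta
  b0_true <- stats::setNames(stats::runif(cf$n_genes, 20, 60), gene_ids)
  beta_true <- gamma_true <- vector("list", cf$n_genes)
  names(beta_true) <- names(gamma_true) <- gene_ids
  expression <- matrix(0, cf$n_genes, n,
                       dimnames = list(gene_ids, design$sample_id))
  for (g in gene_ids) {
    cand <- map$re_id[map$gene_id == g]
    supp <- sample(cand, min(cf$n_support_re, length(cand)))
    # activating regulatory logic: positive RE effects, so the bilinear
    # (beta, gamma) orientation is identifiable via the correlation priors
    beta <- stats::setNames(
      stats::runif(length(supp), cf$beta_range[1], cf$beta_range[2]), supp)
    tf_pool <- tf_ids[colSums(B[supp, , drop = FALSE] > 0) > 0]
    supp_tf <- sample(tf_pool, min(cf$n_support_tf, length(tf_pool)))
    gamma <- stats::setNames(
      stats::runif(length(supp_tf), cf$gamma_range[1], cf$gamma_range[2]),
      supp_tf)
    # a regulating TF complex binds every RE of the gene's support, so no
    # support RE's contribution is scaled into invisibility
    miss <- which(B[supp, supp_tf, drop = FALSE] == 0)
    if (length(miss) > 0) {
      B[supp, supp_tf][miss] <- stats::runif(length(miss),
                                             cf$b_range[1], cf$b_range[2])
    }
    G <- B[supp, supp_tf, drop = FALSE] %*%
      (gamma * tf_expr[supp_tf, , drop = FALSE])
    expression[g, ] <- b0_true[g] + colSums(beta * Z_true[supp, , drop = FALSE] * G) +
      stats::rnorm(n, 0, cf$sigma_l)
    beta_true[[g]] <- beta
    gamma_true[[g]] <- gamma
  }

  # --- cross-context panel for priors ---------------------------------
  ctx <- sprintf("ctx%03d", seq_len(cf$n_ctx))
  O_ctx <- base_eta %o% rep(1, cf$n_ctx) *
    matrix(stats::rlnorm(cf$n_re * cf$n_ctx, 0, cf$panel_sdlog_open), cf$n_re)
  dimnames(O_ctx) <- list(re_ids, ctx)
  # chromatin is the context-specific layer; TF mRNA varies less across
  # tissues than accessibility does
  TF_ctx <- base_tf %o% rep(1, cf$n_ctx) *
    matrix(stats::rlnorm(cf$n_tf * cf$n_ctx, 0, cf$panel_sdlog_tf), cf$n_tf)
  dimnames(TF_ctx) <- list(tf_ids, ctx)
  TG_ctx <- matrix(0, cf$n_genes, cf$n_ctx, dimnames = list(gene_ids, ctx))
  for (g in gene_ids) {
    beta <- beta_true[[g]]
    gamma <- gamma_true[[g]]
    G <- B[names(beta), names(gamma), drop = FALSE] %*%
      (gamma * TF_ctx[names(gamma), , drop = FALSE])
    TG_ctx[g, ] <- b0_true[g] +
      colSums(beta * O_ctx[names(beta), , drop = FALSE] * G) +
      stats::rnorm(cf$n_ctx, 0, cf$sigma_l)
  }
  panel <- list(expression = rbind(TG_ctx, TF_ctx), openness = O_ctx)

  list(
    design = design, expression = expression, tf_expr = tf_expr,
    openness = openness, snps = snps, genes = genes, res = res,
    loops = loops, B = B, map = map, panel = panel,
    h3k27ac = h3k27ac, h3k4me1 = h3k4me1,
    truth = list(
      mu = cf$mu_star, linear_predictor = stats::setNames(L, re_ids),
      P = stats::setNames(P_true, re_ids), S = S_true,
      eta = eta, omega = omega, alpha = alpha_true,
      b0 = b0_true, beta = beta_true, gamma = gamma_true,
      sigma_o = cf$sigma_o, sigma_l = cf$sigma_l,
      shifted_res = shifted
    ),
    config = cf
  )
}
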