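# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except temp files the tests themselves write.

toy_design <- function(n_rep = 2, times = c("0h", "6h", "1d", "3d", "5d")) {
  inds <- c(paste0("A", seq_len(n_rep)), paste0("W", seq_len(n_rep)))
  df <- expand.grid(individual = inds, time = times,
                    stringsAsFactors = FALSE)
  df$population <- ifelse(startsWith(df$individual, "A"),
                          "adaptive", "wildtype")
  df$sample_id <- paste(df$individual, df$time, sep = "_")
  as_sample_design(df[, c("sample_id", "individual", "time", "population")],
                   time_levels = times)
}

# one-time-point design: n_rep adaptive + n_rep wildtype samples
flat_design <- function(n_rep = 5) {
  toy_design(n_rep = n_rep, times = "0h")
}

# a small, fast synthetic world for unit tests
small_config <- function() {
  cf <- default_recovery_config()
  cf$n_re <- 40; cf$n_genes <- 10; cf$n_tf <- 12; cf$n_snp <- 80
  cf$n_ctx <- 60
  cf
}

# tiny hand-made study pieces for network tests
fake_gene_fit <- function(beta, gamma, alpha = NULL, b0 = 0) {
  alpha <- alpha %||% setNames(rep(0, length(beta)), names(beta))
  structure(list(b0 = b0, beta = beta, gamma = gamma, alpha = alpha,
                 sigma2 = 1, Z = NULL, converged = TRUE, empty = FALSE),
            class = "vpeca_gene_fit")
}

fake_expression_fit <- function(fits) {
  structure(list(fits = fits, genes = names(fits), nonzero_tol = 1e-8,
                 seed = 1),
            class = "vpeca_expression_fit")
}

fake_selection_fit <- function(re_id, P_sel, threshold = 0.95) {
  structure(list(
    fit = tibble::tibble(re_id = re_id, n_snps = 1L, P_sel = P_sel,
                         S = as.integer(P_sel > threshold)),
    mu = rep(0, 6), n_iter = 1, converged = TRUE, threshold = threshold),
    class = "vpeca_selection_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_tmp <- function(df) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, path)
  path
}
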