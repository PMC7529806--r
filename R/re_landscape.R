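# RE catalog, per-gene regulatory boundaries, candidate RE->gene map,
# openness quantification and the replicate-consistency row filters.

#' Per-gene regulatory boundary
#'
#' The boundary is the \[-1 Mb, +1 Mb\] window around the TSS,
#' intersected with the smallest chromatin loop whose span contains the
#' TSS (ties broken by leftmost start). Loops wider than the window do
#' not shrink it; with no containing loop the boundary is the full
#' window, clipped at 0.
#'
#' @param gene One-row tibble/list with `chrom`, `tss`.
#' @param loops Loop tibble from [read_intervals()] (`kind = "bedpe"`).
#' @param flank Window half-width in bp.
#' @return A list with `chrom`, `start`, `end`.
#' @export
regulatory_boundary <- function(gene, loops, flank = 1e6) {
  w_start <- max(0, gene$tss - flank)
  w_end <- gene$tss + flank
  if (!is.null(loops) && nrow(loops) > 0) {
    cand <- loops[loops$chrom == gene$chrom &
                    loops$span_start <= gene$tss &
                    loops$span_end > gene$tss, , drop = FALSE]
    if (nrow(cand) > 0) {
      span <- cand$span_end - cand$span_start
      best <- order(span, cand$span_start)[1]
      w_start <- max(w_start, cand$span_start[best])
      w_end <- min(w_end, cand$span_end[best])
    }
  }
  list(chrom = gene$chrom, start = as.numeric(w_start), end = as.numeric(w_end))
}

#' Regulatory boundaries for every gene
#'
#' @param genes Tibble with `gene_id`, `chrom`, `tss`, `strand`.
#' @inheritParams regulatory_boundary
#' @return A tibble with `gene_id`, `chrom`, `start`, `end`.
#' @export
regulatory_boundaries <- function(genes, loops, flank = 1e6) {
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    b <- regulatory_boundary(genes[i, ], loops, flank = flank)
    tibble::tibble(gene_id = genes$gene_id[i], chrom = b$chrom,
                   start = b$start, end = b$end)
  })
}

merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  split(df, df$chrom) |>
    purrr::map_dfr(function(d) {
      r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
      tibble::tibble(chrom = d$chrom[1],
                     start = IRanges::start(r) - 1L,
                     end = IRanges::end(r))
    })
}

#' Build the candidate RE catalog
#'
#' Distal candidate REs are the intersections of the (merged) H3K27ac
#' and H3K4me1 peak sets: regions carrying both marks. One strand-aware
#' promoter per gene is added: the 2 kb immediately upstream of the TSS.
#'
#' @param h3k27ac,h3k4me1 Interval tibbles (`chrom`, `start`, `end`).
#' @param genes Gene annotation tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @param promoter_len Promoter length in bp upstream of the TSS.
#' @return RE tibble: `re_id`, `chrom`, `start`, `end`,
#'   `class` (promoter/distal), `gene_id` (promoters only).
#' @export
build_candidate_res <- function(h3k27ac, h3k4me1, genes, promoter_len = 2000) {
  a <- merge_intervals(h3k27ac)
  b <- merge_intervals(h3k4me1)
  distal <- purrr::map_dfr(intersect(unique(a$chrom), unique(b$chrom)), function(ch) {
    ra <- IRanges::IRanges(start = a$start[a$chrom == ch] + 1, end = a$end[a$chrom == ch])
    rb <- IRanges::IRanges(start = b$start[b$chrom == ch] + 1, end = b$end[b$chrom == ch])
    r <- IRanges::intersect(ra, rb)
    if (length(r) == 0) return(NULL)
    tibble::tibble(chrom = ch, start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })
  if (nrow(distal) > 0) {
    distal <- distal |>
      dplyr::mutate(re_id = paste0("RE_", .data$chrom, "_", .data$start, "_", .data$end),
                    class = "distal", gene_id = NA_character_)
  } else {
    distal <- tibble::tibble(chrom = character(), start = integer(), end = integer(),
                             re_id = character(), class = character(),
                             gene_id = character())
  }
  prom <- genes |>
    dplyr::mutate(
      start = ifelse(.data$strand == "+",
                     pmax(0, .data$tss - promoter_len), .data$tss),
      end = ifelse(.data$strand == "+",
                   pmax(1, .data$tss), .data$tss + promoter_len),
      re_id = paste0("prom_", .data$gene_id),
      class = "promoter"
    ) |>
    dplyr::select("re_id", "chrom", "start", "end", "class", "gene_id")
  dplyr::bind_rows(prom, distal[, names(prom)])
}

#' Candidate RE set per gene
#'
#' `I_l` contains the REs whose interval overlaps the gene's regulatory
#' boundary, optionally filtered by the absolute cross-context
#' correlation prior. Genes without a promoter RE are skipped with a
#' warning.
#'
#' @param res RE catalog from [build_candidate_res()].
#' @param genes Gene annotation tibble.
#' @param boundaries Output of [regulatory_boundaries()].
#' @param prior_beta0 Optional RE x gene prior-correlation matrix.
#' @param min_abs_prior Keep only REs with `|beta0| >= min_abs_prior`
#'   (promoters always kept); 0 disables the filter.
#' @return A tibble with `gene_id`, `re_id`, `is_promoter`.
#' @export
candidate_map <- function(res, genes, boundaries, prior_beta0 = NULL,
                          min_abs_prior = 0) {
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes$gene_id[i]
    b <- boundaries[boundaries$gene_id == g, ]
    if (nrow(b) == 0) return(NULL)
    sel <- res$chrom == b$chrom & res$start < b$end & res$end > b$start
    prom_id <- res$re_id[sel & res$class == "promoter" &
                           !is.na(res$gene_id) & res$gene_id == g]
    if (length(prom_id) == 0) {
      warning("gene ", g, " has no promoter RE inside its boundary; skipped")
      return(NULL)
    }
    ids <- res$re_id[sel]
    if (min_abs_prior > 0 && !is.null(prior_beta0)) {
      pr <- prior_beta0[ids, g]
      keep <- abs(pr) >= min_abs_prior | ids %in% prom_id
      ids <- ids[keep]
    }
    tibble::tibble(gene_id = g, re_id = ids, is_promoter = ids %in% prom_id)
  })
}

#' Openness scores from read counts
#'
#' The openness of an RE in a sample is the fold change of its reads
#' per base pair over the genome-average reads per base pair:
#' `O = (count/length) / (library_size/genome_len)`. Uniform coverage
#' gives 1 everywhere, and the score is invariant to jointly rescaling
#' all library sizes.
#'
#' @param read_counts RE x sample count matrix.
#' @param re_lengths RE lengths in bp (recycled by row).
#' @param library_sizes Per-sample total read counts.
#' @param genome_len Genome length in bp.
#' @return RE x sample openness matrix.
#' @export
openness_scores <- function(read_counts, re_lengths, library_sizes, genome_len) {
  if (any(library_sizes <= 0)) stop("zero or negative library size")
  if (any(re_lengths <= 0)) stop("RE lengths must be > 0")
  if (any(read_counts < 0)) stop("negative read count")
  dens <- sweep(read_counts, 1, re_lengths, "/")
  sweep(dens, 2, library_sizes / genome_len, "/")
}

#' Replicate-consistency row filter
#'
#' Drops rows that are zero in every sample, and rows where within any
#' replicate group (same population and time) the max/min ratio exceeds
#' the threshold; a group with min 0 and max > 0 counts as inconsistent
#' (infinite ratio).
#'
#' @param values Entity x sample matrix.
#' @param design Sample design tibble aligned to the columns.
#' @param max_min_ratio Threshold on the within-group max/min ratio.
#' @return A list with `kept` (filtered matrix) and `report`, a tibble
#'   of `id`, `kept`, `reason` (`all_zero` / `replicate_inconsistent`).
#' @export
filter_rows <- function(values, design, max_min_ratio = 500) {
  stopifnot(ncol(values) == nrow(design))
  groups <- split(seq_len(ncol(values)),
                  paste(design$population, design$time, sep = "."))
  all_zero <- rowSums(values != 0) == 0
  inconsistent <- rep(FALSE, nrow(values))
  for (idx in groups) {
    g <- values[, idx, drop = FALSE]
    gmax <- apply(g, 1, max)
    gmin <- apply(g, 1, min)
    bad <- (gmin == 0 & gmax > 0) | (gmin > 0 & gmax / gmin > max_min_ratio)
    inconsistent <- inconsistent | bad
  }
  reason <- dplyr::case_when(
    all_zero ~ "all_zero",
    inconsistent ~ "replicate_inconsistent",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  report <- tibble::tibble(
    id = rownames(values) %||% as.character(seq_len(nrow(values))),
    kept = keep,
    reason = reason
  )
  list(kept = values[keep, , drop = FALSE], report = report)
}
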