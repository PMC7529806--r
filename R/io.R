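# Readers/writers and alignment checks for the tabular and interval inputs.

#' Read a sample design table
#'
#' The design ties every sample to an individual, a time point and a
#' population label. Time is an ordered factor over the five hypoxia
#' exposure points (0h, 6h, 1d, 3d, 5d by default); the population is a
#' binary adaptive/wildtype label and the derived indicator
#' `delta = 1` for adaptive samples enters the accessibility and
#' activity models.
#'
#' @param path TSV file with columns `sample_id`, `individual`, `time`,
#'   `population`.
#' @param time_levels Ordered time levels; defaults to the five-point
#'   hypoxia time course.
#' @return A tibble with one row per sample and a `delta` column.
#' @export
read_design <- function(path, time_levels = c("0h", "6h", "1d", "3d", "5d")) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  needed <- c("sample_id", "individual", "time", "population")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("design file is missing column(s): ", paste(missing, collapse = ", "))
  }
  as_sample_design(df, time_levels = time_levels)
}

#' Validate a sample design data frame
#'
#' @param df Data frame with columns `sample_id`, `individual`, `time`,
#'   `population`.
#' @inheritParams read_design
#' @return A validated tibble with `time` as an ordered factor and a
#'   0/1 `delta` indicator (1 = adaptive).
#' @export
as_sample_design <- function(df, time_levels = c("0h", "6h", "1d", "3d", "5d")) {
  df <- tibble::as_tibble(df)
  bad_time <- setdiff(unique(df$time), time_levels)
  if (length(bad_time) > 0) {
    stop("unknown time level(s): ", paste(bad_time, collapse = ", "))
  }
  bad_pop <- setdiff(unique(df$population), c("adaptive", "wildtype"))
  if (length(bad_pop) > 0) {
    stop("population must be 'adaptive' or 'wildtype', got: ",
         paste(bad_pop, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in design")
  dup <- df |> dplyr::count(.data$individual, .data$time) |> dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicated (individual, time) pair(s) in design: ",
         paste(dup$individual, dup$time, sep = "/", collapse = ", "))
  }
  mixed <- df |>
    dplyr::distinct(.data$individual, .data$population) |>
    dplyr::count(.data$individual) |>
    dplyr::filter(.data$n > 1)
  if (nrow(mixed) > 0) {
    stop("individual(s) with more than one population label: ",
         paste(mixed$individual, collapse = ", "))
  }
  df |>
    dplyr::mutate(
      time = factor(.data$time, levels = time_levels, ordered = TRUE),
      delta = as.integer(.data$population == "adaptive")
    )
}

read_matrix_tsv <- function(path, what = "matrix") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop(what, ": duplicated row ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[, -1, drop = FALSE], is.numeric, logical(1)))
    stop(what, ": non-numeric column(s) in ", path, ": ",
         paste(names(bad), collapse = ", "))
  }
  rownames(m) <- ids
  m
}

check_alignment <- function(m, design, what) {
  missing <- setdiff(design$sample_id, colnames(m))
  if (length(missing) > 0) {
    stop(what, " matrix is missing design sample(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(colnames(m), design$sample_id)
  if (length(extra) > 0) {
    warning(what, " matrix has sample(s) not in design (dropped): ",
            paste(extra, collapse = ", "))
  }
  m <- m[, design$sample_id, drop = FALSE]
  if (any(!is.finite(m))) stop(what, " matrix contains non-finite values")
  if (any(m < 0)) stop(what, " matrix contains negative values")
  m
}

#' Read expression/openness matrices together with the sample design
#'
#' Columns of both matrices are aligned to the design's sample order;
#' a sample present in the design but absent from either matrix is an
#' error naming the sample.
#'
#' @param expression_path,openness_path TSV matrices: first column the
#'   gene/RE id, remaining columns one per sample.
#' @param design_path TSV design table (see [read_design()]).
#' @return A list with elements `expression` (genes x samples matrix),
#'   `openness` (REs x samples matrix) and `design` (tibble).
#' @export
read_design_and_matrices <- function(expression_path, openness_path, design_path) {
  design <- read_design(design_path)
  expr <- check_alignment(read_matrix_tsv(expression_path, "expression"),
                          design, "expression")
  open <- check_alignment(read_matrix_tsv(openness_path, "openness"),
                          design, "openness")
  if (any(rowSums(is.na(expr)) == ncol(expr))) stop("all-missing gene row in expression")
  list(expression = expr, openness = open, design = design)
}

#' Read genomic intervals (BED) or chromatin loops (BEDPE)
#'
#' Coordinates are 0-based half-open throughout. BED records become
#' regulatory-element rows (`re_id`, 4th column when present); BEDPE
#' records become loop rows whose `span` covers both anchors. BEDPE
#' lines with anchors on different chromosomes are skipped with a
#' warning.
#'
#' @param path BED3+/BEDPE file.
#' @param kind `"bed"` or `"bedpe"`.
#' @return A tibble of intervals (`chrom`, `start`, `end`, `re_id`) or
#'   loops (`chrom`, anchor and span coordinates).
#' @export
read_intervals <- function(path, kind = c("bed", "bedpe")) {
  kind <- match.arg(kind)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    if (kind == "bed") {
      return(tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), re_id = character()))
    }
    return(tibble::tibble(chrom = character(),
                          start1 = integer(), end1 = integer(),
                          start2 = integer(), end2 = integer(),
                          span_start = integer(), span_end = integer()))
  }
  fields <- stringr::str_split(lines, "\t")
  n_min <- if (kind == "bed") 3L else 6L
  rows <- purrr::imap(fields, function(f, i) {
    if (length(f) < n_min) {
      stop("malformed ", kind, " line ", i, " in ", path,
           " (expected >= ", n_min, " fields)")
    }
    f
  })
  if (kind == "bed") {
    out <- tibble::tibble(
      chrom = purrr::map_chr(rows, 1),
      start = suppressWarnings(as.integer(purrr::map_chr(rows, 2))),
      end = suppressWarnings(as.integer(purrr::map_chr(rows, 3))),
      re_id = purrr::map_chr(rows, function(f) {
        if (length(f) >= 4) f[[4]] else NA_character_
      })
    )
    if (any(is.na(out$start) | is.na(out$end))) {
      stop("non-numeric coordinate in ", path, " at line ",
           which(is.na(out$start) | is.na(out$end))[1])
    }
    out$re_id <- ifelse(is.na(out$re_id),
                        paste(out$chrom, out$start, out$end, sep = "_"),
                        out$re_id)
    bad <- out$start >= out$end
    if (any(bad)) {
      stop("empty or inverted interval at line ", which(bad)[1],
           " in ", path, " (start >= end)")
    }
    return(out)
  }
  out <- tibble::tibble(
    chrom1 = purrr::map_chr(rows, 1),
    start1 = suppressWarnings(as.integer(purrr::map_chr(rows, 2))),
    end1 = suppressWarnings(as.integer(purrr::map_chr(rows, 3))),
    chrom2 = purrr::map_chr(rows, 4),
    start2 = suppressWarnings(as.integer(purrr::map_chr(rows, 5))),
    end2 = suppressWarnings(as.integer(purrr::map_chr(rows, 6)))
  )
  if (any(is.na(out$start1) | is.na(out$end1) | is.na(out$start2) | is.na(out$end2))) {
    stop("non-numeric coordinate in BEDPE file ", path)
  }
  bad <- out$start1 >= out$end1 | out$start2 >= out$end2
  if (any(bad)) {
    stop("empty or inverted anchor at line ", which(bad)[1], " in ", path)
  }
  mixed <- out$chrom1 != out$chrom2
  if (any(mixed)) {
    warning(sum(mixed), " BEDPE record(s) with anchors on different ",
            "chromosomes skipped")
    out <- out[!mixed, , drop = FALSE]
  }
  tibble::tibble(
    chrom = out$chrom1,
    start1 = out$start1, end1 = out$end1,
    start2 = out$start2, end2 = out$end2,
    span_start = pmin(out$start1, out$start2),
    span_end = pmax(out$end1, out$end2)
  )
}

#' Write a triplet network to TSV
#'
#' @param triplets A `vpeca_network` (see [assemble_triplets()]) or a
#'   tibble with the triplet columns.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_network <- function(triplets, path) {
  df <- if (inherits(triplets, "vpeca_network")) triplets$triplets else tibble::as_tibble(triplets)
  cols <- c("TF", "RE_id", "TG", "beta", "gamma", "alpha", "P_selected",
            "class", "omega_flag")
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) stop("network is missing column(s): ",
                                paste(missing, collapse = ", "))
  readr::write_tsv(df[, cols], path)
  invisible(path)
}

#' Read a triplet network written by [write_network()]
#'
#' @param path TSV file.
#' @return A tibble of triplets.
#' @export
read_network_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    TF = readr::col_character(),
                    RE_id = readr::col_character(),
                    TG = readr::col_character(),
                    beta = readr::col_double(),
                    gamma = readr::col_double(),
                    alpha = readr::col_double(),
                    P_selected = readr::col_double(),
                    class = readr::col_character(),
                    omega_flag = readr::col_logical()
                  ))
}

#' Read a motif-hit table and collapse it to an RE x TF strength matrix
#'
#' One TF can match through several motifs; per the reference-genome
#' simplification, hits are individual-invariant and the strength
#' `B[k, m]` is the sum of all match strengths of all motifs assigned
#' to TF `m` on RE `k`.
#'
#' @param path TSV with columns `motif_id`, `TF`, `re_id`, `strength`.
#' @param re_ids,tf_ids Optional universe of row/column ids; defaults to
#'   the ids present in the file.
#' @return A non-negative RE x TF matrix.
#' @export
read_motif_hits <- function(path, re_ids = NULL, tf_ids = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          motif_id = readr::col_character(),
                          TF = readr::col_character(),
                          re_id = readr::col_character(),
                          strength = readr::col_double()
                        ))
  if (any(df$strength < 0)) stop("negative motif match strength")
  motif_hit_matrix(df, re_ids = re_ids, tf_ids = tf_ids)
}

#' Build the RE x TF motif strength matrix from a long hit table
#'
#' @param hits Tibble with columns `TF`, `re_id`, `strength`.
#' @inheritParams read_motif_hits
#' @return RE x TF matrix of summed strengths.
#' @export
motif_hit_matrix <- function(hits, re_ids = NULL, tf_ids = NULL) {
  re_ids <- re_ids %||% sort(unique(hits$re_id))
  tf_ids <- tf_ids %||% sort(unique(hits$TF))
  B <- matrix(0, length(re_ids), length(tf_ids),
              dimnames = list(re_ids, tf_ids))
  agg <- hits |>
    dplyr::group_by(.data$re_id, .data$TF) |>
    dplyr::summarise(strength = sum(.data$strength), .groups = "drop")
  keep <- agg$re_id %in% re_ids & agg$TF %in% tf_ids
  agg <- agg[keep, , drop = FALSE]
  B[cbind(agg$re_id, agg$TF)] <- agg$strength
  B
}

`%||%` <- function(a, b) if (is.null(a)) b else a
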