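#' Pairwise Spearman correlation between samples
#'
#' Sample-similarity QC: Spearman rank correlation (average ranks for ties)
#' between every pair of sample columns. With `gene_filter = "all"` the full
#' gene set enters every pair; with `"detected_in_either"` each pair is
#' computed on the genes whose FPKM meets the cutoff in at least one of the
#' two samples (the "all detected genes" convention of scatter-plot QC).
#' Being a rank statistic, the result is identical with or without the
#' log2(x + 1) transform.
#'
#' @param fpkm FPKM tibble (`gene` + sample columns); also accepts a tissue
#'   profile to correlate tissues instead of samples.
#' @param gene_filter `"all"` (default) or `"detected_in_either"`.
#' @param cutoff FPKM detection limit used by `"detected_in_either"`.
#' @return An object of class `"spearman_cor"`: the symmetric correlation
#'   matrix with unit diagonal and the sample ids as dimnames. Pairs whose
#'   filtered values are constant (or with fewer than 3 genes after filtering)
#'   are `NA`. Use [tidy()] for a long tibble.
#' @examples
#' fpkm <- tibble::tibble(gene = letters[1:5],
#'                        s1 = c(1, 2, 3, 4, 5), s2 = c(2, 1, 5, 4, 3))
#' spearman_matrix(fpkm)
#' @export
spearman_matrix <- function(fpkm, gene_filter = c("all", "detected_in_either"),
                            cutoff = 1) {
  fpkm <- validate_fpkm(fpkm)
  gene_filter <- match.arg(gene_filter)
  m <- as.matrix(fpkm[, -1, drop = FALSE])
  if (ncol(m) < 2L) abort("need at least 2 samples")
  if (nrow(m) < 3L) abort("need at least 3 genes")
  ids <- colnames(m)
  n <- ncol(m)
  if (gene_filter == "all") {
    cc <- suppressWarnings(stats::cor(m, method = "spearman"))
  } else {
    cc <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        keep <- m[, i] >= cutoff | m[, j] >= cutoff
        if (sum(keep) >= 3L) {
          cc[i, j] <- suppressWarnings(
            stats::cor(m[keep, i], m[keep, j], method = "spearman")
          )
        }
        cc[j, i] <- cc[i, j]
      }
    }
  }
  # A constant column yields NaN from cor(); report NA, keep the diagonal at 1.
  cc[is.nan(cc)] <- NA_real_
  diag(cc) <- 1
  structure(cc, class = c("spearman_cor", "matrix", "array"),
            gene_filter = gene_filter, cutoff = cutoff)
}

#' @exportS3Method generics::tidy
tidy.spearman_cor <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(
    sample_a = ids[idx[, 1]],
    sample_b = ids[idx[, 2]],
    rho = x[idx]
  ) %>% arrange(.data$sample_a, .data$sample_b)
}

#' @exportS3Method generics::glance
glance.spearman_cor <- function(x, ...) {
  off <- x[upper.tri(x)]
  tibble(
    n_samples = nrow(x),
    gene_filter = attr(x, "gene_filter"),
    min_rho = min(off, na.rm = TRUE),
    median_rho = stats::median(off, na.rm = TRUE),
    max_rho = max(off, na.rm = TRUE)
  )
}

#' Write a correlation matrix
#'
#' Square TSV with a header row and a leading id column.
#'
#' @param cor_matrix Result of [spearman_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cor_matrix <- function(cor_matrix, path) {
  df <- as_tibble(as.data.frame(unclass(cor_matrix)))
  df <- tibble(sample = rownames(cor_matrix), !!!df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
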