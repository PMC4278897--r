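#' Read an FPKM expression table
#'
#' Reads a tab-separated gene-by-sample table of FPKM values (fragments per
#' kilobase of exon model per million mapped reads). The first column holds
#' gene identifiers; the header row holds sample identifiers; the body is
#' numeric and nonnegative. The table is validated on read and the input gene
#' order is preserved.
#'
#' @param path Path to a TSV file ("." decimal separator, UTF-8).
#' @return A tibble with a `gene` character column followed by one numeric
#'   column per sample.
#' @seealso [write_fpkm_table()], [validate_fpkm()]
#' @export
read_fpkm_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FPKM table not found: ", path))
  }
  x <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, na = character(), name_repair = "minimal")
  names(x)[1] <- "gene"
  validate_fpkm(x)
}

#' Write an FPKM expression table
#'
#' Writes the matrix as TSV with full numeric precision, so that
#' `read_fpkm_table(write_fpkm_table(x, p))` round-trips exactly.
#'
#' @param fpkm A validated FPKM tibble (`gene` column + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fpkm_table <- function(fpkm, path) {
  fpkm <- validate_fpkm(fpkm)
  readr::write_tsv(fpkm, path, progress = FALSE)
  invisible(path)
}

#' Validate an FPKM table
#'
#' Checks the invariants of an expression matrix: unique gene and sample
#' identifiers, and a finite, nonnegative numeric body. Errors name the
#' offending identifier or cell.
#'
#' @param fpkm A data frame whose first column is the gene identifier.
#' @return The table as a tibble (first column renamed to `gene`), invisibly
#'   validated.
#' @export
validate_fpkm <- function(fpkm) {
  if (!is.data.frame(fpkm) || ncol(fpkm) < 2L) {
    abort("FPKM table must be a data frame with a gene column and >= 1 sample column")
  }
  smp <- names(fpkm)[-1]
  dup_s <- smp[duplicated(smp)]
  if (length(dup_s) > 0L) {
    abort(paste0("duplicate sample id: ", dup_s[1]))
  }
  x <- as_tibble(fpkm)
  names(x)[1] <- "gene"
  x$gene <- as.character(x$gene)
  dup_g <- x$gene[duplicated(x$gene)]
  if (length(dup_g) > 0L) {
    abort(paste0("duplicate gene id: ", dup_g[1]))
  }
  for (s in smp) {
    v <- x[[s]]
    if (!is.numeric(v)) {
      abort(paste0("non-numeric values in sample column '", s, "'"))
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0L) {
      abort(paste0(
        "invalid FPKM value at gene '", x$gene[bad[1]], "', sample '", s,
        "': must be finite and >= 0"
      ))
    }
  }
  x
}

#' Read a sample annotation table
#'
#' TSV with columns `sample_id`, `tissue`, `donor`, `compartment`
#' (one of `whole`, `islet`, `exocrine`) and `lane` (may be empty; the lane
#' groups samples multiplexed together on one sequencing lane).
#'
#' @param path Path to the TSV file.
#' @return A tibble with those five character columns.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("sample annotation not found: ", path))
  }
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  validate_annotation(x)
}

#' Write a sample annotation table
#'
#' @param annotation A validated annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_annotation <- function(annotation, path) {
  annotation <- validate_annotation(annotation)
  readr::write_tsv(annotation, path, progress = FALSE)
  invisible(path)
}

#' Validate a sample annotation table
#'
#' @param annotation A data frame with columns `sample_id`, `tissue`, `donor`,
#'   `compartment`, `lane` (`donor` and `lane` may be missing/NA).
#' @param fpkm Optional FPKM table; if given, every sample column must have
#'   exactly one annotation row.
#' @return The annotation as a tibble.
#' @export
validate_annotation <- function(annotation, fpkm = NULL) {
  required <- c("sample_id", "tissue", "compartment")
  missing_cols <- setdiff(required, names(annotation))
  if (length(missing_cols) > 0L) {
    abort(paste0("annotation missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(annotation)
  if (!"donor" %in% names(x)) x$donor <- NA_character_
  if (!"lane" %in% names(x)) x$lane <- NA_character_
  x <- x[, c("sample_id", "tissue", "donor", "compartment", "lane")]
  x[] <- lapply(x, as.character)
  dup <- x$sample_id[duplicated(x$sample_id)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate sample annotation for: ", dup[1]))
  }
  if (any(is.na(x$tissue) | x$tissue == "")) {
    abort("tissue label must be nonempty for every sample")
  }
  bad_cmp <- setdiff(unique(x$compartment), c("whole", "islet", "exocrine"))
  if (length(bad_cmp) > 0L) {
    abort(paste0("unknown compartment: ", bad_cmp[1],
                 " (must be whole, islet or exocrine)"))
  }
  if (!is.null(fpkm)) {
    smp <- names(fpkm)[-1]
    unannotated <- setdiff(smp, x$sample_id)
    if (length(unannotated) > 0L) {
      abort(paste0("sample without annotation: ", unannotated[1]))
    }
  }
  x
}

#' Average replicate samples into a tissue profile
#'
#' Collapses sample columns to one column per tissue, each entry the unweighted
#' arithmetic mean FPKM of that tissue's samples (on the FPKM scale, not the
#' log scale). The mean per-tissue FPKM is the expression estimate the
#' specificity classification operates on.
#'
#' @param fpkm FPKM tibble (`gene` + sample columns).
#' @param annotation Sample annotation tibble.
#' @param compartment Restrict to samples of one compartment (`"whole"`,
#'   `"islet"`, `"exocrine"`); `NULL` (default) keeps all annotated samples.
#' @return A tissue profile: tibble with `gene` plus one numeric column per
#'   tissue, tissues in first-appearance order of the annotation.
#' @examples
#' fpkm <- tibble::tibble(gene = "g1", s1 = 4, s2 = 6)
#' ann <- tibble::tibble(sample_id = c("s1", "s2"), tissue = "pancreas",
#'                       donor = c("d1", "d2"), compartment = "whole",
#'                       lane = NA_character_)
#' average_replicates(fpkm, ann) # pancreas = 5
#' @export
average_replicates <- function(fpkm, annotation, compartment = NULL) {
  fpkm <- validate_fpkm(fpkm)
  annotation <- validate_annotation(annotation, fpkm = fpkm)
  ann <- annotation[annotation$sample_id %in% names(fpkm)[-1], ]
  if (!is.null(compartment)) {
    ann <- ann[ann$compartment %in% compartment, ]
  }
  if (nrow(ann) == 0L) {
    abort("no samples selected for averaging")
  }
  tissues <- unique(ann$tissue)
  m <- as.matrix(fpkm[, -1, drop = FALSE])
  out <- lapply(tissues, function(tt) {
    cols <- ann$sample_id[ann$tissue == tt]
    rowMeans(m[, cols, drop = FALSE])
  })
  names(out) <- tissues
  tibble(gene = fpkm$gene, !!!out)
}

#' Log2 transform with unit pseudo-count
#'
#' Elementwise `log2(x + 1)` on every sample/tissue column, so FPKM 0 maps to
#' 0 and FPKM 1 to 1. Used for visualisation scales; rank-based statistics are
#' unaffected by it.
#'
#' @param fpkm FPKM or tissue-profile tibble (`gene` + numeric columns).
#' @return Same-shape tibble of `log2(FPKM + 1)`.
#' @export
log2_pseudo <- function(fpkm) {
  fpkm <- validate_fpkm(fpkm)
  fpkm %>% mutate(across(-"gene", ~ log2(.x + 1)))
}
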