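# Default 27-tissue panel (target tissue: pancreas).
DEFAULT_TISSUES <- c(
  "adipose", "adrenal_gland", "appendix", "bone_marrow", "brain", "colon",
  "duodenum", "endometrium", "esophagus", "gallbladder", "heart", "kidney",
  "liver", "lung", "lymph_node", "ovary", "pancreas", "placenta", "prostate",
  "salivary_gland", "skeletal_muscle", "skin", "small_intestine", "spleen",
  "stomach", "testis", "thyroid"
)

#' Simulation configuration
#'
#' Parameters for the synthetic FPKM panel generator. The defaults emulate the
#' study conditions the classifier is designed for: a 27-tissue human panel
#' with 1-4 replicates per tissue, a log-normal baseline spanning roughly five
#' orders of magnitude of FPKM, planted genes of every specificity category
#' with an 8-fold margin (comfortably above the 5-fold classification
#' threshold), multiplicative replicate noise, samples multiplexed 15 per
#' sequencing lane, and ~0.1% within-lane barcode leakage.
#'
#' @param n_tissues Number of tissues (default 27; the default tissue names
#'   are used when 27, generic labels otherwise).
#' @param target Target tissue label (default `"pancreas"` on the default
#'   panel, first tissue otherwise).
#' @param replicates Replicates per tissue: a single count, a `c(min, max)`
#'   range sampled per tissue, or a vector of length `n_tissues`.
#' @param category_counts Named integer vector of genes to plant per category
#'   (names from [spec_categories()]).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline FPKM draw (natural-log scale).
#' @param margin Planted enrichment fold margin; must exceed `fold`.
#' @param group_size_range `c(min, max)` planted group sizes.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   replicate noise (0 = noiseless).
#' @param leakage_rate Within-lane barcode leakage rate `r` (0 <= r < 1).
#' @param lane_size Samples multiplexed per sequencing lane.
#' @param detection_cutoff,fold Classification thresholds the planted margins
#'   are built against; `fold` must exceed 3 for the constructions to be
#'   airtight.
#' @param seed RNG seed used by [simulate_dataset()].
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(n_tissues = 27L,
                              target = NULL,
                              replicates = c(1L, 4L),
                              category_counts = c(
                                not_detected = 700L, tissue_enriched = 100L,
                                group_enriched = 100L, tissue_enhanced = 100L,
                                expressed_in_all = 600L, mixed = 400L
                              ),
                              baseline_meanlog = log(10), baseline_sdlog = 2,
                              margin = 8, group_size_range = c(2L, 7L),
                              noise_cv = 0, leakage_rate = 0.001,
                              lane_size = 15L,
                              detection_cutoff = 1, fold = 5,
                              seed = 1L) {
  tissues <- if (n_tissues == 27L) DEFAULT_TISSUES else sprintf("tissue%02d", seq_len(n_tissues))
  target <- target %||% if (n_tissues == 27L) "pancreas" else tissues[1]
  if (!target %in% tissues) abort("target must be one of the simulated tissues")
  counts <- setNames(rep(0L, 6L), SPEC_CATEGORIES)
  counts[names(category_counts)] <- as.integer(category_counts)
  if (any(counts < 0L) || sum(counts) == 0L) abort("category counts must be >= 0 and sum > 0")
  if (n_tissues < 3L) abort("need at least 3 tissues")
  stopifnot(margin > fold, fold > 3, noise_cv >= 0,
            leakage_rate >= 0, leakage_rate < 1, detection_cutoff > 0)
  if (counts[["tissue_enhanced"]] > 0L && n_tissues < 2 * margin) {
    abort("tissue_enhanced planting needs n_tissues >= 2 * margin")
  }
  structure(list(
    n_tissues = as.integer(n_tissues), tissues = tissues, target = target,
    replicates = replicates, category_counts = counts,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    margin = margin, group_size_range = as.integer(group_size_range),
    noise_cv = noise_cv, leakage_rate = leakage_rate,
    lane_size = as.integer(lane_size),
    detection_cutoff = detection_cutoff, fold = fold, seed = as.integer(seed)
  ), class = "sim_config")
}

# One planted per-tissue row for a given category. Each construction
# guarantees the category's defining inequality holds with the configured
# margin while every higher-precedence (and lower-precedence) rule is blocked.
plant_row <- function(category, cfg, t_idx) {
  n <- cfg$n_tissues
  cutoff <- cfg$detection_cutoff
  margin <- cfg$margin
  base <- function(k) rlnorm(k, cfg$baseline_meanlog, cfg$baseline_sdlog)
  v <- numeric(n)
  group <- NA_character_
  if (category == "not_detected") {
    v[-t_idx] <- base(n - 1L) * (runif(n - 1L) < 0.5)
    v[t_idx] <- runif(1, 0, cutoff * 0.999)
  } else if (category == "tissue_enriched") {
    others <- base(n - 1L)
    v[-t_idx] <- others
    v[t_idx] <- margin * max(max(others), cutoff)
  } else if (category == "group_enriched") {
    sizes <- seq(cfg$group_size_range[1], min(cfg$group_size_range[2], n - 1L))
    k <- sizes[sample.int(length(sizes), 1L)]
    members <- c(t_idx, sample(setdiff(seq_len(n), t_idx), k - 1L))
    outside <- setdiff(seq_len(n), members)
    v[outside] <- base(length(outside))
    floor_out <- max(max(v[outside]), cutoff)
    # Group values within a factor 2 of each other: min >= margin * outside
    # max (the defining inequality), while no member is 5-fold above another
    # (blocks tissue_enriched and any smaller sub-group).
    v[members] <- runif(k, margin * floor_out, 2 * margin * floor_out)
    group <- paste(sort(cfg$tissues[members]), collapse = ";")
  } else if (category == "tissue_enhanced") {
    tv <- max(10 * cutoff, rlnorm(1, log(200), 1))
    ratio <- runif(1, 2, 3)
    v[t_idx] <- tv
    # Smooth geometric decay: consecutive sorted ratio < fold blocks enriched
    # and any 2-7 group, while the mean stays below target / margin.
    v[-t_idx] <- tv / ratio^seq_len(n - 1L)
  } else if (category == "expressed_in_all") {
    spread <- min(3, (1 + cfg$fold) / 2)
    lv <- max(2 * cutoff, rlnorm(1, log(10), 1))
    v <- runif(n, lv, spread * lv)
  } else if (category == "mixed") {
    dcand <- 2:(n - 1L)
    d <- dcand[sample.int(length(dcand), 1L)]
    u <- runif(1, cutoff, 2 * cutoff * 0.999)
    others <- sample(setdiff(seq_len(n), t_idx))
    comp <- others[1]
    v[t_idx] <- u
    v[comp] <- 10 * u
    extra <- d - 2L
    if (extra > 0L) {
      v[others[1L + seq_len(extra)]] <- pmax(10 * u / 2^seq_len(extra), cutoff)
    }
    undet <- others[(1L + extra + 1L):length(others)]
    if (length(undet) > 0L) {
      v[undet] <- 0.9 * cutoff / 2^(seq_along(undet) - 1L)
    }
  } else {
    abort(paste0("unknown category: ", category))
  }
  list(values = v, group = group)
}

#' Simulate an FPKM panel with planted specificity structure
#'
#' Generates a gene-by-sample FPKM matrix, its sample annotation (tissue,
#' donor, compartment, lane) and the planted ground truth. Genes of each
#' category satisfy their defining inequality with the configured margin
#' before noise and leakage are applied; replicates are the tissue value times
#' multiplicative log-normal noise; barcode leakage (if `leakage_rate > 0`)
#' mixes a small fraction of signal between samples sharing a lane. Output is
#' deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @param seed Overrides `config$seed` when given.
#' @return List with `fpkm` (tibble, `gene` + sample columns), `annotation`
#'   (sample annotation tibble), `truth` (tibble `gene`, `category`, `group`,
#'   `margin`), and `profile_clean` (the noiseless gene-by-tissue tibble the
#'   planting produced).
#' @examples
#' sim <- simulate_dataset(simulation_config(category_counts = c(
#'   tissue_enriched = 5, mixed = 5), noise_cv = 0, leakage_rate = 0), seed = 7)
#' dim(sim$fpkm)
#' @export
simulate_dataset <- function(config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% config$seed)
  n <- config$n_tissues
  t_idx <- match(config$target, config$tissues)
  counts <- config$category_counts
  n_genes <- sum(counts)
  if (n_genes == 0L) abort("no genes to simulate")

  cats <- rep(names(counts), counts)
  cats <- sample(cats)  # shuffle so category blocks are not contiguous
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  m <- matrix(0, n_genes, n, dimnames = list(genes, config$tissues))
  groups <- rep(NA_character_, n_genes)
  for (i in seq_len(n_genes)) {
    p <- plant_row(cats[i], config, t_idx)
    m[i, ] <- p$values
    groups[i] <- p$group
  }
  truth <- tibble(
    gene = genes,
    category = factor(cats, levels = SPEC_CATEGORIES),
    group = groups,
    margin = config$margin
  )
  profile_clean <- tibble(gene = genes, !!!as.list(as.data.frame(m)))

  # Replicates per tissue
  reps <- config$replicates
  n_reps <- if (length(reps) == 1L) {
    rep(as.integer(reps), n)
  } else if (length(reps) == 2L) {
    rcand <- seq(as.integer(reps[1]), as.integer(reps[2]))
    rcand[sample.int(length(rcand), n, replace = TRUE)]
  } else if (length(reps) == n) {
    as.integer(reps)
  } else {
    abort("replicates must be a count, a c(min, max) range, or one count per tissue")
  }

  sample_tissue <- rep(config$tissues, times = n_reps)
  sample_idx <- sequence(n_reps)
  sample_ids <- paste0(sample_tissue, "_", sample_idx)
  n_samples <- length(sample_ids)

  sdlog <- sqrt(log(1 + config$noise_cv^2))
  sm <- matrix(0, n_genes, n_samples, dimnames = list(genes, sample_ids))
  for (j in seq_len(n_samples)) {
    noise <- if (sdlog > 0) rlnorm(n_genes, -sdlog^2 / 2, sdlog) else 1
    sm[, j] <- m[, sample_tissue[j]] * noise
  }

  annotation <- tibble(
    sample_id = sample_ids,
    tissue = sample_tissue,
    donor = paste0("donor_", seq_len(n_samples)),
    compartment = "whole",
    lane = paste0("lane_", ceiling(seq_len(n_samples) / config$lane_size))
  )
  fpkm <- tibble(gene = genes, !!!as.list(as.data.frame(sm)))
  if (config$leakage_rate > 0) {
    fpkm <- apply_barcode_leakage(fpkm, annotation, config$leakage_rate)
  }
  list(fpkm = fpkm, annotation = annotation, truth = truth,
       profile_clean = profile_clean)
}

#' Apply within-lane barcode leakage
#'
#' Models index misassignment among samples multiplexed on one sequencing
#' lane as proportional mixing on the FPKM scale: per gene, each sample keeps
#' `1 - r` of its signal and receives an equal share `r / (n_lane - 1)` of
#' each lanemate's signal. Lanes with a single sample are unchanged; the
#' per-gene total within a lane is conserved, and the operator is linear and
#' order-independent.
#'
#' @param fpkm FPKM tibble.
#' @param annotation Sample annotation; every sample must carry a lane.
#' @param rate Leakage rate `r`, `0 <= r < 1`.
#' @return FPKM tibble of the same shape.
#' @export
apply_barcode_leakage <- function(fpkm, annotation, rate) {
  fpkm <- validate_fpkm(fpkm)
  annotation <- validate_annotation(annotation, fpkm = fpkm)
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    abort("leakage rate must be in [0, 1)")
  }
  smp <- names(fpkm)[-1]
  lane_of <- setNames(annotation$lane, annotation$sample_id)[smp]
  if (any(is.na(lane_of) | lane_of == "")) {
    abort(paste0("sample without a lane: ", smp[which(is.na(lane_of) | lane_of == "")[1]]))
  }
  if (rate == 0) return(fpkm)
  m <- as.matrix(fpkm[, -1, drop = FALSE])
  for (ln in unique(lane_of)) {
    cols <- which(lane_of == ln)
    k <- length(cols)
    if (k < 2L) next
    sub <- m[, cols, drop = FALSE]
    tot <- rowSums(sub)
    m[, cols] <- (1 - rate) * sub + (rate / (k - 1)) * (tot - sub)
  }
  tibble(gene = fpkm$gene, !!!as.list(as.data.frame(m)))
}

#' Recovery report against planted truth
#'
#' Compares predicted categories with the planted ground truth: 6x6 confusion
#' matrix, overall accuracy and per-category accuracy.
#'
#' @param truth Truth tibble from [simulate_dataset()] (`gene`, `category`).
#' @param predicted Classification tibble from
#'   [classify_tissue_specificity()].
#' @return Object of class `"recovery_report"`: list with `confusion`
#'   (truth x predicted table), `accuracy`, `per_category` (tibble
#'   `category`, `n`, `accuracy`). [tidy()] returns the confusion matrix in
#'   long form; [glance()] the overall accuracy.
#' @export
recovery_report <- function(truth, predicted) {
  if (length(setdiff(truth$gene, predicted$gene)) > 0L ||
      length(setdiff(predicted$gene, truth$gene)) > 0L) {
    abort("truth and predicted classifications cover different gene sets")
  }
  pred <- predicted[match(truth$gene, predicted$gene), ]
  tc <- factor(as.character(truth$category), levels = SPEC_CATEGORIES)
  pc <- factor(as.character(pred$category), levels = SPEC_CATEGORIES)
  confusion <- table(truth = tc, predicted = pc)
  acc <- mean(as.character(tc) == as.character(pc))
  per_cat <- tibble(
    category = factor(SPEC_CATEGORIES, levels = SPEC_CATEGORIES),
    n = as.integer(rowSums(confusion)),
    accuracy = ifelse(rowSums(confusion) > 0,
                      diag(confusion) / rowSums(confusion), NA_real_)
  )
  structure(list(confusion = confusion, accuracy = acc, per_category = per_cat),
            class = "recovery_report")
}

#' @exportS3Method generics::tidy
tidy.recovery_report <- function(x, ...) {
  as_tibble(as.data.frame(x$confusion, responseName = "n"))
}

#' @exportS3Method generics::glance
glance.recovery_report <- function(x, ...) {
  tibble(n_genes = sum(x$confusion), accuracy = x$accuracy)
}

#' Write a simulated dataset
#'
#' Writes `matrix.tsv`, `annotation.tsv` and `truth.tsv` into a directory.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fpkm_table(sim$fpkm, file.path(dir, "matrix.tsv"))
  write_sample_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  truth <- sim$truth
  truth$category <- as.character(truth$category)
  readr::write_tsv(truth, file.path(dir, "truth.tsv"), na = "NA", progress = FALSE)
  invisible(dir)
}
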