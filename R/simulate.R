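#' Configuration for the synthetic cohort generator
#'
#' Bundles all knobs of the seeded synthetic single-nucleus cohort. Defaults
#' emulate a 15-case / 16-control cohort with three planted molecular
#' subtypes of 6, 4 and 5 patients across three annotated cell types.
#'
#' @param seed integer seed; identical (config, seed) pairs reproduce the
#'   cohort byte for byte.
#' @param n_subtypes number of planted case subtypes.
#' @param patients_per_subtype integer vector, one entry per subtype.
#' @param n_controls number of control individuals.
#' @param cell_types character vector of cell-type names.
#' @param cells_per_patient_per_type nuclei simulated per patient per type.
#' @param n_genes size of the gene universe.
#' @param n_gene_sets number of gene sets written to the GMT output.
#' @param genes_per_set length-2 integer range of set sizes.
#' @param de_genes_per_subtype_per_type planted DE genes per (subtype,
#'   cell type); disjoint across subtypes within a cell type.
#' @param de_log2fc planted absolute log2 fold change.
#' @param de_min_base minimum baseline mean for a gene to be eligible for
#'   DE planting (effects in essentially unexpressed genes are neither
#'   realistic nor recoverable); if too few genes qualify the highest-mean
#'   genes are used.
#' @param set_shift_fraction fraction of a "shifted" set's members drawn from
#'   one subtype's planted DE genes of a single direction.
#' @param shifted_sets_per_subtype_per_type coordinately shifted sets planted
#'   per (subtype, cell type).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param dropout_logit_slope,dropout_logit_intercept Bernoulli keep
#'   probability is plogis(intercept + slope * log(baseline mean)); the
#'   baseline (pre-effect) mean is used so planted effects survive to
#'   observed group means.
#' @param patient_effect_range per-patient multiplier range applied to the
#'   planted log2 effects, giving patients distinct severities.
#' @param clinical_linkage coefficient tying the combined clinical severity
#'   to a patient's mean planted absolute effect; 0 gives a clean null.
#' @param clinical_noise_sd Gaussian noise on clinical category scores.
#' @param bulk_noise_sd Gaussian noise of the pseudo-bulk profiles.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_subtypes = 3L,
                       patients_per_subtype = c(6L, 4L, 5L),
                       n_controls = 16L,
                       cell_types = c("CT1", "CT2", "CT3"),
                       cells_per_patient_per_type = 100L,
                       n_genes = 500L,
                       n_gene_sets = 50L,
                       genes_per_set = c(10L, 40L),
                       de_genes_per_subtype_per_type = 30L,
                       de_log2fc = 1.0,
                       de_min_base = 0.5,
                       set_shift_fraction = 0.8,
                       shifted_sets_per_subtype_per_type = 2L,
                       nb_dispersion = 0.4,
                       dropout_logit_slope = 1.0,
                       dropout_logit_intercept = 1.5,
                       patient_effect_range = c(0.85, 1.15),
                       clinical_linkage = 10,
                       clinical_noise_sd = 1.0,
                       bulk_noise_sd = 0.2) {
  cfg <- as.list(environment())
  if (length(cfg$patients_per_subtype) != cfg$n_subtypes)
    stopf("patients_per_subtype must have length n_subtypes (%d)", cfg$n_subtypes)
  if (cfg$de_genes_per_subtype_per_type > cfg$n_genes)
    stopf("de_genes_per_subtype_per_type (%d) exceeds n_genes (%d)",
          cfg$de_genes_per_subtype_per_type, cfg$n_genes)
  if (cfg$de_genes_per_subtype_per_type * cfg$n_subtypes > cfg$n_genes)
    stopf("cannot plant %d disjoint DE genes per subtype in %d genes",
          cfg$de_genes_per_subtype_per_type, cfg$n_genes)
  counts <- c(cfg$patients_per_subtype, cfg$n_controls,
              cfg$cells_per_patient_per_type, cfg$n_genes, cfg$n_gene_sets)
  if (any(counts <= 0)) stopf("all cohort counts must be positive")
  if (cfg$nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (cfg$set_shift_fraction < 0 || cfg$set_shift_fraction > 1)
    stopf("set_shift_fraction must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-cell-type single-nucleus cohort with planted subtypes
#'
#' Draws negative-binomial counts per (gene, cell) with log-normal baseline
#' means, plants subtype-by-cell-type DE genes as multiplicative shifts of
#' the group mean, applies Bernoulli dropout with keep logit linear in the
#' baseline log mean, writes gene sets (a subset planted to shift
#' coordinately with one subtype's DE genes), and generates five clinical
#' category scores linked to each patient's mean planted effect magnitude.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a list of class \code{sim_cohort} with elements \code{counts}
#'   (named list per cell type of sparse genes x cells count matrices),
#'   \code{cells}, \code{patients}, \code{gene_ids}, \code{sets} (named list
#'   of member vectors), \code{clinical} and \code{truth} (planted subtype
#'   labels, DE features with signed effects, shifted sets, per-patient
#'   effect multipliers, baseline means).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  G <- cfg$n_genes
  gene_ids <- sprintf("G%04d", seq_len(G))
  n_cases <- sum(cfg$patients_per_subtype)
  case_ids <- sprintf("P%02d", seq_len(n_cases))
  control_ids <- sprintf("C%02d", seq_len(cfg$n_controls))
  subtype_of_patient <- setNames(
    rep(seq_len(cfg$n_subtypes), cfg$patients_per_subtype), case_ids)

  patients <- data.frame(
    patient_id = c(case_ids, control_ids),
    diagnosis = rep(c("case", "control"), c(n_cases, cfg$n_controls)),
    age = round(runif(n_cases + cfg$n_controls, 6, 22), 1),
    sex = sample(c("M", "F"), n_cases + cfg$n_controls, replace = TRUE),
    RIN = round(rnorm(n_cases + cfg$n_controls, 7, 0.5), 2),
    PMI = round(runif(n_cases + cfg$n_controls, 10, 30), 1),
    region = sample(c("PFC", "ACC"), n_cases + cfg$n_controls, replace = TRUE),
    stringsAsFactors = FALSE)

  # per-patient severity multiplier on the planted log2 effects
  patient_effect <- setNames(
    runif(n_cases, cfg$patient_effect_range[1], cfg$patient_effect_range[2]),
    case_ids)

  # baseline means: gene-level log-normal x cell-type modulation
  base_gene <- rlnorm(G, meanlog = 0, sdlog = 1)
  base_means <- sapply(cfg$cell_types, function(ct)
    base_gene * rlnorm(G, meanlog = 0, sdlog = 0.5))
  rownames(base_means) <- gene_ids

  # plant DE genes: disjoint across subtypes within each cell type
  de_features <- list()
  for (ct in cfg$cell_types) {
    need <- cfg$de_genes_per_subtype_per_type * cfg$n_subtypes
    eligible <- gene_ids[base_means[, ct] >= cfg$de_min_base]
    if (length(eligible) < need)
      eligible <- gene_ids[order(-base_means[, ct])][seq_len(need)]
    pool <- sample(eligible, need)
    for (s in seq_len(cfg$n_subtypes)) {
      genes_s <- pool[((s - 1) * cfg$de_genes_per_subtype_per_type + 1):
                        (s * cfg$de_genes_per_subtype_per_type)]
      de_features[[paste(s, ct, sep = "|")]] <- data.frame(
        gene = genes_s,
        effect = sample(c(-1, 1), length(genes_s), replace = TRUE) * cfg$de_log2fc,
        stringsAsFactors = FALSE)
    }
  }

  counts <- list()
  cells_list <- list()
  all_patients <- patients$patient_id
  for (ct in cfg$cell_types) {
    n_cells_ct <- length(all_patients) * cfg$cells_per_patient_per_type
    mu <- matrix(0, nrow = G, ncol = n_cells_ct)
    cell_patient <- rep(all_patients, each = cfg$cells_per_patient_per_type)
    for (p in all_patients) {
      mu_p <- base_means[, ct]
      if (p %in% case_ids) {
        s <- subtype_of_patient[[p]]
        de <- de_features[[paste(s, ct, sep = "|")]]
        idx <- match(de$gene, gene_ids)
        mu_p[idx] <- mu_p[idx] * 2^(de$effect * patient_effect[[p]])
      }
      mu[, cell_patient == p] <- mu_p
    }
    x <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                nrow = G)
    keep_prob <- plogis(cfg$dropout_logit_intercept +
                          cfg$dropout_logit_slope * log(base_means[, ct]))
    keep <- matrix(rbinom(length(x), 1L, rep(keep_prob, times = n_cells_ct)),
                   nrow = G)
    x <- x * keep
    dimnames(x) <- list(gene_ids,
                        sprintf("%s_%s_%03d", ct, cell_patient,
                                sequence(rep(cfg$cells_per_patient_per_type,
                                             length(all_patients)))))
    counts[[ct]] <- methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
    cells_list[[ct]] <- data.frame(
      cell_id = colnames(x),
      patient_id = cell_patient,
      diagnosis = patients$diagnosis[match(cell_patient, patients$patient_id)],
      cell_type = ct,
      region = patients$region[match(cell_patient, patients$patient_id)],
      batch = sample(c("b1", "b2"), n_cells_ct, replace = TRUE),
      ribo_fraction = round(rbeta(n_cells_ct, 2, 20), 4),
      stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells_list)
  rownames(cells) <- NULL

  ## gene sets: planted shifted sets first, then random filler sets
  sets <- list()
  shifted_sets <- list()
  set_slot <- 1L
  size_range <- cfg$genes_per_set
  for (ct in cfg$cell_types) {
    for (s in seq_len(cfg$n_subtypes)) {
      de <- de_features[[paste(s, ct, sep = "|")]]
      for (k in seq_len(cfg$shifted_sets_per_subtype_per_type)) {
        if (set_slot > cfg$n_gene_sets) break
        dir <- sample(c(-1, 1), 1)
        cand <- de$gene[sign(de$effect) == dir]
        if (length(cand) < 4) { cand <- de$gene; dir <- sign(mean(de$effect)) }
        m <- sample(seq(size_range[1], size_range[2]), 1)
        n_core <- max(2L, min(length(cand), round(cfg$set_shift_fraction * m)))
        core <- sample(cand, n_core)
        filler_pool <- setdiff(gene_ids, de$gene)
        filler <- sample(filler_pool, max(0L, m - n_core))
        nm <- sprintf("SET%03d", set_slot)
        sets[[nm]] <- c(core, filler)
        shifted_sets[[paste(s, ct, sep = "|")]] <- rbind(
          shifted_sets[[paste(s, ct, sep = "|")]],
          data.frame(set = nm, shift = dir, stringsAsFactors = FALSE))
        set_slot <- set_slot + 1L
      }
    }
  }
  while (set_slot <= cfg$n_gene_sets) {
    m <- sample(seq(size_range[1], size_range[2]), 1)
    sets[[sprintf("SET%03d", set_slot)]] <- sample(gene_ids, m)
    set_slot <- set_slot + 1L
  }

  ## clinical scores (cases only): linked to mean planted |effect|
  severity <- cfg$clinical_linkage * patient_effect * cfg$de_log2fc
  clin_cats <- c("A", "B_verbal", "B_nonverbal", "C", "D")
  clinical <- data.frame(patient_id = case_ids, stringsAsFactors = FALSE)
  for (cat in clin_cats) {
    raw <- severity + rnorm(n_cases, 0, cfg$clinical_noise_sd)
    clinical[[cat]] <- pmax(0L, as.integer(round(raw)))
  }

  truth <- list(
    subtype_of_patient = subtype_of_patient,
    de_features = de_features,
    shifted_sets = shifted_sets,
    patient_effect = patient_effect,
    clinical_scores = clinical,
    base_means = base_means,
    config = unclass(cfg))

  structure(list(counts = counts, cells = cells, patients = patients,
                 gene_ids = gene_ids, sets = sets, clinical = clinical,
                 truth = truth),
            class = "sim_cohort")
}

#' Simulate a matched pseudo-bulk cohort from planted truth
#'
#' Collapses the planted per-cell-type mean profiles into one patients x
#' genes matrix: each patient's bulk value is the cell-type-weighted mean of
#' log2(planted mean + 1) plus Gaussian noise. Subtype labels are shared
#' with the single-nucleus truth.
#'
#' @param config the \code{\link{sim_config}} used for the cohort.
#' @param truth the \code{truth} element of a \code{\link{simulate_cohort}}
#'   result.
#' @param weights optional cell-type mixture weights (default equal).
#' @return patients x genes numeric matrix (cases and controls).
#' @export
simulate_bulk <- function(config, truth, weights = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cts <- config$cell_types
  if (is.null(weights)) weights <- rep(1 / length(cts), length(cts))
  if (length(weights) != length(cts)) stopf("need one weight per cell type")
  weights <- weights / sum(weights)
  base <- truth$base_means
  gene_ids <- rownames(base)
  case_ids <- names(truth$subtype_of_patient)
  control_ids <- sprintf("C%02d", seq_len(config$n_controls))
  all_ids <- c(case_ids, control_ids)
  seed2 <- (config$seed + 1000003L) %% 2147483647L
  with_seed(seed2, {
    bulk <- matrix(0, nrow = length(all_ids), ncol = length(gene_ids),
                   dimnames = list(all_ids, gene_ids))
    for (p in all_ids) {
      prof <- numeric(length(gene_ids))
      for (i in seq_along(cts)) {
        mu_p <- base[, cts[i]]
        if (p %in% case_ids) {
          s <- truth$subtype_of_patient[[p]]
          de <- truth$de_features[[paste(s, cts[i], sep = "|")]]
          idx <- match(de$gene, gene_ids)
          mu_p[idx] <- mu_p[idx] * 2^(de$effect * truth$patient_effect[[p]])
        }
        prof <- prof + weights[i] * log2(mu_p + 1)
      }
      bulk[p, ] <- pmax(prof + rnorm(length(gene_ids), 0, config$bulk_noise_sd), 0)
    }
    bulk
  })
}

#' Write a simulated cohort to plain-text files
#'
#' Per cell type: MatrixMarket counts (genes as rows, 1-based coordinate,
#' integer) plus a cells.tsv; shared genes.tsv, patients.tsv, sets.gmt,
#' clinical.tsv and truth.json. Round-trips losslessly through
#' \code{\link{read_cohort}}.
#'
#' @param cohort a \code{\link{simulate_cohort}} result.
#' @param out_dir output directory, created if missing.
#' @return \code{out_dir}, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(out_dir) &&
      !suppressWarnings(dir.create(out_dir, recursive = TRUE)))
    stopf("cannot create output directory '%s'", out_dir)
  for (ct in names(cohort$counts)) {
    tag <- sanitize_name(ct)
    write_mtx(cohort$counts[[ct]], file.path(out_dir, paste0(tag, "_counts.mtx")))
    ct_cells <- cohort$cells[cohort$cells$cell_type == ct, , drop = FALSE]
    write_tsv(ct_cells, file.path(out_dir, paste0(tag, "_cells.tsv")))
  }
  write_tsv(data.frame(gene_id = cohort$gene_ids),
            file.path(out_dir, "genes.tsv"))
  write_tsv(cohort$patients, file.path(out_dir, "patients.tsv"))
  write_gmt(cohort$sets, file.path(out_dir, "sets.gmt"))
  write_tsv(cohort$clinical, file.path(out_dir, "clinical.tsv"))
  truth <- cohort$truth
  # named atomic vectors serialize as bare arrays; keep names via lists
  truth$subtype_of_patient <- as.list(truth$subtype_of_patient)
  truth$patient_effect <- as.list(truth$patient_effect)
  truth$base_means <- list(genes = rownames(truth$base_means),
                           cell_types = colnames(truth$base_means),
                           values = unname(as.list(as.data.frame(truth$base_means))))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)
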