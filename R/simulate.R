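#' Configuration of the synthetic multi-study generator
#'
#' Describes a set of small expression studies with a planted class signal,
#' mirroring the structure of public colonic UC cohorts: a few studies of
#' 4-25 samples per class, thousands of genes, several probes per gene,
#' missing values, study-specific affine scale/offset (platform) differences,
#' a small set of class-informative genes and a few correlated gene blocks.
#'
#' @param n_controls,n_cases Integer vectors, one entry per study (defaults
#'   `c(4, 24, 10)` controls and `c(4, 25, 10)` UC cases, totalling 38
#'   controls and 39 cases over three studies).
#' @param n_genes Number of genes (default 2000).
#' @param n_informative Number of class-informative genes (default 20).
#' @param effect_size Mean shift added to informative genes in UC samples,
#'   in units of the per-gene biological sd (default 1.5).
#' @param n_corr_blocks,block_size Number and size of correlated gene blocks
#'   among the non-informative genes (defaults 5 blocks of 3).
#' @param rho_sim Target pairwise within-block correlation (default 0.9).
#' @param probes_per_gene_probs Probabilities of a gene being measured by 1,
#'   2 or 3 probes (default `c(0.5, 0.3, 0.2)`).
#' @param probe_noise_sd Technical sd added per probe measurement
#'   (default 0.3).
#' @param missing_rate Fraction of probe entries missing completely at
#'   random (default 0.02).
#' @param study_scale,study_offset Per-study affine parameters `a_s`, `b_s`
#'   applied to every probe value (defaults `c(1, 2.5, 0.6)` and
#'   `c(0, 5, -2)`, emulating platform scale differences).
#' @param gene_drop_rate Fraction of genes each study fails to measure
#'   (default 0.1), forcing a non-trivial gene intersection at merge time.
#' @param seed Integer seed for the shared ground truth; study s draws its
#'   noise from `seed + s`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_controls = c(4, 24, 10), n_cases = c(4, 25, 10),
                       n_genes = 2000, n_informative = 20, effect_size = 1.5,
                       n_corr_blocks = 5, block_size = 3, rho_sim = 0.9,
                       probes_per_gene_probs = c(0.5, 0.3, 0.2),
                       probe_noise_sd = 0.3, missing_rate = 0.02,
                       study_scale = c(1, 2.5, 0.6),
                       study_offset = c(0, 5, -2),
                       gene_drop_rate = 0.1, seed = 1L) {
  if (length(n_controls) != length(n_cases)) {
    abort("`n_controls` and `n_cases` must have one entry per study")
  }
  if (any(n_controls < 1) || any(n_cases < 1)) abort("per-study class counts must be positive")
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1)")
  if (effect_size < 0) abort("`effect_size` must be >= 0")
  if (rho_sim < 0 || rho_sim >= 1) abort("`rho_sim` must be in [0, 1)")
  if (n_informative + n_corr_blocks * block_size > n_genes) {
    abort("informative genes and correlated blocks exceed `n_genes`")
  }
  n_studies <- length(n_controls)
  structure(list(n_controls = as.integer(n_controls),
                 n_cases = as.integer(n_cases),
                 n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 n_corr_blocks = as.integer(n_corr_blocks),
                 block_size = as.integer(block_size),
                 rho_sim = rho_sim,
                 probes_per_gene_probs = probes_per_gene_probs / sum(probes_per_gene_probs),
                 probe_noise_sd = probe_noise_sd,
                 missing_rate = missing_rate,
                 study_scale = rep_len(study_scale, n_studies),
                 study_offset = rep_len(study_offset, n_studies),
                 gene_drop_rate = gene_drop_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Ground truth shared by all studies of one simulation: gene identities,
# baseline means, informative set, correlated-block membership, per-study
# gene panels (after random drop) and affine parameters.
make_truth <- function(config) {
  withr::with_seed(config$seed, {
    genes <- sprintf("GENE%04d", seq_len(config$n_genes))
    mu <- rnorm(config$n_genes, mean = 7, sd = 1)       # log2-intensity-like baseline
    informative <- sort(sample(genes, config$n_informative))
    pool <- setdiff(genes, informative)
    blocks <- NULL
    if (config$n_corr_blocks > 0 && config$block_size > 1) {
      picked <- sample(pool, config$n_corr_blocks * config$block_size)
      blocks <- split(picked, rep(seq_len(config$n_corr_blocks),
                                  each = config$block_size))
    }
    n_probes <- sample(seq_along(config$probes_per_gene_probs),
                       config$n_genes, replace = TRUE,
                       prob = config$probes_per_gene_probs)
    study_genes <- purrr::map(seq_along(config$n_controls), function(s) {
      keep <- runif(config$n_genes) >= config$gene_drop_rate
      if (!any(keep)) keep[1] <- TRUE
      genes[keep]
    })
    list(genes = genes, mu = setNames(mu, genes), informative = informative,
         blocks = blocks, n_probes = setNames(n_probes, genes),
         study_genes = study_genes,
         study_scale = config$study_scale, study_offset = config$study_offset,
         seed = config$seed)
  })
}

#' Simulate one probe-level expression study
#'
#' Gene-level values are `N(mu_j + effect_size * informative_j * y_i, 1)`;
#' genes inside a correlated block share a per-sample latent factor giving
#' pairwise correlation `rho_sim`. Each probe measures its gene through the
#' study's affine transform `a_s * g + b_s`, a fixed probe offset and
#' Gaussian technical noise, and entries are blanked missing-completely-at-
#' random at the configured rate. Deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param study Study index (1-based).
#' @param seed Integer seed for this study's noise (defaults to
#'   `config$seed + study`).
#' @param truth Shared ground truth; computed from `config` when omitted.
#' @return A list with `probes` (probe-level tibble), `map` (probe map
#'   tibble), `labels` (`sample_id`, `label` tibble) and `truth`.
#' @export
simulate_study <- function(config, study, seed = config$seed + study,
                           truth = make_truth(config)) {
  if (study < 1 || study > length(config$n_controls)) abort("invalid study index")
  n0 <- config$n_controls[study]
  n1 <- config$n_cases[study]
  n <- n0 + n1
  y <- c(rep(0L, n0), rep(1L, n1))
  sample_ids <- sprintf("s%d_%02d", study, seq_len(n))
  genes <- truth$study_genes[[study]]
  withr::with_seed(as.integer(seed), {
    g <- matrix(rnorm(length(genes) * n, mean = truth$mu[genes], sd = 1),
                nrow = length(genes), ncol = n)
    rownames(g) <- genes
    # planted class effect
    inf_here <- intersect(truth$informative, genes)
    g[inf_here, y == 1L] <- g[inf_here, y == 1L] + config$effect_size
    # correlated blocks via a shared latent factor per sample
    r <- config$rho_sim
    for (block in truth$blocks) {
      bg <- intersect(block, genes)
      if (length(bg) < 2) next
      f <- rnorm(n)
      noise <- matrix(rnorm(length(bg) * n), nrow = length(bg))
      g[bg, ] <- truth$mu[bg] + sqrt(r) * rep(f, each = length(bg)) +
        sqrt(1 - r) * noise
      g[intersect(bg, inf_here), y == 1L] <-
        g[intersect(bg, inf_here), y == 1L] + config$effect_size
    }
    # probe layer
    probe_gene <- rep(genes, times = truth$n_probes[genes])
    probe_ids <- paste0(probe_gene, "_p",
                        unlist(lapply(truth$n_probes[genes], seq_len)))
    probe_offset <- rnorm(length(probe_ids), sd = 0.5)
    a_s <- truth$study_scale[study]
    b_s <- truth$study_offset[study]
    vals <- a_s * g[probe_gene, , drop = FALSE] + b_s + probe_offset +
      matrix(rnorm(length(probe_ids) * n, sd = config$probe_noise_sd),
             nrow = length(probe_ids))
    if (config$missing_rate > 0) {
      mask <- matrix(runif(length(vals)) < config$missing_rate,
                     nrow = nrow(vals))
      # never blank an entire probe row or sample column
      mask[cbind(seq_len(nrow(mask)),
                 max.col(-mask))[rowSums(!mask) == 0, , drop = FALSE]] <- FALSE
      full_col <- colSums(!mask) == 0
      mask[1, full_col] <- FALSE
      vals[mask] <- NA
    }
  })
  rownames(vals) <- probe_ids
  colnames(vals) <- sample_ids
  probes <- tibble::as_tibble(as.data.frame(vals, optional = TRUE),
                              .name_repair = "minimal")
  probes <- tibble::add_column(probes, probe_id = probe_ids, .before = 1)
  list(probes = probes,
       map = tibble::tibble(probe_id = probe_ids, gene_symbol = probe_gene),
       labels = tibble::tibble(sample_id = sample_ids, label = y),
       truth = truth)
}

#' Simulate a full multi-study collection
#'
#' All studies share one ground truth (gene identities, informative set,
#' correlated blocks) but draw independent noise, use different affine
#' platform parameters, and each misses a random fraction of the genes.
#'
#' @param config A [sim_config()].
#' @return A list with `studies` (list of study bundles, see
#'   [simulate_study()]) and `truth`.
#' @export
simulate_multi_study <- function(config = sim_config()) {
  if (length(config$n_controls) < 2) abort("configure at least two studies")
  truth <- make_truth(config)
  studies <- purrr::map(seq_along(config$n_controls), function(s) {
    simulate_study(config, s, seed = config$seed + s, truth = truth)
  })
  names(studies) <- paste0("study", seq_along(studies))
  list(studies = studies, truth = truth)
}

#' Simulate a held-out validation study
#'
#' Draws a fresh study from the same ground truth as a training simulation
#' (same genes, informative set and correlated blocks) but with its own
#' sample counts, platform affine parameters and noise seed — the synthetic
#' analogue of validating on an expression cohort not used for training.
#' Defaults mirror an inactive-UC validation cohort (11 controls, 23 cases).
#'
#' @param config The [sim_config()] used for training.
#' @param n_controls,n_cases Validation class sizes (defaults 11 and 23).
#' @param scale,offset Affine platform parameters of the validation study.
#' @param seed Noise seed (default `config$seed + 10000`).
#' @param truth Shared ground truth; computed from `config` when omitted.
#' @return A study bundle as returned by [simulate_study()].
#' @export
simulate_validation_study <- function(config, n_controls = 11, n_cases = 23,
                                      scale = 1.8, offset = 3,
                                      seed = config$seed + 10000L,
                                      truth = make_truth(config)) {
  vcfg <- config
  vcfg$n_controls <- as.integer(n_controls)
  vcfg$n_cases <- as.integer(n_cases)
  vtruth <- truth
  vtruth$study_genes <- list(truth$genes)
  vtruth$study_scale <- scale
  vtruth$study_offset <- offset
  simulate_study(vcfg, study = 1, seed = seed, truth = vtruth)
}

#' Preprocess simulated studies into a training matrix
#'
#' Convenience wrapper running the standard pipeline on a simulated
#' collection: collapse probes to genes, KNN-impute per study, merge on the
#' gene intersection and z-score per sample.
#'
#' @param sim Result of [simulate_multi_study()].
#' @param k Imputation neighbours (default 2).
#' @return A labelled, z-scored samples-by-genes tibble.
#' @export
preprocess_simulated <- function(sim, k = 2) {
  per_study <- purrr::map(sim$studies, function(st) {
    collapse_probes_to_genes(st$probes, st$map) |>
      attach_labels(st$labels) |>
      impute_missing_knn(k = k)
  })
  merge_by_gene_intersection(per_study) |>
    zscore_per_sample()
}
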