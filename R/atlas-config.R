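#' Default major-class layout for the synthetic retina atlas
#'
#' Nine major classes (two progenitor states plus seven differentiated
#' classes) with macular birth-age Gaussians (mean/sd in days), overall
#' proportions, and flags marking progenitors and classes represented in the
#' adult reference. Peripheral birth means are the macular means shifted by
#' \code{macula_lag_days} (the macula matures first). Means are ordered to
#' follow the canonical retinal birth order (RGC early, cones/HC, then AC,
#' rods, BC and MG late).
#'
#' @return A data.frame with columns \code{class}, \code{birth_mu},
#'   \code{birth_sd}, \code{proportion}, \code{progenitor}, \code{in_adult}.
#' @export
default_classes <- function() {
  data.frame(
    class      = c("PRPC", "NRPC", "RGC", "Cone", "HC", "AC", "Rod", "BC", "MG"),
    birth_mu   = c(70, 84, 77, 84, 91, 105, 119, 133, 147),
    birth_sd   = c(12, 12, 10, 10, 10, 11, 12, 12, 12),
    proportion = c(0.20, 0.15, 0.08, 0.08, 0.08, 0.09, 0.12, 0.10, 0.10),
    progenitor = c(TRUE, TRUE, rep(FALSE, 7)),
    in_adult   = c(FALSE, FALSE, rep(TRUE, 7)),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic developing-retina atlas
#'
#' Collects every knob of the generator: the cell/gene budget, the per-class
#' birth-age Gaussians, the macula-to-periphery developmental lag, the
#' sampling design (ages, in days, at which cells are collected), the
#' negative-binomial count model, and the sizes/effect sizes of each planted
#' structure (class markers, latent-time modules, fate-biased TFs,
#' location DEGs, peak-gene links, class-specific peaks).
#'
#' @param n_cells Total developmental cells (split equally between macula and
#'   periphery).
#' @param n_genes Number of genes.
#' @param classes Class table as returned by [default_classes()].
#' @param macula_lag_days Non-negative lag (days) added to macular birth means
#'   to obtain peripheral birth means.
#' @param sampling_ages Ages (days post-conception) of the sampling design;
#'   every cell's recorded age is one of these.
#' @param nb_dispersion Negative-binomial size parameter theta
#'   (variance = mu + mu^2/theta).
#' @param marker_effect Fold change (>= 1) of class-marker and fate-TF genes
#'   in their target population.
#' @param n_marker_genes Markers planted per class.
#' @param n_module_genes Genes planted per latent-time module (three modules:
#'   decreasing, transiently peaked, increasing).
#' @param module_amplitude Amplitude (natural-log scale) of the module shapes.
#' @param maturation_sd Slope scale (days) of the latent maturation curve
#'   \code{pnorm(age, birth_mu, maturation_sd)}.
#' @param maturation_beta_sd Standard deviation of the per-gene maturation
#'   slopes (natural-log scale) carried by the unstructured gene block; sets
#'   how strongly expression drifts toward the adult profile.
#' @param latent_time_noise_sd Gaussian noise added to true maturation to form
#'   the recorded latent time.
#' @param deg_lfc Natural-log fold change of planted location DEGs.
#' @param n_location_degs Number of planted macula-vs-periphery DEGs (half in
#'   each direction).
#' @param n_adult_per_class Adult reference cells per adult class.
#' @param linkage_window_bp Maximum peak-to-gene distance used when planting
#'   linked peaks.
#' @param n_linked_peaks Number of peaks planted with accessibility that is an
#'   affine function of their gene's pseudobulk expression.
#' @param n_background_peaks Unlinked peaks with independent accessibility.
#' @param n_dar_per_class Class-specific accessible peaks planted per class.
#' @param dar_log2fc Planted log2 accessibility gain of class-specific peaks.
#' @param link_noise_sd Noise sd of the planted peak-gene affine relation.
#' @param chromatin_lead Lead (latent-time units) by which a gene's chromatin
#'   trajectory anticipates its expression trajectory.
#' @param embedding_dim Dimensionality of the low-dimensional embedding that
#'   carries the velocity field.
#' @param velocity_noise_sd Isotropic noise added to planted velocity vectors.
#' @param seed Integer seed; the whole atlas is a deterministic function of
#'   the configuration.
#'
#' @return An object of class \code{atlas_config} (a validated list).
#' @export
atlas_config <- function(n_cells = 6000L,
                         n_genes = 300L,
                         classes = default_classes(),
                         macula_lag_days = 14,
                         sampling_ages = seq(35, 203, by = 14),
                         nb_dispersion = 2,
                         marker_effect = 4,
                         n_marker_genes = 5L,
                         n_module_genes = 30L,
                         module_amplitude = 1.5,
                         maturation_sd = 20,
                         maturation_beta_sd = 1.2,
                         latent_time_noise_sd = 0.04,
                         deg_lfc = 1,
                         n_location_degs = 20L,
                         n_adult_per_class = 100L,
                         linkage_window_bp = 250000L,
                         n_linked_peaks = 40L,
                         n_background_peaks = 70L,
                         n_dar_per_class = 5L,
                         dar_log2fc = 2,
                         link_noise_sd = 0.25,
                         chromatin_lead = 0.15,
                         embedding_dim = 10L,
                         velocity_noise_sd = 0.3,
                         seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    classes = classes, macula_lag_days = macula_lag_days,
    sampling_ages = as.numeric(sampling_ages),
    nb_dispersion = nb_dispersion, marker_effect = marker_effect,
    n_marker_genes = as.integer(n_marker_genes),
    n_module_genes = as.integer(n_module_genes),
    module_amplitude = module_amplitude,
    maturation_sd = maturation_sd,
    maturation_beta_sd = maturation_beta_sd,
    latent_time_noise_sd = latent_time_noise_sd,
    deg_lfc = deg_lfc, n_location_degs = as.integer(n_location_degs),
    n_adult_per_class = as.integer(n_adult_per_class),
    linkage_window_bp = as.integer(linkage_window_bp),
    n_linked_peaks = as.integer(n_linked_peaks),
    n_background_peaks = as.integer(n_background_peaks),
    n_dar_per_class = as.integer(n_dar_per_class),
    dar_log2fc = dar_log2fc,
    link_noise_sd = link_noise_sd, chromatin_lead = chromatin_lead,
    embedding_dim = as.integer(embedding_dim),
    velocity_noise_sd = velocity_noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "atlas_config"
  validate_atlas_config(cfg)
}

validate_atlas_config <- function(cfg) {
  cl <- cfg$classes
  need <- c("class", "birth_mu", "birth_sd", "proportion", "progenitor", "in_adult")
  if (!all(need %in% names(cl)))
    stop2("classes table must have columns: class, birth_mu, birth_sd, proportion, progenitor, in_adult",
          "invalid_config")
  if (anyDuplicated(cl$class))
    stop2("duplicate class names", "invalid_config")
  if (any(cl$birth_sd <= 0))
    stop2("class birth sds must be > 0", "invalid_config")
  if (abs(sum(cl$proportion) - 1) > 1e-8)
    stop2("class proportions must sum to 1", "invalid_config")
  if (any(cl$proportion < 0))
    stop2("class proportions must be non-negative", "invalid_config")
  if (is.na(cfg$macula_lag_days) || cfg$macula_lag_days < 0)
    stop2("macula_lag_days must be >= 0", "invalid_config")
  if (cfg$n_cells < 2L || cfg$n_genes < 10L)
    stop2("n_cells must be >= 2 and n_genes >= 10", "invalid_config")
  if (cfg$nb_dispersion <= 0)
    stop2("nb_dispersion must be positive", "invalid_config")
  if (cfg$marker_effect < 1)
    stop2("marker_effect must be >= 1", "invalid_config")
  if (length(cfg$sampling_ages) < 2L || any(cfg$sampling_ages <= 0))
    stop2("sampling_ages must be at least two positive ages", "invalid_config")
  n_structured <- cfg$n_marker_genes * nrow(cl) +
    3L * cfg$n_module_genes + cfg$n_location_degs + 12L
  if (n_structured > cfg$n_genes)
    stop2(sprintf("n_genes (%d) too small for planted structure (%d genes needed)",
                  cfg$n_genes, n_structured), "invalid_config")
  cfg
}

#' @export
print.atlas_config <- function(x, ...) {
  cat("atlas_config:", x$n_cells, "cells x", x$n_genes, "genes,",
      nrow(x$classes), "classes\n")
  cat("  macula lag:", x$macula_lag_days, "days; sampling ages:",
      paste(range(x$sampling_ages), collapse = "-"), "days (",
      length(x$sampling_ages), "samples )\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
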