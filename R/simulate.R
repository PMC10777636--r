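#' Configuration for the synthetic community generator
#'
#' Defines a log-normal latent-factor compositional model with multinomial
#' read sampling. Taxa are indexed `OTU0001..`. Ecological modules fill taxa
#' sequentially from the first taxon; the planted core set (elevated
#' baseline log-abundance, so core taxa are both top-decile abundant and
#' ubiquitous) is spread across the module blocks in proportion to module
#' size — every cluster of the planted network contains core members, as in
#' real core-microbiota networks, which also makes the renormalized core
#' community composition zone-dependent. Core taxa exceeding the total
#' module size spill into the unassigned block. Soil function variables are
#' linear in the driver and antagonist latent factors, not in observed
#' abundances, keeping the planted causal direction unambiguous.
#'
#' @param n_zones Number of sampling zones (labels AL, RZ, TZ, Z4...).
#' @param reps_per_zone Replicates per zone; scalar or vector of length
#'   `n_zones`.
#' @param n_taxa,n_core Total taxa and planted core-set size.
#' @param n_modules Number of planted ecological modules.
#' @param module_sizes Integer vector of module sizes (sum <= n_taxa).
#' @param within_module_cor Latent correlation of module members, in (0,1).
#' @param driver_module,antagonist_module Indices of the module whose latent
#'   factor drives the soil functions positively resp. negatively.
#' @param effect_size_zone Shift (in SD units) applied to the driver factor
#'   (+) and antagonist factor (-) in the root zone.
#' @param effect_size_function Loading of each soil function on the driver
#'   minus antagonist factor contrast.
#' @param noise_sd SD of independent noise added to each soil function.
#' @param n_functions Number of soil function variables (default the study's
#'   ten: SOC, TN, AN, AP, UE, CAT, ACP, PPO, POD, INV).
#' @param depth Sequencing depth (reads per sample) for multinomial sampling.
#' @param core_log_boost,core_log_sd Mean and SD of the core-taxon baseline
#'   log-abundance elevation.
#' @param baseline_sd SD of non-core baseline log-abundances (mean 0).
#' @param trophic_bias Probability that a driver-module taxon is assigned a
#'   copiotrophic phylum (and an antagonist-module taxon an oligotrophic one).
#' @param seed Integer seed; identical config + seed gives bitwise-identical
#'   tables.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_zones = 3, reps_per_zone = 4,
                         n_taxa = 400, n_core = 40,
                         n_modules = 5, module_sizes = NULL,
                         within_module_cor = 0.8,
                         driver_module = 1, antagonist_module = 2,
                         effect_size_zone = 2,
                         effect_size_function = 1.5,
                         noise_sd = 0.5,
                         n_functions = 10,
                         depth = 50000,
                         core_log_boost = 6, core_log_sd = 0.3,
                         baseline_sd = 1,
                         trophic_bias = 0.8,
                         seed = 1) {
  if (is.null(module_sizes)) module_sizes <- rep(40L, n_modules)
  module_sizes <- as.integer(module_sizes)
  if (length(reps_per_zone) == 1) reps_per_zone <- rep(reps_per_zone, n_zones)
  stopifnot(
    n_zones >= 1, length(reps_per_zone) == n_zones, all(reps_per_zone >= 1),
    n_taxa >= 1, n_core >= 0, n_core <= n_taxa,
    length(module_sizes) == n_modules, all(module_sizes >= 1),
    sum(module_sizes) <= n_taxa,
    within_module_cor > 0, within_module_cor < 1,
    driver_module >= 1, driver_module <= n_modules,
    antagonist_module >= 1, antagonist_module <= n_modules,
    effect_size_zone >= 0, effect_size_function >= 0, noise_sd >= 0,
    n_functions >= 1, depth >= 1,
    trophic_bias >= 0, trophic_bias <= 1
  )
  if (n_modules > 1 && driver_module == antagonist_module)
    stop("driver and antagonist modules must differ")
  structure(as.list(environment()), class = "synth_config")
}

zone_labels <- function(n) {
  base <- c("AL", "RZ", "TZ")
  if (n <= 3) base[seq_len(n)] else c(base, paste0("Z", 4:n))
}

copiotroph_phyla <- c("Proteobacteria", "Actinobacteria",
                      "Bacteroidetes", "Firmicutes")
oligotroph_phyla <- c("Acidobacteria", "Chloroflexi",
                      "Planctomycetes", "Verrucomicrobia")
neutral_phyla <- c("Gemmatimonadetes", "Nitrospirae")
fungal_phyla <- c("Ascomycota", "Basidiomycota", "Zygomycota")

# Plausible field values for the ten soil variables (g/kg, mg/kg, activity
# units); only their order of magnitude matters as min-max standardization
# removes affine scale.
.function_base_levels <- c(SOC = 15.2, TN = 1.6, AN = 118, AP = 9.8,
                           UE = 46, CAT = 21, ACP = 32, PPO = 7.4,
                           POD = 12.5, INV = 24)

#' Generate a synthetic community with planted ground truth
#'
#' Simulates OTU counts, taxonomy, sample metadata and soil functions under
#' the model described in [synth_config()], and returns the planted truth
#' (core set, module labels, driver signs, latent factors) for recovery
#' testing.
#'
#' Model, per sample s and module m: latent factor f_m(s) ~ N(0,1), with
#' +/- `effect_size_zone` added to the driver/antagonist factor in zone RZ;
#' member log-abundance = baseline + sqrt(rho) f_m + sqrt(1-rho) eps;
#' non-module taxa baseline + eps. Counts are multinomial draws of the
#' softmax-transformed log-abundances at `depth` reads. Each function
#' variable is `effect_size_function * (f_driver - f_antagonist)` plus
#' N(0, noise_sd) noise, affinely mapped onto a plausible positive range.
#'
#' @param config A [synth_config()].
#' @return List with elements `otu` (counts [otu_table()]), `taxonomy`
#'   (data.frame), `meta` (data.frame), `fx` ([function_table()]) and
#'   `truth` (list: `core_set`, `module_label`, `driver_sign`,
#'   `latent_factors`, `config`).
#' @export
synth_community <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  zones <- zone_labels(cf$n_zones)
  zone_of <- rep(zones, cf$reps_per_zone)
  rep_of <- unlist(lapply(cf$reps_per_zone, seq_len))
  samples <- paste0(zone_of, rep_of)
  ord <- order(samples)
  samples <- samples[ord]; zone_of <- zone_of[ord]; rep_of <- rep_of[ord]
  n_s <- length(samples)
  shift_zone <- if ("RZ" %in% zones) "RZ" else zones[min(2, length(zones))]

  taxa <- sprintf("OTU%0*d", max(4L, nchar(cf$n_taxa)), seq_len(cf$n_taxa))
  module_label <- integer(cf$n_taxa)
  idx <- 1L
  for (m in seq_len(cf$n_modules)) {
    module_label[idx:(idx + cf$module_sizes[m] - 1L)] <- m
    idx <- idx + cf$module_sizes[m]
  }
  names(module_label) <- taxa

  # core taxa spread across module blocks proportionally to module size;
  # overflow beyond the total module size lands in the unassigned block
  core_idx <- integer(0)
  if (cf$n_core > 0) {
    in_modules <- min(cf$n_core, sum(cf$module_sizes))
    quota <- floor(in_modules * cf$module_sizes / sum(cf$module_sizes))
    rem <- in_modules - sum(quota)
    if (rem > 0) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1L
    for (m in seq_len(cf$n_modules))
      core_idx <- c(core_idx, which(module_label == m)[seq_len(quota[m])])
    overflow <- cf$n_core - in_modules
    if (overflow > 0)
      core_idx <- c(core_idx, which(module_label == 0)[seq_len(overflow)])
    core_idx <- sort(core_idx)
  }
  core <- taxa[core_idx]

  # latent module factors, zone-shifted on the driver/antagonist contrast
  set.seed(cf$seed + 1L)
  f <- matrix(stats::rnorm(cf$n_modules * n_s), cf$n_modules, n_s,
              dimnames = list(paste0("M", seq_len(cf$n_modules)), samples))
  in_rz <- zone_of == shift_zone
  f[cf$driver_module, in_rz] <- f[cf$driver_module, in_rz] + cf$effect_size_zone
  f[cf$antagonist_module, in_rz] <- f[cf$antagonist_module, in_rz] - cf$effect_size_zone

  # baseline log-abundances: core taxa elevated so they land in the top
  # decile and are present in every sample at the default depth
  set.seed(cf$seed + 2L)
  mu <- stats::rnorm(cf$n_taxa, 0, cf$baseline_sd)
  if (cf$n_core > 0)
    mu[core_idx] <- cf$core_log_boost +
      stats::rnorm(cf$n_core, 0, cf$core_log_sd)

  set.seed(cf$seed + 3L)
  eps <- matrix(stats::rnorm(cf$n_taxa * n_s), cf$n_taxa, n_s)
  rho <- cf$within_module_cor
  X <- mu + eps  # non-module default
  for (m in seq_len(cf$n_modules)) {
    rows <- which(module_label == m)
    X[rows, ] <- mu[rows] +
      sqrt(rho) * matrix(f[m, ], length(rows), n_s, byrow = TRUE) +
      sqrt(1 - rho) * eps[rows, ]
  }

  # multinomial read sampling of softmax-transformed log-abundances
  set.seed(cf$seed + 4L)
  counts <- matrix(0, cf$n_taxa, n_s, dimnames = list(taxa, samples))
  for (s in seq_len(n_s)) {
    p <- exp(X[, s] - max(X[, s]))
    counts[, s] <- stats::rmultinom(1, cf$depth, p / sum(p))
  }
  if (cf$n_core > 0) {
    occ <- rowSums(counts[core, , drop = FALSE] > 0) / n_s
    if (any(occ < 0.95))
      warning(sprintf(
        "depth %d too low to realize core occupancy: minimum achieved %.3f",
        cf$depth, min(occ)))
  }

  # soil functions: linear in the driver - antagonist latent contrast
  set.seed(cf$seed + 5L)
  fn_names <- names(.function_base_levels)
  if (cf$n_functions <= length(fn_names)) {
    fn_names <- fn_names[seq_len(cf$n_functions)]
    base <- unname(.function_base_levels[seq_len(cf$n_functions)])
  } else {
    extra <- cf$n_functions - length(fn_names)
    fn_names <- c(fn_names, paste0("FX", seq_len(extra)))
    base <- c(unname(.function_base_levels), rep(10, extra))
  }
  contrast <- f[cf$driver_module, ] - f[cf$antagonist_module, ]
  fx_vals <- matrix(0, n_s, cf$n_functions, dimnames = list(samples, fn_names))
  for (j in seq_len(cf$n_functions)) {
    raw <- cf$effect_size_function * contrast +
      cf$noise_sd * stats::rnorm(n_s)
    fx_vals[, j] <- pmax(base[j] * (1 + 0.1 * raw), 0.01 * base[j])
  }

  # taxonomy: driver-module taxa lean copiotrophic, antagonist oligotrophic;
  # a slice of unassigned taxa is fungal
  set.seed(cf$seed + 6L)
  phylum <- character(cf$n_taxa)
  kingdom <- rep("Bacteria", cf$n_taxa)
  unassigned <- which(module_label == 0)
  n_fungi <- floor(length(unassigned) * 0.25)
  fungi_idx <- if (n_fungi > 0) utils::tail(unassigned, n_fungi) else integer(0)
  kingdom[fungi_idx] <- "Fungi"
  for (i in seq_len(cf$n_taxa)) {
    if (i %in% fungi_idx) {
      phylum[i] <- sample(fungal_phyla, 1, prob = c(0.8, 0.15, 0.05))
    } else if (module_label[i] == cf$driver_module) {
      pool <- if (stats::runif(1) < cf$trophic_bias) copiotroph_phyla else oligotroph_phyla
      phylum[i] <- sample(pool, 1)
    } else if (module_label[i] == cf$antagonist_module) {
      pool <- if (stats::runif(1) < cf$trophic_bias) oligotroph_phyla else copiotroph_phyla
      phylum[i] <- sample(pool, 1)
    } else {
      phylum[i] <- sample(c(copiotroph_phyla, oligotroph_phyla, neutral_phyla), 1)
    }
  }

  driver_sign <- numeric(cf$n_modules)
  driver_sign[cf$driver_module] <- 1
  driver_sign[cf$antagonist_module] <- -1

  list(
    otu = otu_table(counts, kind = "counts"),
    taxonomy = data.frame(otu_id = taxa, kingdom = kingdom, phylum = phylum,
                          stringsAsFactors = FALSE),
    meta = data.frame(sample_id = samples, zone = zone_of,
                      replicate = as.integer(rep_of), stringsAsFactors = FALSE),
    fx = function_table(fx_vals),
    truth = list(core_set = core, module_label = module_label,
                 driver_sign = driver_sign, latent_factors = f,
                 config = cf)
  )
}
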