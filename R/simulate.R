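#' Configuration for the serum-incubation simulator
#'
#' Describes a synthetic exo-metabolome experiment: how many compounds
#' of each kinetic class to simulate, the strain panel (wild type plus
#' paired knockout/overexpression mutants per transporter gene), the
#' measurement noise, and the injection-order drift of the instrument.
#'
#' Kinetic classes:
#' \describe{
#'   \item{IMPORTED}{taken up by cells; expectation `baseline * exp(-r_s t)`.}
#'   \item{EXPORTED}{excreted by cells; expectation `baseline * (1 + r_s t)`
#'     (optionally saturating).}
#'   \item{SERUM_DEGRADING}{decays in serum itself, cells or not.}
#'   \item{SERUM_APPEARING}{appears in serum itself, cells or not.}
#'   \item{INERT}{flat.}
#' }
#' The strain-specific rate `r_s` multiplies the wild-type rate by
#' `oe_factor` in the overexpression mutant of the affected gene, by
#' `ko_factor` in its knockout (transporter redundancy means a single
#' knockout rarely abolishes transport, so `ko_factor > 0` by default),
#' and by 0 in the serum-only control; serum-intrinsic classes keep
#' their rate in every well.
#'
#' @param n_imported,n_exported,n_serum_degrading,n_serum_appearing,n_inert
#'   Compound counts per kinetic class.
#' @param noise_cv Multiplicative lognormal replicate noise, as a
#'   percent coefficient of variation.
#' @param drift_amplitude Fractional amplitude of the smooth monotone
#'   instrument drift across the run (every injection is multiplied by
#'   a half-cosine ramp spanning `1 - a` to `1 + a`).
#' @param qc_every Interleave one pooled-QC injection every `qc_every`
#'   analytical injections (plus one at the start and one at the end).
#' @param strains Data frame with columns `gene`, `has_ko`, `has_oe`
#'   naming the transporter panel.
#' @param oe_factor,ko_factor Rate multipliers for overexpression and
#'   knockout of a compound's affected gene.
#' @param import_rate_range,export_rate_range,serum_rate_range Ranges
#'   (per minute) from which wild-type rates are drawn uniformly.
#' @param baseline_log10_range Range of `log10` baseline peak area.
#' @param time_points Sampling times in minutes.
#' @param n_replicates Technical replicates per strain and time point.
#' @param export_kinetics `"linear"` (default) or `"saturating"`
#'   (exponential approach with a 15-min time constant).
#' @param seed Integer seed used by [simulate_serum_experiment()].
#' @return A validated list of class `sim_config`.
#' @seealso [default_serum_design()] for the study-design defaults.
#' @export
sim_config <- function(n_imported = 12,
                       n_exported = 12,
                       n_serum_degrading = 6,
                       n_serum_appearing = 6,
                       n_inert = 64,
                       noise_cv = 10,
                       drift_amplitude = 0.1,
                       qc_every = 10,
                       strains = tibble::tibble(
                         gene = c("yeaV", "hsrA"),
                         has_ko = TRUE, has_oe = TRUE
                       ),
                       oe_factor = 3,
                       ko_factor = 0.3,
                       import_rate_range = c(0.03, 0.08),
                       export_rate_range = c(0.05, 0.2),
                       serum_rate_range = c(0.02, 0.06),
                       baseline_log10_range = c(4, 6),
                       time_points = c(0, 5, 15, 30),
                       n_replicates = 3,
                       export_kinetics = c("linear", "saturating"),
                       seed = 1L) {
  cfg <- list(
    n_imported = n_imported, n_exported = n_exported,
    n_serum_degrading = n_serum_degrading,
    n_serum_appearing = n_serum_appearing, n_inert = n_inert,
    noise_cv = noise_cv, drift_amplitude = drift_amplitude,
    qc_every = qc_every, strains = tibble::as_tibble(strains),
    oe_factor = oe_factor, ko_factor = ko_factor,
    import_rate_range = import_rate_range,
    export_rate_range = export_rate_range,
    serum_rate_range = serum_rate_range,
    baseline_log10_range = baseline_log10_range,
    time_points = sort(unique(time_points)),
    n_replicates = as.integer(n_replicates),
    export_kinetics = match.arg(export_kinetics),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  counts <- unlist(cfg[c("n_imported", "n_exported", "n_serum_degrading",
                         "n_serum_appearing", "n_inert")])
  if (any(counts < 0)) stop("compound counts must be >= 0", call. = FALSE)
  if (sum(counts) < 1) stop("simulate at least one compound", call. = FALSE)
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (cfg$drift_amplitude < 0 || cfg$drift_amplitude >= 1) {
    stop("drift_amplitude must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$oe_factor < 1) stop("oe_factor must be >= 1", call. = FALSE)
  if (cfg$ko_factor < 0 || cfg$ko_factor > 1) {
    stop("ko_factor must lie in [0, 1]", call. = FALSE)
  }
  if (!all(c("gene", "has_ko", "has_oe") %in% names(cfg$strains))) {
    stop("`strains` needs columns gene, has_ko, has_oe", call. = FALSE)
  }
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (length(cfg$time_points) < 2) stop("need >= 2 time points", call. = FALSE)
  if (cfg$qc_every < 1) stop("qc_every must be >= 1", call. = FALSE)
  cfg
}

#' Default study design of the serum footprinting experiment
#'
#' The simulator defaults frozen to the published experimental design:
#' time points 0, 5, 15 and 30 minutes, three technical replicates per
#' strain and time point, triplicate serum-only control wells at every
#' time point, pooled-QC injections interleaved through the run, and
#' paired knockout/overexpression mutants with a 3-fold overexpression
#' and a residual 0.3 knockout rate multiplier (single-transporter
#' knockouts rarely abolish transport because of redundancy).
#'
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @examples
#' cfg <- default_serum_design()
#' cfg$time_points
#' @export
default_serum_design <- function(...) sim_config(...)

sim_classes <- c("IMPORTED", "EXPORTED", "SERUM_DEGRADING",
                 "SERUM_APPEARING", "INERT")

# Mean-one lognormal noise factors at a given percent CV.
lognormal_noise <- function(n, cv_percent) {
  if (cv_percent == 0) return(rep(1, n))
  cv <- cv_percent / 100
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sigma) - sigma^2 / 2)
}

# Smooth monotone drift over injection order 1..n spanning 1 +/- a.
drift_curve <- function(n, amplitude) {
  if (n == 1 || amplitude == 0) return(rep(1, n))
  u <- (seq_len(n) - 1) / (n - 1)
  1 - amplitude * cos(pi * u)
}

#' Simulate a serum-incubation exo-metabolome experiment
#'
#' Generates a peak-area matrix with the full experimental structure —
#' wild type, knockout and overexpression mutants, serum-only controls
#' at every time point, and pooled-QC injections with smooth
#' injection-order drift — together with the per-compound ground truth.
#'
#' Noiseless expectations per compound and well follow the kinetic
#' classes documented in [sim_config()]; observed intensities are the
#' expectation times the run's drift at that injection order times
#' independent mean-one lognormal noise at `noise_cv`. QC injections
#' measure the pooled mean expectation across all analytical wells.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with elements `matrix` (a [peak_matrix]) and `truth`
#'   (a tibble with one row per simulated feature: `feature_id`,
#'   `true_class`, `baseline`, `rate_wt`, `affected_gene`, `oe_factor`,
#'   `ko_factor`).
#' @examples
#' sim <- simulate_serum_experiment(sim_config(n_inert = 10, seed = 7))
#' sim$matrix
#' dplyr::count(sim$truth, true_class)
#' @export
simulate_serum_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  truth <- sim_compound_specs(config)
  n_feat <- nrow(truth)

  strains <- tibble::tibble(strain = "WT", genotype_class = "WT",
                            transporter_gene = "")
  for (i in seq_len(nrow(config$strains))) {
    g <- config$strains$gene[i]
    if (isTRUE(config$strains$has_ko[i])) {
      strains <- dplyr::add_row(strains, strain = paste0(g, "_KO"),
                                genotype_class = "KO", transporter_gene = g)
    }
    if (isTRUE(config$strains$has_oe[i])) {
      strains <- dplyr::add_row(strains, strain = paste0(g, "_OE"),
                                genotype_class = "OE", transporter_gene = g)
    }
  }
  strains <- dplyr::add_row(strains, strain = "SERUM",
                            genotype_class = "SERUM_CONTROL",
                            transporter_gene = "")

  wells <- tidyr::expand_grid(
    strains,
    time_min = config$time_points,
    replicate = seq_len(config$n_replicates)
  )
  wells$sample_id <- sprintf("%s_t%02d_r%d", wells$strain, wells$time_min,
                             wells$replicate)

  # noiseless expectation, features x analytical wells
  expect <- matrix(NA_real_, n_feat, nrow(wells))
  for (j in seq_len(nrow(wells))) {
    expect[, j] <- sim_expectation(truth, wells$strain[j],
                                   wells$genotype_class[j],
                                   wells$transporter_gene[j],
                                   wells$time_min[j], config)
  }

  # injection sequence: shuffled analytical wells with QCs interleaved
  ord_wells <- sample.int(nrow(wells))
  n_qc <- 2 + floor((nrow(wells) - 1) / config$qc_every)
  qc_expect <- rowMeans(expect)

  seq_kind <- character(0)  # "A" analytical (by shuffled index), "Q" qc
  seq_kind <- c(seq_kind, "Q")
  for (k in seq_along(ord_wells)) {
    seq_kind <- c(seq_kind, "A")
    if (k %% config$qc_every == 0 && k < length(ord_wells)) {
      seq_kind <- c(seq_kind, "Q")
    }
  }
  seq_kind <- c(seq_kind, "Q")
  n_inject <- length(seq_kind)
  drift <- drift_curve(n_inject, config$drift_amplitude)

  samples <- tibble::tibble(
    sample_id = character(n_inject), strain = character(n_inject),
    genotype_class = character(n_inject),
    transporter_gene = character(n_inject),
    time_min = rep(NA_real_, n_inject), replicate = integer(n_inject),
    injection_order = seq_len(n_inject)
  )
  intens <- matrix(NA_real_, n_feat, n_inject)
  a_seen <- 0L
  q_seen <- 0L
  for (o in seq_len(n_inject)) {
    if (seq_kind[o] == "Q") {
      q_seen <- q_seen + 1L
      samples$sample_id[o] <- sprintf("QC_%02d", q_seen)
      samples$strain[o] <- "QC_pool"
      samples$genotype_class[o] <- "QC"
      samples$transporter_gene[o] <- ""
      samples$replicate[o] <- q_seen
      mu <- qc_expect
    } else {
      a_seen <- a_seen + 1L
      w <- ord_wells[a_seen]
      samples$sample_id[o] <- wells$sample_id[w]
      samples$strain[o] <- wells$strain[w]
      samples$genotype_class[o] <- wells$genotype_class[w]
      samples$transporter_gene[o] <- wells$transporter_gene[w]
      samples$time_min[o] <- wells$time_min[w]
      samples$replicate[o] <- wells$replicate[w]
      mu <- expect[, w]
    }
    intens[, o] <- mu * drift[o] * lognormal_noise(n_feat, config$noise_cv)
  }

  intensities <- dplyr::bind_cols(
    tibble::tibble(feature_id = truth$feature_id),
    tibble::as_tibble(`colnames<-`(intens, samples$sample_id))
  )
  features <- tibble::tibble(
    feature_id = truth$feature_id,
    neutral_mass = round(stats::runif(n_feat, 70, 1000), 4),
    rt = round(stats::runif(n_feat, 0.5, 12), 3),
    polarity = "positive"
  )
  mat <- peak_matrix(intensities, samples, features, polarity = "positive")
  list(matrix = mat, truth = truth)
}

sim_compound_specs <- function(config) {
  counts <- c(IMPORTED = config$n_imported, EXPORTED = config$n_exported,
              SERUM_DEGRADING = config$n_serum_degrading,
              SERUM_APPEARING = config$n_serum_appearing,
              INERT = config$n_inert)
  cls <- rep(names(counts), counts)
  n <- length(cls)
  rate <- numeric(n)
  runif_range <- function(k, r) stats::runif(k, r[1], r[2])
  rate[cls == "IMPORTED"] <- runif_range(sum(cls == "IMPORTED"),
                                         config$import_rate_range)
  rate[cls == "EXPORTED"] <- runif_range(sum(cls == "EXPORTED"),
                                         config$export_rate_range)
  rate[cls %in% c("SERUM_DEGRADING", "SERUM_APPEARING")] <-
    runif_range(sum(cls %in% c("SERUM_DEGRADING", "SERUM_APPEARING")),
                config$serum_rate_range)
  genes <- config$strains$gene
  affected <- rep("", n)
  transported <- which(cls %in% c("IMPORTED", "EXPORTED"))
  if (length(genes) > 0 && length(transported) > 0) {
    affected[transported] <- rep_len(genes, length(transported))
  }
  tibble::tibble(
    feature_id = sprintf("F%04d", seq_len(n)),
    true_class = cls,
    baseline = 10^stats::runif(n, config$baseline_log10_range[1],
                               config$baseline_log10_range[2]),
    rate_wt = rate,
    affected_gene = affected,
    oe_factor = config$oe_factor,
    ko_factor = config$ko_factor
  )
}

# Noiseless expectation for all compounds in one well.
sim_expectation <- function(truth, strain, genotype_class, transporter_gene,
                            time_min, config) {
  mult <- rep(1, nrow(truth))
  cellular <- truth$true_class %in% c("IMPORTED", "EXPORTED")
  if (genotype_class == "SERUM_CONTROL") {
    mult[cellular] <- 0
  } else if (genotype_class == "OE") {
    hit <- cellular & truth$affected_gene == transporter_gene
    mult[hit] <- truth$oe_factor[hit]
  } else if (genotype_class == "KO") {
    hit <- cellular & truth$affected_gene == transporter_gene
    mult[hit] <- truth$ko_factor[hit]
  }
  r <- truth$rate_wt * mult
  out <- truth$baseline
  decay <- truth$true_class %in% c("IMPORTED", "SERUM_DEGRADING")
  grow <- truth$true_class %in% c("EXPORTED", "SERUM_APPEARING")
  out[decay] <- truth$baseline[decay] * exp(-r[decay] * time_min)
  if (config$export_kinetics == "linear") {
    out[grow] <- truth$baseline[grow] * (1 + r[grow] * time_min)
  } else {
    tau <- 15
    out[grow] <- truth$baseline[grow] *
      (1 + r[grow] * tau * (1 - exp(-time_min / tau)))
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
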