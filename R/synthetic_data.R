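#' Configuration for a simulated pulse-labeling experiment
#'
#' Bundles the experimental design of a medium-shift pulse-labeling
#' (dynamic SILAC) experiment: the post-shift growth rate, the sampling
#' schedule, the number of unlabeled t0 replicates, and the measurement
#' error model.
#'
#' @param n_proteins number of proteins to simulate.
#' @param mu_post specific growth rate after the shift (h^-1); must be > 0.
#' @param mu_pre specific growth rate before the shift (h^-1); kept for
#'   bookkeeping, the pre-shift culture is assumed at labeling steady state.
#' @param sampling_times minutes post-shift at which samples are taken;
#'   strictly increasing, all > 0. Default: every 15 min from 15 to 120,
#'   the fast-shift design.
#' @param n_t0_replicates number of unlabeled time-zero replicates (default 2).
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   intensity noise (default 0.2).
#' @param detection_limit relative-abundance floor; intensities below it are
#'   reported as missing (default 1e-5, a typical within-sample MS dynamic
#'   range floor).
#' @param seed integer random seed.
#'
#' @return An object of class `"sim_config"` (a named list).
#' @export
simulation_config <- function(n_proteins = 600,
                              mu_post = 0.433,
                              mu_pre = 0.24,
                              sampling_times = seq(15, 120, by = 15),
                              n_t0_replicates = 2,
                              noise_cv = 0.2,
                              detection_limit = 1e-5,
                              seed = 1L) {
  stopifnot(is.numeric(n_proteins), length(n_proteins) == 1L, n_proteins >= 1)
  if (!is.finite(mu_post) || mu_post <= 0)
    stop("mu_post must be a finite positive growth rate (h^-1)")
  if (!is.finite(mu_pre) || mu_pre < 0)
    stop("mu_pre must be finite and non-negative")
  if (length(sampling_times) < 1L || any(!is.finite(sampling_times)) ||
      any(sampling_times <= 0) || is.unsorted(sampling_times, strictly = TRUE))
    stop("sampling_times must be strictly increasing and > 0 (minutes)")
  if (!is.finite(noise_cv) || noise_cv < 0) stop("noise_cv must be >= 0")
  if (!is.finite(detection_limit) || detection_limit < 0)
    stop("detection_limit must be >= 0")
  structure(list(n_proteins = as.integer(n_proteins),
                 mu_post = mu_post, mu_pre = mu_pre,
                 sampling_times = as.numeric(sampling_times),
                 n_t0_replicates = as.integer(n_t0_replicates),
                 noise_cv = noise_cv,
                 detection_limit = detection_limit,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Ground-truth kinetic parameters for simulated proteins
#'
#' One row per protein: pre-shift steady per-cell abundance `a0`, post-shift
#' target abundance `a1` (so `a1/a0` is the expression fold change), active
#' degradation rate `k_deg` (h^-1; 0 means removal by dilution only), and
#' `stagnation_time` (minutes after the shift at which production stops;
#' `Inf` means production never stops).
#'
#' @param protein_id character vector of identifiers.
#' @param a0 pre-shift per-cell abundances (> 0, arbitrary units).
#' @param a1 post-shift target abundances (>= 0); default equal to `a0`.
#' @param k_deg active degradation rates (h^-1, >= 0); default 0.
#' @param stagnation_time minutes after which production stops; default `Inf`.
#'
#' @return A data.frame of class `"protein_truth"`.
#' @export
protein_truth <- function(protein_id, a0, a1 = a0, k_deg = 0,
                          stagnation_time = Inf) {
  n <- length(protein_id)
  if (n == 0L) stop("at least one protein is required")
  a0 <- rep_len(a0, n); a1 <- rep_len(a1, n)
  k_deg <- rep_len(k_deg, n)
  stagnation_time <- rep_len(stagnation_time, n)
  if (any(!is.finite(a0)) || any(a0 <= 0)) stop("a0 must be finite and > 0")
  if (any(!is.finite(a1)) || any(a1 < 0)) stop("a1 must be finite and >= 0")
  if (any(!is.finite(k_deg)) || any(k_deg < 0)) stop("k_deg must be >= 0")
  if (any(is.na(stagnation_time)) || any(stagnation_time < 0))
    stop("stagnation_time must be >= 0 (Inf allowed)")
  structure(data.frame(protein_id = as.character(protein_id),
                       a0 = a0, a1 = a1, k_deg = k_deg,
                       stagnation_time = stagnation_time,
                       stringsAsFactors = FALSE),
            class = c("protein_truth", "data.frame"))
}

#' Dilution-only ground truth with a realistic abundance spread
#'
#' Convenience constructor for a cohort of proteins whose per-cell abundance
#' is unchanged by the shift (`a1 = a0`) and which are removed from the
#' proteome only by dilution through growth (`k_deg = 0`). Abundances are
#' drawn log-normally (sdlog 1) to emulate the spread of a bacterial
#' proteome.
#'
#' @param n number of proteins.
#' @param seed random seed for the abundance draw.
#' @return A `protein_truth` data.frame.
#' @export
dilution_only_truths <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  a0 <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  protein_truth(sprintf("P%04d", seq_len(n)), a0 = a0)
}

# mean-one multiplicative log-normal noise with coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sigma^2 / 2, sd = sigma))
}

# Noise-free per-cell light and heavy abundances at time t (minutes) for one
# protein. Light: pre-existing pool decaying by dilution + degradation.
# Heavy: first-order relaxation toward the post-shift target a1, production
# switched off at stagnation_time.
kinetic_abundances <- function(t_min, mu, truth) {
  k <- (mu + truth$k_deg) / 60           # per minute
  light <- truth$a0 * exp(-k * t_min)
  s <- truth$stagnation_time
  if (t_min <= s) {
    heavy <- truth$a1 * (1 - exp(-k * t_min))
  } else {
    at_s <- truth$a1 * (1 - exp(-k * s))
    heavy <- at_s * exp(-k * (t_min - s))
  }
  c(light = light, heavy = heavy)
}

#' Simulate a pulse-labeling quantification table
#'
#' Generates per-protein light and heavy intensities and heavy/light ratios
#' at each post-shift sampling time, plus unlabeled t0 replicates, from known
#' kinetic ground truth. Pre-existing (light) protein decays with rate
#' `mu + k_deg`; newly made (heavy) protein relaxes toward the post-shift
#' target `a1` with the same rate constant, until production stagnates.
#' Within each sample, abundances are expressed relative to the summed
#' light+heavy signal over all proteins (relative iBAQ), so the reported
#' intensities track proteome fractions; for a cohort dominated by
#' growth-diluting proteins this total tracks cell mass. Multiplicative
#' log-normal noise is then applied per intensity, ratios are recomputed from
#' the noisy intensities, and values below the detection limit are reported
#' missing.
#'
#' @param config a [simulation_config()].
#' @param truths a [protein_truth()] data.frame (non-empty).
#'
#' @return A data.frame with columns `protein_id`, `sample`, `time_min`,
#'   `intensity_L`, `intensity_H`, `ratio_HL`. t0 replicates have
#'   `time_min = 0` and missing heavy intensity and ratio.
#' @export
#' @examples
#' cfg <- simulation_config(n_proteins = 5, noise_cv = 0, seed = 7)
#' tr  <- dilution_only_truths(5, seed = 7)
#' head(simulate_labeling_experiment(cfg, tr))
simulate_labeling_experiment <- function(config, truths) {
  if (!inherits(config, "sim_config")) stop("config must be a simulation_config()")
  if (NROW(truths) == 0L) stop("truths must be non-empty")
  if (NROW(truths) != config$n_proteins)
    stop("truths must have one row per protein (n_proteins = ",
         config$n_proteins, ")")

  set.seed(config$seed)
  times <- config$sampling_times
  n <- nrow(truths)

  samples <- c(sprintf("t0_r%d", seq_len(config$n_t0_replicates)),
               sprintf("t%03d", as.integer(times)))
  sample_time <- c(rep(0, config$n_t0_replicates), times)

  rows <- vector("list", length(samples))
  for (j in seq_along(samples)) {
    tmin <- sample_time[j]
    ab <- vapply(seq_len(n), function(i)
      kinetic_abundances(tmin, config$mu_post, truths[i, ]),
      numeric(2))
    light <- ab["light", ]
    heavy <- if (tmin == 0) rep(0, n) else ab["heavy", ]
    total <- sum(light) + sum(heavy)
    rel_l <- light / total
    rel_h <- heavy / total
    # conservation before noise: sum(rel_l) + sum(rel_h) == 1
    obs_l <- rel_l * lognormal_noise(n, config$noise_cv)
    obs_h <- rel_h * lognormal_noise(n, config$noise_cv)
    obs_l[obs_l < config$detection_limit] <- NA_real_
    obs_h[obs_h < config$detection_limit | rel_h == 0] <-
      if (config$detection_limit > 0) NA_real_ else 0
    if (tmin == 0) obs_h <- rep(NA_real_, n)
    ratio <- ifelse(is.na(obs_h) | is.na(obs_l) | obs_l == 0,
                    NA_real_, obs_h / obs_l)
    rows[[j]] <- data.frame(protein_id = truths$protein_id,
                            sample = samples[j],
                            time_min = tmin,
                            intensity_L = obs_l,
                            intensity_H = obs_h,
                            ratio_HL = ratio,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a labeling table with MaxQuant-flavored column names
#'
#' Pivots the long quantification table into one row per protein with
#' `iBAQ L <sample>`, `iBAQ H <sample>` and `Ratio H/L <sample>` columns, the
#' column layout of a MaxQuant proteinGroups table.
#'
#' @param table output of [simulate_labeling_experiment()].
#' @param path optional file path; when given the table is written as TSV.
#' @return The wide data.frame (invisibly when `path` is given).
#' @export
export_maxquant_layout <- function(table, path = NULL) {
  samples <- unique(table$sample)
  ids <- unique(table$protein_id)
  wide <- data.frame(`Protein IDs` = ids, check.names = FALSE,
                     stringsAsFactors = FALSE)
  for (s in samples) {
    sub <- table[table$sample == s, ]
    idx <- match(ids, sub$protein_id)
    wide[[paste("iBAQ L", s)]] <- sub$intensity_L[idx]
    wide[[paste("iBAQ H", s)]] <- sub$intensity_H[idx]
    wide[[paste("Ratio H/L", s)]] <- sub$ratio_HL[idx]
  }
  if (!is.null(path)) {
    utils::write.table(wide, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(wide))
  }
  wide
}

#' Growth-curve simulation parameters
#'
#' @param lag_minutes length of the lag phase (minutes).
#' @param mu specific growth rate (h^-1) during the exponential phase.
#' @param od_start OD600 at inoculation (> 0).
#' @param od_plateau OD600 plateau (> od_start).
#' @param sample_interval_minutes sampling interval (default 30 min).
#' @param noise_cv multiplicative noise CV on OD readings.
#' @param total_minutes optional run length; default runs two intervals past
#'   the time the plateau is reached.
#' @return A list of class `"growth_sim_spec"`.
#' @export
growth_sim_spec <- function(lag_minutes = 0, mu = 0.6, od_start = 0.05,
                            od_plateau = 1.0, sample_interval_minutes = 30,
                            noise_cv = 0, total_minutes = NULL) {
  if (!is.finite(od_start) || !is.finite(od_plateau) ||
      od_start <= 0 || od_plateau <= od_start)
    stop("need od_plateau > od_start > 0")
  if (!is.finite(mu) || mu < 0) stop("mu must be >= 0")
  if (lag_minutes < 0) stop("lag_minutes must be >= 0")
  structure(list(lag_minutes = lag_minutes, mu = mu, od_start = od_start,
                 od_plateau = od_plateau,
                 sample_interval_minutes = sample_interval_minutes,
                 noise_cv = noise_cv, total_minutes = total_minutes),
            class = "growth_sim_spec")
}

#' Simulate an OD600 growth curve
#'
#' Flat lag at `od_start`, exponential growth at rate `mu`, hard plateau at
#' `od_plateau`, sampled every `sample_interval_minutes`, with optional
#' multiplicative log-normal reading noise.
#'
#' @param spec a [growth_sim_spec()].
#' @param seed random seed (only used when `noise_cv > 0`).
#' @return A data.frame with columns `time_min`, `od600`.
#' @export
simulate_growth_curve <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "growth_sim_spec"))
  t_plateau <- if (spec$mu > 0)
    spec$lag_minutes + 60 * log(spec$od_plateau / spec$od_start) / spec$mu
  else Inf
  total <- spec$total_minutes
  if (is.null(total)) {
    total <- if (is.finite(t_plateau))
      t_plateau + 2 * spec$sample_interval_minutes
    else 10 * spec$sample_interval_minutes
  }
  t <- seq(0, total, by = spec$sample_interval_minutes)
  od <- ifelse(t <= spec$lag_minutes, spec$od_start,
               spec$od_start * exp(spec$mu * (t - spec$lag_minutes) / 60))
  od <- pmin(od, spec$od_plateau)
  if (spec$noise_cv > 0) {
    set.seed(seed)
    od <- od * lognormal_noise(length(od), spec$noise_cv)
  }
  data.frame(time_min = t, od600 = od)
}

#' NMR peak-table simulation parameters
#'
#' True total-normalized peak intensities per condition for lactate, acetate,
#' ornithine, and the remaining ("other") peaks; per-replicate OD600 at
#' harvest; replicate count and noise level.
#'
#' @param conditions character vector of condition labels.
#' @param lactate,acetate,ornithine,other true total-normalized intensities
#'   per condition (recycled); each sample's four values must sum to 1.
#' @param od600 OD600 at harvest per condition (recycled).
#' @param n_replicates replicates per condition.
#' @param noise_cv multiplicative noise CV.
#' @param seed random seed.
#' @return A list of class `"nmr_sim_spec"`.
#' @export
nmr_sim_spec <- function(conditions, lactate, acetate, ornithine = 0,
                         other = NULL, od600 = 0.5, n_replicates = 3,
                         noise_cv = 0, seed = 1L) {
  k <- length(conditions)
  lactate <- rep_len(lactate, k); acetate <- rep_len(acetate, k)
  ornithine <- rep_len(ornithine, k); od600 <- rep_len(od600, k)
  if (is.null(other)) other <- 1 - lactate - acetate - ornithine
  other <- rep_len(other, k)
  ints <- cbind(lactate, acetate, ornithine, other)
  if (any(ints < -1e-12)) stop("intensities must be >= 0")
  if (any(abs(rowSums(ints) - 1) > 1e-9))
    stop("per-condition intensities must sum to 1")
  structure(list(conditions = as.character(conditions), lactate = lactate,
                 acetate = acetate, ornithine = ornithine, other = other,
                 od600 = od600, n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "nmr_sim_spec")
}

#' Simulate relative NMR peak-intensity tables
#'
#' One row per replicate with total-normalized peak intensities (which sum to
#' 1 before noise), plus the harvest OD600.
#'
#' @param spec an [nmr_sim_spec()].
#' @return A data.frame with columns `condition`, `replicate`, `lactate`,
#'   `acetate`, `ornithine`, `other`, `od600`.
#' @export
simulate_nmr_tables <- function(spec) {
  stopifnot(inherits(spec, "nmr_sim_spec"))
  set.seed(spec$seed)
  rows <- list()
  for (i in seq_along(spec$conditions)) {
    for (r in seq_len(spec$n_replicates)) {
      true <- c(lactate = spec$lactate[i], acetate = spec$acetate[i],
                ornithine = spec$ornithine[i], other = spec$other[i])
      obs <- true * lognormal_noise(4, spec$noise_cv)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = spec$conditions[i], replicate = r,
        lactate = obs[["lactate"]], acetate = obs[["acetate"]],
        ornithine = obs[["ornithine"]], other = obs[["other"]],
        od600 = spec$od600[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
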