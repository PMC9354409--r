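# Synthetic compound tables and sensor matrices with known ground truth.
#
# Peak areas are log-normal (the standard model for chromatographic peak
# intensities); strain-unique compounds are planted by group-specific
# presence masks rather than by thresholding noise, so the ground truth is
# unambiguous. One integer seed drives a single pseudo-random stream.

#' Default PEN3-like group mean responses for the simulator
#'
#' Three groups (blank medium plus two fermenting strains) by ten sensors.
#' The pattern emulates what fermentation headspace typically does to a
#' metal-oxide array: strong responses on the sulfide (W1W), methyl (W1S),
#' alcohol/aldehyde (W2S), aromatic/organosulfur (W2W), and nitrogen-oxide
#' (W5S) channels; near-baseline elsewhere. The strain W1W means are set to
#' 5.15 and 4.27 times the blank mean, the magnitude of increase reported
#' for sulfides after fermentation.
#'
#' @return A 3 x 10 numeric matrix with group rownames and sensor colnames.
#' @export
default_sensor_means <- function() {
  sensors <- names(pen3_sensors)
  m <- rbind(
    blank  = c(0.70, 1.40, 0.70, 1.10, 0.80, 3.20, 2.00, 3.80, 1.90, 1.10),
    wild   = c(0.60, 6.50, 0.60, 1.30, 0.80, 9.50, 10.30, 9.00, 5.50, 1.40),
    mutant = c(0.65, 8.00, 0.62, 1.40, 0.85, 11.00, 8.54, 11.50, 6.50, 1.50)
  )
  colnames(m) <- sensors
  m
}

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a two-strain fermentation volatile profile of realistic
#' size: ~30 compounds dominated by esters, two strain-unique compounds per
#' group, log-normal peak areas, and detection thresholds spanning 0.1 to
#' ~300 ug/L on a log-uniform scale with a fraction missing (no literature
#' value) and a fraction known only as an interval. Planted unique compounds
#' receive boosted abundance and a guaranteed low point threshold so that,
#' by construction, they are key odor compounds of their group.
#'
#' @param seed Integer seed; the only source of randomness.
#' @param groups Group labels for the compound table.
#' @param n_compounds Total number of compounds.
#' @param n_unique_per_group Compounds detected in only one group, per group.
#' @param class_mix Named proportions over [chem_classes]; must sum to 1.
#' @param area_meanlog,area_sdlog Log-normal parameters of per-compound base
#'   peak areas.
#' @param noise_sd Log-scale SD of per-group multiplicative noise around the
#'   base area (0 = groups identical up to the presence mask).
#' @param threshold_log10_range Range of log10 thresholds (ug/L).
#' @param threshold_missing_frac Fraction of compounds with no threshold.
#' @param threshold_interval_frac Fraction of known thresholds reported as
#'   intervals (+/- 50% around the drawn value).
#' @param unique_boost Multiplier on the base area of planted unique
#'   compounds.
#' @param unique_threshold Point threshold (ug/L) assigned to planted unique
#'   compounds.
#' @param sensor_means Group x sensor mean-response matrix.
#' @param replicates E-nose replicates per group.
#' @param sensor_noise_sd Additive Gaussian noise SD on sensor responses.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       groups = c("wild", "mutant"),
                       n_compounds = 30L,
                       n_unique_per_group = 2L,
                       class_mix = c(
                         ester = 0.7, alcohol = 0.15,
                         aldehyde = 0.1, other = 0.05
                       ),
                       area_meanlog = log(1e6),
                       area_sdlog = 1,
                       noise_sd = 0.25,
                       threshold_log10_range = c(-1, 2.5),
                       threshold_missing_frac = 0.2,
                       threshold_interval_frac = 0.15,
                       unique_boost = 20,
                       unique_threshold = 0.5,
                       sensor_means = default_sensor_means(),
                       replicates = 6L,
                       sensor_noise_sd = 0.15) {
  cfg <- list(
    seed = as.integer(seed), groups = groups,
    n_compounds = as.integer(n_compounds),
    n_unique_per_group = as.integer(n_unique_per_group),
    class_mix = class_mix,
    area_meanlog = area_meanlog, area_sdlog = area_sdlog,
    noise_sd = noise_sd,
    threshold_log10_range = threshold_log10_range,
    threshold_missing_frac = threshold_missing_frac,
    threshold_interval_frac = threshold_interval_frac,
    unique_boost = unique_boost, unique_threshold = unique_threshold,
    sensor_means = sensor_means,
    replicates = as.integer(replicates),
    sensor_noise_sd = sensor_noise_sd
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$groups) < 1L || anyDuplicated(cfg$groups)) {
    abort("`groups` must be non-empty and unique.")
  }
  if (!setequal(names(cfg$class_mix), chem_classes) ||
    abs(sum(cfg$class_mix) - 1) > 1e-8 || any(cfg$class_mix < 0)) {
    abort("`class_mix` must be non-negative proportions over the chem classes summing to 1.")
  }
  if (cfg$n_unique_per_group * length(cfg$groups) > cfg$n_compounds) {
    abort("Infeasible: n_unique_per_group x groups exceeds n_compounds.")
  }
  if (cfg$area_sdlog < 0 || cfg$noise_sd < 0 || cfg$sensor_noise_sd < 0) {
    abort("Spread parameters must be >= 0.")
  }
  if (cfg$unique_boost <= 0 || cfg$unique_threshold <= 0) {
    abort("Unique-compound parameters must be positive.")
  }
  if (diff(cfg$threshold_log10_range) < 0) {
    abort("`threshold_log10_range` must be increasing.")
  }
  if (cfg$threshold_missing_frac < 0 || cfg$threshold_missing_frac > 1 ||
    cfg$threshold_interval_frac < 0 || cfg$threshold_interval_frac > 1) {
    abort("Threshold fractions must be in [0, 1].")
  }
  if (cfg$replicates < 1L) abort("`replicates` must be >= 1.")
  if (is.null(rownames(cfg$sensor_means)) ||
    is.null(colnames(cfg$sensor_means))) {
    abort("`sensor_means` needs group rownames and sensor colnames.")
  }
  invisible(cfg)
}

#' Simulate a compound table with planted ground truth
#'
#' Draws per-compound base areas once, applies per-group multiplicative
#' log-normal noise, masks planted unique compounds out of all other groups,
#' and assigns detection thresholds. The returned ground truth is computed
#' directly from the noiseless base configuration (plain arithmetic on the
#' generating parameters, independent of the scoring pipeline): the key set
#' of each group is every compound whose odor activity at the lower threshold
#' bound, rescaled to the group's maximum contributor, exceeds 1.
#'
#' @param config A [sim_config()].
#' @return A list with `peaks` (area-mode `peak_tbl`), `thresholds`
#'   (`threshold_db`), `truth` (list: per-group `key` sets, `unique`
#'   plantings, `reference` compounds), and `config`.
#' @export
simulate_peak_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    n <- cfg$n_compounds
    g <- cfg$groups
    ids <- sprintf("compound_%02d", seq_len(n))

    # class assignment: largest-remainder apportionment of the mix
    counts <- floor(cfg$class_mix * n)
    rem <- cfg$class_mix * n - counts
    short <- n - sum(counts)
    if (short > 0) {
      bump <- order(rem, decreasing = TRUE)[seq_len(short)]
      counts[bump] <- counts[bump] + 1
    }
    classes <- sample(rep(names(counts), counts))

    # planted unique compounds: first n_unique * n_groups ids, blockwise.
    # They are always esters, the class strain-unique aroma markers belong
    # to in fermentation volatiles, and one every scoring run keeps.
    n_u <- cfg$n_unique_per_group
    unique_of <- split(
      ids[seq_len(n_u * length(g))],
      rep(g, each = n_u)
    )[g]
    if (n_u == 0L) unique_of <- setNames(rep(list(character()), length(g)), g)
    classes[seq_len(n_u * length(g))] <- "ester"

    base <- rlnorm(n, cfg$area_meanlog, cfg$area_sdlog)
    planted <- unlist(unique_of, use.names = FALSE)
    base[ids %in% planted] <- base[ids %in% planted] * cfg$unique_boost

    # thresholds: log-uniform, some missing, some intervals; planted unique
    # compounds always get a low point threshold
    t_mid <- 10^runif(n, cfg$threshold_log10_range[1], cfg$threshold_log10_range[2])
    missing <- runif(n) < cfg$threshold_missing_frac
    interval <- !missing & runif(n) < cfg$threshold_interval_frac
    is_planted <- ids %in% planted
    missing[is_planted] <- FALSE
    interval[is_planted] <- FALSE
    t_mid[is_planted] <- cfg$unique_threshold

    entries <- tibble(
      compound = ids[!missing],
      kind = ifelse(interval[!missing], "interval", "point"),
      low = ifelse(interval[!missing], t_mid[!missing] / 1.5, t_mid[!missing]),
      high = ifelse(interval[!missing], t_mid[!missing] * 1.5, t_mid[!missing]),
      unit = "ug/L",
      source = "simulated"
    )
    db <- threshold_db(entries)

    # per-group areas: base * lognormal noise, masked for unique compounds
    values <- lapply(g, function(grp) {
      v <- base * exp(rnorm(n, 0, cfg$noise_sd))
      masked <- is_planted & !(ids %in% unique_of[[grp]])
      v[masked] <- NA_real_
      v
    })
    names(values) <- g

    peaks <- peak_table(
      dplyr::bind_cols(
        tibble(
          compound = ids, formula = NA_character_,
          class = classes, odor = NA_character_
        ),
        as_tibble(values)
      ),
      mode = "area"
    )

    # ground truth from the noiseless configuration, by direct arithmetic
    truth_key <- list()
    truth_ref <- character()
    for (grp in g) {
      present <- !(is_planted & !(ids %in% unique_of[[grp]]))
      conc <- base
      conc[!present] <- NA_real_
      rel <- 100 * conc / sum(conc, na.rm = TRUE)
      t_low <- ifelse(missing, NA_real_,
        ifelse(interval, t_mid / 1.5, t_mid)
      )
      ct <- rel / t_low
      point_ok <- present & !missing & !interval
      ref_i <- which(point_ok)[which.max(ct[point_ok])]
      oav <- 100 * ct / ct[ref_i]
      truth_key[[grp]] <- ids[which(present & !is.na(oav) & oav > 1)]
      truth_ref[[grp]] <- ids[ref_i]
    }

    list(
      peaks = peaks,
      thresholds = db,
      truth = list(key = truth_key, unique = unique_of, reference = truth_ref),
      config = cfg
    )
  })
}

#' Simulate an e-nose response matrix
#'
#' Each replicate row is its group's mean response plus i.i.d. Gaussian
#' sensor noise (truncated at zero, since metal-oxide responses are
#' non-negative ratios).
#'
#' @param config A [sim_config()]; uses `sensor_means`, `replicates`, and
#'   `sensor_noise_sd`.
#' @return A list with `sensors` (tibble: `group` + sensor columns) and
#'   `truth` (the mean matrix).
#' @export
simulate_sensor_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    mm <- cfg$sensor_means
    rows <- lapply(rownames(mm), function(grp) {
      noise <- matrix(
        rnorm(cfg$replicates * ncol(mm), 0, cfg$sensor_noise_sd),
        nrow = cfg$replicates
      )
      resp <- pmax(sweep(noise, 2, mm[grp, ], "+"), 0)
      dplyr::bind_cols(
        tibble(group = grp),
        as_tibble(`colnames<-`(resp, colnames(mm)))
      )
    })
    sensors <- dplyr::bind_rows(rows)
    list(sensors = check_sensor_tbl(sensors), truth = mm)
  })
}
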