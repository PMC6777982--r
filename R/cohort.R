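#' Configuration for a synthetic stroke/control cohort
#'
#' Collects every tunable of the synthetic-cohort generator with defaults
#' matching the clinical acquisition the package emulates: 14 stroke and 12
#' control subjects, 40 homotopic pairs (80 regions), 8-minute resting-state
#' runs of 240 volumes at TR = 2 s band-limited to 0.009--0.08 Hz. The
#' planted lag field is
#' \deqn{\tau^*(p) = \mathrm{base\_lag} \cdot e^{-d_p/\lambda} + \mathrm{baseline},}
#' where \eqn{d_p} is the Euclidean distance (mm) from the lesion centroid to
#' the ipsilesional region of pair \eqn{p}; controls receive the baseline
#' only. Connectome edges appear with probability \eqn{e^{-d/\eta}} and carry
#' Poisson streamline-count-like weights decaying with distance.
#'
#' @param n_stroke,n_control group sizes.
#' @param n_pairs homotopic pairs per hemisphere.
#' @param tr repetition time in seconds.
#' @param n_timepoints volumes per run.
#' @param band passband in Hz for the band-limited signal model.
#' @param baseline_lag baseline homotopic lag in seconds (both groups).
#' @param stroke_base_lag amplitude (s) of the lesion-distance lag field.
#' @param lesion_decay_mm spatial decay \eqn{\lambda} of the lag field (mm).
#' @param noise_sd standard deviation of independent band-limited noise
#'   added to each hemisphere's signal (signals have unit sd).
#' @param lesion_radius_mm median radius of the spherical lesion; per-subject
#'   radii are log-normal around it (see `lesion_radius_sdlog`), emulating
#'   the wide spread of clinical lesion volumes. Lesion size is the single
#'   latent dimension coupling functional slowing (the lag field decays with
#'   distance to the lesion *surface*) and structural damage (edges within
#'   the sphere are removed).
#' @param lesion_radius_sdlog log-sd of the per-subject lesion radius.
#' @param edge_decay_mm connectome edge-probability distance decay (mm).
#' @param weight_scale,weight_decay_mm streamline-count weight model:
#'   mean weight `weight_scale * exp(-d / weight_decay_mm)`.
#' @param prob_right_lesion probability a stroke lesion sits in the right
#'   hemisphere.
#' @param seed master integer seed; fixes the whole cohort.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_stroke = 14L, n_control = 12L, n_pairs = 40L,
                          tr = 2, n_timepoints = 240L,
                          band = c(0.009, 0.08),
                          baseline_lag = 0.25, stroke_base_lag = 2.4,
                          lesion_decay_mm = 60, noise_sd = 0.1,
                          lesion_radius_mm = 18, lesion_radius_sdlog = 0.4,
                          edge_decay_mm = 130, weight_scale = 100,
                          weight_decay_mm = 60,
                          prob_right_lesion = 2 / 3,
                          seed = 1L) {
  cfg <- list(
    n_stroke = as.integer(n_stroke), n_control = as.integer(n_control),
    n_pairs = as.integer(n_pairs), tr = tr,
    n_timepoints = as.integer(n_timepoints), band = band,
    baseline_lag = baseline_lag, stroke_base_lag = stroke_base_lag,
    lesion_decay_mm = lesion_decay_mm, noise_sd = noise_sd,
    lesion_radius_mm = lesion_radius_mm,
    lesion_radius_sdlog = lesion_radius_sdlog,
    edge_decay_mm = edge_decay_mm,
    weight_scale = weight_scale, weight_decay_mm = weight_decay_mm,
    prob_right_lesion = prob_right_lesion, seed = as.integer(seed)
  )
  with(cfg, {
    if (n_stroke < 1 || n_control < 0 || n_pairs < 2) {
      stop_invalid("cohort counts must be positive (n_pairs >= 2)")
    }
    if (tr <= 0 || n_timepoints < 8) {
      stop_invalid("need tr > 0 and n_timepoints >= 8")
    }
    if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1]) {
      stop_invalid("`band` must be increasing positive frequencies (Hz)")
    }
    if (band[2] > 1 / (2 * tr)) {
      stop_invalid("passband exceeds the Nyquist frequency 1/(2*tr)")
    }
    if (noise_sd < 0 || baseline_lag < 0 || stroke_base_lag < 0 ||
        lesion_decay_mm <= 0 || lesion_radius_mm <= 0) {
      stop_invalid("lag-field and lesion parameters must be non-negative")
    }
  })
  structure(cfg, class = "cohort_config")
}

#' Band-limited Gaussian process
#'
#' White Gaussian noise filtered in the frequency domain to the passband,
#' then standardized (mean 0, population sd 1). This is the elementary
#' signal of the synthetic BOLD model.
#'
#' @param n number of samples.
#' @param tr sampling interval in seconds.
#' @param band passband in Hz.
#' @return numeric vector of length `n`.
#' @export
band_limited_series <- function(n, tr, band = c(0.009, 0.08)) {
  if (n < 8) stop_invalid("need at least 8 samples")
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * tr)     # folded (two-sided) frequency in Hz
  keep <- f >= band[1] & f <= band[2]
  if (!any(keep)) stop_invalid("passband contains no Fourier bin at this n, tr")
  spec <- fft(rnorm(n))
  spec[!keep] <- 0
  x <- Re(fft(spec, inverse = TRUE)) / n
  standardize(x)
}

#' Delay a series by an arbitrary (fractional) number of seconds
#'
#' Applies the delay as a phase rotation in the frequency domain, so
#' non-integer-sample delays are exact for band-limited signals. The shift
#' is circular; the generator's signals are finite Fourier series, for which
#' the circular shift is the exact shift.
#'
#' @param x numeric vector.
#' @param tr sampling interval in seconds.
#' @param tau_s delay in seconds (positive delays the series).
#' @return the delayed series, same length as `x`.
#' @export
delay_series <- function(x, tr, tau_s) {
  n <- length(x)
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) / (n * tr)  # signed frequency in Hz
  Re(fft(fft(x) * exp(-2i * pi * f * tau_s), inverse = TRUE)) / n
}

#' Generate BOLD matrices with planted homotopic lags
#'
#' For every subject and homotopic pair, a shared band-limited process is
#' assigned to the right-hemisphere region; the left-hemisphere region
#' receives the same process delayed by the planted lag \eqn{\tau^*} plus
#' independent band-limited noise (so a positive estimated lag means the
#' right hemisphere leads). Stroke subjects get a spherical lesion of
#' log-normally varying radius around a centroid drawn near a
#' subcortical/sensorimotor region, and their \eqn{\tau^*} decays with the
#' distance from the ipsilesional region to the lesion surface; controls
#' receive the baseline lag everywhere.
#'
#' @param regions a region table from [gen_parcellation()].
#' @param config a [cohort_config()].
#' @return list with one element per subject: `record` (one-row
#'   `data.frame`), `bold` (regions x timepoints matrix, rows ordered and
#'   named by `region_id`), and `planted` (`pair_id`, `planted_lag_s`).
#' @export
gen_bold_cohort <- function(regions, config = cohort_config()) {
  check_regions(regions)
  cfg <- config
  n_pairs <- max(regions$pair_id)
  coords <- region_coords(regions)
  max_tau <- cfg$stroke_base_lag + cfg$baseline_lag
  if (cfg$n_timepoints < 4 * ceiling(max_tau / cfg$tr)) {
    stop_invalid("n_timepoints too short for the largest planted lag")
  }

  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))

  n_total <- cfg$n_stroke + cfg$n_control
  groups <- rep(c("stroke", "control"), c(cfg$n_stroke, cfg$n_control))
  set.seed(derive_seed(cfg$seed, 2L))
  female_stroke <- sample.int(cfg$n_stroke, 1L)

  lapply(seq_len(n_total), function(i) {
    set.seed(derive_seed(cfg$seed, 100L + i))
    group <- groups[i]
    id <- sprintf("sub%02d", i)

    if (group == "stroke") {
      side <- if (runif(1) < cfg$prob_right_lesion) "right" else "left"
      radius <- min(max(cfg$lesion_radius_mm *
                          exp(rnorm(1, 0, cfg$lesion_radius_sdlog)), 6), 40)
      ipsi <- regions[regions$hemisphere == side, ]
      seed_pool <- ipsi[ipsi$subnetwork %in% c("subcortical", "sensorimotor"), ]
      if (nrow(seed_pool) == 0L) seed_pool <- ipsi
      seed_region <- seed_pool[sample.int(nrow(seed_pool), 1L), ]
      centroid <- as.numeric(seed_region[c("x", "y", "z")]) + rnorm(3, 0, 3)
      lesion_regions <- ipsi$region_id[
        sqrt(colSums((t(region_coords(ipsi)) - centroid)^2)) <= radius
      ]
      ipsi_of_pair <- regions[regions$hemisphere == side, ]
      ipsi_of_pair <- ipsi_of_pair[order(ipsi_of_pair$pair_id), ]
      d_pair <- sqrt(colSums((t(region_coords(ipsi_of_pair)) - centroid)^2))
      # lag decays with distance to the lesion surface, so larger lesions
      # slow more of the hemisphere as well as removing more edges
      tau <- cfg$stroke_base_lag *
        exp(-pmax(d_pair - radius, 0) / cfg$lesion_decay_mm) +
        cfg$baseline_lag
      age <- round(rnorm(1, 54, 8))
      gender <- if (i == female_stroke) "F" else "M"
      onset <- round(min(max(exp(rnorm(1, log(3), 0.8)), 0.5), 12), 1)
      arat <- as.integer(min(max(round(28 - 15 * mean(tau) + rnorm(1, 0, 3)), 0), 57))
    } else {
      side <- NA_character_
      radius <- NA_real_
      centroid <- c(NA_real_, NA_real_, NA_real_)
      lesion_regions <- integer(0)
      tau <- rep(cfg$baseline_lag, n_pairs)
      age <- round(rnorm(1, 58, 3))
      gender <- if ((i - cfg$n_stroke) %% 2 == 0) "F" else "M"
      onset <- NA_real_
      arat <- NA_integer_
    }

    bold <- matrix(NA_real_, nrow = nrow(regions), ncol = cfg$n_timepoints,
                   dimnames = list(regions$region_id, NULL))
    for (p in seq_len(n_pairs)) {
      z <- band_limited_series(cfg$n_timepoints, cfg$tr, cfg$band)
      right <- z
      left <- delay_series(z, cfg$tr, tau[p])
      if (cfg$noise_sd > 0) {
        right <- right + cfg$noise_sd * band_limited_series(cfg$n_timepoints, cfg$tr, cfg$band)
        left <- left + cfg$noise_sd * band_limited_series(cfg$n_timepoints, cfg$tr, cfg$band)
      }
      rid <- regions$region_id[regions$pair_id == p & regions$hemisphere == "right"]
      lid <- regions$region_id[regions$pair_id == p & regions$hemisphere == "left"]
      bold[as.character(rid), ] <- right
      bold[as.character(lid), ] <- left
    }

    record <- data.frame(
      subject_id = id, group = group, age_years = age, gender = gender,
      arat = arat, onset_years = onset, lesion_side = side,
      lesion_centroid = if (group == "stroke")
        paste(sprintf("%.3f", centroid), collapse = ",") else "",
      lesion_regions = paste(lesion_regions, collapse = ";"),
      lesion_radius_mm = radius,
      mean_planted_lag_s = mean(tau),
      stringsAsFactors = FALSE
    )
    list(record = record,
         bold = bold,
         planted = data.frame(pair_id = seq_len(n_pairs), planted_lag_s = tau))
  })
}

#' Generate a spatially embedded synthetic connectome
#'
#' Edges between regions appear with probability `exp(-d / edge_decay_mm)`
#' and carry integer weights `1 + Poisson(weight_scale * exp(-d /
#' weight_decay_mm))`, emulating the distance dependence of streamline
#' counts. The result is symmetric, hollow and non-negative; if the sampled
#' graph is disconnected, the closest node pairs across components are
#' bridged with unit-weight edges so the full-density graph is connected.
#'
#' @param regions region table supplying node coordinates.
#' @param config a [cohort_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return a [connectome()] object.
#' @export
gen_connectome <- function(regions, config = cohort_config(),
                           seed = config$seed) {
  check_regions(regions)
  coords <- region_coords(regions)
  n <- nrow(coords)
  d <- euclidean_matrix(coords)

  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(derive_seed(seed, 3L))

  w <- matrix(0, n, n)
  ut <- upper.tri(d)
  p_edge <- exp(-d[ut] / config$edge_decay_mm)
  present <- runif(length(p_edge)) < p_edge
  lambda <- config$weight_scale * exp(-d[ut] / config$weight_decay_mm)
  weights <- (1 + rpois(length(lambda), lambda)) * present
  w[ut] <- weights
  w <- w + t(w)

  # Bridge components so the full-density graph is connected.
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  comp <- igraph::components(g)
  while (comp$no > 1L) {
    main <- which(comp$membership == which.max(comp$csize))
    rest <- which(comp$membership != which.max(comp$csize))
    dd <- d[rest, main, drop = FALSE]
    k <- arrayInd(which.min(dd), dim(dd))
    i <- rest[k[1]]; j <- main[k[2]]
    w[i, j] <- w[j, i] <- 1
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    comp <- igraph::components(g)
  }
  connectome(w, coords, regions$region_id)
}

#' Construct a connectome object
#'
#' A weighted structural network: symmetric non-negative weight matrix with
#' zero diagonal (streamline counts) plus node coordinates in mm.
#'
#' @param weights N x N symmetric, hollow, non-negative matrix.
#' @param coords N x 3 coordinate matrix (mm).
#' @param region_ids node identifiers.
#' @return object of class `connectome`.
#' @export
connectome <- function(weights, coords, region_ids = seq_len(nrow(weights))) {
  weights <- as.matrix(weights)
  coords <- as.matrix(coords)
  if (nrow(weights) != ncol(weights)) stop_invalid("weights must be square")
  if (nrow(coords) != nrow(weights) || ncol(coords) != 3) {
    stop_invalid("coords must be N x 3, aligned with weights")
  }
  if (any(!is.finite(coords))) stop_invalid("coords must be finite")
  if (any(weights < 0)) stop_invalid("weights must be non-negative")
  if (max(abs(weights - t(weights))) > 1e-8) stop_invalid("weights must be symmetric")
  if (any(diag(weights) != 0)) stop_invalid("weights must have a zero diagonal")
  structure(list(weights = weights, coords = coords,
                 region_ids = region_ids),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  dens <- mean(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<connectome> %d nodes, density %.2f, total weight %d\n",
              n, dens, as.integer(sum(x$weights) / 2)))
  invisible(x)
}

#' Apply a focal spherical lesion to a connectome
#'
#' Every edge with at least one endpoint within `radius_mm` of the centroid
#' has its weight multiplied by `attenuation` (default 0: removed). Symmetry
#' and hollowness are preserved; no weight ever increases.
#'
#' @param conn a [connectome()].
#' @param centroid numeric length-3 lesion centre (mm).
#' @param radius_mm lesion radius (> 0).
#' @param attenuation multiplier in `[0, 1]` for affected edges.
#' @return the lesioned [connectome()].
#' @export
lesion_connectome <- function(conn, centroid, radius_mm, attenuation = 0) {
  stopifnot(inherits(conn, "connectome"))
  if (length(centroid) != 3 || any(!is.finite(centroid))) {
    stop_invalid("`centroid` must be a finite length-3 coordinate")
  }
  if (radius_mm <= 0) stop_invalid("`radius_mm` must be > 0")
  if (attenuation < 0 || attenuation > 1) {
    stop_invalid("`attenuation` must lie in [0, 1]")
  }
  hit <- sqrt(colSums((t(conn$coords) - centroid)^2)) <= radius_mm
  w <- conn$weights
  w[hit, ] <- w[hit, ] * attenuation
  w[, hit] <- t(w[hit, , drop = FALSE])  # keep exactly symmetric
  connectome(w, conn$coords, conn$region_ids)
}

#' Generate a complete synthetic cohort
#'
#' Umbrella generator: parcellation, per-subject BOLD matrices with planted
#' lags, per-subject connectomes (lesioned for stroke subjects), and the
#' planted-lag truth table. Everything is a deterministic function of
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list of class `lag_cohort` with elements `regions`, `subjects`
#'   (one row per subject), `bold` (named list of matrices), `conn` (named
#'   list of [connectome()]s), `truth` (planted lags), `config`.
#' @examples
#' cohort <- gen_cohort(cohort_config(n_stroke = 2, n_control = 2,
#'                                    n_pairs = 6, n_timepoints = 120))
#' cohort$subjects$group
#' @export
gen_cohort <- function(config = cohort_config()) {
  regions <- gen_parcellation(config$n_pairs, seed = config$seed)
  subjects_raw <- gen_bold_cohort(regions, config)

  subjects <- do.call(rbind, lapply(subjects_raw, `[[`, "record"))
  bold <- setNames(lapply(subjects_raw, `[[`, "bold"), subjects$subject_id)
  truth <- do.call(rbind, lapply(seq_along(subjects_raw), function(i) {
    cbind(subject_id = subjects$subject_id[i], subjects_raw[[i]]$planted)
  }))

  conn <- lapply(seq_len(nrow(subjects)), function(i) {
    base <- gen_connectome(regions, config, seed = derive_seed(config$seed, 500L + i))
    if (subjects$group[i] == "stroke") {
      centroid <- as.numeric(strsplit(subjects$lesion_centroid[i], ",")[[1]])
      lesion_connectome(base, centroid, subjects$lesion_radius_mm[i])
    } else {
      base
    }
  })
  names(conn) <- subjects$subject_id

  structure(list(regions = regions, subjects = subjects, bold = bold,
                 conn = conn, truth = truth, config = config),
            class = "lag_cohort")
}

#' @export
print.lag_cohort <- function(x, ...) {
  cat(sprintf("<lag_cohort> %d stroke + %d control, %d regions, T=%d @ TR=%gs\n",
              sum(x$subjects$group == "stroke"),
              sum(x$subjects$group == "control"),
              nrow(x$regions), x$config$n_timepoints, x$config$tr))
  invisible(x)
}

#' Clinical characteristics fixture (15 chronic stroke subjects)
#'
#' The demographics/clinical table of the 15-subject chronic stroke cohort
#' the package's analysis layer was designed around, transcribed verbatim:
#' lesion side, lesion location labels, stroke type (I ischemic /
#' H hemorrhagic), years since onset, and ARAT upper-limb motor score
#' (maximum 57). Ages are ranges for privacy.
#'
#' @return `data.frame` with columns `subject_id`, `age_range`, `gender`,
#'   `lesion_side` ("L"/"R"), `lesion_locations` (comma-separated labels),
#'   `stroke_type`, `onset_years`, `arat`.
#' @examples
#' fx <- table1_fixture()
#' count_lesion_location(fx, "putamen")  # 11
#' @export
table1_fixture <- function() {
  data.frame(
    subject_id = paste0("S", 1:15),
    age_range = c("55-59", "60-64", "45-49", "65-69", "65-69", "45-49",
                  "60-64", "55-59", "55-59", "50-54", "40-44", "40-44",
                  "55-59", "50-54", "45-49"),
    gender = c(rep("M", 13), "F", "M"),
    lesion_side = c("R", "L", "R", "L", "R", "R", "R", "L", "R", "L",
                    "R", "R", "R", "L", "R"),
    lesion_locations = c(
      "brainstem",
      "PLIC, putamen",
      "MFG, SFG, precentral, supramarginal, SMA",
      "insula, putamen, IFG, temporal pole",
      "insula, ITG, IOG, putamen",
      "ITG, MTG, STG, MOG, angular, supramarginal",
      "insula, putamen, rolandic operculum, IFG",
      "insula, IFG, putamen",
      "insula, IFG, putamen, rolandic operculum, temporal pole",
      "putamen, caudate nucleus",
      "insula, rolandic operculum, IFG, STG, putamen, temporal pole",
      "insula, MTG, STG, putamen, temporal pole, rolandic operculum",
      "insula, rolandic operculum, IFG",
      "insula, rolandic operculum, putamen",
      "insula, putamen"
    ),
    stroke_type = c("I", "I", "I", "H", "H", "H", "I", "H", "I", "I",
                    "H", "H", "I", "H", "H"),
    onset_years = c(11, 11, 1, 8, 1, 0.67, 3, 5, 7, 1, 5, 3, 6, 3, 1),
    arat = c(28L, 14L, 19L, 15L, 12L, 4L, 15L, 10L, 8L, 9L, 11L, 3L,
             16L, 10L, 12L),
    stringsAsFactors = FALSE
  )
}

#' Count subjects with a lesion location label
#'
#' @param fixture output of [table1_fixture()].
#' @param label location label, matched as a whole token.
#' @return integer count of subjects whose lesion spans the label.
#' @export
count_lesion_location <- function(fixture, label) {
  toks <- strsplit(fixture$lesion_locations, ",\\s*")
  sum(vapply(toks, function(t) label %in% t, logical(1)))
}
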