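#' Full cohort analysis: lag, communication, statistics
#'
#' Runs the complete analysis chain on a cohort (a `lag_cohort` object from
#' [gen_cohort()], or a cohort directory written by [write_cohort()]):
#'
#' 1. per-subject homotopic lag tables and zero-lag homotopic functional
#'    connectivity;
#' 2. per-subject communication profiles (shortest-path and navigation
#'    efficiency AUC over the density grid, per-pair navigation efficiency
#'    and navigation distance);
#' 3. group contrast of mean absolute lag (stroke vs control, pooled t) and
#'    per-pair contrasts with Benjamini-Hochberg FDR;
#' 4. affected vs unaffected subnetwork contrast (paired across stroke
#'    subjects; all pairs and intact-only pairs);
#' 5. pair-level correlation of log-remapped lag with region-to-lesion
#'    distance, homotopic Euclidean distance and navigation distance
#'    (Pearson), and with navigation efficiency (Spearman on raw lag);
#' 6. subject-level correlations of mean lag with efficiency AUCs under both
#'    schemes, plus partials controlling age and gender;
#' 7. variance partitioning: R-squared of log lag on Euclidean distance
#'    alone vs Euclidean plus navigation distance;
#' 8. Spearman associations of mean lag and homotopic functional
#'    connectivity with the ARAT motor score.
#'
#' @param cohort a `lag_cohort` or a path to a cohort directory.
#' @param tau_max maximum lag shift in seconds.
#' @param densities connection-density grid for the communication profile.
#' @param fdr_q FDR level for rejection sets.
#' @param per_subject_lag_distance also compute the per-stroke-subject
#'   lag--lesion-distance correlations (one row each).
#' @return object of class `lag_analysis`: list with `results` (one row per
#'   statistic: `name`, `statistic`, `estimate`, `p`, `p_adjusted`, `n`),
#'   `subjects`, `pairs`, `lag_tables`, `histograms`.
#' @export
run_full_analysis <- function(cohort, tau_max = 10,
                              densities = seq(0.10, 0.50, by = 0.05),
                              fdr_q = 0.05,
                              per_subject_lag_distance = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "lag_cohort"))
  regions <- cohort$regions
  subjects <- cohort$subjects
  tr <- cohort$config$tr
  eps <- tr / 100
  n_pairs <- max(regions$pair_id)
  pair_ids <- sort(unique(regions$pair_id))

  # region ids per pair, robust to row order
  left_rows <- regions[regions$hemisphere == "left", ]
  right_rows <- regions[regions$hemisphere == "right", ]
  pair_regions <- cbind(left = left_rows$region_id[match(pair_ids, left_rows$pair_id)],
                        right = right_rows$region_id[match(pair_ids, right_rows$pair_id)])

  ## ---- stage 1: lag tables -------------------------------------------------
  lag_tables <- lapply(subjects$subject_id, function(id) {
    homotopic_lags(cohort$bold[[id]], regions, tr, tau_max)
  })
  names(lag_tables) <- subjects$subject_id

  ## ---- stage 2: communication profiles ------------------------------------
  profiles <- lapply(subjects$subject_id, function(id) {
    comm_profile(cohort$conn[[id]], densities, pairs = pair_regions)
  })
  names(profiles) <- subjects$subject_id

  ## ---- subject-level frame -------------------------------------------------
  subj <- subjects
  subj$mean_abs_lag <- vapply(lag_tables, mean_lag, numeric(1))
  subj$mean_fc <- vapply(lag_tables, function(tb)
    mean(tb$zero_lag_r[!tb$degenerate]), numeric(1))
  subj$auc_e_sp <- vapply(profiles, `[[`, numeric(1), "auc_e_sp")
  subj$auc_e_nav <- vapply(profiles, `[[`, numeric(1), "auc_e_nav")

  subj$affected_mean <- subj$unaffected_mean <- subj$affected_intact_mean <- NA_real_
  for (i in which(subj$group == "stroke")) {
    les <- parse_ids(subj$lesion_regions[i])
    cls <- classify_affected(regions, les)
    tb <- lag_tables[[subj$subject_id[i]]]
    if (length(cls$affected)) subj$affected_mean[i] <- mean_lag(tb, cls$affected)
    if (length(cls$unaffected)) subj$unaffected_mean[i] <- mean_lag(tb, cls$unaffected)
    if (length(cls$affected_intact))
      subj$affected_intact_mean[i] <- mean_lag(tb, cls$affected_intact)
  }

  stroke <- subj[subj$group == "stroke", ]
  control <- subj[subj$group == "control", ]

  ## ---- pair-level frame (stroke) -------------------------------------------
  stroke_ids <- stroke$subject_id
  abs_lag_mat <- vapply(lag_tables[stroke_ids], function(tb)
    tb$abs_lag_seconds[match(pair_ids, tb$pair_id)], numeric(n_pairs))
  ctrl_lag_mat <- vapply(lag_tables[control$subject_id], function(tb)
    tb$abs_lag_seconds[match(pair_ids, tb$pair_id)], numeric(n_pairs))

  lesion_dist <- vapply(seq_len(nrow(stroke)), function(i) {
    row <- stroke[i, ]
    d <- region_to_lesion_distance(regions,
                                   parse_centroids(row$lesion_centroid),
                                   row$lesion_side)
    d$distance_mm[match(pair_ids, d$pair_id)]
  }, numeric(n_pairs))

  coords <- region_coords(regions)
  homotopic_dist <- sqrt(rowSums(
    (coords[match(pair_regions[, "left"], regions$region_id), ] -
       coords[match(pair_regions[, "right"], regions$region_id), ])^2))

  pair_nav_eff <- rowMeans(vapply(profiles[stroke_ids], function(pr)
    pr$pair$auc_nav_eff, numeric(n_pairs)))
  pair_dnav <- rowMeans(vapply(profiles[stroke_ids], function(pr)
    pr$pair$mean_dnav, numeric(n_pairs)), na.rm = TRUE)

  pairs_df <- data.frame(
    pair_id = pair_ids,
    mean_abs_lag = rowMeans(abs_lag_mat, na.rm = TRUE),
    mean_lesion_distance = rowMeans(lesion_dist),
    homotopic_distance = homotopic_dist,
    mean_nav_efficiency = pair_nav_eff,
    mean_dnav = pair_dnav
  )
  pairs_df$log_lag <- log_remap(pairs_df$mean_abs_lag, eps = eps)

  ## ---- statistics ----------------------------------------------------------
  res <- list()
  add <- function(name, statistic, estimate, p, n) {
    res[[length(res) + 1L]] <<- data.frame(
      name = name, statistic = statistic, estimate = estimate,
      p = p, n = n, stringsAsFactors = FALSE)
  }

  gt <- two_sample_t(stroke$mean_abs_lag, control$mean_abs_lag)
  add("group_mean_lag_t", "t", gt$t, gt$p, nrow(subj))
  add("stroke_mean_lag_s", "mean", mean(stroke$mean_abs_lag), NA, nrow(stroke))
  add("control_mean_lag_s", "mean", mean(control$mean_abs_lag), NA, nrow(control))

  ok_pair <- is.finite(subj$affected_mean) & is.finite(subj$unaffected_mean)
  if (sum(ok_pair) >= 2) {
    at <- two_sample_t(subj$affected_mean[ok_pair], subj$unaffected_mean[ok_pair],
                       paired = TRUE)
    add("affected_vs_unaffected_t", "t", at$t, at$p, sum(ok_pair))
    add("affected_mean_lag_s", "mean", mean(subj$affected_mean[ok_pair]), NA, sum(ok_pair))
    add("unaffected_mean_lag_s", "mean", mean(subj$unaffected_mean[ok_pair]), NA, sum(ok_pair))
  }
  ok_int <- is.finite(subj$affected_intact_mean) & is.finite(subj$unaffected_mean)
  if (sum(ok_int) >= 2) {
    it <- two_sample_t(subj$affected_intact_mean[ok_int],
                       subj$unaffected_mean[ok_int], paired = TRUE)
    add("affected_intact_vs_unaffected_t", "t", it$t, it$p, sum(ok_int))
  }

  ld <- pearson_cor(pairs_df$log_lag, pairs_df$mean_lesion_distance)
  add("pair_loglag_vs_lesion_distance_r", "r", ld$r, ld$p, ld$n)

  en <- pearson_cor(stroke$mean_abs_lag, stroke$auc_e_nav)
  add("lag_vs_auc_e_nav_r", "r", en$r, en$p, en$n)
  es <- pearson_cor(stroke$mean_abs_lag, stroke$auc_e_sp)
  add("lag_vs_auc_e_sp_r", "r", es$r, es$p, es$n)

  covs <- stroke[, c("age_years", "gender")]
  if (length(unique(covs$gender)) < 2) covs <- covs[, "age_years", drop = FALSE]
  n_cov <- sum(vapply(covs, function(cl)
    if (is.character(cl) || is.factor(cl)) length(unique(cl)) - 1L else 1L,
    integer(1)))
  if (nrow(stroke) >= n_cov + 3) {  # partials need the residual dof
    pn <- partial_pearson(stroke$mean_abs_lag, stroke$auc_e_nav, covs)
    add("lag_vs_auc_e_nav_partial_r", "r", pn$r, pn$p, nrow(stroke))
    ps <- partial_pearson(stroke$mean_abs_lag, stroke$auc_e_sp, covs)
    add("lag_vs_auc_e_sp_partial_r", "r", ps$r, ps$p, nrow(stroke))
  }

  ne <- spearman_cor(pairs_df$mean_abs_lag, pairs_df$mean_nav_efficiency)
  add("pair_lag_vs_nav_efficiency_rho", "rho", ne$rho, ne$p, ne$n)
  hd <- pearson_cor(pairs_df$log_lag, pairs_df$homotopic_distance)
  add("pair_loglag_vs_homotopic_distance_r", "r", hd$r, hd$p, hd$n)

  ok_dn <- is.finite(pairs_df$mean_dnav)
  dn <- pearson_cor(pairs_df$log_lag[ok_dn], pairs_df$mean_dnav[ok_dn])
  add("pair_loglag_vs_dnav_r", "r", dn$r, dn$p, dn$n)

  r2_e <- glm_r2(pairs_df$log_lag[ok_dn],
                 pairs_df$homotopic_distance[ok_dn])
  r2_en <- glm_r2(pairs_df$log_lag[ok_dn],
                  cbind(euclid = pairs_df$homotopic_distance[ok_dn],
                        dnav = pairs_df$mean_dnav[ok_dn]))
  add("r2_euclidean", "R2", r2_e, NA, sum(ok_dn))
  add("r2_euclidean_plus_dnav", "R2", r2_en, NA, sum(ok_dn))

  ar <- spearman_cor(stroke$mean_abs_lag, stroke$arat)
  add("lag_vs_arat_rho", "rho", ar$rho, ar$p, ar$n)
  fc <- spearman_cor(stroke$mean_fc, stroke$arat)
  add("fc_vs_arat_rho", "rho", fc$rho, fc$p, fc$n)

  results <- do.call(rbind, res)
  has_p <- is.finite(results$p)
  results$p_adjusted <- NA_real_
  results$p_adjusted[has_p] <- fdr_bh(results$p[has_p], fdr_q)$p_adjusted

  ## per-pair group t tests, FDR-adjusted as their own family
  pair_t <- do.call(rbind, lapply(seq_along(pair_ids), function(p) {
    xs <- abs_lag_mat[p, ]; yc <- ctrl_lag_mat[p, ]
    ht <- tryCatch(two_sample_t(xs[is.finite(xs)], yc[is.finite(yc)]),
                   error = function(e) list(t = NA_real_, p = NA_real_))
    data.frame(name = sprintf("pair_lag_t_p%02d", pair_ids[p]),
               statistic = "t", estimate = ht$t, p = ht$p,
               n = sum(is.finite(xs)) + sum(is.finite(yc)),
               stringsAsFactors = FALSE)
  }))
  okp <- is.finite(pair_t$p)
  pair_t$p_adjusted <- NA_real_
  pair_t$p_adjusted[okp] <- fdr_bh(pair_t$p[okp], fdr_q)$p_adjusted
  results <- rbind(results, pair_t)

  if (per_subject_lag_distance) {
    ps_rows <- do.call(rbind, lapply(seq_len(nrow(stroke)), function(i) {
      tb <- lag_tables[[stroke$subject_id[i]]]
      ll <- log_remap(tb$abs_lag_seconds[match(pair_ids, tb$pair_id)], eps = eps)
      ct <- tryCatch(pearson_cor(ll, lesion_dist[, i]),
                     error = function(e) list(r = NA_real_, p = NA_real_, n = n_pairs))
      data.frame(name = paste0("subject_loglag_vs_lesion_distance_r_",
                               stroke$subject_id[i]),
                 statistic = "r", estimate = ct$r, p = ct$p, n = ct$n,
                 p_adjusted = NA_real_, stringsAsFactors = FALSE)
    }))
    results <- rbind(results, ps_rows)
  }
  rownames(results) <- NULL

  histograms <- list(
    stroke = lag_histogram(as.vector(abs_lag_mat[is.finite(abs_lag_mat)])),
    control = lag_histogram(as.vector(ctrl_lag_mat[is.finite(ctrl_lag_mat)]))
  )

  structure(list(results = results, subjects = subj, pairs = pairs_df,
                 lag_tables = lag_tables, histograms = histograms,
                 fdr_q = fdr_q),
            class = "lag_analysis")
}

#' @export
print.lag_analysis <- function(x, ...) {
  headline <- x$results[!grepl("^(pair_lag_t_|subject_)", x$results$name), ]
  cat("<lag_analysis>\n")
  for (i in seq_len(nrow(headline))) {
    r <- headline[i, ]
    cat(sprintf("  %-38s %s = %8.4f%s\n", r$name, r$statistic, r$estimate,
                if (is.finite(r$p)) sprintf("  (p = %.4g)", r$p) else ""))
  }
  invisible(x)
}

parse_ids <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ";")[[1]])
}

parse_centroids <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  do.call(rbind, lapply(strsplit(s, ";")[[1]], function(cc)
    as.numeric(strsplit(cc, ",")[[1]])))
}
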