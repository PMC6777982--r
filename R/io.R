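#' Write a numeric matrix as tab-separated text
#'
#' First column holds row ids under the header `id`; values are written at
#' 9 significant digits and `Inf` is serialized as `"inf"` so length and
#' path matrices round-trip.
#'
#' @param m numeric matrix.
#' @param path output file.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  cols <- colnames(m) %||% paste0("c", seq_len(ncol(m)))
  fmt <- function(x) {
    out <- formatC(signif(x, 9), format = "g", digits = 9)
    out[is.infinite(x) & x > 0] <- "inf"
    out[is.infinite(x) & x < 0] <- "-inf"
    out
  }
  lines <- c(paste(c("id", cols), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(ids[i], fmt(m[i, ])), collapse = "\t"), character(1)))
  writeLines(lines, path)
}

#' Read a tab-separated numeric matrix
#'
#' Inverse of [write_matrix()]. Ragged rows, non-numeric cells and
#' duplicate ids raise descriptive parse errors naming the offending line.
#'
#' @param path input file.
#' @return numeric matrix with row/column names.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_invalid(paste0("file not found: ", path))
  lines <- readLines(path)
  if (length(lines) < 2) stop_parse(paste0(path, ": no data rows"))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol_exp <- length(cells[[1]])
  if (cells[[1]][1] != "id") stop_parse(paste0(path, ": header must start with 'id'"))
  bad <- which(vapply(cells, length, integer(1)) != ncol_exp)
  if (length(bad)) {
    stop_parse(sprintf("%s: ragged row at line %d (expected %d fields)",
                       path, bad[1], ncol_exp))
  }
  ids <- vapply(cells[-1], `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop_parse(sprintf("%s: duplicate row id '%s'", path, ids[duplicated(ids)][1]))
  }
  parse_num <- function(v, line) {
    v[v %in% c("inf", "Inf")] <- "Inf"
    v[v %in% c("-inf", "-Inf")] <- "-Inf"
    out <- suppressWarnings(as.numeric(v))
    if (any(is.na(out) & !v %in% "NA")) {
      stop_parse(sprintf("%s: non-numeric cell at line %d", path, line))
    }
    out
  }
  m <- do.call(rbind, lapply(seq_along(cells)[-1], function(i)
    parse_num(cells[[i]][-1], i)))
  dimnames(m) <- list(ids, cells[[1]][-1])
  m
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_invalid(paste0("file not found: ", path))
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a cohort to a directory of tab-separated files
#'
#' Schema: `regions.tsv`, `subjects.tsv`, `truth.tsv` (planted lags),
#' `config.yaml`, and per subject `bold_<id>.tsv` (regions x timepoints) and
#' `conn_<id>.tsv` (N x N integer weights). All files UTF-8,
#' tab-separated, with header rows.
#'
#' @param cohort a `lag_cohort` from [gen_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lag_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(cohort$regions, file.path(dir, "regions.tsv"))
  write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"))
  write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  for (id in cohort$subjects$subject_id) {
    write_matrix(cohort$bold[[id]], file.path(dir, paste0("bold_", id, ".tsv")))
    write_matrix(cohort$conn[[id]]$weights,
                 file.path(dir, paste0("conn_", id, ".tsv")))
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `lag_cohort` list.
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop_invalid(paste0("cohort directory not found: ", dir))
  regions <- read_tsv(file.path(dir, "regions.tsv"))
  check_regions(regions)
  subjects <- read_tsv(file.path(dir, "subjects.tsv"))
  subjects$lesion_centroid <- as.character(subjects$lesion_centroid)
  subjects$lesion_regions <- as.character(subjects$lesion_regions)
  subjects$lesion_centroid[is.na(subjects$lesion_centroid)] <- ""
  subjects$lesion_regions[is.na(subjects$lesion_regions)] <- ""
  truth <- read_tsv(file.path(dir, "truth.tsv"))
  config <- do.call(cohort_config, yaml::read_yaml(file.path(dir, "config.yaml")))
  coords <- as.matrix(regions[, c("x", "y", "z")])
  bold <- list(); conn <- list()
  for (id in subjects$subject_id) {
    bold[[id]] <- read_matrix(file.path(dir, paste0("bold_", id, ".tsv")))
    w <- read_matrix(file.path(dir, paste0("conn_", id, ".tsv")))
    conn[[id]] <- connectome(w, coords, regions$region_id)
  }
  structure(list(regions = regions, subjects = subjects, bold = bold,
                 conn = conn, truth = truth, config = config),
            class = "lag_cohort")
}

#' Read a flat run configuration file (YAML or JSON)
#'
#' Keys mirror [cohort_config()] plus `out`, `tau_max`, `densities`
#' (either a numeric vector or a string `"lo:hi:step"`), and `fdr_q`.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid(paste0("config file not found: ", path))
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$densities) && is.character(cfg$densities)) {
    parts <- as.numeric(strsplit(cfg$densities, ":")[[1]])
    if (length(parts) != 3 || any(!is.finite(parts))) {
      stop_parse("densities string must be 'lo:hi:step'")
    }
    cfg$densities <- seq(parts[1], parts[2], by = parts[3])
  }
  cfg
}

#' Run the full simulate -> lag -> comm -> analyze pipeline
#'
#' Generates (or reuses) a cohort, estimates lag tables, computes
#' communication summaries, runs the cohort statistics, and writes every
#' artifact under `out`: the cohort directory, `lags_<id>.tsv`,
#' `comm_summary.tsv`, `results.tsv` and `summary.txt`. Identical
#' configuration and seed reproduce `results.tsv` byte for byte. Stage
#' names, wall times and the seed are logged to stderr.
#'
#' @param config named list (or path to a YAML/JSON file) with any of the
#'   [cohort_config()] fields plus `out` (output directory, required),
#'   `tau_max`, `densities`, `fdr_q`, `cohort_dir` (skip simulation and read
#'   an existing cohort).
#' @return the `lag_analysis` object, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$out %||% stop_invalid("config must name an output directory `out`")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  tau_max <- config$tau_max %||% 10
  densities <- config$densities %||% seq(0.10, 0.50, by = 0.05)
  fdr_q <- config$fdr_q %||% 0.05

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    message(sprintf("[lagnav] stage=%s elapsed=%.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    val
  }

  cohort <- if (!is.null(config$cohort_dir)) {
    stage("load", read_cohort(config$cohort_dir))
  } else {
    cc_args <- config[intersect(names(config), names(formals(cohort_config)))]
    cfg <- do.call(cohort_config, cc_args)
    message(sprintf("[lagnav] seed=%d", cfg$seed))
    ch <- stage("simulate", gen_cohort(cfg))
    write_cohort(ch, file.path(out, "cohort"))
    ch
  }

  analysis <- stage("analyze",
                    run_full_analysis(cohort, tau_max = tau_max,
                                      densities = densities, fdr_q = fdr_q))

  stage("write", {
    for (id in cohort$subjects$subject_id) {
      tb <- analysis$lag_tables[[id]]
      write_tsv(round_df(tb), file.path(out, paste0("lags_", id, ".tsv")))
    }
    comm <- cbind(subject_id = cohort$subjects$subject_id,
                  round_df(analysis$subjects[, c("auc_e_sp", "auc_e_nav")]))
    write_tsv(comm, file.path(out, "comm_summary.tsv"))
    write_tsv(round_df(analysis$results), file.path(out, "results.tsv"))
    writeLines(utils::capture.output(print(analysis)),
               file.path(out, "summary.txt"))
  })
  invisible(analysis)
}

# 6 significant digits on numeric columns, stable text output
round_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  }
  df
}
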