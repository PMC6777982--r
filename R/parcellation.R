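#' Canonical resting-state subnetwork labels
#'
#' The seven intrinsic subnetworks used to label homotopic region pairs.
#' @export
SUBNETWORKS <- c(
  "default mode", "executive control", "sensorimotor", "fronto-parietal",
  "auditory", "visual", "subcortical"
)

#' Generate a mirror-symmetric synthetic parcellation
#'
#' Builds a region table emulating a bilateral cortical/subcortical
#' parcellation: `n_pairs` homotopic region pairs, one region per hemisphere,
#' with centre-of-mass coordinates mirror-symmetric about the mid-sagittal
#' plane (x = 0) and subnetwork labels cycled over the seven canonical
#' resting-state subnetworks.
#'
#' Region ids `1..n_pairs` are the left hemisphere, `n_pairs+1..2*n_pairs`
#' the right; `homotopic_partner` is an involution linking the two.
#' Coordinates are drawn uniformly inside a brain-sized bounding box
#' (|x| 10--70 mm, y -95--60 mm, z -45--75 mm).
#'
#' @param n_pairs number of homotopic pairs (>= 2); 40 gives the standard
#'   80-region bilateral parcellation.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return a `data.frame` with columns `region_id`, `hemisphere`
#'   ("left"/"right"), `homotopic_partner`, `pair_id`, `x`, `y`, `z` (mm),
#'   `subnetwork`, `lesioned` (all `FALSE`; subject-level lesions are applied
#'   downstream).
#' @examples
#' regions <- gen_parcellation(40, seed = 1)
#' nrow(regions)  # 80
#' @export
gen_parcellation <- function(n_pairs, seed = 1L) {
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || n_pairs < 2 ||
      n_pairs != round(n_pairs)) {
    stop_invalid("`n_pairs` must be a single integer >= 2")
  }
  n_pairs <- as.integer(n_pairs)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(derive_seed(seed, 1L))

  x <- runif(n_pairs, 10, 70)
  y <- runif(n_pairs, -95, 60)
  z <- runif(n_pairs, -45, 75)
  subnet <- SUBNETWORKS[((seq_len(n_pairs) - 1L) %% length(SUBNETWORKS)) + 1L]

  data.frame(
    region_id = seq_len(2L * n_pairs),
    hemisphere = rep(c("left", "right"), each = n_pairs),
    homotopic_partner = c(seq_len(n_pairs) + n_pairs, seq_len(n_pairs)),
    pair_id = rep(seq_len(n_pairs), 2L),
    x = c(-x, x),
    y = c(y, y),
    z = c(z, z),
    subnetwork = rep(subnet, 2L),
    lesioned = FALSE,
    stringsAsFactors = FALSE
  )
}

# Save/restore the global RNG state so generators are pure functions of
# their seed argument and do not perturb the caller's stream.
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed.restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Validate the RegionTable contract shared by every downstream stage.
check_regions <- function(regions) {
  need <- c("region_id", "hemisphere", "homotopic_partner", "pair_id",
            "x", "y", "z", "subnetwork")
  miss <- setdiff(need, names(regions))
  if (length(miss)) {
    stop_invalid(paste0("region table is missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  partner <- regions$homotopic_partner[match(regions$homotopic_partner,
                                             regions$region_id)]
  if (!identical(partner, regions$region_id)) {
    stop_invalid("homotopic pairing is not an involution")
  }
  invisible(regions)
}

region_coords <- function(regions) {
  m <- as.matrix(regions[, c("x", "y", "z")])
  rownames(m) <- regions$region_id
  m
}
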