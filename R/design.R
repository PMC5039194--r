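#' Generate an experiment design table
#'
#' Builds the bookkeeping spine of a phenotyping experiment: every
#' accession x treatment x replicate combination becomes one plant, and
#' plants are assigned in a seeded random order to trays of
#' `rows x cols` pots (default 4 x 5 = 20, the tray format of compact
#' phenotyping platforms).  The last tray may be partially filled.
#'
#' @param accessions Character vector of accession labels, or a single
#'   count `n` (labelled `"acc01"..`).
#' @param treatments A data frame with columns `treatment` and `nacl_mM`
#'   (nominal NaCl concentration, one of 0, 50, 100, 150 mM), or a single
#'   count: 1 gives control only, 2 gives control + 100 mM salt.
#' @param n_replicates Number of replicate plants per accession x
#'   treatment.
#' @param days Integer vector of measurement days, day 0 = treatment
#'   start; must be strictly increasing.
#' @param tray_rows,tray_cols Tray layout (pots per tray = rows * cols).
#' @param seed Integer seed; the randomised tray placement is
#'   deterministic given the seed.
#'
#' @return A tibble of class `pheno_design` with one row per plant:
#'   `plant_id`, `accession`, `treatment`, `nacl_mM`, `replicate`,
#'   `tray`, `tray_row`, `tray_col`.  The measurement `days` and the
#'   tray layout are stored as attributes `days` and `layout`.
#' @examples
#' d <- generate_design(2, 2, n_replicates = 3, days = 0:7, seed = 1)
#' nrow(d)            # 12 plants
#' max(d$tray)        # 1 tray
#' @export
generate_design <- function(accessions, treatments = 2, n_replicates = 8,
                            days = 0:7, tray_rows = 4, tray_cols = 5,
                            seed = 1) {
  if (is.numeric(accessions) && length(accessions) == 1) {
    if (accessions < 1) abort("`accessions` count must be >= 1")
    accessions <- sprintf("acc%02d", seq_len(accessions))
  }
  if (is.data.frame(treatments)) {
    trt <- as_tibble(treatments)
    if (!all(c("treatment", "nacl_mM") %in% names(trt))) {
      abort("`treatments` data frame needs columns `treatment` and `nacl_mM`")
    }
  } else {
    if (treatments < 1) abort("`treatments` count must be >= 1")
    trt <- tibble(
      treatment = c("control", "salt")[seq_len(treatments)],
      nacl_mM = c(0, 100)[seq_len(treatments)]
    )
  }
  if (!all(trt$nacl_mM %in% c(0, 50, 100, 150))) {
    abort("`nacl_mM` must be one of 0, 50, 100, 150")
  }
  if (n_replicates < 1) abort("`n_replicates` must be >= 1")
  if (tray_rows < 1 || tray_cols < 1) abort("tray layout must be positive")
  days <- as.integer(days)
  if (length(days) < 1 || any(diff(days) <= 0)) {
    abort("`days` must be non-empty and strictly increasing")
  }

  plants <- tidyr::expand_grid(
    accession = accessions,
    treatment = trt$treatment,
    replicate = seq_len(n_replicates)
  ) |>
    dplyr::left_join(trt, by = "treatment")

  n <- nrow(plants)
  slots_per_tray <- tray_rows * tray_cols
  withr_seed(seed, {
    ord <- sample.int(n)
  })
  slot <- integer(n)
  slot[ord] <- seq_len(n) # plant -> global slot, randomised
  plants$plant_id <- sprintf("p%03d", seq_len(n))
  plants$tray <- (slot - 1L) %/% slots_per_tray + 1L
  within_tray <- (slot - 1L) %% slots_per_tray
  plants$tray_row <- within_tray %/% tray_cols + 1L
  plants$tray_col <- within_tray %% tray_cols + 1L

  out <- plants[, c("plant_id", "accession", "treatment", "nacl_mM",
                    "replicate", "tray", "tray_row", "tray_col")]
  out <- as_tibble(out)
  attr(out, "days") <- days
  attr(out, "layout") <- c(rows = tray_rows, cols = tray_cols)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("pheno_design", class(out))
  out
}

#' Measurement days of a design
#' @param design A `pheno_design` tibble.
#' @return Integer vector of measurement days.
#' @export
design_days <- function(design) attr(design, "days")

# run code under a local RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
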