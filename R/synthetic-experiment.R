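#' Treatment effect parameters for the experiment simulator
#'
#' Ground-truth effect sizes applied per treatment by
#' [simulate_experiment_tables()].  Defaults emulate a moderate
#' (100 mM NaCl) salt stress on a 640 x 480 tray render: control plants
#' grow linearly at `gr` px/day from `area0` px; salt reduces growth to
#' 60% of control in the early interval and 45% in the late one (the
#' osmotic-phase reduction deepens over time), raises the
#' non-photochemical quenching capacity, and lowers the fraction of
#' open reaction centres and Fv/Fm.
#'
#' @param gr_control Control growth rate, px/day.
#' @param salt_ratio_early,salt_ratio_late True GR(salt)/GR(control)
#'   ratios for the two intervals (the generating SIIT values).
#' @param area0 Area at treatment start, px.
#' @param growth_noise_sd Additive noise on daily areas, px.
#' @param fo Dark-adapted minimum fluorescence (a.u.).
#' @param fvfm_control,fvfm_salt Dark-adapted maximum quantum yield per
#'   treatment (sets Fm via Fo).
#' @param npq_max_control,npq_max_salt Asymptotic NPQ per treatment.
#' @param qp_ss_control,qp_ss_salt Steady-state qP per treatment.
#' @param chlf_noise_sd Additive trace noise (a.u.).
#' @param accession_sd SD of the per-accession log-normal multipliers
#'   applied to growth rates, salt ratios and the photosynthetic salt
#'   response (natural variation).
#' @return A list of class `effect_params`.
#' @export
effect_params <- function(gr_control = 110,
                          salt_ratio_early = 0.6, salt_ratio_late = 0.45,
                          area0 = 250, growth_noise_sd = 15,
                          fo = 0.2, fvfm_control = 0.80, fvfm_salt = 0.75,
                          npq_max_control = 0.8, npq_max_salt = 1.3,
                          qp_ss_control = 0.7, qp_ss_salt = 0.5,
                          chlf_noise_sd = 0.005, accession_sd = 0.08) {
  structure(as.list(environment()), class = "effect_params")
}

#' Simulate the ground-truth tables of a phenotyping experiment
#'
#' Expands a design into per-plant growth series and per-plant
#' fluorescence truth parameters, with a seeded per-accession
#' multiplier creating natural variation around the treatment effects.
#' This is the lightweight core of the simulator; tray images and
#' traces are rendered on demand from these tables (see
#' [run_pipeline()]).
#'
#' @param design A [generate_design()] tibble.
#' @param params An [effect_params()] list.
#' @param intervals Two growth intervals (see
#'   [simulate_growth_series()]); defaults to `[0, 4]`, `[7, 11]`
#'   clipped to the design's day range when shorter.
#' @param seed Integer seed.
#' @return A list: `areas` (tibble `plant_id`, `day`, `area_px`,
#'   `area_true`), `plant_truth` (tibble with per-plant true
#'   `gr_early`, `gr_late` and a `chlf` list column of [chlf_truth()]
#'   objects), `intervals`, `accession_effects`.
#' @export
simulate_experiment_tables <- function(design, params = effect_params(),
                                       intervals = NULL, seed = 1) {
  stopifnot(inherits(params, "effect_params"))
  days <- design_days(design)
  if (is.null(intervals)) {
    intervals <- if (max(days) >= 11) list(c(0, 4), c(7, 11))
                 else list(c(0, 3), c(4, 7))
  }
  check_intervals(intervals)
  accs <- unique(design$accession)
  withr_seed(seed, {
    acc_mult <- exp(rnorm(length(accs), 0, params$accession_sd))
    acc_salt_mult <- exp(rnorm(length(accs), 0, params$accession_sd))
    acc_chlf_mult <- exp(rnorm(length(accs), 0, params$accession_sd))
  })
  eff <- tibble(accession = accs, gr_mult = acc_mult,
                salt_mult = acc_salt_mult, chlf_mult = acc_chlf_mult)

  plant_truth <- design |>
    dplyr::left_join(eff, by = "accession") |>
    dplyr::mutate(
      is_salt = .data$treatment != "control",
      stress = .data$nacl_mM / 100, # scale effects with dose
      gr_early = params$gr_control * .data$gr_mult *
        ifelse(.data$is_salt,
               pmin(1, params$salt_ratio_early ^ .data$stress) * .data$salt_mult,
               1),
      gr_late = params$gr_control * .data$gr_mult *
        ifelse(.data$is_salt,
               pmin(1, params$salt_ratio_late ^ .data$stress) * .data$salt_mult,
               1)
    )
  plant_truth$chlf <- purrr::pmap(
    list(plant_truth$is_salt, plant_truth$stress, plant_truth$chlf_mult),
    function(is_salt, stress, chlf_mult) {
      # accession-specific strength of the photosynthetic salt response
      w <- if (is_salt) min(stress * chlf_mult, 1.5) else 0
      fvfm <- params$fvfm_control + w * (params$fvfm_salt - params$fvfm_control)
      chlf_truth(
        fo = params$fo, fm = params$fo / (1 - fvfm),
        npq_max = (params$npq_max_control +
          w * (params$npq_max_salt - params$npq_max_control)) * chlf_mult,
        qp_ss = min(1, (params$qp_ss_control +
          w * (params$qp_ss_salt - params$qp_ss_control)) / sqrt(chlf_mult)))
    })

  areas <- purrr::pmap(
    list(plant_truth$plant_id, plant_truth$gr_early, plant_truth$gr_late,
         seq_len(nrow(plant_truth))),
    function(pid, ge, gl, i) {
      s <- simulate_growth_series(ge, gl, intervals = intervals, days = days,
                                  area0 = params$area0,
                                  noise_sd = params$growth_noise_sd,
                                  seed = seed + 131L * i)
      dplyr::mutate(s, plant_id = pid, .before = 1)
    }) |> dplyr::bind_rows()

  list(areas = areas,
       plant_truth = dplyr::select(plant_truth, -"gr_mult", -"salt_mult",
                                   -"chlf_mult"),
       intervals = intervals, accession_effects = eff)
}

#' Simulate an accession x trait matrix from two archetypes
#'
#' Builds accession-level salt-response profiles over the eight ChlF
#' traits plus SIIT1/SIIT2 from two archetypes: a "quencher" profile
#' (strong early rise of the non-photochemical block NPQ, PhiNPQ, qN,
#' PhiNO; growth maintained) and a "grower" profile (photochemical
#' block FvFm, FvpFmp, PhiP, qP depressed; growth reduced early).
#' Gaussian noise is added per accession and trait.
#'
#' @param n_accessions Number of accessions (split roughly evenly).
#' @param noise_sd Trait noise SD (trait units; archetypes differ by
#'   ~0.3-0.6 per trait).
#' @param seed Integer seed.
#' @return A list: `matrix` (accessions x 10 traits), `archetype`
#'   (named true memberships, 1 or 2).
#' @export
simulate_archetype_traits <- function(n_accessions = 8, noise_sd = 0.08,
                                      seed = 1) {
  traits <- c("FvFm", "FvpFmp", "PhiP", "qP", "PhiNO", "PhiNPQ", "qN", "NPQ",
              "siit1", "siit2")
  # salt-relative-to-control profiles
  quencher <- c(0.98, 0.90, 0.85, 0.88, 1.10, 1.35, 1.30, 1.60, 0.85, 0.75)
  grower   <- c(0.90, 0.70, 0.55, 0.60, 1.00, 1.05, 1.05, 1.10, 0.55, 0.40)
  n1 <- ceiling(n_accessions / 2)
  arch <- c(rep(1L, n1), rep(2L, n_accessions - n1))
  withr_seed(seed, {
    m <- t(vapply(arch, function(a) {
      base <- if (a == 1L) quencher else grower
      base + rnorm(length(base), 0, noise_sd)
    }, numeric(length(traits))))
  })
  colnames(m) <- traits
  rownames(m) <- sprintf("acc%02d", seq_len(n_accessions))
  names(arch) <- rownames(m)
  list(matrix = m, archetype = arch)
}
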