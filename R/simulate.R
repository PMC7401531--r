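#' Simulation configuration
#'
#' Defaults mirror the study design the pipeline targets: two groups of 8
#' animals sampled at 0, 4 and 24 h (48 lanes), the packaged 27-probe
#' codeset, within-animal correlation 0.5 on the latent log2 scale (the
#' same value the paired power analysis assumes for repeated readings),
#' moderate negative-binomial overdispersion, mild log-normal lane-to-lane
#' scale variation, and a positive-control ladder scaled so POS_E (0.5 fM)
#' sits comfortably above background.
#'
#' @param n_per_group Animals per group.
#' @param times_h Sampling times in hours.
#' @param codeset Codeset tibble (default [default_codeset()]).
#' @param baseline_mean Mean raw count for endogenous genes.
#' @param reference_mean Mean raw count for reference genes.
#' @param dispersion Negative-binomial size for gene probes; `Inf` gives
#'   the Poisson limit.
#' @param log2_effects Tibble (`gene`, `group`, `time_h`, `effect`) of
#'   planted log2 fold changes relative to baseline; NULL = no effects.
#' @param rho_within_animal AR1 correlation of the latent animal
#'   trajectory across consecutive sampling times.
#' @param latent_sd SD (log2 units) of the latent animal trajectory.
#' @param lane_scale_sd SD of log lane scale factors (0 = no lane
#'   variation).
#' @param background_mean Poisson mean of negative-control counts.
#' @param pos_scale Counts per fM for the positive-control ladder.
#' @param qc_failures List of `list(sample_id =, mode =)` entries applied
#'   via [inject_qc_failure()] after generation.
#' @param seed Integer RNG seed; per-lane streams are derived from it.
#' @return A list of class `ncountr_sim_config`.
#' @export
sim_config <- function(n_per_group = 8, times_h = c(0, 4, 24),
                       codeset = default_codeset(),
                       baseline_mean = 500, reference_mean = 2000,
                       dispersion = 20, log2_effects = NULL,
                       rho_within_animal = 0.5, latent_sd = 0.25,
                       lane_scale_sd = 0.1, background_mean = 5,
                       pos_scale = 250, qc_failures = list(),
                       seed = 1) {
  stopifnot(n_per_group >= 1, length(times_h) >= 1,
            !is.unsorted(times_h), baseline_mean > 0, reference_mean > 0,
            dispersion > 0, abs(rho_within_animal) < 1, latent_sd >= 0,
            lane_scale_sd >= 0, background_mean >= 0, pos_scale > 0)
  if (!is.null(log2_effects)) {
    need <- c("gene", "group", "time_h", "effect")
    if (!all(need %in% names(log2_effects))) {
      stop_ncountr("log2_effects needs columns gene, group, time_h, effect",
                   "ncountr_validation_error")
    }
    bad <- setdiff(log2_effects$gene, codeset$name)
    if (length(bad) > 0) {
      stop_ncountr(paste0("log2_effects names unknown gene(s): ",
                          paste(bad, collapse = ", ")),
                   "ncountr_validation_error")
    }
  }
  structure(list(n_per_group = n_per_group, times_h = as.numeric(times_h),
                 codeset = codeset, baseline_mean = baseline_mean,
                 reference_mean = reference_mean, dispersion = dispersion,
                 log2_effects = log2_effects,
                 rho_within_animal = rho_within_animal,
                 latent_sd = latent_sd, lane_scale_sd = lane_scale_sd,
                 background_mean = background_mean, pos_scale = pos_scale,
                 qc_failures = qc_failures, seed = as.integer(seed)),
            class = "ncountr_sim_config")
}

ar1_latent <- function(k, rho, sd) {
  # stationary AR1 path with marginal sd
  z <- rnorm(k)
  x <- numeric(k)
  x[1] <- z[1]
  if (k > 1) {
    for (i in 2:k) x[i] <- rho * x[i - 1] + sqrt(1 - rho^2) * z[i]
  }
  x * sd
}

#' Simulate a run set with known ground truth
#'
#' Each animal carries a latent Gaussian log2 trajectory with AR1
#' correlation across consecutive sampling times. Endogenous and reference
#' counts are negative binomial with mean
#' `baseline_mean * 2^(effect + latent) * lane_scale`; positive controls
#' are Poisson at `pos_scale * concentration_fM * lane_scale`; negative
#' controls are Poisson at `background_mean * lane_scale`. Lane attributes
#' record 555 of 555 fields of view and a binding density derived as total
#' counts / (fov_counted * 100). Per-lane RNG streams derived from the
#' seed make lane subsets independently reproducible.
#'
#' @param config A [sim_config()].
#' @return List with `runset` (a `ncountr_runset`) and `truth`
#'   (planted effects, per-lane scale factors, per-animal latent
#'   trajectories, seed).
#' @export
simulate_runset <- function(config = sim_config()) {
  if (!inherits(config, "ncountr_sim_config")) {
    stop_ncountr("config must come from sim_config()",
                 "ncountr_validation_error")
  }
  cs <- config$codeset
  genes <- probes_of_class_multi(cs, c("endogenous", "reference"))
  gene_class <- stats::setNames(as.character(cs$probe_class), cs$name)
  base_mu <- stats::setNames(
    ifelse(gene_class[genes] == "reference",
           config$reference_mean, config$baseline_mean), genes)
  pos <- cs[cs$probe_class == "positive", ]
  neg_names <- probes_of_class(cs, "negative")

  animals <- sprintf("A%02d", seq_len(2 * config$n_per_group))
  groups <- rep(c("control", "treatment"), each = config$n_per_group)
  design <- tidyr::expand_grid(
    animal_id = animals, time_h = config$times_h) |>
    dplyr::mutate(group = rep(groups, each = length(config$times_h)),
                  sample_id = paste0(.data$animal_id, "_",
                                     .data$time_h, "h")) |>
    dplyr::select("sample_id", "animal_id", "group", "time_h")

  # latent animal trajectories (one stream per animal)
  k <- length(config$times_h)
  latent <- purrr::map_dfr(seq_along(animals), function(i) {
    set.seed(lane_seed(config$seed, 10000 + i))
    tibble::tibble(animal_id = animals[i], time_h = config$times_h,
                   latent = ar1_latent(k, config$rho_within_animal,
                                       config$latent_sd))
  })

  eff_lookup <- function(gene, group, time_h) {
    e <- config$log2_effects
    if (is.null(e)) return(0)
    hit <- e$effect[e$gene == gene & e$group == group & e$time_h == time_h]
    if (length(hit) == 0) 0 else sum(hit)
  }

  lanes <- vector("list", nrow(design))
  scales <- numeric(nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    set.seed(lane_seed(config$seed, i))
    lane_scale <- exp(rnorm(1, 0, config$lane_scale_sd))
    scales[i] <- lane_scale
    lat <- latent$latent[latent$animal_id == row$animal_id &
                           latent$time_h == row$time_h]
    eff <- vapply(genes, function(g) eff_lookup(g, row$group, row$time_h),
                  0)
    mu <- base_mu * 2^(eff + lat) * lane_scale
    gene_counts <- if (is.finite(config$dispersion)) {
      rnbinom(length(mu), mu = mu, size = config$dispersion)
    } else {
      rpois(length(mu), mu)
    }
    pos_counts <- rpois(nrow(pos),
                        config$pos_scale * pos$concentration_fM * lane_scale)
    neg_counts <- rpois(length(neg_names),
                        config$background_mean * lane_scale)
    cnt <- stats::setNames(c(gene_counts, pos_counts, neg_counts),
                           c(genes, pos$name, neg_names))
    cnt <- cnt[cs$name]  # codeset order
    total <- sum(cnt)
    fov <- 555L
    lanes[[i]] <- structure(list(
      sample_id = row$sample_id,
      attributes = tibble::tibble(
        lane_id = sprintf("L%02d", i), fov_requested = fov,
        fov_counted = fov,
        binding_density = round(total / (fov * 100), 4),
        cartridge_id = "CART01"),
      counts = tibble::tibble(
        code_class = unname(rcc_code_class(gene_class[cs$name])),
        name = cs$name,
        accession = cs$accession,
        count = as.integer(unname(cnt)))
    ), class = "ncountr_lane")
  }

  runset <- assemble_runset(lanes, cs, design)
  for (fail in config$qc_failures) {
    runset <- inject_qc_failure(runset, fail$sample_id, fail$mode)
  }
  truth <- list(log2_effects = config$log2_effects,
                lane_scales = tibble::tibble(sample_id = design$sample_id,
                                             scale = scales),
                latent = latent, seed = config$seed)
  list(runset = runset, truth = truth)
}

#' Inject a single-mode QC failure into one lane
#'
#' Minimally perturbs the selected lane so that exactly the chosen check
#' fails under default thresholds: `fov` lowers the counted fields of view
#' to 74% of requested; `binding_density` sets the recorded density just
#' above the upper bound; `linearity` swaps the top and bottom rungs of
#' the positive ladder; `lod` raises the negative controls above POS_E.
#'
#' @param runset A `ncountr_runset`.
#' @param sample_id Lane to perturb.
#' @param mode One of `"fov"`, `"binding_density"`, `"linearity"`,
#'   `"lod"`.
#' @return The modified run set.
#' @export
inject_qc_failure <- function(runset, sample_id,
                              mode = c("fov", "binding_density",
                                       "linearity", "lod")) {
  mode <- match.arg(mode)
  i <- which(runset$lane_attrs$sample_id == sample_id)
  if (length(i) != 1) {
    stop_ncountr(paste0("no lane with sample_id ", sample_id),
                 "ncountr_value_error")
  }
  sel <- runset$counts$sample_id == sample_id
  if (mode == "fov") {
    runset$lane_attrs$fov_counted[i] <-
      as.integer(floor(0.74 * runset$lane_attrs$fov_requested[i]))
  } else if (mode == "binding_density") {
    runset$lane_attrs$binding_density[i] <- 2.5
  } else if (mode == "linearity") {
    a <- sel & runset$counts$name == "POS_A"
    f <- sel & runset$counts$name == "POS_F"
    if (!any(a) || !any(f)) {
      stop_ncountr("lane lacks POS_A/POS_F; cannot break linearity alone",
                   "ncountr_value_error")
    }
    tmp <- runset$counts$count[a]
    runset$counts$count[a] <- runset$counts$count[f]
    runset$counts$count[f] <- tmp
  } else {
    e <- sel & runset$counts$name == "POS_E"
    negs <- sel & runset$counts$name %in%
      probes_of_class(runset$codeset, "negative")
    if (!any(e) || sum(negs) < 2) {
      stop_ncountr("lane lacks POS_E or negatives; cannot break LOD alone",
                   "ncountr_value_error")
    }
    runset$counts$count[negs] <- runset$counts$count[e] + 10
  }
  runset
}

#' Named scenario configurations
#'
#' \describe{
#'   \item{null}{No planted effects; for type-I-error checks.}
#'   \item{paper_like}{Planted upregulation patterns echoing the study's
#'     qualitative findings: IL8 responds at 4 h with a between-group
#'     difference, PGHS2 at 24 h, milder IL6/TNFA responses.}
#'   \item{rho_grid}{No effects, within-animal correlation 0.6, no lane
#'     variation; for correlation recovery.}
#'   \item{qc_one_failure}{A clean run with one engineered imaging
#'     failure in a 24 h treatment-group lane.}
#' }
#'
#' @param seed Base seed shared by the scenarios.
#' @return Named list of [sim_config()] objects.
#' @export
scenario_library <- function(seed = 1) {
  paper_effects <- dplyr::bind_rows(
    tidyr::expand_grid(gene = "IL8", group = c("control", "treatment"),
                       time_h = 4) |>
      dplyr::mutate(effect = c(1.5, 0.4)),
    tidyr::expand_grid(gene = "PGHS2", group = c("control", "treatment"),
                       time_h = 24) |>
      dplyr::mutate(effect = c(1.6, 0.5)),
    tibble::tibble(gene = c("IL6", "TNFA"), group = "control",
                   time_h = c(4, 4), effect = c(0.7, 0.5))
  )
  list(
    null = sim_config(seed = seed),
    paper_like = sim_config(log2_effects = paper_effects, seed = seed),
    rho_grid = sim_config(rho_within_animal = 0.6, lane_scale_sd = 0,
                          seed = seed),
    qc_one_failure = sim_config(
      qc_failures = list(list(sample_id = "A09_24h", mode = "fov")),
      seed = seed)
  )
}

#' Simulate per-gene values exactly matching the GLS model assumptions
#'
#' Gaussian generator on the linear scale: value = mu + planted effect +
#' within-animal AR1 noise, for clean parameter-recovery and error-rate
#' studies of the modelling layer.
#'
#' @param n_per_group Animals per group.
#' @param times_h Sampling times.
#' @param rho Within-animal AR1 correlation (by measurement order).
#' @param sigma Residual SD.
#' @param mu Grand mean.
#' @param effects Tibble (`group`, `time_h`, `delta`) of planted mean
#'   shifts (same units as `value`); NULL = null model.
#' @param seed RNG seed.
#' @return Long tibble: `sample_id`, `animal_id`, `group`, `time_h`,
#'   `value`.
#' @export
simulate_gene_values <- function(n_per_group = 8, times_h = c(0, 4, 24),
                                 rho = 0, sigma = 1, mu = 100,
                                 effects = NULL, seed = 1) {
  set.seed(seed)
  animals <- sprintf("A%02d", seq_len(2 * n_per_group))
  groups <- rep(c("control", "treatment"), each = n_per_group)
  k <- length(times_h)
  purrr::map_dfr(seq_along(animals), function(i) {
    e <- ar1_latent(k, rho, sigma)
    delta <- vapply(times_h, function(t) {
      if (is.null(effects)) return(0)
      hit <- effects$delta[effects$group == groups[i] &
                             effects$time_h == t]
      if (length(hit) == 0) 0 else sum(hit)
    }, 0)
    tibble::tibble(sample_id = paste0(animals[i], "_", times_h, "h"),
                   animal_id = animals[i], group = groups[i],
                   time_h = times_h, value = mu + delta + e)
  })
}
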