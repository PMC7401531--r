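# Shared fixtures built in code.

# a clean deterministic lane congruent with the packaged codeset: gene
# counts well above background, positives exactly proportional to the
# ladder, low negatives
make_clean_lane <- function(sample_id = "S1", lane_id = "L1",
                            codeset = default_codeset()) {
  counts <- vapply(seq_len(nrow(codeset)), function(i) {
    switch(as.character(codeset$probe_class[i]),
           endogenous = 500L + i,
           reference = 2000L + 2L * i,
           positive = as.integer(round(250 * codeset$concentration_fM[i])),
           negative = 4L + (i %% 3L))
  }, integer(1))
  structure(list(
    sample_id = sample_id,
    attributes = tibble::tibble(lane_id = lane_id, fov_requested = 555L,
                                fov_counted = 555L, binding_density = 1.05,
                                cartridge_id = "CART01"),
    counts = tibble::tibble(
      code_class = unname(ncountr:::rcc_code_class(
        as.character(codeset$probe_class))),
      name = codeset$name, accession = codeset$accession,
      count = counts)
  ), class = "ncountr_lane")
}

# a random valid lane for round-trip property tests
make_random_lane <- function(seed, codeset = default_codeset()) {
  set.seed(seed)
  lane <- make_clean_lane(sample_id = paste0("R", seed),
                          lane_id = paste0("L", seed), codeset = codeset)
  lane$counts$count <- as.integer(rpois(nrow(codeset), lambda = 300))
  lane$attributes$fov_counted <- as.integer(sample(400:555, 1))
  lane$attributes$binding_density <- round(runif(1, 0.1, 2.25), 4)
  lane
}

# minimal two-group design around a set of lanes
make_design <- function(n_per_group = 2, times = c(0, 4, 24)) {
  animals <- sprintf("A%02d", seq_len(2 * n_per_group))
  groups <- rep(c("control", "treatment"), each = n_per_group)
  tidyr::expand_grid(animal_id = animals, time_h = times) |>
    dplyr::mutate(group = rep(groups, each = length(times)),
                  sample_id = paste0(animal_id, "_", time_h, "h")) |>
    dplyr::select(sample_id, animal_id, group, time_h)
}

# ordinary least squares via explicit normal equations (independent of the
# package's GLS path)
ols_oracle <- function(y, X) {
  drop(solve(crossprod(X), crossprod(X, y)))
}
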