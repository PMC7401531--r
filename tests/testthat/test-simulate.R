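test_that("the default configuration yields the 48-lane two-group design", {
  sim <- simulate_runset(sim_config(seed = 1))
  rs <- sim$runset
  expect_equal(nrow(rs$design), 48)
  expect_equal(dplyr::n_distinct(rs$design$animal_id), 16)
  expect_equal(sort(unique(rs$design$time_h)), c(0, 4, 24))
  expect_equal(as.numeric(table(rs$design$group)) / 3, c(8, 8))
  expect_equal(nrow(rs$counts), 48 * 27)
})

test_that("simulation is reproducible and RCC output byte-identical per seed", {
  a <- simulate_runset(sim_config(seed = 17))
  b <- simulate_runset(sim_config(seed = 17))
  expect_identical(a$runset$counts, b$runset$counts)
  expect_identical(a$truth$lane_scales, b$truth$lane_scales)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_runset(a$runset, d1)
  write_runset(b$runset, d2)
  f1 <- list.files(d1, pattern = "rcc$")
  expect_gt(length(f1), 0)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  c_ <- simulate_runset(sim_config(seed = 18))
  expect_false(identical(a$runset$counts$count, c_$runset$counts$count))
})

test_that("generated lanes parse back and pass all QC absent injections", {
  sim <- simulate_runset(sim_config(seed = 29))
  dir <- withr::local_tempdir()
  write_runset(sim$runset, dir)
  lanes <- lapply(sort(list.files(dir, pattern = "rcc$",
                                  full.names = TRUE)), read_rcc)
  rs2 <- assemble_runset(lanes, sim$runset$codeset,
                         read.csv(file.path(dir, "design.csv")))
  expect_equal(rs2$counts$count, sim$runset$counts$count)
  expect_true(all(run_qc(rs2)$overall_pass))
})

test_that("the Poisson limit has unit variance-to-mean ratio", {
  cfg <- sim_config(n_per_group = 500, times_h = 0, dispersion = Inf,
                    lane_scale_sd = 0, latent_sd = 0, seed = 101)
  sim <- simulate_runset(cfg)
  vm <- sim$runset$counts |>
    dplyr::filter(!grepl("^(POS|NEG)_", name)) |>
    dplyr::group_by(name) |>
    dplyr::summarise(ratio = var(count) / mean(count), .groups = "drop")
  expect_true(all(vm$ratio > 0.9 & vm$ratio < 1.1))
})

test_that("negative-binomial dispersion produces overdispersion", {
  cfg <- sim_config(n_per_group = 200, times_h = 0, dispersion = 5,
                    lane_scale_sd = 0, latent_sd = 0, seed = 102)
  sim <- simulate_runset(cfg)
  vm <- sim$runset$counts |>
    dplyr::filter(!grepl("^(POS|NEG)_", name)) |>
    dplyr::group_by(name) |>
    dplyr::summarise(ratio = var(count) / mean(count), .groups = "drop")
  expect_true(all(vm$ratio > 5))  # mu/size + 1 >> 1 at these means
})

test_that("each injection mode breaks exactly its own QC check", {
  modes <- c(fov = "fov_pass", binding_density = "bd_pass",
             linearity = "linearity_pass", lod = "lod_pass")
  for (mode in names(modes)) {
    sim <- simulate_runset(sim_config(seed = 37))
    rs <- inject_qc_failure(sim$runset, "A07_4h", mode)
    qc <- run_qc(rs)
    row <- qc[qc$sample_id == "A07_4h", ]
    flags <- c("fov_pass", "bd_pass", "linearity_pass", "lod_pass")
    expect_false(row[[modes[[mode]]]])
    for (other in setdiff(flags, modes[[mode]])) {
      expect_true(row[[other]])
    }
    expect_equal(sum(qc$overall_pass), 47)
  }
  expect_error(inject_qc_failure(simulate_runset(sim_config(seed = 1))$runset,
                                 "NOPE", "fov"),
               class = "ncountr_value_error")
})

test_that("the scenario library covers the documented settings", {
  lib <- scenario_library(seed = 3)
  expect_named(lib, c("null", "paper_like", "rho_grid", "qc_one_failure"))
  expect_null(lib$null$log2_effects)
  expect_true("IL8" %in% lib$paper_like$log2_effects$gene)
  expect_true("PGHS2" %in% lib$paper_like$log2_effects$gene)
  expect_equal(lib$rho_grid$rho_within_animal, 0.6)
  expect_length(lib$qc_one_failure$qc_failures, 1)
  # scenarios regenerate identically from their recorded seed
  s1 <- simulate_runset(lib$paper_like)
  s2 <- simulate_runset(scenario_library(seed = 3)$paper_like)
  expect_identical(s1$runset$counts, s2$runset$counts)
})

test_that("planted effects survive the full pipeline with correct signs", {
  hits_il8 <- 0; hits_pghs2 <- 0
  n_rep <- 8
  for (i in seq_len(n_rep)) {
    cfg <- scenario_library(seed = 500 + i)$paper_like
    sim <- simulate_runset(cfg)
    em <- normalize_runset(sim$runset)
    vals <- expr_values(em)
    joined <- dplyr::inner_join(vals, em$design, by = "sample_id")
    f8 <- fit_gene(vals[vals$gene == "IL8", c("sample_id", "value")],
                   em$design, gene = "IL8")
    # planted control > treatment at 4 h: the control-minus-treatment
    # contrast should come out positive
    hits_il8 <- hits_il8 +
      (contrast_between_groups(f8, 4)$estimate > 0)
    fp <- fit_gene(vals[vals$gene == "PGHS2", c("sample_id", "value")],
                   em$design, gene = "PGHS2")
    hits_pghs2 <- hits_pghs2 +
      (contrast_between_groups(fp, 24)$estimate > 0)
  }
  expect_gte(hits_il8 / n_rep, 0.9)
  expect_gte(hits_pghs2 / n_rep, 0.9)
})

test_that("normalization reduces contrast noise when lanes vary in scale", {
  raw_sd <- c(); norm_sd <- c()
  for (i in 1:12) {
    sim <- simulate_runset(sim_config(seed = 800 + i, lane_scale_sd = 0.4))
    em <- normalize_runset(sim$runset)
    vals <- expr_values(em) |>
      dplyr::inner_join(em$design, by = "sample_id") |>
      dplyr::filter(gene == "IL1B", time_h == 4)
    raw <- sim$runset$counts |>
      dplyr::filter(name == "IL1B") |>
      dplyr::inner_join(sim$runset$design, by = "sample_id") |>
      dplyr::filter(time_h == 4)
    # scale to comparable units before comparing spreads
    raw_sd <- c(raw_sd, sd(raw$count) / mean(raw$count))
    norm_sd <- c(norm_sd, sd(vals$value) / mean(vals$value))
  }
  expect_lt(mean(norm_sd), mean(raw_sd))
})

test_that("invalid configurations are rejected before generation", {
  expect_error(sim_config(log2_effects = tibble::tibble(bad = 1)),
               class = "ncountr_validation_error")
  expect_error(sim_config(log2_effects = tibble::tibble(
    gene = "NOT_A_GENE", group = "control", time_h = 4, effect = 1)),
    class = "ncountr_validation_error")
  expect_error(simulate_runset(list()), class = "ncountr_validation_error")
})
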