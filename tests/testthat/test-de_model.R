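test_that("GLS with independence equals the normal-equations OLS oracle", {
  for (seed in c(11, 23)) {
    d <- simulate_gene_values(rho = 0.4, seed = seed)
    f <- fit_gene(d, spec = model_spec(correlation = "independence"))
    mf <- d |>
      dplyr::filter(time_h %in% c(4, 24)) |>
      dplyr::arrange(animal_id, time_h) |>
      dplyr::inner_join(d |>
                          dplyr::filter(time_h == 0) |>
                          dplyr::select(animal_id, baseline = value),
                        by = "animal_id")
    mf$time_f <- factor(mf$time_h, c(4, 24))
    mf$group <- factor(mf$group, c("control", "treatment"))
    X <- stats::model.matrix(~ group * time_f + baseline, mf)
    expect_equal(unname(f$beta), unname(ols_oracle(mf$value, X)),
                 tolerance = 1e-8)
  }
})

test_that("AR1 REML agrees with an independent GLS implementation", {
  d <- simulate_gene_values(rho = 0.5, seed = 21)
  f <- fit_gene(d)
  mf <- d |>
    dplyr::filter(time_h %in% c(4, 24)) |>
    dplyr::arrange(animal_id, time_h) |>
    dplyr::inner_join(d |>
                        dplyr::filter(time_h == 0) |>
                        dplyr::select(animal_id, baseline = value),
                      by = "animal_id")
  mf$time_f <- factor(mf$time_h, c(4, 24))
  mf$group <- factor(mf$group, c("control", "treatment"))
  g <- nlme::gls(value ~ group * time_f + baseline, data = mf,
                 correlation = nlme::corAR1(form = ~ 1 | animal_id),
                 method = "REML")
  expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$rho,
               unname(coef(g$modelStruct$corStruct,
                           unconstrained = FALSE)),
               tolerance = 1e-5)
  expect_equal(f$sigma2, g$sigma^2, tolerance = 1e-6)
})

test_that("the reported rho maximizes the REML log-likelihood", {
  for (seed in c(2, 9, 31)) {
    d <- simulate_gene_values(rho = 0.5, seed = seed)
    f <- fit_gene(d)
    # independent evaluation of the profiled REML objective at a given rho
    obj <- function(rho) {
      s <- sqrt(1 - rho^2)
      y <- f$model_frame$value; X <- f$X
      blocks <- rle(as.character(f$model_frame$animal_id))$lengths
      starts <- cumsum(blocks) - blocks + 1
      first <- rep(FALSE, length(y)); first[starts] <- TRUE
      later <- which(!first)
      ys <- y; Xs <- X
      ys[later] <- (y[later] - rho * y[later - 1]) / s
      Xs[later, ] <- (X[later, ] - rho * X[later - 1, ]) / s
      beta <- ols_oracle(ys, Xs)
      rss <- sum((ys - Xs %*% beta)^2)
      np <- length(y) - ncol(X)
      sigma2 <- rss / np
      -0.5 * (np * log(2 * pi * sigma2) + np +
                length(later) * log(1 - rho^2) +
                determinant(crossprod(Xs))$modulus[1])
    }
    for (dr in c(-0.05, 0.05)) {
      r2 <- f$rho + dr
      if (abs(r2) < 0.98) expect_lte(obj(r2), f$reml_loglik + 1e-8)
    }
  }
})

test_that("lsmeans produce one cell per group-time and reduce to cell means", {
  d <- simulate_gene_values(rho = 0, seed = 5)
  f <- fit_gene(d, spec = model_spec(baseline_as_covariate = FALSE,
                                     correlation = "independence"))
  lsm <- f$lsmeans
  expect_equal(nrow(lsm), 4)  # 2 groups x 2 times
  cell_means <- d |>
    dplyr::filter(time_h %in% c(4, 24)) |>
    dplyr::group_by(group, time_h) |>
    dplyr::summarise(m = mean(value), .groups = "drop")
  merged <- dplyr::inner_join(lsm, cell_means, by = c("group", "time_h"))
  expect_equal(merged$estimate, merged$m, tolerance = 1e-8)
})

test_that("between-group contrast is exactly zero for mirrored groups", {
  d <- simulate_gene_values(rho = 0.3, seed = 8)
  ctrl <- d[d$group == "control", ]
  mirror <- ctrl
  mirror$group <- "treatment"
  mirror$animal_id <- sub("^A0", "B0", mirror$animal_id)
  mirror$sample_id <- paste0(mirror$animal_id, "_", mirror$time_h, "h")
  both <- rbind(ctrl, mirror)
  f <- fit_gene(both)
  ct <- contrast_between_groups(f, 4)
  expect_equal(ct$estimate, 0, tolerance = 1e-10)
})

test_that("vs-baseline contrast equals the matched-pairs t test with two times", {
  for (seed in c(3, 4, 10)) {
    d <- simulate_gene_values(times_h = c(0, 4), rho = 0, seed = seed)
    ct <- contrast_vs_baseline(d, spec = model_spec(times_modeled = 4),
                               group = "control", time = 4)
    w <- d |>
      dplyr::filter(group == "control") |>
      tidyr::pivot_wider(id_cols = animal_id, names_from = time_h,
                         values_from = value)
    tt <- stats::t.test(w$`4`, w$`0`, paired = TRUE)
    expect_equal(ct$statistic, unname(tt$statistic), tolerance = 1e-8)
    expect_equal(ct$df, unname(tt$parameter))
    expect_equal(ct$p_value, tt$p.value, tolerance = 1e-8)
  }
})

test_that("identical baseline and follow-up give a zero vs-baseline contrast", {
  d <- simulate_gene_values(times_h = c(0, 4), rho = 0, seed = 6)
  d$value[d$time_h == 4] <- d$value[d$time_h == 0]
  ct <- contrast_vs_baseline(d, spec = model_spec(times_modeled = 4),
                             group = "control", time = 4)
  expect_equal(ct$estimate, 0, tolerance = 1e-10)
  expect_equal(ct$p_value, 1, tolerance = 1e-6)
})

test_that("a planted within-group shift of 3 residual SDs is detected", {
  hits <- 0
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    d <- simulate_gene_values(
      rho = 0.3, seed = 4000 + i,
      effects = tibble::tibble(group = "control", time_h = 4, delta = 3))
    ct <- contrast_vs_baseline(d, group = "control", time = 4)
    hits <- hits + (ct$p_value <= 0.05)
  }
  expect_gt(hits / n_rep, 0.9)
})

test_that("rho is recovered in moderately large designs", {
  # fit the three-timepoint model that matches the generator (the
  # baseline-covariate model estimates a partial correlation instead)
  sp <- model_spec(times_modeled = c(0, 4, 24),
                   baseline_as_covariate = FALSE)
  est <- vapply(1:20, function(i) {
    d <- simulate_gene_values(n_per_group = 50, rho = 0.6, seed = 7000 + i)
    fit_gene(d, spec = sp)$rho
  }, 0)
  expect_lt(abs(median(est) - 0.6), 0.1)
})

test_that("fit_all_genes handles the 12-gene panel and degenerate genes", {
  sim <- simulate_runset(sim_config(seed = 31))
  em <- normalize_runset(sim$runset)
  de <- fit_all_genes(em)
  expect_length(de$fits, 12)
  expect_true(all(c("gene", "contrast", "estimate", "se", "df",
                    "p_value", "significant") %in% names(de$contrasts)))
  # 2 between-group + up to 4 vs-baseline contrasts per gene
  expect_equal(nrow(de$contrasts), 12 * 6)
  # degenerate genes are reported, not silently dropped
  vals <- expr_values(em)
  vals$value[vals$gene == "IL10"] <- 7
  de2 <- fit_all_genes(vals, em$design)
  expect_equal(de2$skipped$gene, "IL10")
  expect_match(de2$skipped$reason, "constant")
  expect_length(de2$fits, 11)
  # BH adjustment is optional and off by default
  expect_false("p_adj" %in% names(de$contrasts))
  de3 <- fit_all_genes(em, adjust_p = TRUE)
  expect_true(all(de3$contrasts$p_adj >= de3$contrasts$p_value - 1e-12))
})

test_that("results are invariant to sample order", {
  sim <- simulate_runset(sim_config(seed = 33))
  em <- normalize_runset(sim$runset)
  vals <- expr_values(em)
  de1 <- fit_all_genes(vals, em$design)
  set.seed(1)
  de2 <- fit_all_genes(vals[sample(nrow(vals)), ], em$design)
  expect_equal(dplyr::arrange(de1$contrasts, gene, contrast),
               dplyr::arrange(de2$contrasts, gene, contrast),
               tolerance = 1e-10)
})

test_that("residual normality diagnostics behave under null and skew", {
  d <- simulate_gene_values(rho = 0, seed = 12)
  f <- fit_gene(d)
  rn <- residual_normality(f)
  expect_true(rn$shapiro_w > 0 && rn$shapiro_w <= 1)
  expect_true(rn$shapiro_p >= 0 && rn$shapiro_p <= 1)
  expect_true(rn$anderson_darling_a2 > 0)
  # strong right skew is flagged most of the time (three-timepoint
  # model, 48 residuals)
  sp48 <- model_spec(times_modeled = c(0, 4, 24),
                     baseline_as_covariate = FALSE)
  low <- 0
  for (i in 1:25) {
    set.seed(5000 + i)
    dd <- d
    dd$value <- rexp(nrow(dd)) * 50
    low <- low + (residual_normality(fit_gene(dd, spec = sp48))$shapiro_p
                  < 0.05)
  }
  expect_gt(low / 25, 0.8)
  # constant residuals are a defined failure
  dc <- d
  dc$value <- dc$value[1]
  expect_error(fit_all_genes_constant <- residual_normality(
    structure(list(model_frame = data.frame(value = rep(1, 10)),
                   X = matrix(1, 10, 1), beta = 1, sigma2 = 0),
              class = "ncountr_gene_fit")),
    class = "ncountr_insufficient_data_error")
})

test_that("tidy and glance expose coefficients and fit summaries", {
  d <- simulate_gene_values(rho = 0.3, seed = 14)
  f <- fit_gene(d, gene = "IL8")
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_equal(nrow(td), length(f$beta))
  gl <- glance(f)
  expect_true(gl$rho > -1 && gl$rho < 1)
  expect_gt(gl$sigma2, 0)
})

test_that("estimation errors are raised for unusable designs", {
  d <- simulate_gene_values(seed = 15)
  # single-animal group
  solo <- d[d$animal_id %in% c("A01", "A09"), ]
  expect_error(fit_gene(solo), class = "ncountr_estimation_error")
  # missing baseline with the covariate model
  nb <- d[!(d$animal_id == "A01" & d$time_h == 0), ]
  expect_error(fit_gene(nb), class = "ncountr_estimation_error")
  # unknown contrast time
  f <- fit_gene(d)
  expect_error(contrast_between_groups(f, 12),
               class = "ncountr_value_error")
})
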