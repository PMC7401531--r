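#' Model specification for per-gene repeated-measures fits
#'
#' The default model treats the post-baseline times (4 and 24 h) as the
#' repeated responses, with each animal's 0 h value entering as a baseline
#' covariate, fixed effects of group, time and their interaction, and AR1
#' correlation (by measurement order) between the repeated measures within
#' an animal, estimated by REML.
#'
#' @param response_transform `"identity"` (counts modeled on the normalized
#'   scale) or `"log2p1"` (log2(x + 1)).
#' @param times_modeled Post-baseline times treated as repeated responses.
#' @param baseline_as_covariate Adjust for each animal's 0 h value?
#' @param correlation Within-animal correlation structure: `"ar1"`,
#'   `"independence"` or `"compound_symmetry"`.
#' @param alpha Significance level for contrast flags.
#' @return A list of class `ncountr_model_spec`.
#' @export
model_spec <- function(response_transform = c("identity", "log2p1"),
                       times_modeled = c(4, 24),
                       baseline_as_covariate = TRUE,
                       correlation = c("ar1", "independence",
                                       "compound_symmetry"),
                       alpha = 0.05) {
  stopifnot(length(times_modeled) >= 1, alpha > 0, alpha < 1)
  structure(list(response_transform = match.arg(response_transform),
                 times_modeled = sort(as.numeric(times_modeled)),
                 baseline_as_covariate = isTRUE(baseline_as_covariate),
                 correlation = match.arg(correlation),
                 alpha = alpha),
            class = "ncountr_model_spec")
}

apply_transform <- function(x, transform) {
  if (transform == "log2p1") log2(x + 1) else x
}

# Block-diagonal within-animal correlation matrix by measurement order.
corr_block <- function(n, rho, structure) {
  if (structure == "independence" || n == 1) return(diag(n))
  idx <- seq_len(n)
  if (structure == "ar1") {
    rho^abs(outer(idx, idx, "-"))
  } else {
    m <- matrix(rho, n, n); diag(m) <- 1; m
  }
}

# REML fit of y = X beta + e, Var(e) = sigma2 * blockdiag(R(rho)), with
# sigma2 profiled out and rho maximized by Brent search on (-0.98, 0.98).
# Rows must be grouped by animal (consecutive) in measurement order.
fit_gls_core <- function(y, X, animal, structure = "ar1") {
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) {
    stop_ncountr("singular fixed-effect design (rank-deficient model matrix)",
                 "ncountr_estimation_error")
  }
  blocks <- rle(as.character(animal))$lengths
  ends <- cumsum(blocks)
  starts <- ends - blocks + 1

  # row bookkeeping for the vectorized AR1 whitening
  first_row <- rep(FALSE, n)
  first_row[starts] <- TRUE
  later <- which(!first_row)

  eval_rho <- function(rho) {
    ys <- y; Xs <- X; logdetV <- 0
    if (structure == "ar1") {
      # closed-form AR1 whitening: rows after the first in each block
      # become (x_t - rho x_{t-1}) / sqrt(1 - rho^2)
      if (abs(rho) >= 1) return(NULL)
      s <- sqrt(1 - rho^2)
      if (length(later) > 0) {
        ys[later] <- (y[later] - rho * y[later - 1]) / s
        Xs[later, ] <- (X[later, , drop = FALSE] -
                          rho * X[later - 1, , drop = FALSE]) / s
        logdetV <- length(later) * log(1 - rho^2)
      }
    } else if (structure == "compound_symmetry") {
      for (b in seq_along(blocks)) {
        nb <- blocks[b]
        if (nb == 1) next
        R <- corr_block(nb, rho, structure)
        L <- tryCatch(chol(R), error = function(e) NULL)
        if (is.null(L)) return(NULL)
        rows <- starts[b]:ends[b]
        ys[rows] <- backsolve(L, y[rows], transpose = TRUE)
        Xs[rows, ] <- backsolve(L, X[rows, , drop = FALSE], transpose = TRUE)
        logdetV <- logdetV + 2 * sum(log(diag(L)))
      }
    }
    XtX <- crossprod(Xs)
    ch <- tryCatch(chol(XtX), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- backsolve(ch, backsolve(ch, crossprod(Xs, ys), transpose = TRUE))
    rss <- sum((ys - Xs %*% beta)^2)
    sigma2 <- rss / (n - p)
    reml_ll <- -0.5 * ((n - p) * log(2 * pi * sigma2) + (n - p) +
                         logdetV + 2 * sum(log(diag(ch))))
    list(rho = rho, beta = drop(beta), sigma2 = sigma2,
         vcov = sigma2 * chol2inv(ch), reml_ll = reml_ll)
  }

  if (structure == "independence" || all(blocks == 1)) {
    fit <- eval_rho(0)
    if (is.null(fit)) {
      stop_ncountr("GLS estimation failed", "ncountr_estimation_error")
    }
    return(fit)
  }

  obj <- function(rho) {
    f <- eval_rho(rho)
    if (is.null(f)) return(1e10)
    -f$reml_ll
  }
  opt <- stats::optimize(obj, interval = c(-0.98, 0.98), tol = 1e-10)
  rho_hat <- opt$minimum
  # Newton polish on the profiled objective: Brent stalls near sqrt(eps),
  # leaving O(1e-8) error in rho and hence in contrast SEs
  for (h in c(1e-4, 1e-6)) {
    for (it in 1:3) {
      if (rho_hat <= -0.98 + h || rho_hat >= 0.98 - h) break
      f0 <- obj(rho_hat); fm <- obj(rho_hat - h); fp <- obj(rho_hat + h)
      hess <- (fm - 2 * f0 + fp) / h^2
      if (!is.finite(hess) || hess <= 0) break
      step <- -(fp - fm) / (2 * h) / hess
      if (!is.finite(step) || abs(step) > 0.1) break
      rho_hat <- rho_hat + step
      if (abs(step) < 1e-13) break
    }
  }
  fit <- eval_rho(rho_hat)
  if (is.null(fit) || !is.finite(fit$reml_ll)) {
    stop_ncountr("REML estimation did not converge",
                 "ncountr_estimation_error")
  }
  fit
}

# Assemble the model frame for one gene: join expression to design, apply
# the response transform, attach baseline covariate, order by animal/time.
build_model_frame <- function(data, design, spec) {
  if (!is.null(design)) {
    data <- dplyr::inner_join(data, read_design(design), by = "sample_id")
  }
  need <- c("animal_id", "group", "time_h", "value")
  if (!all(need %in% names(data))) {
    stop_ncountr(paste0("model data needs columns ",
                        paste(need, collapse = ", ")),
                 "ncountr_format_error")
  }
  if (!is.factor(data$group)) {
    lev <- unique(as.character(data$group))
    lev <- c(intersect(c("control", "treatment"), lev),
             setdiff(lev, c("control", "treatment")))
    data$group <- factor(data$group, levels = lev)
  }
  data <- dplyr::mutate(data,
                        value = apply_transform(.data$value,
                                                spec$response_transform))
  baseline <- data |>
    dplyr::filter(.data$time_h == 0) |>
    dplyr::select("animal_id", baseline = "value")
  mf <- data |>
    dplyr::filter(.data$time_h %in% spec$times_modeled) |>
    dplyr::arrange(.data$animal_id, .data$time_h)
  if (spec$baseline_as_covariate) {
    mf <- dplyr::inner_join(mf, baseline, by = "animal_id")
    lost <- setdiff(unique(data$animal_id[data$time_h %in%
                                            spec$times_modeled]),
                    unique(mf$animal_id))
    if (length(lost) > 0) {
      stop_ncountr(paste0("animal(s) lack a baseline (0 h) value: ",
                          paste(lost, collapse = ", ")),
                   "ncountr_estimation_error")
    }
  }
  per_group <- mf |>
    dplyr::distinct(.data$group, .data$animal_id) |>
    dplyr::count(.data$group)
  if (nrow(per_group) < 2 || any(per_group$n < 2)) {
    stop_ncountr("need >= 2 animals in each of two groups",
                 "ncountr_estimation_error")
  }
  mf
}

model_matrix_for <- function(mf, spec) {
  mf$time_f <- factor(mf$time_h, levels = spec$times_modeled)
  mf$group <- droplevels(mf$group)
  form <- if (spec$baseline_as_covariate && length(spec$times_modeled) > 1) {
    ~ group * time_f + baseline
  } else if (spec$baseline_as_covariate) {
    ~ group + baseline
  } else if (length(spec$times_modeled) > 1) {
    ~ group * time_f
  } else {
    ~ group
  }
  X <- stats::model.matrix(form, mf)
  within_cols <- grepl("time_f", colnames(X))
  list(X = X, within_cols = within_cols, mf = mf)
}

#' Fit the repeated-measures GLS model for one gene
#'
#' @param data Tibble with `sample_id` and `value` (plus `animal_id`,
#'   `group`, `time_h` if `design` is NULL).
#' @param design Study-design tibble or CSV path; joined by `sample_id`.
#' @param spec A [model_spec()].
#' @param gene Optional gene label carried into outputs.
#' @return An object of class `ncountr_gene_fit`: coefficients, their
#'   covariance, AR1 correlation `rho`, residual variance `sigma2`, REML
#'   log-likelihood, least-squares means, and the degrees-of-freedom
#'   bookkeeping used for contrasts.
#' @export
fit_gene <- function(data, design = NULL, spec = model_spec(),
                     gene = "gene") {
  mf0 <- build_model_frame(data, design, spec)
  mm <- model_matrix_for(mf0, spec)
  mf <- mm$mf
  fit <- fit_gls_core(mf$value, mm$X, mf$animal_id, spec$correlation)

  n <- nrow(mf)
  m <- dplyr::n_distinct(mf$animal_id)
  q_within <- sum(mm$within_cols)
  q_between <- ncol(mm$X) - q_within
  df_within <- max(1, n - m - q_within)
  df_between <- max(1, m - q_between)

  obj <- structure(
    list(gene = gene, spec = spec,
         beta = stats::setNames(fit$beta, colnames(mm$X)),
         beta_se = stats::setNames(sqrt(diag(fit$vcov)), colnames(mm$X)),
         vcov = fit$vcov, rho = fit$rho, sigma2 = fit$sigma2,
         reml_loglik = fit$reml_ll,
         model_frame = mf, X = mm$X, within_cols = mm$within_cols,
         df_within = df_within, df_between = df_between,
         n_obs = n, n_animals = m),
    class = "ncountr_gene_fit")
  obj$lsmeans <- lsmeans(obj)
  obj
}

lsm_row <- function(fit, group, time) {
  mf <- fit$model_frame
  L <- numeric(length(fit$beta))
  names(L) <- names(fit$beta)
  L["(Intercept)"] <- 1
  g2 <- levels(mf$group)[2]
  if (paste0("group", g2) %in% names(L) && group == g2) {
    L[paste0("group", g2)] <- 1
  }
  for (tl in levels(mf$time_f)[-1]) {
    tn <- paste0("time_f", tl)
    if (tn %in% names(L) && as.character(time) == tl) L[tn] <- 1
    it <- paste0("group", g2, ":time_f", tl)
    if (it %in% names(L) && group == g2 && as.character(time) == tl) {
      L[it] <- 1
    }
  }
  if ("baseline" %in% names(L)) L["baseline"] <- mean(mf$baseline)
  L
}

#' Least-squares means for every (group, time) cell
#'
#' Model-based cell means with the baseline covariate held at its grand
#' mean, with standard errors from the GLS covariance.
#'
#' @param fit A `ncountr_gene_fit`.
#' @param spec Unused; the fit's own spec governs.
#' @return Tibble: `group`, `time_h`, `estimate`, `se`.
#' @export
lsmeans <- function(fit, spec = NULL) {
  mf <- fit$model_frame
  cells <- expand.grid(group = levels(mf$group),
                       time_h = fit$spec$times_modeled,
                       stringsAsFactors = FALSE)
  purrr::pmap_dfr(cells, function(group, time_h) {
    L <- lsm_row(fit, group, time_h)
    tibble::tibble(group = group, time_h = time_h,
                   estimate = sum(L * fit$beta),
                   se = sqrt(drop(t(L) %*% fit$vcov %*% L)))
  })
}

contrast_from_L <- function(fit, L, label, alpha, df = NULL) {
  est <- sum(L * fit$beta)
  se <- sqrt(drop(t(L) %*% fit$vcov %*% L))
  df <- df %||%
    if (any(L[fit$within_cols] != 0)) fit$df_within else fit$df_between
  tstat <- est / se
  p <- 2 * stats::pt(-abs(tstat), df)
  tibble::tibble(contrast = label, estimate = est, se = se, df = df,
                 statistic = tstat, p_value = p,
                 significant = p <= alpha)
}

#' Between-group contrast at one time point
#'
#' Tests LSM(control, t) - LSM(treatment, t) = 0 with a t statistic;
#' degrees of freedom follow the between-within partition (contrasts
#' involving the repeated factor use within-animal df).
#'
#' @param fit A `ncountr_gene_fit`.
#' @param time One of the fitted times.
#' @return One-row contrast tibble.
#' @export
contrast_between_groups <- function(fit, time) {
  if (!time %in% fit$spec$times_modeled) {
    stop_ncountr(paste0("time ", time, " not in the fitted times"),
                 "ncountr_value_error")
  }
  gl <- levels(fit$model_frame$group)
  L <- lsm_row(fit, gl[1], time) - lsm_row(fit, gl[2], time)
  # group-at-time slices involve the group:time effect, so they take the
  # within-animal df regardless of which time is the reference level
  contrast_from_L(fit, L,
                  paste0(gl[1], "-", gl[2], "@", time, "h"),
                  fit$spec$alpha,
                  df = if (length(fit$spec$times_modeled) > 1)
                    fit$df_within else fit$df_between)
}

#' Within-group contrast against baseline
#'
#' Fits the companion repeated-measures model on the selected group's data
#' over {0 h} and the requested post-baseline times (no baseline
#' covariate; AR1 by measurement order) and tests LSM(group, time) -
#' LSM(group, 0) = 0. With two time points and freely estimated
#' correlation this reproduces the matched-pairs t test exactly.
#'
#' @param data,design As in [fit_gene()].
#' @param spec A [model_spec()]; its `times_modeled` define the
#'   post-baseline times entering the companion fit.
#' @param group `"control"` or `"treatment"`.
#' @param time The post-baseline time to compare with 0 h.
#' @return One-row contrast tibble.
#' @export
contrast_vs_baseline <- function(data, design = NULL, spec = model_spec(),
                                 group, time) {
  if (!time %in% spec$times_modeled) {
    stop_ncountr(paste0("time ", time, " not in spec$times_modeled"),
                 "ncountr_value_error")
  }
  if (!is.null(design)) {
    data <- dplyr::inner_join(data, read_design(design), by = "sample_id")
  }
  sub <- data |>
    dplyr::filter(.data$group == !!group,
                  .data$time_h %in% c(0, spec$times_modeled)) |>
    dplyr::mutate(value = apply_transform(.data$value,
                                          spec$response_transform)) |>
    dplyr::arrange(.data$animal_id, .data$time_h)
  have_base <- sub |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::filter(any(.data$time_h == 0), any(.data$time_h == time)) |>
    dplyr::ungroup()
  if (dplyr::n_distinct(have_base$animal_id) < 2) {
    stop_ncountr("need baseline and time-t values for >= 2 animals",
                 "ncountr_estimation_error")
  }
  sub <- have_base
  times <- sort(unique(sub$time_h))
  sub$time_f <- factor(sub$time_h, levels = times)
  X <- stats::model.matrix(~time_f, sub)
  fit <- fit_gls_core(sub$value, X, sub$animal_id, spec$correlation)
  within_cols <- grepl("time_f", colnames(X))
  n <- nrow(sub)
  m <- dplyr::n_distinct(sub$animal_id)
  shell <- structure(
    list(spec = spec, beta = stats::setNames(fit$beta, colnames(X)),
         vcov = fit$vcov, within_cols = within_cols,
         df_within = max(1, n - m - sum(within_cols)),
         df_between = max(1, m - (ncol(X) - sum(within_cols)))),
    class = "ncountr_gene_fit")
  L <- numeric(length(fit$beta))
  names(L) <- colnames(X)
  L[paste0("time_f", time)] <- 1
  contrast_from_L(shell, L, paste0(group, ":", time, "h-0h"), spec$alpha)
}

#' Fit every endogenous gene and collect contrasts
#'
#' @param em A fully normalized `ncountr_expr`, or a long tibble
#'   (`sample_id`, `gene`, `value`).
#' @param design Study design (tibble or CSV path); defaults to the
#'   expression object's own design.
#' @param spec A [model_spec()].
#' @param adjust_p Add a Benjamini-Hochberg adjusted column? Off by
#'   default (inference is reported unadjusted).
#' @return A list of class `ncountr_de_result`: `fits` (named list of
#'   `ncountr_gene_fit`), `contrasts` (long tibble over genes: the
#'   between-group contrast at each modeled time and the within-group
#'   vs-baseline contrasts), `lsmeans`, and `skipped` (degenerate genes
#'   with reasons).
#' @export
fit_all_genes <- function(em, design = NULL, spec = model_spec(),
                          adjust_p = FALSE) {
  if (inherits(em, "ncountr_expr")) {
    if (!identical(em$stage, "fully_normalized")) {
      stop_ncountr("expression object must be fully normalized",
                   "ncountr_pipeline_order_error")
    }
    values <- expr_values(em, "endogenous")
    design <- design %||% em$design
  } else {
    values <- em
  }
  design <- read_design(design)
  genes <- unique(values$gene)
  fits <- list()
  skipped <- tibble::tibble(gene = character(), reason = character())
  rows <- list()
  lsm <- list()
  for (g in genes) {
    d <- values[values$gene == g, c("sample_id", "value")]
    if (stats::sd(d$value) == 0) {
      skipped <- dplyr::bind_rows(skipped,
                                  tibble::tibble(gene = g,
                                                 reason = "constant values"))
      next
    }
    fit <- tryCatch(fit_gene(d, design, spec, gene = g),
                    ncountr_error = function(e) e)
    if (inherits(fit, "error")) {
      skipped <- dplyr::bind_rows(
        skipped, tibble::tibble(gene = g, reason = conditionMessage(fit)))
      next
    }
    fits[[g]] <- fit
    between <- purrr::map_dfr(spec$times_modeled,
                              function(t) contrast_between_groups(fit, t))
    joined <- dplyr::inner_join(d, design, by = "sample_id")
    within <- purrr::map_dfr(levels(droplevels(design$group)), function(gr) {
      purrr::map_dfr(spec$times_modeled, function(t) {
        tryCatch(contrast_vs_baseline(joined, NULL, spec, gr, t),
                 ncountr_error = function(e) NULL)
      })
    })
    rows[[g]] <- dplyr::mutate(dplyr::bind_rows(between, within),
                               gene = g, .before = 1)
    lsm[[g]] <- dplyr::mutate(fit$lsmeans, gene = g, .before = 1)
  }
  contrasts <- dplyr::bind_rows(rows)
  if (adjust_p && nrow(contrasts) > 0) {
    contrasts$p_adj <- stats::p.adjust(contrasts$p_value, method = "BH")
  }
  structure(list(fits = fits, contrasts = contrasts,
                 lsmeans = dplyr::bind_rows(lsm), skipped = skipped),
            class = "ncountr_de_result")
}

#' Residual normality diagnostics
#'
#' Shapiro-Wilk and Anderson-Darling tests on the marginal standardized
#' residuals. Advisory only; never gates a fit.
#'
#' @param fit A `ncountr_gene_fit`.
#' @return Tibble: `shapiro_w`, `shapiro_p`, `anderson_darling_a2`,
#'   `anderson_darling_p`.
#' @export
residual_normality <- function(fit) {
  res <- fit$model_frame$value - drop(fit$X %*% fit$beta)
  if (length(res) < 8) {
    stop_ncountr("need >= 8 residuals", "ncountr_insufficient_data_error")
  }
  if (stats::sd(res) == 0) {
    stop_ncountr("residuals are constant; normality tests undefined",
                 "ncountr_insufficient_data_error")
  }
  std <- res / (sqrt(fit$sigma2))
  sw <- stats::shapiro.test(std)
  ad <- nortest::ad.test(std)
  tibble::tibble(shapiro_w = unname(sw$statistic),
                 shapiro_p = sw$p.value,
                 anderson_darling_a2 = unname(ad$statistic),
                 anderson_darling_p = ad$p.value)
}

#' @export
print.ncountr_gene_fit <- function(x, ...) {
  cat("<ncountr_gene_fit>", x$gene, "- rho =", signif(x$rho, 4),
      ", sigma2 =", signif(x$sigma2, 4), ", REML logLik =",
      signif(x$reml_loglik, 6), "\n")
  invisible(x)
}

#' @export
print.ncountr_de_result <- function(x, ...) {
  cat("<ncountr_de_result>", length(x$fits), "genes fitted,",
      nrow(x$skipped), "skipped\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy ncountr_gene_fit
tidy.ncountr_gene_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                 std.error = unname(x$beta_se),
                 statistic = unname(x$beta / x$beta_se))
}

#' @export
#' @method glance ncountr_gene_fit
glance.ncountr_gene_fit <- function(x, ...) {
  tibble::tibble(rho = x$rho, sigma2 = x$sigma2,
                 reml_loglik = x$reml_loglik, n_obs = x$n_obs,
                 n_animals = x$n_animals,
                 df_within = x$df_within, df_between = x$df_between)
}

#' @export
#' @method tidy ncountr_de_result
tidy.ncountr_de_result <- function(x, ...) x$contrasts

#' @export
#' @method glance ncountr_de_result
glance.ncountr_de_result <- function(x, ...) {
  tibble::tibble(n_genes = length(x$fits), n_skipped = nrow(x$skipped),
                 n_significant = sum(x$contrasts$significant))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
#' @method autoplot ncountr_gene_fit
autoplot.ncountr_gene_fit <- function(object, ...) {
  ggplot2::ggplot(object$lsmeans,
                  ggplot2::aes(x = factor(.data$time_h), y = .data$estimate,
                               colour = .data$group, group = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$se,
                                        ymax = .data$estimate + .data$se),
                           width = 0.15,
                           position = ggplot2::position_dodge(0.2)) +
    ggplot2::labs(title = object$gene, x = "time (h)",
                  y = "least-squares mean ± SE")
}

#' @export
#' @method autoplot ncountr_de_result
autoplot.ncountr_de_result <- function(object, ...) {
  ggplot2::ggplot(object$lsmeans,
                  ggplot2::aes(x = factor(.data$time_h), y = .data$estimate,
                               colour = .data$group, group = .data$group)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$se,
                                        ymax = .data$estimate + .data$se),
                           width = 0.15) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "least-squares mean ± SE")
}
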