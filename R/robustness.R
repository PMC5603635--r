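#' Bland-Altman error summary
#'
#' Bias (arithmetic mean) and scatter (sample standard deviation, n-1
#' denominator) of a set of measurement errors, the two numbers a
#' Bland-Altman agreement analysis reports: the bias is the systematic error
#' of the tested method against the reference, the SD its precision.
#'
#' @param errors Numeric vector of errors (estimate - reference), at least
#'   2 finite values.
#' @return A list with `bias`, `sd` and `n`.
#' @export
bland_altman <- function(errors) {
  errors <- errors[is.finite(errors)]
  vr_check(length(errors) >= 2, "at least 2 finite error values are required",
           "invalid_parameter")
  list(bias = mean(errors), sd = stats::sd(errors), n = length(errors))
}

#' Compare the scatters of two estimators with an F test
#'
#' Two-sided F test on the ratio of the two sample variances, with the
#' larger variance in the numerator (so F >= 1 by construction). The test is
#' preceded by an Anderson-Darling normality check of each error sample,
#' whose p-values are reported; a normality failure triggers a warning but
#' does not gate the F test, since both are reported side by side.
#'
#' @param errors_a,errors_b Numeric error vectors (>= 2 finite values each).
#' @param alpha Significance level (default 0.01).
#' @return An object of class `variance_comparison` with `f_statistic`,
#'   `df` (numerator, denominator), `p_value`, `significant_at_alpha`,
#'   `alpha`, `normality_p` (length 2, NA when n < 8) and the two sample
#'   sizes.
#' @export
compare_variances <- function(errors_a, errors_b, alpha = 0.01) {
  a <- errors_a[is.finite(errors_a)]
  b <- errors_b[is.finite(errors_b)]
  vr_check(length(a) >= 2 && length(b) >= 2,
           "both samples need at least 2 finite values", "invalid_parameter")
  va <- stats::var(a); vb <- stats::var(b)
  vr_check(va > 0 || vb > 0, "both samples have zero variance; F undefined",
           "undefined_ratio")
  norm_p <- vapply(list(a, b), function(x) {
    if (length(x) >= 8 && stats::sd(x) > 0) nortest::ad.test(x)$p.value
    else NA_real_
  }, numeric(1))
  if (any(!is.na(norm_p) & norm_p < alpha))
    warning("error sample departs from normality (Anderson-Darling p < alpha); ",
            "F test reported anyway", call. = FALSE)
  if (va >= vb) {
    f <- va / vb; df <- c(length(a) - 1L, length(b) - 1L)
  } else {
    f <- vb / va; df <- c(length(b) - 1L, length(a) - 1L)
  }
  p <- min(1, 2 * stats::pf(f, df[1], df[2], lower.tail = FALSE))
  structure(list(f_statistic = f, df = df, p_value = p,
                 significant_at_alpha = p < alpha, alpha = alpha,
                 normality_p = norm_p, n = c(length(a), length(b))),
            class = "variance_comparison")
}

#' @export
print.variance_comparison <- function(x, ...) {
  cat(sprintf("<variance_comparison> F(%d, %d) = %.4g, p = %.3g%s\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value,
              if (x$significant_at_alpha)
                sprintf(" (significant at alpha = %g)", x$alpha) else ""))
  invisible(x)
}

# Deterministic per-(breath, level) noise sub-seed: derived from the master
# seed by a counter scheme (level enters by value, < 64), so extending the
# level grid never reshuffles existing draws. Always < 2^31.
noise_subseed <- function(master_seed, breath_index, level_percent) {
  as.integer((as.numeric(master_seed) %% 65521) * 32768 +
               (breath_index - 1) * 64 + round(level_percent))
}

#' Run the full perturbation sweep over a breath pool
#'
#' For each perturbation kind (random noise RN, transient disconnection TD)
#' and each severity level, every regular breath in the pool is perturbed
#' (one fresh noise realisation per breath per level, seeded deterministically
#' from the master seed), compliance is estimated with both the multilinear
#' fit and the network, and the error against the interrupter-technique
#' reference of the paired hold breath is recorded. Per level, the
#' Bland-Altman bias/SD of each estimator and an F test comparing the two
#' scatters are computed.
#'
#' Non-physical multilinear fits enter the statistics as their numeric
#' values — a naive monitor would report them — while non-finite estimates
#' (singular fits) are excluded from bias/SD with their count reported.
#'
#' @param pool A `breath_pool` from [generate_pool()].
#' @param ann_model A trained `ann_model` (or `NULL` to sweep only the
#'   multilinear fit).
#' @param kinds Character subset of `c("RN", "TD")`.
#' @param levels Severity grid in percent; default 0, 2, ..., 50 (level 0 is
#'   the unperturbed baseline).
#' @param master_seed Master seed for the noise draws.
#' @param mlf_window MLF fitting window: `NULL` (default) fits the whole
#'   breath, mirroring the reference method's whole-breath averaging;
#'   `"inspiratory"` fits each breath's inspiratory limb plus the
#'   valve-closure transition sample (the pure constant-flow limb leaves
#'   resistance and PEEP unidentifiable); or a global `c(first, last)` range.
#' @param volume_scale Passed to [build_input_pattern()].
#' @param alpha Significance level of the per-level F tests.
#' @param plateau_window Passed to [interrupter_crs()].
#' @return An object of class `sweep_result`: a list with `tables` (named
#'   list of per-estimator-per-kind data frames: level, bias, sd, n,
#'   n_excluded), `comparisons` (data frame: kind, level, f, p, significant,
#'   normality p per estimator), `errors` (long data frame of every error
#'   record) and `references` (per-breath reference compliances).
#' @export
run_sweep <- function(pool, ann_model = NULL,
                      kinds = c("RN", "TD"),
                      levels = seq(0, 50, by = 2),
                      master_seed = 1,
                      mlf_window = NULL,
                      volume_scale = "paw_max",
                      alpha = 0.01,
                      plateau_window = 0.2) {
  stopifnot(inherits(pool, "breath_pool"))
  kinds <- match.arg(kinds, c("RN", "TD"), several.ok = TRUE)
  if (!is.null(ann_model)) {
    stopifnot(inherits(ann_model, "ann_model"))
    vr_check(isTRUE(ann_model$trained), "ann_model must be trained",
             "invalid_configuration")
  }
  estimators <- c("MLF", if (!is.null(ann_model)) "ANN")
  n_pool <- length(pool)
  refs <- vapply(pool, function(rec)
    interrupter_crs(rec$hold, plateau_window = plateau_window)$c_rs_ref,
    numeric(1))

  recs <- vector("list", length(kinds) * length(levels) * n_pool)
  k <- 0L
  for (kind in kinds) {
    for (lev in levels) {
      for (i in seq_len(n_pool)) {
        br <- pool[[i]]$regular
        pert <- if (kind == "RN")
          add_random_noise(br, lev, seed = noise_subseed(master_seed, i, lev))
        else apply_disconnection(br, lev)
        win <- if (identical(mlf_window, "inspiratory"))
          c(br$insp_start, min(br$insp_end, length(br$paw)))
        else mlf_window
        est_mlf <- tryCatch(mlf_estimate_crs(pert, window = win),
                            ventrobust_error = function(e) {
                              warning(sprintf("MLF failed on breath %d (%s %g%%): %s",
                                              i, kind, lev, conditionMessage(e)),
                                      call. = FALSE)
                              NA_real_
                            })
        est_ann <- if (!is.null(ann_model))
          ann_estimate_crs(ann_model, pert, volume_scale = volume_scale)
        else NA_real_
        k <- k + 1L
        recs[[k]] <- data.frame(breath = i, kind = kind, level = lev,
                                reference = refs[i],
                                MLF = est_mlf, ANN = est_ann)
      }
    }
  }
  errors <- do.call(rbind, recs)
  for (est in estimators)
    errors[[paste0("err_", est)]] <- errors[[est]] - errors$reference

  tables <- list()
  for (est in estimators) {
    for (kind in kinds) {
      rows <- lapply(levels, function(lev) {
        e <- errors[errors$kind == kind & errors$level == lev,
                    paste0("err_", est)]
        ba <- bland_altman(e)
        data.frame(level = lev, bias = ba$bias, sd = ba$sd, n = n_pool,
                   n_excluded = sum(!is.finite(e)))
      })
      tables[[paste0(est, "_", kind)]] <- do.call(rbind, rows)
    }
  }

  comparisons <- NULL
  if (!is.null(ann_model)) {
    comparisons <- do.call(rbind, lapply(kinds, function(kind) {
      do.call(rbind, lapply(levels, function(lev) {
        sub <- errors[errors$kind == kind & errors$level == lev, ]
        vc <- withCallingHandlers(
          compare_variances(sub$err_MLF, sub$err_ANN, alpha = alpha),
          warning = function(w) invokeRestart("muffleWarning"))
        data.frame(kind = kind, level = lev,
                   f_statistic = vc$f_statistic, p_value = vc$p_value,
                   significant = vc$significant_at_alpha,
                   normality_p_mlf = vc$normality_p[1],
                   normality_p_ann = vc$normality_p[2])
      }))
    }))
  }

  structure(list(tables = tables, comparisons = comparisons,
                 errors = errors,
                 references = data.frame(breath = seq_len(n_pool),
                                         c_rs_ref = refs),
                 master_seed = master_seed, levels = levels, kinds = kinds),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", paste(x$kinds, collapse = " + "), " sweep, ",
      length(x$levels), " levels x ", nrow(x$references), " breaths\n", sep = "")
  for (nm in names(x$tables)) {
    tab <- x$tables[[nm]]
    cat(sprintf("  %s: bias %.3g .. %.3g, SD %.3g .. %.3g ml/cmH2O\n", nm,
                min(tab$bias), max(tab$bias), min(tab$sd), max(tab$sd)))
  }
  invisible(x)
}

#' Write the sweep tables as delimited text
#'
#' Writes one tab-separated table per perturbation kind (columns: level,
#' mlf_bias, mlf_sd, ann_bias, ann_sd — errors are estimate minus reference,
#' in ml/cmH2O) plus the per-level variance-comparison table.
#'
#' @param result A `sweep_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sweep_tables <- function(result, dir) {
  stopifnot(inherits(result, "sweep_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (kind in result$kinds) {
    mlf <- result$tables[[paste0("MLF_", kind)]]
    ann <- result$tables[[paste0("ANN_", kind)]]
    tab <- data.frame(level = mlf$level, mlf_bias = mlf$bias, mlf_sd = mlf$sd)
    if (!is.null(ann)) { tab$ann_bias <- ann$bias; tab$ann_sd <- ann$sd }
    p <- file.path(dir, sprintf("error_table_%s.tsv", tolower(kind)))
    utils::write.table(tab, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(result$comparisons)) {
    p <- file.path(dir, "variance_comparison.tsv")
    utils::write.table(result$comparisons, p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Bland-Altman scatter plot for one sweep condition
#'
#' Plots error (estimate - reference) against the reference compliance for
#' both estimators at one kind/level, with dashed bias and bias +/- 2 SD
#' lines per estimator. Base graphics; intended as a quick visual analogue
#' of the per-level agreement panels.
#'
#' @param result A `sweep_result`.
#' @param kind `"RN"` or `"TD"`.
#' @param level A level present in the sweep grid.
#' @param ylim Optional y-axis limits (the MLF errors under disconnection can
#'   dwarf everything else).
#' @return Invisibly, the subset of error records plotted.
#' @export
plot_bland_altman <- function(result, kind, level, ylim = NULL) {
  stopifnot(inherits(result, "sweep_result"))
  sub <- result$errors[result$errors$kind == kind & result$errors$level == level, ]
  vr_check(nrow(sub) > 0, "no records for that kind/level", "invalid_parameter")
  has_ann <- "err_ANN" %in% names(sub) && any(is.finite(sub$err_ANN))
  ys <- c(sub$err_MLF, if (has_ann) sub$err_ANN)
  if (is.null(ylim)) ylim <- range(ys[is.finite(ys)])
  plot(sub$reference, sub$err_MLF, pch = 1, col = "firebrick", ylim = ylim,
       xlab = "reference C_RS [ml/cmH2O]",
       ylab = "error (estimate - reference) [ml/cmH2O]",
       main = sprintf("%s at %g%%", kind, level))
  if (has_ann) graphics::points(sub$reference, sub$err_ANN, pch = 3,
                                col = "steelblue")
  for (est in c("MLF", if (has_ann) "ANN")) {
    e <- sub[[paste0("err_", est)]]
    ba <- bland_altman(e)
    col <- if (est == "MLF") "firebrick" else "steelblue"
    graphics::abline(h = ba$bias, col = col, lty = 2)
    graphics::abline(h = ba$bias + c(-2, 2) * ba$sd, col = col, lty = 3)
  }
  graphics::legend("topright", legend = c("MLF", if (has_ann) "ANN"),
                   col = c("firebrick", if (has_ann) "steelblue"),
                   pch = c(1, if (has_ann) 3), bty = "n")
  invisible(sub)
}
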