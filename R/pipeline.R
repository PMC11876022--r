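ivw_with_switch <- function(h, config) {
  d <- harmonized_rows(h)
  if (nrow(d) == 1) return(wald_ratio(d))
  fixed <- mr_ivw(d, "fixed")
  if (fixed$q_pval < config$het_p_switch) mr_ivw(d, "random") else fixed
}

# Instruments for one exposure, then harmonize against an outcome table.
instrument_and_harmonize <- function(exposure, outcome, ld, config) {
  ins <- select_instruments(exposure, ld,
                            p_thresh = config$p_thresh,
                            r2_thresh = config$r2_thresh,
                            window_kb = config$window_kb,
                            f_min = config$f_min,
                            f_k_mode = config$f_k_mode,
                            r2_formula = config$r2_formula)
  if (ins$k < 1) return(list(instruments = ins, harmonized = NULL))
  keep <- as.data.frame(exposure)
  keep <- keep[keep$snp %in% ins$snps$snp, , drop = FALSE]
  h <- harmonize(summary_stats(keep, trait_id = trait_id(exposure)), outcome,
                 palindrome_policy = config$palindrome_policy,
                 eaf_window = config$eaf_window)
  list(instruments = ins, harmonized = h)
}

#' Univariate causal screen of many exposures against one outcome
#'
#' For each exposure: select instruments, harmonize against the outcome,
#' run the estimator battery ([mr_all()]) and the sensitivity battery
#' ([sensitivity_report()]). An exposure passes the screen when its
#' headline IVW p-value is below `config$alpha` (after the optional
#' `config$p_adjust` correction across exposures) and the Steiger test
#' supports the exposure-to-outcome direction with Steiger p below
#' `config$alpha`.
#'
#' @param exposures List of [summary_stats()] objects (named or not).
#' @param outcome [summary_stats()] object.
#' @param ld [ld_matrix()] covering all candidate instruments.
#' @param config [mr_config()].
#' @return List of class `mr_screen`: `estimates` (long data.frame over
#'   exposures and methods), `screen` (one row per exposure: `exposure`,
#'   `nsnp`, `ivw_beta`, `ivw_se`, `ivw_pval`, `steiger_direction`,
#'   `steiger_pval`, `passed`, `note`), and `sensitivity` (named list of
#'   reports).
#' @export
run_univariate_screen <- function(exposures, outcome, ld, config = mr_config()) {
  if (length(exposures) == 0) {
    return(structure(list(estimates = data.frame(), screen = data.frame(),
                          sensitivity = list()), class = "mr_screen"))
  }
  est_rows <- list()
  screen_rows <- list()
  sens_all <- list()
  for (i in seq_along(exposures)) {
    ex <- exposures[[i]]
    id <- trait_id(ex)
    res <- instrument_and_harmonize(ex, outcome, ld, config)
    if (is.null(res$harmonized) ||
        nrow(harmonized_rows(res$harmonized)) < 1) {
      screen_rows[[i]] <- data.frame(
        exposure = id, nsnp = 0L, ivw_beta = NA_real_, ivw_se = NA_real_,
        ivw_pval = NA_real_, steiger_direction = NA, steiger_pval = NA_real_,
        passed = FALSE, note = "no surviving instrument",
        stringsAsFactors = FALSE)
      next
    }
    h <- res$harmonized
    ests <- mr_all(h, n_boot = config$n_boot, seed = config$seed,
                   bandwidth_factor = config$bandwidth_factor,
                   het_p_switch = config$het_p_switch)
    ests <- data.frame(exposure = id, ests, stringsAsFactors = FALSE)
    ests$or_95ci <- sprintf("%.6f (%.6f, %.6f)", ests$or, ests$ci_low,
                            ests$ci_high)
    est_rows[[i]] <- ests
    sens <- sensitivity_report(h, alpha = config$alpha)
    sens_all[[id]] <- sens
    head_method <- if ("ivw" %in% ests$method) "ivw" else "wald_ratio"
    head <- ests[ests$method == head_method, ][1, ]
    st <- sens$steiger
    screen_rows[[i]] <- data.frame(
      exposure = id, nsnp = head$nsnp,
      ivw_beta = head$beta, ivw_se = head$se, ivw_pval = head$pval,
      steiger_direction = if (is.null(st)) NA else st$direction_correct,
      steiger_pval = if (is.null(st)) NA_real_ else st$steiger_pval,
      passed = NA, note = "", stringsAsFactors = FALSE)
  }
  screen <- do.call(rbind, screen_rows)
  adj <- stats::p.adjust(screen$ivw_pval, method = config$p_adjust)
  screen$ivw_pval_adj <- adj
  screen$passed <- !is.na(adj) & adj < config$alpha &
    !is.na(screen$steiger_direction) & screen$steiger_direction &
    !is.na(screen$steiger_pval) & screen$steiger_pval < config$alpha
  rownames(screen) <- NULL
  estimates <- if (length(est_rows)) do.call(rbind, est_rows) else data.frame()
  rownames(estimates) <- NULL
  structure(list(estimates = estimates, screen = screen,
                 sensitivity = sens_all),
            class = "mr_screen")
}

#' @export
print.mr_screen <- function(x, ...) {
  cat(sprintf("Univariate screen: %d exposure(s), %d passed\n",
              nrow(x$screen), sum(x$screen$passed)))
  if (nrow(x$screen)) print(x$screen, row.names = FALSE)
  invisible(x)
}

#' Mediation workflow: screen, pair, joint model, classify
#'
#' Reproduces the staged screening design:
#' \enumerate{
#'   \item univariate screen of every exposure and every mediator against
#'     the outcome (IVW p and Steiger direction, [run_univariate_screen()]);
#'     both must pass;
#'   \item univariate MR of each surviving exposure on each surviving
#'     mediator; pairs must be significant with Steiger support;
#'   \item for each surviving pair, a two-exposure multivariable MR on the
#'     outcome and the product-of-coefficients mediation with Sobel test
#'     and stepwise classification ([estimate_mediation()]).
#' }
#'
#' @param exposures,mediators Lists of [summary_stats()] objects.
#' @param outcome [summary_stats()] object.
#' @param ld [ld_matrix()].
#' @param config [mr_config()].
#' @return List of class `mr_mediation_workflow`: `exposure_screen`,
#'   `mediator_screen` (stage-1 `mr_screen` objects), `pair_screen`
#'   (stage-2 table), `models` (list of `mr_mediation`), `mediation`
#'   (flat table via [mediation_table()]), `counts` (records surviving each
#'   stage).
#' @export
run_mediation_workflow <- function(exposures, mediators, outcome, ld,
                                   config = mr_config()) {
  scr_exp <- run_univariate_screen(exposures, outcome, ld, config)
  scr_med <- run_univariate_screen(mediators, outcome, ld, config)
  keep_exp <- exposures[vapply(exposures, trait_id, character(1)) %in%
                          scr_exp$screen$exposure[scr_exp$screen$passed]]
  keep_med <- mediators[vapply(mediators, trait_id, character(1)) %in%
                          scr_med$screen$exposure[scr_med$screen$passed]]

  pair_rows <- list()
  models <- list()
  model_i <- 0
  for (ex in keep_exp) {
    for (md in keep_med) {
      res <- instrument_and_harmonize(ex, md, ld, config)
      pair_id <- paste(trait_id(ex), trait_id(md), sep = " -> ")
      if (is.null(res$harmonized) ||
          nrow(harmonized_rows(res$harmonized)) < 1) {
        pair_rows[[pair_id]] <- data.frame(
          exposure = trait_id(ex), mediator = trait_id(md),
          ivw_pval = NA_real_, steiger_direction = NA, passed = FALSE,
          note = "no surviving instrument", stringsAsFactors = FALSE)
        next
      }
      fit <- ivw_with_switch(res$harmonized, config)
      st <- tryCatch(steiger_test(res$harmonized), error = function(e) NULL)
      ok <- fit$pval < config$alpha && !is.null(st) &&
        st$direction_correct && st$steiger_pval < config$alpha
      pair_rows[[pair_id]] <- data.frame(
        exposure = trait_id(ex), mediator = trait_id(md),
        ivw_pval = fit$pval,
        steiger_direction = if (is.null(st)) NA else st$direction_correct,
        passed = ok, note = "", stringsAsFactors = FALSE)
      if (!ok) next
      model_i <- model_i + 1
      model_id <- sprintf("model_%d", model_i)
      med <- tryCatch(
        estimate_mediation(ex, md, outcome, ld, config, model_id = model_id),
        error = function(e) e)
      if (inherits(med, "error")) {
        pair_rows[[pair_id]]$note <- paste("mediation failed:",
                                           conditionMessage(med))
        next
      }
      models[[model_id]] <- med
    }
  }
  pair_screen <- if (length(pair_rows)) do.call(rbind, pair_rows) else data.frame()
  rownames(pair_screen) <- NULL
  counts <- data.frame(
    stage = c("exposures_in", "exposures_passed", "mediators_in",
              "mediators_passed", "pairs_tested", "pairs_passed",
              "models_fitted"),
    n = c(length(exposures), length(keep_exp), length(mediators),
          length(keep_med), nrow(pair_screen),
          sum(pair_screen$passed %||% logical(0)), length(models)))
  structure(list(exposure_screen = scr_exp, mediator_screen = scr_med,
                 pair_screen = pair_screen, models = models,
                 mediation = if (length(models)) mediation_table(models)
                             else data.frame(),
                 counts = counts),
            class = "mr_mediation_workflow")
}

#' @export
print.mr_mediation_workflow <- function(x, ...) {
  cat("Mediation workflow\n")
  print(x$counts, row.names = FALSE)
  if (nrow(x$mediation)) {
    cat("\nModels:\n")
    print(x$mediation[, c("model", "exposure", "mediator", "beta_m",
                          "sobel_pval", "classification", "proportion")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Persist a screen or workflow result as TSV/JSON files
#'
#' Writes the estimate and screen tables of an `mr_screen` (estimates.tsv,
#' screen.tsv, one sensitivity JSON per exposure) or the stage tables of an
#' `mr_mediation_workflow` (exposure/mediator screens, pair_screen.tsv,
#' mediation.tsv, counts.tsv) under `dir`. Every number in the final
#' mediation table is recomputable from the persisted intermediates.
#'
#' @param x `mr_screen` or `mr_mediation_workflow`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "mr_screen")) {
    write_tsv(x$estimates, file.path(dir, "estimates.tsv"))
    write_tsv(x$screen, file.path(dir, "screen.tsv"))
    for (id in names(x$sensitivity)) {
      write_sensitivity(x$sensitivity[[id]],
                        file.path(dir, paste0("sensitivity_", id, ".json")))
    }
  } else if (inherits(x, "mr_mediation_workflow")) {
    write_results(x$exposure_screen, file.path(dir, "exposure_screen"))
    write_results(x$mediator_screen, file.path(dir, "mediator_screen"))
    write_tsv(x$pair_screen, file.path(dir, "pair_screen.tsv"))
    write_tsv(x$mediation, file.path(dir, "mediation.tsv"))
    write_tsv(x$counts, file.path(dir, "counts.tsv"))
  } else {
    stop("unsupported object", call. = FALSE)
  }
  invisible(dir)
}
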