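# Orchestration of the factorial simulation: 3 calibration model sets x 3
# IRT scaling methods x 4 ability shifts, with replications and the
# discard-and-regenerate rule for non-convergent calibrations.

.scaling_methods <- c("MS", "SL", "FCIP")
.default_shifts <- c(0.00, 0.10, 0.25, 0.50)

#' A single study condition
#'
#' @param model_set calibration model set (see [calibration_config()]).
#' @param scaling `"MS"`, `"SL"`, or `"FCIP"`.
#' @param shift new-year ability mean shift (study values 0.00, 0.10,
#'   0.25, 0.50).
#' @return list of class `"study_condition"`.
#' @export
study_condition <- function(model_set, scaling, shift) {
  model_set <- match.arg(model_set, .model_sets)
  scaling <- match.arg(scaling, .scaling_methods)
  if (!is.finite(shift)) stop("shift must be finite")
  structure(list(model_set = model_set, scaling = scaling, shift = shift),
            class = "study_condition")
}

#' Study configuration
#'
#' Defaults reproduce the full design scale (50,000 examinees, 50
#' replications, 60-node grid); simulations at reduced scale are obtained
#' by lowering `n` and `replications` and, optionally, the grid size.
#'
#' @param n examinees per administration (>= 100).
#' @param replications replications per condition (>= 1).
#' @param seed master seed; every random draw in the study derives from it.
#' @param generator_spec an [item_generator_spec()].
#' @param prior a [prior_spec()] shared by all calibrations.
#' @param conv_tol,max_cycles EM convergence settings.
#' @param grid a [quadrature_grid()].
#' @param model_sets,scalings,shifts condition filters (defaults: the full
#'   3 x 3 x 4 design).
#' @param x_cuts Form X cut scores, default `c(21, 37, 49)`.
#' @param retry_cap maximum regenerations of one dataset before aborting.
#' @param D logistic scaling constant.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return list of class `"study_config"`.
#' @export
study_config <- function(n = 50000L, replications = 50L, seed = 1L,
                         generator_spec = item_generator_spec(),
                         prior = prior_spec(),
                         conv_tol = 0.001, max_cycles = 200L,
                         grid = quadrature_grid(),
                         model_sets = .model_sets,
                         scalings = .scaling_methods,
                         shifts = .default_shifts,
                         x_cuts = c(21, 37, 49),
                         retry_cap = 10L, D = default_D(),
                         out_dir = NULL) {
  if (n < 100) stop("n must be >= 100")
  if (replications < 1) stop("replications must be >= 1")
  model_sets <- match.arg(model_sets, .model_sets, several.ok = TRUE)
  scalings <- match.arg(scalings, .scaling_methods, several.ok = TRUE)
  structure(list(n = as.integer(n), replications = as.integer(replications),
                 seed = as.integer(seed), generator_spec = generator_spec,
                 prior = prior, conv_tol = conv_tol,
                 max_cycles = as.integer(max_cycles), grid = grid,
                 model_sets = model_sets, scalings = scalings,
                 shifts = shifts, x_cuts = x_cuts,
                 retry_cap = as.integer(retry_cap), D = D,
                 out_dir = out_dir),
            class = "study_config")
}

.cal_cfg <- function(config, model_set, mode = "separate") {
  calibration_config(model_set = model_set, prior = config$prior,
                     conv_tol = config$conv_tol,
                     max_cycles = config$max_cycles, mode = mode,
                     D = config$D)
}

.anchor_rows <- function(df) df[df$role == "anchor", , drop = FALSE]
.unique_rows <- function(df) df[df$role == "unique", , drop = FALSE]

# Generate one administration and calibrate it under every requested model
# set (separately and, for the new year, by FCIP), regenerating the data
# with a fresh substream until every calibration converges.
.calibrated_administration <- function(form, label, shift, rep, config,
                                       need_sep = TRUE,
                                       fcip_anchors = NULL) {
  discards <- 0L
  for (attempt in 0:config$retry_cap) {
    th <- generate_abilities(
      config$n, shift,
      seed = derive_seed(config$seed, "theta", label, shift, rep, attempt))
    resp <- simulate_responses(
      form, th, config$D,
      seed = derive_seed(config$seed, "resp", label, shift, rep, attempt))
    sep_fits <- list()
    fcip_fits <- list()
    ok <- TRUE
    for (ms in config$model_sets) {
      if (need_sep) {
        fit <- calibrate(resp, .cal_cfg(config, ms), config$grid)
        if (!fit$converged) { ok <- FALSE; break }
        sep_fits[[ms]] <- fit
      }
      if (!is.null(fcip_anchors)) {
        fit <- calibrate_fcip(resp, fcip_anchors[[ms]],
                              .cal_cfg(config, ms, "fcip"), config$grid)
        if (!fit$converged) { ok <- FALSE; break }
        fcip_fits[[ms]] <- fit
      }
    }
    if (ok)
      return(list(resp = resp, fits = sep_fits, fcip_fits = fcip_fits,
                  discards = discards))
    discards <- discards + 1L
  }
  stop("calibration failed to converge after ", config$retry_cap,
       " regenerations (", label, ", shift ", shift, ", replication ",
       rep, ")")
}

#' Run the full misfit-consequence simulation study
#'
#' For each replication: simulates the reference (X+A) administration once
#' and calibrates it under every requested model set (shared across shifts
#' and scaling methods); then, for each ability shift, simulates the
#' new-year (Y+A) administration and calibrates it separately (for MS/SL)
#' and by FCIP against the reference anchor estimates. Estimated
#' conversion tables are built by IRT true-score equating and compared to
#' the true table from the generating parameters; examinees of each Y
#' cohort are classified under the true and estimated conversion-derived
#' cut scores. Any administration whose calibration fails to converge
#' under any model set is discarded and regenerated from a fresh
#' substream.
#'
#' @param config a [study_config()].
#' @return list of class `"study_result"`: `conditions` (per-condition
#'   aggregates), `table` (Table-1-analog data frame), `curves`
#'   (Figure-1-analog per-score MEE/RMSEE data frame), `true_table`,
#'   `params`, and `config`. If `config$out_dir` is set, writes
#'   `study_table.csv`, `error_curves.csv`, and `study_results.json`
#'   there.
#' @export
run_study <- function(config = study_config()) {
  params <- generate_item_parameters(config$generator_spec,
                                     seed = config$seed)
  true_table <- true_score_conversion(params$form_y, params$form_x,
                                      config$D)
  true_cuts <- derive_cut_scores(true_table, config$x_cuts)
  score_range <- true_table$nc_score[!true_table$extrapolated]
  form_xa <- rbind(params$form_x, params$anchor)
  form_ya <- rbind(params$form_y, params$anchor)
  uniq_cols <- which(form_ya$role == "unique")

  ckey <- function(ms, sc, sh) paste(ms, sc, format(sh, nsmall = 2))
  acc <- list()   # per condition: tables, reports, discards
  for (ms in config$model_sets) for (sc in config$scalings)
    for (sh in config$shifts)
      acc[[ckey(ms, sc, sh)]] <- list(tables = list(), reports = list(),
                                      discards = 0L)

  need_sep <- any(c("MS", "SL") %in% config$scalings)
  need_fcip <- "FCIP" %in% config$scalings

  for (rep in seq_len(config$replications)) {
    xadm <- .calibrated_administration(form_xa, "X", 0, rep, config)
    x_anchor_est <- lapply(xadm$fits,
                           function(f) .anchor_rows(f$params))
    for (sh in config$shifts) {
      yadm <- .calibrated_administration(
        form_ya, "Y", sh, rep, config, need_sep = need_sep,
        fcip_anchors = if (need_fcip) x_anchor_est else NULL)
      nc_y <- rowSums(unclass(yadm$resp)[, uniq_cols, drop = FALSE])
      pc_true <- classify(nc_y, true_cuts)

      for (ms in config$model_sets) {
        x_uniq_est <- .unique_rows(xadm$fits[[ms]]$params)
        for (sc in config$scalings) {
          y_on_x <- if (sc == "FCIP") {
            .unique_rows(yadm$fcip_fits[[ms]]$params)
          } else {
            yfit <- yadm$fits[[ms]]
            k <- if (sc == "MS") {
              ms_constants(x_anchor_est[[ms]], .anchor_rows(yfit$params))
            } else {
              sl_constants(x_anchor_est[[ms]], .anchor_rows(yfit$params),
                           config$grid, config$D)
            }
            .unique_rows(transform_item_parameters(yfit$params, k))
          }
          est_table <- true_score_conversion(y_on_x, x_uniq_est, config$D)
          est_cuts <- derive_cut_scores(est_table, config$x_cuts)
          pc_est <- classify(nc_y, est_cuts)
          key <- ckey(ms, sc, sh)
          acc[[key]]$tables[[length(acc[[key]]$tables) + 1L]] <- est_table
          acc[[key]]$reports[[length(acc[[key]]$reports) + 1L]] <-
            classification_report(pc_est, pc_true)
          acc[[key]]$discards <- acc[[key]]$discards + xadm$discards +
            yadm$discards
        }
      }
    }
  }

  conditions <- list()
  rows <- list()
  curve_rows <- list()
  for (ms in config$model_sets) for (sh in config$shifts)
    for (sc in config$scalings) {
      key <- ckey(ms, sc, sh)
      a <- acc[[key]]
      err <- equating_errors(a$tables, true_table, score_range)
      avg <- function(field) mean(vapply(a$reports, `[[`, 0, field))
      cls <- list(accuracy = avg("accuracy"), over = avg("over"),
                  under = avg("under"),
                  passing_estimated = avg("passing_estimated"),
                  passing_true = avg("passing_true"),
                  passing_misclassification =
                    avg("passing_misclassification"))
      conditions[[key]] <- structure(
        list(condition = study_condition(ms, sc, sh), errors = err,
             classification = cls, replications = length(a$tables),
             discarded = a$discards),
        class = "condition_result")
      rows[[key]] <- data.frame(
        shift = sh, model_set = ms, scaling = sc,
        remsee = err$remsee,
        dtm_flag = flag_practical_significance(err$remsee),
        accuracy = cls$accuracy, under = cls$under, over = cls$over,
        passing_rate = cls$passing_estimated,
        true_passing_rate = cls$passing_true,
        passing_misclassification = cls$passing_misclassification,
        replications = length(a$tables), discarded = a$discards)
      curve_rows[[key]] <- data.frame(
        shift = sh, model_set = ms, scaling = sc, score = err$score,
        mee = err$mee, rmsee = err$rmsee)
    }
  table1 <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  curves <- do.call(rbind, c(curve_rows, list(make.row.names = FALSE)))

  out <- structure(list(conditions = conditions, table = table1,
                        curves = curves, true_table = true_table,
                        params = params, config = config),
                   class = "study_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(table1, file.path(config$out_dir, "study_table.csv"),
              row.names = FALSE)
    write.csv(curves, file.path(config$out_dir, "error_curves.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(schema = "eqmisfit-study-1", table = table1,
           true_table = as.data.frame(true_table)),
      file.path(config$out_dir, "study_results.json"),
      dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run a single study condition
#'
#' Convenience wrapper around [run_study()] restricted to one
#' (model set, scaling method, ability shift) cell.
#'
#' @param condition a [study_condition()].
#' @param config a [study_config()]; its condition filters are overridden.
#' @return the cell's `"condition_result"`: equating-error summary,
#'   replication-averaged classification report, replication count, and
#'   the number of discarded (regenerated) datasets.
#' @export
run_condition <- function(condition, config = study_config()) {
  config$model_sets <- condition$model_set
  config$scalings <- condition$scaling
  config$shifts <- condition$shift
  res <- run_study(config)
  res$conditions[[1]]
}
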