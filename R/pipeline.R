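#' Trainer interfaces for cross-validation
#'
#' A trainer is a `fit`/`predict` pair consumed by [five_by_two_cv()]:
#' `mlp_trainer()` wraps the four-hidden-unit perceptron (a fresh, seeded
#' initialisation per fold); `lr_trainer()` wraps forward stepwise logistic
#' regression refitted within each training half (scores are the fitted
#' probabilities).
#'
#' @param config An [mlp_config()]; its seed is replaced by the per-fold
#'   seed supplied by the protocol.
#' @param n_hidden Hidden units.
#' @return List with elements `fit(X, y, seed)` and `predict(model, X)`.
#' @export
mlp_trainer <- function(config = mlp_config(), n_hidden = 4L) {
  list(
    fit = function(X, y, seed) {
      cfg <- config
      cfg$seed <- as.integer(seed %% (2^31 - 1))
      mlp_train(X, y, cfg, n_hidden = n_hidden)
    },
    predict = function(model, X) predict(model, X),
    label = "ANN"
  )
}

#' @rdname mlp_trainer
#' @param alpha_enter,alpha_stay Stepwise entry/stay levels.
#' @param stepwise If `FALSE`, fit the full model without selection.
#' @export
lr_trainer <- function(alpha_enter = 0.3, alpha_stay = 0.35, stepwise = TRUE) {
  list(
    fit = function(X, y, seed) {
      X <- as.data.frame(X)
      if (stepwise) {
        forward_stepwise(X, y, alpha_enter, alpha_stay)$fit
      } else {
        fit_logistic(X, y)
      }
    },
    predict = function(model, X) {
      X <- as.data.frame(X)
      M <- cbind(1, as.matrix(X[, model$terms, drop = FALSE]))
      stats::plogis(drop(M %*% model$coefficients))
    },
    label = "LR"
  )
}

#' Pipeline configuration
#'
#' @param endpoint `"sdi1"` (any morphometric fracture vs none) or `"sdi5"`
#'   (fracture burden SDI >= 5 vs none; SDI 1-4 excluded).
#' @param cohort A [cohort_config()] to simulate from, or a path to a cohort
#'   CSV (one row per patient, raw fields plus an `sdi` column).
#' @param twist A [twist_config()] for the selection stage.
#' @param mlp An [mlp_config()] for the cross-validated classifier arm.
#' @param seed Master seed; every stage seed is derived from it.
#' @param out_dir Output directory for the run's reports.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(endpoint = c("sdi1", "sdi5"),
                            cohort = cohort_config(),
                            twist = twist_config(),
                            mlp = mlp_config(),
                            seed = 1L,
                            out_dir = tempfile("sdiann-run-")) {
  endpoint <- match.arg(endpoint)
  if (is.character(cohort) && !file.exists(cohort)) {
    stop("cohort CSV does not exist: ", cohort, call. = FALSE)
  }
  structure(list(endpoint = endpoint, cohort = cohort, twist = twist,
                 mlp = mlp, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the end-to-end study replica
#'
#' Orchestrates every stage for one endpoint: simulate (or load) the cohort,
#' encode the 45-variable design, complete-case filter, evolutionary
#' split/mask selection, twin-perceptron 5x2 cross-validation on the
#' selected variables, forward stepwise logistic regression on all 45
#' variables over the identical partitions, and the paired ROC-AUC
#' comparison. Writes fold tables, the side-by-side summary, ROC point
#' CSVs, the selection result and a manifest of all derived seeds to
#' `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_run` (invisibly returns nothing extra):
#'   list with `ann`, `lr` (crossval reports), `twist`, `comparison`,
#'   `group_table`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(
    cohort = substream_seed(config$seed, "cohort"),
    twist = substream_seed(config$seed, "twist"),
    cv = substream_seed(config$seed, "cv")
  )

  if (is.character(config$cohort)) {
    records <- utils::read.csv(config$cohort)
    if (!"sdi" %in% names(records)) {
      stop("stage cohort: CSV must contain an `sdi` column", call. = FALSE)
    }
    sdi <- records$sdi
    source_desc <- config$cohort
  } else {
    cc <- config$cohort
    cc$seed <- seeds$cohort
    cohort <- generate_cohort(cc)
    records <- cohort$records
    sdi <- cohort$sdi
    source_desc <- sprintf("simulated n=%d", cc$n_patients)
  }

  encoded <- encode_features(records)
  spec <- attr(encoded, "spec")
  filtered <- exclude_incomplete(encoded, columns = spec$name)
  kept_ids <- filtered$kept$patient_id
  keep_row <- encoded$patient_id %in% kept_ids
  encoded <- filtered$kept
  sdi <- sdi[keep_row]

  status <- sdi_endpoint(sdi, config$endpoint)
  use <- status != "excluded"
  y <- as.integer(status[use] == "case")
  if (sum(y == 1) == 0L) {
    stop("stage endpoint (", config$endpoint, "): case group is empty",
         call. = FALSE)
  }
  if (sum(y == 0) == 0L) {
    stop("stage endpoint (", config$endpoint, "): control group is empty",
         call. = FALSE)
  }
  table45 <- encoded[use, , drop = FALSE]
  X_raw <- as.matrix(table45[, spec$name])
  scaled <- scale_inputs(table45, fit_on = seq_len(nrow(table45)))
  X_scaled <- as.matrix(scaled$table[, spec$name])

  tw_cfg <- config$twist
  tw_cfg$seed <- seeds$twist
  twist_res <- run_twist(X_scaled, y, tw_cfg)

  partitions <- make_partitions(y, seeds$cv)
  ann <- five_by_two_cv(X_scaled[, twist_res$selected, drop = FALSE], y,
                        mlp_trainer(config$mlp, tw_cfg$n_hidden),
                        seed = seeds$cv, partitions = partitions)
  lr <- five_by_two_cv(X_raw, y, lr_trainer(), seed = seeds$cv,
                       partitions = partitions)

  comparison <- compare_arms(ann, lr,
                             n_vars = c(length(twist_res$selected),
                                        length(spec$name)))

  cont_cols <- spec$name[spec$kind == "continuous"]
  yes_cols <- spec$name[grepl("(_yes$|^age_ge68$|^bmi_le21$|^calcium_le300_yes$)",
                              spec$name) & spec$kind == "binary"]
  group_table <- group_compare(table45[, c(cont_cols, setdiff(yes_cols, cont_cols))], y)

  manifest <- list(
    package_version = as.character(utils::packageVersion("sdiann")),
    endpoint = config$endpoint, source = source_desc,
    n_records = length(status), n_analysed = length(y),
    n_cases = sum(y), n_controls = sum(y == 0),
    master_seed = config$seed, stage_seeds = seeds,
    selected = twist_res$selected
  )

  run <- structure(list(ann = ann, lr = lr, twist = twist_res,
                        comparison = comparison, group_table = group_table,
                        manifest = manifest, out_dir = config$out_dir),
                   class = "pipeline_run")
  write_run(run)
  run
}

write_run <- function(run) {
  dir.create(run$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(run$out_dir, f)
  jsonlite::write_json(run$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  twist_to_json(run$twist, p("twist.json"))
  utils::write.table(run$ann$folds, p("ann_folds.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(run$lr$folds, p("lr_folds.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(run$comparison$summary, p("summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  roc6 <- function(r) data.frame(lapply(r$points, round, digits = 6))
  utils::write.csv(roc6(run$ann$roc), p("roc_ann.csv"), row.names = FALSE)
  utils::write.csv(roc6(run$lr$roc), p("roc_lr.csv"), row.names = FALSE)
  utils::write.table(run$group_table, p("group_table.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(run$comparison$auc_test, p("auc_comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(run$out_dir)
}

#' Side-by-side comparison of the two arms
#'
#' Builds the summary table (variables used, average sensitivity,
#' specificity, accuracy, AUC with a Hanley-McNeil 95\% CI per arm) and the
#' paired correlated-AUC z-test. Both reports must have been evaluated on
#' identical partitions.
#'
#' @param ann,lr `crossval_report` objects from [five_by_two_cv()].
#' @param n_vars Optional integer vector: variables used by each arm.
#' @return List with `summary` (two-row data frame) and `auc_test`
#'   (the [compare_auc()] result).
#' @export
compare_arms <- function(ann, lr, n_vars = c(NA_integer_, NA_integer_)) {
  stopifnot(inherits(ann, "crossval_report"), inherits(lr, "crossval_report"))
  if (!identical(ann$partitions, lr$partitions)) {
    stop("arms were evaluated on different partitions; rerun with shared ",
         "splits (same seed) for a paired comparison", call. = FALSE)
  }
  auc_test <- compare_auc(ann$roc, lr$roc, paired = TRUE)
  row_of <- function(label, rep, nv) {
    se <- auc_se_hanley(rep$roc$auc, rep$roc$n_cases, rep$roc$n_controls)
    data.frame(arm = label, n_vars = nv,
               sn = round_half_up(rep$averages$sn, 1),
               sp = round_half_up(rep$averages$sp, 1),
               accuracy = round_half_up(rep$averages$accuracy, 1),
               auc = rep$roc$auc,
               auc_lo = max(0, rep$roc$auc - 1.96 * se),
               auc_hi = min(1, rep$roc$auc + 1.96 * se))
  }
  list(summary = rbind(row_of("ANN", ann, n_vars[1]),
                       row_of("LR", lr, n_vars[2])),
       auc_test = auc_test)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run (", x$manifest$endpoint, "): n =", x$manifest$n_analysed,
      "(", x$manifest$n_cases, "cases )\n")
  print(x$comparison$summary, row.names = FALSE)
  cat(sprintf("paired AUC comparison: z = %.3f, p = %.4g\n",
              x$comparison$auc_test$z, x$comparison$auc_test$p))
  invisible(x)
}
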