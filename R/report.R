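#' Path to a bundled example series configuration
#'
#' The package ships a small example series for the haloalkane dehalogenase
#' (DhlA) SN2 step — acetate attacking 1,2-dichloroethane — across active-site
#' environments with three, two, one and zero aromatic residues plus aqueous
#' solution. Nucleophile and leaving-group charges are reported group
#' charges from QM cluster calculations of that system; the accompanying
#' geometries are synthetic placeholders (collinear O1-C1-Cl1 plus inert
#' padding atoms) constructed to carry the reported transition-state
#' C1--Cl1 and O1--C1 bond lengths, since full coordinates are not part of
#' the tabulated data. The zero-residue environment has no transition-state
#' geometry (its distance descriptor is not tabulated) and contributes only
#' its group charges. The water environment is flagged `role: predict` and
#' is therefore held out of every scaling fit.
#'
#' @param which `"free_energy"` (default) for the free-energy barrier
#'   series, or `"potential_energy"` for the potential-energy variant.
#' @return Path to the bundled YAML config, loadable by [load_series()].
#' @examples
#' series <- load_series(dhla_example_config())
#' descriptor_table(series)
#' @export
dhla_example_config <- function(which = c("free_energy",
                                          "potential_energy")) {
  which <- match.arg(which)
  f <- switch(which,
              free_energy = "series.yaml",
              potential_energy = "series_potential_energy.yaml")
  system.file("extdata", "dhla", f, package = "catdesc", mustWork = TRUE)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(stage, ": ", conditionMessage(e), call. = FALSE))
}

#' End-to-end descriptor analysis of a series
#'
#' Runs the whole pipeline on one series config: load and validate, compute
#' the descriptor table, fit a scaling line per descriptor over the fit
#' environments, score every `role: predict` environment with both lines,
#' check the reactivity ordering, and (optionally) report barrier
#' differences against a reference environment. All outputs are written
#' under `outdir` together with a run manifest recording the package
#' version, config checksum, seed, timestamp and per-stage status.
#'
#' @param config Path to a series YAML/JSON config (see [load_series()]).
#' @param outdir Output directory, created if needed.
#' @param seed Integer seed recorded in the manifest and set before the run
#'   (the pipeline itself is deterministic; the seed covers any stochastic
#'   extension).
#' @param reference Optional environment label for barrier differences.
#' @return Invisibly, a list with `series`, `table`, `models` (per
#'   descriptor), `predictions` (data.frame), `orders`, `differences` and
#'   `manifest`.
#' @export
run_report <- function(config, outdir, seed = 1L, reference = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  stages <- character(0L)
  done <- function(s) stages <<- c(stages, s)

  series <- run_stage("load", load_series(config))
  done("load")

  tab <- run_stage("descriptors", descriptor_table(series))
  write_descriptor_table(tab, file.path(outdir, "descriptors.tsv"))
  done("descriptors")

  fit_rows <- tab[!tab$predict_only, , drop = FALSE]
  if (any(is.na(fit_rows$barrier)))
    stop("scaling: missing barrier for fit environment(s) ",
         paste(fit_rows$label[is.na(fit_rows$barrier)], collapse = ", "),
         call. = FALSE)
  models <- list()
  for (d in c("dcat", "qcat")) {
    if (sum(!is.na(fit_rows[[d]])) >= 2L) {
      models[[d]] <- run_stage("scaling", fit_scaling(tab, d))
      write_scaling_model(models[[d]],
                          file.path(outdir, paste0("model_", d, ".json")))
    }
  }
  if (length(models) == 0L)
    stop("scaling: no descriptor has >= 2 fit environments", call. = FALSE)
  done("scaling")

  pred_rows <- tab[tab$predict_only, , drop = FALSE]
  predictions <- NULL
  if (nrow(pred_rows)) {
    predictions <- do.call(rbind, lapply(seq_len(nrow(pred_rows)),
      function(i) {
        do.call(rbind, lapply(names(models), function(d) {
          x <- pred_rows[[d]][i]
          if (is.na(x)) return(NULL)
          p <- predict(models[[d]], x)
          data.frame(label = pred_rows$label[i], descriptor = d,
                     x = x, predicted_barrier = p$fit,
                     se_pred = p$se_pred, extrapolated = p$extrapolated,
                     reported_barrier = pred_rows$barrier[i],
                     stringsAsFactors = FALSE)
        }))
      }))
    utils::write.table(predictions, file.path(outdir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  done("predict")

  orders <- list()
  for (d in names(models)) {
    orders[[d]] <- run_stage("ordering",
      reactivity_order(fit_rows, d))
  }
  done("ordering")

  differences <- NULL
  if (!is.null(reference)) {
    differences <- run_stage("compare", compare_environments(tab, reference))
    utils::write.table(
      data.frame(label = names(differences),
                 delta_barrier_kcal_mol = as.numeric(differences)),
      file.path(outdir, "barrier_differences.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  done("compare")

  summary_json <- list(
    models = lapply(models, function(m)
      list(descriptor = m$descriptor, slope = m$slope,
           intercept = m$intercept, r_squared = m$r_squared,
           residual_se = m$residual_se, n = m$n)),
    orders = lapply(orders, function(o)
      list(labels = o$labels, monotone = o$monotone, ties = o$ties)))
  jsonlite::write_json(summary_json, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  data_files <- setdiff(list.files(outdir), "manifest.json")
  manifest <- list(
    tool = "catdesc",
    version = as.character(utils::packageVersion("catdesc")),
    config = basename(config),
    config_md5 = unname(tools::md5sum(config)),
    seed = as.integer(seed),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    stages = stages,
    outputs = as.list(tools::md5sum(file.path(outdir, sort(data_files)))))
  names(manifest$outputs) <- sort(data_files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  done("manifest")

  invisible(list(series = series, table = tab, models = models,
                 predictions = predictions, orders = orders,
                 differences = differences, manifest = manifest))
}
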