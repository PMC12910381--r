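# Batch execution: parse a pipeline definition (JSON or YAML), run the chosen
# workflow end-to-end into an output directory, and leave exactly one marker
# file — zero-length pipeline.success, or pipeline.failure naming the failing
# stage. Failures never propagate past run_pipeline().

proteomics_option_defaults <- function() {
  list(min_group_fraction = 2 / 3, normalization = "none", imputation = "qrilc",
       fc_cutoffs = c(-1, 1), alpha = 0.01, seed = 42L,
       remove_contaminants = TRUE, contaminant_file = NULL,
       comparison_file = NULL, comparisons = NULL, control_group = NULL)
}

interactomics_option_defaults <- function() {
  list(pseudocount = 0.1, top_k = 3L, bfdr_max = 0.05, fc_a_min = 3,
       control_freq_max = 0.5, seed = 42L,
       remove_contaminants = TRUE, contaminant_file = NULL,
       control_group = NULL, saint_output = NULL,
       known_interactions = NULL, markers = NULL, annotations = NULL,
       enrichment = FALSE)
}

suggest_key <- function(key, valid) {
  d <- utils::adist(key, valid)
  hint <- valid[which.min(d)]
  if (min(d) <= 3) paste0("; did you mean '", hint, "'?") else ""
}

#' Parse a pipeline definition file
#'
#' The definition is a structured key-value document (JSON for `.json`, YAML
#' for `.yml`/`.yaml`) with top-level keys `workflow` (`"proteomics"` or
#' `"interactomics"`), `data_file`, `sample_table_file`, optional `seed`, and
#' an `options` block holding workflow-specific settings. Unknown workflow
#' names and unknown option keys are rejected with the list of valid keys
#' (and a closest-match suggestion). Interactomics definitions must designate
#' controls, either through an `is_control` sample-table column or an
#' `options$control_group`.
#'
#' @param path Definition file path.
#' @param base_dir Directory against which relative file paths are resolved;
#'   defaults to the definition's directory.
#' @return List of class `pipeline_definition` with defaults filled in.
#' @export
parse_pipeline_definition <- function(path, base_dir = dirname(path)) {
  ext <- tolower(tools::file_ext(path))
  def <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    stop("unrecognized definition extension '.", ext, "'; use .json, .yml or .yaml")
  )
  known_top <- c("workflow", "data_file", "sample_table_file", "options",
                 "seed", "versions")
  unknown <- setdiff(names(def), known_top)
  if (length(unknown)) {
    stop("unknown definition key(s): ", paste(unknown, collapse = ", "),
         suggest_key(unknown[1L], known_top),
         "; valid keys: ", paste(known_top, collapse = ", "))
  }
  if (is.null(def$workflow) || !def$workflow %in% c("proteomics", "interactomics")) {
    stop("workflow must be 'proteomics' or 'interactomics'; got '",
         if (is.null(def$workflow)) "" else def$workflow, "'")
  }
  for (f in c("data_file", "sample_table_file")) {
    if (is.null(def[[f]])) stop("definition is missing required key '", f, "'")
  }
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base_dir, p)
  }
  def$data_file <- resolve(def$data_file)
  def$sample_table_file <- resolve(def$sample_table_file)
  defaults <- if (def$workflow == "proteomics") proteomics_option_defaults()
              else interactomics_option_defaults()
  opts <- if (is.null(def$options)) list() else def$options
  unknown <- setdiff(names(opts), names(defaults))
  if (length(unknown)) {
    stop("unknown option key '", unknown[1L], "'",
         suggest_key(unknown[1L], names(defaults)),
         "; valid keys: ", paste(sort(names(defaults)), collapse = ", "))
  }
  merged <- utils::modifyList(defaults, opts, keep.null = TRUE)
  if (!is.null(def$seed)) merged$seed <- as.integer(def$seed)
  for (f in c("contaminant_file", "comparison_file", "saint_output",
              "known_interactions", "markers", "annotations")) {
    if (!is.null(merged[[f]])) merged[[f]] <- resolve(merged[[f]])
  }
  if (def$workflow == "interactomics" && is.null(merged$control_group)) {
    st <- tryCatch(read_sample_table(def$sample_table_file), error = function(e) NULL)
    if (is.null(st) || !any(st$is_control)) {
      stop("interactomics requires control designation: either an is_control ",
           "column in the sample table or options$control_group")
    }
  }
  structure(list(workflow = def$workflow, data_file = def$data_file,
                 sample_table_file = def$sample_table_file, options = merged),
            class = "pipeline_definition")
}

#' @export
print.pipeline_definition <- function(x, ...) {
  cat(sprintf("<pipeline_definition> %s workflow on %s\n", x$workflow, x$data_file))
  invisible(x)
}

#' Write the parameter record of a run
#'
#' Serializes every resolved option (defaults included), the seed, the input
#' files, and software versions as a JSON document that is itself a valid
#' pipeline definition, so a run can be reproduced by pointing
#' [parse_pipeline_definition()] at its own record.
#'
#' @param definition A [parse_pipeline_definition()] result.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_parameter_record <- function(definition, path) {
  rec <- list(
    workflow = definition$workflow,
    data_file = definition$data_file,
    sample_table_file = definition$sample_table_file,
    seed = definition$options$seed,
    options = definition$options,
    versions = list(
      protflow = as.character(utils::packageVersion("protflow")),
      r = paste(R.version$major, R.version$minor, sep = ".")
    )
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

write_marker <- function(outdir, success, message = NULL) {
  if (success) {
    file.create(file.path(outdir, "pipeline.success"))
  } else {
    writeLines(message, file.path(outdir, "pipeline.failure"))
  }
}

#' Run a pipeline definition end to end
#'
#' Executes ingest, QC and the workflow-specific stages, writing every result
#' table, the intermediate matrices, the parameter record and a run log into
#' `outdir`. On any stage error the partial outputs are kept and a
#' `pipeline.failure` file names the failing stage and the error; otherwise a
#' zero-length `pipeline.success` is written. Exactly one marker file is
#' produced and no error escapes this function. With identical inputs and
#' seed, reruns into a fresh directory are byte-identical apart from the
#' timestamps in the run log.
#'
#' @param definition A [parse_pipeline_definition()] result (or path to one).
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a list with `success`, `stage` (failing stage or `NA`),
#'   `error` message (or `NA`) and `outputs` (paths written).
#' @export
run_pipeline <- function(definition, outdir) {
  if (is.character(definition)) definition <- parse_pipeline_definition(definition)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(outdir, c("pipeline.success", "pipeline.failure")))
  log <- list()
  outputs <- character()
  stage_name <- NA_character_
  emit <- function(name, path) { outputs[[name]] <<- path; path }
  res <- tryCatch({
    runner <- if (definition$workflow == "proteomics") run_proteomics_stages
              else run_interactomics_stages
    stage <- function(name, expr) {
      stage_name <<- name
      t0 <- Sys.time()
      out <- force(expr)
      log[[length(log) + 1L]] <<- list(stage = name, status = "ok",
                                       seconds = as.numeric(Sys.time() - t0, units = "secs"))
      out
    }
    runner(definition, outdir, stage, emit)
    emit("parameter_record",
         write_parameter_record(definition, file.path(outdir, "parameter_record.json")))
    list(success = TRUE, stage = NA_character_, error = NA_character_)
  }, error = function(e) {
    log[[length(log) + 1L]] <<- list(stage = stage_name, status = "error",
                                     message = conditionMessage(e))
    list(success = FALSE, stage = stage_name, error = conditionMessage(e))
  })
  jsonlite::write_json(list(workflow = definition$workflow, stages = log,
                            finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (res$success) {
    write_marker(outdir, TRUE)
  } else {
    write_marker(outdir, FALSE, sprintf(
      "Pipeline failed at stage '%s': %s", res$stage, res$error))
  }
  invisible(c(res, list(outputs = outputs)))
}

ingest_stages <- function(definition, stage, kind_wanted) {
  opts <- definition$options
  mats <- stage("detect_format", {
    desc <- detect_format(definition$data_file)
    read_abundance(definition$data_file, desc)
  })
  am <- if (kind_wanted %in% names(mats)) mats[[kind_wanted]] else mats[[1L]]
  samples <- stage("read_sample_table", read_sample_table(definition$sample_table_file))
  if (!is.null(opts$control_group)) {
    samples$is_control <- samples$is_control | samples$sample_group %in% opts$control_group
  }
  am <- stage("remove_contaminants", {
    cont <- if (!is.null(opts$contaminant_file)) read_contaminants(opts$contaminant_file)
            else read_contaminants(bundled_contaminant_file())
    remove_contaminants(am, cont, enabled = isTRUE(opts$remove_contaminants))$matrix
  })
  aligned <- stage("align_samples", align_samples(am, samples))
  aligned
}

run_qc_stage <- function(aligned, outdir, stage, emit) {
  qc <- stage("qc_metrics", qc_report(aligned$matrix, aligned$samples))
  emit("qc_report", write_qc_report(qc, file.path(outdir, "qc_report.json")))
  readr::write_tsv(qc$id_counts, emit("qc_id_counts", file.path(outdir, "qc_id_counts.tsv")))
  readr::write_tsv(qc$missing_pct, emit("qc_missing", file.path(outdir, "qc_missing_pct.tsv")))
  readr::write_tsv(qc$coverage$per_protein,
                   emit("qc_coverage", file.path(outdir, "qc_coverage.tsv")))
  readr::write_tsv(qc$intensity_summary,
                   emit("qc_intensity", file.path(outdir, "qc_intensity_summary.tsv")))
  if (nrow(qc$cv_by_group)) {
    readr::write_tsv(qc$cv_by_group, emit("qc_cv", file.path(outdir, "qc_cv_by_group.tsv")))
  }
  qc
}

run_proteomics_stages <- function(definition, outdir, stage, emit) {
  opts <- definition$options
  cfg <- proteomics_config(min_group_fraction = opts$min_group_fraction,
                           normalization = opts$normalization,
                           imputation = opts$imputation,
                           fc_cutoffs = unlist(opts$fc_cutoffs),
                           alpha = opts$alpha, seed = opts$seed)
  aligned <- ingest_stages(definition, stage, "intensity")
  run_qc_stage(aligned, outdir, stage, emit)

  filt <- stage("filter_by_consistency",
                filter_by_consistency(aligned$matrix, aligned$samples,
                                      cfg$min_group_fraction))
  write_generic_matrix(filt$matrix, emit("filtered", file.path(outdir, "filtered_matrix.tsv")))
  writeLines(filt$dropped_ids, emit("dropped", file.path(outdir, "filtered_out_ids.txt")))

  normed <- stage("normalization", switch(cfg$normalization,
    none = filt$matrix,
    median = normalize_median(filt$matrix),
    quantile = normalize_quantile(filt$matrix)
  ))
  if (cfg$normalization != "none") {
    write_generic_matrix(normed, emit("normalized", file.path(outdir, "normalized_matrix.tsv")))
  }

  imp <- stage("imputation", switch(cfg$imputation,
    qrilc = impute_qrilc(normed, seed = cfg$seed),
    min_downshift = impute_min_downshift(normed, seed = cfg$seed),
    group_mean = impute_group_mean(normed, aligned$samples)
  ))
  write_generic_matrix(imp$matrix, emit("imputed", file.path(outdir, "imputed_matrix_log2.tsv")))

  pca <- stage("pca", pca_samples(imp$matrix))
  readr::write_tsv(pca$scores, emit("pca_scores", file.path(outdir, "pca_scores.tsv")))
  readr::write_tsv(tibble::tibble(component = seq_along(pca$var_explained),
                                  var_explained = pca$var_explained),
                   emit("pca_var", file.path(outdir, "pca_variance_explained.tsv")))

  clust <- stage("clustering", cluster_samples(imp$matrix))
  write_dendrogram_newick(clust, emit("dendrogram", file.path(outdir, "sample_dendrogram.nwk")))

  comparisons <- stage("comparisons", {
    if (!is.null(opts$comparison_file)) {
      read_comparisons(opts$comparison_file)
    } else if (!is.null(opts$comparisons)) {
      cmp <- opts$comparisons
      if (is.data.frame(cmp)) {
        tibble::as_tibble(cmp)
      } else if (is.matrix(cmp)) {  # JSON array-of-pairs simplifies to a matrix
        tibble::tibble(test_group = cmp[, 1L], control_group = cmp[, 2L])
      } else {
        tibble::tibble(test_group = vapply(cmp, `[[`, character(1L), 1L),
                       control_group = vapply(cmp, `[[`, character(1L), 2L))
      }
    } else {
      groups <- unique(aligned$samples$sample_group)
      ctrl <- if (!is.null(opts$control_group)) opts$control_group else groups[1L]
      tibble::tibble(test_group = setdiff(groups, ctrl), control_group = ctrl)
    }
  })
  da <- stage("differential_abundance", {
    res <- differential_abundance(imp$matrix, aligned$samples, comparisons)
    classify_volcano(res, fc_cutoffs = cfg$fc_cutoffs, alpha = cfg$alpha)
  })
  readr::write_tsv(da, emit("differential", file.path(outdir, "differential_abundance.tsv")))
  invisible(NULL)
}

run_interactomics_stages <- function(definition, outdir, stage, emit) {
  opts <- definition$options
  aligned <- ingest_stages(definition, stage, "spectral_count")
  run_qc_stage(aligned, outdir, stage, emit)

  sc <- stage("spectral_counts", spectral_counts(aligned$matrix, aligned$samples))
  stage("write_saint_inputs",
        write_saint_inputs(sc, outdir = file.path(outdir, "saint_input")))
  fc <- stage("crapome_fold_change",
              crapome_fold_change(sc, pseudocount = opts$pseudocount,
                                  top_k = opts$top_k))
  readr::write_tsv(fc, emit("fold_change", file.path(outdir, "fold_change_scores.tsv")))

  saint <- stage("read_saint_output", {
    if (!is.null(opts$saint_output)) read_saint_output(opts$saint_output) else NULL
  })
  rec <- stage("filter_high_confidence",
               filter_high_confidence(fc, saint = saint, bfdr_max = opts$bfdr_max,
                                      fc_a_min = opts$fc_a_min,
                                      control_freq_max = opts$control_freq_max))
  if (!is.null(opts$known_interactions)) {
    known <- stage("map_known_interactions",
                   map_known_interactions(rec, read_known_interactions(opts$known_interactions)))
    rec <- known$records
    readr::write_tsv(known$known_fraction,
                     emit("known_fraction", file.path(outdir, "known_fraction.tsv")))
  }
  readr::write_tsv(rec, emit("interactors", file.path(outdir, "interactome_records.tsv")))

  if (!is.null(opts$markers)) {
    prof <- stage("ms_microscopy", ms_microscopy_profile(rec, read_marker_table(opts$markers)))
    readr::write_tsv(prof, emit("ms_microscopy", file.path(outdir, "ms_microscopy.tsv")))
  }
  if (isTRUE(opts$enrichment) && !is.null(opts$annotations)) {
    enr <- stage("enrichment", {
      ann <- read_annotations(opts$annotations)
      background <- unique(c(rownames(sc$counts), ann$accession))
      prey_set <- unique(rec$prey[rec$passed])
      enrichment_hypergeometric(prey_set, ann, background)
    })
    readr::write_tsv(enr, emit("enrichment", file.path(outdir, "enrichment.tsv")))
  }
  net <- stage("export_network", export_network(rec))
  readr::write_tsv(net$edges, emit("edges", file.path(outdir, "network_edges.tsv")))
  readr::write_tsv(net$nodes, emit("nodes", file.path(outdir, "network_nodes.tsv")))
  invisible(NULL)
}
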