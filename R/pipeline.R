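#' Assemble a pipeline run configuration
#'
#' @param mirnas,transcripts FASTA paths (required for the prediction and
#'   degradome stages).
#' @param signals two-channel signal CSV (optional; enables the
#'   microarray stage).
#' @param tags degradome tag file, TSV or `-count` FASTA (optional;
#'   enables the degradome stage).
#' @param ct qPCR Ct CSV (optional; enables the qPCR stage).
#' @param out_dir output directory.
#' @param cutoff,core_range,max_bulges scoring parameters (see
#'   [scoring_scheme()]).
#' @param min_reads degradome site support threshold.
#' @param preset microarray threshold preset (see [threshold_preset()]).
#' @param mode microarray call mode, `"full"` or `"fold_only"`.
#' @param reference_assay,calibrator_sample,test_sample qPCR design.
#' @param seed pipeline seed recorded in the manifest and used by any
#'   stochastic stage.
#' @return A named list with class `run_config`.
#' @export
run_config <- function(mirnas = NULL, transcripts = NULL, signals = NULL,
                       tags = NULL, ct = NULL, out_dir = "mircleave_out",
                       cutoff = 4, core_range = c(2L, 13L),
                       max_bulges = 1L, min_reads = 1,
                       preset = "strict_fold", mode = "full",
                       reference_assay = "5.8S",
                       calibrator_sample = NULL, test_sample = NULL,
                       seed = 1L) {
  structure(list(mirnas = mirnas, transcripts = transcripts,
                 signals = signals, tags = tags, ct = ct,
                 out_dir = out_dir, cutoff = cutoff,
                 core_range = as.integer(core_range),
                 max_bulges = as.integer(max_bulges),
                 min_reads = min_reads, preset = preset, mode = mode,
                 reference_assay = reference_assay,
                 calibrator_sample = calibrator_sample,
                 test_sample = test_sample, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a key = value run configuration file
#'
#' Plain-text lines `key = value`; `#` starts a comment. Keys mirror the
#' arguments of [run_config()]; `core_range` is written `2:13`.
#'
#' @param path config file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "[[:space:]]*=[[:space:]]*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  args <- as.list(vals)
  names(args) <- keys
  numeric_keys <- c("cutoff", "max_bulges", "min_reads", "seed")
  for (k in intersect(numeric_keys, keys)) args[[k]] <- as.numeric(args[[k]])
  if ("core_range" %in% keys) {
    args$core_range <- as.integer(strsplit(args$core_range, ":")[[1]])
  }
  do.call(run_config, args)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes the stages enabled by the configured inputs -- microarray
#' differential expression, target prediction, degradome validation, and
#' qPCR quantification -- and writes `diff.tsv`, `targets.tsv`,
#' `events.tsv`, per-transcript t-plot tables under `tplots/`,
#' `ratios.tsv`, and a `run_manifest.txt` recording package version,
#' parameters and seed. Any stage failure aborts with the stage name and
#' cause.
#'
#' @param config a [run_config()] (or path to a config file).
#' @return Invisibly, the output directory path.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- scoring_scheme(cutoff = config$cutoff,
                           core_range = config$core_range,
                           max_bulges = config$max_bulges)
  done <- character(0)

  if (!is.null(config$signals)) {
    run_stage("microarray", {
      signals <- read_signal_table(config$signals)
      th <- threshold_preset(config$preset)
      diff <- analyze_microarray(signals, th$p_threshold,
                                 th$log2_threshold, mode = config$mode)
      utils::write.table(diff, file.path(config$out_dir, "diff.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
    done <- c(done, "microarray")
  }

  targets <- NULL
  if (!is.null(config$mirnas) && !is.null(config$transcripts)) {
    run_stage("predict", {
      mirnas <- read_fasta(config$mirnas)
      transcripts <- read_fasta(config$transcripts)
      targets <- predict_targets(mirnas, transcripts, scheme)
      write_target_table(targets, file.path(config$out_dir,
                                            "targets.tsv"))
    })
    done <- c(done, "predict")
  }

  if (!is.null(config$tags)) {
    run_stage("degradome", {
      if (is.null(targets)) stop("degradome stage needs predicted targets")
      tags <- read_tags(config$tags)
      transcripts <- read_fasta(config$transcripts)
      profiles <- map_tags(tags, transcripts)
      events <- validate_targets(targets, profiles,
                                 min_reads = config$min_reads)
      write_target_table(events, file.path(config$out_dir, "events.tsv"))
      tdir <- file.path(config$out_dir, "tplots")
      dir.create(tdir, showWarnings = FALSE)
      for (tid in unique(events$transcript_id)) {
        tab <- t_plot_table(profiles, tid,
                            events$cleavage_site[events$transcript_id ==
                                                   tid])
        utils::write.table(tab, file.path(tdir, paste0(tid, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
    done <- c(done, "degradome")
  }

  if (!is.null(config$ct)) {
    run_stage("qpcr", {
      if (is.null(config$calibrator_sample) ||
          is.null(config$test_sample)) {
        stop("qPCR stage needs calibrator_sample and test_sample")
      }
      ct <- read_ct_table(config$ct)
      ratios <- summarize_replicates(ct, list(
        test_sample = config$test_sample,
        calibrator_sample = config$calibrator_sample,
        reference_assay = config$reference_assay))
      utils::write.table(ratios, file.path(config$out_dir, "ratios.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
    done <- c(done, "qpcr")
  }

  manifest <- c(
    paste0("mircleave_version = ",
           as.character(utils::packageVersion("mircleave"))),
    paste0("stages = ", paste(done, collapse = ",")),
    paste0("cutoff = ", config$cutoff),
    paste0("core_range = ", paste(config$core_range, collapse = ":")),
    paste0("max_bulges = ", config$max_bulges),
    paste0("min_reads = ", config$min_reads),
    paste0("preset = ", config$preset),
    paste0("mode = ", config$mode),
    paste0("seed = ", config$seed))
  writeLines(manifest, file.path(config$out_dir, "run_manifest.txt"))
  invisible(config$out_dir)
}
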