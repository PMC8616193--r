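# One-command orchestration: arms -> align -> classify -> matrices ->
# profile report, optionally resuming after an external DESeq2/edgeR step
# with a DE table to filter and report. Differential-expression statistics
# themselves stay external; this pipeline produces their input and consumes
# their output. Intermediate files (per-sample SAM) go to intermediate/;
# a JSON manifest records the configuration, package version and a checksum
# of every input and output file.

#' Assemble a pipeline run configuration
#'
#' @param mode \code{"precursor"} (mature + precursor FASTA) or \code{"gff"}
#'   (mature loci GFF3 + genome FASTA).
#' @param mature path to the mature miR FASTA.
#' @param precursor path to the precursor FASTA (precursor mode).
#' @param gff,genome paths to the miR GFF3 and genome FASTA (gff mode).
#' @param groups named list of exactly two character vectors; each element
#'   is a vector of per-sample read files (FASTQ/FASTA) or SAM files, named
#'   by sample id (file base name when unnamed).
#' @param reads_are_sam treat group entries as externally aligned SAM files
#'   instead of read files.
#' @param ext arm extension (0-8, default 6).
#' @param min_len,max_len read length window (default 18-26 nt).
#' @param detect_nta detect 3' non-template additions (default TRUE).
#' @param de_table optional DE result table (DESeq2/edgeR dialect) to filter
#'   and report.
#' @param min_base_mean,min_abs_log2fc,max_pvalue,max_padj DE filter
#'   thresholds (see [filter_de()]).
#' @param top_n,n_arms DE report sizes (see [top_de()], [arm_summary()]).
#' @param len_window length-distribution display window.
#' @param outdir output directory (created if absent).
#' @return a validated \code{run_config} list.
#' @export
run_config <- function(mode = c("precursor", "gff"), mature, precursor = NULL,
                       gff = NULL, genome = NULL, groups, reads_are_sam = FALSE,
                       ext = 6L, min_len = 18L, max_len = 26L,
                       detect_nta = TRUE, de_table = NULL,
                       min_base_mean = NULL, min_abs_log2fc = 1,
                       max_pvalue = NULL, max_padj = 0.05,
                       top_n = 20L, n_arms = 10L, len_window = c(20L, 35L),
                       outdir) {
  mode <- match.arg(mode)
  stopifnot(is.list(groups), length(groups) == 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- c("group1", "group2")
  }
  if (any(lengths(groups) == 0L)) stop("both sample groups must be non-empty", call. = FALSE)
  groups <- lapply(groups, function(g) {
    if (is.null(names(g)) || any(!nzchar(names(g)))) {
      names(g) <- tools::file_path_sans_ext(basename(g))
    }
    g
  })
  sample_ids <- unlist(lapply(groups, names), use.names = FALSE)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id across groups: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  inputs <- c(mature = mature,
              if (mode == "precursor") c(precursor = precursor)
              else c(gff = gff, genome = genome),
              if (!is.null(de_table)) c(de_table = de_table),
              unlist(groups))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("input file(s) not found: ",
         paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(mode = mode, mature = mature, precursor = precursor, gff = gff,
         genome = genome, groups = groups, reads_are_sam = reads_are_sam,
         ext = as.integer(ext), min_len = as.integer(min_len),
         max_len = as.integer(max_len), detect_nta = detect_nta,
         de_table = de_table, min_base_mean = min_base_mean,
         min_abs_log2fc = min_abs_log2fc, max_pvalue = max_pvalue,
         max_padj = max_padj, top_n = as.integer(top_n),
         n_arms = as.integer(n_arms), len_window = as.integer(len_window),
         outdir = outdir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; \code{groups} maps group
#' names to lists of file paths.
#'
#' @param path YAML file.
#' @return a validated \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$groups <- lapply(y$groups, unlist)
  do.call(run_config, y)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    message("stage '", stage, "' failed: ", conditionMessage(e))
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full arm-building / alignment / classification / reporting pipeline
#'
#' Stages: build arms, align (or ingest) each sample, classify, write count
#' matrices and the arm database, render the profile report, and -- when a
#' DE table is supplied -- filter it and render the DE report. Outputs are
#' deterministic for identical inputs; a partial failure leaves the outputs
#' of completed stages in place, and the error names the failed stage.
#'
#' @param config a \code{run_config} ([run_config()] or [read_run_config()]).
#' @return invisibly, a list with the classification result, matrices,
#'   profile statistics and the paths of all files written.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  intdir <- file.path(outdir, "intermediate")
  dir.create(intdir, showWarnings = FALSE)
  files <- character()

  matures <- run_stage("reference", {
    read_mature_fasta(config$mature)
  })
  arms <- run_stage("reference", {
    if (config$mode == "precursor") {
      build_arms_from_precursors(matures, read_precursor_fasta(config$precursor),
                                 ext = config$ext)
    } else {
      build_arms_from_gff(read_mirna_gff(config$gff),
                          read_genome_fasta(config$genome), ext = config$ext)
    }
  })
  arms_fa <- file.path(outdir, "arms.fa")
  run_stage("reference", write_arms_fasta(arms, arms_fa))
  files["arms"] <- arms_fa

  sample_files <- do.call(c, unname(config$groups))  # keep per-sample names
  raw <- list()
  for (s in names(sample_files)) {
    f <- sample_files[[s]]
    aln <- run_stage("align", {
      if (!file.exists(f)) stop("missing input for sample '", s, "': ", f)
      if (config$reads_are_sam) read_sam(f, arms)
      else align_exact(read_reads(f), arms)
    })
    if (!config$reads_are_sam) {
      sam <- file.path(intdir, paste0(s, ".sam"))
      run_stage("align", write_sam(aln, arms, sam))
      files[paste0("sam_", s)] <- sam
    }
    raw[[s]] <- aln
  }

  groups_ids <- lapply(config$groups, names)
  result <- run_stage("classify", {
    filtered <- lapply(raw, function(aln) {
      keep_ids <- unique(aln$read_id[nchar(aln$sequence) >= config$min_len &
                                       nchar(aln$sequence) <= config$max_len])
      aln[aln$read_id %in% keep_ids, , drop = FALSE]
    })
    classify_samples(filtered, arms, matures, detect_nta = config$detect_nta)
  })

  mats <- run_stage("matrices", build_count_matrices(result, groups_ids))
  files["counts_combined"] <- file.path(outdir, "counts_combined.tsv")
  write_count_matrix(mats$combined, files[["counts_combined"]])
  for (nm in names(mats$categories)) {
    f <- file.path(outdir, sprintf("counts_%s.tsv", nm))
    write_count_matrix(mats$categories[[nm]], f)
    files[paste0("counts_", nm)] <- f
  }
  files["arm_database"] <- file.path(outdir, "arm_database.tsv")
  run_stage("matrices", export_arm_database(result, arms, files[["arm_database"]]))

  stats <- run_stage("profile", profile_stats(result, raw, groups_ids,
                                              len_window = config$len_window))
  prof_files <- run_stage("profile", {
    render_profile_report(stats, file.path(outdir, "profile_report.pdf"))
  })
  files[paste0("profile_", names(prof_files))] <- prof_files

  de_filtered <- NULL
  if (!is.null(config$de_table)) {
    de_filtered <- run_stage("de", {
      rows <- read_de_table(config$de_table)
      filter_de(rows, min_base_mean = config$min_base_mean,
                min_abs_log2fc = config$min_abs_log2fc,
                max_pvalue = config$max_pvalue, max_padj = config$max_padj)
    })
    files["de_filtered"] <- file.path(outdir, "de_filtered.tsv")
    utils::write.table(de_filtered, files[["de_filtered"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    de_files <- run_stage("de", {
      render_de_report(top_de(de_filtered, n = config$top_n),
                       arm_summary(de_filtered, n_arms = config$n_arms),
                       file.path(outdir, "de_report.pdf"))
    })
    files[paste0("de_", names(de_files))] <- de_files
  }

  manifest <- list(
    package = as.character(utils::packageVersion("armiR")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config[setdiff(names(config), "outdir")],
    inputs = as.list(tools::md5sum(unname(c(config$mature, config$precursor,
                                            config$gff, config$genome,
                                            config$de_table, sample_files)))),
    outputs = as.list(tools::md5sum(unname(files)))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  files["manifest"] <- manifest_path

  invisible(list(arms = arms, result = result, matrices = mats, stats = stats,
                 de_filtered = de_filtered, files = files))
}
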