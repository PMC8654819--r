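#' Build a pipeline run configuration
#'
#' A run is configured either with a `simulate` block (a fully synthetic,
#' ground-truthed experiment) or with file `inputs` (a genome FASTA plus
#' per-replicate sample/control SAM files). Filter, peak and annotation
#' defaults follow the pipeline's standard settings: mean base quality
#' >= 20, deleted region < 20 bp, exact flag pairs, peaks at depth >= 1.
#'
#' @param sgrna An [sgrna_spec()] (or list with `spacer`, `pam`,
#'   `cut_offset`).
#' @param simulate `NULL`, or a list understood by [simulate_experiment()]:
#'   `n_contigs`, `contig_length`, `mismatch_counts`, `cleave_probs`, and
#'   any [sim_params()] field.
#' @param inputs `NULL`, or a list with `genome_fasta`, `replicates`
#'   (character vector of sample SAM paths, >= 2), `controls` (matching
#'   control SAM paths), and optionally `truth_contig`/`truth_cut_pos`.
#' @param min_mean_q,max_deletion,deletion_metric Read-pair filter settings.
#' @param min_height,merge_gap Peak-calling settings.
#' @param flank,tolerance Annotation settings (protospacer search flank;
#'   on-target labelling tolerance).
#' @param n_replicates Number of replicate experiments (simulate mode).
#' @param seed Master seed; all per-library seeds derive from it.
#' @param output_dir Optional directory for [write_report()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(sgrna, simulate = NULL, inputs = NULL,
                       min_mean_q = 20, max_deletion = 20,
                       deletion_metric = "max",
                       min_height = 1L, merge_gap = 0L,
                       flank = 25L, tolerance = 5L,
                       n_replicates = 2L, seed = 1L, output_dir = NULL) {
  if (is.null(simulate) && is.null(inputs))
    stopf("config error: provide either a simulate block or file inputs")
  if (!inherits(sgrna, "sgrna_spec"))
    sgrna <- sgrna_spec(sgrna$spacer, sgrna$pam %||% "NGG",
                        sgrna$cut_offset %||% 3L)
  if (n_replicates < 1L) stopf("config error: need at least 1 replicate")
  if (min_mean_q <= 0 || max_deletion <= 0 || min_height < 1L)
    stopf("config error: thresholds must be positive")
  structure(list(sgrna = sgrna, simulate = simulate, inputs = inputs,
                 min_mean_q = min_mean_q, max_deletion = max_deletion,
                 deletion_metric = deletion_metric,
                 min_height = as.integer(min_height),
                 merge_gap = as.integer(merge_gap),
                 flank = as.integer(flank), tolerance = as.integer(tolerance),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [run_config()]; the `sgrna` block must
#' carry at least a `spacer`.
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$sgrna$spacer)) stopf("config error: sgrna.spacer is required")
  do.call(run_config, c(
    list(sgrna = sgrna_spec(y$sgrna$spacer, y$sgrna$pam %||% "NGG",
                            y$sgrna$cut_offset %||% 3L)),
    y[setdiff(names(y), "sgrna")]))
}

#' Simulate a complete multi-replicate CIRCLE-seq experiment
#'
#' Generates a genome with planted sites and, for each replicate, a sample
#' library and its matched negative control (sharing artifact loci).
#'
#' @param config A `run_config` with a `simulate` block.
#' @return A list with `genome`, `sites`, and `replicates`, a list of
#'   `list(sample = circleseq_sim, control = circleseq_sim)`.
#' @export
simulate_experiment <- function(config) {
  sb <- config$simulate
  if (is.null(sb)) stopf("config has no simulate block")
  genome <- make_genome(config$seed, sb$n_contigs %||% 1L,
                        sb$contig_length %||% 50000L)
  planted <- plant_sites(genome, config$sgrna,
                         sb$mismatch_counts %||% c(0L, 1:6),
                         sb$cleave_probs, seed = config$seed + 500L)
  par_fields <- setdiff(intersect(names(sb), names(formals(sim_params))),
                        c("seed", "artifact_exclude"))
  excl <- if (nrow(planted$sites))
    data.frame(contig = planted$sites$contig, pos = planted$sites$cut_pos,
               stringsAsFactors = FALSE) else NULL
  reps <- lapply(seq_len(config$n_replicates), function(i) {
    p <- do.call(sim_params, c(sb[par_fields],
                               list(artifact_exclude = excl,
                                    seed = config$seed + 1000L * i)))
    list(sample = simulate_reads(planted$genome, planted$sites, p),
         control = simulate_negative_control(planted$genome, p))
  })
  list(genome = planted$genome, sites = planted$sites, replicates = reps)
}

#' Run the full nomination pipeline
#'
#' Fixed stage order: quality/flag/deletion filtering of every library,
#' coverage, peak calling, per-replicate negative-control subtraction,
#' replicate intersection, log10 ranking, protospacer annotation, on-target
#' labelling. Identical config + seed give identical results.
#'
#' @param config A [run_config()].
#' @return A list of class `circlenom_run` with `ranked` (the annotated
#'   candidate table), `filter_reports`, `stage_counts`, per-replicate
#'   `peaks`, `tracks`, `sites` (truth, simulate mode) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$simulate)) {
    exp <- simulate_experiment(config)
    genome <- exp$genome
    sites <- exp$sites
    libs <- lapply(exp$replicates, function(r)
      list(sample = r$sample$pairs, control = r$control$pairs,
           lens = r$sample$contig_lengths))
    truth_contig <- if (nrow(sites)) sites$contig[1L] else NULL
    truth_cut <- if (nrow(sites)) sites$cut_pos[1L] else NULL
  } else {
    inp <- config$inputs
    genome <- read_genome_fasta(inp$genome_fasta)
    sites <- empty_sites()
    if (length(inp$replicates) < config$n_replicates)
      stopf("config error: %d replicate SAMs given, %d required",
            length(inp$replicates), config$n_replicates)
    libs <- lapply(seq_along(inp$replicates), function(i) {
      s <- read_sam_pairs(inp$replicates[[i]])
      ctl <- if (!is.null(inp$controls) && length(inp$controls) >= i)
        read_sam_pairs(inp$controls[[i]]) else NULL
      list(sample = s, control = ctl, lens = attr(s, "contig_lengths"))
    })
    truth_contig <- inp$truth_contig
    truth_cut <- inp$truth_cut_pos
  }

  filter_reports <- list()
  rep_peaks <- list()
  tracks <- list()
  for (i in seq_along(libs)) {
    lib <- libs[[i]]
    fs <- filter_pairs(lib$sample, config$min_mean_q, config$max_deletion,
                       config$deletion_metric)
    filter_reports[[sprintf("replicate%d_sample", i)]] <- fs$report
    tr_s <- coverage_track(fs$kept, lib$lens)
    pk_s <- call_peaks(tr_s, config$min_height, config$merge_gap)
    if (!is.null(lib$control)) {
      fc <- filter_pairs(lib$control, config$min_mean_q, config$max_deletion,
                         config$deletion_metric)
      filter_reports[[sprintf("replicate%d_control", i)]] <- fc$report
      pk_c <- call_peaks(coverage_track(fc$kept, lib$lens),
                         config$min_height, config$merge_gap)
      pk <- subtract_control(pk_s, pk_c)
    } else {
      warning(sprintf(
        "replicate %d has no negative control: subtraction skipped", i),
        call. = FALSE)
      pk_c <- empty_peaks()
      pk <- pk_s
    }
    rep_peaks[[i]] <- list(sample = pk_s, control = pk_c, subtracted = pk)
    tracks[[i]] <- tr_s
  }

  common <- Reduce(intersect_replicates, lapply(rep_peaks, `[[`, "subtracted"))
  ranked <- rank_sites(common)
  ranked <- annotate_peaks(ranked, genome, config$sgrna,
                           flank = config$flank, track = tracks[[1L]])
  if (!is.null(truth_contig))
    ranked <- label_on_target(ranked, truth_contig, truth_cut,
                              config$tolerance)

  stage_counts <- data.frame(
    replicate = seq_along(rep_peaks),
    sample_peaks = vapply(rep_peaks, function(r) nrow(r$sample), integer(1)),
    control_peaks = vapply(rep_peaks, function(r) nrow(r$control), integer(1)),
    after_subtraction = vapply(rep_peaks, function(r) nrow(r$subtracted),
                               integer(1)))
  result <- structure(list(ranked = ranked, common_peaks = common,
                           filter_reports = filter_reports,
                           stage_counts = stage_counts,
                           replicate_peaks = rep_peaks, tracks = tracks,
                           sites = sites, config = config),
                      class = "circlenom_run")
  if (!is.null(config$output_dir)) write_report(result, config$output_dir)
  result
}

#' Write the pipeline report and tables
#'
#' Emits `report.json` (machine-readable: parameter echo, per-library filter
#' counts, per-stage peak counts, top candidates), `ranked_candidates.tsv`,
#' `peaks.bedGraph` (the surviving common peaks) and `run.log`. Refuses a
#' non-empty existing directory unless `force = TRUE`.
#'
#' @param result A `circlenom_run`.
#' @param dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @param top_n Number of top candidates echoed into the JSON report.
#' @return Named vector of files written, invisibly.
#' @export
write_report <- function(result, dir, force = FALSE, top_n = 20L) {
  stopifnot(inherits(result, "circlenom_run"))
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force)
    stopf("output directory %s is not empty (use force = TRUE)", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  prov <- sprintf("# seed=%d min_mean_q=%s max_deletion=%s min_height=%d",
                  cfg$seed, cfg$min_mean_q, cfg$max_deletion, cfg$min_height)
  files <- c(json = file.path(dir, "report.json"),
             tsv = file.path(dir, "ranked_candidates.tsv"),
             bedgraph = file.path(dir, "peaks.bedGraph"),
             log = file.path(dir, "run.log"))
  report <- list(
    parameters = list(seed = cfg$seed, min_mean_q = cfg$min_mean_q,
                      max_deletion = cfg$max_deletion,
                      deletion_metric = cfg$deletion_metric,
                      min_height = cfg$min_height, merge_gap = cfg$merge_gap,
                      flank = cfg$flank, tolerance = cfg$tolerance,
                      n_replicates = cfg$n_replicates,
                      spacer = cfg$sgrna$spacer, pam = cfg$sgrna$pam),
    filter_reports = result$filter_reports,
    stage_counts = result$stage_counts,
    n_candidates = nrow(result$ranked),
    top_candidates = utils::head(result$ranked, top_n))
  jsonlite::write_json(report, files["json"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  con <- file(files["tsv"], "wb")
  writeLines(prov, con, sep = "\n")
  utils::write.table(result$ranked, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  write_bedgraph(result$common_peaks, files["bedgraph"], header = prov)
  writeLines(c(prov, sprintf("stages: filter -> coverage -> peaks -> %s",
                             "subtract -> intersect -> rank -> annotate"),
               sprintf("candidates: %d", nrow(result$ranked))),
             files["log"])
  invisible(files)
}
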