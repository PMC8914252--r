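# End-to-end orchestration: generate (or load) -> pileup -> call ->
# subtract -> annotate -> origin/skew statistics -> site scan ->
# input-vs-IP coverage test -> report bundle on disk.

#' Pipeline configuration
#'
#' Exactly one of `synthetic` (a [synthetic_config()]) or `inputs` (paths
#' to real data files) must be provided.
#'
#' @param synthetic a [synthetic_config()] describing a simulated study.
#' @param inputs optional list with paths: `fasta`, `gff3`,
#'   `replicon_config`, and `reads` (named list/character of BED paths
#'   keyed as in `library_keys()$key`).
#' @param peaks a [peak_caller_config()].
#' @param ori_window half-width (bp) of the origin window for the
#'   coverage comparison.
#' @param skew_window display window (bp) for the exported skew track.
#' @param locator_window window (bp) used by the ori/ter locator (see
#'   [locate_ori_ter_window()]).
#' @param tau ori-proximal fraction for the binomial clustering test.
#' @param outdir output directory; `NULL` disables file output.
#' @param seed overrides the synthetic seed when given.
#' @param quiet suppress stage messages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), inputs = NULL,
                            peaks = peak_caller_config(), ori_window = 1000,
                            skew_window = 100,
                            locator_window = locate_ori_ter_window(),
                            tau = 0.1, outdir = NULL, seed = NULL,
                            quiet = FALSE) {
  if (!is.null(inputs)) {
    stopifnot(all(c("fasta", "gff3", "replicon_config", "reads") %in%
                    names(inputs)))
    synthetic <- NULL
  }
  if (is.null(synthetic) && is.null(inputs)) {
    stop_format("provide either a synthetic block or input paths")
  }
  if (!is.null(seed) && !is.null(synthetic)) synthetic$seed <- seed
  cfg <- list(synthetic = synthetic, inputs = inputs, peaks = peaks,
              ori_window = ori_window, skew_window = skew_window,
              locator_window = locator_window, tau = tau, outdir = outdir,
              seed = if (!is.null(synthetic)) synthetic$seed else seed,
              quiet = quiet)
  class(cfg) <- "pipeline_config"
  cfg
}

# pool replicate libraries, re-offsetting read ids so they stay unique
pool_libraries <- function(libs, keys) {
  off <- 0
  parts <- lapply(keys, function(k) {
    df <- libs[[k]]
    df$id <- df$id + off
    off <<- off + max(df$id, 0)
    df
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Compare a called peak set against planted truth
#'
#' A truth peak is recovered when at least one called peak overlaps it by
#' `>= 1` bp; a called peak is a true discovery when it overlaps at least
#' one truth peak.
#'
#' @param called,truth peak data.frames (`replicon, start, end`).
#' @param replicons a [replicon_set()].
#' @return list with `recall`, `precision`, `n_called`, `n_truth`.
#' @export
evaluate_against_truth <- function(called, truth, replicons) {
  if (nrow(truth) == 0) {
    return(list(recall = NA_real_, precision = NA_real_,
                n_called = nrow(called), n_truth = 0))
  }
  missed <- subtract_overlapping(truth, called, replicons)
  false_pos <- subtract_overlapping(called, truth, replicons)
  list(recall = 1 - nrow(missed) / nrow(truth),
       precision = if (nrow(called) == 0) NA_real_
                   else 1 - nrow(false_pos) / nrow(called),
       n_called = nrow(called), n_truth = nrow(truth))
}

load_real_inputs <- function(inputs) {
  seqs <- read_fasta(inputs$fasta)
  replicons <- read_replicon_config(inputs$replicon_config)
  replicons$sequence <- unname(seqs[replicons$name])
  genes <- read_gff3(inputs$gff3)
  libs <- lapply(inputs$reads, function(p) {
    df <- read_bed(p)
    df$id <- if ("name" %in% names(df)) match(df$name, unique(df$name))
             else seq_len(nrow(df))
    df[, c("replicon", "start", "end", "strand", "id")]
  })
  list(replicons = replicons, genes = genes, libs = libs, truth = NULL)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load), per-construct pooled peak calling,
#' two-step construct subtraction, context/fork annotation, ori-distance
#' statistics, GC-skew and ori/ter localization, site-occupancy scan, and
#' input-vs-IP coverage comparison. With `outdir` set, writes peaks per
#' construct (BED), unique peaks (BED), annotated peaks and summaries
#' (TSV), ori statistics (TSV), skew tracks (bedGraph), site-scan and
#' coverage reports (TSV), circular-plot track files, and a
#' machine-readable `run_summary.json` carrying every parameter, the
#' seed, and a config hash (also stamped as a `#` header in every table).
#' Identical config + seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return result bundle (invisibly when writing files): list with the
#'   genome, libraries, per-construct peak sets, unique peaks, annotated
#'   peaks, summaries, ori statistics, skew tracks, site scan, coverage
#'   report, truth evaluation (synthetic mode), and parameters.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!config$quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_format("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e))
    })
  }

  if (!is.null(config$synthetic)) {
    genome <- stage("simulate-genome", generate_genome(config$synthetic))
    libs <- stage("simulate-reads", generate_reads(genome, config$synthetic))
    truth <- genome$truth
    say("simulate: %d replicons, %d genes, %d true peaks, %d IS copies",
        nrow(genome$replicons), nrow(genome$genes),
        nrow(truth$peaks %||% data.frame()), nrow(truth$is_copies))
  } else {
    real <- stage("load-inputs", load_real_inputs(config$inputs))
    genome <- real
    libs <- real$libs
    truth <- NULL
  }
  replicons <- genome$replicons
  genes <- genome$genes
  keys <- library_keys()
  keys <- keys[keys$key %in% names(libs), , drop = FALSE]
  pcfg <- config$peaks
  if (is.null(pcfg$genome_size)) pcfg$genome_size <- sum(replicons$length)

  # per-construct pooled peak calling
  constructs <- unique(keys$construct)
  peak_sets <- stage("call-peaks", {
    sets <- lapply(constructs, function(con) {
      ip_keys <- keys$key[keys$construct == con & keys$fraction == "IP"]
      in_keys <- keys$key[keys$construct == con & keys$fraction == "input"]
      call_peaks(pool_libraries(libs, ip_keys),
                 pool_libraries(libs, in_keys), replicons, pcfg)
    })
    names(sets) <- constructs
    sets
  })
  for (con in constructs) say("call-peaks: %s -> %d peaks", con,
                              nrow(peak_sets[[con]]))

  uniq <- stage("unique-peaks", unique_peaks(
    peak_sets[["pKG4_FlagIEP"]], peak_sets[["pKG_FlagIEP"]],
    peak_sets[["pKGEMA4"]], replicons))
  say("unique-peaks: %d of %d retained", nrow(uniq),
      nrow(peak_sets[["pKG4_FlagIEP"]]))

  annotated <- stage("annotate", annotate_peaks(uniq, genes, replicons))
  summaries <- summarize_by_replicon(annotated)

  # ori-distance statistics: per replicon and genome-wide
  dists <- stage("ori-stats", ori_distances(uniq, replicons))
  ori_tests <- list()
  for (rn in replicons$name) {
    u <- dists$u[dists$replicon == rn]
    if (length(u) >= 5) ori_tests[[rn]] <- ori_uniformity_test(u, config$tau)
  }
  if (nrow(dists) >= 5) {
    ori_tests[["genome"]] <- ori_uniformity_test(dists$u, config$tau)
  }

  # GC skew + locator (sequences present in synthetic mode)
  skew_tracks <- list(); ori_estimates <- list()
  if (!anyNA(replicons$sequence)) {
    for (i in seq_len(nrow(replicons))) {
      rn <- replicons$name[i]
      skew_tracks[[rn]] <- gc_skew(replicons$sequence[i],
                                   window = config$skew_window, replicon = rn)
      loc_track <- gc_skew(replicons$sequence[i],
                           window = min(config$locator_window,
                                        replicons$length[i] %/% 8),
                           replicon = rn)
      ori_estimates[[rn]] <- locate_ori_ter(loc_track)
    }
  }

  # site scan (needs sequences)
  site <- NULL
  if (!anyNA(replicons$sequence)) {
    scan <- stage("site-scan", scan_libraries(libs, replicons))
    site <- list(scan = scan,
                 occupancy = compare_site_occupancy(scan))
  }

  # input-vs-IP coverage comparison per replicon (pooled 9 vs 9)
  coverage_report <- stage("coverage-test", {
    do.call(rbind, lapply(seq_len(nrow(replicons)), function(i) {
      rr <- replicons[i, , drop = FALSE]
      tracks <- lapply(stats::setNames(keys$key, keys$key), function(k)
        pileup(libs[[k]], rr, extension = pcfg$extension))
      compare_input_vs_ip(tracks, rr, ori_window = config$ori_window)
    }))
  })

  evaluation <- NULL
  if (!is.null(truth) && !is.null(truth$peaks)) {
    evaluation <- evaluate_against_truth(uniq, truth$peaks, replicons)
    say("truth: recall %.3f, precision %.3f",
        evaluation$recall, evaluation$precision)
  }

  bundle <- list(replicons = replicons, genes = genes, truth = truth,
                 libraries = libs, peak_sets = peak_sets,
                 unique_peaks = uniq, annotated = annotated,
                 summaries = summaries, ori_distances = dists,
                 ori_tests = ori_tests, skew_tracks = skew_tracks,
                 ori_estimates = ori_estimates, site = site,
                 coverage_report = coverage_report,
                 evaluation = evaluation, config = config)
  if (!is.null(config$outdir)) {
    stage("write-outputs", write_pipeline_outputs(bundle, config$outdir))
    return(invisible(bundle))
  }
  bundle
}

write_pipeline_outputs <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  config <- bundle$config
  hash <- rlang::hash(config[setdiff(names(config), "outdir")])
  hdr <- sprintf(" seed=%s config_hash=%s",
                 format(config$seed %||% NA), hash)
  replicons <- bundle$replicons

  tsv <- function(df, name) {
    path <- file.path(outdir, name)
    con <- file(path, "w")
    writeLines(paste0("#", hdr), con)
    close(con)
    suppressWarnings(utils::write.table(
      df, path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  }

  for (con_name in names(bundle$peak_sets)) {
    write_peaks(bundle$peak_sets[[con_name]], replicons,
                file.path(outdir, paste0("peaks_", con_name, ".bed")),
                header = hdr)
  }
  write_peaks(bundle$unique_peaks, replicons,
              file.path(outdir, "unique_peaks.bed"), header = hdr)
  tsv(bundle$annotated, "annotated_peaks.tsv")
  tsv(bundle$summaries$category, "summary_context.tsv")
  tsv(bundle$summaries$fork, "summary_fork.tsv")
  tsv(bundle$ori_distances, "ori_distances.tsv")
  if (length(bundle$ori_tests)) {
    tsv(data.frame(scope = names(bundle$ori_tests),
                   do.call(rbind, lapply(bundle$ori_tests, as.data.frame))),
        "ori_tests.tsv")
  }
  tsv(bundle$coverage_report, "coverage_test.tsv")
  if (!is.null(bundle$site)) {
    tsv(bundle$site$scan, "site_scan.tsv")
    tsv(bundle$site$occupancy$ratios, "site_occupancy_ratios.tsv")
    if (!is.null(bundle$site$occupancy$depletion_test)) {
      tsv(bundle$site$occupancy$depletion_test, "site_depletion_test.tsv")
    }
  }
  for (rn in names(bundle$skew_tracks)) {
    write_skew_bedgraph(bundle$skew_tracks[[rn]],
                        file.path(outdir, paste0("skew_", rn, ".bedgraph")),
                        header = hdr)
  }
  write_circos_tracks(bundle, file.path(outdir, "circos"))

  summary <- list(
    seed = config$seed, config_hash = hash,
    parameters = config[setdiff(names(config), c("outdir", "quiet"))],
    stage_counts = list(
      genes = nrow(bundle$genes),
      peaks_per_construct = lapply(bundle$peak_sets, nrow),
      unique_peaks = nrow(bundle$unique_peaks)),
    evaluation = bundle$evaluation,
    ori_estimates = bundle$ori_estimates)
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE, pretty = TRUE)
  invisible(outdir)
}

# plain-text track files (chrom start end value) mirroring the circular
# genome plot: forward/reverse genes, unique peaks, IS copies, skew
write_circos_tracks <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    data.table::fwrite(df, file.path(dir, name), sep = "\t",
                       col.names = FALSE, scipen = 50)
  }
  g <- bundle$genes
  w(data.frame(g$replicon, g$start, g$end, 1)[g$strand == "+", ],
    "genes_forward.txt")
  w(data.frame(g$replicon, g$start, g$end, 1)[g$strand == "-", ],
    "genes_reverse.txt")
  if (nrow(bundle$unique_peaks)) {
    segs <- peak_segments(bundle$unique_peaks, bundle$replicons)
    w(data.frame(segs$replicon, segs$start, segs$end, 1), "peaks.txt")
  }
  if (!is.null(bundle$truth) && !is.null(bundle$truth$is_copies)) {
    is_df <- bundle$truth$is_copies
    w(data.frame(is_df$replicon, is_df$cassette_start, is_df$cassette_end, 1),
      "is_copies.txt")
  }
  for (rn in names(bundle$skew_tracks)) {
    tr <- bundle$skew_tracks[[rn]]
    w(data.frame(rn, tr$start, tr$end, signif(tr$skew, 6)),
      paste0("skew_", rn, ".txt"))
  }
  invisible(dir)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `synthetic`
#' and `peaks` blocks are passed to their constructors.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) {
    args <- y$synthetic
    if (!is.null(args$replicons)) {
      args$replicons <- as.data.frame(lapply(args$replicons, unlist),
                                      stringsAsFactors = FALSE)
    }
    do.call(synthetic_config, args)
  } else NULL
  pk <- if (!is.null(y$peaks)) do.call(peak_caller_config, y$peaks)
        else peak_caller_config()
  rest <- y[setdiff(names(y), c("synthetic", "peaks"))]
  do.call(pipeline_config,
          c(list(synthetic = syn, inputs = y$inputs, peaks = pk),
            rest[setdiff(names(rest), "inputs")]))
}
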