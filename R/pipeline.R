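#' Run the full analysis pipeline
#'
#' Orchestrates every stage end-to-end from a single configuration:
#' classification of genes by windowed antisense counts, class metagene and
#' correlation profiles, NDR sizing, gene-body/turnover analysis, promoter
#' factor enrichment and (when a mutant is configured) the class-shift
#' comparison. All tabular results are written as TSV into
#' `config$outdir`, together with `run_log.txt` recording every default
#' that was applied, and `summary.json` with the headline numbers. Outputs
#' are fully determined by (inputs, config, seed).
#'
#' @param config a list, or the path to a YAML file. Recognised fields:
#'   `outdir` (required); either `synthetic` (a list of
#'   [generator_config()] overrides, e.g. `list(seed = 1)`, plus optional
#'   `mutant: TRUE`) or `inputs` (named paths: `genes`, `genes_dialect`,
#'   `netseq_watson`, `netseq_crick`, `occupancy`, `h3`, optional `mods`
#'   (named list of modification bedGraphs), `nucleosome_calls`,
#'   `turnover_probes`, `occupancy_matrix`); and optional analysis settings
#'   `window` (default `c(0, 300)`), `overlap_limit` (0),
#'   `enrichment_alpha` (1e-4), `vicinity` (`c(-300, 300)`),
#'   `profile_range` (`c(-1000, 1500)`), `profile_bin` (10),
#'   `test_positions` (`c(0, 600)`).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_run_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("antisensr pipeline run",
                 paste0("settings: ", jsonlite::toJSON(cfg$settings,
                                                       auto_unbox = TRUE)))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  out <- function(f) file.path(cfg$outdir, f)

  # --- inputs -------------------------------------------------------------
  if (!is.null(cfg$synthetic)) {
    gcfg <- do.call(generator_config, cfg$synthetic$overrides)
    ds <- generate_dataset(gcfg)
    mut <- if (isTRUE(cfg$synthetic$mutant)) generate_mutant(gcfg, ds)
    note("synthetic dataset: %d genes, seed %d", gcfg$n_genes, gcfg$seed)
  } else {
    ds <- read_input_dataset(cfg$inputs)
    mut <- read_mutant_dataset(cfg$inputs)
    note("inputs read from files")
  }
  s <- cfg$settings

  # --- classification -----------------------------------------------------
  genes <- filter_genes(ds$genes, s$overlap_limit)
  note("gene filter: %d of %d genes kept (overlap_limit = %d bp, default %s)",
       nrow(genes), nrow(ds$genes), s$overlap_limit,
       if (s$overlap_limit == 0L) "applied" else "overridden")
  anti <- count_window_reads(genes, ds$netseq, "antisense",
                             s$window[1L], s$window[2L])
  sens <- count_window_reads(genes, ds$netseq, "sense",
                             s$window[1L], s$window[2L])
  counts <- tibble(gene_id = genes$gene_id, sense = sens$count,
                   antisense = anti$count)
  classes <- assign_five_classes(anti)
  write_class_assignment(classes, out("classes.tsv"))
  readr::write_tsv(counts, out("window_counts.tsv"))
  class_groups <- split(classes$gene_id, classes$class)

  # --- metagene + correlation profiles ------------------------------------
  occ_meta <- metagene_profile(genes, ds$occupancy, group = class_groups,
                               range = s$profile_range, bin = s$profile_bin)
  readr::write_tsv(as_tibble(occ_meta), out("occupancy_metagene.tsv"))
  note("metagene/correlation profiles: range [%d, %d) bp, %d bp bins",
       s$profile_range[1L], s$profile_range[2L], s$profile_bin)
  mods <- Filter(Negate(is.null),
                 list(h3ac = ds$mod_h3ac, h3k36me3 = ds$mod_h3k36me3))
  corr_profiles <- purrr::imap(mods, function(track, nm) {
    norm <- normalize_to_h3(track, ds$h3)
    cp <- correlation_profile(genes, norm, counts,
                              range = s$profile_range, bin = s$profile_bin)
    readr::write_tsv(as_tibble(cp), out(sprintf("correlation_profile_%s.tsv", nm)))
    cp
  })
  note("H3 modifications normalised to H3 before profiling (default)")
  occ_test <- extremum_group_test(genes, ds$occupancy,
                                  class_groups[["5"]], class_groups[["1"]],
                                  polarity = "min", vicinity = s$vicinity,
                                  bin = s$profile_bin)
  note("occupancy extremum test: vicinity [%d, %d] bp (default +/-300)",
       s$vicinity[1L], s$vicinity[2L])

  # --- NDR ----------------------------------------------------------------
  ndr <- ndr_sizes(ds$nucleosomes, genes)
  ndr_groups <- tidy.class_assignment(classes) |>
    mutate(group = as.character(.data$class)) |> select("gene_id", "group")
  ndr_medians <- group_median_ndr(ndr, ndr_groups, contrast = c("5", "1"))
  readr::write_tsv(ndr_medians, out("ndr_group_medians.tsv"))

  # --- gene body + turnover -----------------------------------------------
  results <- list(genes = genes, counts = counts, classes = classes,
                  occupancy_metagene = occ_meta,
                  correlation_profiles = corr_profiles,
                  occupancy_extremum_test = occ_test,
                  ndr_medians = ndr_medians)
  if (!is.null(ds$mod_h3ac)) {
    body <- body_window_table(genes, normalize_to_h3(ds$mod_h3ac, ds$h3),
                              ds$netseq)
    body_corr <- body_window_correlation(body)
    readr::write_tsv(body_corr, out("body_correlation_h3ac.tsv"))
    results$body_correlation <- body_corr
  }
  if (!is.null(ds$probes)) {
    nt <- nucleosome_turnover(ds$probes, ds$nucleosomes, genes)
    turn <- turnover_class_distributions(nt, classes)
    readr::write_tsv(turn$summary, out("turnover_distributions.tsv"))
    readr::write_tsv(turn$tests, out("turnover_tests.tsv"))
    results$turnover <- turn
  }

  # --- promoter factor enrichment -----------------------------------------
  if (!is.null(ds$occupancy_matrix)) {
    enr <- factor_enrichment(ds$occupancy_matrix,
                             class_groups[["5"]], class_groups[["1"]],
                             alpha = s$enrichment_alpha)
    readr::write_tsv(as_tibble(enr), out("enrichment.tsv"))
    note("enrichment: raw p cutoff %g, no multiple-testing correction",
         s$enrichment_alpha)
    results$enrichment <- enr
  }

  # --- mutant comparison --------------------------------------------------
  if (!is.null(mut)) {
    norm <- normalize_libraries(list(wt = ds$netseq, mut = mut$netseq))
    mut_anti <- count_window_reads(genes, norm$mut, "antisense",
                                   s$window[1L], s$window[2L])
    mut_sens <- count_window_reads(genes, norm$mut, "sense",
                                   s$window[1L], s$window[2L])
    wt_anti_n <- count_window_reads(genes, norm$wt, "antisense",
                                    s$window[1L], s$window[2L])
    wt_classes <- assign_five_classes(wt_anti_n)
    mut_classes <- reassign_classes(mut_anti, wt_classes)
    shifts <- group_by_shift(wt_classes, mut_classes, strain = "mutant")
    readr::write_tsv(as_tibble(shifts), out("shift_groups.tsv"))
    dp <- difference_profile(genes, shifts, ds$occupancy, mut$occupancy,
                             range = s$profile_range, bin = s$profile_bin,
                             test_positions = s$test_positions)
    readr::write_tsv(dp$profile, out("difference_profile_occupancy.tsv"))
    if (!is.null(dp$tests))
      readr::write_tsv(dp$tests, out("difference_tests_occupancy.tsv"))
    wt_counts_n <- tibble(gene_id = genes$gene_id, sense = sens$count,
                          antisense = wt_anti_n$count)
    mut_counts_n <- tibble(gene_id = genes$gene_id, sense = mut_sens$count,
                           antisense = mut_anti$count)
    sc <- shift_vs_sense_scatter(wt_counts_n, mut_counts_n)
    readr::write_tsv(sc$deltas, out("shift_scatter.tsv"))
    note("class shifts on the wild-type class scale (default); +/-1 shifts excluded")
    results$shifts <- shifts
    results$difference_profile <- dp
    results$shift_scatter <- sc
  }

  # --- summary ------------------------------------------------------------
  summary <- list(
    n_genes = nrow(genes),
    class_sizes = as.list(table(classes$class)),
    class1_fraction = mean(classes$class == 1L),
    sense_antisense_rho = spearman_cor(counts$sense, counts$antisense)$rho,
    ndr_medians = setNames(as.list(ndr_medians$median_ndr),
                           paste0("class", ndr_medians$group)),
    occupancy_extremum_p = occ_test$p_value
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(log_lines, out("run_log.txt"))
  invisible(results)
}

validate_run_config <- function(config) {
  if (is.null(config$outdir)) abort("config needs an `outdir`")
  defaults <- list(window = c(0L, 300L), overlap_limit = 0L,
                   enrichment_alpha = 1e-4, vicinity = c(-300L, 300L),
                   profile_range = c(-1000L, 1500L), profile_bin = 10L,
                   test_positions = c(0L, 600L))
  settings <- utils::modifyList(defaults,
                                config[intersect(names(config), names(defaults))])
  if (settings$enrichment_alpha <= 0) abort("enrichment_alpha must be positive")
  if (is.null(config$synthetic) && is.null(config$inputs))
    abort("config needs either `synthetic` or `inputs`")
  synthetic <- NULL
  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    if (isTRUE(sy)) sy <- list()
    synthetic <- list(
      mutant = isTRUE(sy$mutant),
      overrides = sy[setdiff(names(sy), "mutant")] %||% list())
  } else {
    need <- c("genes", "netseq_watson", "netseq_crick", "occupancy", "h3",
              "nucleosome_calls")
    missing <- setdiff(need, names(config$inputs))
    if (length(missing))
      abort(paste0("inputs missing: ", paste(missing, collapse = ", ")))
    paths <- unlist(config$inputs[setdiff(names(config$inputs),
                                          c("genes_dialect", "mods",
                                            "mutant"))], use.names = TRUE)
    paths <- c(paths, unlist(config$inputs$mods),
               unlist(config$inputs$mutant))
    absent <- paths[!file.exists(paths)]
    if (length(absent))
      abort(paste0("input file(s) not found: ", paste(absent, collapse = ", ")))
  }
  list(outdir = config$outdir, settings = settings, synthetic = synthetic,
       inputs = config$inputs)
}

read_input_dataset <- function(inputs) {
  genes <- read_genes(inputs$genes, inputs$genes_dialect %||% "bed")
  mods <- inputs$mods %||% list()
  # bedGraphs only declare coverage up to their last record, so chromosome
  # sizes are harmonised across all signal files (uncovered tails are 0)
  raw <- Filter(Negate(is.null), list(
    watson = read_bedgraph(inputs$netseq_watson),
    crick = read_bedgraph(inputs$netseq_crick),
    occupancy = read_bedgraph(inputs$occupancy),
    h3 = read_bedgraph(inputs$h3),
    h3ac = if (!is.null(mods$h3ac)) read_bedgraph(mods$h3ac),
    h3k36me3 = if (!is.null(mods$h3k36me3)) read_bedgraph(mods$h3k36me3)))
  chroms <- unique(unlist(lapply(raw, names)))
  sizes <- vapply(chroms, function(ch) {
    max(c(genes$end[genes$chrom == ch],
          vapply(raw, function(l) length(l[[ch]]) %||% 0L, numeric(1))))
  }, numeric(1))
  pad <- function(l) lapply(setNames(chroms, chroms), function(ch) {
    v <- l[[ch]] %||% numeric(0)
    c(v, numeric(sizes[[ch]] - length(v)))
  })
  list(
    genes = genes,
    netseq = stranded_track(pad(raw$watson), pad(raw$crick)),
    occupancy = unstranded_track(pad(raw$occupancy)),
    h3 = unstranded_track(pad(raw$h3)),
    mod_h3ac = if (!is.null(raw$h3ac)) unstranded_track(pad(raw$h3ac)),
    mod_h3k36me3 = if (!is.null(raw$h3k36me3))
      unstranded_track(pad(raw$h3k36me3)),
    nucleosomes = read_nucleosome_calls(inputs$nucleosome_calls),
    probes = if (!is.null(inputs$turnover_probes))
      read_turnover_probes(inputs$turnover_probes),
    occupancy_matrix = if (!is.null(inputs$occupancy_matrix))
      read_occupancy_matrix(inputs$occupancy_matrix)
  )
}

read_mutant_dataset <- function(inputs) {
  m <- inputs$mutant
  if (is.null(m)) return(NULL)
  list(
    netseq = read_stranded_signal(m$netseq_watson, m$netseq_crick),
    occupancy = read_unstranded_signal(m$occupancy)
  )
}
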