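#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the stages end-to-end, in the read-path order
#' triage -> tail trimming -> profiles -> poly(A) filter/cluster/export,
#' plus the independent structure-angle and conservation paths, with every
#' parameter echoed into a machine-readable run report. Unknown
#' configuration keys are rejected; a stage failure aborts with the failing
#' stage named. Given a seed, all outputs are deterministic.
#'
#' The configuration is a nested list (or a YAML file path) with top-level
#' keys `seed`, `out_dir`, and any of the sections `reads`, `structure`,
#' `conservation`:
#'
#' * `reads`: `fastq` (path) or `simulate` (arguments of
#'   [simulate_product_read_set()]); triage route via `references` (named
#'   sequences or FASTA path) with `k`, `min_hits`, or via a pre-aligned
#'   `sam` file; `min_tail`, `max_mismatch`, `thresholds`, `max_pos`,
#'   `min_polya_run`, `min_copies`.
#' * `structure`: `path` (PDB/mmCIF) or `simulate` (arguments of
#'   [simulate_planar_assembly()]); `units`; optional `axis_mode`,
#'   `helix_range`.
#' * `conservation`: `alignment` (aligned FASTA path) or `simulate`
#'   (arguments of [simulate_ncrna_family()]); `reference_id`;
#'   `min_consensus`, `min_len`, `rna`.
#'
#' When `out_dir` is set, stage tables are written as TSV, the motif input
#' as FASTA, and the report as JSON.
#'
#' @param config Nested list or YAML file path.
#' @return A list of class `run_report`: per-stage parameters, input/output
#'   counts, results, output paths and wall-clock seconds.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  check_keys(config, c("seed", "out_dir", "reads", "structure", "conservation"),
             "top-level")
  seed <- config$seed
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = seed, out_dir = out_dir, stages = list())

  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      abort(sprintf("Pipeline stage %s failed: %s", dQuote(name),
                    conditionMessage(e)))
    })
    res$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  if (!is.null(config$reads)) {
    report$stages$reads <- run_stage("reads", function() {
      pipeline_reads(config$reads, seed = seed, out_dir = out_dir)
    })
  }
  if (!is.null(config$structure)) {
    report$stages$structure <- run_stage("structure", function() {
      pipeline_structure(config$structure, seed = seed, out_dir = out_dir)
    })
  }
  if (!is.null(config$conservation)) {
    report$stages$conservation <- run_stage("conservation", function() {
      pipeline_conservation(config$conservation, seed = seed, out_dir = out_dir)
    })
  }
  if (length(report$stages) == 0) {
    abort("Configuration selects no stage: provide `reads`, `structure` and/or `conservation`.")
  }
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(run_report_json(report),
                         file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  report
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown %s configuration key(s): %s",
                  where, paste(unknown, collapse = ", ")))
  }
  invisible(x)
}

pipeline_reads <- function(cfg, seed = NULL, out_dir = NULL) {
  check_keys(cfg, c("fastq", "simulate", "references", "sam", "k", "min_hits",
                    "min_tail", "max_mismatch", "thresholds", "max_pos",
                    "min_polya_run", "min_copies"), "reads")
  params <- list(
    k = cfg$k %||% 15L, min_hits = cfg$min_hits %||% 2L,
    min_tail = cfg$min_tail %||% 5L, max_mismatch = cfg$max_mismatch %||% 1L,
    thresholds = cfg$thresholds %||% c(5, 10, 15, 20, 25, 30, 35, 40),
    max_pos = cfg$max_pos %||% 122L,
    min_polya_run = cfg$min_polya_run %||% 10L,
    min_copies = cfg$min_copies %||% 10L
  )
  out <- list(params = params, warnings = character())
  note <- function(msg) out$warnings <<- c(out$warnings, msg)

  # --- input
  if (!is.null(cfg$sam)) {
    unmapped <- withCallingHandlers(
      read_sam_unmapped(cfg$sam),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    out$counts <- list(n_input = NA_integer_, n_unmapped = nrow(unmapped))
    out$route <- "sam"
  } else {
    reads <- if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- seed
      do.call(simulate_product_read_set, sim_args)
    } else if (!is.null(cfg$fastq)) {
      read_fastx(cfg$fastq)
    } else {
      abort("`reads` needs one of: fastq, simulate, sam.")
    }
    if (nrow(reads) == 0) abort("Empty read set.")
    out$counts <- list(n_input = nrow(reads))
    if (!is.null(cfg$references)) {
      refs <- cfg$references
      if (is.character(refs) && length(refs) == 1 && file.exists(refs)) {
        tbl <- read_fastx(refs)
        refs <- setNames(tbl$seq, tbl$read_id)
      }
      triage <- triage_reads(reads, refs, k = params$k,
                             min_hits = params$min_hits)
      stopifnot(nrow(triage$assignments) == nrow(reads))
      out$triage <- glance(triage)
      unmapped <- unmapped_reads(reads, triage)
      out$route <- "kmer"
    } else {
      unmapped <- reads
      out$route <- "all_unmapped"
    }
    out$counts$n_unmapped <- nrow(unmapped)
  }
  if (nrow(unmapped) == 0) abort("No unmapped reads to analyze.")

  # --- trim, profiles
  out$composition_raw <- base_composition(unmapped)
  trimmed <- withCallingHandlers(
    trim_polyc_tail(unmapped, min_tail = params$min_tail,
                    max_mismatch = params$max_mismatch),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  out$trim <- trim_report(trimmed)
  out$counts$n_after_trim <- nrow(trimmed)
  stopifnot(nrow(trimmed) + out$trim$reads_dropped_all_tail == nrow(unmapped))
  out$spectrum <- homopolymer_spectrum(trimmed, thresholds = params$thresholds)
  out$ncpm <- n_count_cpm(trimmed)
  out$positional <- positional_frequency(trimmed, max_pos = params$max_pos)

  # --- cluster / motif input
  polya <- filter_polya(trimmed, min_run = params$min_polya_run)
  out$counts$n_polya <- nrow(polya)
  clusters <- cluster_identical(polya)
  stopifnot(sum(clusters$n_copies) == nrow(polya))
  retained <- retain_min_copies(clusters, min_copies = params$min_copies)
  out$counts$n_clusters <- nrow(clusters)
  out$counts$n_retained <- nrow(retained)
  out$clusters <- retained

  if (!is.null(out_dir)) {
    paths <- list(
      spectrum = file.path(out_dir, "homopolymer_spectrum.tsv"),
      positional = file.path(out_dir, "positional_frequency.tsv"),
      composition = file.path(out_dir, "base_composition.tsv"),
      clusters = file.path(out_dir, "clusters.tsv"),
      meme_fasta = file.path(out_dir, "meme_input.fasta")
    )
    readr::write_tsv(tidy(out$spectrum), paths$spectrum)
    readr::write_tsv(tidy(out$positional), paths$positional)
    readr::write_tsv(dplyr::bind_rows(
      dplyr::mutate(out$composition_raw, stage = "pre_trim"),
      dplyr::mutate(out$trim$composition_after, stage = "post_trim")),
      paths$composition)
    readr::write_tsv(dplyr::select(as_tibble(clusters), -"member_ids"),
                     paths$clusters)
    suppressWarnings(export_meme_fasta(retained, paths$meme_fasta))
    out$meme_command <- meme_command(paths$meme_fasta)
    out$paths <- paths
  } else {
    out$meme_command <- meme_command("meme_input.fasta")
  }
  out
}

pipeline_structure <- function(cfg, seed = NULL, out_dir = NULL) {
  check_keys(cfg, c("path", "simulate", "units", "axis_mode", "helix_range",
                    "windows"), "structure")
  model <- if (!is.null(cfg$path)) {
    read_structure(cfg$path)
  } else if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    do.call(simulate_planar_assembly, sim_args)
  } else {
    abort("`structure` needs one of: path, simulate.")
  }
  units <- cfg$units %||% lapply(unique(model$chain), identity)
  args <- list(structure = model, units = units)
  if (!is.null(cfg$axis_mode)) args$axis_mode <- cfg$axis_mode
  if (!is.null(cfg$helix_range)) args$helix_range <- cfg$helix_range
  if (!is.null(cfg$windows)) args$windows <- cfg$windows
  rep <- do.call(assembly_report, args)
  out <- list(params = list(units = names(rep$frames),
                            axis_mode = cfg$axis_mode %||% "unit_pca"),
              counts = list(n_units = length(rep$frames),
                            n_atoms = nrow(model)),
              report = rep, summary = glance(rep))
  if (!is.null(out_dir)) {
    path <- file.path(out_dir, "assembly_angles.json")
    jsonlite::write_json(
      list(normal = rep$normal, angles = rep$angles,
           median_angle_deg = rep$median_angle,
           classification = rep$classification),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    out$paths <- list(angles = path)
  }
  out
}

pipeline_conservation <- function(cfg, seed = NULL, out_dir = NULL) {
  check_keys(cfg, c("alignment", "simulate", "reference_id", "min_consensus",
                    "min_len", "rna"), "conservation")
  params <- list(min_consensus = cfg$min_consensus %||% 0.95,
                 min_len = cfg$min_len %||% 4L,
                 rna = cfg$rna %||% FALSE)
  if (!is.null(cfg$alignment)) {
    aln <- read_alignment(cfg$alignment)
    ref_id <- cfg$reference_id %||% aln$id[1]
  } else if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    fam <- do.call(simulate_ncrna_family, sim_args)
    aln <- fam$alignment
    ref_id <- fam$reference_id
  } else {
    abort("`conservation` needs one of: alignment, simulate.")
  }
  stripped <- strip_reference_gaps(aln, ref_id)
  profile <- column_profile(stripped)
  tracts <- conserved_tracts(profile, min_consensus = params$min_consensus,
                             min_len = params$min_len, rna = params$rna)
  out <- list(params = c(params, list(reference_id = ref_id)),
              counts = list(n_sequences = nrow(aln),
                            n_columns_in = nchar(aln$seq[1]),
                            n_columns_stripped = nrow(profile),
                            n_tracts = nrow(tracts)),
              profile = profile, tracts = tracts)
  if (!is.null(out_dir)) {
    paths <- list(profile = file.path(out_dir, "conservation_profile.tsv"),
                  tracts = file.path(out_dir, "conserved_tracts.tsv"))
    readr::write_tsv(tidy(profile), paths$profile)
    readr::write_tsv(tracts, paths$tracts)
    out$paths <- paths
  }
  out
}

# Reduce a run report to JSON-friendly scalars/tables.
run_report_json <- function(report) {
  strip <- function(x) {
    if (inherits(x, "assembly_angles")) return(glance(x))
    if (is.data.frame(x)) return(as_tibble(unclass(x)))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  list(seed = report$seed,
       stages = lapply(report$stages, function(st) {
         st$report <- NULL
         st$profile <- NULL
         st$positional <- NULL
         if (!is.null(st$clusters) && "member_ids" %in% names(st$clusters)) {
           st$clusters <- dplyr::select(as_tibble(st$clusters), -"member_ids")
         }
         strip(st)
       }))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> stages: %s\n",
              paste(names(x$stages), collapse = ", ")))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %s: %s (%.2fs)\n", nm,
                paste(sprintf("%s=%s", names(st$counts), unlist(st$counts)),
                      collapse = ", "),
                st$elapsed_s))
  }
  invisible(x)
}
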