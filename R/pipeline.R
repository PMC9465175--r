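# Pipeline orchestration: one validated configuration drives all report
# stages and emits the report bundle.

default_run_config <- function() list(
  fasta = NULL,
  feature_table = NULL,
  genbank = NULL,
  genome_length = NULL,
  genetic_code = "standard",
  gc_skew_orientation = "g_minus_c",
  min_homopolymer = 10L,
  microsat_unit = 2L,
  microsat_min_copies = 5L,
  min_repeat = 30L,
  junction_pairs = list(c("atp8", "atp6"), c("trnS2", "nad1")),
  junction_motifs = c("ATGATAA", "TTAACTA"),
  flanks = c(15L, 15L),
  max_mismatch = 0L,
  outdir = "mitoprofile_reports",
  verbose = TRUE)

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration, fills defaults and rejects unknown keys.
#' An empty file yields all defaults.
#'
#' @param path YAML file, or `NULL`/a list for programmatic use.
#' @return validated configuration list (class `RunConfig`).
#' @export
validate_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
          else if (is.list(path)) path
          else {
            if (!file.exists(path)) stop("no such config file: ", path)
            yaml::read_yaml(path) %||% list()
          }
  defaults <- default_run_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  if (!cfg$genetic_code %in% c("standard", "invertebrate_mito"))
    stop("genetic_code must be 'standard' or 'invertebrate_mito', got '",
         cfg$genetic_code, "'")
  if (!cfg$gc_skew_orientation %in% c("g_minus_c", "c_minus_g"))
    stop("gc_skew_orientation must be 'g_minus_c' or 'c_minus_g', got '",
         cfg$gc_skew_orientation, "'")
  for (p in c("fasta", "feature_table", "genbank")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("config ", p, " file does not exist: ", cfg[[p]])
  }
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Run the full report pipeline
#'
#' Loads the genome and annotation (GenBank, or FASTA plus a
#' Table-2-dialect feature table), runs every analysis stage and writes
#' the report bundle: `table2_like.tsv` (arrangement), `table3_like.tsv`
#' (composition), `table4_like.tsv` (codon usage), `control_region.tsv`,
#' `junctions.tsv`, `trna_structures.txt` and `summary.log`. Stage timings
#' go to the log; rerunning with identical inputs and configuration gives
#' byte-identical outputs.
#'
#' @param config a [validate_config()] result (or list/path accepted by
#'   it), or a list with `genome`/`table` entries supplied in memory.
#' @param genome,table optional in-memory inputs overriding file inputs.
#' @return named vector of output paths, invisibly.
#' @export
run_pipeline <- function(config = NULL, genome = NULL, table = NULL) {
  cfg <- if (inherits(config, "RunConfig")) config else validate_config(config)
  log_lines <- character(0)
  # timings go to stderr; the written log stays deterministic so reruns
  # are byte-identical
  log_stage <- function(stage, t0) {
    if (isTRUE(cfg$verbose))
      message(sprintf("%s: completed in %.2f s", stage,
                      as.numeric(proc.time()[3] - t0)))
    log_lines <<- c(log_lines, sprintf("%s: completed", stage))
  }

  t0 <- proc.time()[3]
  if (is.null(genome) || is.null(table)) {
    if (!is.null(cfg$genbank)) {
      gb <- read_genbank(cfg$genbank)
      genome <- gb$genome; table <- gb$table
    } else if (!is.null(cfg$fasta) && !is.null(cfg$feature_table)) {
      genome <- read_fasta(cfg$fasta)[[1]]
      table <- read_feature_table(cfg$feature_table, genome$length,
                                  genome_id = genome$id)
    } else {
      stop("no input: supply genbank, or fasta + feature_table ",
           "(missing annotation path)")
    }
  }
  log_stage("load", t0)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(arrangement = file.path(cfg$outdir, "table2_like.tsv"),
             composition = file.path(cfg$outdir, "table3_like.tsv"),
             codons = file.path(cfg$outdir, "table4_like.tsv"),
             control_region = file.path(cfg$outdir, "control_region.tsv"),
             junctions = file.path(cfg$outdir, "junctions.tsv"),
             trna = file.path(cfg$outdir, "trna_structures.txt"),
             log = file.path(cfg$outdir, "summary.log"))

  t0 <- proc.time()[3]
  write_feature_table(table, paths["arrangement"])
  log_stage("arrangement", t0)

  t0 <- proc.time()[3]
  comp <- composition_report(genome, table,
                             gc_orientation = cfg$gc_skew_orientation)
  write_composition_report(comp, paths["composition"])
  log_stage("composition", t0)

  t0 <- proc.time()[3]
  pcgs <- Filter(function(f) f$gene_class == "PCG", table$features)
  partition <- genetic_code_partition(cfg$genetic_code)
  if (length(pcgs)) {
    cds <- vapply(pcgs, function(f) extract_feature_sequence(genome, f),
                  character(1))
    usage <- codon_usage_report(count_codons(cds), partition)
    utils::write.table(usage, paths["codons"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  log_stage("codons", t0)

  t0 <- proc.time()[3]
  cr <- region_report(genome, table, cfg$min_homopolymer, cfg$microsat_unit,
                      cfg$microsat_min_copies, cfg$min_repeat)
  utils::write.table(cr$features, paths["control_region"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("control_region", t0)

  t0 <- proc.time()[3]
  names_avail <- vapply(table$features, `[[`, character(1), "name")
  jrows <- list()
  for (i in seq_along(cfg$junction_pairs)) {
    pair <- cfg$junction_pairs[[i]]
    if (!all(pair %in% names_avail)) {
      warning("junction pair ", paste(pair, collapse = "/"),
              " not annotated; skipped")
      next
    }
    w <- junction_window(genome, table, pair[1], pair[2],
                         cfg$flanks[1], cfg$flanks[2])
    motif <- cfg$junction_motifs[min(i, length(cfg$junction_motifs))]
    hits <- motif_scan(list(w), motif, cfg$max_mismatch)
    jrows[[length(jrows) + 1L]] <- data.frame(
      gene_a = pair[1], gene_b = pair[2], window = w$seq,
      motif = motif, n_hits = nrow(hits),
      first_hit = if (nrow(hits)) hits$position[1] else NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (length(jrows))
    utils::write.table(do.call(rbind, jrows), paths["junctions"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  log_stage("junctions", t0)

  t0 <- proc.time()[3]
  has_trna <- any(vapply(table$features, `[[`, character(1),
                         "gene_class") == "tRNA")
  if (has_trna) {
    folds <- fold_all(genome, table)
    utils::write.table(folds$report, paths["trna"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  log_stage("trna", t0)

  writeLines(c(sprintf("mitoprofile %s",
                       as.character(utils::packageVersion("mitoprofile"))),
               sprintf("genome: %s (%d bp)", genome$id, genome$length),
               sprintf("genetic_code: %s", cfg$genetic_code),
               sprintf("gc_skew_orientation: %s", cfg$gc_skew_orientation),
               log_lines),
             paths["log"])
  invisible(paths)
}
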