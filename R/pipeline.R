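#' Run configuration for an end-to-end pipeline run
#'
#' Collects inputs and stage parameters. All referenced files are checked at
#' construction time, before any compute.
#'
#' @param genome_paths Character vector of genome files (GenBank, or FASTA
#'   with GFF3 sidecars).
#' @param metadata_path Optional metadata TSV ([read_genome_metadata()]).
#' @param out_dir Output directory.
#' @param homology A [homology_params()] object.
#' @param ani An [ani_params()] object.
#' @param detection A [detection_params()] object.
#' @param hits_path Optional precomputed hit TSV (internal schema, see
#'   [write_hits_tsv()]); skips the search stage.
#' @param ani_path Optional precomputed ANI TSV; skips the ANI stage.
#' @param annotations_path Optional functional annotation TSV.
#' @return A `run_config` list.
#' @export
run_config <- function(genome_paths, metadata_path = NULL, out_dir,
                       homology = homology_params(), ani = ani_params(),
                       detection = detection_params(),
                       hits_path = NULL, ani_path = NULL,
                       annotations_path = NULL) {
  for (p in c(genome_paths, metadata_path, hits_path, ani_path,
              annotations_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured input does not exist: ", p, call. = FALSE)
    }
  }
  if (length(genome_paths) < 2L) {
    stop("need at least two genomes", call. = FALSE)
  }
  structure(list(
    genome_paths = genome_paths, metadata_path = metadata_path,
    out_dir = out_dir, homology = homology, ani = ani,
    detection = detection, hits_path = hits_path, ani_path = ani_path,
    annotations_path = annotations_path
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys: `genomes` (list of paths or a directory), `metadata`, `out_dir`,
#' `hits`, `ani_table`, `annotations`, and parameter blocks `homology`,
#' `ani`, `detection` whose entries override the corresponding constructor
#' defaults.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  genomes <- y$genomes
  if (length(genomes) == 1L && dir.exists(genomes[[1L]])) {
    genomes <- list.files(genomes[[1L]],
                          pattern = "\\.(gb|gbk|gbff|fa|fna|fasta)$",
                          full.names = TRUE)
  }
  build <- function(ctor, overrides) {
    if (is.null(overrides)) ctor() else do.call(ctor, overrides)
  }
  run_config(
    genome_paths = unlist(genomes),
    metadata_path = y$metadata,
    out_dir = if (is.null(y$out_dir)) "." else y$out_dir,
    homology = build(homology_params, y$homology),
    ani = build(ani_params, y$ani),
    detection = build(detection_params, y$detection),
    hits_path = y$hits, ani_path = y$ani_table,
    annotations_path = y$annotations)
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[hgtscan:%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Stages: ingest genomes, ANI matrix (or load precomputed), all-vs-all
#' homology search (or load precomputed hits), detection (filter, islands,
#' groups), summaries. Every stage's table is persisted as TSV under
#' `out_dir`, and a JSON manifest records resolved parameters, input
#' checksums and per-stage counts. Re-running with identical inputs gives
#' byte-identical TSV outputs. On error, partial outputs are kept and a
#' `FAILED` marker file names the failing stage.
#'
#' @param config A `run_config` from [run_config()] / [read_run_config()].
#' @return An `hgt_run` list: genomes, meta, ani, hits, detection,
#'   summaries, manifest (invisibly written to `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(config$out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  stage <- "ingest"
  result <- tryCatch({
    pipeline_log(stage, "reading %d genome(s)", length(config$genome_paths))
    genomes <- lapply(config$genome_paths, read_genome)
    ids <- vapply(genomes, `[[`, "", "genome_id")
    if (anyDuplicated(ids)) stop("duplicated genome_id among inputs")
    meta <- if (!is.null(config$metadata_path)) {
      read_genome_metadata(config$metadata_path)
    } else metadata_from_genomes(genomes)
    genomes <- apply_metadata(genomes, meta)
    gtab <- do.call(rbind, lapply(genomes, genes_table))
    write.table(gtab, file.path(config$out_dir, "genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    pipeline_log(stage, "%d genomes, %d CDS", length(genomes), nrow(gtab))

    stage <- "ani"
    ani <- if (!is.null(config$ani_path)) {
      pipeline_log(stage, "loading precomputed ANI from %s", config$ani_path)
      read_ani_tsv(config$ani_path, genome_ids = ids)
    } else {
      build_ani_matrix(genomes, config$ani)
    }
    write_ani_tsv(ani, file.path(config$out_dir, "ani.tsv"))
    pipeline_log(stage, "%d pairs (%d defined)", nrow(ani),
                 sum(ani$defined))

    stage <- "search"
    hits <- if (!is.null(config$hits_path)) {
      pipeline_log(stage, "loading precomputed hits from %s",
                   config$hits_path)
      read_hits_tsv(config$hits_path)
    } else {
      search_all_vs_all(genomes, config$homology)
    }
    write_hits_tsv(hits, file.path(config$out_dir, "hits.tsv"))
    pipeline_log(stage, "%d hits", nrow(hits))

    stage <- "detect"
    det <- detect_hgt(hits, ani, genomes, meta, config$detection)
    write_detection_tsvs(det, config$out_dir)
    pipeline_log(stage, "%d candidates, %d islands, %d groups",
                 nrow(det$candidates), nrow(det$islands), nrow(det$groups))

    stage <- "summarize"
    per_genome <- per_genome_summary(det, genomes)
    write.table(per_genome, file.path(config$out_dir, "per_genome.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tallies <- NULL
    if (!is.null(config$annotations_path)) {
      ann <- load_annotations(config$annotations_path)
      tallies <- list(
        all_cds = tally_categories(det$candidates, ann, "all_cds"),
        annotated_only = tally_categories(det$candidates, ann,
                                          "annotated_only"))
      write.table(tallies$all_cds,
                  file.path(config$out_dir, "category_tally.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    footer <- attr(per_genome, "footer")
    pipeline_log(stage, "%d/%d genomes carry HGT candidates (%.1f%%)",
                 footer$n_with_hgt, footer$n_genomes, footer$pct_with_hgt)

    manifest <- build_manifest(config, genomes, hits, det, footer)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    structure(list(genomes = genomes, meta = meta, ani = ani, hits = hits,
                   detection = det, per_genome = per_genome,
                   tallies = tallies, manifest = manifest),
              class = "hgt_run")
  }, error = function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               failed_marker)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

write_detection_tsvs <- function(det, out_dir) {
  cand <- merge(det$candidates,
                merge(det$members[c("island_id", "genome_id", "gene_id")],
                      det$island_groups, by = "island_id"),
                by = c("genome_id", "gene_id"), all.x = TRUE)
  cand <- cand[order(cand$genome_id, cand$gene_id), , drop = FALSE]
  write.table(cand, file.path(out_dir, "candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(det$islands, file.path(out_dir, "islands.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(det$groups, file.path(out_dir, "groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(det$connections, file.path(out_dir, "connections.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(det$promiscuous, file.path(out_dir, "promiscuous.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

build_manifest <- function(config, genomes, hits, det, footer) {
  version <- as.character(utils::packageVersion("hgtscan"))
  checksums <- vapply(config$genome_paths, function(p)
    unname(tools::md5sum(p)), "")
  list(
    tool = "hgtscan", version = version,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(
      homology = unclass(config$homology),
      ani = unclass(config$ani),
      detection = unclass(config$detection)),
    inputs = list(genomes = as.list(checksums),
                  metadata = config$metadata_path),
    counts = list(
      genomes = length(genomes),
      genes = sum(vapply(genomes, function(g) nrow(g$genes), 0L)),
      hits = nrow(hits),
      candidates = nrow(det$candidates),
      islands = nrow(det$islands),
      groups = nrow(det$groups),
      genomes_with_hgt = footer$n_with_hgt,
      pct_genomes_with_hgt = footer$pct_with_hgt))
}
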