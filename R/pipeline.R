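#' Run the small-RNA analysis pipeline end to end
#'
#' Executes the stages in their fixed order — preprocess, miRNA profiling,
#' differential expression, target prediction, siRNA discovery, siRNA
#' clusters — writing the TSV outputs of each stage under \code{outdir} and
#' a JSON run manifest (config hash, per-stage outputs and row counts, tool
#' version, seed). A subset of stages can be requested; later stages then
#' reuse the in-memory results of the stages run before them, so the subset
#' must be a prefix-closed selection.
#'
#' @param inputs named list of input paths: \code{libraries} (named
#'   character vector of FASTQ/FASTA files, names are library ids),
#'   \code{mirna_ref}, \code{contaminants}, \code{transcripts},
#'   \code{repeats}, \code{repeat_annotation} (TSV with columns
#'   \code{reference}, \code{class}), \code{est_ids} (character vector).
#' @param outdir output directory.
#' @param config an \code{srna_config} list (or path to a YAML config).
#' @param stages optional character subset of
#'   \code{c("preprocess", "profile", "diffexp", "targets", "sirna",
#'   "clusters")}.
#' @return the run manifest (invisibly), a list with per-stage output paths
#'   and row counts.
#' @export
run_pipeline <- function(inputs, outdir, config = pipeline_config(),
                         stages = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  all_stages <- c("preprocess", "profile", "diffexp", "targets", "sirna",
                  "clusters")
  if (is.null(stages)) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  need <- all_stages[seq_len(max(match(stages, all_stages)))]
  for (f in c("mirna_ref", "contaminants", "transcripts")) {
    if (!is.null(inputs[[f]]) && !file.exists(inputs[[f]])) {
      stop("missing input file for '", f, "': ", inputs[[f]])
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "canesrna",
                   version = as.character(utils::packageVersion("canesrna")),
                   seed = config$rng_seed,
                   stages = list())
  note <- function(stage, path, rows) {
    manifest$stages[[stage]] <<- c(manifest$stages[[stage]],
                                   list(list(output = basename(path),
                                             rows = rows)))
  }

  ## preprocess -------------------------------------------------------------
  contaminants <- read_fasta(inputs$contaminants)
  read_list <- list()
  reports <- list()
  for (lib in names(inputs$libraries)) {
    raw <- read_sequences(inputs$libraries[[lib]])
    res <- preprocess_library(raw, contaminants, config)
    read_list[[lib]] <- res$reads
    reports[[lib]] <- cbind(data.frame(library = lib), res$report)
    fa <- file.path(outdir, paste0(lib, "_collapsed.fasta"))
    write_collapsed_fasta(res$reads, fa)
    note("preprocess", fa, nrow(res$reads))
  }
  report <- do.call(rbind, reports)
  rp <- write_table(report, file.path(outdir, "filter_report.tsv"))
  note("preprocess", rp, nrow(report))
  libraries <- data.frame(id = names(read_list),
                          total_filtered_reads =
                            report$after_contaminant,
                          stringsAsFactors = FALSE)
  counts <- merge_libraries(read_list)
  result <- list(reports = report, libraries = libraries, counts = counts)
  if (!"profile" %in% need) return(finish_manifest(manifest, config, outdir,
                                                   result))

  ## miRNA profiling ---------------------------------------------------------
  mirna_ref <- read_fasta(inputs$mirna_ref)
  profile <- profile_mirnas(counts, mirna_ref, libraries, config)
  expr <- profile$expression
  expr_out <- expr
  for (lib in libraries$id) {
    expr_out[[paste0("rpm_", lib)]] <- format_rpm(expr[[paste0("rpm_", lib)]])
  }
  en <- write_table(expr_out, file.path(outdir, "electronic_northern.tsv"))
  note("profile", en, nrow(expr))
  if (nrow(profile$hits)) {
    comp <- composition_summary(profile$hits, config$l_min, config$l_max)
    cp <- write_table(comp$length_hist, file.path(outdir, "composition.tsv"))
    note("profile", cp, nrow(comp$length_hist))
  }
  result$profile <- profile
  if (!"diffexp" %in% need) return(finish_manifest(manifest, config, outdir,
                                                   result))

  ## differential expression -------------------------------------------------
  pairs <- utils::combn(libraries$id, 2L)
  calls <- lapply(seq_len(ncol(pairs)), function(k) {
    test_differential_expression(expr, pairs[1L, k], pairs[2L, k],
                                 libraries, config$alpha)
  })
  calls <- do.call(rbind, calls)
  rc <- write_table(calls, file.path(outdir, "regulation_calls.tsv"))
  note("diffexp", rc, nrow(calls))
  result$regulation <- calls
  if (!"targets" %in% need) return(finish_manifest(manifest, config, outdir,
                                                   result))

  ## target prediction --------------------------------------------------------
  transcripts <- read_fasta(inputs$transcripts)
  matched <- unique(profile$hits$sequence)
  names(matched) <- profile$hits$mirna_id[match(matched,
                                                profile$hits$sequence)]
  sites <- predict_targets(matched, transcripts, config)
  ts <- write_table(sites, file.path(outdir, "target_sites.tsv"))
  note("targets", ts, nrow(sites))
  result$sites <- sites
  if (!"sirna" %in% need) return(finish_manifest(manifest, config, outdir,
                                                 result))

  ## siRNA discovery -----------------------------------------------------------
  cand <- find_sirna_candidates(profile, sites, transcripts, counts, config)
  cand_out <- cand
  attr(cand_out, "venn") <- NULL
  sc <- write_table(cand_out, file.path(outdir, "sirna_candidates.tsv"))
  note("sirna", sc, nrow(cand))
  if (!is.null(attr(cand, "venn"))) {
    vn <- write_table(attr(cand, "venn"),
                      file.path(outdir, "venn_sirna.tsv"))
    note("sirna", vn, nrow(attr(cand, "venn")))
  }
  result$sirna <- cand
  if (!"clusters" %in% need) return(finish_manifest(manifest, config, outdir,
                                                    result))

  ## siRNA clusters -------------------------------------------------------------
  refs <- read_fasta(inputs$repeats)
  annot <- read_table_tsv(inputs$repeat_annotation)
  pool <- counts[!(counts$sequence %in% profile$hits$sequence), ,
                 drop = FALSE]
  mapping <- map_reads_to_references(pool, refs, libraries$id)
  clusters <- build_clusters(mapping$placements, config$merge_gap)
  tab <- annotate_clusters(mapping, pool, annot, inputs$est_ids,
                           libraries$id)
  ct <- write_table(clusters, file.path(outdir, "cluster_table.tsv"))
  note("clusters", ct, nrow(clusters))
  fr <- cbind(data.frame(category = rownames(tab$fractions)),
              tab$fractions)
  cf <- write_table(fr, file.path(outdir, "category_fractions.tsv"))
  note("clusters", cf, nrow(fr))
  lh <- write_table(tab$length_hist,
                    file.path(outdir, "category_length_hist.tsv"))
  note("clusters", lh, nrow(tab$length_hist))
  result$clusters <- clusters
  result$cluster_fractions <- tab$fractions
  result$cluster_length_hist <- tab$length_hist
  finish_manifest(manifest, config, outdir, result)
}

finish_manifest <- function(manifest, config, outdir, result) {
  cfg <- config
  cfg$inputs <- NULL
  manifest$config_hash <- substr(
    tools::md5sum(files = {
      f <- tempfile()
      writeLines(yaml::as.yaml(cfg[order(names(cfg))]), f)
      f
    })[[1L]], 1L, 12L)
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  result$manifest <- manifest
  invisible(result)
}
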