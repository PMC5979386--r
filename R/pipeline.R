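# Orchestration of the full analysis: preprocess -> mirna_discovery ->
# quantify_de -> degradome_targets -> go_enrichment, with a run manifest
# and deterministic outputs under a fixed seed.

stage_defaults <- function() list(
  preprocess = list(min_overlap = 5L, len_range = c(18L, 30L),
                    max_mono = 0.8, min_quality = 20),
  discovery = list(flank = 250L, rpm_cutoff = 2, min_libraries = 2L,
                   mfe_ceiling = -18.2, min_paired = 14L,
                   dominance = 0.7, mature_len = c(20L, 23L),
                   max_loci = 20L),
  de = list(pseudocount = 0.01),
  degradome = list(min_tag_len = 15L, score_cutoff = 7, alpha = 0.05,
                   n_perm = 1000L, cut_pos = 10L),
  go = list(alpha = 0.05))

#' Assemble and validate a pipeline configuration
#'
#' @param unigenes,catalog,contaminants,go_annotation,fragment_counts
#'   input file paths (`fragment_counts` optional).
#' @param srna named character vector of sRNA FASTQ paths, one per
#'   library.
#' @param degradome named character vector of degradome FASTA/FASTQ
#'   paths (NULL disables the degradome and GO stages).
#' @param adaptor3 3' adaptor to trim from the sRNA reads.
#' @param outdir output directory.
#' @param seed RNG seed for the stochastic stages.
#' @param params per-stage parameter overrides: a named list of lists
#'   with blocks `preprocess`, `discovery`, `de`, `degradome`, `go`;
#'   unknown block or parameter names are rejected.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(unigenes, srna, catalog, contaminants,
                            adaptor3, outdir, degradome = NULL,
                            go_annotation = NULL, fragment_counts = NULL,
                            seed = 1L, params = list()) {
  over <- params
  pars <- stage_defaults()
  bad <- setdiff(names(over), names(pars))
  if (length(bad)) stop("unknown configuration block: ",
                        paste(bad, collapse = ", "))
  for (st in names(over)) {
    bad <- setdiff(names(over[[st]]), names(pars[[st]]))
    if (length(bad)) stop("unknown parameter in '", st, "': ",
                          paste(bad, collapse = ", "))
    pars[[st]][names(over[[st]])] <- over[[st]]
  }
  cfg <- list(unigenes = unigenes, srna = srna, catalog = catalog,
              contaminants = contaminants, degradome = degradome,
              go_annotation = go_annotation,
              fragment_counts = fragment_counts, adaptor3 = adaptor3,
              outdir = outdir, seed = as.integer(seed), params = pars)
  req <- c(cfg$unigenes, cfg$srna, cfg$catalog, cfg$contaminants,
           cfg$degradome, cfg$go_annotation, cfg$fragment_counts)
  missing <- req[!file.exists(req)]
  if (length(missing))
    stop("configuration error, input file(s) not found: ",
         paste(missing, collapse = ", "))
  if (is.null(names(cfg$srna)) || any(!nzchar(names(cfg$srna))))
    stop("srna paths must be named by library")
  if (!is.null(cfg$degradome) &&
      !identical(sort(names(cfg$degradome)), sort(names(cfg$srna))))
    stop("degradome paths must be named by the same libraries as srna")
  structure(cfg, class = "pipeline_config")
}

# convenience: pipeline config pointing at a generated synthetic bundle
#' @rdname pipeline_config
#' @param bundle result of [generate_dataset()] (or its `paths` element).
#' @export
pipeline_config_from_bundle <- function(bundle, outdir, seed = 1L,
                                        adaptor3 = "TGGAATTCTCGGGTGCCAAGG",
                                        params = list()) {
  p <- if (!is.null(bundle$paths)) bundle$paths else bundle
  pipeline_config(unigenes = p$unigenes, srna = p$srna,
                  catalog = p$catalog, contaminants = p$contaminants,
                  degradome = p$degradome, go_annotation = p$go_annotation,
                  fragment_counts = p$fragment_counts,
                  adaptor3 = adaptor3, outdir = outdir, seed = seed,
                  params = params)
}

read_srna_library <- function(path, min_quality = 20) {
  if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) {
    x <- read_fastq(path)
    q <- methods::as(Biostrings::quality(x), "IntegerList")
    mq <- vapply(q, function(v) mean(v), numeric(1))
    as.character(x)[mq >= min_quality]
  } else if (grepl("_x[0-9]+", readLines(path, n = 1))) {
    cf <- read_collapsed_fasta(path)
    rep(cf$sequence, cf$count)
  } else {
    as.character(Biostrings::readDNAStringSet(path))
  }
}

#' Run the complete pipeline
#'
#' Executes preprocessing, miRNA discovery, differential expression over
#' all library pairs, degradome target calling per library, and GO
#' enrichment of the union of target genes; writes all result tables
#' under `config$outdir` together with a JSON run manifest. Reruns with
#' the same config and seed reproduce the result tables byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `tags`, `mirnas`, `precursors`, `de`,
#'   `sites`, `enrichment`, `fpkm`, `summary`, `paths`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  pars <- config$params
  libs <- names(config$srna)
  set.seed(config$seed)

  ## preprocess ---------------------------------------------------------
  message("[preprocess] reading and cleaning ", length(libs), " libraries")
  reads <- lapply(config$srna, read_srna_library,
                  min_quality = pars$preprocess$min_quality)
  trimmed <- lapply(reads, trim_adaptor, adaptor3 = config$adaptor3,
                    min_overlap = pars$preprocess$min_overlap)
  tags0 <- filter_and_collapse(trimmed, pars$preprocess$len_range,
                               pars$preprocess$max_mono)
  rc <- remove_contaminants(tags0, config$contaminants)
  tags <- rc$tags
  message("[preprocess] clean reads: ",
          paste(tag_totals(tags), collapse = "/"),
          "; unique tags: ", nrow(tags))
  write_collapsed_fasta(tags, config$outdir)
  tag_path <- file.path(config$outdir, "tag_table.tsv")
  write_tsv(as.data.frame(tags), tag_path)
  ld <- length_distribution(tags, pars$preprocess$len_range)
  write_tsv(ld, file.path(config$outdir, "length_distribution.tsv"))
  clean_rep <- data.frame(library = libs,
                          clean_total = as.numeric(tag_totals(tags)),
                          contaminant_reads = as.numeric(rc$removed_reads))
  rem <- attr(tags, "removed")
  for (cn in colnames(rem)) clean_rep[[cn]] <- rem[libs, cn]
  write_tsv(clean_rep, file.path(config$outdir, "cleaning_report.tsv"))

  ## miRNA discovery ----------------------------------------------------
  message("[discovery] matching catalog and folding precursors")
  unigenes <- Biostrings::readDNAStringSet(config$unigenes)
  names(unigenes) <- sub("\\s.*$", "", names(unigenes))
  disc <- do.call(discover_mirnas,
                  c(list(tags = tags, catalog = config$catalog,
                         unigenes = unigenes), pars$discovery))
  mirnas <- disc$mirnas
  message("[discovery] accepted miRNAs: ", nrow(mirnas),
          " (", sum(mirnas$class == "known_perfect"), " known-perfect, ",
          sum(mirnas$class == "known_variant"), " known-variant, ",
          sum(mirnas$class == "novel"), " novel)")
  mirna_path <- file.path(config$outdir, "mirna_table.tsv")
  write_tsv(mirnas, mirna_path)
  if (length(disc$precursors)) {
    write_fasta(vapply(disc$precursors, `[[`, character(1), "sequence"),
                file.path(config$outdir, "precursors.fa"),
                names = names(disc$precursors))
    writeLines(unlist(lapply(names(disc$precursors), function(id)
      c(paste0(">", id), as_rna(disc$precursors[[id]]$sequence),
        disc$precursors[[id]]$structure))),
      file.path(config$outdir, "precursors.db"))
  }
  write_precursor_gff3(disc$precursors,
                       file.path(config$outdir, "precursors.gff3"))

  ## differential expression --------------------------------------------
  de <- list()
  if (nrow(mirnas) && length(libs) > 1) {
    cmb <- utils::combn(libs, 2)
    for (j in seq_len(ncol(cmb))) {
      pair <- cmb[, j]
      d <- differential(mirnas, pair, pars$de$pseudocount)
      de[[paste(pair, collapse = "_vs_")]] <- d
      write_tsv(d, file.path(config$outdir,
                             sprintf("de_%s_vs_%s.tsv", pair[1], pair[2])))
    }
  }

  ## FPKM table ---------------------------------------------------------
  fpkm_tab <- NULL
  if (!is.null(config$fragment_counts)) {
    fr <- read_tsv(config$fragment_counts)
    fpkm_tab <- fr[c("unigene", "length")]
    for (lib in libs) {
      cn <- paste0("fragments.", lib)
      if (cn %in% names(fr))
        fpkm_tab[[paste0("fpkm.", lib)]] <-
          fpkm(fr[[cn]], fr$length, sum(fr[[cn]]))
    }
    write_tsv(fpkm_tab, file.path(config$outdir, "fpkm_table.tsv"))
  }

  ## degradome targets --------------------------------------------------
  sites <- NULL
  enrichment <- NULL
  profiles <- list()
  if (!is.null(config$degradome) && nrow(mirnas)) {
    all_sites <- list()
    for (lib in libs) {
      message("[degradome] mapping tags and calling sites: ", lib)
      prof <- clean_and_map_tags(config$degradome[[lib]], unigenes,
                                 config$contaminants,
                                 pars$degradome$min_tag_len)
      profiles[[lib]] <- prof
      s <- call_targets(mirnas, unigenes, prof, library_id = lib,
                        score_cutoff = pars$degradome$score_cutoff,
                        alpha = pars$degradome$alpha,
                        n_perm = pars$degradome$n_perm,
                        cut_pos = pars$degradome$cut_pos)
      all_sites[[lib]] <- s
      if (nrow(s)) {
        tpd <- do.call(rbind, lapply(unique(s$transcript), function(tx)
          cbind(transcript = tx, tplot_data(prof, tx))))
        write_tsv(tpd, file.path(config$outdir,
                                 paste0("tplot_", lib, ".tsv")))
      }
    }
    sites <- do.call(rbind, all_sites)
    rownames(sites) <- NULL
    message("[degradome] called sites: ", nrow(sites),
            " (categories: ",
            paste(table(factor(sites$category, levels = 0:4)),
                  collapse = "/"), ")")
    write_tsv(sites, file.path(config$outdir, "sites.tsv"))
    writeLines(render_alignment_report(sites, mirnas, unigenes),
               file.path(config$outdir, "alignment_report.txt"))
    edges <- unique(sites[c("mirna_id", "transcript", "library")])
    write_tsv(edges, file.path(config$outdir, "edges.tsv"))

    ## GO enrichment ----------------------------------------------------
    if (!is.null(config$go_annotation) && nrow(sites)) {
      ann <- read_tsv(config$go_annotation)
      names(ann) <- c("gene", "go_id", "namespace")[seq_along(names(ann))]
      enrichment <- enrich_go(unique(sites$transcript), ann,
                              names(unigenes), pars$go$alpha)
      write_tsv(enrichment, file.path(config$outdir, "go_enrichment.tsv"))
      # bar-chart-ready summary of the terms below alpha
      write_tsv(enrichment[enrichment$shown,
                           c("term", "namespace", "k", "p_value")],
                file.path(config$outdir, "go_summary.tsv"))
    }
  }

  result <- list(tags = tags, mirnas = mirnas,
                 precursors = disc$precursors, pseudo = disc$pseudo,
                 de = de, sites = sites, enrichment = enrichment,
                 fpkm = fpkm_tab, degradome_profiles = profiles,
                 libraries = libs, outdir = config$outdir)
  result$summary <- summarize_run(result)
  write_tsv(result$summary$counts,
            file.path(config$outdir, "summary.tsv"))

  manifest <- list(
    package = "degradomiR",
    version = as.character(packageVersion("degradomiR")),
    seed = config$seed, parameters = config$params,
    inputs = lapply(
      list(unigenes = config$unigenes, catalog = config$catalog,
           contaminants = config$contaminants, srna = config$srna,
           degradome = config$degradome,
           go_annotation = config$go_annotation),
      function(p) if (is.null(p)) NULL
                  else as.list(tools::md5sum(unlist(p)))))
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(result)
}

#' Summarise a pipeline run
#'
#' Per-class miRNA counts, per-library target counts, and the number of
#' target genes shared between two and among all libraries.
#'
#' @param result list returned by [run_all()].
#' @return list with `counts` (one-row data frame) and
#'   `targets_by_library` (named list of target gene sets).
#' @export
summarize_run <- function(result) {
  libs <- result$libraries
  mir <- result$mirnas
  cls <- if (!is.null(mir) && nrow(mir)) table(
    factor(mir$class, levels = c("known_perfect", "known_variant",
                                 "novel")))
  else setNames(rep(0L, 3), c("known_perfect", "known_variant", "novel"))
  tsets <- setNames(lapply(libs, function(lib) {
    s <- result$sites
    if (is.null(s) || !nrow(s)) character(0)
    else unique(s$transcript[s$library == lib])
  }), libs)
  all_t <- unique(unlist(tsets))
  in_n <- vapply(all_t, function(tx)
    sum(vapply(tsets, function(ts) tx %in% ts, logical(1))), integer(1))
  counts <- data.frame(
    known_perfect = as.integer(cls["known_perfect"]),
    known_variant = as.integer(cls["known_variant"]),
    novel = as.integer(cls["novel"]),
    targets_total = length(all_t))
  for (lib in libs)
    counts[[paste0("targets_", lib)]] <- length(tsets[[lib]])
  counts$targets_shared_2 <- if (length(in_n)) sum(in_n == 2L) else 0L
  counts$targets_shared_all <-
    if (length(in_n)) sum(in_n == length(libs)) else 0L
  list(counts = counts, targets_by_library = tsets)
}
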