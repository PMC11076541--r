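# End-to-end orchestration: configuration, stage dispatch, TSV/JSON
# reports with provenance.

#' Default pipeline configuration
#'
#' Every stage parameter with its documented default. The returned list
#' round-trips through YAML ([read_run_config()] /
#' [write_run_config()]).
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    input = list(fasta = NULL, structure = NULL, bands = NULL),
    stages = list(scan = TRUE, blocks = TRUE, haplo = TRUE,
                  codons = FALSE, structure = FALSE, cluster = FALSE),
    scan = list(distance_model = "expected_mismatch"),
    blocks = list(max_gap = 10, min_block_sites = 2),
    haplo = list(cap = 2^20, threshold = 0.97),
    codons = list(orf_start = 1, code_table = "standard"),
    structure = list(partner_rule = "any"),
    cluster = list(coefficient = "dice", min_band_size = 0),
    consensus = list(h = 0.3),
    simulate = list(seed = 1),
    output = list(dir = "ambigscan_out", precision = 6)
  )
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && is.list(base[[k]]))
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default.
#'
#' @param path YAML file path.
#' @return Full configuration list.
#' @export
read_run_config <- function(path) {
  .merge_config(default_run_config(), yaml::read_yaml(path))
}

#' Write a pipeline configuration to YAML
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

#' Write the per-site table of a census as TSV
#' @param census A `diversity_census`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_tsv <- function(census, path) {
  stopifnot(inherits(census, "diversity_census"))
  utils::write.table(census$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.provenance <- function(config) {
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  list(package = "ambigscan",
       version = as.character(utils::packageVersion("ambigscan")),
       config_md5 = hash)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order — scan, blocks, haplo, codons,
#' structure, cluster — writing per-stage TSV/Newick/FASTA outputs and a
#' top-level JSON summary into the output directory. Identical
#' configuration (including any seeds) yields byte-identical outputs. A
#' stage failure halts the run with an error naming the stage; outputs of
#' completed stages are retained.
#'
#' @param config Configuration list (see [default_run_config()]) or path
#'   to a YAML file.
#' @param quiet Suppress progress messages (default `FALSE`; messages go
#'   to stderr).
#' @return The summary list, invisibly. The same content is written to
#'   `summary.json` in the output directory.
#' @export
run_pipeline <- function(config = default_run_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- .merge_config(default_run_config(), config)
  out_dir <- config$output$dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[ambigscan] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  summary <- list(provenance = .provenance(config), parameters = config)

  seqs <- NULL
  needs_fasta <- isTRUE(config$stages$scan) || isTRUE(config$stages$haplo) ||
    isTRUE(config$stages$codons)
  if (needs_fasta) {
    if (is.null(config$input$fasta))
      stop("stage 'input' failed: no FASTA input configured", call. = FALSE)
    seqs <- stage("input", read_ambiguous_fasta(config$input$fasta))
    say(length(seqs), " sequence(s) read from ", config$input$fasta)
  }

  census <- NULL
  if (isTRUE(config$stages$scan)) {
    census <- stage("scan", if (length(seqs) == 1L) scan_sequence(seqs)
                    else scan_alignment(seqs))
    write_site_tsv(census, file.path(out_dir, "sites.tsv"))
    write_json_report(census$census, file.path(out_dir, "census.json"))
    summary$census <- census$census
    say("scan: ", census$census$n_variable, " variable site(s)")
  }

  if (isTRUE(config$stages$blocks) && !is.null(census)) {
    blocks <- stage("blocks", detect_blocks(
      census, max_gap = config$blocks$max_gap,
      min_block_sites = config$blocks$min_block_sites))
    utils::write.table(blocks, file.path(out_dir, "blocks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$blocks <- blocks
    say("blocks: ", nrow(blocks), " block(s)")
  }

  if (isTRUE(config$stages$haplo)) {
    # counts and bounds only; explicit resolution lists are a library call
    haplo <- stage("haplo", lapply(seq_along(seqs), function(i) {
      hs <- enumerate_haplotypes(seqs[[i]], cap = 0)
      hs$source_id <- names(seqs)[i]
      split <- otu_split(seqs[[i]], threshold = config$haplo$threshold)
      list(id = names(seqs)[i],
           n_ambiguous_sites = hs$n_ambiguous_sites,
           n_haplotypes = hs$n_haplotypes,
           max_pairwise_divergence = hs$max_pairwise_divergence,
           min_allele_count = hs$min_allele_count,
           otu_threshold = split$threshold,
           otu_splits = split$splits,
           otu_margin = split$margin)
    }))
    summary$haplotypes <- haplo
    say("haplo: min allele counts ",
        paste(range(vapply(haplo, `[[`, numeric(1), "min_allele_count")),
              collapse = ".."))
  }

  if (isTRUE(config$stages$codons)) {
    tab <- stage("codons", summarize_coding(
      seqs, coding_frame(config$codons$orf_start, config$codons$code_table)))
    utils::write.table(tab$effects, file.path(out_dir, "codon_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$codons <- tab[c("n_codons_total", "n_affected_union",
                            "n_affected_per_sequence", "pct_affected_union",
                            "third_position_fraction")]
    say("codons: ", tab$n_affected_union, " nonsynonymous (union)")
  }

  if (isTRUE(config$stages$structure)) {
    if (is.null(config$input$structure))
      stop("stage 'structure' failed: no structure input configured",
           call. = FALSE)
    vr <- stage("structure", read_vienna(config$input$structure))
    sites <- if (!is.null(census)) census$sites$position
      else scan_sequence(vr$sequence)$sites$position
    rep <- stage("structure", structure_site_report(
      vr$sequence, vr$structure, sites,
      partner_rule = config$structure$partner_rule))
    summary$structure <- list(loop_fraction = rep$loop_fraction,
                              wobble_neutral_fraction =
                                rep$wobble_neutral_fraction)
    say("structure: loop fraction ", format(rep$loop_fraction))
  }

  if (isTRUE(config$stages$cluster)) {
    if (is.null(config$input$bands))
      stop("stage 'cluster' failed: no band-matrix input configured",
           call. = FALSE)
    bm <- stage("cluster", read_band_matrix(config$input$bands))
    bm <- stage("cluster", filter_bands(bm, config$cluster$min_band_size))
    d <- stage("cluster", band_distance_matrix(bm, config$cluster$coefficient))
    tree <- stage("cluster", upgma(d))
    pat <- stage("cluster", distinct_patterns(bm))
    utils::write.table(d, file.path(out_dir, "distances.tsv"),
                       sep = "\t", quote = FALSE)
    write_newick(tree, file.path(out_dir, "upgma.nwk"))
    write_json_report(
      list(n_patterns = pat$n_patterns, classes = pat$classes,
           undistinguishable_pairs = apply(pat$undistinguishable_pairs, 1,
                                           paste, collapse = "|")),
      file.path(out_dir, "patterns.json"))
    summary$cluster <- list(n_strains = nrow(bm$presence),
                            n_bands = ncol(bm$presence),
                            n_patterns = pat$n_patterns,
                            coefficient = config$cluster$coefficient,
                            newick = tree$newick)
    say("cluster: ", pat$n_patterns, " distinct pattern(s)")
  }

  write_json_report(summary, file.path(out_dir, "summary.json"))
  invisible(summary)
}
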