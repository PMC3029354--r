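#' Pipeline run configuration
#'
#' Either supply the four input paths, or set `simulate = TRUE` with a
#' [sim_config()] to generate the inputs first — exactly one of the two.
#'
#' @param gff,fasta Annotation and sequence paths.
#' @param alignments Named character vector of aligned-FASTA paths, one per
#'   family (names are the family labels).
#' @param clades Path to the species-to-clade TSV.
#' @param simulate Generate inputs with the synthetic-data module.
#' @param sim A [sim_config()] when `simulate = TRUE`.
#' @param out Output directory for the report bundle.
#' @param t A [thresholds()].
#' @param s A [scoring_scheme()].
#' @param site_identity `"column"` or `"column+phase"`.
#' @param shuffle,window_k Shuffle options for the similarity test.
#' @param seed Master seed for the similarity stage (and, when simulating,
#'   the default for `sim` if that carries none).
#' @param strict Abort on per-record projection failures (default) or
#'   collect them as warnings.
#' @return A `run_config` list.
#' @export
run_config <- function(gff = NULL, fasta = NULL, alignments = NULL,
                       clades = NULL, simulate = FALSE, sim = NULL,
                       out = "intronsites-out", t = thresholds(),
                       s = scoring_scheme(),
                       site_identity = c("column", "column+phase"),
                       shuffle = "mono", window_k = 20L, seed = 1L,
                       strict = TRUE) {
  site_identity <- match.arg(site_identity)
  have_paths <- !is.null(gff) || !is.null(fasta) || !is.null(alignments) ||
    !is.null(clades)
  if (simulate && have_paths)
    stop("supply either input paths or simulate = TRUE, not both")
  if (!simulate) {
    if (is.null(gff) || is.null(fasta) || is.null(alignments) ||
        is.null(clades))
      stop("gff, fasta, alignments and clades are all required ",
           "(or set simulate = TRUE)")
    for (p in c(gff, fasta, unname(alignments), clades))
      if (!file.exists(p)) stop("input file not found: ", p)
    if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
      stop("'alignments' must be named by family")
  } else {
    if (is.null(sim)) sim <- sim_config(seed = seed)
  }
  structure(list(gff = gff, fasta = fasta, alignments = alignments,
                 clades = clades, simulate = simulate, sim = sim, out = out,
                 t = t, s = s, site_identity = site_identity,
                 shuffle = shuffle, window_k = window_k,
                 seed = as.integer(seed), strict = strict),
            class = "run_config")
}

#' Run the full intron insertion-site analysis
#'
#' Executes the four stages end to end — gene-model extraction, site
#' projection, hot-spot detection, intron-pair similarity — and writes the
#' report bundle into the output directory: `genes.tsv`, `introns.fasta`,
#' `site_matrix_<family>.tsv`, `annotated_alignment_<family>.txt`,
#' `hotspots.tsv`, `pairs.tsv`, `pair_summary.tsv` and a machine-readable
#' `manifest.json` (package version, seed, thresholds, input digests,
#' counts, collected warnings). With one seed the bundle is byte-identical
#' across runs.
#'
#' @param cfg A [run_config()].
#' @param verbose Emit progress messages.
#' @return Invisibly, a list with the in-memory results: `genes`,
#'   `introns`, `matrices`, `hotspots`, `pairs`, `summary`, `truth` (when
#'   simulating) and `out`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (cfg$simulate) {
    simres <- simulate_dataset(cfg$sim, file.path(cfg$out, "sim"),
                               verbose = verbose)
    cfg$gff <- simres$paths$gff
    cfg$fasta <- simres$paths$fasta
    cfg$alignments <- simres$paths$alignments
    cfg$clades <- simres$paths$clades
    truth <- simres$truth
  }

  msg("reading gene models", verbose = verbose)
  genes <- read_gene_models(cfg$gff, cfg$fasta, verbose = verbose)
  introns <- extract_all_introns(genes, cfg$fasta, verbose = verbose)
  clades <- read_clade_table(cfg$clades)

  gt <- gene_table(genes, introns)
  write_tsv(gt, file.path(cfg$out, "genes.tsv"))
  write_introns_fasta(introns, file.path(cfg$out, "introns.fasta"))

  msg("projecting insertion sites", verbose = verbose)
  matrices <- list()
  for (f in names(cfg$alignments)) {
    aln <- read_family_alignment(cfg$alignments[[f]], f)
    sm <- build_site_matrix(introns, aln, clades, genes = genes,
                            site_identity = cfg$site_identity,
                            strict = cfg$strict, verbose = verbose)
    matrices[[f]] <- sm
    write_site_matrix(sm, file.path(cfg$out,
                                    sprintf("site_matrix_%s.tsv", f)))
    write_annotated_alignment(sm, aln, file.path(
      cfg$out, sprintf("annotated_alignment_%s.txt", f)))
  }

  msg("detecting hot spots", verbose = verbose)
  hs <- hotspot_report(matrices, clades, cfg$t)
  write_tsv(hs, file.path(cfg$out, "hotspots.tsv"))

  msg("testing intron-pair similarity (", cfg$t$n_shuffles,
      " shuffles per pair)", verbose = verbose)
  pairs <- find_similar_pairs(introns, matrices, t = cfg$t, s = cfg$s,
                              seed = cfg$seed, shuffle = cfg$shuffle,
                              window_k = cfg$window_k, verbose = verbose)
  write_tsv(pairs, file.path(cfg$out, "pairs.tsv"))
  summary <- summarize_pairs(pairs)
  write_tsv(summary$categories, file.path(cfg$out, "pair_summary.tsv"))
  write_tsv(summary$species_pairs, file.path(cfg$out,
                                             "pair_species_pairs.tsv"))

  inputs <- setNames(
    c(cfg$gff, cfg$fasta, cfg$clades, unname(cfg$alignments)),
    c("gff", "fasta", "clades",
      paste0("alignment_", names(cfg$alignments))))
  manifest <- list(
    package = "intronsites",
    version = as.character(packageVersion("intronsites")),
    seed = cfg$seed,
    site_identity = cfg$site_identity,
    thresholds = unclass(cfg$t),
    scoring = unclass(cfg$s),
    shuffle = cfg$shuffle,
    input_md5 = as.list(setNames(unname(tools::md5sum(inputs)),
                                 names(inputs))),
    n_genes = nrow(gt),
    n_introns = nrow(introns),
    n_projected = sum(vapply(matrices, function(m) nrow(m$cells),
                             integer(1))),
    n_unprojected = sum(vapply(matrices, function(m) length(m$excluded),
                               integer(1))),
    n_sites = lapply(matrices, n_sites),
    n_hotspots = nrow(hs),
    n_similar_pairs = summary$n_pairs,
    note = paste("No multiple-testing correction is applied across",
                 "intron pairs; the E-value cutoff is per pair."),
    warnings = unlist(lapply(matrices, `[[`, "errors"), use.names = FALSE))
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  msg("report bundle written to ", cfg$out, verbose = verbose)
  invisible(list(genes = genes, introns = introns, matrices = matrices,
                 gene_table = gt, hotspots = hs, pairs = pairs,
                 summary = summary, truth = truth, out = cfg$out))
}
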