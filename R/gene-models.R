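#' Translate a coding sequence
#'
#' Translates a CDS under the standard genetic code. A terminal stop codon is
#' dropped (and recorded via the `has_stop` attribute); an internal stop is a
#' hard error; codons containing ambiguity symbols translate to `"X"`.
#'
#' @param cds A nucleotide string whose length is divisible by 3, in coding
#'   orientation (5' to 3' of the mRNA).
#' @return The amino-acid string, with attribute `has_stop` (logical).
#' @examples
#' translate_cds("ATGGCTTAA")  # "MA"
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  if (nchar(cds) %% 3 != 0)
    stop("CDS length ", nchar(cds), " is not divisible by 3")
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "solve",
    no.init.codon = TRUE)))  # no initiator-codon rule: TTG/CTG stay L
  n <- nchar(aa)
  stops <- which(strsplit(aa, "")[[1]] == "*")
  internal <- stops[stops < n]
  if (length(internal) > 0L)
    stop("internal stop codon at codon ", internal[1L])
  has_stop <- n > 0L && substr(aa, n, n) == "*"
  if (has_stop) aa <- substr(aa, 1L, n - 1L)
  structure(aa, has_stop = has_stop)
}

#' @noRd
new_gene_model <- function(gene_id, species, family, copy_label, seqid,
                           strand, exons, cds_seq, protein_seq, has_stop) {
  structure(
    list(gene_id = gene_id, species = species, family = family,
         copy_label = copy_label, seqid = seqid, strand = strand,
         exons = exons, cds_seq = cds_seq, protein_seq = protein_seq,
         has_stop = has_stop),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s, %s, %s) %s strand, %d exon(s), CDS %d nt, protein %d aa%s\n",
              x$gene_id, x$species, x$family %||% "?", x$copy_label %||% "?",
              x$strand, nrow(x$exons), nchar(x$cds_seq), nchar(x$protein_seq),
              if (x$has_stop) " (+stop)" else ""))
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a

#' Read gene models from GFF3 and FASTA
#'
#' Reconstructs one gene model per annotated gene: coding exon structure is
#' taken from `CDS` features (exon features are ignored), minus-strand genes
#' are returned in coding orientation, and each model carries its CDS and
#' translated protein. Genes whose CDS length is not a multiple of 3, or that
#' contain an internal stop codon, are excluded with a warning rather than
#' aborting the run.
#'
#' @param gff Path to a GFF3 file (1-based inclusive coordinates) with
#'   `gene`, `mRNA` and `CDS` features. Genes with several mRNAs use the
#'   first one (by ID) with a warning.
#' @param fasta Path to a FASTA file covering every referenced region. A
#'   missing sequence region is a hard error naming the gene.
#' @param family_map Either `NULL` (the default: the gene family label is the
#'   first match of `family_regex` in the gene id or Name), a data frame
#'   with columns `gene_id` and `family`, or the path of a TSV with those
#'   columns.
#' @param species_map Optional named character vector mapping contig name to
#'   species. A `species=` attribute on the gene feature takes precedence;
#'   with neither, the contig name is used as the species.
#' @param family_regex Regex whose first capture group (or whole match) is
#'   the family label; default matches the four core histone families.
#' @param verbose Emit progress/warning messages.
#' @return A list of `gene_model` objects, ordered by species, family and
#'   genomic position. Copy labels (`H2A_1`, `H2A_2`, ...) are assigned per
#'   species and family by ascending genomic position (ties broken by contig
#'   name); the label is cosmetic and never enters any computation.
#' @export
read_gene_models <- function(gff, fasta, family_map = NULL, species_map = NULL,
                             family_regex = "(H2A|H2B|H3|H4)", verbose = TRUE) {
  gr <- rtracklayer::import(gff, format = "gff3")
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  parent <- vapply(md$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                   character(1))

  gene_idx <- which(type == "gene")
  mrna_idx <- which(type == "mRNA")
  cds_idx <- which(type == "CDS")
  if (length(gene_idx) == 0L) stop("no gene features found in ", gff)

  gene_of_mrna <- setNames(parent[mrna_idx], ids[mrna_idx])
  # Resolve each CDS to its gene (via mRNA, or directly)
  cds_gene <- parent[cds_idx]
  via_mrna <- cds_gene %in% names(gene_of_mrna)
  cds_mrna <- ifelse(via_mrna, cds_gene, NA_character_)
  cds_gene[via_mrna] <- gene_of_mrna[cds_gene[via_mrna]]

  fam_lookup <- NULL
  if (!is.null(family_map)) {
    if (is.character(family_map) && length(family_map) == 1L)
      family_map <- read.delim(family_map, comment.char = "#",
                               stringsAsFactors = FALSE)
    stopifnot(is.data.frame(family_map),
              all(c("gene_id", "family") %in% names(family_map)))
    fam_lookup <- setNames(as.character(family_map$family),
                           as.character(family_map$gene_id))
  }

  models <- list()
  for (gi in gene_idx) {
    gid <- ids[gi]
    rows <- cds_idx[which(cds_gene == gid)]
    if (length(rows) == 0L) next
    # one mRNA per gene; otherwise keep the lexicographically first
    mr <- sort(unique(stats::na.omit(cds_mrna[match(rows, cds_idx)])))
    if (length(mr) > 1L) {
      msg("gene ", gid, ": ", length(mr), " mRNAs annotated; using ", mr[1L],
          verbose = verbose)
      rows <- rows[cds_mrna[match(rows, cds_idx)] %in% mr[1L]]
    }
    seqid <- as.character(GenomicRanges::seqnames(gr)[rows][1L])
    strand <- as.character(GenomicRanges::strand(gr)[rows][1L])
    if (!strand %in% c("+", "-"))
      stop("gene ", gid, ": CDS strand must be + or -")
    st <- GenomicRanges::start(gr)[rows]
    en <- GenomicRanges::end(gr)[rows]
    o <- order(st)
    st <- st[o]; en <- en[o]
    if (strand == "-") { st <- rev(st); en <- rev(en) }
    exons <- data.frame(start = st, end = en)

    if (!seqid %in% names(seqs))
      stop("gene ", gid, ": sequence region '", seqid, "' missing from FASTA")
    contig <- seqs[[seqid]]
    if (max(en) > length(contig))
      stop("gene ", gid, ": CDS interval exceeds contig '", seqid, "' length")

    pieces <- vapply(seq_len(nrow(exons)), function(k) {
      s <- as.character(Biostrings::subseq(contig, min(st[k], en[k]), max(st[k], en[k])))
      if (strand == "-") revcomp(s) else s
    }, character(1))
    cds_seq <- paste(pieces, collapse = "")

    if (nchar(cds_seq) %% 3 != 0) {
      msg("gene ", gid, " excluded: CDS length ", nchar(cds_seq),
          " not divisible by 3", verbose = verbose)
      next
    }
    prot <- tryCatch(translate_cds(cds_seq), error = function(e) e)
    if (inherits(prot, "error")) {
      msg("gene ", gid, " excluded: ", conditionMessage(prot), verbose = verbose)
      next
    }

    species <- as.character(md$species[gi] %||% NA_character_)
    if (is.na(species) && !is.null(species_map) && seqid %in% names(species_map))
      species <- unname(species_map[seqid])
    if (is.na(species)) species <- seqid

    fam <- if (!is.null(fam_lookup)) unname(fam_lookup[gid]) else {
      nm <- as.character(md$Name[gi] %||% gid)
      m <- regmatches(gid, regexpr(family_regex, gid))
      if (!length(m)) m <- regmatches(nm, regexpr(family_regex, nm))
      if (length(m)) m[[1L]] else NA_character_
    }
    if (is.na(fam))
      msg("gene ", gid, ": no family label assigned", verbose = verbose)

    models[[gid]] <- new_gene_model(
      gene_id = gid, species = species, family = fam, copy_label = NA_character_,
      seqid = seqid, strand = strand, exons = exons, cds_seq = cds_seq,
      protein_seq = as.character(prot), has_stop = attr(prot, "has_stop"))
  }
  if (length(models) == 0L) stop("no usable gene models in ", gff)

  # copy labels per species+family by ascending genomic position
  meta <- data.frame(
    gene_id = vapply(models, `[[`, "", "gene_id"),
    species = vapply(models, `[[`, "", "species"),
    family = vapply(models, `[[`, "", "family"),
    seqid = vapply(models, `[[`, "", "seqid"),
    pos = vapply(models, function(m) min(m$exons$start), numeric(1)),
    stringsAsFactors = FALSE)
  o <- order(meta$species, meta$family, meta$seqid, meta$pos, meta$gene_id)
  meta <- meta[o, ]
  rank <- stats::ave(seq_len(nrow(meta)),
                     paste(meta$species, meta$family),
                     FUN = seq_along)
  for (k in seq_len(nrow(meta))) {
    gid <- meta$gene_id[k]
    models[[gid]]$copy_label <-
      if (is.na(meta$family[k])) NA_character_ else
        paste0(meta$family[k], "_", rank[k])
  }
  unname(models[meta$gene_id])
}

#' Extract CDS-interrupting introns from a gene model
#'
#' One intron per gap between consecutive coding exons, in coding (5' to 3')
#' order. The codon phase is the number of coding nucleotides upstream of the
#' intron modulo 3; the anchor residue is the first protein residue any of
#' whose codon nucleotides lie downstream of the intron
#' (`floor(cds_offset / 3)`, 0-based).
#'
#' @param gene A `gene_model`.
#' @param genome Optional `DNAStringSet` (or path to a FASTA) supplying the
#'   contig sequences; when given, each intron carries its nucleotide
#'   sequence in coding orientation and non-GT..AG boundaries produce a
#'   warning message.
#' @param verbose Emit boundary warnings.
#' @return A data frame with one row per intron: `intron_id`, `gene_id`,
#'   `species`, `family`, `ordinal`, `genomic_start`, `genomic_end`,
#'   `length_nt`, `cds_offset`, `phase`, `anchor_residue`, `seq`.
#' @export
extract_introns <- function(gene, genome = NULL, verbose = TRUE) {
  stopifnot(inherits(gene, "gene_model"))
  ex <- gene$exons
  n <- nrow(ex)
  empty <- data.frame(
    intron_id = character(0), gene_id = character(0), species = character(0),
    family = character(0), ordinal = integer(0), genomic_start = integer(0),
    genomic_end = integer(0), length_nt = integer(0), cds_offset = integer(0),
    phase = integer(0), anchor_residue = integer(0), seq = character(0),
    stringsAsFactors = FALSE)
  if (n < 2L) return(empty)

  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))

  widths <- abs(ex$end - ex$start) + 1L
  out <- empty
  for (k in seq_len(n - 1L)) {
    if (gene$strand == "+") {
      gs <- ex$end[k] + 1L; ge <- ex$start[k + 1L] - 1L
    } else {
      gs <- ex$end[k + 1L] + 1L; ge <- ex$start[k] - 1L
    }
    len <- ge - gs + 1L
    if (len < 1L)
      stop("gene ", gene$gene_id, ": exons ", k, " and ", k + 1L,
           " overlap or abut (non-positive intron length)")
    if (len < 4L)
      msg("gene ", gene$gene_id, ": intron ", k, " is only ", len, " nt",
          verbose = verbose)
    offset <- sum(widths[seq_len(k)])
    sq <- NA_character_
    if (!is.null(genome)) {
      if (!gene$seqid %in% names(genome))
        stop("gene ", gene$gene_id, ": contig '", gene$seqid, "' missing")
      sq <- as.character(Biostrings::subseq(genome[[gene$seqid]], gs, ge))
      if (gene$strand == "-") sq <- revcomp(sq)
      if (len >= 4L &&
          (substr(sq, 1L, 2L) != "GT" || substr(sq, len - 1L, len) != "AG"))
        msg("gene ", gene$gene_id, ": intron ", k,
            " has non-canonical boundaries ", substr(sq, 1L, 2L), "..",
            substr(sq, len - 1L, len), verbose = verbose)
    }
    out <- rbind(out, data.frame(
      intron_id = paste0(gene$gene_id, "_i", k),
      gene_id = gene$gene_id, species = gene$species, family = gene$family,
      ordinal = k, genomic_start = gs, genomic_end = ge, length_nt = len,
      cds_offset = offset, phase = offset %% 3L,
      anchor_residue = offset %/% 3L, seq = sq, stringsAsFactors = FALSE))
  }
  out
}

#' Extract introns from every gene model
#'
#' @param genes List of `gene_model` objects.
#' @inheritParams extract_introns
#' @return One data frame (see [extract_introns()]) covering all genes.
#' @export
extract_all_introns <- function(genes, genome = NULL, verbose = TRUE) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  do.call(rbind, c(lapply(genes, extract_introns, genome = genome,
                          verbose = verbose),
                   list(make.row.names = FALSE)))
}

#' Per-gene summary table (gene and intron counts)
#'
#' The per-species gene/intron census: one row per gene with its species,
#' family, copy label and number of CDS-interrupting introns.
#'
#' @param genes List of `gene_model` objects.
#' @param introns Intron table from [extract_all_introns()].
#' @return A data frame with columns `gene_id`, `species`, `family`,
#'   `copy_label`, `n_introns`.
#' @export
gene_table <- function(genes, introns) {
  ids <- vapply(genes, `[[`, "", "gene_id")
  cnt <- table(introns$gene_id)
  n <- as.integer(cnt[ids])
  n[is.na(n)] <- 0L
  data.frame(
    gene_id = ids,
    species = vapply(genes, `[[`, "", "species"),
    family = vapply(genes, `[[`, "", "family"),
    copy_label = vapply(genes, `[[`, "", "copy_label"),
    n_introns = n,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write intron sequences as FASTA
#'
#' Headers encode `intron_id phase=<p> length=<nt>`.
#' @param introns Intron table with non-missing `seq`.
#' @param path Output path.
#' @export
write_introns_fasta <- function(introns, path) {
  stopifnot(!anyNA(introns$seq))
  x <- Biostrings::DNAStringSet(introns$seq)
  names(x) <- sprintf("%s phase=%d length=%d", introns$intron_id,
                      introns$phase, introns$length_nt)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
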