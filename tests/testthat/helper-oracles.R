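# Brute-force local alignment score by whole-gap-run maximization:
# an alignment is a sequence of moves (substitution, or a gap run of length
# k costing gap_open + (k-1) * gap_extend) that may start and stop anywhere.
# Cubic and structurally different from the affine three-state recurrence.
bf_local_score <- function(a, b, sc = scoring_scheme()) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  m <- length(A); n <- length(B)
  M <- matrix(0, m + 1L, n + 1L)   # M[i,j]: best extension starting at (i,j)
  for (i in (m + 1L):1L) for (j in (n + 1L):1L) {
    v <- 0
    if (i <= m && j <= n) {
      s <- if (A[i] == B[j] && A[i] != "N") sc$match else sc$mismatch
      v <- max(v, s + M[i + 1L, j + 1L])
    }
    if (i <= m) for (k in seq_len(m - i + 1L))
      v <- max(v, sc$gap_open + (k - 1L) * sc$gap_extend,
               sc$gap_open + (k - 1L) * sc$gap_extend + M[i + k, j])
    if (j <= n) for (k in seq_len(n - j + 1L))
      v <- max(v, sc$gap_open + (k - 1L) * sc$gap_extend + M[i, j + k])
    M[i, j] <- v
  }
  as.integer(max(M))
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Minimal site_matrix construction for hot-spot tests: `spec` is a data
# frame with columns clade, column, count; one intron row is created per
# count at each (clade, column).
make_site_matrix <- function(spec, family = "H2A", phase = 0L) {
  cells <- do.call(rbind, lapply(seq_len(nrow(spec)), function(k) {
    n <- spec$count[k]
    data.frame(
      gene_id = sprintf("%s_g%02d_%d", spec$clade[k], k, seq_len(n)),
      species = paste0(spec$clade[k], "_sp"),
      clade = spec$clade[k], column = spec$column[k], phase = phase,
      intron_id = sprintf("%s_c%d_i%d", spec$clade[k], spec$column[k],
                          seq_len(n)),
      length_nt = 50L, stringsAsFactors = FALSE)
  }))
  cols <- sort(unique(cells$column))
  sites <- data.frame(site_id = sprintf("%s_s%02d", family,
                                        seq_along(cols)),
                      column = cols, phase = phase,
                      stringsAsFactors = FALSE)
  cells$site_id <- sites$site_id[match(cells$column, sites$column)]
  genes <- unique(cells[, c("gene_id", "species", "clade")])
  structure(list(family = family, site_identity = "column", sites = sites,
                 cells = cells[, c("gene_id", "species", "clade", "site_id",
                                   "intron_id", "length_nt", "column",
                                   "phase")],
                 genes = genes, n_columns = max(cols) + 10L,
                 excluded = character(0), errors = character(0)),
            class = "site_matrix")
}

# synthetic pair table: n1/n2/n3 pairs in the three categories; `species`
# optionally a list of length-2 character vectors recycled over rows
pair_frame_for_test <- function(n1, n2, n3, species = NULL) {
  cats <- rep(c("same_site_same_gene", "diff_site_same_gene", "diff_gene"),
              times = c(n1, n2, n3))
  n <- length(cats)
  if (n == 0L)
    return(data.frame(intron_a = character(0), intron_b = character(0),
                      species_a = character(0), species_b = character(0),
                      family_a = character(0), family_b = character(0),
                      site_a = character(0), site_b = character(0),
                      score = integer(0), evalue = numeric(0),
                      empirical_p = numeric(0), category = character(0),
                      same_species = logical(0), stringsAsFactors = FALSE))
  if (is.null(species))
    species <- lapply(seq_len(max(n, 1L)), function(i)
      c(sprintf("sp%03d", i), sprintf("sp%03d", i + 1L)))
  species <- rep(species, length.out = max(n, 1L))
  data.frame(
    intron_a = sprintf("ia%03d", seq_len(n)),
    intron_b = sprintf("ib%03d", seq_len(n)),
    species_a = vapply(species, `[`, "", 1L)[seq_len(n)],
    species_b = vapply(species, `[`, "", 2L)[seq_len(n)],
    family_a = "H2A", family_b = "H2A", site_a = "s", site_b = "s",
    score = 100L, evalue = 0.001, empirical_p = 0.005,
    category = cats,
    same_species = vapply(species, function(x) x[1L] == x[2L],
                          TRUE)[seq_len(n)],
    stringsAsFactors = FALSE)
}

# gene_model constructor for direct arithmetic tests
make_gene_model <- function(gene_id = "g1", exons, strand = "+",
                            cds_seq = "", protein_seq = "",
                            species = "sp", family = "H2A",
                            seqid = "contig") {
  structure(list(gene_id = gene_id, species = species, family = family,
                 copy_label = paste0(family, "_1"), seqid = seqid,
                 strand = strand, exons = exons, cds_seq = cds_seq,
                 protein_seq = protein_seq, has_stop = TRUE),
            class = "gene_model")
}

# write a tiny GFF3 + FASTA pair for hand-built genes; `genes` is a list of
# lists with fields: gid, seqid, strand, exons (data.frame start/end in
# ascending genomic order)
write_tiny_annotation <- function(genes, contigs, dir) {
  gff <- "##gff-version 3"
  for (g in genes) {
    lo <- min(g$exons$start); hi <- max(g$exons$end)
    gff <- c(gff,
      sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s", g$seqid, lo, hi,
              g$strand, g$gid),
      sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$seqid, lo, hi, g$strand, g$gid, g$gid))
    for (e in seq_len(nrow(g$exons)))
      gff <- c(gff, sprintf(
        "%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s.t1",
        g$seqid, g$exons$start[e], g$exons$end[e], g$strand, g$gid, e,
        g$gid))
  }
  gff_path <- file.path(dir, "tiny.gff3")
  fa_path <- file.path(dir, "tiny.fasta")
  writeLines(gff, gff_path)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs), fa_path)
  list(gff = gff_path, fasta = fa_path)
}
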