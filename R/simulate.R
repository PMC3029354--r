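#' @noRd
loc2contig <- function(a, b, P, G, strand) {
  if (strand == "+") c(P + a - 1L, P + b - 1L) else c(P + G - b, P + G - a)
}

#' Generate a synthetic multi-clade gene-family dataset with planted introns
#'
#' Simulates, from one seed, a complete input bundle for the pipeline plus
#' full truth tables. One ancestral protein per family evolves by
#' substitution only (so the true protein alignment is gap-free and emitted
#' directly); per-clade planted insertion sites receive one ancestral intron
#' sequence each, copied into carrier genes at the configured occupancy and
#' mutated at the intron divergence with GT..AG boundaries preserved;
#' private one-off introns arise at a small per-gene rate in every clade.
#' Genes are laid onto one contig per species with random strands and
#' intergenic spacers, and written as mutually consistent GFF3 + FASTA.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param verbose Emit progress messages.
#' @return A list with `paths` (gff, fasta, alignments, clades, truth
#'   files), `truth` (see Details) and `config`. `truth` holds data frames:
#'   `genes`, `introns` (with planted column, ancestor key and origin),
#'   `sites` (planted sites), `site_counts` (realized distinct columns per
#'   family), `hotspots` (clade/family/column satisfying the 1/3 rule on
#'   the planted introns), `shared_hotspots` (clade pairs hot at the same
#'   column) and `homolog_pairs` (intron pairs descending from one
#'   ancestral intron).
#' @export
simulate_dataset <- function(cfg, dir, verbose = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  codons <- codon_table()

  species_df <- do.call(rbind, lapply(seq_len(cfg$n_clades), function(ci) {
    cl <- cfg$clade_names[ci]
    data.frame(
      species = sprintf("%s%d_sp%02d", substr(gsub("[^A-Za-z0-9]", "", cl),
                                              1L, 4L),
                        ci, seq_len(cfg$species_per_clade[ci])),
      clade = cl, stringsAsFactors = FALSE)
  }))

  fam_len <- setNames(
    vapply(cfg$families, function(f)
      sample(seq(cfg$protein_length[1L], cfg$protein_length[2L]), 1L),
      integer(1)),
    cfg$families)
  fam_anc <- setNames(lapply(cfg$families, function(f)
    random_protein(fam_len[[f]])), cfg$families)
  clade_prot <- list()  # [[family]][[clade]]
  for (f in cfg$families) {
    clade_prot[[f]] <- setNames(lapply(cfg$clade_names, function(cl)
      mutate_sequence(fam_anc[[f]], cfg$protein_divergence_between, AA20)),
      cfg$clade_names)
  }

  # planted sites: per family, shared columns first, then clade-private ones
  rich <- cfg$intron_rich_clades
  k <- cfg$n_sites_per_clade_family
  sh <- cfg$cross_clade_shared_sites
  sites <- NULL      # family, clade, site_index, column, phase, dominant
  anc_intron <- list()  # [[family|clade|index]] = ancestral sequence
  for (f in cfg$families) {
    L <- fam_len[[f]]
    need <- if (length(rich) && k > 0L) sh + length(rich) * (k - sh) else 0L
    if (need == 0L) next
    pool <- sample(seq(2L, L - 1L), need)
    shared_cols <- if (sh > 0L) pool[seq_len(sh)] else integer(0)
    used <- sh
    col_phase <- setNames(sample(0:2, need, replace = TRUE), pool)
    for (cl in rich) {
      own <- if (k > sh) pool[used + seq_len(k - sh)] else integer(0)
      used <- used + (k - sh)
      cols <- c(shared_cols, own)
      for (j in seq_len(k)) {
        key <- paste(f, cl, j, sep = "|")
        anc_intron[[key]] <- random_intron_seq(draw_intron_length(cfg))
        sites <- rbind(sites, data.frame(
          family = f, clade = cl, site_index = j, column = cols[j],
          phase = unname(col_phase[as.character(cols[j])]),
          dominant = j == 1L, ancestor_key = key, stringsAsFactors = FALSE))
      }
    }
  }

  genes <- NULL
  introns <- NULL
  gff <- c("##gff-version 3", paste0("# seed: ", cfg$seed))
  contigs <- list()

  for (si in seq_len(nrow(species_df))) {
    sp <- species_df$species[si]
    cl <- species_df$clade[si]
    pieces <- character(0)
    cursor <- 0L
    sp_prot <- list()
    for (f in cfg$families)
      sp_prot[[f]] <- mutate_sequence(clade_prot[[f]][[cl]],
                                      cfg$protein_divergence_within, AA20)
    for (f in cfg$families) {
      L <- fam_len[[f]]
      fam_sites <- if (is.null(sites)) NULL else
        sites[sites$family == f & sites$clade == cl, , drop = FALSE]
      n_par <- sample(seq(cfg$paralogs_per_species_family[1L],
                          cfg$paralogs_per_species_family[2L]), 1L)
      for (p in seq_len(n_par)) {
        gid <- sprintf("%s_%s_%d", sp, f, p)
        prot <- mutate_sequence(sp_prot[[f]], cfg$protein_divergence_within,
                                AA20)
        cds <- reverse_translate(prot, codons)
        C <- nchar(cds)

        # plant introns: clade sites by occupancy, plus rare private ones
        idf <- NULL
        if (!is.null(fam_sites) && nrow(fam_sites) > 0L) {
          for (j in seq_len(nrow(fam_sites))) {
            occ <- if (fam_sites$dominant[j]) cfg$site_occupancy else
              cfg$minor_occupancy
            if (runif(1L) >= occ) next
            sq <- mutate_intron(anc_intron[[fam_sites$ancestor_key[j]]],
                                cfg$intron_divergence)
            idf <- rbind(idf, data.frame(
              column = fam_sites$column[j], phase = fam_sites$phase[j],
              seq = sq, origin = "clade_site",
              ancestor_key = fam_sites$ancestor_key[j],
              stringsAsFactors = FALSE))
          }
        }
        if (runif(1L) < cfg$private_site_rate) {
          planted_cols <- if (is.null(sites)) integer(0) else
            sites$column[sites$family == f]
          avail <- setdiff(seq(2L, L - 1L),
                           c(planted_cols, if (is.null(idf)) NULL else
                             idf$column))
          if (length(avail) > 0L) {
            pc <- avail[sample.int(length(avail), 1L)]
            idf <- rbind(idf, data.frame(
              column = pc, phase = sample(0:2, 1L),
              seq = random_intron_seq(draw_intron_length(cfg)),
              origin = "private", ancestor_key = NA_character_,
              stringsAsFactors = FALSE))
          }
        }
        if (!is.null(idf)) {
          idf$cds_offset <- 3L * (idf$column - 1L) + idf$phase
          idf <- idf[order(idf$cds_offset), , drop = FALSE]
          idf$ordinal <- seq_len(nrow(idf))
          idf$intron_id <- paste0(gid, "_i", idf$ordinal)
          idf$local_start <- NA_integer_
          idf$local_end <- NA_integer_
        }

        # assemble the gene's genomic sequence and local exon coordinates
        strand <- c("+", "-")[sample.int(2L, 1L)]
        offs <- if (is.null(idf)) integer(0) else idf$cds_offset
        bounds <- c(0L, offs, C)
        seg <- substring(cds, utils::head(bounds, -1L) + 1L,
                         bounds[-1L])
        gene_seq <- seg[1L]
        pos <- nchar(seg[1L])
        ex_local <- data.frame(start = 1L, end = pos)
        if (length(offs) > 0L) {
          for (q in seq_along(offs)) {
            intr <- idf$seq[q]
            istart <- pos + 1L
            pos <- pos + nchar(intr)
            idf$local_start[q] <- istart
            idf$local_end[q] <- pos
            gene_seq <- paste0(gene_seq, intr, seg[q + 1L])
            ex_local <- rbind(ex_local, data.frame(
              start = pos + 1L, end = pos + nchar(seg[q + 1L])))
            pos <- pos + nchar(seg[q + 1L])
          }
        }
        G <- nchar(gene_seq)

        spacer <- random_dna(sample(40:80, 1L))
        pieces <- c(pieces, spacer)
        cursor <- cursor + nchar(spacer)
        P <- cursor + 1L
        pieces <- c(pieces, if (strand == "+") gene_seq else
          revcomp(gene_seq))
        cursor <- cursor + G

        ex_gen <- t(vapply(seq_len(nrow(ex_local)), function(e)
          loc2contig(ex_local$start[e], ex_local$end[e], P, G, strand),
          integer(2)))
        # GFF rows (ascending genomic coordinates)
        o <- order(ex_gen[, 1L])
        gff <- c(gff,
          sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;species=%s;clade=%s",
                  sp, P, P + G - 1L, strand, gid, gid, sp, cl),
          sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                  sp, P, P + G - 1L, strand, gid, gid))
        widths <- ex_local$end - ex_local$start + 1L
        gff_phase <- (3L - (cumsum(c(0L, widths))[seq_len(nrow(ex_local))] %% 3L)) %% 3L
        for (e in o)
          gff <- c(gff, sprintf(
            "%s\tsim\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s.t1",
            sp, ex_gen[e, 1L], ex_gen[e, 2L], strand, gff_phase[e], gid, e,
            gid))

        genes <- rbind(genes, data.frame(
          gene_id = gid, species = sp, clade = cl, family = f,
          copy_label = paste0(f, "_", p), strand = strand,
          protein = prot, cds = cds,
          n_introns = if (is.null(idf)) 0L else nrow(idf),
          stringsAsFactors = FALSE))
        if (!is.null(idf)) {
          gi <- t(vapply(seq_len(nrow(idf)), function(q)
            loc2contig(idf$local_start[q], idf$local_end[q], P, G, strand),
            integer(2)))
          introns <- rbind(introns, data.frame(
            intron_id = idf$intron_id, gene_id = gid, species = sp,
            clade = cl, family = f, ordinal = idf$ordinal,
            genomic_start = gi[, 1L], genomic_end = gi[, 2L],
            length_nt = nchar(idf$seq), cds_offset = idf$cds_offset,
            phase = idf$phase, anchor_residue = idf$cds_offset %/% 3L,
            column = idf$column, seq = idf$seq, origin = idf$origin,
            ancestor_key = idf$ancestor_key, stringsAsFactors = FALSE))
        }
      }
    }
    pieces <- c(pieces, random_dna(sample(40:80, 1L)))
    contigs[[sp]] <- paste(pieces, collapse = "")
  }

  if (is.null(introns))
    introns <- data.frame(intron_id = character(0), gene_id = character(0),
                          species = character(0), clade = character(0),
                          family = character(0), ordinal = integer(0),
                          genomic_start = integer(0), genomic_end = integer(0),
                          length_nt = integer(0), cds_offset = integer(0),
                          phase = integer(0), anchor_residue = integer(0),
                          column = integer(0), seq = character(0),
                          origin = character(0), ancestor_key = character(0),
                          stringsAsFactors = FALSE)

  truth <- list(genes = genes, introns = introns,
                sites = if (is.null(sites)) data.frame() else sites)
  truth$site_counts <- do.call(rbind, lapply(cfg$families, function(f) {
    data.frame(family = f,
               n_sites = length(unique(introns$column[introns$family == f])),
               n_introns = sum(introns$family == f),
               stringsAsFactors = FALSE)
  }))
  truth$hotspots <- truth_hotspots(introns, cfg)
  truth$shared_hotspots <- truth_shared_hotspots(truth$hotspots)
  truth$homolog_pairs <- truth_homolog_pairs(introns)

  paths <- list(
    gff = file.path(dir, "genes.gff3"),
    fasta = file.path(dir, "genome.fasta"),
    clades = file.path(dir, "clades.tsv"),
    alignments = setNames(file.path(dir, sprintf("alignment_%s.fasta",
                                                 cfg$families)),
                          cfg$families))
  writeLines(gff, paths$gff)
  gseq <- Biostrings::DNAStringSet(unlist(contigs))
  Biostrings::writeXStringSet(gseq, paths$fasta)
  writeLines(c(paste0("# seed: ", cfg$seed), "species\tclade",
               paste(species_df$species, species_df$clade, sep = "\t")),
             paths$clades)
  for (f in cfg$families) {
    rows <- genes[genes$family == f, , drop = FALSE]
    aa <- Biostrings::AAStringSet(setNames(rows$protein, rows$gene_id))
    Biostrings::writeXStringSet(aa, paths$alignments[[f]])
  }
  for (nm in c("genes", "introns", "hotspots", "site_counts",
               "homolog_pairs")) {
    p <- file.path(dir, paste0("truth_", nm, ".tsv"))
    con <- file(p, "w")
    writeLines(paste0("# seed: ", cfg$seed), con)
    close(con)
    suppressWarnings(write.table(truth[[nm]], p, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    paths[[paste0("truth_", nm)]] <- p
  }
  msg("simulated ", nrow(genes), " genes, ", nrow(introns), " introns (",
      length(unique(species_df$species)), " species, ",
      length(cfg$families), " families)", verbose = verbose)
  list(paths = paths, truth = truth, config = cfg)
}

#' Hot spots implied by a planted intron table (1/3 rule, exact arithmetic)
#' @noRd
truth_hotspots <- function(introns, cfg, num = 1L, den = 3L) {
  out <- NULL
  for (f in unique(introns$family)) {
    for (cl in unique(introns$clade)) {
      sub <- introns[introns$family == f & introns$clade == cl, ,
                     drop = FALSE]
      total <- nrow(sub)
      if (total == 0L) next
      cnt <- table(sub$column)
      hot <- names(cnt)[den * as.integer(cnt) >= num * total]
      if (length(hot) == 0L) next
      out <- rbind(out, data.frame(
        clade = cl, family = f, column = as.integer(hot),
        n_at_site = as.integer(cnt[hot]), n_total = total,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(clade = character(0), family = character(0),
                      column = integer(0), n_at_site = integer(0),
                      n_total = integer(0), stringsAsFactors = FALSE)
  out[order(out$family, out$clade, out$column), , drop = FALSE]
}

#' @noRd
truth_shared_hotspots <- function(hs) {
  out <- NULL
  for (f in unique(hs$family)) {
    sub <- hs[hs$family == f, , drop = FALSE]
    clades <- sort(unique(sub$clade))
    if (length(clades) < 2L) next
    for (i in seq_len(length(clades) - 1L)) for (j in seq(i + 1L,
                                                          length(clades))) {
      shared <- intersect(sub$column[sub$clade == clades[i]],
                          sub$column[sub$clade == clades[j]])
      if (length(shared))
        out <- rbind(out, data.frame(family = f, clade_a = clades[i],
                                     clade_b = clades[j],
                                     column = sort(shared),
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(family = character(0), clade_a = character(0),
                      clade_b = character(0), column = integer(0),
                      stringsAsFactors = FALSE)
  out
}

#' All unordered pairs of introns sharing an ancestral intron sequence
#' @noRd
truth_homolog_pairs <- function(introns) {
  keys <- unique(stats::na.omit(introns$ancestor_key))
  out <- NULL
  for (k in keys) {
    ids <- sort(introns$intron_id[!is.na(introns$ancestor_key) &
                                    introns$ancestor_key == k])
    if (length(ids) < 2L) next
    cmb <- combn(ids, 2L)
    out <- rbind(out, data.frame(intron_a = cmb[1L, ], intron_b = cmb[2L, ],
                                 ancestor_key = k, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(intron_a = character(0), intron_b = character(0),
                      ancestor_key = character(0), stringsAsFactors = FALSE)
  out
}

#' Read a species-to-clade table
#'
#' @param path TSV with columns `species` and `clade`; `#` comment lines
#'   are ignored.
#' @return Data frame `species`, `clade`.
#' @export
read_clade_table <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("species", "clade") %in% names(df)))
    stop("clade table ", path, " must have 'species' and 'clade' columns")
  df[, c("species", "clade")]
}
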