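test_that("translation follows the standard code, drops the stop, flags ambiguity", {
  expect_equal(as.character(translate_cds("ATGGCTTAA")), "MA")
  expect_true(attr(translate_cds("ATGGCTTAA"), "has_stop"))
  expect_equal(as.character(translate_cds("ATGNNNTAA")), "MX")
  expect_equal(as.character(translate_cds("ATGGCT")), "MA")
  expect_false(attr(translate_cds("ATGGCT"), "has_stop"))
  expect_error(translate_cds("ATGTAAGCTTAA"), "internal stop codon at codon 2")
  expect_error(translate_cds("ATGGC"), "not divisible by 3")
})

test_that("a single-exon plus-strand gene is reconstructed with stop-aware protein length", {
  dir <- withr::local_tempdir()
  cds <- paste0("ATG", strrep("GCT", 99), "TAA")  # 303 nt, 100 aa + stop
  tiny <- write_tiny_annotation(
    list(list(gid = "spX_H2A_1", seqid = "c1", strand = "+",
              exons = data.frame(start = 1L, end = 303L))),
    c(c1 = cds), dir)
  genes <- read_gene_models(tiny$gff, tiny$fasta, verbose = FALSE)
  expect_length(genes, 1L)
  g <- genes[[1L]]
  expect_equal(nrow(g$exons), 1L)
  expect_equal(nchar(g$cds_seq), 303L)
  expect_equal(nchar(g$protein_seq), 100L)
  expect_true(g$has_stop)
  expect_equal(g$family, "H2A")
  expect_equal(g$copy_label, "H2A_1")
  expect_equal(nrow(extract_introns(g, verbose = FALSE)), 0L)
})

test_that("minus-strand exons come back in coding order as reverse complements", {
  dir <- withr::local_tempdir()
  cds <- paste0("ATG", strrep("GCT", 32), "TAA")  # 102 nt
  contig <- strsplit(strrep("A", 160), "")[[1L]]
  # coding piece 1 (51 nt) sits at genomic 100..150, piece 2 at 10..60
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  contig[100:150] <- strsplit(rc(substr(cds, 1, 51)), "")[[1L]]
  contig[10:60] <- strsplit(rc(substr(cds, 52, 102)), "")[[1L]]
  tiny <- write_tiny_annotation(
    list(list(gid = "spX_H2B_1", seqid = "c1", strand = "-",
              exons = data.frame(start = c(10L, 100L), end = c(60L, 150L)))),
    c(c1 = paste(contig, collapse = "")), dir)
  genes <- read_gene_models(tiny$gff, tiny$fasta, verbose = FALSE)
  g <- genes[[1L]]
  expect_equal(g$exons$start, c(100L, 10L))  # coding order 5'->3'
  expect_equal(g$exons$end, c(150L, 60L))
  expect_equal(g$cds_seq, cds)
  introns <- extract_introns(g, tiny$fasta, verbose = FALSE)
  expect_equal(introns$genomic_start, 61L)
  expect_equal(introns$genomic_end, 99L)
  expect_equal(introns$cds_offset, 51L)
  expect_equal(introns$phase, 0L)
  expect_equal(introns$anchor_residue, 17L)
})

test_that("intron phase and anchor arithmetic follows the coding offset", {
  g <- make_gene_model(exons = data.frame(start = c(1L, 50L),
                                          end = c(10L, 57L)))
  it <- extract_introns(g, verbose = FALSE)
  expect_equal(nrow(it), 1L)
  expect_equal(it$cds_offset, 10L)
  expect_equal(it$phase, 1L)
  expect_equal(it$anchor_residue, 3L)

  g3 <- make_gene_model(exons = data.frame(start = c(1L, 30L, 60L),
                                           end = c(9L, 38L, 68L)))
  it3 <- extract_introns(g3, verbose = FALSE)
  expect_equal(it3$cds_offset, c(9L, 18L))
  expect_equal(it3$phase, c(0L, 0L))
  expect_equal(it3$anchor_residue, c(3L, 6L))
  expect_equal(it3$ordinal, c(1L, 2L))
})

test_that("overlapping exons are a hard error", {
  g <- make_gene_model(exons = data.frame(start = c(1L, 8L),
                                          end = c(10L, 20L)))
  expect_error(extract_introns(g, verbose = FALSE), "overlap")
})

test_that("a CDS whose length is not a multiple of 3 is excluded, not fatal", {
  dir <- withr::local_tempdir()
  good <- paste0("ATG", strrep("GCT", 10), "TAA")
  tiny <- write_tiny_annotation(
    list(list(gid = "ok_H3_1", seqid = "c1", strand = "+",
              exons = data.frame(start = 1L, end = 36L)),
         list(gid = "bad_H3_1", seqid = "c1", strand = "+",
              exons = data.frame(start = 50L, end = 60L))),
    c(c1 = paste0(good, strrep("A", 30))), dir)
  expect_message(genes <- read_gene_models(tiny$gff, tiny$fasta),
                 "not divisible by 3")
  expect_equal(vapply(genes, `[[`, "", "gene_id"), "ok_H3_1")
})

test_that("a missing sequence region names the gene in a hard error", {
  dir <- withr::local_tempdir()
  tiny <- write_tiny_annotation(
    list(list(gid = "gX_H4_1", seqid = "nowhere", strand = "+",
              exons = data.frame(start = 1L, end = 30L))),
    c(c1 = strrep("A", 60)), dir)
  expect_error(read_gene_models(tiny$gff, tiny$fasta, verbose = FALSE),
               "gX_H4_1.*nowhere")
})

test_that("synthetic GFF3/FASTA round-trips to the planted gene models exactly", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_clades = 2L, species_per_clade = c(2L, 3L),
                    families = c("H2A", "H3"),
                    paralogs_per_species_family = c(1L, 3L), seed = 42L)
  sim <- simulate_dataset(cfg, dir, verbose = FALSE)
  genes <- read_gene_models(sim$paths$gff, sim$paths$fasta, verbose = FALSE)
  got <- data.frame(gene_id = vapply(genes, `[[`, "", "gene_id"),
                    cds = vapply(genes, `[[`, "", "cds_seq"),
                    protein = vapply(genes, `[[`, "", "protein_seq"),
                    copy_label = vapply(genes, `[[`, "", "copy_label"),
                    stringsAsFactors = FALSE)
  tr <- sim$truth$genes
  expect_setequal(got$gene_id, tr$gene_id)
  i <- match(tr$gene_id, got$gene_id)
  expect_equal(got$cds[i], tr$cds)
  expect_equal(got$protein[i], tr$protein)
  expect_equal(got$copy_label[i], tr$copy_label)

  it <- extract_all_introns(genes, sim$paths$fasta, verbose = FALSE)
  it <- it[order(it$intron_id), ]
  tt <- sim$truth$introns[order(sim$truth$introns$intron_id), ]
  expect_equal(it$intron_id, tt$intron_id)
  for (col in c("cds_offset", "phase", "anchor_residue", "seq",
                "genomic_start", "genomic_end", "length_nt"))
    expect_equal(it[[col]], tt[[col]], ignore_attr = TRUE, label = col)
})

test_that("reverse-complementing contigs and flipping strands leaves intron anatomy invariant", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_clades = 2L, species_per_clade = c(2L, 2L),
                    families = "H4", paralogs_per_species_family = c(1L, 2L),
                    seed = 11L)
  sim <- simulate_dataset(cfg, dir, verbose = FALSE)
  seqs <- Biostrings::readDNAStringSet(sim$paths$fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  clen <- setNames(Biostrings::width(seqs), names(seqs))
  flipped <- Biostrings::reverseComplement(seqs)
  fa2 <- file.path(dir, "flipped.fasta")
  Biostrings::writeXStringSet(flipped, fa2)
  lines <- readLines(sim$paths$gff)
  out <- vapply(lines, function(l) {
    if (startsWith(l, "#")) return(l)
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    L <- clen[[f[1L]]]
    s <- as.integer(f[4L]); e <- as.integer(f[5L])
    f[4L] <- as.character(L - e + 1L); f[5L] <- as.character(L - s + 1L)
    f[7L] <- if (f[7L] == "+") "-" else "+"
    paste(f, collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  gff2 <- file.path(dir, "flipped.gff3")
  writeLines(out, gff2)

  a <- extract_all_introns(read_gene_models(sim$paths$gff, sim$paths$fasta,
                                            verbose = FALSE),
                           sim$paths$fasta, verbose = FALSE)
  b <- extract_all_introns(read_gene_models(gff2, fa2, verbose = FALSE),
                           fa2, verbose = FALSE)
  a <- a[order(a$intron_id), ]; b <- b[order(b$intron_id), ]
  expect_equal(a$intron_id, b$intron_id)
  for (col in c("cds_offset", "phase", "anchor_residue", "seq"))
    expect_equal(a[[col]], b[[col]], label = col)
})

test_that("re-splicing exons and translating reproduces the recorded protein", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_clades = 2L, species_per_clade = c(1L, 2L),
                    families = c("H2B", "H4"), seed = 5L)
  sim <- simulate_dataset(cfg, dir, verbose = FALSE)
  genes <- read_gene_models(sim$paths$gff, sim$paths$fasta, verbose = FALSE)
  for (g in genes)
    expect_equal(as.character(translate_cds(g$cds_seq)), g$protein_seq)
})
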