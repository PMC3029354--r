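test_that("column maps count through gaps correctly", {
  m <- build_column_map("MA-CD")
  expect_equal(m$res_to_col, c(1L, 2L, 4L, 5L))
  expect_equal(project_intron(2L, m), 4L)   # residue 'C'
  expect_equal(m$col_to_res, c(1L, 2L, NA, 3L, 4L))

  allgap <- build_column_map("----")
  expect_length(allgap$res_to_col, 0L)
  expect_true(all(is.na(allgap$col_to_res)))

  m2 <- build_column_map("MAAC-DE")
  expect_equal(project_intron(3L, m2), 4L)
  expect_error(project_intron(7L, m2), "outside the degapped row")
  expect_error(project_intron(-1L, m2), "outside the degapped row")
})

test_that("degapping then re-inserting through the map reproduces random rows", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(5:60, 1L)
    ch <- sample(c(LETTERS[1:20], "-"), n, replace = TRUE)
    row <- paste(ch, collapse = "")
    m <- build_column_map(row)
    rebuilt <- rep("-", m$n_columns)
    degap <- strsplit(gsub("-", "", row, fixed = TRUE), "")[[1L]]
    rebuilt[m$res_to_col] <- degap
    expect_equal(paste(rebuilt, collapse = ""), row)
  }
})

make_aln <- function(rows, family = "H2A") {
  structure(list(family = family, aln = rows,
                 n_columns = unique(nchar(rows))), class = "aligned_family")
}

make_introns <- function(gene_id, anchor, phase = 0L, family = "H2A") {
  n <- length(gene_id)
  if (n == 0L)
    return(data.frame(intron_id = character(0), gene_id = character(0),
                      species = character(0), family = character(0),
                      ordinal = integer(0), genomic_start = integer(0),
                      genomic_end = integer(0), length_nt = integer(0),
                      cds_offset = integer(0), phase = integer(0),
                      anchor_residue = integer(0), seq = character(0),
                      stringsAsFactors = FALSE))
  data.frame(intron_id = sprintf("i%02d", seq_len(n)), gene_id = gene_id,
             species = sub("_.*", "", gene_id), family = family,
             ordinal = 1L, genomic_start = 1L, genomic_end = 50L,
             length_nt = 50L, cds_offset = 3L * anchor + phase,
             phase = phase, anchor_residue = anchor, seq = NA_character_,
             stringsAsFactors = FALSE)
}

clades2 <- data.frame(species = c("sp1", "sp2", "sp3"),
                      clade = c("A", "A", "B"), stringsAsFactors = FALSE)

test_that("introns at one aligned position collapse to a single site", {
  aln <- make_aln(c(sp1_g1 = "MAC-DE", sp2_g1 = "MAC-DE", sp3_g1 = "MACWDE"))
  it <- make_introns(c("sp1_g1", "sp2_g1", "sp3_g1"), anchor = c(2L, 2L, 2L))
  sm <- build_site_matrix(it, aln, clades2, verbose = FALSE)
  expect_equal(n_sites(sm), 1L)
  expect_equal(nrow(sm$cells), 3L)
  expect_equal(unique(sm$cells$column), 3L)

  # same anchor count, different gap context: sp3 anchor 3 is column 4
  it2 <- make_introns(c("sp1_g1", "sp3_g1"), anchor = c(3L, 3L))
  sm2 <- build_site_matrix(it2, aln, clades2, verbose = FALSE)
  expect_equal(sm2$cells$column, c(5L, 4L))
  expect_equal(n_sites(sm2), 2L)
})

test_that("an empty intron set yields a valid empty matrix", {
  aln <- make_aln(c(sp1_g1 = "MACDE"))
  sm <- build_site_matrix(make_introns(character(0), integer(0)), aln,
                          clades2, verbose = FALSE)
  expect_equal(n_sites(sm), 0L)
  expect_equal(nrow(sm$cells), 0L)
})

test_that("phase participates in site identity only when configured", {
  aln <- make_aln(c(sp1_g1 = "MACDE", sp2_g1 = "MACDE"))
  it <- make_introns(c("sp1_g1", "sp2_g1"), anchor = c(2L, 2L),
                     phase = c(0L, 2L))
  sm_col <- build_site_matrix(it, aln, clades2, verbose = FALSE)
  expect_equal(n_sites(sm_col), 1L)
  expect_true(is.na(sm_col$sites$phase))  # mixed phases at one column
  sm_cp <- build_site_matrix(it, aln, clades2,
                             site_identity = "column+phase", verbose = FALSE)
  expect_equal(n_sites(sm_cp), 2L)
})

test_that("stop-codon-anchored introns are excluded with a warning; strict mode distinguishes errors", {
  aln <- make_aln(c(sp1_g1 = "MACDE", sp2_g1 = "MACDE"))
  it <- make_introns(c("sp1_g1", "sp2_g1"), anchor = c(5L, 2L))
  expect_message(sm <- build_site_matrix(it, aln, clades2),
                 "stop codon")
  expect_equal(sm$excluded, "i01")
  expect_equal(nrow(sm$cells), 1L)

  bad <- make_introns("sp9_gX", anchor = 1L)
  expect_error(build_site_matrix(rbind(it, bad), aln, clades2,
                                 verbose = FALSE), "absent from")
  sm2 <- build_site_matrix(rbind(it, bad), aln, clades2, strict = FALSE,
                           verbose = FALSE)
  expect_length(sm2$errors, 1L)
  expect_equal(nrow(sm2$cells), 1L)
})

test_that("cell counts conserve projectable introns and survive row permutation and gap insertion", {
  set.seed(77)
  for (rep in 1:10) {
    n_genes <- sample(3:6, 1L)
    len <- 30L
    rows <- setNames(
      vapply(seq_len(n_genes), function(i) {
        ch <- sample(c(LETTERS[1:20], "-"), len, replace = TRUE, prob =
                       c(rep(1, 20), 5))
        # ensure at least 5 residues
        ch[1:5] <- "M"
        paste(ch, collapse = "")
      }, character(1)),
      paste0("sp", seq_len(n_genes), "_g1"))
    aln <- make_aln(rows)
    cl <- data.frame(species = paste0("sp", seq_len(n_genes)),
                     clade = "A", stringsAsFactors = FALSE)
    it <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      nres <- nchar(gsub("-", "", rows[[i]], fixed = TRUE))
      k <- sample(0:3, 1L)
      if (k == 0L) return(NULL)
      make_introns(rep(names(rows)[i], k),
                   anchor = sample(0:(nres - 1L), k))
    }))
    it$intron_id <- sprintf("i%03d", seq_len(nrow(it)))
    sm <- build_site_matrix(it, aln, cl, verbose = FALSE)
    expect_equal(nrow(sm$cells), nrow(it))

    perm <- make_aln(rows[sample(names(rows))])
    smp <- build_site_matrix(it, perm, cl, verbose = FALSE)
    expect_equal(n_sites(smp), n_sites(sm))
    expect_equal(sort(smp$sites$column), sort(sm$sites$column))

    # all-gap column inserted at a random position shifts later sites by 1
    cut <- sample(0:len, 1L)
    rows2 <- setNames(vapply(rows, function(r)
      paste0(substr(r, 1L, cut), "-", substr(r, cut + 1L, len)),
      character(1)), names(rows))
    sm2 <- build_site_matrix(it, make_aln(rows2), cl, verbose = FALSE)
    shift <- as.integer(sm$sites$column > cut)
    expect_equal(sm2$sites$column, sm$sites$column + shift)
  }
})

test_that("alignment reader enforces equal row lengths and degap validation catches mismatches", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "aln.fasta")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(
    c(g1 = "MA-CD", g2 = "MACDE")), p)
  aln <- read_family_alignment(p, "H2A")
  expect_equal(aln$n_columns, 5L)
  writeLines(c(">g1", "MACD", ">g2", "MACDE"), p)
  expect_error(read_family_alignment(p, "H2A"), "unequal")

  ok <- make_gene_model(gene_id = "g1",
                        exons = data.frame(start = 1L, end = 15L),
                        protein_seq = "MACD")
  expect_true(validate_alignment(aln, list(ok)))
  bad <- make_gene_model(gene_id = "g1",
                         exons = data.frame(start = 1L, end = 18L),
                         protein_seq = "MAXCD")
  expect_error(validate_alignment(aln, list(bad)), "does not degap")
})
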