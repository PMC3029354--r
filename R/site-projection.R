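#' Residue/column map for one gapped alignment row
#'
#' @param gapped_row A gapped amino-acid string (gap symbol `-`).
#' @return A list with `res_to_col` (integer vector: 1-based alignment column
#'   of each residue of the degapped sequence) and `col_to_res` (integer
#'   vector over columns; `NA` at gap columns), plus `n_columns`.
#' @examples
#' build_column_map("MA-CD")$res_to_col  # 1 2 4 5
#' @export
build_column_map <- function(gapped_row) {
  stopifnot(is.character(gapped_row), length(gapped_row) == 1L)
  ch <- strsplit(gapped_row, "")[[1L]]
  is_res <- ch != "-"
  res_to_col <- which(is_res)
  col_to_res <- rep(NA_integer_, length(ch))
  col_to_res[is_res] <- seq_len(sum(is_res))
  list(res_to_col = as.integer(res_to_col), col_to_res = col_to_res,
       n_columns = length(ch))
}

#' Read a per-family protein multiple alignment
#'
#' @param path Aligned FASTA; one row per gene, header = gene id.
#' @param family Family label attached to the alignment.
#' @return An `aligned_family`: list with `family`, `aln` (named character
#'   vector of gapped rows) and `n_columns`.
#' @export
read_family_alignment <- function(path, family) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  aln <- as.character(x)
  w <- unique(nchar(aln))
  if (length(w) != 1L)
    stop("alignment ", path, ": rows have unequal lengths ",
         paste(w, collapse = ", "))
  structure(list(family = family, aln = aln, n_columns = w),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("<aligned_family> %s: %d rows x %d columns\n",
              x$family, length(x$aln), x$n_columns))
  invisible(x)
}

#' Check an alignment against the gene models it claims to align
#'
#' Degapping each row must reproduce that gene's protein exactly.
#' @param alignment An `aligned_family`.
#' @param genes List of `gene_model` objects (superset of the rows).
#' @return Invisibly `TRUE`; hard error on any mismatch.
#' @export
validate_alignment <- function(alignment, genes) {
  prot <- setNames(vapply(genes, `[[`, "", "protein_seq"),
                   vapply(genes, `[[`, "", "gene_id"))
  for (gid in names(alignment$aln)) {
    if (!gid %in% names(prot)) next
    degap <- gsub("-", "", alignment$aln[[gid]], fixed = TRUE)
    if (degap != prot[[gid]])
      stop("alignment row ", gid, " does not degap to its protein sequence")
  }
  invisible(TRUE)
}

#' Project one intron onto alignment coordinates
#'
#' @param anchor_residue 0-based anchor residue of the intron.
#' @param map Column map from [build_column_map()] for the host gene's row.
#' @return 1-based alignment column of the anchor residue.
#' @export
project_intron <- function(anchor_residue, map) {
  if (anchor_residue < 0L || anchor_residue >= length(map$res_to_col))
    stop("anchor residue ", anchor_residue,
         " outside the degapped row (length ", length(map$res_to_col), ")")
  map$res_to_col[[anchor_residue + 1L]]
}

#' Build the insertion-site presence matrix for one gene family
#'
#' Projects every intron of the family onto the protein alignment and
#' collects, per gene and per distinct insertion site, the introns observed
#' there. Site identity defaults to the alignment column alone (phase is
#' recorded but does not split sites); `"column+phase"` applies the stricter
#' definition. Introns anchored at the stop codon (anchor residue equal to
#' the protein length) cannot be projected and are excluded with a warning.
#'
#' @param introns Intron table (see [extract_all_introns()]) for one family.
#' @param alignment An `aligned_family` covering every host gene.
#' @param clades Data frame with columns `species`, `clade`.
#' @param genes Optional list of `gene_model`s used to validate the
#'   alignment and to list intronless genes as empty matrix rows.
#' @param site_identity `"column"` (default) or `"column+phase"`.
#' @param strict If `TRUE` (default) a projection failure aborts; otherwise
#'   failures are collected in the `errors` field.
#' @param verbose Emit exclusion warnings.
#' @return A `site_matrix`: list with `family`, `site_identity`, `sites`
#'   (data frame `site_id`, `column`, `phase` in ascending column, then
#'   phase, order), `cells` (data frame `gene_id`, `species`, `clade`,
#'   `site_id`, `intron_id`, `length_nt`), `genes`, `n_columns`, `excluded`
#'   (intron ids skipped at the stop codon) and `errors`.
#' @export
build_site_matrix <- function(introns, alignment, clades, genes = NULL,
                              site_identity = c("column", "column+phase"),
                              strict = TRUE, verbose = TRUE) {
  site_identity <- match.arg(site_identity)
  stopifnot(inherits(alignment, "aligned_family"),
            all(c("species", "clade") %in% names(clades)))
  fam <- alignment$family
  introns <- introns[introns$family %in% fam, , drop = FALSE]
  if (!is.null(genes)) {
    genes <- genes[vapply(genes, function(g) identical(g$family, fam), TRUE)]
    validate_alignment(alignment, genes)
  }
  clade_of <- setNames(as.character(clades$clade), as.character(clades$species))

  maps <- lapply(alignment$aln, build_column_map)
  cells <- data.frame(gene_id = character(0), species = character(0),
                      clade = character(0), column = integer(0),
                      phase = integer(0), intron_id = character(0),
                      length_nt = integer(0), stringsAsFactors = FALSE)
  excluded <- character(0)
  errors <- character(0)
  for (k in seq_len(nrow(introns))) {
    it <- introns[k, ]
    mp <- maps[[it$gene_id]]
    if (is.null(mp)) {
      e <- paste0("intron ", it$intron_id, ": gene ", it$gene_id,
                  " absent from the ", fam, " alignment")
      if (strict) stop(e) else { errors <- c(errors, e); next }
    }
    if (it$anchor_residue >= length(mp$res_to_col)) {
      msg("intron ", it$intron_id,
          " anchors at/after the stop codon; excluded from projection",
          verbose = verbose)
      excluded <- c(excluded, it$intron_id)
      next
    }
    col <- tryCatch(project_intron(it$anchor_residue, mp),
                    error = function(e) e)
    if (inherits(col, "error")) {
      e <- paste0("intron ", it$intron_id, ": ", conditionMessage(col))
      if (strict) stop(e) else { errors <- c(errors, e); next }
    }
    cells <- rbind(cells, data.frame(
      gene_id = it$gene_id, species = it$species,
      clade = unname(clade_of[it$species]) %||% NA_character_,
      column = col, phase = it$phase, intron_id = it$intron_id,
      length_nt = it$length_nt, stringsAsFactors = FALSE))
  }

  if (nrow(cells) > 0L) {
    key <- if (site_identity == "column") as.character(cells$column) else
      paste(cells$column, cells$phase, sep = "/")
    u <- unique(data.frame(key = key, column = cells$column,
                           phase = cells$phase, stringsAsFactors = FALSE))
    # one row per identity key; phase NA when a column-only site mixes phases
    agg <- do.call(rbind, lapply(split(u, u$key), function(d) {
      data.frame(key = d$key[1L], column = d$column[1L],
                 phase = if (length(unique(d$phase)) == 1L) d$phase[1L]
                         else NA_integer_,
                 stringsAsFactors = FALSE)
    }))
    agg <- agg[order(agg$column, agg$phase, na.last = TRUE), , drop = FALSE]
    agg$site_id <- sprintf("%s_s%02d", fam, seq_len(nrow(agg)))
    cells$site_id <- agg$site_id[match(key, agg$key)]
    sites <- agg[, c("site_id", "column", "phase")]
    rownames(sites) <- NULL
  } else {
    sites <- data.frame(site_id = character(0), column = integer(0),
                        phase = integer(0), stringsAsFactors = FALSE)
    cells$site_id <- character(0)
  }

  gene_ids <- if (!is.null(genes)) vapply(genes, `[[`, "", "gene_id") else
    names(alignment$aln)
  gene_species <- if (!is.null(genes)) vapply(genes, `[[`, "", "species") else
    rep(NA_character_, length(gene_ids))
  gdf <- data.frame(gene_id = gene_ids, species = gene_species,
                    clade = unname(clade_of[gene_species]),
                    stringsAsFactors = FALSE)

  structure(list(
    family = fam, site_identity = site_identity, sites = sites,
    cells = cells[, c("gene_id", "species", "clade", "site_id", "intron_id",
                      "length_nt", "column", "phase")],
    genes = gdf, n_columns = alignment$n_columns,
    excluded = excluded, errors = errors), class = "site_matrix")
}

#' @export
print.site_matrix <- function(x, ...) {
  cat(sprintf("<site_matrix> %s: %d distinct sites, %d introns in %d genes (%s identity)\n",
              x$family, nrow(x$sites), nrow(x$cells), nrow(x$genes),
              x$site_identity))
  if (length(x$excluded))
    cat("  excluded (stop-codon anchor):", length(x$excluded), "\n")
  invisible(x)
}

#' Number of distinct insertion sites in a site matrix
#' @param sm A `site_matrix`.
#' @export
n_sites <- function(sm) nrow(sm$sites)

#' Write a site matrix as TSV
#'
#' Rows are genes, columns are insertion sites (headed by alignment column),
#' cells list `intron_id(length)` entries.
#' @param sm A `site_matrix`.
#' @param path Output path.
#' @export
write_site_matrix <- function(sm, path) {
  sites <- sm$sites
  genes <- sm$genes[order(sm$genes$clade, sm$genes$species, sm$genes$gene_id), ]
  m <- matrix("", nrow = nrow(genes), ncol = nrow(sites),
              dimnames = list(genes$gene_id,
                              sprintf("col%d", sites$column)))
  if (nrow(sm$cells) > 0L) {
    for (k in seq_len(nrow(sm$cells))) {
      cl <- sm$cells[k, ]
      j <- match(cl$site_id, sites$site_id)
      i <- match(cl$gene_id, genes$gene_id)
      if (is.na(i)) next
      ent <- sprintf("%s(%d)", cl$intron_id, cl$length_nt)
      m[i, j] <- if (nzchar(m[i, j])) paste(m[i, j], ent, sep = ";") else ent
    }
  }
  df <- data.frame(gene_id = genes$gene_id, species = genes$species,
                   clade = genes$clade, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write an annotated alignment with an "I" marker row
#'
#' Reproduces the annotated-alignment report style: the first row marks each
#' intron insertion-site column with the character `I`, followed by the
#' gapped rows of the family alignment.
#' @param sm A `site_matrix`.
#' @param alignment The `aligned_family` the matrix was built from.
#' @param path Output path.
#' @param width Characters per alignment block.
#' @export
write_annotated_alignment <- function(sm, alignment, path, width = 60L) {
  marks <- rep(" ", alignment$n_columns)
  marks[sm$sites$column] <- "I"
  marker <- paste(marks, collapse = "")
  ids <- names(alignment$aln)
  label_w <- max(nchar(c("site", ids))) + 2L
  con <- file(path, "w")
  on.exit(close(con))
  starts <- seq(1L, alignment$n_columns, by = width)
  for (s in starts) {
    e <- min(s + width - 1L, alignment$n_columns)
    writeLines(sprintf("%-*s%s", label_w, "site", substr(marker, s, e)), con)
    for (gid in ids)
      writeLines(sprintf("%-*s%s", label_w, gid,
                         substr(alignment$aln[[gid]], s, e)), con)
    writeLines("", con)
  }
  invisible(path)
}
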