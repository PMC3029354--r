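#' Configuration for the synthetic dataset generator
#'
#' Describes a desk-scale multi-clade, multi-family gene set with planted
#' intron insertion sites. Defaults emulate the structure of a 24-genome
#' fungal core-histone survey: four clades with 1/8/11/4 species, the four
#' histone families, a few paralogs per species, two intron-rich clades
#' whose planted sites include one column shared across clades, and rare
#' private introns elsewhere (the intron-poor yeast-like clades receive only
#' those).
#'
#' @param n_clades Number of clades (>= 2).
#' @param species_per_clade Integer vector (recycled) of species counts.
#' @param clade_names Clade labels; defaults to the four fungal clades of
#'   the default table.
#' @param families Gene family labels.
#' @param paralogs_per_species_family Length-2 range of paralog counts.
#' @param protein_length Length-2 range; one length is drawn per family
#'   (substitution-only evolution keeps it fixed, so the true alignment is
#'   gap-free).
#' @param n_sites_per_clade_family Planted sites per intron-rich clade per
#'   family; the first is the dominant site.
#' @param cross_clade_shared_sites How many of those sites share their
#'   alignment column (and phase) across the intron-rich clades.
#' @param site_occupancy Probability a gene of the clade carries an intron
#'   at the dominant planted site.
#' @param minor_occupancy Occupancy of the non-dominant planted sites
#'   (default `site_occupancy / 3`), kept lower so the dominant site can
#'   satisfy the hot-spot rule.
#' @param private_site_rate Per-gene probability of one private intron at a
#'   random unplanted column (any clade).
#' @param intron_rich_clades Clade labels that receive planted sites;
#'   default the last two clades.
#' @param intron_length_meanlog,intron_length_sdlog,intron_length_range
#'   Log-normal intron length model, truncated to the range (default
#'   20-250 nt).
#' @param protein_divergence_within,protein_divergence_between Per-residue
#'   substitution probabilities applied within a clade (species and paralog
#'   level) and between the family ancestor and each clade.
#' @param intron_divergence Per-nucleotide substitution probability applied
#'   to each copy of a site's ancestral intron (GT..AG ends preserved).
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_clades = 4L,
                       species_per_clade = c(1L, 8L, 11L, 4L),
                       clade_names = NULL,
                       families = c("H2A", "H2B", "H3", "H4"),
                       paralogs_per_species_family = c(1L, 4L),
                       protein_length = c(100L, 140L),
                       n_sites_per_clade_family = 3L,
                       cross_clade_shared_sites = 1L,
                       site_occupancy = 0.8,
                       minor_occupancy = site_occupancy / 3,
                       private_site_rate = 0.05,
                       intron_rich_clades = NULL,
                       intron_length_meanlog = log(70),
                       intron_length_sdlog = 0.5,
                       intron_length_range = c(20L, 250L),
                       protein_divergence_within = 0.03,
                       protein_divergence_between = 0.15,
                       intron_divergence = 0.05,
                       seed = 1L) {
  if (is.null(clade_names))
    clade_names <- c("Taphrinomycotina", "Saccharomycotina",
                     "Pezizomycotina", "Basidiomycota")[seq_len(min(n_clades, 4L))]
  if (length(clade_names) < n_clades)
    clade_names <- c(clade_names,
                     paste0("clade", seq_len(n_clades - length(clade_names)) +
                              length(clade_names)))
  clade_names <- clade_names[seq_len(n_clades)]
  species_per_clade <- rep_len(as.integer(species_per_clade), n_clades)
  if (is.null(intron_rich_clades))
    intron_rich_clades <- clade_names[seq(max(1L, n_clades - 1L), n_clades)]
  cfg <- structure(list(
    n_clades = as.integer(n_clades),
    species_per_clade = species_per_clade,
    clade_names = clade_names,
    families = families,
    paralogs_per_species_family = as.integer(paralogs_per_species_family),
    protein_length = as.integer(protein_length),
    n_sites_per_clade_family = as.integer(n_sites_per_clade_family),
    cross_clade_shared_sites = as.integer(cross_clade_shared_sites),
    site_occupancy = site_occupancy,
    minor_occupancy = minor_occupancy,
    private_site_rate = private_site_rate,
    intron_rich_clades = intron_rich_clades,
    intron_length_meanlog = intron_length_meanlog,
    intron_length_sdlog = intron_length_sdlog,
    intron_length_range = as.integer(intron_length_range),
    protein_divergence_within = protein_divergence_within,
    protein_divergence_between = protein_divergence_between,
    intron_divergence = intron_divergence,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Beyond range checks, verifies that the planted dominant site is expected
#' to satisfy the hot-spot rule: with occupancy `p` at the dominant site,
#' `q` at each of the `k - 1` minor sites and private rate `r`, the expected
#' fraction of a clade's introns at the dominant site is
#' `p / (p + (k-1) q + r)`; a configuration for which this falls below the
#' hot-spot fraction cannot plant a hot spot and is rejected.
#'
#' @param cfg A `sim_config`.
#' @param hotspot_num,hotspot_den Hot-spot fraction used for the
#'   achievability check (default 1/3).
#' @return Invisibly `TRUE`; hard error on an invalid configuration.
#' @export
validate_sim_config <- function(cfg, hotspot_num = 1L, hotspot_den = 3L) {
  probs <- c(cfg$site_occupancy, cfg$minor_occupancy, cfg$private_site_rate,
             cfg$protein_divergence_within, cfg$protein_divergence_between,
             cfg$intron_divergence)
  stopifnot(all(probs >= 0 & probs <= 1), cfg$n_clades >= 2L,
            length(cfg$families) >= 1L,
            cfg$paralogs_per_species_family[1L] >= 1L,
            diff(cfg$paralogs_per_species_family) >= 0L,
            cfg$protein_length[1L] >= 10L, diff(cfg$protein_length) >= 0L,
            cfg$n_sites_per_clade_family >= 0L,
            cfg$cross_clade_shared_sites <= cfg$n_sites_per_clade_family,
            cfg$intron_length_range[1L] >= 4L,
            diff(cfg$intron_length_range) >= 0L,
            all(cfg$intron_rich_clades %in% cfg$clade_names),
            all(cfg$species_per_clade >= 1L))
  k <- cfg$n_sites_per_clade_family
  if (k >= 1L && length(cfg$intron_rich_clades) > 0L) {
    p <- cfg$site_occupancy
    if (p <= 0)
      stop("site_occupancy is 0: no planted intron can exist, ",
           "so no planted hot spot is possible")
    expected_share <- p / (p + (k - 1L) * cfg$minor_occupancy +
                             cfg$private_site_rate)
    if (hotspot_den * expected_share < hotspot_num)
      stop("configuration cannot plant a hot spot: expected dominant-site ",
           "share ", signif(expected_share, 3), " is below ",
           hotspot_num, "/", hotspot_den,
           " (occupancy too low relative to minor/private introns)")
  }
  invisible(TRUE)
}

#' Mutate a sequence by i.i.d. per-position substitution
#'
#' Each position independently mutates with the given probability to a
#' uniformly chosen *different* symbol of the alphabet. Length is preserved.
#' Uses the current RNG state.
#'
#' @param seq Character string over `alphabet`.
#' @param p Per-position substitution probability in \[0, 1\].
#' @param alphabet Character vector of symbols (default the 4 DNA bases).
#' @return Mutated string.
#' @export
mutate_sequence <- function(seq, p, alphabet = c("A", "C", "G", "T")) {
  stopifnot(p >= 0, p <= 1)
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(runif(length(ch)) < p)
  for (i in hit) {
    alt <- alphabet[alphabet != ch[i]]
    ch[i] <- alt[sample.int(length(alt), 1L)]
  }
  paste(ch, collapse = "")
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

#' @noRd
random_protein <- function(len) {
  paste(AA20[sample.int(20L, len, replace = TRUE)], collapse = "")
}

#' @noRd
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Reverse-translate a protein with uniformly random synonymous codons
#' @noRd
reverse_translate <- function(protein, codons) {
  aa <- strsplit(protein, "")[[1L]]
  cod <- vapply(aa, function(a) {
    cs <- codons[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1))
  stop_codon <- c("TAA", "TAG", "TGA")[sample.int(3L, 1L)]
  paste(c(cod, stop_codon), collapse = "")
}

#' @noRd
random_dna <- function(len) {
  paste(c("A", "C", "G", "T")[sample.int(4L, len, replace = TRUE)],
        collapse = "")
}

#' @noRd
random_intron_seq <- function(len) {
  paste0("GT", random_dna(len - 4L), "AG")
}

#' Mutate an intron keeping the GT..AG boundary dinucleotides intact
#' @noRd
mutate_intron <- function(seq, p) {
  n <- nchar(seq)
  if (n <= 4L || p == 0) return(seq)
  paste0(substr(seq, 1L, 2L),
         mutate_sequence(substr(seq, 3L, n - 2L), p),
         substr(seq, n - 1L, n))
}

#' @noRd
draw_intron_length <- function(cfg) {
  len <- round(stats::rlnorm(1L, cfg$intron_length_meanlog,
                             cfg$intron_length_sdlog))
  as.integer(min(max(len, cfg$intron_length_range[1L]),
                 cfg$intron_length_range[2L]))
}
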