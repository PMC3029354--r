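#' Analysis thresholds
#'
#' @param hotspot_num,hotspot_den Numerator and denominator of the hot-spot
#'   fraction as exact integers (default 1/3: a site is a hot spot when it
#'   carries at least one third of a clade's introns in the family).
#' @param n_shuffles Shuffled replicates per intron pair (default 200).
#' @param evalue_cutoff Similarity selection cutoff on the extreme-value
#'   E-value (default 0.02).
#' @return A `thresholds` list.
#' @export
thresholds <- function(hotspot_num = 1L, hotspot_den = 3L,
                       n_shuffles = 200L, evalue_cutoff = 0.02) {
  stopifnot(hotspot_num >= 1L, hotspot_den >= hotspot_num,
            n_shuffles >= 1L, evalue_cutoff > 0)
  structure(list(hotspot_num = as.integer(hotspot_num),
                 hotspot_den = as.integer(hotspot_den),
                 n_shuffles = as.integer(n_shuffles),
                 evalue_cutoff = evalue_cutoff),
            class = "thresholds")
}

#' Detect clade-level intron hot spots
#'
#' A site is a hot spot of a clade when the introns of that clade at the
#' site are at least the threshold fraction of all that clade's introns in
#' the gene family. The comparison is exact integer arithmetic
#' (`den * n_at_site >= num * n_total`), so the boundary case (e.g. exactly
#' one third) counts.
#'
#' @param sm A `site_matrix`.
#' @param clade Clade label (must occur in the matrix's clade assignments).
#' @param t A [thresholds()] object.
#' @return Data frame: `clade`, `family`, `site_id`, `column`, `phase`,
#'   `n_at_site`, `n_clade_family_introns`, `fraction`, in ascending column
#'   order. Zero rows when the clade has no introns in the family.
#' @export
detect_hotspots <- function(sm, clade, t = thresholds()) {
  stopifnot(inherits(sm, "site_matrix"))
  known <- unique(c(sm$genes$clade, sm$cells$clade))
  if (!clade %in% known)
    stop("unknown clade '", clade, "' for family ", sm$family)
  cc <- sm$cells[!is.na(sm$cells$clade) & sm$cells$clade == clade, ,
                 drop = FALSE]
  total <- nrow(cc)
  empty <- data.frame(clade = character(0), family = character(0),
                      site_id = character(0), column = integer(0),
                      phase = integer(0), n_at_site = integer(0),
                      n_clade_family_introns = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE)
  if (total == 0L) return(empty)
  cnt <- table(cc$site_id)
  hit <- names(cnt)[t$hotspot_den * as.integer(cnt) >= t$hotspot_num * total]
  if (length(hit) == 0L) return(empty)
  s <- sm$sites[match(hit, sm$sites$site_id), , drop = FALSE]
  out <- data.frame(clade = clade, family = sm$family, site_id = s$site_id,
                    column = s$column, phase = s$phase,
                    n_at_site = as.integer(cnt[hit]),
                    n_clade_family_introns = total,
                    fraction = as.integer(cnt[hit]) / total,
                    stringsAsFactors = FALSE)
  out <- out[order(out$column, out$phase, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hot spots shared between two clades
#'
#' Intersection of two hot-spot sets from the same family, by site identity.
#'
#' @param a,b Hot-spot data frames from [detect_hotspots()] on the same
#'   family's site matrix.
#' @return Data frame of shared sites (`family`, `site_id`, `column`,
#'   `phase`) in ascending column order.
#' @export
shared_hotspots <- function(a, b) {
  if (nrow(a) > 0L && nrow(b) > 0L && !identical(a$family[1L], b$family[1L]))
    stop("hot-spot lists come from different families: ",
         a$family[1L], " vs ", b$family[1L])
  shared <- intersect(a$site_id, b$site_id)
  src <- rbind(a, b)
  s <- unique(src[src$site_id %in% shared,
                  c("family", "site_id", "column", "phase")])
  s <- s[order(s$column, s$phase, na.last = TRUE), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Flag hot spots occupied by any intron of another clade
#'
#' For each hot spot, reports whether the other clade has at least one
#' intron at that site (it need not be a hot spot there).
#'
#' @param hotspots Hot-spot data frame from [detect_hotspots()].
#' @param sm The same family's `site_matrix`.
#' @param other_clade Clade whose occupancy is checked.
#' @return The hot-spot data frame with a logical column
#'   `shared_with_<other_clade>`.
#' @export
hotspot_vs_other_clade <- function(hotspots, sm, other_clade) {
  stopifnot(inherits(sm, "site_matrix"))
  if (nrow(hotspots) > 0L && !all(hotspots$family == sm$family))
    stop("hot spots and site matrix are from different families")
  occ <- sm$cells[!is.na(sm$cells$clade) & sm$cells$clade == other_clade,
                  "site_id"]
  hotspots[[paste0("shared_with_", other_clade)]] <-
    hotspots$site_id %in% occ
  hotspots
}

#' Hot-spot report across all clades and families
#'
#' Runs [detect_hotspots()] for every clade in every supplied site matrix
#' and annotates each hot spot with per-other-clade occupancy flags.
#'
#' @param matrices Named list of `site_matrix` objects (one per family).
#' @param clades Data frame `species`, `clade`.
#' @param t A [thresholds()] object.
#' @return One combined data frame.
#' @export
hotspot_report <- function(matrices, clades, t = thresholds()) {
  clade_levels <- sort(unique(as.character(clades$clade)))
  out <- NULL
  for (sm in matrices) {
    for (cl in clade_levels) {
      hs <- detect_hotspots(sm, cl, t)
      if (nrow(hs) == 0L) next
      for (other in clade_levels) {
        if (other == cl) {
          hs[[paste0("shared_with_", other)]] <- NA
        } else {
          hs <- hotspot_vs_other_clade(hs, sm, other)
        }
      }
      out <- if (is.null(out)) hs else rbind(out, hs)
    }
  }
  if (is.null(out)) {
    out <- data.frame(clade = character(0), family = character(0),
                      site_id = character(0), column = integer(0),
                      phase = integer(0), n_at_site = integer(0),
                      n_clade_family_introns = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
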