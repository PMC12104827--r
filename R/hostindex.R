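# Host-usage-weighted mutagenicity index per butterfly species.

#' Host-use weights from butterfly host-plant lists
#'
#' Converts a table of recorded larval host taxa (one row per butterfly
#' species x host taxon, with the host's plant family) into per-family use
#' weights: the fraction of a butterfly's listed host taxa that fall in
#' each family.  Hosts whose family cannot be resolved (empty or `NA`
#' family) are dropped, listed in an exclusions report attached as the
#' `"exclusions"` attribute, and the remaining weights renormalized to
#' sum to one.
#'
#' @param host_records data frame with columns `butterfly_species`,
#'   `host_taxon`, `plant_family`.
#' @return data frame with columns `butterfly_species`, `plant_family`,
#'   `weight`; attribute `"exclusions"` holds the dropped rows.
#' @export
weights_from_host_lists <- function(host_records) {
  stopifnot(is.data.frame(host_records))
  need <- c("butterfly_species", "host_taxon", "plant_family")
  missing_cols <- setdiff(need, names(host_records))
  if (length(missing_cols) > 0) {
    stop("host record table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fam <- as.character(host_records$plant_family)
  bad <- is.na(fam) | !nzchar(trimws(fam))
  exclusions <- host_records[bad, , drop = FALSE]
  keep <- host_records[!bad, , drop = FALSE]
  if (nrow(keep) == 0) {
    stop("no host records with a resolvable plant family", call. = FALSE)
  }
  counts <- stats::aggregate(
    list(n = rep(1L, nrow(keep))),
    by = list(butterfly_species = keep$butterfly_species,
              plant_family = keep$plant_family),
    FUN = sum)
  totals <- tapply(counts$n, counts$butterfly_species, sum)
  counts$weight <- counts$n / as.numeric(totals[counts$butterfly_species])
  out <- counts[order(counts$butterfly_species, counts$plant_family),
                c("butterfly_species", "plant_family", "weight")]
  rownames(out) <- NULL
  attr(out, "exclusions") <- exclusions
  out
}

#' Species mutagenicity index
#'
#' The evolutionary-history-with-mutagens index of a butterfly species:
#' the host-use-weighted average of plant-family mutagenicity scores,
#' e.g. 0.8 x score(Brassicaceae) + 0.2 x score(Capparaceae) for a species
#' with 80% of hosts in Brassicaceae.  Being a convex combination, the
#' index always lies within the range of the contributing family scores.
#'
#' @param host_use data frame of host-use weights
#'   (`butterfly_species`, `plant_family`, `weight`); per species the
#'   weights must be nonnegative and sum to 1 within 1e-9.
#' @param scores family score table from [family_scores()].
#' @return data frame with columns `butterfly_species`, `index`,
#'   `n_families`, `any_fallback`.
#' @export
species_mutagenicity_index <- function(host_use, scores) {
  stopifnot(is.data.frame(host_use), is.data.frame(scores))
  if (any(host_use$weight < 0)) {
    stop("negative host-use weight", call. = FALSE)
  }
  sums <- tapply(host_use$weight, host_use$butterfly_species, sum)
  off <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(off) > 0) {
    stop("host-use weights do not sum to 1 for: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  idx <- match(host_use$plant_family, scores$family)
  unmatched <- unique(host_use$plant_family[is.na(idx)])
  if (length(unmatched) > 0) {
    stop("no mutagenicity score for host plant family(ies): ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  sc <- scores$score[idx]
  lev <- scores$level[idx]
  if (anyNA(sc)) {
    stop("missing (flagged) mutagenicity score for family(ies): ",
         paste(unique(host_use$plant_family[is.na(sc)]), collapse = ", "),
         call. = FALSE)
  }
  sp <- unique(host_use$butterfly_species)
  out <- data.frame(
    butterfly_species = sp,
    index = vapply(sp, function(s) {
      rows <- host_use$butterfly_species == s
      sum(host_use$weight[rows] * sc[rows])
    }, numeric(1)),
    n_families = vapply(sp, function(s) {
      length(unique(host_use$plant_family[host_use$butterfly_species == s]))
    }, integer(1)),
    any_fallback = vapply(sp, function(s) {
      any(lev[host_use$butterfly_species == s] == "order_fallback")
    }, logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$butterfly_species), , drop = FALSE]
}
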