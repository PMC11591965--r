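#' Map alignment columns to structure residues
#'
#' The sequence row of the structure's taxon defines the correspondence:
#' its k-th non-gap column maps to the k-th residue of the structure. Gap
#' columns of that row are unmapped.
#'
#' @param alignment character matrix (taxa x sites) with rownames.
#' @param structure_taxon name of the alignment row describing the
#'   structure's sequence.
#' @param residue_ids residue identifiers of the structure, in order
#'   (vector, or the `residue_ids` data frame of a [trajectory()]).
#' @return named vector: names are mapped alignment column indices, values
#'   the corresponding residue identifiers.
#' @export
map_alignment_to_structure <- function(alignment, structure_taxon,
                                       residue_ids) {
  if (!structure_taxon %in% rownames(alignment))
    stop_nd("taxon '", structure_taxon, "' not found in the alignment")
  if (is.data.frame(residue_ids)) residue_ids <- residue_ids$resno
  row <- alignment[structure_taxon, ]
  cols <- which(!(row %in% GAP_CHARS))
  if (length(cols) != length(residue_ids))
    stop_nd(sprintf(
      "ungapped length of '%s' (%d) does not match residue count (%d)",
      structure_taxon, length(cols), length(residue_ids)))
  setNames(residue_ids, cols)
}

#' Min-max normalization to \[0, 1\]
#'
#' `(x - min) / (max - min)`; invariant under affine transformations of
#' the input.
#'
#' @param values numeric vector with at least two distinct values.
#' @return vector rescaled so the extremes are exactly 0 and 1.
#' @export
normalize_scores <- function(values) {
  rng <- range(values, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop_nd("cannot normalize a constant score vector")
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Correlation between divergence and centrality scores
#'
#' @param q_norm,centrality_norm paired per-residue scores (n >= 3).
#' @return list with `pearson`, `spearman` and `n`.
#' @export
correlate_scores <- function(q_norm, centrality_norm) {
  if (length(q_norm) != length(centrality_norm))
    stop_nd("score vectors must be paired")
  ok <- is.finite(q_norm) & is.finite(centrality_norm)
  if (sum(ok) < 3L) stop_nd("need at least 3 paired residues")
  if (sd(q_norm[ok]) == 0 || sd(centrality_norm[ok]) == 0)
    stop_nd("zero variance in a score vector")
  list(pearson = cor(q_norm[ok], centrality_norm[ok], method = "pearson"),
       spearman = cor(q_norm[ok], centrality_norm[ok], method = "spearman"),
       n = sum(ok))
}

#' Integration table: divergence posterior vs network centrality
#'
#' Joins the per-site divergence posterior (via the site-residue map) with
#' the three per-residue centrality measures, min-max normalizes every
#' score, and flags hotspots per measure ([select_hotspots()] rule).
#' Residues without a mapped alignment column get `NA` divergence scores
#' and are excluded from correlations and hotspot calls.
#'
#' @param posterior per-site posterior probabilities (alignment columns).
#' @param centrality a [centrality_table()] whose rows follow the
#'   structure's residue order.
#' @param site_map a [map_alignment_to_structure()] result; by default the
#'   identity map (site k = residue k).
#' @param residue_ids residue identifiers matching `centrality` rows;
#'   defaults to `centrality$node`.
#' @param q_min,c_min,band hotspot thresholds, see [select_hotspots()].
#' @return object of class `integration_table`: a data frame with raw and
#'   normalized scores and `hotspot_*` flags, plus a `correlations`
#'   attribute (list per measure).
#' @export
integration_table <- function(posterior, centrality, site_map = NULL,
                              residue_ids = NULL,
                              q_min = 0.5, c_min = 0.5, band = 0.15) {
  stopifnot(inherits(centrality, "centrality_table"))
  residue_ids <- residue_ids %||% centrality$node
  n_res <- nrow(centrality)
  if (is.null(site_map))
    site_map <- setNames(residue_ids, seq_len(n_res))
  q_raw <- rep(NA_real_, n_res)
  ridx <- match(as.character(site_map), as.character(residue_ids))
  sidx <- as.integer(names(site_map))
  bad <- is.na(ridx) | sidx > length(posterior)
  q_raw[ridx[!bad]] <- posterior[sidx[!bad]]
  out <- data.frame(residue = residue_ids,
                    q_raw = q_raw,
                    betweenness = centrality$betweenness,
                    closeness = centrality$closeness,
                    degree = centrality$degree,
                    stringsAsFactors = FALSE)
  mapped <- !is.na(q_raw)
  out$q_norm <- NA_real_
  out$q_norm[mapped] <- normalize_scores(q_raw[mapped])
  cors <- list()
  for (m in c("betweenness", "closeness", "degree")) {
    out[[paste0(m, "_norm")]] <- normalize_scores(out[[m]])
    cors[[m]] <- correlate_scores(out$q_norm[mapped],
                                  out[[paste0(m, "_norm")]][mapped])
    out[[paste0("hotspot_", m)]] <- mapped &
      !is.na(out$q_norm) & out$q_norm >= q_min &
      out[[paste0(m, "_norm")]] >= c_min &
      abs(out$q_norm - out[[paste0(m, "_norm")]]) <= band
  }
  attr(out, "correlations") <- cors
  attr(out, "thresholds") <- c(q_min = q_min, c_min = c_min, band = band)
  class(out) <- c("integration_table", "data.frame")
  out
}

#' @export
print.integration_table <- function(x, ...) {
  cors <- attr(x, "correlations")
  cat(sprintf("<integration_table> %d residues (%d mapped)\n",
              nrow(x), sum(!is.na(x$q_raw))))
  for (m in names(cors))
    cat(sprintf("  q vs %-11s pearson %+.3f  spearman %+.3f  (hotspots: %d)\n",
                m, cors[[m]]$pearson, cors[[m]]$spearman,
                sum(x[[paste0("hotspot_", m)]])))
  invisible(x)
}

#' Select hotspot residues
#'
#' A residue is a hotspot for a centrality measure when its normalized
#' divergence score and normalized centrality are both high *and* close to
#' each other — the "diagonal" of a divergence-vs-centrality scatter:
#' `q_norm >= q_min`, `c_norm >= c_min`, `|q_norm - c_norm| <= band`.
#'
#' @param table an [integration_table()].
#' @param q_min,c_min minimum normalized scores (defaults 0.5).
#' @param band maximum |q_norm - c_norm| (default 0.15).
#' @return list of residue vectors, one per centrality measure.
#' @export
select_hotspots <- function(table, q_min = 0.5, c_min = 0.5, band = 0.15) {
  stopifnot(inherits(table, "integration_table"))
  check_number(q_min, "q_min", lower = 0, upper = 1)
  check_number(c_min, "c_min", lower = 0, upper = 1)
  check_number(band, "band", lower = 0)
  out <- list()
  for (m in c("betweenness", "closeness", "degree")) {
    cn <- table[[paste0(m, "_norm")]]
    sel <- !is.na(table$q_norm) & table$q_norm >= q_min & cn >= c_min &
      abs(table$q_norm - cn) <= band
    out[[m]] <- table$residue[sel]
  }
  out
}
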