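# Compositional transforms and similarity statistics used to characterize
# observed microbiomes: fourth-root variance stabilization, Bray-Curtis
# dissimilarity, and SIMPER decomposition of within-/between-group
# (dis)similarity into per-taxon contributions.

#' Fourth-root transform
#'
#' Elementwise `x^(1/4)`, the variance-stabilizing transform applied to
#' relative abundances before similarity and regression analyses.  Monotone;
#' maps 0 to 0.
#'
#' @param x non-negative numeric vector/matrix.
#' @return transformed values, same shape.
#' @export
fourth_root <- function(x) {
  if (!is.numeric(x) || any(x < 0, na.rm = TRUE))
    stop_("fourth_root requires non-negative numeric input")
  x^0.25
}

#' Bray-Curtis dissimilarity
#'
#' `sum(|a - b|) / sum(a + b)` between two equal-length non-negative
#' abundance vectors; 0 for identical vectors, 1 for disjoint supports.
#'
#' @param a,b non-negative numeric vectors of equal length, not both all
#'   zero.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  check_numeric_vec(a, "a", nonneg = TRUE)
  check_numeric_vec(b, "b", nonneg = TRUE)
  if (length(a) != length(b))
    stop_("vectors differ in length (%d vs %d)", length(a), length(b))
  tot <- sum(a + b)
  if (tot == 0) stop_("both vectors are all-zero; Bray-Curtis undefined")
  sum(abs(a - b)) / tot
}

# per-taxon Bray-Curtis decomposition for one sample pair:
# dissim contribution of taxon t = |a_t - b_t| / sum(a + b)        (sums to BC)
# similarity contribution       = 2 min(a_t, b_t) / sum(a + b)     (sums to 1-BC)
.bc_parts <- function(a, b) {
  tot <- sum(a + b)
  list(diss = abs(a - b) / tot, sim = 2 * pmin(a, b) / tot)
}

#' SIMPER: similarity percentages
#'
#' Decomposes average Bray-Curtis (dis)similarity into per-taxon
#' contributions, PRIMER-style: for each group, the within-group average
#' similarity `100 * (1 - mean pairwise dissimilarity)` with per-taxon
#' similarity contributions; across the two groups, the average
#' dissimilarity with per-taxon dissimilarity contributions.  Contributions
#' sum exactly to the reported averages; taxa are ranked by contribution and
#' flagged up to a cumulative cutoff (default 90%) below which the remainder
#' are considered low contributors.
#'
#' Supply the table already transformed (conventionally with
#' [fourth_root()]); no transform is applied here.
#'
#' @param table sample x taxon abundance matrix (transformed).
#' @param groups group label per sample (exactly two distinct values for the
#'   between-group analysis; a group needs >= 2 samples for its within-group
#'   similarity).
#' @param cutoff cumulative-contribution cutoff, percent.
#' @return object of class `sml_simper`: list with `within` (named average
#'   similarity % per group), `between` (average dissimilarity %),
#'   `contrib` (between-group data.frame `taxon`, `mean_contrib_pct`,
#'   `sd_contrib`, `contrib_share_pct`, `cum_contrib_share_pct`,
#'   `below_cutoff`), and `within_contrib` (same per group, similarity
#'   contributions).
#' @export
simper <- function(table, groups, cutoff = 90) {
  m <- as.matrix(table)
  groups <- as.character(groups)
  if (length(groups) != nrow(m))
    stop_("need one group label per sample (%d labels, %d samples)",
          length(groups), nrow(m))
  lev <- unique(groups)
  if (is.null(colnames(m))) colnames(m) <- paste0("taxon", seq_len(ncol(m)))

  contrib_table <- function(mat, share_of) {
    mean_c <- 100 * colMeans(mat)
    sd_c <- 100 * apply(mat, 2L, stats::sd)
    ord <- order(mean_c, decreasing = TRUE)
    share <- 100 * mean_c[ord] / share_of
    cum <- cumsum(share)
    data.frame(taxon = colnames(m)[ord],
               mean_contrib_pct = unname(mean_c[ord]),
               sd_contrib = unname(sd_c[ord]),
               contrib_share_pct = unname(share),
               cum_contrib_share_pct = unname(cum),
               below_cutoff = unname(c(FALSE, utils::head(cum, -1L) >= cutoff)),
               stringsAsFactors = FALSE, row.names = NULL)
  }

  within <- stats::setNames(rep(NA_real_, length(lev)), lev)
  within_contrib <- stats::setNames(vector("list", length(lev)), lev)
  for (g in lev) {
    idx <- which(groups == g)
    if (length(idx) < 2L) next
    pairs <- utils::combn(idx, 2L)
    simc <- t(apply(pairs, 2L, function(pr)
      .bc_parts(m[pr[1L], ], m[pr[2L], ])$sim))
    within[g] <- 100 * mean(rowSums(simc))
    within_contrib[[g]] <- contrib_table(simc, within[g])
  }

  between <- NA_real_; contrib <- NULL
  if (length(lev) == 2L) {
    ia <- which(groups == lev[1L]); ib <- which(groups == lev[2L])
    dissc <- do.call(rbind, lapply(ia, function(i)
      t(vapply(ib, function(j) .bc_parts(m[i, ], m[j, ])$diss,
               numeric(ncol(m))))))
    between <- 100 * mean(rowSums(dissc))
    contrib <- contrib_table(dissc, between)
  }

  structure(list(within = within, between = between, contrib = contrib,
                 within_contrib = within_contrib, groups = lev,
                 cutoff = cutoff),
            class = "sml_simper")
}

#' @export
print.sml_simper <- function(x, ...) {
  cat("<sml_simper>\n")
  for (g in names(x$within))
    cat(sprintf("  group %s, average similarity: %.2f%%\n", g, x$within[g]))
  if (!is.na(x$between))
    cat(sprintf("  groups %s & %s, average dissimilarity: %.2f%%\n",
                x$groups[1L], x$groups[2L], x$between))
  invisible(x)
}

#' @rdname simper
#' @param x an `sml_simper` result.
#' @param path output CSV path (`taxon,mean_contrib_pct,cum_contrib_pct,group_context`).
#' @export
write_simper <- function(x, path) {
  if (!inherits(x, "sml_simper")) stop_("`x` must be an sml_simper result")
  rows <- list()
  for (g in names(x$within_contrib)) {
    wc <- x$within_contrib[[g]]
    if (is.null(wc)) next
    rows[[length(rows) + 1L]] <- data.frame(
      taxon = wc$taxon, mean_contrib_pct = wc$mean_contrib_pct,
      cum_contrib_pct = wc$cum_contrib_share_pct,
      group_context = paste0("within:", g), stringsAsFactors = FALSE)
  }
  if (!is.null(x$contrib))
    rows[[length(rows) + 1L]] <- data.frame(
      taxon = x$contrib$taxon, mean_contrib_pct = x$contrib$mean_contrib_pct,
      cum_contrib_pct = x$contrib$cum_contrib_share_pct,
      group_context = "between", stringsAsFactors = FALSE)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter taxa by mean relative abundance
#'
#' Retains a taxon when its mean relative abundance reaches `cutoff` percent
#' in at least one of the supplied per-zone tables (comparison is `>=`, so a
#' taxon sitting exactly on the cutoff is kept).  Taxon order of the first
#' table is preserved.
#'
#' @param tables named list of [abundance_table()]s sharing a taxon
#'   namespace (e.g., `list(inner = ..., outer = ...)`).
#' @param cutoff mean-abundance cutoff, percent (default 1).
#' @return character vector of retained taxon IDs.
#' @export
filter_classes <- function(tables, cutoff = 1) {
  if (!is.list(tables) || length(tables) < 1L)
    stop_("`tables` must be a non-empty list of abundance tables")
  taxa <- colnames(tables[[1L]])
  for (tb in tables[-1L]) {
    if (!setequal(colnames(tb), taxa))
      stop_("tables do not share a taxon namespace (difference: %s)",
            paste(union(setdiff(colnames(tb), taxa),
                        setdiff(taxa, colnames(tb))), collapse = ", "))
  }
  means <- vapply(tables, function(tb) colMeans(as.matrix(tb)[, taxa,
                                                              drop = FALSE]),
                  numeric(length(taxa)))
  keep <- apply(as.matrix(means) >= cutoff, 1L, any)
  taxa[keep]
}
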