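#' Contrast pyramids with and without a focal QTL
#'
#' Within one pyramid group, splits the lines by presence of the focal locus
#' and compares the two subgroups: mean per-line epistasis, mean trait value,
#' and a Welch two-sample t-test on the line-level epistasis estimates.
#' When both subgroups are non-empty the focal locus is additionally
#' attributed its own epistatic effect via [attribute_focal_epistasis()].
#'
#' @param panel a [genotype_panel()].
#' @param estimates per-line `epistasis_estimate` data frame from
#'   [estimate_epistasis()].
#' @param focal locus name.
#' @param groups pyramid group labels to contrast (default `"2QL"`,
#'   `"3QL"`, `"4QL"`).
#' @return data frame of class `focal_contrast`: per group the subgroup
#'   sizes, mean epistasis, mean trait value, Welch `t`/`df`/`p` (NA when a
#'   subgroup has fewer than 2 lines), `focal_attributed_i` and
#'   `without_per_qtl_i` (NA plus `flag` when a subgroup is empty).
#' @export
focal_contrast <- function(panel, estimates, focal,
                           groups = c("2QL", "3QL", "4QL")) {
  stopifnot(inherits(panel, "genotype_panel"))
  split_ <- split_by_focal_locus(panel, focal, groups)
  rows <- lapply(groups, function(g) {
    n_qtl <- as.integer(sub("QL", "", g))
    w_ids <- intersect(split_[[g]]$with, estimates$line_id)
    wo_ids <- intersect(split_[[g]]$without, estimates$line_id)
    iw <- estimates$i[match(w_ids, estimates$line_id)]
    iwo <- estimates$i[match(wo_ids, estimates$line_id)]
    serw <- estimates$Pn[match(w_ids, estimates$line_id)]
    serwo <- estimates$Pn[match(wo_ids, estimates$line_id)]
    tt <- if (length(iw) >= 2L && length(iwo) >= 2L)
      students_t(iw, iwo, var_equal = FALSE)
    else list(t = NA_real_, df = NA_real_, p = NA_real_)
    both <- length(iw) > 0L && length(iwo) > 0L
    data.frame(
      group = g, focal = focal,
      with_n = length(iw), without_n = length(iwo),
      with_mean_i = if (length(iw)) mean(iw) else NA_real_,
      without_mean_i = if (length(iwo)) mean(iwo) else NA_real_,
      with_mean_ser = if (length(serw)) mean(serw) else NA_real_,
      without_mean_ser = if (length(serwo)) mean(serwo) else NA_real_,
      t = tt$t, df = tt$df, p = tt$p,
      focal_attributed_i = if (both)
        attribute_focal_epistasis(mean(iw), mean(iwo), n_qtl) else NA_real_,
      without_per_qtl_i = if (length(iwo)) mean(iwo) / n_qtl else NA_real_,
      flag = if (both) "" else "empty subgroup: attribution skipped",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("focal_contrast", "data.frame")
  out
}

#' Focal contrast from pre-aggregated subgroup summaries
#'
#' Group-summary analogue of [focal_contrast()]: subgroup mean epistasis is
#' derived by linearity from the published subgroup trait means, the
#' genotype matrix and the known single-QTL effects. No significance test is
#' possible without line-level data (`t`, `df`, `p` are `NA`).
#'
#' @param panel a [genotype_panel()].
#' @param subgroup_summaries data frame with columns `group`, `subgroup`
#'   (`"with"`/`"without"`), `mean` (trait, raw %), `n` (line count,
#'   cross-checked against the panel).
#' @param effects named vector of single-QTL additive effects.
#' @param focal locus name.
#' @param P0 control mean (raw %).
#' @return `focal_contrast` data frame (see [focal_contrast()]).
#' @export
focal_contrast_from_summaries <- function(panel, subgroup_summaries, effects,
                                          focal, P0) {
  stopifnot(inherits(panel, "genotype_panel"))
  ss <- as.data.frame(subgroup_summaries)
  need <- c("group", "subgroup", "mean", "n")
  miss <- setdiff(need, names(ss))
  if (length(miss)) stop_("subgroup summaries missing column(s): ",
                          paste(miss, collapse = ", "))
  groups <- unique(ss$group)
  split_ <- split_by_focal_locus(panel, focal, groups)
  sum_a <- function(ids) mean(vapply(ids, function(id)
    sum(effects[colnames(panel$presence)[panel$presence[id, ]]]), 0))
  rows <- lapply(groups, function(g) {
    n_qtl <- as.integer(sub("QL", "", g))
    sub_i <- sub_ser <- c(with = NA_real_, without = NA_real_)
    sub_n <- c(with = length(split_[[g]]$with),
               without = length(split_[[g]]$without))
    for (tag in c("with", "without")) {
      r <- ss[ss$group == g & ss$subgroup == tag, ]
      if (nrow(r) == 0L) next
      ids <- split_[[g]][[tag]]
      if (length(ids) == 0L) next
      if (r$n[1L] != length(ids))
        stop_("subgroup size mismatch for ", g, "/", tag, ": summary says ",
              r$n[1L], ", panel has ", length(ids))
      sub_ser[tag] <- r$mean[1L]
      sub_i[tag] <- (r$mean[1L] - P0) - sum_a(ids)
    }
    both <- !anyNA(sub_i)
    data.frame(
      group = g, focal = focal,
      with_n = unname(sub_n["with"]), without_n = unname(sub_n["without"]),
      with_mean_i = unname(sub_i["with"]),
      without_mean_i = unname(sub_i["without"]),
      with_mean_ser = unname(sub_ser["with"]),
      without_mean_ser = unname(sub_ser["without"]),
      t = NA_real_, df = NA_real_, p = NA_real_,
      focal_attributed_i = if (both)
        attribute_focal_epistasis(sub_i[["with"]], sub_i[["without"]], n_qtl)
        else NA_real_,
      without_per_qtl_i = unname(sub_i["without"]) / n_qtl,
      flag = if (both) "" else "empty subgroup: attribution skipped",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("focal_contrast", "data.frame")
  out
}

#' Attribute an epistatic effect to a focal QTL
#'
#' Decomposes the mean epistasis of pyramids carrying the focal locus into
#' the focal locus's own contribution and that of the remaining `n - 1`
#' loci, using the focal-free subgroup's per-QTL epistasis as the stand-in
#' for the non-focal loci:
#' `focal_i = with_mean_i - (n - 1) * without_mean_i / n`.
#'
#' @param with_mean_i mean epistasis of lines carrying the focal locus.
#' @param without_mean_i mean epistasis of same-size lines lacking it.
#' @param n QTL count of the group (`>= 2`).
#' @return the focal locus's attributed epistatic effect (percentage
#'   points).
#' @export
attribute_focal_epistasis <- function(with_mean_i, without_mean_i, n) {
  if (any(n < 2)) stop_("attribution needs n >= 2")
  if (anyNA(c(with_mean_i, without_mean_i)))
    stop_("attribution needs both subgroup means")
  with_mean_i - (n - 1) * without_mean_i / n
}
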