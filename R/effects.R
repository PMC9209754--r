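#' Single-QTL additive effect
#'
#' The additive effect of a locus is the difference between the trait mean
#' of the single-segment substitution line (SSSL) carrying it and the mean
#' of the isogenic control, on whatever scale both summaries share.
#'
#' @param ssl_summary,control_summary one-row `trait_summary` data frames
#'   (see [summarize_trait()]); both must be on the same scale.
#' @return signed effect (SSSL mean minus control mean).
#' @export
additive_single <- function(ssl_summary, control_summary) {
  effect_diff(ssl_summary, control_summary)
}

#' Multi-QTL combination effect
#'
#' The combination effect of an n-QTL pyramid is the difference between the
#' pyramid's trait mean and the control mean (`Pn - P0`).
#'
#' @inheritParams additive_single
#' @param pyramid_summary one-row `trait_summary` for the pyramiding line or
#'   pyramid group.
#' @return signed effect (pyramid mean minus control mean).
#' @export
combination_effect <- function(pyramid_summary, control_summary) {
  effect_diff(pyramid_summary, control_summary)
}

#' @noRd
effect_diff <- function(a, b) {
  for (s in list(a, b))
    if (!all(c("mean", "scale") %in% names(s)) || nrow(as.data.frame(s)) != 1L)
      stop_("expected one-row trait summaries with `mean` and `scale`")
  if (a$scale != b$scale)
    stop_("scale mismatch: ", a$scale, " vs ", b$scale)
  as.numeric(a$mean) - as.numeric(b$mean)
}

#' Additive-by-additive epistasis, point formula
#'
#' `i = (Pn - P0) - sum(a)`: the deviation of a pyramid's combination effect
#' from the sum of its constituent single-QTL additive effects. Negative
#' values indicate less-than-additive (diminishing-returns) interaction.
#'
#' @param P0 control mean.
#' @param Pn pyramid mean.
#' @param a numeric vector of single-QTL additive effects (length `n >= 2`).
#' @return the epistasis estimate.
#' @export
epistasis_point <- function(P0, Pn, a) {
  if (length(a) < 2L) stop_("epistasis is undefined for fewer than 2 QTLs")
  (Pn - P0) - sum(a)
}

#' Estimate per-line epistasis with season-blocked significance tests
#'
#' For every pyramiding line (2 or more QTLs) in the panel, estimates the
#' additive-by-additive epistasis `i = (Pn - P0) - sum(a_i)` and tests
#' `H0: i = 0`.
#'
#' Seasons act as blocks: within each cropping season `s` the linear
#' combination `i_s = Pn_s + (n - 1) P0_s - sum_j SSSL_{j,s}` is formed from
#' the season means of the pyramid, the control and the contributing SSSLs
#' (algebraically identical to the defining formula when the additive
#' effects come from the same data), and a one-sample Student's t across
#' seasons (`df = seasons - 1`) tests the null. This blocking absorbs the
#' covariance induced by the shared control term without requiring
#' plant-level records. The test runs on the arcsine-square-root scale by
#' default, while the reported estimate and SE stay on the raw percentage
#' scale. A variance-propagation alternative treating line means as
#' independent (`se_method = "line_means"`, Welch--Satterthwaite df) is
#' available for data without common season blocks.
#'
#' @param panel a [genotype_panel()].
#' @param records phenotype records covering the pyramids, the control and
#'   the SSSLs named in `ssl_map`.
#' @param control control line id.
#' @param ssl_map named character vector mapping loci to the SSSL line ids
#'   that carry them; a name of the form `"locusA+locusB"` declares a
#'   two-locus segment measured only jointly (it contributes one joint
#'   additive effect and counts as 2 towards `n`). Default: every 1-QTL
#'   line in the panel stands for its locus.
#' @param single_effects optional named vector of externally known additive
#'   effects (same names as `ssl_map`); default: estimated from the SSSL and
#'   control records on the raw scale.
#' @param test_scale scale on which the t-test runs.
#' @param se_method `"season_blocks"` (default) or `"line_means"`.
#' @return data frame of class `epistasis_estimate`: `line_id`, `n`, `P0`,
#'   `Pn`, `combination_effect`, `sum_a`, `i`, `se_i`, `t`, `df`, `p`,
#'   `stars`.
#' @export
estimate_epistasis <- function(panel, records, control = "HJX74",
                               ssl_map = NULL, single_effects = NULL,
                               test_scale = c("arcsine_sqrt", "raw_percent"),
                               se_method = c("season_blocks", "line_means")) {
  test_scale <- match.arg(test_scale)
  se_method <- match.arg(se_method)
  stopifnot(inherits(panel, "genotype_panel"))
  records <- phenotype_records(records)
  if (!control %in% records$line_id)
    stop_("no phenotype records for control line ", control)
  if (is.null(ssl_map)) {
    one <- panel$lines$line_id[!panel$lines$is_control &
                                 panel$lines$qtl_count == 1L]
    loci1 <- vapply(one, function(id)
      colnames(panel$presence)[panel$presence[id, ]], "")
    ssl_map <- stats::setNames(one, loci1)
  }
  if (length(ssl_map) && is.null(names(ssl_map)))
    stop_("`ssl_map` must be named by locus")
  # season-level line means (replicates averaged within season)
  season_tab <- function(scale) {
    v <- if (scale == "arcsine_sqrt") arcsine_sqrt(records$ser) else records$ser
    stats::aggregate(list(value = v),
                     by = list(line_id = records$line_id,
                               season_id = records$season_id), FUN = mean)
  }
  raw_tab <- season_tab("raw_percent")
  tst_tab <- if (test_scale == "raw_percent") raw_tab
             else season_tab("arcsine_sqrt")
  line_season <- function(tab, id) {
    r <- tab[tab$line_id == id, ]
    stats::setNames(r$value, r$season_id)
  }
  sm_raw <- lapply(stats::setNames(nm = unique(records$line_id)),
                   line_season, tab = raw_tab)
  sm_tst <- lapply(stats::setNames(nm = unique(records$line_id)),
                   line_season, tab = tst_tab)
  P0_bar <- mean(sm_raw[[control]])
  if (is.null(single_effects)) {
    single_effects <- vapply(ssl_map, function(id) {
      if (!id %in% names(sm_raw))
        stop_("no phenotype records for SSSL ", id)
      mean(sm_raw[[id]]) - P0_bar
    }, 0)
    names(single_effects) <- names(ssl_map)
  }
  pyramids <- panel$lines$line_id[!panel$lines$is_control &
                                    panel$lines$qtl_count >= 2L]
  pyramids <- intersect(pyramids, names(sm_raw))
  rows <- lapply(pyramids, function(id) {
    loci <- colnames(panel$presence)[panel$presence[id, ]]
    entries <- cover_loci(loci, names(single_effects))
    n <- length(loci)
    Pn_bar <- mean(sm_raw[[id]])
    sum_a <- sum(single_effects[entries])
    i_hat <- (Pn_bar - P0_bar) - sum_a
    ssl_ids <- ssl_map[entries]
    need <- c(id, control, ssl_ids)
    seas <- Reduce(intersect, lapply(sm_raw[need], names))
    i_seasons <- function(sm) {
      vapply(seas, function(s) {
        sm[[id]][s] + (n - 1) * sm[[control]][s] -
          sum(vapply(ssl_ids, function(l) sm[[l]][s], 0))
      }, 0)
    }
    if (se_method == "season_blocks") {
      if (length(seas) < 2L)
        stop_("line ", id, ": fewer than 2 seasons shared with control/SSSLs")
      ir <- i_seasons(sm_raw)
      it <- i_seasons(sm_tst)
      se_i <- stats::sd(ir) / sqrt(length(ir))
      df <- length(it) - 1L
      if (stats::sd(it) == 0) {
        # degenerate (e.g. noise-free data): no sampling variability
        tt <- if (mean(it) == 0) 0 else sign(mean(it)) * Inf
        p <- if (tt == 0) 1 else 0
      } else {
        tt <- mean(it) / (stats::sd(it) / sqrt(length(it)))
        p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
      }
    } else {
      vars <- vapply(sm_raw[need], function(v)
        stats::var(v) / length(v), 0)
      w <- c(1, (n - 1), rep(-1, length(ssl_ids)))^2
      se_i <- sqrt(sum(w * vars))
      dfs <- vapply(sm_raw[need], function(v) length(v) - 1L, 1L)
      df <- se_i^4 / sum((w * vars)^2 / dfs)
      tt <- i_hat / se_i
      p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    }
    data.frame(line_id = id, n = n, P0 = P0_bar, Pn = Pn_bar,
               combination_effect = Pn_bar - P0_bar, sum_a = sum_a,
               i = i_hat, se_i = se_i, t = tt, df = df, p = p,
               stars = sig_stars(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("epistasis_estimate", "data.frame")
  out
}

# Cover a line's locus set with disjoint effect entries; joint entries are
# written "locusA+locusB". Errors name the first uncoverable locus.
#' @noRd
cover_loci <- function(loci, entry_names) {
  remaining <- loci
  used <- character()
  joint <- entry_names[grepl("+", entry_names, fixed = TRUE)]
  for (j in joint) {
    parts <- strsplit(j, "+", fixed = TRUE)[[1L]]
    if (all(parts %in% remaining)) {
      used <- c(used, j)
      remaining <- setdiff(remaining, parts)
    }
  }
  for (l in remaining) {
    if (!l %in% entry_names)
      stop_("no single-QTL additive effect available for locus ", l)
    used <- c(used, l)
  }
  used
}

#' Per-QTL epistatic effect
#'
#' Divides a pyramid's total epistasis evenly over its `n` QTLs.
#'
#' @param i epistasis estimate (percentage points).
#' @param n QTL count (`>= 2`).
#' @return `i / n`.
#' @export
per_qtl_epistasis <- function(i, n) {
  if (any(n < 2)) stop_("per-QTL epistasis needs n >= 2")
  i / n
}

#' Percentage of epistatic effect in the genetic effect per QTL
#'
#' Expresses the magnitude of the per-QTL epistatic effect relative to the
#' mean single-QTL additive effect: `100 * |per_qtl_i| / mean_single`.
#'
#' @param per_qtl_i per-QTL epistatic effect (percentage points).
#' @param mean_single_additive mean single-QTL additive effect (`> 0`).
#' @return percentage.
#' @export
epistasis_fraction <- function(per_qtl_i, mean_single_additive) {
  if (any(mean_single_additive <= 0))
    stop_("mean single-QTL additive effect must be positive")
  100 * abs(per_qtl_i) / mean_single_additive
}

#' Classify QTLs into effect levels
#'
#' Partitions single-QTL additive effects into `k` contiguous levels by
#' exact one-dimensional least-squares clustering (dynamic programming over
#' the sorted effects, minimising the total within-level sum of squares).
#' Ties between equally good partitions are broken towards the smaller
#' uppermost level. Levels are labelled in ascending order of their means
#' (`low`, `moderate`, `high` for `k = 3`).
#'
#' @param effects named numeric vector of additive effects.
#' @param k number of levels.
#' @return list of class `effect_classification`: `assignment` (data frame
#'   `locus`, `effect`, `level`), `level_means` (named, ascending),
#'   `within_ss`.
#' @export
classify_effect_levels <- function(effects, k = 3L) {
  if (length(effects) < k)
    stop_("cannot form ", k, " levels from ", length(effects), " effects")
  if (length(unique(effects)) < k)
    stop_("only ", length(unique(effects)), " distinct effect values; ",
          "use a smaller k")
  ord <- order(effects)
  x <- effects[ord]
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ss <- function(a, b) { # within-SS of x[a..b]
    s <- cs[b] - if (a > 1L) cs[a - 1L] else 0
    s2 <- cs2[b] - if (a > 1L) cs2[a - 1L] else 0
    s2 - s^2 / (b - a + 1L)
  }
  D <- matrix(Inf, k, n)      # D[j, b]: best SS for x[1..b] in j levels
  B <- matrix(NA_integer_, k, n)
  for (b in 1:n) D[1L, b] <- ss(1L, b)
  if (k > 1L) for (j in 2:k) for (b in j:n) {
    for (a in j:b) {  # level j = x[a..b]; prefer larger a on ties
      cand <- D[j - 1L, a - 1L] + ss(a, b)
      if (cand <= D[j, b] + 1e-12) { D[j, b] <- min(cand, D[j, b]); B[j, b] <- a }
    }
  }
  bounds <- integer(k + 1L); bounds[k + 1L] <- n
  b <- n
  for (j in k:2) { a <- B[j, b]; bounds[j] <- a - 1L; b <- a - 1L }
  bounds[1L] <- 0L
  level <- integer(n)
  for (j in 1:k) level[(bounds[j] + 1L):bounds[j + 1L]] <- j
  labels <- if (k == 3L) c("low", "moderate", "high") else paste0("level", 1:k)
  assignment <- data.frame(locus = names(x) %||% as.character(seq_len(n)),
                           effect = unname(x),
                           level = labels[level],
                           stringsAsFactors = FALSE)
  lm_ <- vapply(1:k, function(j) mean(x[level == j]), 0)
  names(lm_) <- labels
  structure(list(assignment = assignment, level_means = lm_,
                 within_ss = D[k, n]),
            class = "effect_classification")
}

#' @export
print.effect_classification <- function(x, ...) {
  cat("effect levels (ascending):\n")
  for (l in names(x$level_means)) {
    idx <- x$assignment$level == l
    cat(sprintf("  %-9s mean %5.1f  n=%d  [%s]\n", l, x$level_means[[l]],
                sum(idx), paste(x$assignment$locus[idx], collapse = ", ")))
  }
  invisible(x)
}

#' Aggregate single-QTL effects by donor species
#'
#' @param effects named numeric vector of single-QTL additive effects.
#' @param metadata data frame with `name` and `donor_species` covering every
#'   locus in `effects`.
#' @return data frame: `donor_species`, `n`, `mean`, `min`, `max`.
#' @export
aggregate_by_donor <- function(effects, metadata) {
  idx <- match(names(effects), metadata$name)
  if (anyNA(idx) || anyNA(metadata$donor_species[idx]))
    stop_("missing donor metadata for: ",
          paste(names(effects)[is.na(idx) |
                                 is.na(metadata$donor_species[idx])],
                collapse = ", "))
  donor <- metadata$donor_species[idx]
  out <- do.call(rbind, lapply(split(effects, donor), function(v)
    data.frame(n = length(v), mean = mean(v), min = min(v), max = max(v))))
  out$donor_species <- rownames(out)
  rownames(out) <- NULL
  out[, c("donor_species", "n", "mean", "min", "max")]
}

#' Group-level epistasis from pre-aggregated summaries
#'
#' When only published group means are available (no per-line records), the
#' group-average epistasis follows from linearity: the mean over the group's
#' lines of `(Pn - P0) - sum(a)` equals `(group mean - P0)` minus the
#' group-average additive-effect sum, which is computable from the genotype
#' matrix and the known single-QTL effects.
#'
#' @param panel a [genotype_panel()].
#' @param summaries `trait_summary` with one row per pyramid group
#'   (subjects `"2QL"` ... `"6QL"`; `"1QL"` rows contribute combination
#'   effects only) and one row for the control subject.
#' @param effects named vector of single-QTL additive effects covering every
#'   panel locus.
#' @param control_subject subject name of the control row.
#' @return data frame: `group`, `n_qtl`, `n_lines`, `Pn`,
#'   `combination_effect`, `mean_sum_a`, `i`, `per_qtl_i`,
#'   `epistasis_fraction` (the last three `NA` for 1-QTL groups).
#' @export
group_epistasis_from_summaries <- function(panel, summaries, effects,
                                           control_subject = "HJX74") {
  stopifnot(inherits(panel, "genotype_panel"))
  summaries <- as.data.frame(summaries)
  if (!control_subject %in% summaries$subject)
    stop_("control subject ", control_subject, " not in summaries")
  P0 <- summaries$mean[summaries$subject == control_subject][1L]
  miss <- setdiff(colnames(panel$presence), names(effects))
  if (length(miss)) stop_("no additive effect for locus: ",
                          paste(miss, collapse = ", "))
  a_mean <- mean(effects[colnames(panel$presence)])
  by_grp <- lines_by_group(panel)
  grps <- intersect(summaries$subject, names(by_grp))
  if (!length(grps)) stop_("no pyramid-group subjects found in summaries")
  rows <- lapply(grps, function(g) {
    ids <- by_grp[[g]]
    n_qtl <- as.integer(sub("QL", "", g))
    Pn <- summaries$mean[summaries$subject == g][1L]
    sum_a <- mean(vapply(ids, function(id)
      sum(effects[colnames(panel$presence)[panel$presence[id, ]]]), 0))
    comb <- Pn - P0
    if (n_qtl >= 2L) {
      i <- comb - sum_a
      pq <- per_qtl_epistasis(i, n_qtl)
      fr <- epistasis_fraction(pq, a_mean)
    } else {
      i <- pq <- fr <- NA_real_
    }
    data.frame(group = g, n_qtl = n_qtl, n_lines = length(ids), Pn = Pn,
               combination_effect = comb, mean_sum_a = sum_a, i = i,
               per_qtl_i = pq, epistasis_fraction = fr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$n_qtl), ]
  rownames(out) <- NULL
  out
}
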